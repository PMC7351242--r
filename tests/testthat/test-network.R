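test_that("random networks satisfy the structural invariants over many draws", {
  set.seed(101)
  sizes <- list(c(6L, 15L), c(16L, 40L), c(32L, 80L))
  n_draws <- 4000L
  n_pos <- 0L
  n_edges_total <- 0L
  violations <- 0L
  for (d in seq_len(n_draws)) {
    sz <- sizes[[(d %% length(sizes)) + 1L]]
    net <- random_grn(sz[1L], sz[2L])
    J <- net$J
    if (sum(J != 0L) != sz[2L] || any(diag(J) != 0L) ||
        any(J != 0L & t(J) != 0L))
      violations <- violations + 1L
    n_pos <- n_pos + sum(J == 1L)
    n_edges_total <- n_edges_total + sz[2L]
  }
  expect_identical(violations, 0L)
  # equiprobable signs: binomial 3 sigma around 1/2
  p_hat <- n_pos / n_edges_total
  expect_lt(abs(p_hat - 0.5), 3 * sqrt(0.25 / n_edges_total))
})

test_that("network construction rejects invalid matrices and sizes", {
  expect_error(random_grn(3, 4), "between 1 and 3")
  expect_error(random_grn(1, 1), "at least 2")
  expect_error(grn(matrix(c(1L, 0L, 0L, 0L), 2, 2)), "self-regulation")
  expect_error(grn(matrix(c(0L, 1L, 1L, 0L), 2, 2)), "mutual regulation")
  expect_error(grn(matrix(c(0L, 2L, 0L, 0L), 2, 2)), "must be -1, 0 or 1")
  expect_error(grn(matrix(0L, 2, 3)), "square")
  expect_error(grn(matrix(0L, 2, 2), output = 1L), "differ from the input")
})

test_that("structural_check reports reachability in both directions", {
  ok <- structural_check(chain2(), 2L)
  expect_true(ok$input_reaches_all)
  expect_true(all(ok$nodes_reaching))
  expect_identical(ok$violation, "none")

  # star out of the input only: gene 3 cannot reach candidate output 2
  J <- matrix(0L, 3, 3)
  J[2, 1] <- 1L
  J[3, 1] <- 1L
  star <- grn(J)
  chk <- structural_check(star, 2L)
  expect_true(chk$input_reaches_all)
  expect_identical(chk$nodes_reaching, c(TRUE, TRUE, FALSE))
  expect_identical(chk$violation, "output_unreachable")

  # input with no out-edges
  J2 <- matrix(0L, 3, 3)
  J2[3, 2] <- 1L
  iso <- grn(J2)
  expect_false(structural_check(iso, 3L)$input_reaches_all)
  expect_error(structural_check(chain2(), 1L), "differ from the input")
})

test_that("edge moves conserve K, keep invariants and are reproducible", {
  set.seed(7)
  net <- random_grn(8, 12)
  bad_k <- 0L
  for (i in 1:2000) {
    net <- propose_edge_move(net)   # grn() validates diagonal/mutual
    if (net$n_edges != 12L) bad_k <- bad_k + 1L
  }
  expect_identical(bad_k, 0L)
  set.seed(123)
  a <- propose_edge_move(net)
  set.seed(123)
  b <- propose_edge_move(net)
  expect_identical(a$J, b$J)

  # at full capacity the vacated pair is the only admissible target
  full <- random_grn(3, 3)
  moved <- propose_edge_move(full)
  expect_identical(sum(moved$J != 0L), 3L)
  changed <- which(full$J != moved$J, arr.ind = TRUE)
  # the move touches one unordered pair: either nothing visible changed
  # (same place, maybe same sign) or the edge stayed within that pair
  pairs <- unique(t(apply(changed, 1, sort)))
  expect_lte(nrow(pairs), 1L)
})

test_that("mutations apply, invert and refuse invalid sites", {
  net <- chain2()
  mut <- mutation("delete_edge", i = 2, j = 1)
  deleted <- apply_mutation(net, mut)
  expect_identical(deleted$n_edges, 0L)
  expect_identical(deleted$output, 2L)
  restored <- apply_mutation(deleted, mutation("add_edge", i = 2, j = 1,
                                               sign = 1L))
  expect_identical(restored$J, net$J)

  expect_error(apply_mutation(deleted, mut), "no edge")
  expect_error(apply_mutation(net, mutation("add_edge", i = 1, j = 2,
                                            sign = 1L)),
               "mutual regulation")
  expect_error(apply_mutation(net, mutation("add_edge", i = 1, j = 1,
                                            sign = 1L)),
               "self-regulating")
  expect_error(apply_mutation(net, mutation("knockout_node", node = 1)),
               "input gene")
  expect_error(apply_mutation(net, mutation("knockout_node", node = 2)),
               "output gene")

  ko <- apply_mutation(chain3(), mutation("knockout_node", node = 2))
  expect_identical(sum(ko$J != 0L), 0L)
})

test_that("enumeration yields every admissible network exactly once", {
  e21 <- enumerate_networks(2, 1)
  expect_length(e21, 4L)
  e33 <- enumerate_networks(3, 3)
  expect_length(e33, 64L)
  # closed form: choose(P, K) placements x 2^K orientations x 2^K signs
  expect_equal(length(e33), choose(3, 3) * 2^3 * 2^3)
  keys <- vapply(e33, function(n) paste(n$J, collapse = ","), character(1))
  expect_identical(anyDuplicated(keys), 0L)
  for (n in e33) {
    expect_identical(n$n_edges, 3L)
    expect_true(all(diag(n$J) == 0L))
    expect_false(any(n$J != 0L & t(n$J) != 0L))
  }
  expect_error(enumerate_networks(10, 20, cap = 1e6), "cap")
})
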