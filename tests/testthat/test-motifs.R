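test_that("hand-built triangles are classified correctly", {
  # directed 3-cycle, all activating: one positive feedback loop
  J <- matrix(0L, 3, 3)
  J[2, 1] <- 1L; J[3, 2] <- 1L; J[1, 3] <- 1L
  expect_identical(as.integer(count_motifs(grn(J))), c(1L, 0L, 0L, 0L))

  # one repression in the cycle: negative feedback loop
  J[1, 3] <- -1L
  expect_identical(as.integer(count_motifs(grn(J))), c(0L, 1L, 0L, 0L))

  # feedforward 1 -> 2, 2 -> 3, 1 -> 3 with one repression: incoherent FFL
  F <- matrix(0L, 3, 3)
  F[2, 1] <- 1L; F[3, 2] <- 1L; F[3, 1] <- -1L
  expect_identical(as.integer(count_motifs(grn(F))), c(0L, 0L, 0L, 1L))
  # all activating: coherent FFL
  F[3, 1] <- 1L
  expect_identical(as.integer(count_motifs(grn(F))), c(0L, 0L, 1L, 0L))

  # too few genes or edges: nothing to count
  expect_identical(sum(count_motifs(chain2())), 0L)
  expect_identical(sum(count_motifs(chain3())), 0L)
})

test_that("compiled census agrees with the exhaustive triple oracle", {
  set.seed(31)
  for (rep in 1:40) {
    n <- sample(4:8, 1)
    k <- sample(3:(n * (n - 1) / 2), 1)
    net <- random_grn(n, k)
    expect_identical(as.integer(count_motifs(net)),
                     as.integer(motif_oracle(net)))
  }
})

test_that("global sign flip swaps positive and negative classes", {
  set.seed(32)
  for (rep in 1:25) {
    net <- random_grn(8, 16)
    a <- count_motifs(net)
    b <- count_motifs(grn(-net$J))
    expect_identical(a[["pos_fbl"]], b[["neg_fbl"]])
    expect_identical(a[["neg_fbl"]], b[["pos_fbl"]])
    expect_identical(a[["pos_ffl"]], b[["neg_ffl"]])
    expect_identical(a[["neg_ffl"]], b[["pos_ffl"]])
  }
})

test_that("counts are invariant under node relabeling", {
  set.seed(33)
  for (rep in 1:15) {
    net <- random_grn(7, 14)
    perm <- sample(7)
    expect_identical(as.integer(count_motifs(grn(net$J[perm, perm]))),
                     as.integer(count_motifs(net)))
  }
})

test_that("random ensembles balance positive and negative loop classes", {
  set.seed(34)
  nets <- replicate(1000, random_grn(8, 16), simplify = FALSE)
  h <- ensemble_motif_histogram(nets)
  tot <- h$totals
  # each triangle's sign class is an independent fair coin under random
  # signs: compare paired classes within 3 binomial sigma
  for (pair in list(c("pos_fbl", "neg_fbl"), c("pos_ffl", "neg_ffl"))) {
    n <- tot[pair[1]] + tot[pair[2]]
    expect_lt(abs(tot[[pair[1]]] - n / 2), 3 * sqrt(n * 0.25) + 1)
  }
  # orientation balance: FFLs outnumber FBLs 3:1 among random triangles
  # (of the 8 orientations of a triangle, 2 are cycles)
  n_all <- sum(tot)
  expect_lt(abs((tot[["pos_fbl"]] + tot[["neg_fbl"]]) / n_all - 0.25),
            3 * sqrt(0.25 * 0.75 / n_all))
})
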