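test_that("noise specifications carry the study amplitudes by default", {
  expect_equal(noise_spec("input")$amplitude, 0.3)
  expect_equal(noise_spec("internal")$amplitude, 0.1)
  expect_error(noise_spec("input", -1))
})

test_that("zero-amplitude noise reproduces the noiseless protocol exactly", {
  net <- assign_output(chain2())
  set.seed(71)
  clean <- step_protocol(net)
  set.seed(71)
  zero_in <- step_protocol(net, noise = noise_spec("input", 0))
  set.seed(71)
  zero_int <- step_protocol(net, noise = noise_spec("internal", 0))
  expect_identical(clean$trajectory, zero_in$trajectory)
  expect_identical(clean$trajectory, zero_int$trajectory)
})

test_that("deleting the only regulation of the output is lethal", {
  scan <- edge_deletion_scan(chain2())
  expect_identical(nrow(scan$sites), 1L)
  expect_equal(scan$f_prime, 0)        # output unregulated: 0.5 at both inputs
  expect_identical(scan$n_lethal, 1L)
})

test_that("knocking out a relay gene silences the response", {
  scan <- node_knockout_scan(chain3())
  expect_identical(scan$sites$node, 2L)
  expect_equal(scan$f_prime, 0)
  expect_identical(scan$n_lethal, 1L)
})

test_that("mutation scans are non-destructive and self-consistent", {
  set.seed(72)
  net <- random_valid_net(8, 14)
  before <- net$J
  del <- edge_deletion_scan(net)
  ko <- node_knockout_scan(net)
  add <- edge_addition_scan(net)
  expect_identical(net$J, before)
  expect_identical(nrow(del$sites), 14L)
  expect_true(all(del$f_prime >= 0 & del$f_prime <= 1))
  expect_true(all(add$f_prime >= 0 & add$f_prime <= 1))
  # adding an edge and then deleting it restores the original fitness
  pos <- add$sites[1, ]
  mutant <- apply_mutation(net, mutation("add_edge", i = pos$i, j = pos$j,
                                         sign = pos$sign))
  del2 <- edge_deletion_scan(mutant)
  new_edge <- del2$sites$i == pos$i & del2$sites$j == pos$j
  expect_identical(sum(new_edge), 1L)
  expect_equal(del2$f_prime[new_edge], attr(net, "f"), tolerance = 1e-12)
})

test_that("lethal classification is monotone in the threshold", {
  set.seed(73)
  for (rep in 1:5) {
    net <- random_valid_net(8, 14)
    fp <- edge_deletion_scan(net)$f_prime
    sizes <- vapply(c(0.3, 0.6, 0.9, 0.99), function(th) sum(fp < th),
                    numeric(1))
    expect_true(all(diff(sizes) >= 0))
  }
})

test_that("a full-capacity network admits no edge addition", {
  net <- assign_output(grn(rbind(c(0L, 0L, 0L),
                                 c(1L, 0L, 0L),
                                 c(1L, 1L, 0L)), output = 3L))
  scan <- edge_addition_scan(net)
  expect_identical(length(scan$f_prime), 0L)
  expect_true(is.na(scan$robust_fraction))
})

test_that("input noise does not break followers and internal noise can rescue", {
  p2 <- dyn_params(a = 2)
  tog <- assign_output(read_grn_csv(system.file("extdata",
                                                "toggle_n16_synthetic.csv",
                                                package = "grnland")), p2)
  set.seed(74)
  np <- noise_protocol(tog, p2, spec = noise_spec("input"))
  expect_true(np$follows)
  expect_true(np$follows_noisy)   # bistability acts as a low-pass filter
  expect_false(np$nir)

  nir_net <- assign_output(read_grn_csv(system.file("extdata",
                                                    "nir_n16_synthetic.csv",
                                                    package = "grnland")), p2)
  set.seed(99)  # noise realization under which this net shows rescue
  np2 <- noise_protocol(nir_net, p2, spec = noise_spec("internal"))
  expect_false(np2$follows)
  expect_true(np2$nir)
})

test_that("TSwoLE selection intersects toggles with zero lethal edges", {
  fake_scan <- function(n_lethal) {
    structure(list(n_lethal = as.integer(n_lethal)), class = "mutation_scan")
  }
  nets <- vector("list", 4)
  classes <- c("toggle", "toggle", "one_way", "monostable")
  scans <- lapply(c(0, 2, 0, 0), fake_scan)
  expect_identical(tswole_filter(nets, classes, scans), 1L)
  expect_identical(tswole_filter(list(), character(), list()), integer())
})
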