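test_that("fitness bins partition [0, 1] with a closed last bin", {
  b <- fitness_bins()
  expect_identical(b$n_bins, 100L)
  expect_equal(range(b$edges), c(0, 1))
  expect_true(all(diff(b$edges) > 0))
  expect_identical(bin_index(0, b), 1L)
  expect_identical(bin_index(0.0099, b), 1L)
  expect_identical(bin_index(0.01, b), 2L)
  expect_identical(bin_index(0.999, b), 100L)
  expect_identical(bin_index(1, b), 100L)
})

test_that("exact enumeration density on the 2-gene system matches hand count", {
  d <- exact_density_small(2, 1)
  # 2 positions x 2 signs = 4 networks; only the two with an edge from the
  # input onto gene 2 are valid, and both have the chain fitness
  expect_equal(attr(d, "n_total"), 4)
  expect_equal(attr(d, "n_valid"), 2)
  resolved <- which(!is.na(d$table$prob))
  expect_identical(resolved, bin_index(chain2_fitness_oracle()))
  expect_equal(d$table$prob[resolved], 1)
})

test_that("exact density is normalized and consistent under bin refinement", {
  fine <- exact_density_small(3, 3, bins = 100)
  coarse <- exact_density_small(3, 3, bins = 10)
  expect_equal(sum(fine$table$prob, na.rm = TRUE), 1, tolerance = 1e-9)
  expect_equal(sum(coarse$table$prob, na.rm = TRUE), 1, tolerance = 1e-9)
  # aggregate fine bins tenfold: per-coarse-bin mass must agree exactly
  agg <- tapply(ifelse(is.na(fine$table$prob), 0, fine$table$prob),
                rep(1:10, each = 10), sum)
  expect_equal(as.numeric(agg),
               ifelse(is.na(coarse$table$prob), 0, coarse$table$prob),
               tolerance = 1e-12)
})

test_that("measurement under exact weights produces a flat histogram", {
  set.seed(51)
  ex <- exact_density_small(4, 4)
  state <- random_valid_net(4, 4)
  w <- weights_from_density(ex, state)
  s <- entropic_sample(w, n_mcs = 4e4, sample_interval = 10)
  resolved <- which(!is.na(ex$table$prob))
  counts <- s$histogram[resolved]
  n <- sum(counts)
  expect_equal(n, length(s$f))
  # under exact weights every resolved bin is visited equally often;
  # allow 5 sigma multinomial fluctuation (correlated samples inflate the
  # variance, hence the generous band)
  p0 <- 1 / length(resolved)
  for (ct in counts)
    expect_lt(abs(ct - n * p0), 8 * sqrt(n * p0 * (1 - p0)))
})

test_that("learned weights recover the exact density on a small system", {
  set.seed(52)
  w <- wang_landau(4, 4, control = wl_control(final_log_f = 1e-6))
  expect_true(w$converged)
  s <- entropic_sample(w, n_mcs = 1e5, sample_interval = 10)
  est <- estimate_density(s, w)
  ex <- exact_density_small(4, 4)
  expect_lt(kl_divergence(ex, est), 0.05)
  expect_equal(sum(est$table$prob, na.rm = TRUE), 1, tolerance = 1e-9)
})

test_that("identical seeds reproduce identical sample streams", {
  set.seed(53)
  w1 <- wang_landau(4, 4, control = wl_control(final_log_f = 1e-3))
  s1 <- entropic_sample(w1, n_mcs = 2000)
  set.seed(53)
  w2 <- wang_landau(4, 4, control = wl_control(final_log_f = 1e-3))
  s2 <- entropic_sample(w2, n_mcs = 2000)
  expect_identical(w1$log_states, w2$log_states)
  expect_identical(s1$f, s2$f)
})

test_that("the landscape fitter assembles weights, samples and density", {
  set.seed(54)
  land <- grn_landscape(4, connectivity = 2, n_mcs = 5000, n_runs = 2,
                        control = wl_control(final_log_f = 1e-4))
  expect_s3_class(land, "grn_landscape")
  expect_identical(land$n_edges, 4L)
  expect_identical(length(land$samples$f), 2L * 500L)
  expect_equal(sum(land$density$table$prob, na.rm = TRUE), 1,
               tolerance = 1e-9)
  sm <- summary(land)
  expect_true(sm$mass_below_0.2 > 0.9)  # tiny systems have low fitness
  expect_error(grn_landscape(5, connectivity = 5), "even")
  expect_output(print(land), "fitness landscape")
})

test_that("seeding the walk with a valid network is honoured", {
  set.seed(55)
  seed_net <- random_valid_net(4, 4)
  w <- wang_landau(4, 4, control = wl_control(final_log_f = 1e-2),
                   init = seed_net)
  expect_true(sum(w$visited) >= 1)
  # gene 4 feeds the loop but is unreachable from the input: invalid seed
  bad <- grn(rbind(c(0L, 0L, 1L, 0L),
                   c(1L, 0L, 0L, 1L),
                   c(0L, 1L, 0L, 0L),
                   c(0L, 0L, 0L, 0L)))
  expect_false(evaluate_fitness(bad)$valid)
  expect_error(wang_landau(4, 4, init = bad), "invalid")
})

test_that("kl_divergence is zero on identical densities and detects gaps", {
  ex <- exact_density_small(3, 3)
  expect_equal(kl_divergence(ex, ex), 0)
})
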