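test_that("response function matches the sigmoid and its limits", {
  expect_equal(response_function(0), 0.5)
  expect_equal(response_function(1), 1 / (1 + exp(-1)))
  expect_equal(response_function(1e3), 1)
  expect_equal(response_function(-1e3), 0)
  x <- seq(-5, 5, 0.25)
  expect_true(all(diff(response_function(x)) > 0))
  expect_equal(response_function(0.3, a = 2, b = 0.1),
               1 / (1 + exp(-2 * 0.2)))
})

test_that("one dynamics step reproduces the update rule", {
  # unregulated genes settle towards spontaneous expression 0.5
  empty <- grn(matrix(0L, 3, 3))
  expect_equal(grn_step(empty, c(0.1, 0.9, 0.4)), rep(0.5, 3))

  net <- chain2()
  expect_equal(grn_step(net, c(0.5, 0.5), input_level = 1),
               c(sigmoid(1), sigmoid(0.5)))

  # zero noise matrix reproduces the noiseless rule exactly
  st <- c(0.3, 0.8)
  expect_identical(grn_step(net, st, 1, noise = matrix(0, 2, 2)),
                   grn_step(net, st, 1))

  # clamped gene is silenced
  expect_equal(grn_step(net, st, 1, clamped = 2L)[2], 0)
})

test_that("relaxation finds the chain fixed points known in closed form", {
  net <- chain2()
  r0 <- grn_relax(net, 0)
  expect_true(r0$fixed_point)
  expect_equal(r0$response, c(0.5, sigmoid(0.5)), tolerance = 1e-9)
  r1 <- grn_relax(net, 1)
  expect_true(r1$fixed_point)
  expect_equal(r1$response, c(sigmoid(1), sigmoid(sigmoid(1))),
               tolerance = 1e-9)
  # compiled relaxation agrees with plain R iteration
  expect_equal(r1$response, iterate_oracle(net$J, 1, c(0.5, 0.5)),
               tolerance = 1e-9)
})

test_that("non-converging orbits are flagged and averaged over the window", {
  # a frustrated 4-gene circuit that sustains oscillation at steep response
  J <- matrix(c(0L, 1L, 0L, 1L,
                0L, 0L, 0L, -1L,
                1L, -1L, 0L, 0L,
                0L, 0L, -1L, 0L), 4, 4)
  osc <- grn(J)
  steep <- dyn_params(a = 8, max_steps = 400L, avg_window = 100L)
  r <- grn_relax(osc, 0, params = steep)
  expect_false(r$fixed_point)
  # oracle: iterate in R and average the same trailing window
  x <- rep(0.5, 4)
  traj <- matrix(NA_real_, 400, 4)
  for (t in 1:400) {
    x <- sigmoid(as.numeric(J %*% x), a = 8)
    traj[t, ] <- x
  }
  expect_equal(r$response, colMeans(traj[301:400, ]), tolerance = 1e-12)
  expect_true(all(r$response >= 0 & r$response <= 1))
})

test_that("fitness of the two-gene chain matches the closed form", {
  fit <- evaluate_fitness(chain2())
  oracle <- chain2_fitness_oracle()
  expect_equal(fit$f, oracle, tolerance = 1e-9)
  expect_identical(fit$output, 2L)
  expect_true(fit$valid)
  expect_equal(fit$sensitivities, c(sigmoid(1) - 0.5, oracle),
               tolerance = 1e-9)
})

test_that("fitness is invariant under relabeling of non-input genes", {
  set.seed(21)
  for (rep in 1:20) {
    net <- random_grn(7, 12)
    fit <- evaluate_fitness(net)
    perm <- c(1L, 1L + sample(6L))
    J2 <- net$J[perm, perm]
    fit2 <- evaluate_fitness(grn(J2))
    expect_equal(fit2$f, fit$f, tolerance = 1e-12)
    expect_equal(fit2$sensitivities, fit$sensitivities[perm],
                 tolerance = 1e-12)
  }
})

test_that("sensitivities and fitness always lie in [0, 1]", {
  set.seed(22)
  for (rep in 1:50) {
    net <- random_grn(10, 20)
    fit <- evaluate_fitness(net)
    expect_true(all(fit$sensitivities >= 0 & fit$sensitivities <= 1))
    expect_gte(fit$f, 0)
    expect_lte(fit$f, 1)
    expect_identical(fit$f, fit$sensitivities[fit$output])
  }
})

test_that("invalid structures are flagged but still scored", {
  # input cannot reach gene 3
  J <- matrix(0L, 3, 3)
  J[2, 1] <- 1L
  J[2, 3] <- 1L
  fit <- evaluate_fitness(grn(J))
  expect_false(fit$valid)
  expect_identical(fit$invalid_reason, "input_unreachable")
  expect_true(is.finite(fit$f))
})

test_that("fixed-output mutant fitness matches full evaluation on intact nets", {
  set.seed(23)
  for (rep in 1:10) {
    net <- random_valid_net(8, 14)
    expect_equal(fitness_fixed_output(net), attr(net, "f"), tolerance = 1e-12)
  }
})

test_that("trajectory simulation matches stepwise iteration", {
  net <- chain2()
  tr <- simulate(net, input_level = 1, steps = 20)
  x <- c(0.5, 0.5)
  for (t in 1:20) x <- grn_step(net, x, 1)
  expect_equal(unname(tr[20, ]), x, tolerance = 1e-12)
  # with noise the trajectory differs but stays in [0, 1]
  set.seed(24)
  trn <- simulate(net, input_level = 1, steps = 20,
                  noise = noise_spec("internal"))
  expect_false(identical(tr, trn))
  expect_true(all(trn >= 0 & trn <= 1))
})
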