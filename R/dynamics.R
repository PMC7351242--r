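#' Dynamics parameters
#'
#' Parameters of the sigmoidal expression map and of steady-state
#' detection. The response function is `R(x) = 1 / (1 + exp(-a (x - b)))`
#' with steepness `a = 1` and threshold `b = 0` by default, so an
#' unregulated gene settles at the spontaneous expression 0.5.
#'
#' The iteration is declared at a fixed point when the max-norm change of
#' one step falls below `tol`; the default `1e-10` sits far below the 0.01
#' bistability criterion and the 0.001 input sweep step, so fixed-point
#' detection never interferes with those thresholds. If no fixed point is
#' found within `max_steps`, the response is the componentwise mean over
#' the trailing `avg_window` steps (limit cycles are an ordinary outcome,
#' flagged, not an error).
#'
#' @param a sigmoid steepness (dimensionless, > 0).
#' @param b sigmoid threshold (dimensionless).
#' @param tol fixed-point tolerance in expression units.
#' @param max_steps iteration budget per relaxation.
#' @param avg_window trailing window used to average non-converged orbits;
#'   must not exceed `max_steps`.
#' @return a list of class `dyn_params`.
#' @export
dyn_params <- function(a = 1, b = 0, tol = 1e-10, max_steps = 5000L,
                       avg_window = 1000L) {
  stopifnot(a > 0, tol > 0, max_steps >= 1, avg_window >= 1,
            avg_window <= max_steps)
  structure(list(a = a, b = b, tol = tol,
                 max_steps = as.integer(max_steps),
                 avg_window = as.integer(avg_window)),
            class = "dyn_params")
}

#' Sigmoidal response function
#'
#' `R(x) = 1 / (1 + exp(-a (x - b)))`, strictly increasing with values in
#' (0, 1). With the defaults `a = 1`, `b = 0`, `R(0) = 0.5`.
#'
#' @param x regulatory input (real vector).
#' @param a,b steepness and threshold.
#' @return values in (0, 1).
#' @export
response_function <- function(x, a = 1, b = 0) {
  1 / (1 + exp(-a * (x - b)))
}

#' One step of the expression dynamics
#'
#' Computes `x_i(t+1) = R(I [i == input] + sum_{j != i} J_ij (x_j + xi_ij))`
#' in plain R; this is the reference single-step implementation against
#' which the compiled relaxation path can be cross-checked. Genes listed in
#' `clamped` are silenced (expression pinned to 0).
#'
#' @param net a `grn`.
#' @param state expression vector in `[0, 1]^N`.
#' @param input_level input signal I applied to the input gene.
#' @param params a [dyn_params()].
#' @param noise optional N x N matrix of per-pair disturbances `xi_ij`
#'   added to `x_j` as seen by gene i (internal noise); `NULL` for none.
#' @param clamped integer vector of silenced genes.
#' @return the next expression vector.
#' @export
grn_step <- function(net, state, input_level = 0, params = dyn_params(),
                     noise = NULL, clamped = integer()) {
  stopifnot(inherits(net, "grn"), length(state) == net$n_genes)
  J <- net$J
  n <- net$n_genes
  if (is.null(noise)) {
    h <- as.numeric(J %*% state)
  } else {
    stopifnot(identical(dim(noise), dim(J)))
    h <- rowSums(J * (matrix(state, n, n, byrow = TRUE) + noise))
  }
  h[net$input] <- h[net$input] + input_level
  out <- response_function(h, params$a, params$b)
  out[clamped] <- 0
  out
}

#' Relax the dynamics to a steady state
#'
#' Iterates the expression map at fixed input from `state` (all genes at
#' the spontaneous expression 0.5 by default) until a fixed point is
#' reached or the step budget runs out, in which case the response is the
#' average over the trailing window.
#'
#' @param net a `grn`.
#' @param input_level input signal I.
#' @param state initial expression vector; default all 0.5.
#' @param params a [dyn_params()].
#' @param clamped integer vector of silenced genes.
#' @return a list of class `steady_state` with `response` (per-gene steady
#'   expression), `fixed_point` (logical) and `steps`.
#' @export
grn_relax <- function(net, input_level = 0, state = NULL,
                      params = dyn_params(), clamped = integer()) {
  stopifnot(inherits(net, "grn"))
  if (is.null(state)) {
    state <- rep(0.5, net$n_genes)
    state[clamped] <- 0
  }
  stopifnot(length(state) == net$n_genes, all(state >= 0), all(state <= 1))
  res <- cpp_relax(net$J, net$input - 1L, input_level, state,
                   unclass(params), as.integer(clamped) - 1L)
  structure(res, class = "steady_state")
}

#' Evaluate sensitivities and fitness of a network
#'
#' Relaxes the network at input I = 0 and I = 1, both from the uniform 0.5
#' start, and computes per-gene sensitivities `s_i = |xbar_i(1) - xbar_i(0)|`.
#' The non-input gene with the largest sensitivity is the output gene
#' (ties broken towards the lowest index) and its sensitivity is the
#' fitness `f`. The result is flagged invalid when the input gene fails to
#' reach every gene or some gene has no path to the selected output; `f`
#' is reported regardless, so callers decide on rejection.
#'
#' @param net a `grn`.
#' @param params a [dyn_params()].
#' @return a list of class `grn_fitness` with `sensitivities`, `output`,
#'   `f`, `valid`, `invalid_reason`, `fixed_point` (at I = 0 and 1).
#' @examples
#' chain <- grn(matrix(c(0, 1, 0, 0), 2, 2))  # gene 1 activates gene 2
#' evaluate_fitness(chain)$f                  # 0.05258...
#' @export
evaluate_fitness <- function(net, params = dyn_params()) {
  stopifnot(inherits(net, "grn"))
  res <- cpp_evaluate(net$J, net$input - 1L, unclass(params))
  structure(list(sensitivities = res$sensitivities,
                 output = res$output + 1L,
                 f = res$f,
                 valid = res$valid,
                 invalid_reason = c("none", "input_unreachable",
                                    "output_unreachable")[res$reason + 1L],
                 fixed_point = res$fixed_point),
            class = "grn_fitness")
}

#' Mutant fitness with the output gene held fixed
#'
#' Used by the mutation scans: re-evaluates `f' = |xbar_out(1) - xbar_out(0)|`
#' for a (possibly mutated) network keeping the original input and output
#' designations, without re-selecting the output or re-validating the
#' structure.
#'
#' @param net a `grn` with assigned output.
#' @param params a [dyn_params()].
#' @param clamped optional single silenced gene (knockouts).
#' @return the scalar mutant fitness.
#' @export
fitness_fixed_output <- function(net, params = dyn_params(),
                                 clamped = NA_integer_) {
  stopifnot(inherits(net, "grn"), !is.na(net$output))
  cpp_eval_fixed_output(net$J, net$input - 1L, net$output - 1L,
                        unclass(params),
                        if (is.na(clamped)) -1L else as.integer(clamped) - 1L)
}

#' Assign the fitness-selected output gene to a network
#'
#' @param net a `grn`.
#' @param params a [dyn_params()].
#' @return the network with `output` set; attribute `"fitness"` carries
#'   the full [evaluate_fitness()] result.
#' @export
assign_output <- function(net, params = dyn_params()) {
  fit <- evaluate_fitness(net, params)
  net$output <- fit$output
  attr(net, "fitness") <- fit
  net
}

#' Sample structurally valid random networks and their fitness
#'
#' Rejection-generates uniformly random networks (fresh placement and
#' signs each try), evaluates each, and keeps those passing the structural
#' validity rules, until `n` fitnesses are collected.
#'
#' @param n number of valid networks required.
#' @param n_genes,n_edges network size.
#' @param params a [dyn_params()].
#' @param max_tries give up after this many generation attempts.
#' @return a data.frame with columns `f` and `output`; attribute
#'   `"tries"` records the number of attempts.
#' @export
random_fitness_sample <- function(n, n_genes, n_edges,
                                  params = dyn_params(), max_tries = 2000 * n) {
  res <- cpp_random_valid_fitness(as.integer(n_genes), as.integer(n_edges),
                                  as.integer(n), unclass(params),
                                  as.numeric(max_tries))
  if (length(res$f) < n)
    warning(sprintf("only %d valid networks in %g tries", length(res$f),
                    res$tries))
  out <- data.frame(f = res$f, output = res$output + 1L)
  attr(out, "tries") <- res$tries
  out
}

#' @export
print.grn_fitness <- function(x, ...) {
  cat(sprintf("Fitness f = %.6f at output gene %d (%s)\n", x$f, x$output,
              if (x$valid) "structurally valid"
              else paste0("invalid: ", x$invalid_reason)))
  cat("Sensitivities:", format(round(x$sensitivities, 4)), "\n")
  invisible(x)
}

#' Simulate an expression trajectory
#'
#' Iterates the dynamics for a fixed number of steps at constant input,
#' recording every state; mainly a debugging and visualization aid.
#'
#' @param object a `grn`.
#' @param nsim number of independent trajectories (only > 1 with noise).
#' @param seed optional seed, as for [stats::simulate()].
#' @param input_level constant input I.
#' @param steps number of steps.
#' @param params a [dyn_params()].
#' @param noise optional [noise_spec()] applied at every step.
#' @param state initial expression vector; default all 0.5.
#' @param ... unused.
#' @return a `steps` x N matrix of expressions (row t = state after step
#'   t), or a list of such matrices when `nsim > 1`.
#' @export
simulate.grn <- function(object, nsim = 1, seed = NULL, input_level = 0,
                         steps = 100L, params = dyn_params(), noise = NULL,
                         state = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- object$n_genes
  one <- function() {
    x <- state %||% rep(0.5, n)
    out <- matrix(NA_real_, steps, n,
                  dimnames = list(NULL, paste0("g", seq_len(n))))
    for (t in seq_len(steps)) {
      I <- input_level
      xi <- NULL
      if (!is.null(noise) && noise$amplitude > 0) {
        if (noise$kind == "input") {
          I <- I + runif(1, -noise$amplitude, noise$amplitude)
        } else {
          xi <- matrix(runif(n * n, -noise$amplitude, noise$amplitude), n, n)
        }
      }
      x <- grn_step(object, x, I, params, noise = xi)
      out[t, ] <- x
    }
    out
  }
  if (nsim == 1) one() else replicate(nsim, one(), simplify = FALSE)
}
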