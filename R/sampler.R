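#' Fitness binning of [0, 1]
#'
#' The fitness range is divided into `n_bins` half-open bins
#' `[lo, hi)`, the last bin closed, mirroring the 100-bin partition used
#' throughout the landscape estimation.
#'
#' @param n_bins number of bins.
#' @return a list of class `fitness_bins` with `n_bins` and `edges`.
#' @export
fitness_bins <- function(n_bins = 100L) {
  n_bins <- as.integer(n_bins)
  stopifnot(n_bins >= 1L)
  structure(list(n_bins = n_bins, edges = seq(0, 1, length.out = n_bins + 1L)),
            class = "fitness_bins")
}

#' Bin index of a fitness value
#' @param f fitness values in `[0, 1]`.
#' @param bins a [fitness_bins()].
#' @return integer bin indices in `1..n_bins`.
#' @export
bin_index <- function(f, bins = fitness_bins()) {
  as.integer(pmin(pmax(floor(f * bins$n_bins), 0), bins$n_bins - 1L)) + 1L
}

#' Wang-Landau schedule
#'
#' Controls for the weight-learning stage. The modification factor starts
#' at `log_f0` (natural-log units), halves whenever the visit histogram
#' over all bins seen so far is flat (minimum at least `flatness` times
#' the mean), and the run stops once it drops below `final_log_f`.
#' `max_proposals` caps the total number of elementary moves; if hit, the
#' weights learned so far are returned with `converged = FALSE` (they are
#' still usable for measurement, which corrects residual weight error
#' through the histogram).
#'
#' @param log_f0 initial modification factor (log scale).
#' @param flatness histogram flatness criterion in (0, 1).
#' @param final_log_f stopping value of the modification factor.
#' @param check_interval proposals between flatness checks.
#' @param max_proposals hard cap on elementary moves.
#' @param fresh_sign randomize the sign of relocated edges.
#' @param init_max_tries attempts to find a valid initial network.
#' @return a list of class `wl_control`.
#' @export
wl_control <- function(log_f0 = 1.0, flatness = 0.8, final_log_f = 1e-8,
                       check_interval = 1000L, max_proposals = 5e7,
                       fresh_sign = TRUE, init_max_tries = 1e5) {
  stopifnot(log_f0 > 0, flatness > 0, flatness < 1, final_log_f > 0,
            final_log_f < log_f0)
  structure(list(log_f0 = log_f0, flatness = flatness,
                 final_log_f = final_log_f,
                 check_interval = as.integer(check_interval),
                 max_proposals = as.numeric(max_proposals),
                 fresh_sign = isTRUE(fresh_sign),
                 init_max_tries = as.integer(init_max_tries)),
            class = "wl_control")
}

#' Learn multicanonical weights by the Wang-Landau method
#'
#' Performs a random walk in network space with the edge-relocation move.
#' Proposals that violate the structural rules (input fails to reach every
#' gene, or the maximum-sensitivity gene is unreachable from some gene)
#' are rejected outright, so the chain lives on valid networks only.
#' Valid proposals are accepted with probability
#' `min(1, exp(ln g(bin_old) - ln g(bin_new)))` where `ln g` is the
#' running estimate of the log number of networks per fitness bin; after
#' every attempted move the current bin's `ln g` is raised by the
#' modification factor and its histogram incremented (rejected moves
#' update the current state's bin, as Markov-chain correctness requires).
#'
#' @param n_genes,n_edges network size.
#' @param bins a [fitness_bins()] or a bin count.
#' @param params a [dyn_params()].
#' @param control a [wl_control()].
#' @param init optional `grn` to start the walk from (must be structurally
#'   valid); the stationary law does not depend on the starting point, but
#'   a high-fitness seed makes the walk discover the rare end of the range
#'   top-down, which is often much cheaper. Default: random valid network.
#' @return a list of class `wl_weights` with `log_weight`
#'   (per-bin `-ln g`, the multicanonical weight, `NA` for never-visited
#'   bins), `log_states` (`ln g`, shifted to max 0), `visit_histogram`,
#'   `converged`, `final_mod_factor`, the final chain state (`state`,
#'   `state_f`, `state_output`) and bookkeeping counters.
#' @export
wang_landau <- function(n_genes, n_edges, bins = fitness_bins(),
                        params = dyn_params(), control = wl_control(),
                        init = NULL) {
  if (is.numeric(bins)) bins <- fitness_bins(bins)
  if (!is.null(init)) {
    stopifnot(inherits(init, "grn"), init$n_genes == n_genes,
              init$n_edges == n_edges)
    init <- init$J
  }
  res <- cpp_wang_landau(as.integer(n_genes), as.integer(n_edges),
                         bins$n_bins, unclass(params),
                         control$log_f0, control$flatness,
                         control$final_log_f, control$check_interval,
                         control$max_proposals, control$fresh_sign,
                         control$init_max_tries, init)
  structure(list(log_weight = -res$log_states,
                 log_states = res$log_states,
                 visit_histogram = res$visit_histogram,
                 visited = res$visited,
                 converged = res$converged,
                 final_mod_factor = res$final_mod_factor,
                 n_proposals = res$n_proposals,
                 n_stages = res$n_stages,
                 accept_rate = res$accept_rate,
                 state = res$state,
                 state_f = res$state_f,
                 state_output = res$state_output,
                 bins = bins, n_genes = as.integer(n_genes),
                 n_edges = as.integer(n_edges), params = params,
                 control = control),
            class = "wl_weights")
}

#' @export
print.wl_weights <- function(x, ...) {
  cat(sprintf("Wang-Landau weights: N = %d, K = %d, %d bins\n",
              x$n_genes, x$n_edges, x$bins$n_bins))
  cat(sprintf("  %s after %.3g proposals (%d stages), final mod factor %.2e\n",
              if (x$converged) "converged" else "stopped at proposal cap",
              x$n_proposals, x$n_stages, x$final_mod_factor))
  cat(sprintf("  bins visited: %d, acceptance rate %.2f\n",
              sum(x$visited), x$accept_rate))
  invisible(x)
}

#' Entropic-sampling measurement run
#'
#' Fixed-weight Metropolis sampling using learned (or exact) weights. One
#' Monte Carlo step (MCS) is K attempted edge relocations; a `(network,
#' fitness)` sample is recorded every `sample_interval` MCS to damp the
#' correlation between successive samples. Networks whose fitness falls in
#' `keep_range` are retained as full `grn` objects (up to `keep_max` per
#' run).
#'
#' @param weights a `wl_weights` (or compatible list with `log_states`,
#'   `state`, `bins`, `params`, `n_edges`).
#' @param n_mcs Monte Carlo steps per run.
#' @param sample_interval MCS between recorded samples.
#' @param n_runs independent measurement runs (each continues the chain;
#'   their histograms accumulate).
#' @param keep_range length-2 fitness interval of networks to retain, or
#'   `NULL`.
#' @param keep_max cap on retained networks per run.
#' @return a list of class `entropic_samples` with `f` (recorded fitness
#'   values), `histogram` (per-bin recorded counts, summed over runs),
#'   `networks` (list of retained `grn`s with outputs assigned), `n_runs`,
#'   `accept_rate`.
#' @export
entropic_sample <- function(weights, n_mcs = 1e4, sample_interval = 10L,
                            n_runs = 1L, keep_range = NULL, keep_max = 10000L) {
  stopifnot(inherits(weights, "wl_weights"))
  lo <- if (is.null(keep_range)) 2 else keep_range[1L]
  hi <- if (is.null(keep_range)) 2 else keep_range[2L]
  kmax <- if (is.null(keep_range)) 0L else as.integer(keep_max)
  state <- weights$state
  fs <- numeric(0)
  hist <- numeric(weights$bins$n_bins)
  nets <- list()
  acc <- numeric(n_runs)
  for (run in seq_len(n_runs)) {
    res <- cpp_entropic(state, weights$log_states, as.numeric(n_mcs),
                        as.integer(sample_interval), unclass(weights$params),
                        weights$control$fresh_sign, lo, hi, kmax)
    fs <- c(fs, res$f)
    hist <- hist + res$histogram
    if (length(res$kept)) {
      batch <- mapply(function(J, out) grn(J, output = out + 1L),
                      res$kept, res$kept_output, SIMPLIFY = FALSE)
      for (b in seq_along(batch)) attr(batch[[b]], "f") <- res$kept_f[b]
      nets <- c(nets, batch)
    }
    acc[run] <- res$accept_rate
    state <- res$state
  }
  structure(list(f = fs, histogram = hist, networks = nets,
                 n_runs = as.integer(n_runs),
                 sample_interval = as.integer(sample_interval),
                 n_mcs = n_mcs, accept_rate = mean(acc),
                 bins = weights$bins),
            class = "entropic_samples")
}

#' Estimate the density of states over fitness
#'
#' Combines the measurement histogram with the sampling weights:
#' `ln Omega(bin) = ln hist(bin) + ln g(bin)`, normalized so that
#' `sum(Omega)` over resolved (non-empty) bins is 1. Bins never hit during
#' measurement are unresolved (`NA`) and excluded from the normalization.
#'
#' @param samples an [entropic_sample()] result.
#' @param weights the `wl_weights` the run was performed with.
#' @return an object of class `grn_density`; a data.frame-like table with
#'   `bin_lo`, `bin_hi`, `log_states` (ln relative number of networks),
#'   `prob`, `count`.
#' @export
estimate_density <- function(samples, weights) {
  stopifnot(inherits(samples, "entropic_samples"),
            inherits(weights, "wl_weights"))
  if (all(samples$histogram == 0)) stop("measurement histogram is empty")
  lng <- weights$log_states
  lnw <- ifelse(samples$histogram > 0, log(samples$histogram) + lng, NA_real_)
  new_density(lnw, samples$histogram, samples$bins,
              n_runs = samples$n_runs, exact = FALSE)
}

new_density <- function(log_unnorm, counts, bins, n_runs, exact) {
  ok <- !is.na(log_unnorm)
  z <- max(log_unnorm[ok])
  lse <- z + log(sum(exp(log_unnorm[ok] - z)))
  lno <- log_unnorm - lse
  structure(list(table = data.frame(bin_lo = bins$edges[-(bins$n_bins + 1L)],
                                    bin_hi = bins$edges[-1L],
                                    log_states = lno,
                                    prob = exp(lno),
                                    count = counts),
                 bins = bins, n_runs = n_runs, exact = exact),
            class = "grn_density")
}

#' Exact density of states by exhaustive enumeration
#'
#' Enumerates every admissible network, keeps the structurally valid ones
#' under the same rejection rule the sampler uses, evaluates their exact
#' fitness and bins it. Only feasible for small systems; the number of
#' networks is `choose(N(N-1)/2, K) * 4^K`.
#'
#' @param n_genes,n_edges network size.
#' @param bins a [fitness_bins()] or a bin count.
#' @param params a [dyn_params()].
#' @param cap refuse enumeration beyond this many networks.
#' @return a `grn_density` (exact); attribute `"n_valid"` and
#'   `"n_total"` record the enumeration tally.
#' @export
exact_density_small <- function(n_genes, n_edges, bins = fitness_bins(),
                                params = dyn_params(), cap = 1e7) {
  if (is.numeric(bins)) bins <- fitness_bins(bins)
  size <- cpp_enumeration_size(n_genes, n_edges)
  if (size > cap)
    stop(sprintf("enumeration would visit %.3g networks (cap %.3g)",
                 size, cap))
  res <- cpp_exact_density(as.integer(n_genes), as.integer(n_edges),
                           bins$n_bins, unclass(params))
  if (res$n_valid == 0) stop("no structurally valid network exists")
  d <- new_density(ifelse(res$counts > 0, log(res$counts), NA_real_),
                   res$counts, bins, n_runs = 1L, exact = TRUE)
  attr(d, "n_valid") <- res$n_valid
  attr(d, "n_total") <- res$n_total
  d
}

#' Kullback-Leibler divergence between two fitness densities
#'
#' Computed over the bins resolved in the reference density `p`;
#' unresolved bins of `q` under a resolved bin of `p` contribute
#' `Inf`.
#'
#' @param p reference `grn_density` (e.g. exact).
#' @param q estimated `grn_density`.
#' @return KL(p || q) in nats.
#' @export
kl_divergence <- function(p, q) {
  stopifnot(inherits(p, "grn_density"), inherits(q, "grn_density"),
            p$bins$n_bins == q$bins$n_bins)
  pp <- p$table$prob
  qq <- q$table$prob
  keep <- !is.na(pp) & pp > 0
  if (any(keep & (is.na(qq) | qq == 0))) return(Inf)
  sum(pp[keep] * (log(pp[keep]) - log(qq[keep])))
}

#' Estimate the fitness landscape of random GRNs
#'
#' The package's top-level estimator: learns multicanonical weights by
#' [wang_landau()], runs `n_runs` entropic-sampling measurement passes,
#' and combines histogram and weights into the density of states over
#' fitness (the "fitness landscape"). With default settings the sampler
#' resolves appearance probabilities many orders of magnitude below what
#' plain random sampling can reach.
#'
#' @param n_genes number of genes N.
#' @param n_edges number of edges K; alternatively give `connectivity`
#'   C = 2K/N.
#' @param connectivity mean degree C, used when `n_edges` is missing
#'   (`K = C N / 2`, which must be an integer).
#' @param bins a [fitness_bins()] or bin count.
#' @param params a [dyn_params()].
#' @param control a [wl_control()].
#' @param n_mcs Monte Carlo steps per measurement run.
#' @param sample_interval MCS between recorded samples.
#' @param n_runs independent measurement runs.
#' @param keep_range fitness interval of networks to retain (e.g.
#'   `c(0.99, 1)` for the fittest ensemble), or `NULL`.
#' @param keep_max cap on retained networks per run.
#' @param init optional starting `grn` passed to [wang_landau()].
#' @return an object of class `grn_landscape` with components `density`
#'   (a `grn_density`), `weights`, `samples`, and the call configuration.
#'   Methods: `print`, `summary`, `plot`, `as.data.frame`.
#' @examples
#' \donttest{
#' set.seed(7)
#' ls4 <- grn_landscape(4, 4, n_mcs = 2000, n_runs = 2,
#'                      control = wl_control(final_log_f = 1e-4))
#' summary(ls4)
#' }
#' @export
grn_landscape <- function(n_genes, n_edges = NULL, connectivity = NULL,
                          bins = fitness_bins(), params = dyn_params(),
                          control = wl_control(), n_mcs = 1e4,
                          sample_interval = 10L, n_runs = 5L,
                          keep_range = NULL, keep_max = 10000L, init = NULL) {
  if (is.null(n_edges)) {
    if (is.null(connectivity))
      stop("give either n_edges or connectivity")
    k2 <- connectivity * n_genes
    if (k2 %% 2 != 0)
      stop("connectivity * n_genes must be even so that K = C N / 2 is integer")
    n_edges <- k2 / 2
  }
  if (is.numeric(bins)) bins <- fitness_bins(bins)
  w <- wang_landau(n_genes, n_edges, bins, params, control, init = init)
  s <- entropic_sample(w, n_mcs = n_mcs, sample_interval = sample_interval,
                       n_runs = n_runs, keep_range = keep_range,
                       keep_max = keep_max)
  d <- estimate_density(s, w)
  structure(list(density = d, weights = w, samples = s,
                 n_genes = as.integer(n_genes), n_edges = as.integer(n_edges),
                 call = match.call()),
            class = "grn_landscape")
}

#' @export
print.grn_density <- function(x, ...) {
  resolved <- !is.na(x$table$prob)
  cat(sprintf("%s density of states over fitness: %d bins, %d resolved\n",
              if (x$exact) "Exact" else "Estimated", x$bins$n_bins,
              sum(resolved)))
  rng <- range(x$table$prob[resolved])
  cat(sprintf("  probability range %.3g .. %.3g\n", rng[1L], rng[2L]))
  invisible(x)
}

#' @export
as.data.frame.grn_density <- function(x, ...) x$table

#' @export
print.grn_landscape <- function(x, ...) {
  cat(sprintf("GRN fitness landscape: N = %d, K = %d (C = %.1f)\n",
              x$n_genes, x$n_edges, 2 * x$n_edges / x$n_genes))
  print(x$density)
  cat(sprintf("  %d recorded samples over %d run(s); %d networks retained\n",
              length(x$samples$f), x$samples$n_runs,
              length(x$samples$networks)))
  invisible(x)
}

#' @export
summary.grn_landscape <- function(object, ...) {
  tab <- object$density$table
  resolved <- !is.na(tab$prob)
  top <- tab[resolved & tab$bin_hi > max(tab$bin_hi[resolved]) - 1e-12, ,
             drop = FALSE]
  out <- list(n_genes = object$n_genes, n_edges = object$n_edges,
              n_bins = object$density$bins$n_bins,
              n_resolved = sum(resolved),
              converged = object$weights$converged,
              n_samples = length(object$samples$f),
              mass_below_0.2 = sum(tab$prob[resolved & tab$bin_hi <= 0.2 + 1e-12]),
              top_bin_prob = top$prob[1L],
              top_bin = c(top$bin_lo[1L], top$bin_hi[1L]))
  class(out) <- "summary.grn_landscape"
  out
}

#' @export
print.summary.grn_landscape <- function(x, ...) {
  cat(sprintf("GRN fitness landscape (N = %d, K = %d)\n", x$n_genes, x$n_edges))
  cat(sprintf("  bins resolved: %d of %d; weights %s; %d recorded samples\n",
              x$n_resolved, x$n_bins,
              if (x$converged) "converged" else "not converged", x$n_samples))
  cat(sprintf("  probability mass at f < 0.2: %.4f\n", x$mass_below_0.2))
  cat(sprintf("  highest resolved bin [%.2f, %.2f): probability %.3g\n",
              x$top_bin[1L], x$top_bin[2L], x$top_bin_prob))
  invisible(x)
}

#' @export
plot.grn_density <- function(x, ylab = "relative number of networks",
                             xlab = "fitness f", log = "y", ...) {
  tab <- x$table
  mid <- (tab$bin_lo + tab$bin_hi) / 2
  graphics::plot(mid, tab$prob, log = log, xlab = xlab, ylab = ylab,
                 pch = 16, cex = 0.6, ...)
  invisible(x)
}

#' @export
plot.grn_landscape <- function(x, ...) plot(x$density, ...)

#' Restrict learned weights to a fitness window
#'
#' Windowed multicanonical measurement: bins outside `range` are marked
#' unresolved, which the measurement chain treats as repelling, so the
#' run concentrates on the window (for instance the fittest bins) instead
#' of diffusing across the whole landscape. The densities measured inside
#' a window are relative within it; use full-range runs for globally
#' normalized landscapes.
#'
#' @param weights a `wl_weights`.
#' @param range length-2 fitness interval to keep.
#' @param state optional `grn` inside the window to start the chain from;
#'   default keeps the stored chain state.
#' @return a `wl_weights` confined to the window.
#' @export
restrict_weights <- function(weights, range, state = NULL) {
  stopifnot(inherits(weights, "wl_weights"), length(range) == 2L)
  b <- weights$bins
  keep <- b$edges[-1L] > range[1L] & b$edges[-(b$n_bins + 1L)] < range[2L]
  out <- weights
  out$log_states[!keep] <- NA_real_
  out$log_weight[!keep] <- NA_real_
  out$visited <- out$visited & keep
  if (!is.null(state)) {
    stopifnot(inherits(state, "grn"))
    out$state <- state$J
    out$state_f <- NA_real_
    out$state_output <- state$output
  }
  out
}
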