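#' Noise specification
#'
#' Input noise adds an independent uniform draw in
#' `[-amplitude, amplitude]` to the input signal I at every time step (I
#' may transiently go negative; this is permitted). Internal noise adds an
#' independent uniform draw `xi_ij` to the expression `x_j` as seen by
#' each regulated gene i, per existing regulatory pair and per step. The
#' default amplitudes are 0.3 for input noise and 0.1 for internal noise.
#'
#' @param kind `"input"` or `"internal"`.
#' @param amplitude half-width of the uniform noise; defaults to 0.3
#'   (input) or 0.1 (internal).
#' @return a list of class `noise_spec`.
#' @export
noise_spec <- function(kind = c("input", "internal"), amplitude = NULL) {
  kind <- match.arg(kind)
  if (is.null(amplitude)) amplitude <- if (kind == "input") 0.3 else 0.1
  stopifnot(amplitude >= 0)
  structure(list(kind = kind, amplitude = amplitude), class = "noise_spec")
}

#' Noise-robustness protocol
#'
#' Runs the 0 -> 1 -> 0 step protocol once without noise and once with the
#' given noise, and reports whether the network follows the input in each
#' case. A *noise-induced response* (NIR) is flagged when the network
#' fails to follow deterministically but succeeds under noise — the noise
#' releases it from the wrong fixed point.
#'
#' @param net a `grn` with assigned output.
#' @param params a [dyn_params()].
#' @param spec a [noise_spec()].
#' @param ... further arguments passed to [step_protocol()].
#' @return a list of class `noise_protocol` with `follows`,
#'   `follows_noisy` and `nir`.
#' @export
noise_protocol <- function(net, params = dyn_params(),
                           spec = noise_spec("input"), ...) {
  clean <- step_protocol(net, params, ...)
  noisy <- step_protocol(net, params, noise = spec, ...)
  structure(list(follows = clean$follows,
                 follows_noisy = noisy$follows,
                 nir = !clean$follows && noisy$follows,
                 spec = spec, clean = clean, noisy = noisy),
            class = "noise_protocol")
}

#' @export
print.noise_protocol <- function(x, ...) {
  cat(sprintf("Noise protocol (%s noise, amplitude %g):\n",
              x$spec$kind, x$spec$amplitude))
  cat(sprintf("  follows without noise: %s; with noise: %s; NIR: %s\n",
              x$follows, x$follows_noisy, x$nir))
  invisible(x)
}

new_mutation_scan <- function(sites, f_prime, threshold, kind,
                              direction = c("lethal", "robust")) {
  direction <- match.arg(direction)
  lethal <- if (direction == "lethal") f_prime < threshold else NULL
  structure(list(sites = sites, f_prime = f_prime,
                 threshold = threshold, kind = kind,
                 lethal = lethal,
                 n_lethal = if (is.null(lethal)) NA_integer_ else sum(lethal),
                 robust_fraction = if (direction == "robust") {
                   if (length(f_prime)) mean(f_prime >= threshold) else NA_real_
                 } else NA_real_),
            class = "mutation_scan")
}

#' Single-edge deletion scan
#'
#' Deletes each existing edge in turn, re-evaluates the mutant fitness
#' `f'` with the input and output genes held fixed, and restores the
#' edge. Edges whose deletion drops `f'` below `lethal_threshold`
#' (default 0.9) are lethal; their count is `n_L`. The scan is
#' non-destructive.
#'
#' @param net a `grn` with assigned output.
#' @param params a [dyn_params()].
#' @param lethal_threshold mutant-fitness cutoff below which a deletion is
#'   lethal.
#' @return a `mutation_scan` with per-edge sites (`i` regulated, `j`
#'   regulator, `sign`), `f_prime`, `lethal`, `n_lethal`.
#' @export
edge_deletion_scan <- function(net, params = dyn_params(),
                               lethal_threshold = 0.9) {
  stopifnot(inherits(net, "grn"), !is.na(net$output))
  res <- cpp_edge_deletion_scan(net$J, net$input - 1L, net$output - 1L,
                                unclass(params))
  new_mutation_scan(data.frame(i = res$i + 1L, j = res$j + 1L,
                               sign = res$sign),
                    res$f_prime, lethal_threshold, "edge_deletion")
}

#' Single-gene knockout scan
#'
#' Silences each gene other than the input and output genes in turn: its
#' expression is clamped to 0 and its regulatory row and column are
#' zeroed, so the gene neither regulates nor is regulated. The mutant
#' fitness `f'` is evaluated with the output fixed, and the gene restored.
#' Lethal genes (`f' < lethal_threshold`) are counted as `n_LN`.
#'
#' @inheritParams edge_deletion_scan
#' @return a `mutation_scan` with per-gene `sites$node`, `f_prime`,
#'   `lethal`, `n_lethal`.
#' @export
node_knockout_scan <- function(net, params = dyn_params(),
                               lethal_threshold = 0.9) {
  stopifnot(inherits(net, "grn"), !is.na(net$output))
  nodes <- setdiff(seq_len(net$n_genes), c(net$input, net$output))
  res <- cpp_node_knockout_scan(net$J, net$input - 1L, net$output - 1L,
                                unclass(params), as.integer(nodes) - 1L)
  new_mutation_scan(data.frame(node = res$node + 1L), res$f_prime,
                    lethal_threshold, "node_knockout")
}

#' Single-edge addition scan
#'
#' Adds an edge at each admissible empty position (off-diagonal, reverse
#' direction also empty), for each sign in `signs`, re-evaluates `f'`
#' with the output fixed, and removes it again. `robust_fraction` is the
#' share of additions keeping `f' >= high_threshold`; a network at full
#' edge capacity has no admissible addition and reports `NA`.
#'
#' @inheritParams edge_deletion_scan
#' @param high_threshold mutant-fitness cutoff above which an addition
#'   counts as fitness-preserving; mirrors the deletion lethality
#'   threshold so a single criterion is used throughout.
#' @param signs signs to try per empty position.
#' @return a `mutation_scan` with per-site `i`, `j`, `sign`, `f_prime`
#'   and `robust_fraction`.
#' @export
edge_addition_scan <- function(net, params = dyn_params(),
                               high_threshold = 0.9, signs = c(-1L, 1L)) {
  stopifnot(inherits(net, "grn"), !is.na(net$output),
            all(signs %in% c(-1L, 1L)))
  res <- cpp_edge_addition_scan(net$J, net$input - 1L, net$output - 1L,
                                unclass(params), as.integer(signs))
  new_mutation_scan(data.frame(i = res$i + 1L, j = res$j + 1L,
                               sign = res$sign),
                    res$f_prime, high_threshold, "edge_addition",
                    direction = "robust")
}

#' @export
print.mutation_scan <- function(x, ...) {
  cat(sprintf("Mutation scan (%s): %d sites, threshold %g\n",
              x$kind, length(x$f_prime), x$threshold))
  if (!is.na(x$n_lethal))
    cat(sprintf("  lethal sites: %d\n", x$n_lethal))
  if (!is.na(x$robust_fraction))
    cat(sprintf("  fitness-preserving fraction: %.3f\n", x$robust_fraction))
  invisible(x)
}

#' Select toggle switches without a lethal edge (TSwoLE)
#'
#' Given an ensemble of networks with their switch classes and edge
#' deletion scans, returns the indices of networks that are toggle
#' switches and have no lethal edge — the subset found to be notably
#' robust against both edge deletion and edge addition.
#'
#' @param ensemble list of `grn` objects.
#' @param classes character vector of switch classes (from
#'   [classify_switch()]), parallel to `ensemble`.
#' @param deletion_scans list of `mutation_scan` results, parallel to
#'   `ensemble`.
#' @return integer indices into `ensemble`.
#' @export
tswole_filter <- function(ensemble, classes, deletion_scans) {
  stopifnot(length(ensemble) == length(classes),
            length(ensemble) == length(deletion_scans))
  if (!length(ensemble)) return(integer())
  nl <- vapply(deletion_scans, function(s) s$n_lethal, integer(1))
  which(classes == "toggle" & nl == 0L)
}
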