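#' Count triangular three-gene motifs
#'
#' Enumerates all unordered gene triples carrying exactly three edges.
#' Because self- and mutual regulation are excluded, such triads are
#' always triangles: either a directed 3-cycle (feedback loop, FBL) or a
#' configuration where one gene regulates two and one is regulated by two
#' (feedforward loop, FFL). A loop is positive (FBL) / coherent (FFL) when
#' the product of its three interaction signs is `+1`, i.e. it contains an
#' even number of repressions, and negative / incoherent otherwise.
#'
#' @param net a `grn`.
#' @return named integer vector of class `motif_counts` with components
#'   `pos_fbl`, `neg_fbl`, `pos_ffl`, `neg_ffl`.
#' @export
count_motifs <- function(net) {
  stopifnot(inherits(net, "grn"))
  structure(cpp_count_motifs(net$J), class = "motif_counts")
}

#' @export
print.motif_counts <- function(x, ...) {
  cat("Triangular motif counts:\n")
  cat(sprintf("  +FBL %d   -FBL %d   +FFL %d   -FFL %d\n",
              x[["pos_fbl"]], x[["neg_fbl"]], x[["pos_ffl"]],
              x[["neg_ffl"]]))
  invisible(x)
}

#' Motif count distributions over an ensemble
#'
#' Tabulates, per motif class, the distribution of per-network counts
#' across an ensemble — the comparison of interest being a high-fitness
#' ensemble against the quasi-random low-fitness bin `f` in `[0, 0.01]`.
#'
#' @param ensemble list of `grn` objects.
#' @return a list of class `motif_histogram`: `counts` (matrix, one row
#'   per network, one column per class) and `totals`.
#' @export
ensemble_motif_histogram <- function(ensemble) {
  if (!length(ensemble)) stop("empty ensemble")
  counts <- t(vapply(ensemble, function(n) as.integer(count_motifs(n)),
                     integer(4)))
  colnames(counts) <- c("pos_fbl", "neg_fbl", "pos_ffl", "neg_ffl")
  structure(list(counts = counts, totals = colSums(counts),
                 n_networks = length(ensemble)),
            class = "motif_histogram")
}

#' @export
print.motif_histogram <- function(x, ...) {
  cat(sprintf("Motif census over %d networks\n", x$n_networks))
  cat("  totals: ", paste(names(x$totals), x$totals, sep = " = ",
                          collapse = ", "), "\n")
  cat("  mean per network: ",
      paste(names(x$totals), format(round(x$totals / x$n_networks, 2)),
            sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.motif_histogram <- function(x, ...) {
  cls <- colnames(x$counts)
  mx <- max(x$counts)
  tab <- sapply(cls, function(cl) tabulate(x$counts[, cl] + 1L, mx + 1L))
  graphics::matplot(0:mx, tab, type = "b", pch = 1:4, lty = 1,
                    xlab = "loops per network", ylab = "networks", ...)
  graphics::legend("topright", legend = c("+FBL", "-FBL", "+FFL", "-FFL"),
                   pch = 1:4, col = 1:4, bty = "n")
  invisible(x)
}
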