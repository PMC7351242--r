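#' Construct a gene regulatory network object
#'
#' A `grn` bundles the signed interaction matrix with the designated input
#' gene (always gene 1, where the external signal enters) and, once known,
#' the output gene. `J[i, j]` is the regulation exerted by gene `j` on gene
#' `i`: `+1` activation, `-1` repression, `0` none. The diagonal must be
#' zero (no self-regulation) and no two genes may regulate each other
#' mutually.
#'
#' @param J integer matrix with entries in `{-1, 0, 1}`.
#' @param output output gene index, or `NA` if not yet assigned.
#' @return an object of class `grn` with fields `J`, `n_genes`, `n_edges`,
#'   `input`, `output`.
#' @seealso [random_grn()], [evaluate_fitness()], [structural_check()]
#' @export
grn <- function(J, output = NA_integer_) {
  J <- as.matrix(J)
  storage.mode(J) <- "integer"
  validate_interactions(J)
  n <- nrow(J)
  if (!is.na(output)) {
    output <- as.integer(output)
    if (output < 1L || output > n) stop("output gene index out of range")
    if (output == 1L) stop("output gene must differ from the input gene")
  }
  structure(list(J = J,
                 n_genes = n,
                 n_edges = sum(J != 0L),
                 input = 1L,
                 output = as.integer(output)),
            class = "grn")
}

validate_interactions <- function(J) {
  if (nrow(J) != ncol(J)) stop("interaction matrix must be square")
  if (nrow(J) < 2L) stop("a network needs at least 2 genes")
  bad <- which(!(J %in% c(-1L, 0L, 1L)))
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(J))
    stop(sprintf("entry at (%d, %d) is %s; must be -1, 0 or 1",
                 rc[1L], rc[2L], J[bad[1L]]))
  }
  d <- which(diag(J) != 0L)
  if (length(d))
    stop(sprintf("self-regulation at gene %d is not allowed", d[1L]))
  mut <- which(J != 0L & t(J) != 0L, arr.ind = TRUE)
  if (nrow(mut))
    stop(sprintf("mutual regulation between genes %d and %d is not allowed",
                 mut[1L, 1L], mut[1L, 2L]))
  invisible(J)
}

#' Generate a random network with exactly K edges
#'
#' Places `n_edges` regulatory edges uniformly at random among the
#' admissible positions (off-diagonal, at most one direction per gene
#' pair), each with an equiprobable `+1`/`-1` sign. Structural
#' reachability is *not* enforced here; it is checked downstream by
#' [structural_check()] or [evaluate_fitness()].
#'
#' @param n_genes number of genes N (at least 2).
#' @param n_edges number of edges K; at most `N (N - 1) / 2` because each
#'   unordered gene pair can carry at most one edge.
#' @return a `grn` with `output = NA`.
#' @examples
#' set.seed(1)
#' net <- random_grn(6, 15)
#' sum(net$J != 0)  # exactly 15
#' @export
random_grn <- function(n_genes, n_edges) {
  n_genes <- as.integer(n_genes)
  n_edges <- as.integer(n_edges)
  if (n_genes < 2L) stop("n_genes must be at least 2")
  cap <- (n_genes * (n_genes - 1L)) %/% 2L
  if (n_edges < 1L || n_edges > cap)
    stop(sprintf("n_edges must be between 1 and %d for %d genes",
                 cap, n_genes))
  grn(cpp_random_net(n_genes, n_edges))
}

#' Check structural validity of a network
#'
#' A network is admissible for fitness classification when the input gene
#' has a directed path to every other gene and every gene has a directed
#' path to the output gene, so that no gene is functionally disconnected.
#'
#' @param net a `grn`.
#' @param candidate_output gene index to test as output; must differ from
#'   the input gene.
#' @return a list with `input_reaches_all` (logical), `nodes_reaching`
#'   (logical vector: gene g has a path to `candidate_output`; a gene
#'   trivially reaches itself) and `violation` (`"none"`,
#'   `"input_unreachable"` or `"output_unreachable"`).
#' @export
structural_check <- function(net, candidate_output) {
  stopifnot(inherits(net, "grn"))
  candidate_output <- as.integer(candidate_output)
  if (candidate_output == net$input)
    stop("candidate output must differ from the input gene")
  if (candidate_output < 1L || candidate_output > net$n_genes)
    stop("candidate output out of range")
  J <- net$J != 0L
  reach_from_input <- reachable(J, net$input, forward = TRUE)
  reach_to_output <- reachable(J, candidate_output, forward = FALSE)
  violation <- if (!all(reach_from_input)) "input_unreachable"
               else if (!all(reach_to_output)) "output_unreachable"
               else "none"
  list(input_reaches_all = all(reach_from_input),
       nodes_reaching = reach_to_output,
       violation = violation)
}

# logical adjacency A[i, j]: edge j -> i; forward: nodes reachable from
# start along edges; backward: nodes having a path to start
reachable <- function(A, start, forward = TRUE) {
  n <- nrow(A)
  seen <- logical(n)
  seen[start] <- TRUE
  frontier <- start
  while (length(frontier)) {
    nxt <- if (forward) which(rowSums(A[, frontier, drop = FALSE]) > 0)
           else which(colSums(A[frontier, , drop = FALSE]) > 0)
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  seen
}

#' Elementary Monte Carlo move: relocate one edge
#'
#' Removes a uniformly chosen existing edge and places an edge at a
#' uniformly chosen admissible empty position (off-diagonal, with the
#' reverse direction also empty after the removal), keeping K constant.
#' By default the relocated edge receives a fresh random sign, mirroring
#' the generative symmetry of [random_grn()]; set `fresh_sign = FALSE` to
#' carry the old sign along.
#'
#' The proposal may be structurally invalid; accepting or rejecting it is
#' the sampler's responsibility.
#'
#' @param net a `grn`.
#' @param fresh_sign logical; randomize the sign of the relocated edge.
#' @return a new `grn` with the same number of edges.
#' @export
propose_edge_move <- function(net, fresh_sign = TRUE) {
  stopifnot(inherits(net, "grn"))
  grn(cpp_propose_move(net$J, isTRUE(fresh_sign)), output = net$output)
}

#' Describe a single mutation
#'
#' @param kind `"delete_edge"`, `"add_edge"` or `"knockout_node"`.
#' @param i,j target and source gene of the edge (edge kinds): the edge is
#'   the regulation from gene `j` onto gene `i`.
#' @param node gene to silence (`"knockout_node"` only).
#' @param sign `+1` or `-1` (`"add_edge"` only).
#' @return an object of class `grn_mutation`.
#' @export
mutation <- function(kind = c("delete_edge", "add_edge", "knockout_node"),
                     i = NULL, j = NULL, node = NULL, sign = NULL) {
  kind <- match.arg(kind)
  if (kind == "knockout_node") {
    if (is.null(node)) stop("knockout_node needs `node`")
  } else {
    if (is.null(i) || is.null(j)) stop(kind, " needs `i` and `j`")
    if (kind == "add_edge") {
      if (is.null(sign) || !(sign %in% c(-1L, 1L)))
        stop("add_edge needs sign +1 or -1")
    }
  }
  structure(list(kind = kind, i = as.integer(i %||% NA), j = as.integer(j %||% NA),
                 node = as.integer(node %||% NA),
                 sign = as.integer(sign %||% NA)),
            class = "grn_mutation")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply a mutation to a network
#'
#' Edge deletion zeroes the interaction; edge addition writes the given
#' sign into an admissible empty position; a gene knockout silences the
#' gene by zeroing its row and column (its expression is clamped to 0 in
#' the dynamics). The input and output designations are preserved and no
#' structural re-validation is performed: the mutant's fitness is whatever
#' the dynamics yield.
#'
#' @param net a `grn`.
#' @param mut a [mutation()].
#' @return the mutated `grn`.
#' @export
apply_mutation <- function(net, mut) {
  stopifnot(inherits(net, "grn"), inherits(mut, "grn_mutation"))
  J <- net$J
  switch(mut$kind,
    delete_edge = {
      if (J[mut$i, mut$j] == 0L)
        stop(sprintf("no edge from gene %d onto gene %d to delete",
                     mut$j, mut$i))
      J[mut$i, mut$j] <- 0L
    },
    add_edge = {
      if (mut$i == mut$j) stop("cannot add a self-regulating edge")
      if (J[mut$i, mut$j] != 0L)
        stop(sprintf("position (%d, %d) is already occupied", mut$i, mut$j))
      if (J[mut$j, mut$i] != 0L)
        stop(sprintf("reverse edge (%d, %d) exists: mutual regulation not allowed",
                     mut$j, mut$i))
      J[mut$i, mut$j] <- mut$sign
    },
    knockout_node = {
      if (mut$node == net$input) stop("cannot knock out the input gene")
      if (!is.na(net$output) && mut$node == net$output)
        stop("cannot knock out the output gene")
      J[mut$node, ] <- 0L
      J[, mut$node] <- 0L
    })
  out <- net
  out$J <- J
  out$n_edges <- sum(J != 0L)
  out
}

#' Enumerate every admissible network with N genes and K edges
#'
#' Brute-force generator used as an exact oracle for the sampler on small
#' systems: every placement of `n_edges` among the unordered gene pairs,
#' crossed with every orientation and sign assignment, each exactly once.
#'
#' @param n_genes,n_edges network size.
#' @param cap refuse enumeration beyond this many networks.
#' @return a list of `grn` objects.
#' @export
enumerate_networks <- function(n_genes, n_edges, cap = 1e7) {
  size <- cpp_enumeration_size(n_genes, n_edges)
  if (size > cap)
    stop(sprintf("enumeration would produce %.3g networks (cap %.3g)",
                 size, cap))
  lapply(cpp_enumerate(n_genes, n_edges), grn)
}

#' @export
print.grn <- function(x, ...) {
  cat(sprintf("Gene regulatory network: %d genes, %d edges (C = %.2f)\n",
              x$n_genes, x$n_edges, 2 * x$n_edges / x$n_genes))
  cat(sprintf("  input gene: %d   output gene: %s\n", x$input,
              if (is.na(x$output)) "unassigned" else x$output))
  cat(sprintf("  activations: %d   repressions: %d\n",
              sum(x$J == 1L), sum(x$J == -1L)))
  invisible(x)
}

#' @export
plot.grn <- function(x, ...) {
  if (!requireNamespace("igraph", quietly = TRUE))
    stop("plotting a grn requires the igraph package")
  idx <- which(x$J != 0L, arr.ind = TRUE)
  g <- igraph::graph_from_edgelist(cbind(idx[, 2L], idx[, 1L]))
  igraph::E(g)$color <- ifelse(x$J[idx] > 0L, "steelblue", "firebrick")
  lab <- as.character(seq_len(x$n_genes))
  lab[x$input] <- paste0("I:", lab[x$input])
  if (!is.na(x$output)) lab[x$output] <- paste0("O:", lab[x$output])
  igraph::plot.igraph(g, vertex.label = lab, edge.arrow.size = 0.4, ...)
  invisible(x)
}
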