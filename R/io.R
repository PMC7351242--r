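#' Read an interaction matrix from CSV
#'
#' The file holds N rows and N columns of integers in `{-1, 0, 1}`, entry
#' (row i, column j) being the regulation from gene j onto gene i. An
#' optional header `g1..gN` is accepted. Gene 1 is the input gene.
#' Violations of the structural invariants are reported with their
#' coordinates.
#'
#' @param path CSV file path.
#' @param output optional output gene index to assign.
#' @return a `grn`.
#' @export
read_grn_csv <- function(path, output = NA_integer_) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("[A-Za-z]", first)
  M <- as.matrix(read.table(path, sep = ",", header = has_header,
                            row.names = NULL))
  dimnames(M) <- NULL
  if (any(is.na(M)) || any(M != round(M)))
    stop("interaction matrix entries must be integers")
  grn(M, output = output)
}

#' Write an interaction matrix to CSV
#'
#' @param net a `grn`.
#' @param path destination path.
#' @param header write a `g1..gN` header line.
#' @return `path`, invisibly.
#' @export
write_grn_csv <- function(net, path, header = TRUE) {
  stopifnot(inherits(net, "grn"))
  M <- net$J
  colnames(M) <- if (header) paste0("g", seq_len(net$n_genes)) else NULL
  write.table(M, path, sep = ",", row.names = FALSE, col.names = header,
              quote = FALSE)
  invisible(path)
}

#' Write an ensemble of networks as JSON Lines
#'
#' One record per network: `{"f": ..., "output_node": ..., "matrix":
#' [[...], ...], "meta": {...}}`. Fitness is taken from the `"f"`
#' attribute set by [entropic_sample()], or re-evaluated when absent.
#'
#' @param ensemble list of `grn` objects.
#' @param path destination path.
#' @param params a [dyn_params()] used if fitness must be re-evaluated.
#' @param meta named list stored verbatim in every record.
#' @return `path`, invisibly.
#' @export
write_ensemble_jsonl <- function(ensemble, path, params = dyn_params(),
                                 meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (net in ensemble) {
    f <- attr(net, "f")
    out <- net$output
    if (is.null(f)) {
      fit <- evaluate_fitness(net, params)
      f <- fit$f
      if (is.na(out)) out <- fit$output
    }
    rec <- list(f = f, output_node = out,
                matrix = unname(apply(net$J, 1L, as.integer,
                                      simplify = FALSE)),
                meta = meta)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Read a JSON Lines ensemble archive
#'
#' @param path archive written by [write_ensemble_jsonl()].
#' @return list of `grn` objects with the `"f"` attribute set.
#' @export
read_ensemble_jsonl <- function(path) {
  lines <- readLines(path)
  lapply(lines[nzchar(lines)], function(l) {
    rec <- jsonlite::fromJSON(l, simplifyMatrix = TRUE)
    net <- grn(rec$matrix, output = rec$output_node)
    attr(net, "f") <- rec$f
    net
  })
}

#' Write a density-of-states table as TSV
#'
#' Columns: `bin_lo`, `bin_hi`, `log_states`, `prob`, `count`, `n_runs`.
#'
#' @param density a `grn_density`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_density_tsv <- function(density, path) {
  stopifnot(inherits(density, "grn_density"))
  tab <- density$table
  tab$n_runs <- density$n_runs
  write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Checkpoint learned weights to TSV and restore them
#'
#' Stores the per-bin log number of states plus the final chain state so
#' a measurement run can resume without re-learning.
#'
#' @param weights a `wl_weights`.
#' @param path destination path.
#' @return `path`, invisibly (`write_weights_tsv`); a `wl_weights`
#'   (`read_weights_tsv`).
#' @export
write_weights_tsv <- function(weights, path) {
  stopifnot(inherits(weights, "wl_weights"))
  hdr <- sprintf("# n_genes=%d n_edges=%d n_bins=%d converged=%s state_f=%.17g state_output=%d a=%g b=%g tol=%g max_steps=%d avg_window=%d fresh_sign=%s",
                 weights$n_genes, weights$n_edges, weights$bins$n_bins,
                 weights$converged, weights$state_f, weights$state_output,
                 weights$params$a, weights$params$b, weights$params$tol,
                 weights$params$max_steps, weights$params$avg_window,
                 weights$control$fresh_sign)
  state <- paste0("# state=", paste(as.integer(weights$state), collapse = ","))
  tab <- data.frame(bin = seq_len(weights$bins$n_bins),
                    log_states = weights$log_states,
                    visit_histogram = weights$visit_histogram)
  writeLines(c(hdr, state), path)
  suppressWarnings(write.table(tab, path, sep = "\t", row.names = FALSE,
                               quote = FALSE, append = TRUE))
  invisible(path)
}

#' @rdname write_weights_tsv
#' @export
read_weights_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(sub("^# ", "", lines[1L]), " ")[[1L]]
  kv <- setNames(sub("^[^=]*=", "", hdr), sub("=.*$", "", hdr))
  state_vals <- as.integer(strsplit(sub("^# state=", "", lines[2L]),
                                    ",")[[1L]])
  tab <- read.table(text = lines[-(1:2)], sep = "\t", header = TRUE)
  n <- as.integer(kv[["n_genes"]])
  params <- dyn_params(a = as.numeric(kv[["a"]]), b = as.numeric(kv[["b"]]),
                       tol = as.numeric(kv[["tol"]]),
                       max_steps = as.integer(kv[["max_steps"]]),
                       avg_window = as.integer(kv[["avg_window"]]))
  structure(list(log_weight = -tab$log_states,
                 log_states = tab$log_states,
                 visit_histogram = tab$visit_histogram,
                 visited = !is.na(tab$log_states),
                 converged = as.logical(kv[["converged"]]),
                 final_mod_factor = NA_real_,
                 n_proposals = NA_real_, n_stages = NA_integer_,
                 accept_rate = NA_real_,
                 state = matrix(state_vals, n, n),
                 state_f = as.numeric(kv[["state_f"]]),
                 state_output = as.integer(kv[["state_output"]]),
                 bins = fitness_bins(as.integer(kv[["n_bins"]])),
                 n_genes = n, n_edges = as.integer(kv[["n_edges"]]),
                 params = params,
                 control = wl_control(fresh_sign = as.logical(kv[["fresh_sign"]]))),
            class = "wl_weights")
}

#' Export a simulated trajectory as TSV
#'
#' Long format with columns `step`, `gene`, `expression`.
#'
#' @param net a `grn`.
#' @param path destination path.
#' @param ... passed to [simulate.grn()].
#' @return `path`, invisibly.
#' @export
write_trajectory_tsv <- function(net, path, ...) {
  tr <- simulate(net, ...)
  long <- data.frame(step = rep(seq_len(nrow(tr)), ncol(tr)),
                     gene = rep(seq_len(ncol(tr)), each = nrow(tr)),
                     expression = as.numeric(tr))
  write.table(long, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
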