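#' Run configuration
#'
#' Bundles every tunable of the pipeline into one validated list. All
#' stage-level constants default to the study conditions: sigmoid
#' steepness `a = 1`, threshold `b = 0`, 100 fitness bins, samples every
#' 10 MCS, 5 measurement runs, bistability threshold 0.01 on a 0.001
#' input grid, lethal threshold 0.9, input/internal noise amplitudes
#' 0.3/0.1. Each stochastic stage derives its own seed from `seed`
#' deterministically, so adding later analyses never perturbs earlier
#' stages' randomness.
#'
#' @param n_genes number of genes N.
#' @param n_edges number of edges K; alternatively `connectivity` C with
#'   `K = C N / 2`.
#' @param connectivity mean degree C.
#' @param n_bins fitness bins.
#' @param params a [dyn_params()].
#' @param control a [wl_control()].
#' @param n_mcs measurement MCS per run.
#' @param sample_interval MCS between recorded samples.
#' @param n_runs measurement runs.
#' @param keep_range fitness interval whose networks are retained.
#' @param keep_max retained-network cap per run.
#' @param delta_i input sweep step.
#' @param bistable_threshold branch gap declaring bistability.
#' @param lethal_threshold mutant-fitness lethality cutoff.
#' @param input_noise,internal_noise noise amplitudes.
#' @param seed master seed.
#' @return a list of class `grn_config`.
#' @export
grn_config <- function(n_genes, n_edges = NULL, connectivity = NULL,
                       n_bins = 100L, params = dyn_params(),
                       control = wl_control(), n_mcs = 1e4,
                       sample_interval = 10L, n_runs = 5L,
                       keep_range = c(0.99, 1), keep_max = 2000L,
                       delta_i = 0.001, bistable_threshold = 0.01,
                       lethal_threshold = 0.9, input_noise = 0.3,
                       internal_noise = 0.1, seed = 1L) {
  if (is.null(n_edges)) {
    if (is.null(connectivity)) stop("give n_edges or connectivity")
    k2 <- connectivity * n_genes
    if (k2 %% 2 != 0) stop("connectivity * n_genes must be even")
    n_edges <- k2 / 2
  }
  stopifnot(delta_i > 0, bistable_threshold > 0, lethal_threshold > 0)
  structure(list(n_genes = as.integer(n_genes),
                 n_edges = as.integer(n_edges), n_bins = as.integer(n_bins),
                 params = params, control = control, n_mcs = n_mcs,
                 sample_interval = as.integer(sample_interval),
                 n_runs = as.integer(n_runs), keep_range = keep_range,
                 keep_max = as.integer(keep_max), delta_i = delta_i,
                 bistable_threshold = bistable_threshold,
                 lethal_threshold = lethal_threshold,
                 input_noise = input_noise, internal_noise = internal_noise,
                 seed = as.integer(seed)),
            class = "grn_config")
}

# deterministic per-stage child seed from the master seed
stage_seed <- function(config, label) {
  config$seed + sum(utf8ToInt(label) * seq_along(utf8ToInt(label))) %% 100003L
}

#' Run the full analysis pipeline
#'
#' Landscape estimation (Wang-Landau learning + entropic measurement),
#' extraction of the ensemble in `keep_range`, then per-network
#' bistability classification, noise protocols, mutation scans and motif
#' census. Artifacts (density TSV, weights checkpoint, ensemble JSONL,
#' per-network robustness report JSON, manifest) are written under
#' `out_dir`.
#'
#' @param config a [grn_config()].
#' @param out_dir output directory, created if missing.
#' @param analyses which per-network analyses to run on the retained
#'   ensemble.
#' @return (invisibly) a list with the landscape, the retained ensemble
#'   and a per-network report data.frame.
#' @export
run_pipeline <- function(config, out_dir = ".",
                         analyses = c("bistability", "noise", "mutation",
                                      "motifs")) {
  stopifnot(inherits(config, "grn_config"))
  analyses <- match.arg(analyses, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  set.seed(stage_seed(config, "landscape"))
  land <- grn_landscape(config$n_genes, config$n_edges,
                        bins = fitness_bins(config$n_bins),
                        params = config$params, control = config$control,
                        n_mcs = config$n_mcs,
                        sample_interval = config$sample_interval,
                        n_runs = config$n_runs,
                        keep_range = config$keep_range,
                        keep_max = config$keep_max)
  write_density_tsv(land$density, file.path(out_dir, "density.tsv"))
  write_weights_tsv(land$weights, file.path(out_dir, "weights.tsv"))
  ens <- land$samples$networks
  write_ensemble_jsonl(ens, file.path(out_dir, "ensemble.jsonl"),
                       params = config$params,
                       meta = list(n_genes = config$n_genes,
                                   n_edges = config$n_edges,
                                   keep_range = config$keep_range))

  report <- data.frame(f = vapply(ens, function(n) attr(n, "f"), numeric(1)))
  if ("bistability" %in% analyses && length(ens)) {
    set.seed(stage_seed(config, "bistability"))
    scans <- lapply(ens, hysteresis_scan, params = config$params,
                    delta_i = config$delta_i,
                    threshold = config$bistable_threshold)
    report$bistable <- vapply(scans, `[[`, logical(1), "bistable")
    report$switch_class <- vapply(scans, classify_switch, character(1))
  }
  if ("noise" %in% analyses && length(ens)) {
    set.seed(stage_seed(config, "noise"))
    np_in <- lapply(ens, noise_protocol, params = config$params,
                    spec = noise_spec("input", config$input_noise))
    np_int <- lapply(ens, noise_protocol, params = config$params,
                     spec = noise_spec("internal", config$internal_noise))
    report$follows <- vapply(np_in, `[[`, logical(1), "follows")
    report$follows_noisy_input <- vapply(np_in, `[[`, logical(1),
                                         "follows_noisy")
    report$nir_input <- vapply(np_in, `[[`, logical(1), "nir")
    report$follows_internal_noise <- vapply(np_int, `[[`, logical(1),
                                            "follows_noisy")
    report$nir_internal <- vapply(np_int, `[[`, logical(1), "nir")
  }
  if ("mutation" %in% analyses && length(ens)) {
    set.seed(stage_seed(config, "mutation"))
    del <- lapply(ens, edge_deletion_scan, params = config$params,
                  lethal_threshold = config$lethal_threshold)
    ko <- lapply(ens, node_knockout_scan, params = config$params,
                 lethal_threshold = config$lethal_threshold)
    report$n_L <- vapply(del, `[[`, integer(1), "n_lethal")
    report$n_LN <- vapply(ko, `[[`, integer(1), "n_lethal")
  }
  if ("motifs" %in% analyses && length(ens)) {
    mc <- ensemble_motif_histogram(ens)
    report <- cbind(report, as.data.frame(mc$counts))
  }
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  manifest <- list(package_version = as.character(utils::packageVersion("grnland")),
                   config = unclass(config)[setdiff(names(config),
                                                    c("params", "control"))],
                   params = unclass(config$params),
                   control = unclass(config$control),
                   n_retained = length(ens))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(landscape = land, ensemble = ens, report = report))
}

#' Read a flat key: value configuration file
#'
#' Lines of the form `key: value`; `#` starts a comment. Recognized keys
#' are the arguments of [grn_config()] (scalar-valued ones; `keep_range`
#' as `lo,hi`), plus `a`, `b`, `final_log_f`, `max_proposals`.
#'
#' @param path configuration file.
#' @return a [grn_config()].
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl(":", lines)])
  kv <- strsplit(lines, "\\s*:\\s*")
  vals <- setNames(vapply(kv, `[`, character(1), 2L),
                   vapply(kv, `[`, character(1), 1L))
  num <- function(k, d) if (k %in% names(vals)) as.numeric(vals[[k]]) else d
  args <- list(n_genes = num("n_genes", stop("n_genes is required")),
               n_edges = if ("n_edges" %in% names(vals))
                 as.integer(vals[["n_edges"]]) else NULL,
               connectivity = if ("connectivity" %in% names(vals))
                 as.numeric(vals[["connectivity"]]) else NULL,
               n_bins = num("n_bins", 100),
               params = dyn_params(a = num("a", 1), b = num("b", 0)),
               control = wl_control(final_log_f = num("final_log_f", 1e-8),
                                    max_proposals = num("max_proposals", 5e7)),
               n_mcs = num("n_mcs", 1e4),
               sample_interval = num("sample_interval", 10),
               n_runs = num("n_runs", 5),
               delta_i = num("delta_i", 0.001),
               bistable_threshold = num("bistable_threshold", 0.01),
               lethal_threshold = num("lethal_threshold", 0.9),
               input_noise = num("input_noise", 0.3),
               internal_noise = num("internal_noise", 0.1),
               seed = num("seed", 1))
  if ("keep_range" %in% names(vals))
    args$keep_range <- as.numeric(strsplit(vals[["keep_range"]], ",")[[1L]])
  do.call(grn_config, args)
}
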