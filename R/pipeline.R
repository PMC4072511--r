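# End-to-end pipeline driver: simulate -> process -> features -> motifs ->
# fit -> report, with one master seed from which each stage derives its own
# seed, and a manifest recording the configuration and per-stage row counts.

#' Default pipeline configuration
#'
#' Every parameter with a study-anchored value defaults to it: Butterworth
#' cutoff 0.15, SNR threshold 5 within the first 6 h, GC/FE window sizes
#' 50/40 nt, motif k-mers 6-8 with BH FDR 0.05, clan merge threshold 0.6,
#' 80/20 cross-validation, four replicates of 24 h traces for 240 introns.
#' The configuration round-trips losslessly through YAML.
#'
#' @param seed master seed; per-stage seeds are derived with
#'   [derive_seed()].
#' @param ... named overrides of nested fields, e.g.
#'   `simulate = list(n_introns = 24)`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = as.integer(seed),
    simulate = list(n_introns = 240L, n_replicates = 4L, duration_h = 24,
                    sampling_interval_h = 0.25, noise_sd = 1,
                    background_level = 50, k_expr = 10000,
                    insertion_offset = 195L),
    process = list(cutoff = 0.15, snr_threshold = 5, window_h = 6),
    features = list(gc_window = 50L, fe_window = 40L,
                    offsets = c(-30L, -12L, -6L, 0L, 3L, 12L, 30L),
                    backend = "nussinov_proxy", include_structure = TRUE),
    motifs = list(k_range = 6:8, fdr_alpha = 0.05, merge_threshold = 0.6,
                  n_perm = 200L, max_motifs = 20L),
    model = list(max_k = 38L, min_improve = 1e-4, gate_alpha = 0.05,
                 frac_train = 0.8, cv_repeats = 20L, n_perm = 200L))
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    else cfg[[nm]] <- dots[[nm]]
  }
  structure(cfg, class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#' @param config a [pipeline_config()].
#' @param path YAML path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  structure(yaml::read_yaml(path), class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Simulates a library (unless a plate CSV and intron FASTA are supplied
#' via `config$input`), processes the traces into splicing-efficiency
#' indices, builds the feature database, discovers and localizes motifs on
#' the spliced strains, assembles the greedy predictor of mean expression,
#' cross-validates it, and writes all artifacts plus a manifest into
#' `out_dir`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the main in-memory results
#'   (`results`, `features`, `motifs`, `model`, `cv_rho`, `manifest`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, idx, code) {
    tryCatch(code, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  manifest <- list(seed = config$seed, config = unclass(config))

  # -- simulate ------------------------------------------------------------
  # ground-truth efficiency is a linear function of three sequence features
  # (junction folding energy plus one enhancer and one silencer motif), so
  # the downstream model has signal to recover
  sim <- config$simulate
  lib <- stage("simulate", 1, {
    simulate_recovery_library(sim$n_introns,
                              insertion_offset = sim$insertion_offset,
                              seed = derive_seed(config$seed, 1L))
  })
  introns <- lib$introns
  constructs <- lib$constructs
  design <- plate_design(n_replicates = sim$n_replicates,
                         duration_h = sim$duration_h,
                         sampling_interval_h = sim$sampling_interval_h,
                         noise_sd = sim$noise_sd,
                         background_level = sim$background_level,
                         k_expr = sim$k_expr,
                         seed = derive_seed(config$seed, 2L))
  plate <- stage("simulate", 1,
                 simulate_plate_timeseries(introns, design))
  write_intron_fasta(introns, file.path(out_dir, "introns.fasta"),
                     file.path(out_dir, "introns.tsv"))
  write_plate_csv(plate, file.path(out_dir, "plate.csv"))
  manifest$stages$simulate <- list(n_introns = length(introns),
                                   plate_rows = nrow(plate))

  # -- process -------------------------------------------------------------
  proc <- config$process
  results <- stage("process", 2,
                   process_plate(plate, snr_threshold = proc$snr_threshold,
                                 window_end_h = proc$window_h,
                                 cutoff = proc$cutoff))
  readr::write_tsv(results, file.path(out_dir, "results.tsv"), na = "NA")
  manifest$stages$process <- list(n_strains = nrow(results),
                                  n_spliced = sum(results$spliced))

  # -- motifs --------------------------------------------------------------
  mot <- config$motifs
  lib <- results[results$role == "YiFP", ]
  eff <- setNames(lib$splicing_efficiency, lib$strain)
  spliced_ids <- lib$strain[lib$spliced]
  seqs <- setNames(vapply(introns, `[[`, "", "sequence"),
                   vapply(introns, `[[`, "", "id"))
  motifs <- stage("motifs", 3, {
    y <- eff[spliced_ids]
    qs <- quantile(y, c(1 / 3, 2 / 3), na.rm = TRUE)
    found <- discover_motifs(seqs[names(y)[y >= qs[2]]],
                             seqs[names(y)[y <= qs[1]]],
                             k_range = mot$k_range,
                             alpha_fdr = mot$fdr_alpha,
                             max_motifs = mot$max_motifs)
    merge_clans(found, threshold = mot$merge_threshold)
  })
  if (length(motifs)) {
    write_meme(motifs, file.path(out_dir, "motifs.meme"))
    clans <- tibble::tibble(
      motif_id = vapply(motifs, `[[`, "", "id"),
      clan = vapply(motifs, `[[`, 0L, "clan"),
      class = vapply(motifs, `[[`, "", "class"),
      enrichment_p = vapply(motifs, `[[`, 0, "enrichment_p"))
    readr::write_tsv(clans, file.path(out_dir, "clans.tsv"), na = "NA")
  }
  manifest$stages$motifs <- list(n_motifs = length(motifs))

  # -- features ------------------------------------------------------------
  fea <- config$features
  fcfg <- feature_config(gc_window = fea$gc_window,
                         fe_window = fea$fe_window,
                         gc_offsets = fea$offsets,
                         fe_offsets = fea$offsets,
                         backend = fea$backend,
                         include_structure = fea$include_structure)
  X <- stage("features", 4,
             build_feature_matrix(constructs, motifs, fcfg))
  fm <- tibble::as_tibble(as.data.frame(X), rownames = "intron")
  readr::write_tsv(fm, file.path(out_dir, "features.tsv"), na = "NA")
  jsonlite::write_json(attr(X, "feature_info"),
                       file.path(out_dir, "features.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest$stages$features <- list(n_features = ncol(X))

  # -- fit -----------------------------------------------------------------
  mod <- config$model
  model <- stage("fit", 5, {
    greedy_assemble(X[spliced_ids, , drop = FALSE], eff[spliced_ids],
                    max_k = mod$max_k, min_improve = mod$min_improve,
                    gate_alpha = mod$gate_alpha)
  })
  write_model_json(model, file.path(out_dir, "model.json"))
  cv_rho <- stage("fit", 5, {
    keep <- match(spliced_ids, vapply(constructs, `[[`, "", "intron_id"))
    cross_validate(constructs[keep], eff[spliced_ids], config = fcfg,
                   discover = TRUE, frac_train = mod$frac_train,
                   n_repeats = mod$cv_repeats,
                   seed = derive_seed(config$seed, 5L),
                   k_range = mot$k_range, alpha_fdr = mot$fdr_alpha,
                   max_motifs = mot$max_motifs, max_k = mod$max_k,
                   min_improve = mod$min_improve,
                   gate_alpha = mod$gate_alpha)
  })
  readr::write_tsv(tibble::tibble(repeat_i = seq_along(cv_rho),
                                  test_rho = cv_rho),
                   file.path(out_dir, "cv.tsv"), na = "NA")
  manifest$stages$fit <- list(n_selected = length(model$selected),
                              final_rho = if (length(model$cum_rho))
                                tail(model$cum_rho, 1) else 0,
                              cv_median_rho = median(cv_rho))

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(results = results, features = X, motifs = motifs,
                 model = model, cv_rho = cv_rho, manifest = manifest))
}
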