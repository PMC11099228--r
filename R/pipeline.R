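# Study orchestration: bidirectional UVMR with reverse-causality exclusion,
# sensitivity gating, the mediation screen, FDR, and report emission.

#' Read and validate a study configuration file
#'
#' YAML schema: `exposures`, `mediators`, `outcomes` (lists of summary-stat
#' TSV paths), optional `ld_matrix` path, optional `thresholds` (any
#' [mr_config()] key), and `seed`. Every referenced path must exist.
#'
#' @param path YAML file path.
#' @return List with `exposures`, `mediators`, `outcomes` (named lists of
#'   [summary_dataset()]), `ld`, and `config` (an [mr_config()]).
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) config_error(paste0("config file not found: ", path))
  cfg <- yaml::read_yaml(path)
  for (key in c("exposures", "outcomes")) {
    if (is.null(cfg[[key]]) || length(cfg[[key]]) == 0) {
      config_error(paste0("config must list at least one path under '", key, "'"))
    }
  }
  all_paths <- unlist(cfg[c("exposures", "mediators", "outcomes")])
  if (!is.null(cfg$ld_matrix)) all_paths <- c(all_paths, cfg$ld_matrix)
  missing <- all_paths[!file.exists(all_paths)]
  if (length(missing)) {
    config_error(paste0("referenced path(s) do not exist: ",
                        paste(missing, collapse = ", ")))
  }
  read_set <- function(paths, scale) {
    out <- lapply(paths, read_summary_stats, trait_scale = scale, quiet = TRUE)
    names(out) <- vapply(out, trait_id, character(1))
    out
  }
  thresholds <- cfg$thresholds %||% list()
  if (!is.null(cfg$seed)) thresholds$seed <- cfg$seed
  config <- do.call(mr_config, thresholds)
  list(exposures = read_set(cfg$exposures, "continuous"),
       mediators = read_set(cfg$mediators %||% character(0), "continuous"),
       outcomes = read_set(cfg$outcomes, "log_odds"),
       ld = if (!is.null(cfg$ld_matrix)) read_ld_matrix(cfg$ld_matrix) else NULL,
       config = config)
}

uvmr_pair_row <- function(exposure, outcome, ld, config, p_threshold) {
  res <- tryCatch({
    h <- select_instruments(exposure, outcome, ld, config, p_threshold)
    ests <- mr_all_methods(h, config)
    primary <- ests$ivw %||% ests$wald
    egger_p <- if (!is.null(ests$egger)) ests$egger$extra$egger_intercept_p else NA_real_
    tab <- tidy_estimates(ests, trait_id(exposure), trait_id(outcome))
    list(tab = tab, primary = primary, egger_p = egger_p, h = h,
         reason = "ok")
  }, axismr_error = function(e) {
    list(tab = NULL, primary = NULL, egger_p = NA_real_, h = NULL,
         reason = conditionMessage(e))
  })
  res
}

#' Bidirectional univariable MR over all exposure-outcome pairs
#'
#' Forward MR uses the exposure-side instrument threshold
#' (`config$iv_p_threshold`); reverse MR treats the disease outcome as the
#' exposure at the genome-wide threshold `config$reverse_iv_p_threshold`.
#' Pairs significant in both directions are flagged `reverse_causal` and are
#' excluded from downstream mediation. Pairs whose instruments cannot be
#' selected are skipped with a logged reason, never a crash.
#'
#' @param exposures,outcomes named lists of [summary_dataset()] objects.
#' @param ld optional LD matrix.
#' @param config a [mr_config()].
#' @return List with `forward` and `reverse` estimate tables, `pairs` (per
#'   pair: primary p-values both ways, flags, skip reasons), and
#'   `eligible_pairs` (forward-significant, not reverse-causal, no
#'   pleiotropy flag).
#' @export
run_bidirectional_uvmr <- function(exposures, outcomes, ld = NULL,
                                   config = mr_config()) {
  exposures <- name_datasets(exposures)
  outcomes <- name_datasets(outcomes)
  forward <- list()
  reverse <- list()
  pairs <- list()
  for (eid in names(exposures)) {
    for (oid in names(outcomes)) {
      fw <- uvmr_pair_row(exposures[[eid]], outcomes[[oid]], ld, config,
                          config$iv_p_threshold)
      rv <- uvmr_pair_row(outcomes[[oid]], exposures[[eid]], ld, config,
                          config$reverse_iv_p_threshold)
      if (!is.null(fw$tab)) forward[[length(forward) + 1]] <- fw$tab
      if (!is.null(rv$tab)) {
        rv$tab$direction <- "reverse"
        reverse[[length(reverse) + 1]] <- rv$tab
      }
      fw_p <- if (!is.null(fw$primary)) fw$primary$pvalue else NA_real_
      rv_p <- if (!is.null(rv$primary)) rv$primary$pvalue else NA_real_
      fw_sig <- !is.na(fw_p) && fw_p < config$alpha
      rv_sig <- !is.na(rv_p) && rv_p < config$alpha
      pleio <- !is.na(fw$egger_p) && fw$egger_p < config$alpha
      pairs[[length(pairs) + 1]] <- data.frame(
        exposure_id = eid, outcome_id = oid,
        forward_beta = if (!is.null(fw$primary)) fw$primary$beta else NA_real_,
        forward_p = fw_p, reverse_p = rv_p,
        forward_significant = fw_sig,
        reverse_causal = fw_sig && rv_sig,
        pleiotropy_flag = pleio,
        invalidated = pleio,
        forward_skip_reason = if (is.null(fw$tab)) fw$reason else "",
        reverse_skip_reason = if (is.null(rv$tab)) rv$reason else "",
        eligible = fw_sig && !(fw_sig && rv_sig) && !pleio,
        stringsAsFactors = FALSE)
    }
  }
  bind <- function(l) if (length(l)) do.call(rbind, l) else data.frame()
  pairs <- bind(pairs)
  list(forward = bind(forward), reverse = bind(reverse), pairs = pairs,
       eligible_pairs = if (nrow(pairs)) pairs[pairs$eligible, , drop = FALSE]
                        else pairs)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full two-step study and emit report tables
#'
#' Executes bidirectional UVMR for every exposure-outcome pair, drops
#' reverse-causal and pleiotropy-invalidated pairs, runs the four-step
#' mediation screen over the surviving pairs, appends Benjamini-Hochberg
#' q-values to the primary forward IVW results within each outcome family,
#' computes sensitivity reports for eligible pairs, and writes the report
#' bundle to `out_dir`: `uvmr_forward.tsv`, `uvmr_reverse.tsv`, `pairs.tsv`,
#' `sensitivity.tsv`, `mediation_candidates.tsv` (steps audit),
#' `mediation_results.tsv`, and `run_info.json` (seed and settings). Outputs
#' are byte-stable given identical inputs, configuration, and seed.
#'
#' @param exposures,mediators,outcomes named lists of [summary_dataset()].
#' @param ld optional LD matrix.
#' @param config a [mr_config()].
#' @param out_dir output directory; created if needed. `NULL` skips writing.
#' @return List with all report tables, invisibly when `out_dir` is set.
#' @export
run_full_study <- function(exposures, mediators, outcomes, ld = NULL,
                           config = mr_config(), out_dir = NULL) {
  bi <- run_bidirectional_uvmr(exposures, outcomes, ld, config)

  forward <- bi$forward
  if (nrow(forward)) {
    # FDR within each outcome family over the primary (IVW) results.
    is_primary <- forward$method %in% c("ivw", "wald")
    forward$q_value <- NA_real_
    for (oid in unique(forward$outcome)) {
      fam <- is_primary & forward$outcome == oid
      if (any(fam)) forward$q_value[fam] <- bh_fdr(forward$pvalue[fam])
    }
    inval <- bi$pairs$invalidated[match(paste(forward$exposure, forward$outcome),
                                        paste(bi$pairs$exposure_id,
                                              bi$pairs$outcome_id))]
    forward$invalidated <- inval
  }

  sens_rows <- list()
  if (nrow(bi$eligible_pairs)) {
    for (i in seq_len(nrow(bi$eligible_pairs))) {
      eid <- bi$eligible_pairs$exposure_id[i]
      oid <- bi$eligible_pairs$outcome_id[i]
      row <- tryCatch({
        h <- select_instruments(exposures[[eid]], outcomes[[oid]], ld, config)
        cbind(data.frame(exposure = eid, outcome = oid,
                         stringsAsFactors = FALSE),
              as.data.frame(sensitivity_report(h, config)))
      }, axismr_error = function(e) NULL)
      if (!is.null(row)) sens_rows[[length(sens_rows) + 1]] <- row
    }
  }
  sensitivity <- if (length(sens_rows)) do.call(rbind, sens_rows) else data.frame()

  med <- if (length(mediators)) {
    run_mediation_screen(exposures, mediators, outcomes, ld, config,
                         eligible_pairs = bi$eligible_pairs)
  } else {
    list(results = data.frame(), audit = data.frame())
  }

  out <- list(forward = forward, reverse = bi$reverse, pairs = bi$pairs,
              sensitivity = sensitivity,
              mediation_results = med$results,
              mediation_audit = med$audit)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(forward, file.path(out_dir, "uvmr_forward.tsv"))
    write_tsv(bi$reverse, file.path(out_dir, "uvmr_reverse.tsv"))
    write_tsv(bi$pairs, file.path(out_dir, "pairs.tsv"))
    write_tsv(sensitivity, file.path(out_dir, "sensitivity.tsv"))
    write_tsv(med$audit, file.path(out_dir, "mediation_candidates.tsv"))
    write_tsv(med$results, file.path(out_dir, "mediation_results.tsv"))
    jsonlite::write_json(list(seed = config$seed, config = config,
                              n_exposures = length(exposures),
                              n_mediators = length(mediators),
                              n_outcomes = length(outcomes),
                              package_version = as.character(utils::packageVersion("axismr"))),
                         file.path(out_dir, "run_info.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(out))
  }
  out
}
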