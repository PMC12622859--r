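#' Study-design completeness metrics
#'
#' Operationalises the data-completeness design quality of an AV study on
#' an aligned dataset: the fraction of expected DM days actually observed
#' (expected = `max_days` per instance), the fraction of RM instances with
#' every item answered, and the fraction of selected window days with a
#' daily-RM response. The daily fraction is `NA` (not 0) when no daily RM
#' was aligned.
#'
#' @param aligned An `avtk_aligned` from [build_aligned_dataset()].
#' @return List with `dm_day_completeness`, `rm_instance_completeness`,
#'   `daily_rm_completeness` and `n_instances`.
#' @export
completeness_metrics <- function(aligned) {
  stopifnot(inherits(aligned, "avtk_aligned"))
  if (nrow(aligned) == 0L) stop("no aligned records", call. = FALSE)
  max_days <- attr(aligned, "max_days")
  out <- list(
    dm_day_completeness = sum(aligned$n_dm_days) / (nrow(aligned) * max_days),
    rm_instance_completeness = mean(aligned$rm_complete),
    daily_rm_completeness = NA_real_,
    n_instances = nrow(aligned))
  if (isTRUE(attr(aligned, "has_daily")))
    out$daily_rm_completeness <-
      sum(aligned$n_daily_days) / (nrow(aligned) * max_days)
  out
}

cfa_indicator_data <- function(aligned, min_dm_days = 3L) {
  max_days <- attr(aligned, "max_days")
  k <- attr(aligned, "n_items")
  dm_cols <- paste0("dm_d", seq_len(max_days))
  item_cols <- paste0("item_", seq_len(k))
  keep <- aligned$n_dm_days >= min_dm_days
  list(data = as.matrix(aligned[keep, c(dm_cols, item_cols)]),
       dm_cols = dm_cols, item_cols = item_cols, n_dropped = sum(!keep))
}

analyze_pairing <- function(study, dm_variable, rm_instrument,
                            daily_rm_instrument = NULL,
                            thresholds = fit_thresholds(),
                            max_days = 7L, missing = "listwise",
                            min_dm_days_cfa = 3L) {
  aligned <- build_aligned_dataset(study, dm_variable, rm_instrument,
                                   daily_rm_instrument, max_days = max_days)
  pr <- tryCatch(pearson_r(aligned$dm_mean, aligned$rm_scaled),
                 error = function(e) list(r = NA_real_, n = NA_integer_))
  slr <- tryCatch(fit_slr(aligned$rm_scaled, aligned$dm_mean),
                  error = function(e) list(r2 = NA_real_))
  row <- data.frame(dm_variable = dm_variable, rm_instrument = rm_instrument,
                    pearson_r = pr$r, n_complete = pr$n, slr_r2 = slr$r2,
                    cfa_phi = NA_real_, cfa_n_used = NA_integer_,
                    chisq = NA_real_, df = NA_integer_,
                    cfi = NA_real_, tli = NA_real_, rmsea = NA_real_,
                    srmr = NA_real_, cfi_pass = NA, tli_pass = NA,
                    rmsea_pass = NA, srmr_pass = NA,
                    verdict = NA_character_, converged = NA, heywood = NA,
                    cfa_error = NA_character_, stringsAsFactors = FALSE)
  fit <- NULL
  # Heywood warnings are informative (the flag lands in the report row);
  # errors are captured per pairing so batch runs complete
  cfa_try <- tryCatch(withCallingHandlers({
    ind <- cfa_indicator_data(aligned, min_dm_days_cfa)
    sc <- compute_sample_cov(ind$data, strategy = missing)
    spec <- cfa_model_spec(ind$dm_cols, ind$item_cols)
    fit <- compute_fit_indices(fit_two_factor_cfa(sc$S, sc$n_used, spec))
    ev <- evaluate_fit(fit, thresholds)
    row$cfa_phi <- fit$phi; row$cfa_n_used <- fit$n_used
    row$chisq <- fit$chisq; row$df <- fit$df
    row$cfi <- fit$cfi; row$tli <- fit$tli
    row$rmsea <- fit$rmsea; row$srmr <- fit$srmr
    row$cfi_pass <- ev$cfi_pass; row$tli_pass <- ev$tli_pass
    row$rmsea_pass <- ev$rmsea_pass; row$srmr_pass <- ev$srmr_pass
    row$verdict <- ev$verdict
    row$converged <- fit$converged; row$heywood <- fit$heywood
    row
  }, warning = function(w) invokeRestart("muffleWarning")),
  error = function(e) conditionMessage(e))
  if (is.character(cfa_try)) row$cfa_error <- cfa_try else row <- cfa_try
  list(row = row, aligned = aligned, fit = fit)
}

mlr_rows <- function(study, dm_variable, rm_instruments,
                     daily_rm_instrument = NULL, max_days = 7L) {
  # join aligned records of all multiday RMs on participant + admin date
  frames <- lapply(rm_instruments, function(rmn) {
    al <- build_aligned_dataset(study, dm_variable, rmn, daily_rm_instrument,
                                max_days = max_days)
    key <- paste(al$participant_id, format(al$admin_date))
    cols <- data.frame(key = key, dm_mean = al$dm_mean, rm = al$rm_scaled,
                       stringsAsFactors = FALSE)
    names(cols)[3L] <- rmn
    if (!is.null(daily_rm_instrument)) {
      cols$daily_mean <- al$daily_rm_mean
      dd <- as.matrix(al[, paste0("daily_d", seq_len(max_days))])
      colnames(dd) <- paste0("daily_day_", seq_len(max_days))
      cols <- cbind(cols, dd)
    }
    cols
  })
  joined <- frames[[1L]]
  if (length(frames) > 1L)
    for (f in frames[-1L])
      joined <- merge(joined, f[c("key", setdiff(names(f), names(joined)))],
                      by = "key")
  sets <- list()
  for (rmn in rm_instruments) sets[[rmn]] <- rmn
  if (length(rm_instruments) > 1L)
    sets[["all multiday RMs"]] <- rm_instruments
  if (!is.null(daily_rm_instrument)) {
    sets[["all + daily (mean values)"]] <- c(rm_instruments, "daily_mean")
    sets[["all + daily (individual days)"]] <-
      c(rm_instruments, paste0("daily_day_", seq_len(max_days)))
  }
  out <- lapply(names(sets), function(label) {
    preds <- sets[[label]]
    res <- tryCatch(fit_mlr(joined[, preds, drop = FALSE], joined$dm_mean),
                    error = function(e) NULL)
    data.frame(dm_variable = dm_variable, predictor_set = label,
               model_type = if (length(preds) == 1L) "SLR" else "MLR",
               r2 = if (is.null(res)) NA_real_ else res$r2,
               adj_r2 = if (is.null(res)) NA_real_ else res$adj_r2,
               n = if (is.null(res)) 0L else res$n,
               p = length(preds), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Run the full analytical-validation battery
#'
#' For every pairing of a DM variable with a multiday-recall RM: aligns the
#' data to the RM administration cadence, then computes the Pearson
#' correlation and simple-regression R-squared on the window means, fits
#' the two-factor CFA on the item/day-level indicators with fit-index
#' evaluation, and fits the multiple-regression predictor sets (each RM
#' alone; all multiday RMs; all plus the daily RM as a window mean; all
#' plus the daily RM's individual days). A failure inside one pairing
#' (e.g. CFA non-convergence or too few complete cases) is recorded in the
#' report, not raised.
#'
#' @param study An `avtk_study`.
#' @param pairings Data frame with columns `dm_variable` and
#'   `rm_instrument` (one row per pairing), or `NULL` to cross every DM
#'   variable with every multiday instrument in the study.
#' @param daily_rm_instrument Optional daily-recall instrument name used in
#'   the regression predictor sets.
#' @param thresholds An [fit_thresholds()].
#' @param max_days Maximum DM days per window.
#' @param missing Missing-data strategy for the CFA covariance
#'   (`"listwise"` or `"pairwise"`).
#' @param min_dm_days_cfa Minimum observed DM days for a record to enter
#'   the CFA (records below it cannot support the day-level factor but are
#'   retained for correlation/regression).
#' @return An object of class `avtk_report`: list with data frames
#'   `agreement` (one row per pairing) and `regressions`, plus
#'   `completeness` per pairing and the thresholds used.
#' @export
run_av_analysis <- function(study, pairings = NULL, daily_rm_instrument = NULL,
                            thresholds = fit_thresholds(), max_days = 7L,
                            missing = "listwise", min_dm_days_cfa = 3L) {
  stopifnot(inherits(study, "avtk_study"))
  if (is.null(pairings)) {
    multiday <- names(Filter(Negate(is_daily_instrument), study$instruments))
    multiday <- intersect(multiday, unique(study$rm$instrument))
    dm_vars <- unique(study$dm$variable)
    pairings <- expand.grid(dm_variable = dm_vars, rm_instrument = multiday,
                            stringsAsFactors = FALSE)
  }
  pairings <- as.data.frame(pairings)
  if (nrow(pairings) == 0L)
    stop("no pairings to analyze", call. = FALSE)

  rows <- list(); comp <- list()
  for (i in seq_len(nrow(pairings))) {
    res <- analyze_pairing(study, pairings$dm_variable[i],
                           pairings$rm_instrument[i], daily_rm_instrument,
                           thresholds, max_days, missing, min_dm_days_cfa)
    rows[[i]] <- res$row
    comp[[i]] <- c(list(dm_variable = pairings$dm_variable[i],
                        rm_instrument = pairings$rm_instrument[i]),
                   completeness_metrics(res$aligned))
  }
  regs <- lapply(unique(pairings$dm_variable), function(v) {
    mlr_rows(study, v, unique(pairings$rm_instrument[pairings$dm_variable == v]),
             daily_rm_instrument, max_days)
  })
  structure(list(agreement = do.call(rbind, rows),
                 regressions = do.call(rbind, regs),
                 completeness = do.call(rbind, lapply(comp, as.data.frame)),
                 thresholds = thresholds),
            class = "avtk_report")
}

#' @export
print.avtk_report <- function(x, ...) {
  cat("<avtk_report>\n\nAgreement estimates:\n")
  cols <- c("dm_variable", "rm_instrument", "pearson_r", "cfa_phi", "slr_r2",
            "cfi", "tli", "rmsea", "srmr", "verdict")
  print(x$agreement[, cols], digits = 3, row.names = FALSE)
  cat("\nRegression models:\n")
  print(x$regressions, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Serialise a study report
#'
#' `csv` writes the agreement table (long format, one row per pairing) with
#' full numeric precision; `json` writes the whole report (agreement,
#' regressions, completeness, thresholds) as one document. Either reloads
#' to the same numeric values via [read_report()].
#'
#' @param report An `avtk_report`.
#' @param path Output file path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("csv", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "avtk_report"))
  if (format == "csv") {
    df <- report$agreement
    num <- vapply(df, is.numeric, logical(1))
    for (j in which(num)) df[[j]] <- sprintf("%.17g", df[[j]])
    df[df == "NA"] <- NA
    utils::write.csv(df, path, row.names = FALSE, na = "")
  } else {
    jsonlite::write_json(
      list(agreement = report$agreement, regressions = report$regressions,
           completeness = report$completeness,
           thresholds = unclass(report$thresholds)),
      path, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' Read back a serialised report
#'
#' @param path File written by [write_report()].
#' @param format `"csv"` or `"json"`.
#' @return For `csv`, the agreement data frame; for `json`, a list with
#'   the report's tables.
#' @export
read_report <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}
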