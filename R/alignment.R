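#' Scale a raw RM total to the 0-100 range
#'
#' Item scores of a multiday-recall RM instance are summed and linearly
#' rescaled so the instrument's minimum possible total maps to 0 and its
#' maximum to 100. For the PHQ-9 (9 items scored 0-3) this is the familiar
#' multiplication of the raw sum by 100/27. Instruments flagged as already
#' prescaled pass through unchanged.
#'
#' @param raw_sum Sum of observed item scores (all items must be observed).
#' @param instrument An [instrument_spec()].
#' @return Scaled total in \[0, 100\].
#' @export
scale_rm_total <- function(raw_sum, instrument) {
  if (instrument$prescaled_0_100) return(as.numeric(raw_sum))
  lo <- instrument$n_items * instrument$item_min
  hi <- instrument$n_items * instrument$item_max
  (as.numeric(raw_sum) - lo) * 100 / (hi - lo)
}

#' Scale one RM instance's item scores
#'
#' Returns the 0-100 scaled total for a vector of item scores, or `NA` when
#' any item is unobserved: partially answered instances carry no total and
#' are excluded from analyses that need one.
#'
#' @param item_scores Numeric vector of length `instrument$n_items`
#'   (`NA` marks an unanswered item).
#' @param instrument An [instrument_spec()].
#' @return Scaled total, or `NA_real_` for an incomplete instance.
#' @examples
#' phq9 <- instrument_spec("PHQ-9", 9, 0, 3, 14)
#' scale_rm_instance(rep(3, 9), phq9)  # 100
#' @export
scale_rm_instance <- function(item_scores, instrument) {
  if (length(item_scores) != instrument$n_items)
    stop(sprintf("expected %d item score(s), got %d", instrument$n_items,
                 length(item_scores)), call. = FALSE)
  ok <- !is.na(item_scores)
  if (!all(ok)) return(NA_real_)
  if (!instrument$prescaled_0_100 &&
      any(item_scores < instrument$item_min | item_scores > instrument$item_max))
    stop("item score outside the instrument's range", call. = FALSE)
  scale_rm_total(sum(item_scores), instrument)
}

#' Select the DM days matching an RM recall period
#'
#' The recall period of an RM administered on `admin_date` spans the
#' `recall_days` calendar days ending on (and including) the administration
#' day. Among the days with observed DM data inside that period, the
#' `max_days` days closest to the administration (i.e. the most recent ones)
#' are selected; if fewer are observed, all of them are used. A PHQ-9
#' (14-day recall) answered on Jan 14 with complete daily data therefore
#' selects Jan 8 through Jan 14.
#'
#' @param observed_dates `Date` vector of days with observed DM data (any
#'   order, duplicates ignored).
#' @param admin_date Administration date of the RM instance.
#' @param recall_days Recall period length in days (>= 1).
#' @param max_days Maximum number of days to select (default 7).
#' @return Sorted `Date` vector (oldest first) of the selected days.
#' @export
select_dm_window <- function(observed_dates, admin_date, recall_days,
                             max_days = 7L) {
  if (length(recall_days) != 1L || is.na(recall_days) || recall_days < 1)
    stop("`recall_days` must be a positive integer", call. = FALSE)
  if (length(max_days) != 1L || is.na(max_days) || max_days < 1)
    stop("`max_days` must be a positive integer", call. = FALSE)
  admin_date <- as.Date(admin_date)
  d <- sort(unique(as.Date(observed_dates)))
  d <- d[d >= admin_date - recall_days + 1 & d <= admin_date]
  if (length(d) > max_days) d <- utils::tail(d, max_days)
  d
}

#' Match daily-RM data to a selected DM window
#'
#' Looks up the daily-RM value on each selected window date; days without a
#' recorded response are missing, never an error.
#'
#' @param daily_dates,daily_values Observed daily-RM series (parallel
#'   vectors).
#' @param window_dates Dates returned by [select_dm_window()].
#' @return Numeric vector aligned to `window_dates` with `NA` for
#'   unobserved days.
#' @export
select_daily_rm <- function(daily_dates, daily_values, window_dates) {
  if (length(window_dates) == 0L) return(numeric(0))
  idx <- match(as.Date(window_dates), as.Date(daily_dates))
  out <- rep(NA_real_, length(window_dates))
  ok <- !is.na(idx)
  out[ok] <- daily_values[idx[ok]]
  out
}

#' Mean over the observed values of a window
#'
#' Aggregates the per-day values of one RM administration window to the
#' administration cadence: the arithmetic mean of the observed values, or
#' `NA` when nothing was observed.
#'
#' @param values Numeric vector with `NA` for missing days.
#' @return Scalar mean, or `NA_real_`.
#' @export
aggregate_window_mean <- function(values) {
  if (length(values) == 0L || all(is.na(values))) return(NA_real_)
  mean(values, na.rm = TRUE)
}

#' Align a study's daily data to RM administration instances
#'
#' For every administration instance of `rm_instrument`, selects the DM days
#' inside the recall period (see [select_dm_window()]), matches the daily-RM
#' series to the same days, and aggregates both to window means. Every
#' instance is retained — including instances with no DM data at all — and
#' each aligned record carries completeness flags so downstream analyses can
#' apply their own complete-case rules.
#'
#' The returned data frame has one row per RM instance with the scaled RM
#' total (`rm_scaled`, `NA` when any item is unanswered), per-day DM values
#' in columns `dm_d1..dm_d<max_days>` ordered oldest to newest and
#' right-aligned (the last column is always the selected day closest to the
#' administration; leading columns are `NA` when fewer days were selected),
#' the matching daily-RM values in `daily_d*` columns, the RM item scores in
#' `item_*` columns, and the window means `dm_mean` / `daily_rm_mean`.
#'
#' @param study An `avtk_study`.
#' @param dm_variable Name of the DM variable to align.
#' @param rm_instrument Name of a multiday-recall instrument in the study.
#' @param daily_rm_instrument Optional name of a daily-recall instrument.
#' @param max_days Maximum DM days per window (default 7).
#' @return A data frame of class `avtk_aligned`.
#' @export
build_aligned_dataset <- function(study, dm_variable, rm_instrument,
                                  daily_rm_instrument = NULL, max_days = 7L) {
  stopifnot(inherits(study, "avtk_study"))
  if (!dm_variable %in% study$dm$variable)
    stop("unknown DM variable: ", dm_variable, call. = FALSE)
  spec <- study$instruments[[rm_instrument]]
  if (is.null(spec))
    stop("unknown RM instrument: ", rm_instrument, call. = FALSE)
  if (!is.null(daily_rm_instrument) &&
      is.null(study$instruments[[daily_rm_instrument]]))
    stop("unknown daily RM instrument: ", daily_rm_instrument, call. = FALSE)
  max_days <- as.integer(max_days)

  dm <- study$dm[study$dm$variable == dm_variable, , drop = FALSE]
  dm_by_pid <- split(dm[c("date", "value")], dm$participant_id)
  daily <- NULL
  if (!is.null(daily_rm_instrument) && !is.null(study$daily_rm)) {
    daily <- study$daily_rm[study$daily_rm$instrument == daily_rm_instrument, ,
                            drop = FALSE]
    daily_by_pid <- split(daily[c("date", "value")], daily$participant_id)
  }

  inst <- study$rm[study$rm$instrument == rm_instrument, , drop = FALSE]
  k <- spec$n_items
  n <- nrow(inst)
  dm_mat <- matrix(NA_real_, n, max_days,
                   dimnames = list(NULL, paste0("dm_d", seq_len(max_days))))
  daily_mat <- matrix(NA_real_, n, max_days,
                      dimnames = list(NULL, paste0("daily_d", seq_len(max_days))))
  item_mat <- matrix(NA_real_, n, k,
                     dimnames = list(NULL, paste0("item_", seq_len(k))))
  rm_scaled <- window_start <- dm_mean <- daily_rm_mean <- rep(NA_real_, n)
  n_dm_days <- n_daily_days <- integer(n)

  item_by_id <- split(study$rm_items$score, study$rm_items$instance_id)
  for (i in seq_len(n)) {
    pid <- inst$participant_id[i]
    admin <- inst$date[i]
    scores <- item_by_id[[inst$instance_id[i]]]
    item_mat[i, seq_along(scores)] <- scores
    rm_scaled[i] <- scale_rm_instance(scores, spec)

    pdm <- dm_by_pid[[pid]]
    win <- select_dm_window(if (is.null(pdm)) as.Date(character()) else pdm$date,
                            admin, spec$recall_days, max_days)
    window_start[i] <- as.numeric(admin - spec$recall_days + 1)
    nw <- length(win)
    if (nw > 0L) {
      vals <- pdm$value[match(win, pdm$date)]
      dm_mat[i, (max_days - nw + 1L):max_days] <- vals
      dm_mean[i] <- aggregate_window_mean(vals)
      n_dm_days[i] <- sum(!is.na(vals))
      if (!is.null(daily)) {
        pdr <- daily_by_pid[[pid]]
        dvals <- if (is.null(pdr)) rep(NA_real_, nw) else
          select_daily_rm(pdr$date, pdr$value, win)
        daily_mat[i, (max_days - nw + 1L):max_days] <- dvals
        daily_rm_mean[i] <- aggregate_window_mean(dvals)
        n_daily_days[i] <- sum(!is.na(dvals))
      }
    }
  }

  out <- data.frame(instance_id = inst$instance_id,
                    participant_id = inst$participant_id,
                    admin_date = inst$date,
                    window_start = as.Date(window_start, origin = "1970-01-01"),
                    window_end = inst$date,
                    rm_scaled = rm_scaled,
                    rm_complete = !is.na(rm_scaled) | k == 0L,
                    n_dm_days = n_dm_days,
                    dm_mean = dm_mean,
                    n_daily_days = n_daily_days,
                    daily_rm_mean = daily_rm_mean,
                    stringsAsFactors = FALSE)
  out$rm_complete <- apply(item_mat, 1L, function(r) !anyNA(r))
  out <- cbind(out, as.data.frame(dm_mat), as.data.frame(daily_mat),
               as.data.frame(item_mat))
  rownames(out) <- NULL
  structure(out, class = c("avtk_aligned", "data.frame"),
            dm_variable = dm_variable, rm_instrument = rm_instrument,
            daily_rm_instrument = daily_rm_instrument, max_days = max_days,
            n_items = k, has_daily = !is.null(daily))
}
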