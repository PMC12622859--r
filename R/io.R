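#' Assemble a study-data container
#'
#' Bundles the three ingredients of an analytical-validation study: daily
#' digital-measure (DM) series, multiday-recall reference-measure (RM)
#' administration instances with item-level scores, and daily-recall RM
#' series. Most users will obtain one from [load_study()] or
#' [generate_study()] rather than calling this directly.
#'
#' @param dm Data frame with columns `participant_id`, `date` (`Date`),
#'   `variable`, `value`; one row per participant-date-variable, values
#'   finite and non-negative.
#' @param rm Data frame of RM instances with columns `instance_id`,
#'   `participant_id`, `date` (`Date`), `instrument`.
#' @param rm_items Long data frame of item scores with columns
#'   `instance_id`, `item` (1-based index), `score` (integer or `NA`).
#' @param daily_rm Data frame with columns `participant_id`, `date`,
#'   `instrument`, `value` holding daily-recall RM responses (scaled
#'   totals), or `NULL`.
#' @param instruments Named list of [instrument_spec()] objects covering
#'   every instrument referenced by `rm` and `daily_rm`.
#'
#' @return An object of class `avtk_study`.
#' @export
study_data <- function(dm, rm, rm_items, daily_rm = NULL, instruments) {
  dm <- as.data.frame(dm)
  rm <- as.data.frame(rm)
  rm_items <- as.data.frame(rm_items)
  stopifnot(all(c("participant_id", "date", "variable", "value") %in% names(dm)),
            all(c("instance_id", "participant_id", "date", "instrument") %in% names(rm)),
            all(c("instance_id", "item", "score") %in% names(rm_items)))
  if (nrow(dm)) {
    if (anyDuplicated(dm[c("participant_id", "date", "variable")]))
      stop("duplicate participant-date rows in DM data", call. = FALSE)
    if (any(!is.finite(dm$value)))
      stop("non-finite DM values", call. = FALSE)
  }
  bad <- setdiff(unique(rm$instrument), names(instruments))
  if (length(bad))
    stop("RM data references unknown instrument(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (!is.null(daily_rm) && nrow(daily_rm)) {
    bad <- setdiff(unique(daily_rm$instrument), names(instruments))
    if (length(bad))
      stop("daily RM data references unknown instrument(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(dm = dm, rm = rm, rm_items = rm_items,
                 daily_rm = daily_rm, instruments = instruments),
            class = "avtk_study")
}

#' @export
print.avtk_study <- function(x, ...) {
  cat("<avtk_study>\n")
  cat(sprintf("  DM: %d observation(s), %d variable(s), %d participant(s)\n",
              nrow(x$dm), length(unique(x$dm$variable)),
              length(unique(x$dm$participant_id))))
  cat(sprintf("  RM: %d instance(s) across %d instrument(s)\n",
              nrow(x$rm), length(unique(x$rm$instrument))))
  nd <- if (is.null(x$daily_rm)) 0L else nrow(x$daily_rm)
  cat(sprintf("  daily RM: %d observation(s)\n", nd))
  invisible(x)
}

parse_iso_date <- function(x) {
  out <- as.Date(rep(NA_real_, length(x)))
  ok <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  out[ok] <- as.Date(x[ok], format = "%Y-%m-%d")
  out
}

#' Load an analytical-validation study from CSV files
#'
#' Reads the long-format DM file (`participant_id,date,variable,value`), the
#' RM file (`participant_id,date,instrument,item_1..item_k`) and an
#' instrument configuration file (JSON or YAML). RM rows whose instrument
#' has a one-day recall period are routed to the daily-RM series; their
#' per-day value is the 0-100 scaled total when all items are observed and
#' missing otherwise.
#'
#' Rows with unparseable dates or with item scores outside the instrument's
#' range are rejected; the number of rejected rows is reported via
#' `message()`. Dates must be ISO-8601 calendar dates (no time component).
#' Duplicate participant-date rows for the same DM variable are an error.
#'
#' @param dm_path,rm_path Paths to the DM and RM CSV files.
#' @param spec_path Path to the instrument specification file
#'   (see [read_instrument_specs()]).
#' @return An `avtk_study` object.
#' @export
load_study <- function(dm_path, rm_path, spec_path) {
  for (p in c(dm_path, rm_path, spec_path))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  instruments <- read_instrument_specs(spec_path)

  dm_raw <- utils::read.csv(dm_path, colClasses = "character")
  need <- c("participant_id", "date", "variable", "value")
  if (!all(need %in% names(dm_raw)))
    stop("DM file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  n_rejected <- 0L
  if (nrow(dm_raw)) {
    dates <- parse_iso_date(dm_raw$date)
    vals <- suppressWarnings(as.numeric(dm_raw$value))
    keep <- !is.na(dates) & is.finite(vals)
    n_rejected <- n_rejected + sum(!keep)
    dm <- data.frame(participant_id = dm_raw$participant_id[keep],
                     date = dates[keep], variable = dm_raw$variable[keep],
                     value = vals[keep], stringsAsFactors = FALSE)
  } else {
    dm <- data.frame(participant_id = character(), date = as.Date(character()),
                     variable = character(), value = numeric())
  }

  rm_raw <- utils::read.csv(rm_path, colClasses = "character")
  need <- c("participant_id", "date", "instrument")
  if (!all(need %in% names(rm_raw)))
    stop("RM file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  item_cols <- grep("^item_\\d+$", names(rm_raw), value = TRUE)
  item_cols <- item_cols[order(as.integer(sub("item_", "", item_cols)))]

  rm_list <- list(); items_list <- list(); daily_list <- list()
  if (nrow(rm_raw)) {
    dates <- parse_iso_date(rm_raw$date)
    for (i in seq_len(nrow(rm_raw))) {
      inst_name <- rm_raw$instrument[i]
      spec <- instruments[[inst_name]]
      if (is.null(spec))
        stop(sprintf("RM row %d references unknown instrument '%s'",
                     i, inst_name), call. = FALSE)
      if (is.na(dates[i])) { n_rejected <- n_rejected + 1L; next }
      k <- spec$n_items
      if (length(item_cols) < k)
        stop(sprintf("RM file has %d item column(s) but instrument '%s' needs %d",
                     length(item_cols), inst_name, k), call. = FALSE)
      raw_scores <- rm_raw[i, item_cols[seq_len(k)]]
      scores <- suppressWarnings(as.numeric(unlist(raw_scores)))
      # empty cells are missing; anything else must parse and be in range;
      # Likert instruments additionally require whole-number scores
      blank <- !nzchar(trimws(unlist(raw_scores)))
      scores[blank] <- NA_real_
      bad <- !blank & (is.na(scores) | scores < spec$item_min | scores > spec$item_max)
      if (!spec$prescaled_0_100)
        bad <- bad | (!blank & !is.na(scores) & scores != round(scores))
      if (any(bad)) { n_rejected <- n_rejected + 1L; next }
      if (is_daily_instrument(spec)) {
        val <- if (anyNA(scores)) NA_real_ else scale_rm_total(sum(scores), spec)
        daily_list[[length(daily_list) + 1L]] <- data.frame(
          participant_id = rm_raw$participant_id[i], date = dates[i],
          instrument = inst_name, value = val, stringsAsFactors = FALSE)
      } else {
        id <- sprintf("%s|%s|%s|%d", inst_name, rm_raw$participant_id[i],
                      format(dates[i]), i)
        rm_list[[length(rm_list) + 1L]] <- data.frame(
          instance_id = id, participant_id = rm_raw$participant_id[i],
          date = dates[i], instrument = inst_name, stringsAsFactors = FALSE)
        items_list[[length(items_list) + 1L]] <- data.frame(
          instance_id = id, item = seq_len(k), score = scores,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (n_rejected > 0L)
    message(n_rejected, " input row(s) rejected (unparseable date/value or out-of-range item score)")

  empty_rm <- data.frame(instance_id = character(), participant_id = character(),
                         date = as.Date(character()), instrument = character())
  empty_items <- data.frame(instance_id = character(), item = integer(),
                            score = numeric())
  rm <- if (length(rm_list)) do.call(rbind, rm_list) else empty_rm
  rm_items <- if (length(items_list)) do.call(rbind, items_list) else empty_items
  daily <- if (length(daily_list)) do.call(rbind, daily_list) else NULL
  # canonical ordering so that loading is independent of input row order
  if (nrow(rm)) {
    o <- order(rm$instrument, rm$participant_id, rm$date, rm$instance_id)
    rm <- rm[o, , drop = FALSE]
    rm$instance_id <- sprintf("%s|%s|%s", rm$instrument, rm$participant_id,
                              format(rm$date))
    dup <- ave(seq_len(nrow(rm)), rm$instance_id, FUN = seq_along)
    rm$instance_id <- paste0(rm$instance_id, "#", dup)
    # remap item instance ids to the canonical ones
    old_new <- stats::setNames(rm$instance_id,
                               vapply(rm_list, function(d) d$instance_id, "")[o])
    rm_items$instance_id <- unname(old_new[rm_items$instance_id])
    rm_items <- rm_items[order(rm_items$instance_id, rm_items$item), , drop = FALSE]
    rownames(rm) <- rownames(rm_items) <- NULL
  }
  if (nrow(dm)) {
    dm <- dm[order(dm$variable, dm$participant_id, dm$date), , drop = FALSE]
    rownames(dm) <- NULL
  }
  if (!is.null(daily)) {
    daily <- daily[order(daily$instrument, daily$participant_id, daily$date), ,
                   drop = FALSE]
    rownames(daily) <- NULL
  }
  study_data(dm = dm, rm = rm, rm_items = rm_items, daily_rm = daily,
             instruments = instruments)
}

#' Write a study to CSV files
#'
#' Serialises an `avtk_study` into the same three-file layout read by
#' [load_study()]: `dm.csv`, `rm.csv` (multiday and daily RM rows together;
#' daily rows carry the raw item scores when available) and
#' `instruments.json`. Daily-RM series exported here were stored as scaled
#' totals, so they are written as a single prescaled item.
#'
#' @param study An `avtk_study`.
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(
    data.frame(participant_id = study$dm$participant_id,
               date = format(study$dm$date), variable = study$dm$variable,
               value = sprintf("%.17g", study$dm$value)),
    file.path(dir, "dm.csv"), row.names = FALSE, quote = FALSE)

  specs <- study$instruments
  k_max <- max(c(1L, vapply(specs[unique(study$rm$instrument)], `[[`,
                            integer(1), "n_items")))
  rows <- list()
  if (nrow(study$rm)) {
    wide <- matrix(NA_integer_, nrow(study$rm), k_max)
    for (i in seq_len(nrow(study$rm))) {
      sc <- study$rm_items$score[study$rm_items$instance_id == study$rm$instance_id[i]]
      wide[i, seq_along(sc)] <- sc
    }
    rows[[1L]] <- data.frame(participant_id = study$rm$participant_id,
                             date = format(study$rm$date),
                             instrument = study$rm$instrument,
                             wide, stringsAsFactors = FALSE)
  }
  if (!is.null(study$daily_rm) && nrow(study$daily_rm)) {
    dr <- study$daily_rm
    wide <- matrix(NA_character_, nrow(dr), k_max)
    wide[, 1L] <- ifelse(is.na(dr$value), NA_character_,
                         sprintf("%.17g", dr$value))
    rows[[length(rows) + 1L]] <- data.frame(participant_id = dr$participant_id,
                                            date = format(dr$date),
                                            instrument = dr$instrument,
                                            wide, stringsAsFactors = FALSE)
  }
  hdr <- c("participant_id", "date", "instrument", paste0("item_", seq_len(k_max)))
  rm_out <- if (length(rows)) do.call(rbind, rows) else
    as.data.frame(stats::setNames(rep(list(character(0)), length(hdr)), hdr))
  names(rm_out) <- hdr
  utils::write.csv(rm_out, file.path(dir, "rm.csv"), row.names = FALSE,
                   quote = FALSE, na = "")

  # daily series are stored as scaled totals; export them as one 0-100 item
  specs_out <- lapply(specs, function(s) {
    if (is_daily_instrument(s) && !s$prescaled_0_100)
      instrument_spec(s$name, 1L, 0L, 100L, 1L, prescaled_0_100 = TRUE)
    else s
  })
  write_instrument_specs(specs_out, file.path(dir, "instruments.json"))
  invisible(dir)
}
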