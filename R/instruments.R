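#' Define a clinical outcome assessment (COA) instrument
#'
#' An instrument specification describes the fixed properties of a COA used
#' as a reference measure (RM): how many Likert items it has, the score range
#' of each item, and the recall period its questions refer to.
#'
#' @param name Instrument name, e.g. `"PHQ-9"`. Used to match RM data rows.
#' @param n_items Number of items (positive integer).
#' @param item_min,item_max Integer score range of each item; `item_max`
#'   must exceed `item_min`. The PHQ-9, for example, scores each item 0-3.
#' @param recall_days Length of the recall period in days. `1` marks a
#'   daily-recall instrument; the PHQ-9 asks about the preceding 2 weeks,
#'   so `recall_days = 14`.
#' @param prescaled_0_100 If `TRUE`, instance totals are already on a 0-100
#'   scale and are passed through unmodified instead of being rescaled.
#'
#' @return An object of class `avtk_instrument`.
#' @examples
#' phq9 <- instrument_spec("PHQ-9", n_items = 9, item_min = 0, item_max = 3,
#'                         recall_days = 14)
#' @export
instrument_spec <- function(name, n_items, item_min, item_max, recall_days,
                            prescaled_0_100 = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  n_items <- as.integer(n_items)
  item_min <- as.integer(item_min)
  item_max <- as.integer(item_max)
  recall_days <- as.integer(recall_days)
  if (is.na(n_items) || n_items < 1L)
    stop("`n_items` must be a positive integer", call. = FALSE)
  if (is.na(item_max) || is.na(item_min) || item_max <= item_min)
    stop("`item_max` must exceed `item_min`", call. = FALSE)
  if (is.na(recall_days) || recall_days < 1L)
    stop("`recall_days` must be >= 1", call. = FALSE)
  structure(
    list(name = name, n_items = n_items, item_min = item_min,
         item_max = item_max, recall_days = recall_days,
         prescaled_0_100 = isTRUE(prescaled_0_100)),
    class = "avtk_instrument")
}

#' @export
print.avtk_instrument <- function(x, ...) {
  cat(sprintf("<avtk_instrument> %s: %d item(s) scored %d-%d, %d-day recall%s\n",
              x$name, x$n_items, x$item_min, x$item_max, x$recall_days,
              if (x$prescaled_0_100) " (prescaled 0-100)" else ""))
  invisible(x)
}

is_daily_instrument <- function(spec) spec$recall_days == 1L

#' Read instrument specifications from a configuration file
#'
#' Parses a JSON or YAML file holding a list of instrument definitions, each
#' with the fields of [instrument_spec()]. The format is inferred from the
#' file extension (`.json` vs `.yaml`/`.yml`).
#'
#' @param path Path to the configuration file.
#' @return A named list of `avtk_instrument` objects.
#' @export
read_instrument_specs <- function(path) {
  if (!file.exists(path))
    stop("instrument spec file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    stop("unsupported instrument spec format: .", ext, call. = FALSE)
  }
  if (!is.null(raw$instruments)) raw <- raw$instruments
  specs <- lapply(raw, function(e) {
    instrument_spec(name = e$name, n_items = e$n_items,
                    item_min = e$item_min, item_max = e$item_max,
                    recall_days = e$recall_days,
                    prescaled_0_100 = isTRUE(e$prescaled_0_100))
  })
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(names(specs)))
    stop("duplicate instrument names in spec file", call. = FALSE)
  specs
}

#' Write instrument specifications
#'
#' Inverse of [read_instrument_specs()]; used when exporting simulated
#' studies so they can be reloaded through the standard reader.
#'
#' @param specs Named list of `avtk_instrument` objects.
#' @param path Output path (`.json`, `.yaml` or `.yml`).
#' @return `path`, invisibly.
#' @export
write_instrument_specs <- function(specs, path) {
  lst <- lapply(unname(specs), function(s) s[])
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, pretty = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(lst, path)
  } else stop("unsupported instrument spec format: .", ext, call. = FALSE)
  invisible(path)
}
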