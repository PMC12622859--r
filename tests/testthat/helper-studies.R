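# Shared builders for small deterministic studies and fixture readers.

phq9_spec <- function() instrument_spec("PHQ-9", 9, 0, 3, 14)

# Study with one participant, a PHQ-9 answered on Jan 14 2020 and daily DM
# data on a configurable set of dates; item scores default to all 1s.
tiny_study <- function(dm_dates, item_scores = rep(1, 9),
                       participant = "p1", admin = as.Date("2020-01-14")) {
  instruments <- list("PHQ-9" = phq9_spec())
  dm <- data.frame(participant_id = participant, date = as.Date(dm_dates),
                   variable = "steps",
                   value = as.numeric(seq_along(dm_dates)),
                   stringsAsFactors = FALSE)
  id <- sprintf("PHQ-9|%s|%s#1", participant, format(admin))
  rm <- data.frame(instance_id = id, participant_id = participant,
                   date = admin, instrument = "PHQ-9",
                   stringsAsFactors = FALSE)
  rm_items <- data.frame(instance_id = id, item = 1:9,
                         score = as.numeric(item_scores),
                         stringsAsFactors = FALSE)
  study_data(dm = dm, rm = rm, rm_items = rm_items, instruments = instruments)
}

# Write a study's CSV trio into a temp dir and return the three paths.
write_study_files <- function(dm_lines, rm_lines, dir = withr::local_tempdir(
                                .local_envir = parent.frame())) {
  dm_path <- file.path(dir, "dm.csv")
  rm_path <- file.path(dir, "rm.csv")
  spec_path <- file.path(dir, "instruments.json")
  writeLines(dm_lines, dm_path)
  writeLines(rm_lines, rm_path)
  write_instrument_specs(list("PHQ-9" = phq9_spec(),
                              "DAILY-1" = instrument_spec("DAILY-1", 1, 0, 3, 1)),
                         spec_path)
  list(dm = dm_path, rm = rm_path, spec = spec_path)
}

rm_header <- paste(c("participant_id,date,instrument",
                     paste0("item_", 1:9)), collapse = ",")

read_cfa_fixture <- function(name) {
  lines <- readLines(test_path("fixtures", name))
  lines <- lines[!startsWith(lines, "#")]
  kv <- list()
  mat_rows <- character()
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (parts[1] %in% c("n", "p1", "p2") || startsWith(parts[1], "oracle_")) {
      kv[[parts[1]]] <- as.numeric(parts[2])
    } else mat_rows <- c(mat_rows, ln)
  }
  S <- do.call(rbind, lapply(strsplit(trimws(mat_rows), "\\s+"), as.numeric))
  p1 <- as.integer(kv$p1); p2 <- as.integer(kv$p2)
  colnames(S) <- rownames(S) <- c(paste0("x", seq_len(p1)),
                                  paste0("y", seq_len(p2)))
  list(S = S, n = as.integer(kv$n), p1 = p1, p2 = p2,
       oracle = kv[startsWith(names(kv), "oracle_")])
}

# Analytic model-implied covariance for equal-loading two-factor models.
analytic_sigma <- function(loading, phi, p1, p2) {
  S <- avtk:::cfa_implied_cov(rep(loading, p1 + p2), phi,
                              rep(1 - loading^2, p1 + p2), p1)
  colnames(S) <- rownames(S) <- c(paste0("x", seq_len(p1)),
                                  paste0("y", seq_len(p2)))
  S
}
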