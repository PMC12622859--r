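#' Configuration for a synthetic analytical-validation study
#'
#' Describes the generating model of [generate_study()]: a bivariate
#' standard-normal latent trait pair per RM administration instance (the DM
#' construct and the RM construct, correlated at `latent_corr`), congeneric
#' daily DM values and Likert RM items measuring those traits with common
#' loadings, and optional missingness and within-recall temporal drift.
#'
#' Defaults describe a well-designed AV study of moderate size: 500
#' participants each administered one 9-item, 4-level Likert RM with a
#' 14-day recall; digital data on the 7 days nearest the administration;
#' loadings 0.7 on both sides (about half of each indicator's variance is
#' trait variance, typical of validated COA items); latent correlation 0.5;
#' no drift and no missingness.
#'
#' @param n_participants Number of participants.
#' @param instances_per_participant RM administrations per participant;
#'   windows are consecutive and non-overlapping.
#' @param latent_corr Correlation `rho` between the DM and RM traits,
#'   in (-1, 1).
#' @param dm_loading,rm_loading Standardised loadings in (0, 1); indicator
#'   uniqueness is `1 - loading^2`.
#' @param n_items Number of RM items (>= 3).
#' @param likert_levels Number of Likert categories `L` (items scored
#'   `0..L-1`).
#' @param recall_days RM recall-period length in days.
#' @param dm_days_per_window Days with DM (and daily-RM) data per window,
#'   placed nearest the administration date (`<= recall_days`).
#' @param p_miss_dm,p_miss_rm_item,p_miss_daily Independent missingness
#'   probabilities for DM days, RM items and daily-RM days.
#' @param temporal_drift Drift `delta` in \[0, 1\]: the day-level trait is
#'   `sqrt(1 - delta^2) * eta + delta * zeta` with a fresh standard-normal
#'   `zeta` per window, degrading temporal coherence between the measures
#'   (0 = perfectly stable trait, 1 = no coherence).
#' @param dm_mode `"gaussian"` (used for parameter-recovery work, since the
#'   closed-form reliabilities hold exactly) or `"count"`, a cosmetic
#'   log-normal step-count-like rounding with location `count_mu` and scale
#'   `count_sigma`.
#' @param count_mu,count_sigma Log-scale location/scale for `"count"` mode.
#' @param seed Integer seed; all randomness in [generate_study()] derives
#'   from it.
#' @return An object of class `avtk_sim_config`.
#' @export
sim_config <- function(n_participants = 500L, instances_per_participant = 1L,
                       latent_corr = 0.5, dm_loading = 0.7, rm_loading = 0.7,
                       n_items = 9L, likert_levels = 4L, recall_days = 14L,
                       dm_days_per_window = 7L, p_miss_dm = 0,
                       p_miss_rm_item = 0, p_miss_daily = 0,
                       temporal_drift = 0, dm_mode = c("gaussian", "count"),
                       count_mu = 8, count_sigma = 0.5, seed = 1L) {
  dm_mode <- match.arg(dm_mode)
  stopifnot(n_participants >= 0, instances_per_participant >= 1,
            abs(latent_corr) < 1, dm_loading > 0, dm_loading < 1,
            rm_loading > 0, rm_loading < 1, n_items >= 3, likert_levels >= 2,
            recall_days >= 1, dm_days_per_window >= 1,
            dm_days_per_window <= recall_days,
            p_miss_dm >= 0, p_miss_dm <= 1, p_miss_rm_item >= 0,
            p_miss_rm_item <= 1, p_miss_daily >= 0, p_miss_daily <= 1,
            temporal_drift >= 0, temporal_drift <= 1)
  structure(list(n_participants = as.integer(n_participants),
                 instances_per_participant = as.integer(instances_per_participant),
                 latent_corr = latent_corr, dm_loading = dm_loading,
                 rm_loading = rm_loading, n_items = as.integer(n_items),
                 likert_levels = as.integer(likert_levels),
                 recall_days = as.integer(recall_days),
                 dm_days_per_window = as.integer(dm_days_per_window),
                 p_miss_dm = p_miss_dm, p_miss_rm_item = p_miss_rm_item,
                 p_miss_daily = p_miss_daily, temporal_drift = temporal_drift,
                 dm_mode = dm_mode, count_mu = count_mu,
                 count_sigma = count_sigma, seed = as.integer(seed)),
            class = "avtk_sim_config")
}

# Deterministic sub-seed per generation stage, so each stage's draws are
# reproducible independently of how many draws other stages consume.
substream_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1664525 + 1013904223 + stream) %% 2147483647)
}

#' Draw correlated latent trait pairs
#'
#' Zero-mean, unit-variance bivariate normal pairs with correlation `rho`,
#' one pair per RM administration instance.
#'
#' @param n Number of pairs.
#' @param rho Latent correlation, `|rho| < 1`.
#' @param seed Optional integer seed.
#' @return An `n x 2` matrix with columns `eta1` (DM trait), `eta2`
#'   (RM trait).
#' @export
sample_latent_pairs <- function(n, rho, seed = NULL) {
  if (abs(rho) >= 1) stop("|rho| must be < 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  cbind(eta1 = z1, eta2 = rho * z1 + sqrt(1 - rho^2) * z2)
}

#' Discretise a latent response onto a Likert scale
#'
#' Cuts a standard-normal latent response at the `L - 1` equal-probability
#' normal quantiles, yielding categories `0..L-1` with equal marginal
#' probabilities. Bins are half-open: category `c` covers
#' `[t_c, t_(c+1))`.
#'
#' @param z Numeric vector of latent responses.
#' @param L Number of categories (>= 2).
#' @return Integer vector in `0..L-1`.
#' @export
likert_discretize <- function(z, L) {
  if (L < 2) stop("L must be >= 2", call. = FALSE)
  findInterval(z, stats::qnorm(seq_len(L - 1L) / L))
}

#' Generate item scores for RM administration instances
#'
#' Each item is a congeneric Likert indicator of the RM trait:
#' `likert_discretize(rm_loading * eta2 + sqrt(1 - rm_loading^2) * eps, L)`
#' with independent standard-normal item errors, then each item is set
#' missing independently with probability `p_miss_rm_item`.
#'
#' @param eta2 Vector of RM trait values (one per instance).
#' @param cfg An [sim_config()].
#' @param seed Optional integer seed.
#' @return Integer matrix, instances in rows, items in columns (`NA` =
#'   missing item).
#' @export
generate_rm_instance <- function(eta2, cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(eta2)
  k <- cfg$n_items
  lam <- cfg$rm_loading
  eps <- matrix(stats::rnorm(n * k), n, k)
  scores <- matrix(likert_discretize(lam * eta2 + sqrt(1 - lam^2) * eps,
                                     cfg$likert_levels), n, k)
  if (cfg$p_miss_rm_item > 0) {
    miss <- matrix(stats::runif(n * k) < cfg$p_miss_rm_item, n, k)
    scores[miss] <- NA_integer_
  }
  colnames(scores) <- paste0("item_", seq_len(k))
  scores
}

#' Generate daily DM values for administration windows
#'
#' The trait expressed during a window is
#' `sqrt(1 - delta^2) * eta1 + delta * zeta` with one fresh standard-normal
#' `zeta` per window (`delta = temporal_drift`); each of the
#' `dm_days_per_window` days then measures it congenerically:
#' `dm_loading * trait + sqrt(1 - dm_loading^2) * eps_day` in gaussian
#' mode, or `round(exp(count_mu + count_sigma * (...)))`, floored at zero,
#' in count mode. Days are set missing independently with probability
#' `p_miss_dm`.
#'
#' @param eta1 Vector of DM trait values (one per window).
#' @param cfg An [sim_config()].
#' @param seed Optional integer seed.
#' @return Numeric matrix, windows in rows and days in columns (oldest to
#'   newest; `NA` = missing day).
#' @export
generate_dm_series <- function(eta1, cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(eta1)
  d <- cfg$dm_days_per_window
  delta <- cfg$temporal_drift
  lam <- cfg$dm_loading
  zeta <- stats::rnorm(n)
  trait <- sqrt(1 - delta^2) * eta1 + delta * zeta
  eps <- matrix(stats::rnorm(n * d), n, d)
  std <- lam * trait + sqrt(1 - lam^2) * eps
  vals <- if (cfg$dm_mode == "gaussian") std else
    pmax(round(exp(cfg$count_mu + cfg$count_sigma * std)), 0)
  if (cfg$p_miss_dm > 0) {
    miss <- matrix(stats::runif(n * d) < cfg$p_miss_dm, n, d)
    vals[miss] <- NA_real_
  }
  colnames(vals) <- paste0("day_", seq_len(d))
  vals
}

generate_daily_rm <- function(eta2, cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(eta2)
  d <- cfg$dm_days_per_window
  delta <- cfg$temporal_drift
  lam <- cfg$rm_loading
  zeta <- stats::rnorm(n)
  trait <- sqrt(1 - delta^2) * eta2 + delta * zeta
  eps <- matrix(stats::rnorm(n * d), n, d)
  scores <- matrix(likert_discretize(lam * trait + sqrt(1 - lam^2) * eps,
                                     cfg$likert_levels), n, d)
  vals <- scores * 100 / (cfg$likert_levels - 1L)  # scaled 0-100 totals
  if (cfg$p_miss_daily > 0) {
    miss <- matrix(stats::runif(n * d) < cfg$p_miss_daily, n, d)
    vals[miss] <- NA_real_
  }
  vals
}

#' Generate a complete synthetic AV study with known ground truth
#'
#' Composes [sample_latent_pairs()], [generate_dm_series()],
#' [generate_rm_instance()] and a matching one-item daily RM into an
#' `avtk_study` in exactly the shape the alignment pipeline consumes, plus
#' a ground-truth table of the per-instance latent traits for parameter
#' recovery. Windows of successive instances are consecutive and
#' non-overlapping, anchored at 2020-01-01; within each window, data days
#' are the `dm_days_per_window` days closest to the administration date.
#' All randomness derives from `cfg$seed` through fixed per-stage
#' sub-streams.
#'
#' @param cfg An [sim_config()].
#' @return List of class `avtk_sim` with elements `study` (an
#'   `avtk_study`) and `truth` (data frame of `participant_id`, `instance`,
#'   `admin_date`, `eta1`, `eta2`).
#' @export
generate_study <- function(cfg) {
  stopifnot(inherits(cfg, "avtk_sim_config"))
  L <- cfg$likert_levels
  rm_spec <- instrument_spec("SIM-RM", cfg$n_items, 0L, L - 1L,
                             cfg$recall_days)
  daily_spec <- instrument_spec("SIM-DAILY", 1L, 0L, L - 1L, 1L)
  instruments <- list("SIM-RM" = rm_spec, "SIM-DAILY" = daily_spec)

  P <- cfg$n_participants
  m <- cfg$instances_per_participant
  N <- P * m
  epoch <- as.Date("2020-01-01")
  if (N == 0L) {
    empty_study <- study_data(
      dm = data.frame(participant_id = character(), date = as.Date(character()),
                      variable = character(), value = numeric()),
      rm = data.frame(instance_id = character(), participant_id = character(),
                      date = as.Date(character()), instrument = character()),
      rm_items = data.frame(instance_id = character(), item = integer(),
                            score = numeric()),
      daily_rm = NULL, instruments = instruments)
    return(structure(list(study = empty_study,
                          truth = data.frame(participant_id = character(),
                                             instance = integer(),
                                             admin_date = as.Date(character()),
                                             eta1 = numeric(), eta2 = numeric())),
                     class = "avtk_sim"))
  }

  pid <- sprintf("P%04d", rep(seq_len(P), each = m))
  inst_no <- rep(seq_len(m), P)
  admin_date <- epoch + inst_no * cfg$recall_days - 1L
  eta <- sample_latent_pairs(N, cfg$latent_corr,
                             seed = substream_seed(cfg$seed, 1L))
  dm_vals <- generate_dm_series(eta[, 1L], cfg,
                                seed = substream_seed(cfg$seed, 2L))
  rm_scores <- generate_rm_instance(eta[, 2L], cfg,
                                    seed = substream_seed(cfg$seed, 3L))
  daily_vals <- generate_daily_rm(eta[, 2L], cfg,
                                  seed = substream_seed(cfg$seed, 4L))

  d <- cfg$dm_days_per_window
  # day j (1..d, oldest to newest) falls j - d - 1 + ... relative to admin:
  # offsets -(d-1)..0 days before the administration date
  day_offsets <- -(d - 1L):0L
  day_dates <- rep(admin_date, each = d) + rep(day_offsets, N)
  dm_long <- data.frame(participant_id = rep(pid, each = d),
                        date = day_dates, variable = "dm",
                        value = as.vector(t(dm_vals)),
                        stringsAsFactors = FALSE)
  dm_long <- dm_long[!is.na(dm_long$value), , drop = FALSE]

  daily_long <- data.frame(participant_id = rep(pid, each = d),
                           date = day_dates, instrument = "SIM-DAILY",
                           value = as.vector(t(daily_vals)),
                           stringsAsFactors = FALSE)
  daily_long <- daily_long[!is.na(daily_long$value), , drop = FALSE]

  instance_id <- sprintf("SIM-RM|%s|%s#1", pid, format(admin_date))
  rm <- data.frame(instance_id = instance_id, participant_id = pid,
                   date = admin_date, instrument = "SIM-RM",
                   stringsAsFactors = FALSE)
  rm_items <- data.frame(instance_id = rep(instance_id, each = cfg$n_items),
                         item = rep(seq_len(cfg$n_items), N),
                         score = as.numeric(as.vector(t(rm_scores))),
                         stringsAsFactors = FALSE)

  rownames(dm_long) <- rownames(daily_long) <- NULL
  study <- study_data(dm = dm_long, rm = rm, rm_items = rm_items,
                      daily_rm = if (nrow(daily_long)) daily_long else NULL,
                      instruments = instruments)
  truth <- data.frame(participant_id = pid, instance = inst_no,
                      admin_date = admin_date, eta1 = eta[, 1L],
                      eta2 = eta[, 2L], stringsAsFactors = FALSE)
  structure(list(study = study, truth = truth), class = "avtk_sim")
}

#' Closed-form attenuated correlation for the simulator's default model
#'
#' Under the generating model with no drift and no missingness, classical
#' test theory gives the population correlation between the DM window mean
#' (over `m1` parallel days) and the RM total (over `m2` parallel
#' continuous items) as `rho * sqrt(rel1 * rel2)` with Spearman-Brown
#' reliabilities `rel = m * lambda^2 / (m * lambda^2 + 1 - lambda^2)`.
#' Likert discretisation of the items attenuates the observed value
#' slightly further, so this is an upper-bound reference, not an equality.
#'
#' @param rho Latent correlation.
#' @param lambda_dm,lambda_rm Loadings.
#' @param m_dm,m_rm Number of DM days and RM items.
#' @return The attenuated population correlation.
#' @export
attenuated_r <- function(rho, lambda_dm, lambda_rm, m_dm, m_rm) {
  rel <- function(m, l) m * l^2 / (m * l^2 + 1 - l^2)
  rho * sqrt(rel(m_dm, lambda_dm) * rel(m_rm, lambda_rm))
}
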