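#' Specification for a synthetic EMA/wearable cohort
#'
#' A `cohort_spec` collects the generative parameters for seeded synthetic
#' participants: four EMA prompts per day over a month (the study cadence the
#' pipeline assumes), a latent mood model with planted signed feature effects,
#' ordinal label imbalance, and the missingness/constant-sensor artifacts seen
#' in real wearable deployments.
#'
#' The generated ordinal label is produced by thresholding a latent score
#' `latent = sum_f planted_effects[f] * standardised(x_f) + noise` into seven
#' equal-width bins on the standardised latent scale; `label_skew` shifts the
#' bin boundaries upward, concentrating mass on the low end of the scale as in
#' mild-to-moderately depressed cohorts where scale extremes are rare.
#'
#' @param n_participants number of participants the spec describes.
#' @param days days of follow-up (default 30).
#' @param ema_per_day EMA prompts per day (default 4, at 08/12/16/20h).
#' @param planted_effects named numeric vector of signed effect weights on the
#'   latent mood; names must be schema features.
#' @param noise_sd standard deviation of the latent noise term.
#' @param missing_rate fraction of cells made missing in
#'   `block_missing_features` (must be `< 1`).
#' @param block_missing_features features receiving missingness (few columns,
#'   as in real deployments where one sensor drops out).
#' @param constant_artifact_features wearable/EMA features frozen to a constant
#'   (sensor-fault emulation).
#' @param label_skew shift of the ordinal bin boundaries (0 = symmetric).
#' @param seed integer base seed; combined with the participant id.
#' @param schema a [build_feature_schema()] result (default: built fresh).
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 1L,
                        days = 30L,
                        ema_per_day = 4L,
                        planted_effects = c(
                          "anxious" = 0.8, "distracted" = 0.5,
                          "past-day-sugars" = 0.4, "past-day-caffeine" = 0.3,
                          "prev-night-sleep" = -0.4, "cumm-step-count" = -0.3,
                          "GLbias-dACC" = 0.3),
                        noise_sd = 0.8,
                        missing_rate = 0.05,
                        block_missing_features = c("heart-rate", "ppg-std",
                                                   "prev-night-sleep"),
                        constant_artifact_features = character(),
                        label_skew = 0.4,
                        seed = 1L,
                        schema = build_feature_schema()) {
  spec <- structure(list(
    n_participants = as.integer(n_participants), days = as.integer(days),
    ema_per_day = as.integer(ema_per_day), planted_effects = planted_effects,
    noise_sd = noise_sd, missing_rate = missing_rate,
    block_missing_features = block_missing_features,
    constant_artifact_features = constant_artifact_features,
    label_skew = label_skew, seed = as.integer(seed), schema = schema
  ), class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec, k_folds = 5L) {
  feats <- spec$schema$input_features$name
  if (spec$days * spec$ema_per_day < 2L * k_folds)
    stop_config("days * ema_per_day must be at least ", 2L * k_folds)
  if (!is.numeric(spec$missing_rate) || spec$missing_rate < 0 ||
      spec$missing_rate >= 1)
    stop_config("missing_rate must lie in [0, 1)")
  if (spec$noise_sd < 0) stop_config("noise_sd must be non-negative")
  named <- c(names(spec$planted_effects), spec$block_missing_features,
             spec$constant_artifact_features)
  bad <- setdiff(named, feats)
  if (length(bad))
    stop_config("unknown feature(s) in spec: ", paste(bad, collapse = ", "))
  invisible(spec)
}

new_participant_table <- function(timestamps, X, y, schema,
                                  participant_id = "P-1") {
  stopifnot(is.matrix(X), length(timestamps) == nrow(X),
            length(y) == nrow(X))
  tbl <- structure(list(
    participant_id = participant_id,
    timestamps = timestamps,
    X = X,
    y = as.integer(y),
    mask = is.na(X),
    schema = schema
  ), class = "participant_table")
  validate_participant_table(tbl)
  tbl
}

validate_participant_table <- function(tbl) {
  out <- tbl$schema$output_feature
  if (anyNA(tbl$y)) stop_data("output labels must not be missing")
  if (any(tbl$y < out$min | tbl$y > out$max))
    stop_data("output labels outside [", out$min, ",", out$max, "]")
  if (nrow(tbl$X) > 0 && any(rowSums(!tbl$mask) == 0))
    stop_data("a row with all feature values missing is not permitted")
  if (!identical(unname(tbl$mask), unname(is.na(tbl$X))))
    stop_data("mask out of sync with missing cells")
  invisible(tbl)
}

#' @export
print.participant_table <- function(x, ...) {
  cat("<participant_table> ", x$participant_id, ": ", nrow(x$X), " samples x ",
      ncol(x$X), " features, ", sum(x$mask), " missing cells, labels ",
      paste(range(x$y), collapse = "-"), "\n", sep = "")
  invisible(x)
}

#' Generate one synthetic participant
#'
#' Draws a seeded participant table under a [cohort_spec()]: `days *
#' ema_per_day` rows at fixed daily EMA slots (08:00, 12:00, 16:00, 20:00
#' for the default four), per-kind feature processes, a latent mood score with
#' the spec's planted effects, and ordinal labels from equal-width latent
#' thresholds shifted by `label_skew`. Neurocognitive features are
#' piecewise-constant within assessment epochs (lab days 1, 15 and 30,
#' extrapolated forward), emulating the coarser sampling of in-lab testing.
#' Identical `(spec, seed, participant_id)` give identical tables.
#'
#' @param spec a [cohort_spec()].
#' @param participant_id identifier string; folded into the seed.
#' @return a `participant_table`.
#' @examples
#' tbl <- generate_participant(cohort_spec(seed = 7), "P-1")
#' dim(tbl$X)
#' @export
generate_participant <- function(spec, participant_id = "P-1") {
  validate_cohort_spec(spec)
  schema <- spec$schema
  n <- spec$days * spec$ema_per_day
  feats <- schema$input_features
  seed <- derive_seed(spec$seed, as.character(participant_id))

  with_seed(seed, {
    # timestamps: fixed daily slots spread across 06-24h
    slot_hours <- if (spec$ema_per_day == 4L) c(8, 12, 16, 20) else
      seq(8, 20, length.out = spec$ema_per_day)
    day_idx <- rep(seq_len(spec$days), each = spec$ema_per_day)
    ts <- as.POSIXct("2024-01-01 00:00:00", tz = "UTC") +
      (day_idx - 1) * 86400 + rep(slot_hours, times = spec$days) * 3600

    X <- matrix(NA_real_, n, nrow(feats),
                dimnames = list(NULL, feats$name))
    # neurocognitive epochs: lab days 1, 15, 30 extrapolated forward
    epoch <- findInterval(day_idx, c(1, 15, 30))
    for (j in seq_len(nrow(feats))) {
      f <- feats[j, ]
      if (f$name == "time_of_day") {
        X[, j] <- rep(seq_len(spec$ema_per_day) - 1L, times = spec$days)
        next
      }
      if (f$kind == "neurocognitive") {
        z <- rnorm(3L)                      # one draw per assessment epoch
        z <- z[epoch]
      } else {
        # smooth AR(1) day-to-day process with within-day jitter
        zd <- as.numeric(stats::filter(rnorm(spec$days), 0.6,
                                       method = "recursive"))
        z <- zd[day_idx] + 0.5 * rnorm(n)
      }
      u <- stats::pnorm(z / stats::sd(z))
      vals <- f$min + (f$max - f$min) * u
      if (f$discrete) vals <- round(vals)
      X[, j] <- vals
    }

    # latent mood: planted effects on standardised columns + noise
    latent <- rep(0, n)
    for (fn in names(spec$planted_effects)) {
      col <- X[, fn]
      s <- stats::sd(col)
      if (s == 0) s <- 1
      latent <- latent + spec$planted_effects[[fn]] * (col - mean(col)) / s
    }
    latent <- latent + rnorm(n, sd = spec$noise_sd)
    sl <- stats::sd(latent)
    z <- if (sl > 0) (latent - mean(latent)) / sl else latent * 0
    breaks <- seq(-1.8, 1.8, length.out = 6) + spec$label_skew
    y <- findInterval(z, breaks) + 1L

    tbl <- new_participant_table(ts, X, y, schema, participant_id)

    if (length(spec$constant_artifact_features))
      tbl <- inject_constant_artifact(tbl, spec$constant_artifact_features,
                                      value = 0)
    if (spec$missing_rate > 0 && length(spec$block_missing_features))
      tbl <- inject_missingness(tbl, spec$missing_rate,
                                spec$block_missing_features,
                                mode = "cell_mcar",
                                seed = derive_seed(seed, "miss"))
    tbl
  })
}

#' Generate a cohort of synthetic participants
#'
#' @param spec a [cohort_spec()]; `spec$n_participants` tables are produced
#'   with ids `P-1 ... P-n`.
#' @return named list of `participant_table`s.
#' @export
generate_cohort <- function(spec) {
  ids <- paste0("P-", seq_len(spec$n_participants))
  stats::setNames(lapply(ids, function(id) generate_participant(spec, id)), ids)
}

#' Inject missing cells into selected features
#'
#' Marks cells missing in the listed features, either independently per cell
#' (`cell_mcar`) or in contiguous runs (`block`, emulating sensor dropout for
#' hours at a stretch). A cell whose removal would leave its row entirely
#' missing is skipped, so no all-missing row is ever produced.
#'
#' @param table a `participant_table`.
#' @param rate target missing fraction within the listed features, in `[0,1)`.
#' @param features character vector of feature names (empty = no-op).
#' @param mode `"cell_mcar"` or `"block"`.
#' @param seed integer seed.
#' @return the modified `participant_table`.
#' @export
inject_missingness <- function(table, rate, features,
                               mode = c("cell_mcar", "block"), seed = 1L) {
  mode <- match.arg(mode)
  if (!is.numeric(rate) || rate < 0 || rate >= 1)
    stop_config("rate must lie in [0, 1)")
  if (rate == 0 || length(features) == 0) return(table)
  bad <- setdiff(features, colnames(table$X))
  if (length(bad)) stop_config("unknown feature(s): ", paste(bad, collapse = ", "))

  n <- nrow(table$X)
  X <- table$X
  with_seed(derive_seed(seed, "inject"), {
    for (fn in features) {
      if (mode == "cell_mcar") {
        hit <- which(stats::runif(n) < rate)
      } else {
        hit <- integer(0)
        guard <- 0L
        while (length(hit) < rate * n && guard < 100L) {
          start <- sample.int(n, 1L)
          len <- sample(4:12, 1L)
          hit <- unique(c(hit, start:min(n, start + len - 1L)))
          guard <- guard + 1L
        }
        hit <- utils::head(hit[order(hit)], max(1L, round(rate * n)))
      }
      for (i in hit) {
        # never leave a row all-missing
        if (sum(!is.na(X[i, ])) > 1L || is.na(X[i, fn])) X[i, fn] <- NA_real_
      }
    }
  })
  table$X <- X
  table$mask <- is.na(X)
  validate_participant_table(table)
  table
}

#' Freeze wearable/EMA features to a constant value
#'
#' Emulates the faulty-sensor artifact where a wearable channel reports the
#' same value for the whole study. Only wearable/EMA features may be frozen;
#' a constant neurocognitive feature is plausible real behaviour (consistent
#' test performance), so naming one is treated as a configuration error.
#'
#' @param table a `participant_table`.
#' @param features wearable/EMA feature names (empty = no-op).
#' @param value the constant.
#' @return the modified `participant_table`.
#' @export
inject_constant_artifact <- function(table, features, value = 0) {
  if (length(features) == 0) return(table)
  kinds <- schema_feature_kinds(table$schema)
  bad <- setdiff(features, names(kinds))
  if (length(bad)) stop_config("unknown feature(s): ", paste(bad, collapse = ", "))
  nc <- features[kinds[features] == "neurocognitive"]
  if (length(nc))
    stop_config("constant artifacts only apply to wearable/EMA features, not: ",
                paste(nc, collapse = ", "))
  table$X[, features] <- value
  table$mask <- is.na(table$X)
  table
}
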