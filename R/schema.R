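#' Feature schema for a mood-prediction participant table
#'
#' Builds the fixed 43-feature input schema used throughout the pipeline:
#' 16 features collected through a smartwatch wearable and smartphone EMA
#' prompts (mood-adjacent self-ratings, breathing assessment, past-day diet,
#' heart, activity and sleep aggregates, and the time-of-day bin of the
#' prompt), plus 27 neurocognitive-assessment features derived from six
#' cognitive tasks administered on lab days. The prediction target is the
#' ordinal self-rated `depressed` score on a 1--7 scale (severity increases
#' from 1 to 7), and `datestamp` carries the EMA timestamp.
#'
#' Two neurocognitive features carry their field names (`GLbias-dACC`, the
#' dACC gain-bias signal, and `fo-leftDLPFC`, the left-DLPFC emotion-bias
#' signal); the remaining 25 are named systematically per task and measure
#' (speed, accuracy, consistency, evoked neural response) and are synthetic
#' placeholders, not claims about the original assessment battery.
#'
#' @return An object of class `feature_schema`: a list with
#'   `input_features` (data frame with columns `name`, `kind`, `min`, `max`,
#'   `discrete`), `output_feature` (list with `name`, `min`, `max`) and
#'   `timestamp_feature` (name). Feature kinds are `ema_discrete`,
#'   `ema_continuous`, `wearable_continuous` and `neurocognitive`.
#' @examples
#' sch <- build_feature_schema()
#' nrow(sch$input_features)      # 43
#' table(sch$input_features$kind)
#' @export
build_feature_schema <- function() {
  wearable_ema <- data.frame(
    name = c("distracted", "anxious", "MeanBreathingTime", "Consistency",
             "past-day-fats", "past-day-sugars", "past-day-caffeine",
             "heart-rate", "ppg-std", "cumm-step-count", "cumm-step-calories",
             "cumm-step-distance", "cumm-exercise-calories",
             "cumm-exercise-duration", "prev-night-sleep", "time_of_day"),
    kind = c("ema_discrete", "ema_discrete", "ema_continuous", "ema_continuous",
             "ema_discrete", "ema_discrete", "ema_discrete",
             "wearable_continuous", "wearable_continuous", "wearable_continuous",
             "wearable_continuous", "wearable_continuous", "wearable_continuous",
             "wearable_continuous", "wearable_continuous", "ema_discrete"),
    min = c(1, 1, 1.5, 0, 0, 0, 0, 50, 0, 0, 0, 0, 0, 0, 2, 0),
    max = c(7, 7, 10, 1, 20, 30, 8, 120, 50, 15000, 600, 12, 800, 180, 11, 3),
    stringsAsFactors = FALSE
  )

  tasks <- c("inhibition", "interference", "workingmem", "emobias",
             "intattention", "reward")
  measures <- c("speed", "accuracy", "consistency", "evoked")
  nc_names <- as.vector(t(outer(tasks, measures, paste, sep = "-")))
  # 24 task-by-measure placeholders + 2 named neural signals + 1 global score
  nc_names <- c(nc_names, "GLbias-dACC", "fo-leftDLPFC", "global-cognition")
  nc_min <- rep(c(0, 0, 0, -1), times = length(tasks))
  nc_max <- rep(c(2, 1, 1, 1), times = length(tasks))
  neuro <- data.frame(
    name = nc_names,
    kind = "neurocognitive",
    min = c(nc_min, -1, -1, -2),
    max = c(nc_max, 1, 1, 2),
    stringsAsFactors = FALSE
  )

  input <- rbind(wearable_ema, neuro)
  input$discrete <- input$kind == "ema_discrete"
  rownames(input) <- NULL

  stopifnot(nrow(input) == 43L,
            sum(input$kind != "neurocognitive") == 16L,
            sum(input$kind == "neurocognitive") == 27L)

  structure(list(
    input_features = input,
    output_feature = list(name = "depressed", min = 1L, max = 7L),
    timestamp_feature = "datestamp"
  ), class = "feature_schema")
}

#' @export
print.feature_schema <- function(x, ...) {
  k <- table(x$input_features$kind)
  cat("<feature_schema> 43 input features (",
      paste(names(k), k, sep = ": ", collapse = ", "),
      "), output '", x$output_feature$name, "' on [",
      x$output_feature$min, ",", x$output_feature$max, "]\n", sep = "")
  invisible(x)
}

# kinds counted as wearable/EMA (i.e. not neurocognitive)
wearable_ema_kinds <- c("ema_discrete", "ema_continuous", "wearable_continuous")

schema_feature_kinds <- function(schema) {
  stats::setNames(schema$input_features$kind, schema$input_features$name)
}
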