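# Missing-data handling: the three preparation schemes (deletion, manual
# type-aware imputation, automatic KS-selected imputation), the seven column
# fill methods, and standard normalisation.

#' The seven imputation methods
#'
#' Enumeration of the supported per-column fill methods: `mean`, `median`,
#' `forward_fill`, `backward_fill`, `linear_interpolation`, `iterative`
#' (round-robin regression of each incomplete feature on the others), and
#' `knn` (mean over nearest neighbours measured on mutually observed
#' features).
#'
#' @return character vector of method names.
#' @export
imputation_methods <- function() {
  c("mean", "median", "forward_fill", "backward_fill",
    "linear_interpolation", "iterative", "knn")
}

new_preprocess_report <- function(scheme, dropped_features = character(),
                                  dropped_rows = 0L, excluded = FALSE,
                                  reason = NULL,
                                  chosen_method_per_feature = NULL,
                                  ks_scores = NULL) {
  structure(list(scheme = scheme, dropped_features = dropped_features,
                 dropped_rows = as.integer(dropped_rows), excluded = excluded,
                 reason = reason,
                 chosen_method_per_feature = chosen_method_per_feature,
                 ks_scores = ks_scores),
            class = "preprocess_report")
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat("<preprocess_report> scheme=", x$scheme,
      if (x$excluded) " [participant excluded]" else "",
      ", dropped features: ", length(x$dropped_features),
      ", dropped rows: ", x$dropped_rows, "\n", sep = "")
  invisible(x)
}

#' Sort a participant table by timestamp
#'
#' Stable sort on the EMA timestamps (ties keep their original relative
#' order), applied before any preprocessing so that fill methods that carry
#' values forward/backward respect chronology.
#'
#' @param table a `participant_table`.
#' @return the time-sorted table.
#' @export
time_sort <- function(table) {
  if (anyNA(table$timestamps)) stop_data("unparseable/missing timestamp")
  ord <- order(table$timestamps)   # order() is stable
  table$timestamps <- table$timestamps[ord]
  table$X <- table$X[ord, , drop = FALSE]
  table$y <- table$y[ord]
  table$mask <- table$mask[ord, , drop = FALSE]
  table
}

#' Detect constant feature columns
#'
#' Flags features whose observed (non-missing) values are all equal. Missing
#' cells are ignored: a column observed at a single value carries no signal
#' regardless of gaps. A constant wearable reading over a month indicates a
#' faulty sensor, which is why the deletion scheme excludes such participants.
#'
#' @param table a `participant_table`.
#' @param restrict_to_wearable if `TRUE`, only wearable/EMA features are
#'   reported (constant neurocognitive performance is plausible).
#' @return character vector of flagged feature names.
#' @export
detect_constant_features <- function(table, restrict_to_wearable = TRUE) {
  if (nrow(table$X) == 0) stop_data("empty table")
  kinds <- schema_feature_kinds(table$schema)
  nms <- colnames(table$X)
  flagged <- nms[vapply(nms, function(fn) {
    obs <- table$X[!table$mask[, fn], fn]
    length(obs) > 0 && length(unique(obs)) == 1L
  }, logical(1))]
  if (restrict_to_wearable)
    flagged <- flagged[kinds[flagged] %in% wearable_ema_kinds]
  unname(flagged)
}

#' Deletion preprocessing
#'
#' The simplest scheme: participants with any constant wearable/EMA feature
#' are excluded outright (the constant indicates invalid sensor data), and
#' otherwise every row containing a missing value is removed, leaving a fully
#' observed table.
#'
#' @param table a time-sorted `participant_table`.
#' @return list with `table` (`NULL` when excluded) and `report`
#'   (a `preprocess_report`).
#' @export
deletion_preprocess <- function(table) {
  const <- detect_constant_features(table, restrict_to_wearable = TRUE)
  if (length(const)) {
    return(list(table = NULL,
                report = new_preprocess_report(
                  "deletion", excluded = TRUE,
                  reason = paste0("constant wearable/EMA feature(s): ",
                                  paste(const, collapse = ", ")))))
  }
  keep <- rowSums(table$mask) == 0L
  dropped <- sum(!keep)
  if (!any(keep))
    stop_data("no complete rows remain after deletion")
  table$X <- table$X[keep, , drop = FALSE]
  table$y <- table$y[keep]
  table$timestamps <- table$timestamps[keep]
  table$mask <- table$mask[keep, , drop = FALSE]
  list(table = table,
       report = new_preprocess_report("deletion", dropped_rows = dropped))
}

#' Fill a single column by a simple method
#'
#' Applies one of the five single-column fill methods. `forward_fill` carries
#' the last observed value forward; a leading missing run (with nothing to
#' carry) falls back to the first observed value (and symmetrically for
#' `backward_fill`). `linear_interpolation` interpolates on row index and
#' extends the boundary values outward.
#'
#' @param values numeric vector with `NA`s (at least one observed value).
#' @param method one of `mean`, `median`, `forward_fill`, `backward_fill`,
#'   `linear_interpolation`.
#' @return completed numeric vector; observed entries are untouched.
#' @export
fill_column <- function(values, method) {
  method <- match.arg(method, c("mean", "median", "forward_fill",
                                "backward_fill", "linear_interpolation"))
  obs <- !is.na(values)
  if (!any(obs)) stop_data("all-missing column cannot be filled")
  if (all(obs)) return(values)
  out <- values
  if (method == "mean") {
    out[!obs] <- mean(values[obs])
  } else if (method == "median") {
    out[!obs] <- stats::median(values[obs])
  } else if (method %in% c("forward_fill", "backward_fill")) {
    idx <- which(obs)
    if (method == "forward_fill") {
      pos <- findInterval(seq_along(values), idx)
      pos[pos == 0L] <- 1L            # leading run: backward fallback
      out <- values[idx[pos]]
    } else {
      rev_fill <- fill_column(rev(values), "forward_fill")
      out <- rev(rev_fill)
    }
  } else {
    out <- stats::approx(x = which(obs), y = values[obs],
                         xout = seq_along(values), rule = 2)$y
  }
  out[obs] <- values[obs]
  out
}

#' Iterative (round-robin regression) imputation
#'
#' Missing cells are initialised with column means; each feature with missing
#' values is then modelled by ordinary least squares on all other features,
#' the regression being fitted only on rows that were originally complete, and
#' its missing cells re-predicted. Sweeps repeat round-robin until the largest
#' per-cell change (on the normalised scale) drops below `tol` or `max_iter`
#' sweeps are exhausted. Observed cells are never modified. When no complete
#' row exists the method falls back to mean imputation (reported via a
#' `"moodcast_fallback"` condition).
#'
#' @param table a `participant_table` (or a bare numeric matrix).
#' @param max_iter maximum sweeps (default 10).
#' @param tol convergence tolerance on the per-column-sd scale (default 1e-3).
#' @return completed table (or matrix).
#' @export
iterative_impute <- function(table, max_iter = 10L, tol = 1e-3) {
  is_tbl <- inherits(table, "participant_table")
  X <- if (is_tbl) table$X else table
  miss <- is.na(X)
  if (!any(miss)) return(table)
  p <- ncol(X)
  complete <- rowSums(miss) == 0L

  col_mean <- vapply(seq_len(p), function(j) mean(X[!miss[, j], j]), 0)
  if (anyNA(col_mean)) stop_data("all-missing column cannot be imputed")
  Xw <- X
  for (j in seq_len(p)) Xw[miss[, j], j] <- col_mean[j]

  if (!any(complete) || p < 2L) {
    signalCondition(structure(
      class = c("moodcast_fallback", "condition"),
      list(message = "iterative_impute: no complete rows (or single column); falling back to mean imputation",
           call = NULL)))
    if (is_tbl) { table$X <- Xw; table$mask[] <- FALSE; return(table) }
    return(Xw)
  }

  col_sd <- pmax(apply(X, 2, stats::sd, na.rm = TRUE), .Machine$double.eps)
  targets <- which(colSums(miss) > 0L)
  # OLS coefficients from originally-complete rows are fixed across sweeps
  fits <- lapply(targets, function(j) {
    A <- cbind(1, X[complete, -j, drop = FALSE])
    b <- X[complete, j]
    fit <- stats::lm.fit(A, b)
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0
    cf
  })
  names(fits) <- as.character(targets)

  for (iter in seq_len(max_iter)) {
    delta <- 0
    for (j in targets) {
      cf <- fits[[as.character(j)]]
      rows <- which(miss[, j])
      pred <- drop(cbind(1, Xw[rows, -j, drop = FALSE]) %*% cf)
      delta <- max(delta, max(abs(pred - Xw[rows, j]) / col_sd[j]))
      Xw[rows, j] <- pred
    }
    if (delta < tol) break
  }
  stopifnot(identical(Xw[!miss], X[!miss]))
  if (is_tbl) { table$X <- Xw; table$mask[] <- FALSE; return(table) }
  Xw
}

#' K-nearest-neighbour imputation
#'
#' Each missing cell is replaced by the mean of that feature over the `k`
#' nearest rows, with distance the Euclidean distance over mutually observed
#' features rescaled by the number of shared features
#' (`sqrt(p / n_shared * sum of squared differences)`), so rows sharing few
#' features are not spuriously close. Ties are broken by row order. When no
#' candidate neighbour observes the feature, the column mean is used.
#'
#' @param table a `participant_table` (or a bare numeric matrix).
#' @param k neighbour count (default 5).
#' @return completed table (or matrix).
#' @export
knn_impute <- function(table, k = 5L) {
  if (k < 1L) stop_config("k must be >= 1")
  is_tbl <- inherits(table, "participant_table")
  X <- if (is_tbl) table$X else table
  miss <- is.na(X)
  if (!any(miss)) return(table)
  n <- nrow(X); p <- ncol(X)
  col_mean <- vapply(seq_len(p), function(j) mean(X[!miss[, j], j]), 0)
  if (anyNA(col_mean)) stop_data("all-missing column cannot be imputed")

  Xw <- X
  for (i in which(rowSums(miss) > 0L)) {
    d <- rep(Inf, n)
    for (r in seq_len(n)) {
      if (r == i) next
      shared <- !miss[i, ] & !miss[r, ]
      ns <- sum(shared)
      if (ns == 0L) next
      d[r] <- sqrt(p / ns * sum((X[i, shared] - X[r, shared])^2))
    }
    for (j in which(miss[i, ])) {
      cand <- which(!miss[, j] & is.finite(d))
      if (length(cand) == 0L) { Xw[i, j] <- col_mean[j]; next }
      ord <- cand[order(d[cand])]          # stable: ties keep row order
      nb <- utils::head(ord, k)
      Xw[i, j] <- mean(X[nb, j])
    }
  }
  if (is_tbl) { table$X <- Xw; table$mask[] <- FALSE; return(table) }
  Xw
}

# drop constant wearable/EMA feature columns (shared by manual/auto schemes)
drop_constant_wearable <- function(table) {
  const <- detect_constant_features(table, restrict_to_wearable = TRUE)
  if (length(const)) {
    keep <- setdiff(colnames(table$X), const)
    table$X <- table$X[, keep, drop = FALSE]
    table$mask <- table$mask[, keep, drop = FALSE]
  }
  list(table = table, dropped = const)
}

#' Manual (type-aware) imputation
#'
#' Constant wearable/EMA features are removed as invalid, then each remaining
#' incomplete feature is filled according to its type: discrete EMA features
#' with their most frequent value, continuous features via
#' [iterative_impute()], and neurocognitive features with zero (a zero
#' assessment denotes an empty/void assessment, so zero is the natural
#' stand-in).
#'
#' @param table a time-sorted `participant_table`.
#' @param schema the table's `feature_schema` (defaults to `table$schema`).
#' @return list with completed `table` and `report`.
#' @export
manual_impute <- function(table, schema = table$schema) {
  dc <- drop_constant_wearable(table)
  table <- dc$table
  kinds <- schema_feature_kinds(schema)
  miss_feats <- colnames(table$X)[colSums(table$mask) > 0L]

  nc <- intersect(miss_feats, names(kinds)[kinds == "neurocognitive"])
  for (fn in nc) table$X[table$mask[, fn], fn] <- 0

  disc <- intersect(miss_feats, names(kinds)[kinds == "ema_discrete"])
  for (fn in disc) {
    obs <- table$X[!table$mask[, fn], fn]
    tab <- sort(table(obs), decreasing = TRUE)
    table$X[table$mask[, fn], fn] <- as.numeric(names(tab)[1L])
  }

  cont <- setdiff(miss_feats, c(nc, disc))
  if (length(cont)) {
    # iterate only over continuous targets; other columns already complete
    table <- iterative_impute(table)
  }
  table$mask <- is.na(table$X)
  stopifnot(!any(table$mask))
  list(table = table,
       report = new_preprocess_report("manual", dropped_features = dc$dropped))
}

#' Two-sample Kolmogorov--Smirnov statistic
#'
#' The maximum absolute difference between the empirical CDFs of two samples,
#' evaluated by a direct scan over the union of sample points (well defined
#' with ties, which are common in discrete EMA features).
#'
#' @param a,b non-empty numeric samples.
#' @return the KS statistic in `[0, 1]`.
#' @examples
#' ks_two_sample(c(1, 2, 3, 4), c(1, 2, 3, 10))  # 0.25
#' @export
ks_two_sample <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop_data("empty sample")
  pts <- sort(unique(c(a, b)))
  Fa <- stats::ecdf(a)(pts)
  Fb <- stats::ecdf(b)(pts)
  max(abs(Fa - Fb))
}

#' Automatic imputation with KS-based method selection
#'
#' Constant wearable/EMA features are removed, then for every feature with
#' missing cells each applicable fill method (the five single-column methods,
#' plus iterative and KNN) is run and scored by the two-sample KS statistic
#' between the completed column and the feature's observed values. The
#' method with the smallest KS statistic (i.e. the fill that least distorts
#' the observed marginal distribution) is chosen; ties go to the first method
#' in [imputation_methods()] order. All scores are recorded in the report.
#'
#' @param table a time-sorted `participant_table`.
#' @param schema the table's `feature_schema` (defaults to `table$schema`).
#' @param knn_k neighbour count for the KNN candidate (default 5).
#' @return list with completed `table` and `report` (scheme `"automatic"`,
#'   with `chosen_method_per_feature` and the full `ks_scores` map).
#' @export
auto_impute <- function(table, schema = table$schema, knn_k = 5L) {
  dc <- drop_constant_wearable(table)
  table <- dc$table
  miss_feats <- colnames(table$X)[colSums(table$mask) > 0L]
  if (length(miss_feats) == 0L) {
    return(list(table = table,
                report = new_preprocess_report(
                  "automatic", dropped_features = dc$dropped,
                  chosen_method_per_feature = list(), ks_scores = list())))
  }

  complete_rows <- rowSums(table$mask) == 0L
  multi_ok <- any(complete_rows) && ncol(table$X) >= 2L
  iter_fill <- if (multi_ok) iterative_impute(table$X) else NULL
  knn_fill <- knn_impute(table$X, k = knn_k)

  ks_scores <- list()
  chosen <- list()
  for (fn in miss_feats) {
    obs <- table$X[!table$mask[, fn], fn]
    cand <- list()
    for (m in c("mean", "median", "forward_fill", "backward_fill",
                "linear_interpolation"))
      cand[[m]] <- fill_column(table$X[, fn], m)
    if (!is.null(iter_fill)) cand[["iterative"]] <- iter_fill[, fn]
    cand[["knn"]] <- knn_fill[, fn]
    scores <- vapply(cand, function(v) ks_two_sample(v, obs), 0)
    ks_scores[[fn]] <- scores
    pick <- names(scores)[which.min(scores)]
    chosen[[fn]] <- pick
    table$X[, fn] <- cand[[pick]]
  }
  table$mask <- is.na(table$X)
  stopifnot(!any(table$mask))
  list(table = table,
       report = new_preprocess_report("automatic",
                                      dropped_features = dc$dropped,
                                      chosen_method_per_feature = chosen,
                                      ks_scores = ks_scores))
}

#' Run one of the three preprocessing schemes
#'
#' Convenience dispatcher: time-sorts the table and applies `deletion`,
#' `manual` or `automatic` preprocessing.
#'
#' @param table a `participant_table`.
#' @param scheme one of `"deletion"`, `"manual"`, `"automatic"`.
#' @return list with `table` (`NULL` if the participant was excluded) and
#'   `report`.
#' @export
preprocess <- function(table, scheme = c("deletion", "manual", "automatic")) {
  scheme <- match.arg(scheme)
  table <- time_sort(table)
  switch(scheme,
         deletion = deletion_preprocess(table),
         manual = manual_impute(table),
         automatic = auto_impute(table))
}

#' Standard (z-score) normalisation
#'
#' Centres each feature at its mean and scales to unit standard deviation
#' (`(X - mu) / sigma`, population standard deviation). Zero-variance columns
#' are guarded with `sigma = 1`, mapping them to all-zero. When `params` is
#' supplied (train-fitted), it is applied unchanged, which is how test folds
#' are scaled.
#'
#' @param X complete numeric matrix.
#' @param params optional `normalization_params` from a previous fit.
#' @return list with `X` (normalised matrix) and `params`
#'   (`mu`/`sigma` vectors).
#' @export
standard_normalize <- function(X, params = NULL) {
  if (is.null(params)) {
    mu <- colMeans(X)
    n <- nrow(X)
    sigma <- sqrt(colMeans(sweep(X, 2, mu)^2))  # population sd
    sigma[sigma == 0] <- 1
    params <- structure(list(mu = mu, sigma = sigma),
                        class = "normalization_params")
  }
  Xn <- sweep(sweep(X, 2, params$mu), 2, params$sigma, "/")
  list(X = Xn, params = params)
}
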