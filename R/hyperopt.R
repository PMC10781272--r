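# Hyperparameter search over the 4-dimensional architecture space
# (3 x 31 x 4 x 3 = 1116 candidates) with a suite of from-scratch
# evolutionary/stochastic optimisers operating on a continuous [0,1]^4
# encoding, the 12-combination experiment grid, and overall-best selection.

#' The architecture search space
#'
#' Hidden-layer count 2--4, first-hidden width 30--60, activation in
#' {tanh, relu, elu, linear}, batch size in {4, 6, 8}: 1116 candidates.
#'
#' @return object of class `search_space`.
#' @export
search_space <- function() {
  structure(list(
    n_layers = 2:4,
    input_neurons = 30:60,
    activation = c("tanh", "relu", "elu", "linear"),
    batch_size = c(4L, 6L, 8L)
  ), class = "search_space")
}

space_cardinality <- function(space = search_space()) {
  prod(vapply(space, length, 0L))
}

#' Decode a continuous vector into a candidate
#'
#' Each coordinate of `v` in `[0, 1]` is mapped to the nearest valid value of
#' its dimension (integer or categorical); 0 maps to the lower bound / first
#' level and 1 to the upper bound / last level. [encode_candidate()] is its
#' right inverse: `decode(encode(c)) == c` for every candidate.
#'
#' @param v numeric vector of length 4 (clipped to `[0, 1]`).
#' @param space a [search_space()].
#' @return named list `n_layers`, `input_neurons`, `activation`,
#'   `batch_size`.
#' @export
decode_candidate <- function(v, space = search_space()) {
  stopifnot(length(v) == 4L)
  v <- pmin(pmax(v, 0), 1)
  pick <- function(vals, u) vals[[1L + round_half_up(u * (length(vals) - 1L))]]
  list(n_layers = pick(space$n_layers, v[1L]),
       input_neurons = pick(space$input_neurons, v[2L]),
       activation = pick(space$activation, v[3L]),
       batch_size = pick(space$batch_size, v[4L]))
}

#' Encode a candidate as a vector in `[0, 1]^4`
#'
#' @param cand candidate list as produced by [decode_candidate()].
#' @param space a [search_space()].
#' @return numeric vector of length 4.
#' @export
encode_candidate <- function(cand, space = search_space()) {
  enc <- function(vals, x) (match(x, vals) - 1L) / (length(vals) - 1L)
  c(enc(space$n_layers, cand$n_layers),
    enc(space$input_neurons, cand$input_neurons),
    enc(space$activation, cand$activation),
    enc(space$batch_size, cand$batch_size))
}

candidate_key <- function(cand) {
  paste(cand$n_layers, cand$input_neurons, cand$activation, cand$batch_size,
        sep = "|")
}

#' Enumerate every candidate in the space
#'
#' @param space a [search_space()].
#' @return list of all candidates (1116 for the default space).
#' @export
enumerate_candidates <- function(space = search_space()) {
  grid <- expand.grid(n_layers = space$n_layers,
                      input_neurons = space$input_neurons,
                      activation = space$activation,
                      batch_size = space$batch_size,
                      stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i)
    list(n_layers = grid$n_layers[i], input_neurons = grid$input_neurons[i],
         activation = grid$activation[i], batch_size = grid$batch_size[i]))
}

#' Optimise an objective over the architecture space
#'
#' Runs one of the supported search methods for `budget` generations of
#' `population` candidate evaluations (one evaluation per generation for
#' `one_plus_one`). All methods operate on the `[0,1]^4` encoding; fitness
#' values are cached per decoded candidate, and a proposal that duplicates an
#' already-evaluated candidate reuses its archived fitness while one unseen
#' candidate, drawn uniformly, is evaluated in its place. In this exhaustible
#' 1116-point space that "novelty top-up" keeps the evaluation budget
#' meaningful: any run whose budget covers the space enumerates it completely,
#' and `random` becomes sampling without replacement.
#'
#' Methods: `random` (uniform sampling), `one_plus_one` (single parent,
#' Gaussian mutation with 1/5th-success step adaptation), `pso` (inertia 0.7,
#' cognitive/social constants 1.5), `de` (rand/1/bin, F = 0.8, CR = 0.9),
#' `es` ((mu + lambda) with self-adaptive step sizes), `cma_es` (compact
#' covariance-matrix-adaptation ES), `bayesian` (Latin-hypercube
#' initialisation followed by shrinking Gaussian refinement around the
#' incumbent), and `ngopt_like` (a meta-alias that picks a native method by
#' space size: DE for small enumerable spaces, CMA-ES otherwise).
#'
#' @param objective function mapping a candidate list to a finite numeric
#'   value.
#' @param space a [search_space()].
#' @param method one of the eight method names above.
#' @param budget generations (default 100).
#' @param population candidates per generation (default 10).
#' @param direction `"minimise"` or `"maximise"`.
#' @param seed integer seed.
#' @return object of class `opt_result`: `best` (candidate + fitness),
#'   `history` (data frame of evaluated candidates in order), `method`,
#'   `budget`, `evaluations`, `seed`.
#' @export
optimize_hyperparams <- function(objective, space = search_space(),
                                 method = c("random", "one_plus_one", "pso",
                                            "de", "es", "cma_es", "bayesian",
                                            "ngopt_like"),
                                 budget = 100L, population = 10L,
                                 direction = c("minimise", "maximise"),
                                 seed = 1L) {
  method <- match.arg(method)
  direction <- match.arg(direction)
  if (budget < 1L) stop_config("budget must be >= 1")
  sgn <- if (direction == "minimise") 1 else -1

  if (method == "ngopt_like") {
    inner <- if (space_cardinality(space) <= 2000L) "de" else "cma_es"
    res <- optimize_hyperparams(objective, space, inner, budget, population,
                                direction, seed)
    res$method <- "ngopt_like"
    res$delegated_to <- inner
    return(res)
  }

  all_keys <- vapply(enumerate_candidates(space), candidate_key, "")
  st <- new.env(parent = emptyenv())
  st$archive <- new.env(parent = emptyenv())   # key -> raw fitness
  st$history <- list()
  st$n_seen <- 0L

  eval_cand <- function(cand, gen) {
    key <- candidate_key(cand)
    raw <- objective(cand)
    assign(key, raw, envir = st$archive)
    st$n_seen <- st$n_seen + 1L
    st$history[[length(st$history) + 1L]] <-
      c(cand, list(fitness = raw, iteration = gen))
    raw
  }
  # fitness (internal sign) of a batch of encoded proposals, with top-up
  evaluate <- function(V, gen) {
    apply_rows <- vapply(seq_len(nrow(V)), function(i) {
      cand <- decode_candidate(V[i, ], space)
      key <- candidate_key(cand)
      if (exists(key, envir = st$archive, inherits = FALSE)) {
        if (st$n_seen < length(all_keys)) {
          unseen <- all_keys[!vapply(all_keys, exists, TRUE,
                                     envir = st$archive, inherits = FALSE)]
          pick <- unseen[[sample.int(length(unseen), 1L)]]
          parts <- strsplit(pick, "|", fixed = TRUE)[[1L]]
          extra <- list(n_layers = as.integer(parts[1L]),
                        input_neurons = as.integer(parts[2L]),
                        activation = parts[3L],
                        batch_size = as.integer(parts[4L]))
          eval_cand(extra, gen)
        }
        get(key, envir = st$archive, inherits = FALSE)
      } else {
        eval_cand(cand, gen)
      }
    }, 0)
    sgn * apply_rows
  }

  d <- 4L
  clip01 <- function(M) pmin(pmax(M, 0), 1)

  with_seed(derive_seed(seed, method, "opt"), {
    if (method == "random") {
      for (g in seq_len(budget))
        evaluate(matrix(stats::runif(population * d), population, d), g)

    } else if (method == "one_plus_one") {
      x <- stats::runif(d)
      fx <- evaluate(matrix(x, 1L, d), 1L)
      sigma <- 0.3
      for (g in seq(2L, length.out = max(0L, budget - 1L))) {
        child <- clip01(x + stats::rnorm(d, sd = sigma))
        fc <- evaluate(matrix(child, 1L, d), g)
        if (fc <= fx) {          # success: enlarge step (1/5th rule flavour)
          x <- child; fx <- fc; sigma <- min(0.5, sigma * 1.5)
        } else sigma <- max(0.02, sigma * 1.5^(-0.25))
      }

    } else if (method == "pso") {
      P <- matrix(stats::runif(population * d), population, d)
      V <- matrix(0, population, d)
      f <- evaluate(P, 1L)
      pbest <- P; pbest_f <- f
      g_i <- which.min(pbest_f)
      for (g in seq(2L, length.out = max(0L, budget - 1L))) {
        r1 <- matrix(stats::runif(population * d), population, d)
        r2 <- matrix(stats::runif(population * d), population, d)
        gb <- matrix(pbest[g_i, ], population, d, byrow = TRUE)
        V <- 0.7 * V + 1.5 * r1 * (pbest - P) + 1.5 * r2 * (gb - P)
        P <- clip01(P + V)
        f <- evaluate(P, g)
        upd <- f < pbest_f
        pbest[upd, ] <- P[upd, ]; pbest_f[upd] <- f[upd]
        g_i <- which.min(pbest_f)
      }

    } else if (method == "de") {
      population <- max(4L, population)   # rand/1 needs 3 distinct others
      P <- matrix(stats::runif(population * d), population, d)
      f <- evaluate(P, 1L)
      FF <- 0.8; CR <- 0.9
      for (g in seq(2L, length.out = max(0L, budget - 1L))) {
        Tr <- P
        for (i in seq_len(population)) {
          abc <- sample(setdiff(seq_len(population), i), 3L)
          mut <- P[abc[1L], ] + FF * (P[abc[2L], ] - P[abc[3L], ])
          jr <- sample.int(d, 1L)
          cross <- stats::runif(d) < CR
          cross[jr] <- TRUE
          Tr[i, cross] <- mut[cross]
        }
        Tr <- clip01(Tr)
        ft <- evaluate(Tr, g)
        upd <- ft <= f
        P[upd, ] <- Tr[upd, ]; f[upd] <- ft[upd]
      }

    } else if (method == "es") {
      mu <- max(2L, population %/% 2L)
      P <- matrix(stats::runif(population * d), population, d)
      S <- matrix(0.2, population, d)
      f <- evaluate(P, 1L)
      tau <- 1 / sqrt(2 * d)
      for (g in seq(2L, length.out = max(0L, budget - 1L))) {
        ord <- order(f)
        par <- P[ord[seq_len(mu)], , drop = FALSE]
        par_s <- S[ord[seq_len(mu)], , drop = FALSE]
        par_f <- f[ord[seq_len(mu)]]
        idx <- sample.int(mu, population, replace = TRUE)
        Snew <- pmax(par_s[idx, , drop = FALSE] *
                       exp(tau * matrix(stats::rnorm(population * d),
                                        population, d)), 0.01)
        Pnew <- clip01(par[idx, , drop = FALSE] +
                         Snew * matrix(stats::rnorm(population * d),
                                       population, d))
        fnew <- evaluate(Pnew, g)
        # (mu + lambda) survivor selection
        allP <- rbind(par, Pnew); allS <- rbind(par_s, Snew)
        allf <- c(par_f, fnew)
        keep <- order(allf)[seq_len(population)]
        P <- allP[keep, , drop = FALSE]; S <- allS[keep, , drop = FALSE]
        f <- allf[keep]
      }

    } else if (method == "cma_es") {
      lambda <- max(4L, population)
      mu <- lambda %/% 2L
      w <- log(mu + 0.5) - log(seq_len(mu)); w <- w / sum(w)
      mueff <- 1 / sum(w^2)
      cc <- (4 + mueff / d) / (d + 4 + 2 * mueff / d)
      cs <- (mueff + 2) / (d + mueff + 5)
      c1 <- 2 / ((d + 1.3)^2 + mueff)
      cmu <- min(1 - c1, 2 * (mueff - 2 + 1 / mueff) / ((d + 2)^2 + mueff))
      damps <- 1 + 2 * max(0, sqrt((mueff - 1) / (d + 1)) - 1) + cs
      chiN <- sqrt(d) * (1 - 1 / (4 * d) + 1 / (21 * d^2))
      m <- stats::runif(d); sigma <- 0.3
      C <- diag(d); ps <- rep(0, d); pc <- rep(0, d)
      for (g in seq_len(budget)) {
        ev <- eigen(C, symmetric = TRUE)
        Dg <- sqrt(pmax(ev$values, 1e-12)); B <- ev$vectors
        Zs <- matrix(stats::rnorm(lambda * d), lambda, d)
        Ys <- Zs %*% diag(Dg) %*% t(B)
        Xs <- clip01(sweep(sigma * Ys, 2, m, "+"))
        f <- evaluate(Xs, g)
        ord <- order(f)[seq_len(mu)]
        ym <- drop(w %*% Ys[ord, , drop = FALSE])
        m <- clip01(m + sigma * ym)
        Cinv_half <- B %*% diag(1 / Dg) %*% t(B)
        ps <- (1 - cs) * ps +
          sqrt(cs * (2 - cs) * mueff) * drop(Cinv_half %*% ym)
        hsig <- sqrt(sum(ps^2)) / sqrt(1 - (1 - cs)^(2 * g)) / chiN <
          1.4 + 2 / (d + 1)
        pc <- (1 - cc) * pc + hsig * sqrt(cc * (2 - cc) * mueff) * ym
        Cmu_sum <- matrix(0, d, d)
        for (i in seq_len(mu))
          Cmu_sum <- Cmu_sum + w[i] * tcrossprod(Ys[ord[i], ])
        C <- (1 - c1 - cmu) * C + c1 * (tcrossprod(pc) +
               (1 - hsig) * cc * (2 - cc) * C) + cmu * Cmu_sum
        C <- (C + t(C)) / 2
        sigma <- sigma * exp((cs / damps) * (sqrt(sum(ps^2)) / chiN - 1))
        sigma <- min(max(sigma, 1e-3), 1)
      }

    } else if (method == "bayesian") {
      P <- lhs::randomLHS(population, d)
      f <- evaluate(P, 1L)
      best_x <- P[which.min(f), ]
      for (g in seq(2L, length.out = max(0L, budget - 1L))) {
        sig <- 0.3 * (0.05 / 0.3)^((g - 1) / max(1L, budget - 1L))
        Pn <- clip01(matrix(best_x, population, d, byrow = TRUE) +
                       matrix(stats::rnorm(population * d, sd = sig),
                              population, d))
        Pn[1L, ] <- stats::runif(d)   # keep one global explorer
        fn <- evaluate(Pn, g)
        if (min(fn) < min(f)) best_x <- Pn[which.min(fn), ]
        f <- c(f, fn)
      }
    }
  })

  hist_df <- do.call(rbind, lapply(st$history, function(h)
    data.frame(n_layers = h$n_layers, input_neurons = h$input_neurons,
               activation = h$activation, batch_size = h$batch_size,
               fitness = h$fitness, iteration = h$iteration,
               stringsAsFactors = FALSE)))
  fits <- hist_df$fitness * sgn
  b <- which.min(fits)
  structure(list(
    best = list(candidate = list(n_layers = hist_df$n_layers[b],
                                 input_neurons = hist_df$input_neurons[b],
                                 activation = hist_df$activation[b],
                                 batch_size = hist_df$batch_size[b]),
                fitness = hist_df$fitness[b]),
    history = hist_df, method = method, budget = budget,
    population = population, direction = direction,
    evaluations = nrow(hist_df), seed = seed
  ), class = "opt_result")
}

#' @export
print.opt_result <- function(x, ...) {
  cat("<opt_result> ", x$method, ": best fitness ",
      signif(x$best$fitness, 5), " after ", x$evaluations,
      " evaluations\n", sep = "")
  invisible(x)
}

grid_cells <- function(schemes) {
  cells <- list()
  for (scheme in schemes) {
    for (metric in c("f1", "balanced_accuracy"))
      cells[[length(cells) + 1L]] <- list(problem_type = "classification",
                                          scheme = scheme, metric = metric)
    for (metric in c("mse", "mae"))
      cells[[length(cells) + 1L]] <- list(problem_type = "regression",
                                          scheme = scheme, metric = metric)
  }
  cells
}

#' Run the preprocessing-by-metric experiment grid
#'
#' For every combination of problem type (classification, regression),
#' preprocessing scheme and optimisation metric (classification optimised on
#' macro-F1 or balanced accuracy; regression on MSE or MAE) -- 12 cells for
#' the three schemes -- each requested optimiser searches the architecture
#' space, the objective being the mean 5-fold test metric of the candidate
#' architecture. Each cell keeps each optimiser's best and then the
#' best-of-all-optimisers. A cell whose scheme excluded the participant is
#' marked absent.
#'
#' @param table a raw `participant_table`.
#' @param schemes preprocessing schemes (default all three).
#' @param methods optimiser names (default all eight).
#' @param budget,population optimiser budget per cell (see
#'   [optimize_hyperparams()]).
#' @param epochs,k_folds,patience training settings per evaluation.
#' @param seed integer seed.
#' @return object of class `experiment_grid`: list of cell results, each with
#'   `problem_type`, `scheme`, `metric`, `absent` flag, per-optimiser bests,
#'   winning `candidate`/`method`, and the winner's `cv_report` (with MAE and
#'   MAPE regardless of the optimised metric).
#' @export
run_experiment_grid <- function(table,
                                schemes = c("deletion", "manual", "automatic"),
                                methods = c("random", "one_plus_one", "pso",
                                            "de", "es", "cma_es", "bayesian",
                                            "ngopt_like"),
                                budget = 100L, population = 10L,
                                epochs = 100L, k_folds = 5L, patience = 10L,
                                seed = 1L) {
  prepped <- lapply(schemes, function(s) preprocess(table, s))
  names(prepped) <- schemes

  cells <- grid_cells(schemes)
  results <- lapply(cells, function(cell) {
    pp <- prepped[[cell$scheme]]
    if (is.null(pp$table)) {
      return(c(cell, list(absent = TRUE, reason = pp$report$reason)))
    }
    direction <- if (cell$metric %in% c("f1", "balanced_accuracy"))
      "maximise" else "minimise"
    loss_kind <- if (cell$problem_type == "regression") cell$metric else NULL
    cell_seed <- derive_seed(seed, cell$problem_type, cell$scheme, cell$metric)

    objective <- function(cand) {
      arch <- arch_spec(cand$n_layers, cand$input_neurons, cand$activation,
                        cand$batch_size, cell$problem_type)
      cv <- train_with_cv(pp$table, arch, loss_kind = loss_kind,
                          epochs = epochs, k = k_folds, patience = patience,
                          seed = cell_seed)
      unname(cv$mean$test[[cell$metric]])
    }

    per_method <- lapply(methods, function(m)
      optimize_hyperparams(objective, method = m, budget = budget,
                           population = population, direction = direction,
                           seed = derive_seed(cell_seed, m)))
    names(per_method) <- methods
    fits <- vapply(per_method, function(r) r$best$fitness, 0)
    win_i <- if (direction == "minimise") which.min(fits) else which.max(fits)
    win <- per_method[[win_i]]

    arch <- arch_spec(win$best$candidate$n_layers,
                      win$best$candidate$input_neurons,
                      win$best$candidate$activation,
                      win$best$candidate$batch_size, cell$problem_type)
    cv <- train_with_cv(pp$table, arch, loss_kind = loss_kind,
                        epochs = epochs, k = k_folds, patience = patience,
                        seed = cell_seed)
    c(cell, list(absent = FALSE, method_bests = fits,
                 best_method = methods[win_i],
                 candidate = win$best$candidate, objective = win$best$fitness,
                 cv_report = cv, preprocess_report = pp$report,
                 seed = cell_seed, loss_kind = loss_kind,
                 train_settings = list(epochs = epochs, k_folds = k_folds,
                                       patience = patience)))
  })
  structure(results, class = "experiment_grid")
}

#' Select the overall best model across the grid
#'
#' Among non-absent cells the winner is the one with the lowest mean 5-fold
#' test MAE -- the one metric shared by classification and regression models.
#' Exact ties fall back to the lower mean test MAPE, then to the smaller
#' parameter count.
#'
#' @param grid an `experiment_grid`.
#' @param table the raw `participant_table` the grid was built on (used to
#'   size the parameter-count tie-break).
#' @return list with `cell` (the winning grid cell) and `cv_report`.
#' @export
select_overall_best <- function(grid, table = NULL) {
  present <- Filter(function(cell) !cell$absent, grid)
  if (length(present) == 0L)
    stop_data("all grid cells are absent; participant unusable")
  maes <- vapply(present, function(c) unname(c$cv_report$mean$test[["mae"]]), 0)
  mapes <- vapply(present, function(c) unname(c$cv_report$mean$test[["mape"]]), 0)
  nf <- if (!is.null(table)) ncol(table$X) else 43L
  npar <- vapply(present, function(c) n_model_params(c$cv_report$arch, nf), 0)
  ord <- order(maes, mapes, npar)
  best <- present[[ord[1L]]]
  list(cell = best, cv_report = best$cv_report)
}
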