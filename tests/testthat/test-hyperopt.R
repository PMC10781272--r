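test_that("candidate encoding round-trips through every corner and the bounds", {
  space <- search_space()
  expect_equal(space_cardinality(space), 1116L)
  # corners
  corners <- expand.grid(n_layers = c(2L, 4L), input_neurons = c(30L, 60L),
                         activation = c("tanh", "linear"),
                         batch_size = c(4L, 8L), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(corners))) {
    cand <- list(n_layers = corners$n_layers[i],
                 input_neurons = corners$input_neurons[i],
                 activation = corners$activation[i],
                 batch_size = corners$batch_size[i])
    expect_identical(decode_candidate(encode_candidate(cand)), cand)
  }
  expect_identical(decode_candidate(c(0, 0, 0, 0)),
                   list(n_layers = 2L, input_neurons = 30L,
                        activation = "tanh", batch_size = 4L))
  expect_identical(decode_candidate(c(1, 1, 1, 1)),
                   list(n_layers = 4L, input_neurons = 60L,
                        activation = "linear", batch_size = 8L))
  # full-space round trip
  for (cand in enumerate_candidates(space))
    expect_identical(decode_candidate(encode_candidate(cand, space), space),
                     cand)
})

test_that("tiny budgets behave and histories respect direction", {
  res <- optimize_hyperparams(sphere_objective, method = "random",
                              budget = 1, population = 1, seed = 3)
  expect_equal(res$evaluations, 1L)
  expect_equal(res$best$fitness, res$history$fitness[1])

  for (m in c("pso", "de", "es", "one_plus_one")) {
    r <- optimize_hyperparams(sphere_objective, method = m, budget = 6,
                              population = 5, seed = 7)
    expect_lte(r$evaluations, 6L * 5L)
    expect_equal(r$best$fitness, min(r$history$fitness))
    # every history row decodes into the space
    expect_true(all(r$history$n_layers %in% 2:4))
    expect_true(all(r$history$input_neurons %in% 30:60))
    expect_true(all(r$history$activation %in%
                      c("tanh", "relu", "elu", "linear")))
    expect_true(all(r$history$batch_size %in% c(4L, 6L, 8L)))
  }
  # maximisation flips the comparison
  rmax <- optimize_hyperparams(sphere_objective, method = "random",
                               budget = 5, population = 5,
                               direction = "maximise", seed = 7)
  expect_equal(rmax$best$fitness, max(rmax$history$fitness))
  expect_error(optimize_hyperparams(sphere_objective, method = "simplex"))
})

test_that("optimisation is deterministic under a fixed seed", {
  for (m in c("random", "pso", "de", "cma_es", "bayesian")) {
    r1 <- optimize_hyperparams(sphere_objective, method = m, budget = 8,
                               population = 6, seed = 11)
    r2 <- optimize_hyperparams(sphere_objective, method = m, budget = 8,
                               population = 6, seed = 11)
    expect_identical(r1$history, r2$history)
  }
})

test_that("optimiser bests improve with budget on a unimodal objective", {
  for (m in c("pso", "de", "es")) {
    med <- vapply(c(3L, 15L), function(b) {
      stats::median(vapply(1:5, function(s)
        optimize_hyperparams(sphere_objective, method = m, budget = b,
                             population = 6, seed = s)$best$fitness, 0))
    }, 0)
    expect_lte(med[2], med[1])
  }
})

test_that("the experiment grid has the right shape and selection is consistent", {
  tbl <- planted_table(effect = 2, noise = 0.3, seed = 33)
  # single scheme, single optimiser: 4 cells (2 problem types x 2 metrics)
  grid <- run_experiment_grid(tbl, schemes = "manual", methods = "random",
                              budget = 1L, population = 2L, epochs = 3L,
                              seed = 5)
  expect_length(grid, 4L)
  expect_setequal(vapply(grid, `[[`, "", "problem_type"),
                  c("classification", "regression"))
  expect_setequal(vapply(grid, `[[`, "", "metric"),
                  c("f1", "balanced_accuracy", "mse", "mae"))
  for (cell in grid) {
    expect_false(cell$absent)
    dir_min <- cell$metric %in% c("mse", "mae")
    ref <- if (dir_min) min(cell$method_bests) else max(cell$method_bests)
    expect_equal(cell$objective, ref)   # winner attains the per-cell optimum
  }

  best <- select_overall_best(grid, tbl)
  maes <- vapply(grid, function(c) unname(c$cv_report$mean$test[["mae"]]), 0)
  expect_equal(unname(best$cv_report$mean$test[["mae"]]), min(maes))
})

test_that("a constant-sensor participant is absent from deletion cells", {
  tbl <- planted_table(effect = 2, noise = 0.3, seed = 34)
  tbl <- inject_constant_artifact(tbl, "heart-rate", 72)
  grid <- run_experiment_grid(tbl, schemes = c("deletion", "manual"),
                              methods = "random", budget = 1L,
                              population = 2L, epochs = 3L, seed = 6)
  expect_length(grid, 8L)
  del <- Filter(function(c) c$scheme == "deletion", grid)
  expect_true(all(vapply(del, `[[`, TRUE, "absent")))
  man <- Filter(function(c) c$scheme == "manual", grid)
  expect_false(any(vapply(man, `[[`, TRUE, "absent")))
  # the dropped sensor column is reported
  expect_true("heart-rate" %in% man[[1]]$preprocess_report$dropped_features)
})

test_that("overall-best tie-breaks follow MAE, then MAPE, then model size", {
  mk_cell <- function(mae, mape, nl = 2L, inp = 30L) {
    arch <- arch_spec(nl, inp, "tanh", 4, "regression")
    list(problem_type = "regression", scheme = "manual", metric = "mae",
         absent = FALSE,
         cv_report = list(mean = list(test = list(mae = mae, mape = mape)),
                          arch = arch))
  }
  g1 <- structure(list(mk_cell(0.5, 20), mk_cell(0.3, 30), mk_cell(0.9, 10)),
                  class = "experiment_grid")
  expect_equal(select_overall_best(g1)$cell$cv_report$mean$test$mae, 0.3)
  g2 <- structure(list(mk_cell(0.4, 20), mk_cell(0.4, 10)),
                  class = "experiment_grid")
  expect_equal(select_overall_best(g2)$cell$cv_report$mean$test$mape, 10)
  g3 <- structure(list(mk_cell(0.4, 10, inp = 60L), mk_cell(0.4, 10, inp = 30L)),
                  class = "experiment_grid")
  expect_equal(select_overall_best(g3)$cell$cv_report$arch$input_neurons, 30L)
  expect_error(select_overall_best(structure(list(list(absent = TRUE)),
                                             class = "experiment_grid")),
               class = "moodcast_data_error")
})
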