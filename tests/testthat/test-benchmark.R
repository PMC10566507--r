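test_that("splits are seeded, disjoint and exhaustive", {
  plan <- split_plan(n_splits = 5, seed = 3)
  s1 <- make_splits(100, plan)
  s2 <- make_splits(100, plan)
  expect_identical(s1, s2)
  for (sp in s1) {
    expect_length(sp$train, 90)
    expect_length(intersect(sp$train, sp$test), 0)
    expect_setequal(c(sp$train, sp$test), 1:100)
  }
  # the five splits pairwise differ
  trains <- lapply(s1, `[[`, "train")
  for (i in 1:4) for (j in (i + 1):5) {
    expect_false(identical(trains[[i]], trains[[j]]))
  }
  expect_error(split_plan(train_frac = 1.2), "train fraction")
  expect_error(make_splits(5, plan), "too few")
})

test_that("metrics follow their definitions", {
  y <- c(10, 30, 50, 70, 90)
  expect_equal(evaluate(y, y), c(r2 = 1, mae = 0))
  m <- evaluate(y, rep(mean(y), 5))
  expect_equal(m[["r2"]], 0)
  expect_equal(m[["mae"]], mean(abs(y - mean(y))))
  expect_equal(evaluate(y, y + 5)[["mae"]], 5)
  expect_error(evaluate(rep(1, 5), 1:5), "zero variance")
})

test_that("the model registry behaves at its anchor points", {
  set.seed(1)
  X <- matrix(rnorm(500 * 2), 500, 2, dimnames = list(NULL, paste0("x", 1:2)))
  y <- 50 + 10 * X[, 1] - 8 * X[, 2]
  tr <- 1:450; te <- 451:500
  base <- fit_predict(model_spec("mean_baseline"), X[tr, ], y[tr], X[te, ])
  expect_true(all(base == mean(y[tr])))
  rf <- fit_predict(model_spec("random_forest"), X[tr, ], y[tr], X[te, ])
  expect_gt(evaluate(y[te], rf)[["r2"]], 0.9)  # noise-free signal
  expect_true(all(rf >= 0 & rf <= 100))
  # ridge at infinite penalty collapses to the training mean
  ridge_inf <- glmnet::glmnet(X[tr, ], y[tr], alpha = 0, lambda = 1e9)
  expect_equal(unname(predict(ridge_inf, X[te, ])[, 1]),
               rep(mean(y[tr]), length(te)), tolerance = 1e-3)
  expect_error(model_spec("transformer"), "unknown model family")
})

test_that("seeded families are reproducible", {
  set.seed(2)
  X <- matrix(rnorm(200 * 5), 200, 5, dimnames = list(NULL, paste0("x", 1:5)))
  y <- 50 + 5 * X[, 1] + rnorm(200)
  for (fam in c("random_forest", "gradient_boosting", "mlp")) {
    p1 <- fit_predict(model_spec(fam, seed = 7), X[1:150, ], y[1:150],
                      X[151:200, ])
    p2 <- fit_predict(model_spec(fam, seed = 7), X[1:150, ], y[1:150],
                      X[151:200, ])
    expect_identical(p1, p2)
  }
})

test_that("the benchmark grid aggregates per-split metrics without leakage", {
  gen <- small_synthetic()
  ds <- gen$dataset
  y <- yields(ds)
  blk <- assemble_reaction_features(ds, c("fingerprint", "context"),
                                    roles = c("acid", "amine"))
  # canary: constant in train, varying in test -> must be dropped, so
  # results equal those without the canary
  plan <- split_plan(n_splits = 2, seed = 1)
  sp <- make_splits(length(y), plan)[[1]]
  canary <- numeric(length(y))
  canary[sp$test] <- rnorm(length(sp$test))
  with_canary <- feature_block("c", cbind(blk$matrix, canary = canary))
  keep <- amideml:::fit_variance_filter(with_canary$matrix[sp$train, ], 1e-8)
  expect_false("canary" %in% colnames(with_canary$matrix[, keep]))

  grid <- run_benchmark(list(fingerprint = blk), y,
                        list(baseline = model_spec("mean_baseline"),
                             ridge = model_spec("ridge")), plan)
  expect_equal(nrow(grid), 2)
  expect_true(all(grid$r2_sd >= 0))
  raw <- attr(grid, "raw")
  expect_length(raw, 2)
  expect_equal(ncol(raw[["ridge|fingerprint"]]), 2)
  expect_gt(grid$r2_mean[grid$model == "ridge"],
            grid$r2_mean[grid$model == "baseline"])
})

test_that("stacking is the exact mean of base predictions", {
  gen <- small_synthetic()
  ds <- gen$dataset
  y <- yields(ds)
  blocks <- list(
    a = assemble_reaction_features(ds, "battery2d", roles = "acid"),
    b = assemble_reaction_features(ds, c("battery2d", "context"),
                                   roles = "amine"))
  spec <- stack_spec(list(a = model_spec("ridge"), b = model_spec("ridge")))
  sp <- make_splits(length(y), split_plan(n_splits = 1, seed = 2))[[1]]
  out <- stack_fit_predict(spec, blocks, y, sp$train, sp$test)
  expect_equal(out$prediction, rowMeans(out$base_predictions))
  # identical bases make the stack equal any base
  spec2 <- stack_spec(list(a = model_spec("ridge"), b = model_spec("ridge")))
  out2 <- stack_fit_predict(spec2, blocks["a"][c(1, 1)] |>
                              stats::setNames(c("a", "b")), y,
                            sp$train, sp$test)
  expect_equal(out2$prediction, out2$base_predictions[, 1])
  expect_error(stack_fit_predict(spec, blocks["a"], y, sp$train, sp$test),
               "needs block")
})

test_that("negative augmentation adds only unseen zero-yield pairs", {
  ds <- subset_dataset(small_synthetic()$dataset, 1:100)
  expect_identical(augment_negatives(ds, 0), ds)
  aug <- augment_negatives(ds, 0.1, seed = 4)
  expect_length(aug$records, 110)
  added <- aug$records[101:110]
  existing <- unique(vapply(ds$records, function(r) {
    paste(r$acid$smiles, r$amine$smiles)
  }, character(1)))
  for (r in added) {
    expect_equal(r$yield_percent, 0)
    expect_true(isTRUE(attr(r, "synthetic_negative")))
    expect_false(paste(r$acid$smiles, r$amine$smiles) %in% existing)
    expect_length(validate_record(r), 0)
  }
})

test_that("amine-class subsets partition the dataset", {
  ds <- subset_dataset(small_synthetic()$dataset, 1:80)
  subs <- subset_by_amine_class(ds)
  expect_named(subs, c("primary_aliphatic", "primary_aromatic", "secondary"))
  expect_equal(sum(vapply(subs, function(d) length(d$records), numeric(1))),
               length(ds$records))
  for (r in subs$primary_aromatic$records) {
    expect_identical(classify_amine(r$amine), "primary_aromatic")
  }
})
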