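# Model-evaluation harness: fixed 90/10 splits, a model-family registry,
# R2/MAE metrics, the four-block stacking meta-predictor, negative
# augmentation, and amine-class subset analyses.

#' Split plan for repeated train/test evaluation
#'
#' @param n_splits Number of fixed splits (default 5).
#' @param train_frac Training fraction (default 0.9).
#' @param seed Base seed; split `k` uses `seed + k - 1`.
#' @return An object of class `split_plan`.
#' @export
split_plan <- function(n_splits = 5L, train_frac = 0.9, seed = 0L) {
  if (train_frac <= 0 || train_frac >= 1) stop("train fraction must be in (0, 1)")
  obj <- list(n_splits = as.integer(n_splits), train_frac = train_frac,
              seeds = as.integer(seed) + seq_len(n_splits) - 1L)
  class(obj) <- "split_plan"
  obj
}

#' Realize train/test index sets
#'
#' @param n_rows Number of rows to split.
#' @param plan A [split_plan].
#' @return List of `list(train, test)` integer index pairs; per split the
#'   train set holds `floor(train_frac * n_rows)` rows and train/test
#'   partition the rows.
#' @export
make_splits <- function(n_rows, plan = split_plan()) {
  if (n_rows <= 10) stop("too few rows to split: ", n_rows)
  lapply(plan$seeds, function(s) {
    with_seed(s, {
      train <- sort(sample.int(n_rows, floor(plan$train_frac * n_rows)))
      list(train = train, test = setdiff(seq_len(n_rows), train))
    })
  })
}

#' Regression metrics: coefficient of determination and mean absolute error
#'
#' `R2 = 1 - SS_res / SS_tot` with `SS_tot` taken about the test-set mean;
#' MAE is in yield percentage points.
#'
#' @param y_true,y_pred Equal-length numeric vectors (length >= 2).
#' @return Named vector `c(r2, mae)`.
#' @export
evaluate <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 2)
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) stop("R2 undefined: zero variance in y_true")
  c(r2 = 1 - sum((y_true - y_pred)^2) / ss_tot,
    mae = mean(abs(y_true - y_pred)))
}

#' Model specification
#'
#' @param family One of `"mean_baseline"`, `"ridge"`, `"lasso"`, `"svm"`,
#'   `"random_forest"`, `"gradient_boosting"`, `"mlp"`.
#' @param params Named list of family hyperparameters overriding the
#'   defaults (forest: 500 trees; boosting: 500 rounds, depth 3, eta 0.05;
#'   MLP: one hidden layer of 64 units, weight decay 1e-3; SVM: RBF kernel on
#'   standardized inputs).
#' @param seed Seed for stochastic families.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(family, params = list(), seed = 1L) {
  families <- c("mean_baseline", "ridge", "lasso", "svm", "random_forest",
                "gradient_boosting", "mlp")
  if (!family %in% families) stop("unknown model family: ", family)
  obj <- list(family = family, params = params, seed = as.integer(seed))
  class(obj) <- "model_spec"
  obj
}

param_or <- function(spec, name, default) {
  if (!is.null(spec$params[[name]])) spec$params[[name]] else default
}

#' Fit a model and predict on a test matrix
#'
#' Predictions are clipped to `[0, 100]`; seeded families are deterministic
#' for a fixed spec.
#'
#' @param spec A [model_spec].
#' @param X_train,X_test Numeric matrices with identical columns.
#' @param y_train Training yields.
#' @return Numeric prediction vector over `X_test` rows.
#' @export
fit_predict <- function(spec, X_train, y_train, X_test) {
  stopifnot(nrow(X_train) == length(y_train), ncol(X_train) == ncol(X_test))
  if (!all(is.finite(X_train)) || !all(is.finite(X_test))) {
    stop("feature matrix contains non-finite values; variance-filter first")
  }
  pred <- with_seed(spec$seed, switch(spec$family,
    mean_baseline = rep(mean(y_train), nrow(X_test)),
    ridge = glmnet_predict(X_train, y_train, X_test, alpha = 0, spec),
    lasso = glmnet_predict(X_train, y_train, X_test, alpha = 1, spec),
    svm = {
      keep <- which(apply(X_train, 2, stats::sd) > 0)
      fit <- e1071::svm(X_train[, keep, drop = FALSE], y_train,
                        kernel = "radial", scale = TRUE,
                        cost = param_or(spec, "cost", 10),
                        epsilon = param_or(spec, "epsilon", 0.1))
      as.numeric(stats::predict(fit, X_test[, keep, drop = FALSE]))
    },
    random_forest = {
      fit <- ranger::ranger(x = X_train, y = y_train,
                            num.trees = param_or(spec, "num_trees", 500L),
                            mtry = param_or(spec, "mtry",
                                            max(1L, floor(ncol(X_train) / 3))),
                            seed = spec$seed, num.threads = 1)
      stats::predict(fit, X_test, num.threads = 1)$predictions
    },
    gradient_boosting = {
      fit <- xgboost::xgboost(
        x = X_train, y = y_train,
        nrounds = param_or(spec, "nrounds", 500L),
        learning_rate = param_or(spec, "eta", 0.05),
        max_depth = param_or(spec, "max_depth", 3L),
        nthreads = 1, seed = spec$seed, verbosity = 0)
      stats::predict(fit, X_test)
    },
    mlp = {
      mu <- colMeans(X_train)
      sdv <- apply(X_train, 2, stats::sd)
      keep <- which(sdv > 0)
      zs <- function(m) sweep(sweep(m[, keep, drop = FALSE], 2, mu[keep]),
                              2, sdv[keep], "/")
      fit <- nnet::nnet(zs(X_train), y_train / 100,
                        size = param_or(spec, "size", 64L),
                        decay = param_or(spec, "decay", 1e-3),
                        maxit = param_or(spec, "maxit", 300L),
                        linout = TRUE, trace = FALSE, MaxNWts = 1e6)
      100 * as.numeric(stats::predict(fit, zs(X_test)))
    }))
  pmin(100, pmax(0, pred))
}

glmnet_predict <- function(X_train, y_train, X_test, alpha, spec) {
  if (ncol(X_train) < 2) {
    df <- data.frame(x = X_train[, 1], y = y_train)
    fit <- stats::lm(y ~ x, df)
    return(stats::predict(fit, data.frame(x = X_test[, 1])))
  }
  # binary-dominated blocks (fingerprints, context) gain a lot from sparsity
  if (mean(X_train != 0) < 0.25) {
    X_train <- Matrix::Matrix(X_train, sparse = TRUE)
    X_test <- Matrix::Matrix(X_test, sparse = TRUE)
  }
  fit <- glmnet::cv.glmnet(X_train, y_train, alpha = alpha,
                           nfolds = param_or(spec, "nfolds", 3L),
                           nlambda = param_or(spec, "nlambda", 60L),
                           standardize = TRUE)
  as.numeric(stats::predict(fit, X_test, s = "lambda.min"))
}

# --- benchmark grid ----------------------------------------------------------

#' Run the model x feature-block benchmark grid
#'
#' For every (model, block) cell and every split: the variance filter (and
#' optional per-block RFE) is fitted on the training fold only, the model is
#' fitted and evaluated on the held-out fold, and R2/MAE are aggregated as
#' mean and standard deviation over splits.
#'
#' @param blocks Named list of [feature_block]s (full-data matrices; all
#'   per-row transforms are pure, fold-dependent filtering happens inside).
#' @param y Yield vector aligned with block rows.
#' @param specs Named list of [model_spec]s.
#' @param plan A [split_plan].
#' @param variance_threshold Train-fold variance cutoff (default `1e-8`,
#'   which also drops train-constant columns).
#' @return A `benchmark_result`: data.frame with one row per cell plus a
#'   `raw` attribute holding per-split values.
#' @export
run_benchmark <- function(blocks, y, specs, plan = split_plan(),
                          variance_threshold = 1e-8) {
  stopifnot(length(blocks) >= 1, length(specs) >= 1)
  n <- length(y)
  for (b in blocks) stopifnot(nrow(b$matrix) == n)
  splits <- make_splits(n, plan)
  raw <- list()
  cells <- list()
  for (bn in names(blocks)) {
    X <- blocks[[bn]]$matrix
    for (mn in names(specs)) {
      vals <- vapply(seq_along(splits), function(si) {
        tr <- splits[[si]]$train; te <- splits[[si]]$test
        keep <- fit_variance_filter(X[tr, , drop = FALSE], variance_threshold)
        pred <- fit_predict(specs[[mn]], X[tr, keep, drop = FALSE], y[tr],
                            X[te, keep, drop = FALSE])
        evaluate(y[te], pred)
      }, numeric(2))
      raw[[paste(mn, bn, sep = "|")]] <- vals
      cells[[length(cells) + 1]] <- data.frame(
        model = mn, block = bn,
        r2_mean = mean(vals["r2", ]), r2_sd = stats::sd(vals["r2", ]),
        mae_mean = mean(vals["mae", ]), mae_sd = stats::sd(vals["mae", ]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, cells)
  attr(out, "raw") <- raw
  class(out) <- c("benchmark_result", class(out))
  out
}

# --- stacking ----------------------------------------------------------------

#' Stacking specification: one base model per descriptor block
#'
#' The meta-rule is the arithmetic mean of the four base predictions.
#'
#' @param base_specs Named list of [model_spec]s, one per block name
#'   (default: gradient boosting on each of fingerprint, battery2d, aev, qm).
#' @return An object of class `stack_spec`.
#' @export
stack_spec <- function(base_specs = NULL) {
  if (is.null(base_specs)) {
    # linear bases for the wide sparse descriptor blocks, boosted trees for
    # the compact QM table (which carries most of its signal in nonlinear
    # combinations of a few dozen columns)
    base_specs <- list(
      fingerprint = model_spec("ridge"),
      battery2d = model_spec("ridge"),
      aev = model_spec("ridge"),
      qm = model_spec("gradient_boosting"))
  }
  obj <- list(base_specs = base_specs)
  class(obj) <- "stack_spec"
  obj
}

#' Fit the stacking ensemble and predict
#'
#' Fits one base model per feature block on the training rows and returns
#' the exact arithmetic mean of the base predictions on the test rows.
#'
#' @param spec A [stack_spec].
#' @param blocks Named list of [feature_block]s covering all of
#'   `names(spec$base_specs)`.
#' @param y Yield vector aligned with block rows.
#' @param train,test Integer row indices.
#' @param variance_threshold Train-fold variance cutoff.
#' @return List with `prediction` (meta) and `base_predictions` (matrix,
#'   one column per block).
#' @export
stack_fit_predict <- function(spec, blocks, y, train, test,
                              variance_threshold = 1e-8) {
  missing_blocks <- setdiff(names(spec$base_specs), names(blocks))
  if (length(missing_blocks) > 0) {
    stop("stacking needs block(s): ", paste(missing_blocks, collapse = ", "))
  }
  base_pred <- vapply(names(spec$base_specs), function(bn) {
    X <- blocks[[bn]]$matrix
    keep <- fit_variance_filter(X[train, , drop = FALSE], variance_threshold)
    fit_predict(spec$base_specs[[bn]], X[train, keep, drop = FALSE], y[train],
                X[test, keep, drop = FALSE])
  }, numeric(length(test)))
  list(prediction = rowMeans(base_pred), base_predictions = base_pred)
}

#' Evaluate the stacking ensemble over a split plan
#'
#' @inheritParams stack_fit_predict
#' @param plan A [split_plan].
#' @return Data.frame with one row per split: `r2`, `mae`.
#' @export
run_stack_benchmark <- function(spec, blocks, y, plan = split_plan(),
                                variance_threshold = 1e-8) {
  splits <- make_splits(length(y), plan)
  res <- lapply(splits, function(sp) {
    out <- stack_fit_predict(spec, blocks, y, sp$train, sp$test,
                             variance_threshold)
    m <- evaluate(y[sp$test], out$prediction)
    base_mae <- apply(out$base_predictions, 2,
                      function(p) mean(abs(y[sp$test] - p)))
    data.frame(r2 = m[["r2"]], mae = m[["mae"]],
               max_base_mae = max(base_mae))
  })
  do.call(rbind, res)
}

# --- augmentation and subsets ------------------------------------------------

#' Inject artificial negative reactions
#'
#' Adds `floor(fraction * n)` records built from random acid-amine pairs not
#' present in the dataset, with products from [condense_product()], yield 0,
#' and context sampled from the dataset's observed contexts. Added records
#' carry `attr(record, "synthetic_negative") = TRUE`.
#'
#' @param dataset A [reaction_dataset].
#' @param fraction Fraction of the dataset size to add (>= 0).
#' @param seed Seed.
#' @return The augmented [reaction_dataset].
#' @export
augment_negatives <- function(dataset, fraction, seed = 1L) {
  if (fraction < 0) stop("fraction must be >= 0")
  n_add <- floor(fraction * length(dataset$records))
  if (n_add == 0) return(dataset)
  acids <- unique(vapply(dataset$records, function(r) r$acid$smiles, character(1)))
  amines <- unique(vapply(dataset$records, function(r) r$amine$smiles, character(1)))
  existing <- unique(vapply(dataset$records, function(r) {
    paste(r$acid$smiles, r$amine$smiles)
  }, character(1)))
  with_seed(seed, {
    pool_keys <- setdiff(as.vector(outer(acids, amines, paste)), existing)
    if (length(pool_keys) < n_add) {
      stop("fragment pool exhausted: only ", length(pool_keys),
           " unseen pairs available")
    }
    chosen <- sample(pool_keys, n_add)
    parts <- strsplit(chosen, " ", fixed = TRUE)
    ctx_donor <- sample(seq_along(dataset$records), n_add, replace = TRUE)
    prods <- condense_products_batch(vapply(parts, `[`, character(1), 1),
                                     vapply(parts, `[`, character(1), 2))
    new_recs <- lapply(seq_len(n_add), function(i) {
      donor <- dataset$records[[ctx_donor[i]]]
      r <- reaction_record(
        reaction_id = sprintf("NEG%05d", i),
        acid = molecule(parts[[i]][1], "acid"),
        amine = molecule(parts[[i]][2], "amine"),
        product = molecule(prods[i], "product"),
        coupling_agent = donor$coupling_agent,
        yield_percent = 0,
        context = donor$context)
      attr(r, "synthetic_negative") <- TRUE
      r
    })
    reaction_dataset(c(dataset$records, new_recs), dataset$context_vocab)
  })
}

#' Partition a dataset by amine class
#'
#' @param dataset A [reaction_dataset].
#' @return Named list of three [reaction_dataset]s (`primary_aliphatic`,
#'   `primary_aromatic`, `secondary`); empty classes give empty datasets.
#' @export
subset_by_amine_class <- function(dataset) {
  cls <- vapply(dataset$records, function(r) {
    tryCatch(classify_amine(r$amine),
             error = function(e) stop("reaction ", r$reaction_id, ": ",
                                      conditionMessage(e)))
  }, character(1))
  out <- lapply(c(primary_aliphatic = "primary_aliphatic",
                  primary_aromatic = "primary_aromatic",
                  secondary = "secondary"), function(k) {
    subset_dataset(dataset, which(cls == k))
  })
  out
}
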