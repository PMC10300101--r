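#' The SVM hyperparameter grid
#'
#' Candidate configurations for the classifier: a linear kernel crossed
#' with 11 values of the regularization parameter C (1e-4, 1e-3, 1e-2,
#' 0.1, 0.5, 1, 2, 5, 10, 20, 50), plus an RBF kernel crossed with the
#' same 11 C values and the same 11 values for the kernel precision
#' gamma — 11 + 121 = 132 configurations. Order is deterministic: linear
#' configurations first (by C), then RBF in C-major, gamma-minor order.
#'
#' @param cost_grid Candidate C values.
#' @param gamma_grid Candidate gamma values (RBF only).
#' @param kernels Kernels to include.
#' @return Data frame with columns `kernel`, `cost`, `gamma` (`NA` for
#'   linear).
#' @export
svm_config_grid <- function(cost_grid = c(1e-4, 1e-3, 1e-2, 0.1, 0.5, 1, 2, 5, 10, 20, 50),
                            gamma_grid = cost_grid,
                            kernels = c("linear", "radial")) {
  parts <- list()
  if ("linear" %in% kernels)
    parts$linear <- data.frame(kernel = "linear", cost = cost_grid,
                               gamma = NA_real_)
  if ("radial" %in% kernels) {
    g <- expand.grid(gamma = gamma_grid, cost = cost_grid,
                     KEEP.OUT.ATTRS = FALSE)
    parts$radial <- data.frame(kernel = "radial", cost = g$cost,
                               gamma = g$gamma)
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

.fit_svm <- function(x, y, kernel, cost, gamma, seed = 1) {
  set.seed(seed)
  args <- list(x = x, y = y, kernel = kernel, cost = cost,
               scale = FALSE, probability = FALSE)
  if (kernel == "radial") args$gamma <- gamma
  do.call(e1071::svm, args)
}

.decision_scores <- function(fit, x, orientation = 1) {
  p <- stats::predict(fit, x, decision.values = TRUE)
  orientation * as.numeric(attr(p, "decision.values"))
}

#' Tune SVM hyperparameters by stratified cross-validation
#'
#' Evaluates every configuration of [svm_config_grid()] by stratified
#' k-fold cross-validation of the mean held-out F1 score. The
#' standardizer is re-fitted inside each fold on the fold-training rows
#' only, so held-out rows never influence scaling. Ties are broken by
#' grid order.
#'
#' @param features Raw (unstandardized) n x 22 feature matrix.
#' @param labels Logical labels (`TRUE` = called by the hotspot panel).
#' @param folds Number of folds (default 4).
#' @param seed Fold-assignment seed.
#' @param grid Configuration grid; defaults to [svm_config_grid()].
#' @param threshold Decision threshold applied to scores (default 0).
#' @return One-row data frame (the winning configuration) with attributes
#'   `mean_f1` and `cv_f1` (all configurations).
#' @export
tune_hyperparameters <- function(features, labels, folds = 4, seed = 1,
                                 grid = svm_config_grid(), threshold = 0) {
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(labels))
  if (length(unique(labels)) < 2)
    stop("tune_hyperparameters: need both classes")
  fold <- stratified_folds(labels, k = folds, seed = seed)
  y_all <- factor(ifelse(labels, "pos", "neg"), levels = c("neg", "pos"))

  fold_data <- lapply(seq_len(folds), function(f) {
    tr <- fold != f
    s <- fit_standardizer(features[tr, , drop = FALSE])
    list(xtr = apply_standardizer(s, features[tr, , drop = FALSE]),
         xte = apply_standardizer(s, features[!tr, , drop = FALSE]),
         ytr = y_all[tr], lab_te = labels[!tr])
  })

  mean_f1 <- vapply(seq_len(nrow(grid)), function(cfg) {
    f1s <- vapply(fold_data, function(fd) {
      if (length(unique(fd$ytr)) < 2) return(NA_real_)
      fit <- .fit_svm(fd$xtr, fd$ytr, grid$kernel[cfg], grid$cost[cfg],
                      grid$gamma[cfg], seed = seed)
      sc <- .decision_scores(fit, fd$xte, .orientation(fit, fd$xtr, fd$ytr))
      metrics_from_decisions(fd$lab_te, sc >= threshold)$f1
    }, numeric(1))
    mean(f1s, na.rm = TRUE)
  }, numeric(1))

  best <- which.max(mean_f1)
  out <- grid[best, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "mean_f1") <- mean_f1[best]
  attr(out, "cv_f1") <- mean_f1
  out
}

# libsvm's decision-value sign depends on which label it saw first;
# derive the orientation that makes positive scores mean "pos".
.orientation <- function(fit, xtr, ytr) {
  sc <- as.numeric(attr(stats::predict(fit, xtr, decision.values = TRUE),
                        "decision.values"))
  d <- mean(sc[ytr == "pos"]) - mean(sc[ytr == "neg"])
  if (is.na(d) || d >= 0) 1 else -1
}

#' Train the SVM variant filter
#'
#' Fits the standardizer on the training rows, standardizes, and trains
#' an SVM with the given configuration. The returned model carries its
#' own standardizer, configuration, feature order, decision-score
#' orientation and a fingerprint of the training data, and is applied
#' with [svm_predict()].
#'
#' @param features Raw n x 22 feature matrix.
#' @param labels Logical labels.
#' @param config One-row configuration (from [tune_hyperparameters()] or
#'   [svm_config_grid()]).
#' @param seed Solver seed (training is deterministic given data, config
#'   and seed).
#' @return Object of class `svm_filter_model`.
#' @export
svm_train <- function(features, labels, config, seed = 1) {
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(labels))
  if (length(unique(labels)) < 2) stop("svm_train: need both classes")
  s <- fit_standardizer(features)
  x <- apply_standardizer(s, features)
  y <- factor(ifelse(labels, "pos", "neg"), levels = c("neg", "pos"))
  fit <- .fit_svm(x, y, config$kernel, config$cost, config$gamma, seed = seed)
  structure(list(
    fit = fit,
    standardizer = s,
    config = as.list(config[1, c("kernel", "cost", "gamma")]),
    feature_names = colnames(features),
    orientation = .orientation(fit, x, y),
    n_train = nrow(features),
    fingerprint = list(n = nrow(features), n_pos = sum(labels),
                       colsum = unname(round(colSums(features), 6)))
  ), class = "svm_filter_model")
}

#' @export
print.svm_filter_model <- function(x, ...) {
  cat(sprintf("<svm_filter_model: %s kernel, C=%g%s, trained on %d calls>\n",
              x$config$kernel, x$config$cost,
              if (!is.na(x$config$gamma)) sprintf(", gamma=%g", x$config$gamma) else "",
              x$n_train))
  invisible(x)
}

#' Score calls with a trained SVM filter
#'
#' Standardizes the raw features with the model's own standardizer and
#' returns the decision score per call; a call is kept when its score is
#' at least `threshold`. The default threshold 0 is the operating point
#' used throughout the pipeline; raise it for higher specificity or
#' lower it for higher sensitivity.
#'
#' @param model An `svm_filter_model` from [svm_train()].
#' @param features Raw feature matrix with the model's 22 columns.
#' @param threshold Decision threshold (default 0).
#' @return List with `score` (numeric) and `keep` (logical).
#' @export
svm_predict <- function(model, features, threshold = 0) {
  stopifnot(inherits(model, "svm_filter_model"))
  features <- as.matrix(features)
  if (ncol(features) != length(model$feature_names))
    stop(sprintf("svm_predict: %d feature columns, expected %d",
                 ncol(features), length(model$feature_names)))
  if (nrow(features) == 0)
    return(list(score = numeric(0), keep = logical(0)))
  x <- apply_standardizer(model$standardizer, features)
  score <- .decision_scores(model$fit, x, model$orientation)
  list(score = score, keep = score >= threshold)
}

#' Leave-one-patient-out evaluation of filtering strategies
#'
#' Evaluates filtering strategies on labeled cohort data: at each outer
#' iteration the calls of one patient are held out as the test set and
#' the remaining patients form the training set. For the SVM strategy,
#' hyperparameters are tuned on the training patients by inner stratified
#' k-fold cross-validation, the model is re-trained on all training
#' patients with the winning configuration, and applied to the held-out
#' patient; the standardizer is always fitted on training rows only. The
#' rule-based strategy selects its cutoffs by the same inner
#' cross-validation. The `"none"` strategy keeps everything (the
#' no-filtering reference), and `"postprocess"` keeps calls flagged by a
#' precomputed cascade decision, independent of any training.
#'
#' @param calls Calls data frame for the whole cohort.
#' @param features Raw n x 22 feature matrix aligned with `calls`.
#' @param labels Logical labels (`TRUE` = called by the hotspot panel).
#' @param patients Patient id per call.
#' @param strategies Subset of `c("none", "rule", "svm", "postprocess")`.
#' @param missed Named integer vector: per-patient count of ground-truth
#'   variants the large panel never called (counted as false negatives
#'   for every strategy). Default: none.
#' @param cascade_keep Logical vector aligned with `calls` (required for
#'   the `"postprocess"` strategy).
#' @param folds Inner folds (default 4).
#' @param seed Base seed; the inner fold seed is `seed + iteration`.
#' @param grid SVM configuration grid.
#' @param rule_grid Rule grid for the rule-based strategy.
#' @param threshold SVM decision threshold.
#' @return Object of class `lopo_result`: per-strategy list with
#'   `pooled` (a `metrics_report`), `per_patient` (data frame),
#'   `configs` (chosen config per iteration) and `train_patients`.
#' @export
lopo_evaluate <- function(calls, features, labels, patients,
                          strategies = c("none", "rule", "svm"),
                          missed = NULL, cascade_keep = NULL,
                          folds = 4, seed = 1,
                          grid = svm_config_grid(),
                          rule_grid = generate_grid(),
                          threshold = 0) {
  features <- as.matrix(features)
  stopifnot(nrow(calls) == length(labels), length(labels) == length(patients),
            nrow(features) == length(labels))
  strategies <- match.arg(strategies, c("none", "rule", "svm", "postprocess"),
                          several.ok = TRUE)
  if ("postprocess" %in% strategies && is.null(cascade_keep))
    stop("lopo_evaluate: the 'postprocess' strategy needs cascade_keep")
  pts <- unique(patients)
  if (length(pts) < 2) stop("lopo_evaluate: need at least 2 patients")
  if (is.null(missed)) missed <- stats::setNames(integer(length(pts)), pts)

  res <- lapply(strategies, function(s)
    list(counts = list(), configs = list(), train_patients = list()))
  names(res) <- strategies

  for (it in seq_along(pts)) {
    p <- pts[it]
    te <- patients == p
    tr <- !te
    tr_pts <- setdiff(pts, p)
    n_missed <- if (p %in% names(missed)) missed[[p]] else 0L
    it_seed <- seed + it

    for (s in strategies) {
      keep_te <- switch(s,
        none = rep(TRUE, sum(te)),
        postprocess = cascade_keep[te],
        rule = {
          rule <- select_rule_cv(calls[tr, , drop = FALSE], labels[tr],
                                 folds = folds, seed = it_seed,
                                 grid = rule_grid)
          res$rule$configs[[it]] <- rule
          .rule_keep(calls[te, , drop = FALSE], rule$min_coverage,
                     rule$min_vaf, rule$min_quality)
        },
        svm = {
          cfg <- tune_hyperparameters(features[tr, , drop = FALSE], labels[tr],
                                      folds = folds, seed = it_seed,
                                      grid = grid, threshold = threshold)
          model <- svm_train(features[tr, , drop = FALSE], labels[tr],
                             cfg, seed = it_seed)
          res$svm$configs[[it]] <- cfg
          svm_predict(model, features[te, , drop = FALSE],
                      threshold = threshold)$keep
        })
      res[[s]]$counts[[it]] <- data.frame(
        patient = p,
        tp = sum(keep_te & labels[te]),
        fp = sum(keep_te & !labels[te]),
        tn = sum(!keep_te & !labels[te]),
        fn = sum(!keep_te & labels[te]) + n_missed,
        n_calls = sum(te)
      )
      res[[s]]$train_patients[[it]] <- tr_pts
    }
  }

  out <- lapply(strategies, function(s) {
    cc <- do.call(rbind, res[[s]]$counts)
    per_patient <- cc[rowSums(cc[, c("tp", "fp", "tn", "fn")]) > 0, , drop = FALSE]
    if (nrow(per_patient) > 0) {
      mm <- t(vapply(seq_len(nrow(per_patient)), function(i) {
        m <- compute_metrics(per_patient$tp[i], per_patient$fp[i],
                             per_patient$tn[i], per_patient$fn[i])
        c(precision = m$precision, recall = m$recall, f1 = m$f1,
          mcc = m$mcc, youden_j = m$youden_j)
      }, numeric(5)))
      per_patient <- cbind(per_patient, mm)
    }
    list(pooled = compute_metrics(sum(cc$tp), sum(cc$fp), sum(cc$tn), sum(cc$fn)),
         counts = cc,
         per_patient = per_patient,
         configs = res[[s]]$configs,
         train_patients = res[[s]]$train_patients)
  })
  names(out) <- strategies
  structure(list(strategies = out, patients = pts), class = "lopo_result")
}

#' @export
print.lopo_result <- function(x, ...) {
  cat(sprintf("<lopo_result: %d patients>\n", length(x$patients)))
  for (s in names(x$strategies)) {
    cat(sprintf("  %-11s ", s)); print(x$strategies[[s]]$pooled)
  }
  invisible(x)
}

#' Train the final production model on the whole cohort
#'
#' Repeats the stratified k-fold tuning on all cohort data, selects the
#' best configuration, and re-trains the model on everything with that
#' configuration. Intended for applying the filter to regions without
#' ground truth and to new patients.
#'
#' @inheritParams tune_hyperparameters
#' @return An `svm_filter_model` whose `config` carries the winning
#'   configuration and `tuning` attribute the tuning table.
#' @export
train_final <- function(features, labels, folds = 4, seed = 1,
                        grid = svm_config_grid(), threshold = 0) {
  cfg <- tune_hyperparameters(features, labels, folds = folds, seed = seed,
                              grid = grid, threshold = threshold)
  model <- svm_train(features, labels, cfg, seed = seed)
  attr(model, "tuning") <- cfg
  model
}

#' Save / load a trained model
#'
#' Serializes the model (SVM fit, standardizer, configuration, feature
#' order, orientation and training fingerprint) so that a reloaded model
#' reproduces identical decision scores.
#'
#' @param model An `svm_filter_model`.
#' @param path File path.
#' @return `path` (write) or the model (read).
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "svm_filter_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "svm_filter_model"))
    stop("read_model: file does not contain an svm_filter_model")
  model
}
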