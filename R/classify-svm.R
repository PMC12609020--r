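# Feature-path classification: NCA feature weighting with the 0.05 cutoff,
# RBF-SVM with stratified 5-fold cross-validation, and the metric panel.
# Positive class throughout is OA (detecting disease).

#' Neighbourhood component analysis feature weights
#'
#' Maximises the regularised leave-one-out soft-nearest-neighbour objective
#' `mean_i p_i - lambda * sum_j w_j^2` where
#' `p_ij = softmax_j(-sum_k w_k^2 |x_ik - x_jk|)` and `p_i` sums `p_ij`
#' over same-class neighbours. Features are standardised first; gradient
#' ascent starts from `w = 1/sqrt(p)` (unit initial length scale, so the
#' starting pairwise distances are O(1) regardless of dimension) with
#' backtracking step halving, and stops when an accepted step improves the
#' objective by less than `tol`. Reported weights are `w^2` normalised to
#' sum 1, so the 0.05 exclusion cutoff is commensurate with the 1/p
#' average weight.
#'
#' @param X Numeric matrix (n x p), `p >= 2`.
#' @param y Binary labels (factor or character/numeric with 2 levels).
#' @param lambda Ridge penalty; defaults to `1/n`.
#' @param max_iter Iteration cap.
#' @param tol Convergence tolerance on the objective gain per iteration.
#' @param seed Integer seed (reserved for stochastic variants; the default
#'   deterministic initialisation ignores it).
#' @return A list of class `vag_nca`: `weights` (normalised, sum 1),
#'   `weights_raw`, `kept` (indices with weight >= 0.05), `objective`,
#'   `iterations`, `lambda`.
#' @export
nca_weights <- function(X, y, lambda = NULL, max_iter = 200L, tol = 1e-3,
                        seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(p >= 2, n >= 4)
  if (!all(is.finite(X))) abort("Non-finite feature values.")
  y <- as.integer(factor(y))
  if (length(unique(y)) != 2) abort("`y` must have exactly two classes.")
  lambda <- lambda %||% (1 / n)
  Xs <- scale(X)
  Xs[is.nan(Xs)] <- 0  # constant columns
  same <- outer(y, y, `==`); diag(same) <- FALSE
  # |x_ik - x_jk| per feature: n x n x p handled as a list of p matrices
  A <- lapply(seq_len(p), function(k) abs(outer(Xs[, k], Xs[, k], `-`)))
  objective <- function(w) {
    d <- Reduce(`+`, Map(function(a, wk2) a * wk2, A, w^2))
    e <- exp(-d); diag(e) <- 0
    pij <- e / pmax(rowSums(e), .Machine$double.xmin)
    mean(rowSums(pij * same)) - lambda * sum(w^2)
  }
  gradient <- function(w) {
    d <- Reduce(`+`, Map(function(a, wk2) a * wk2, A, w^2))
    e <- exp(-d); diag(e) <- 0
    rs <- pmax(rowSums(e), .Machine$double.xmin)
    pij <- e / rs
    p_i <- rowSums(pij * same)
    g <- vapply(seq_len(p), function(k) {
      Ak <- A[[k]]
      sum(p_i * rowSums(pij * Ak)) - sum((pij * Ak)[same])
    }, numeric(1))
    2 * w * g / n - 2 * lambda * w
  }
  w <- rep(1 / sqrt(p), p)
  obj <- objective(w)
  step <- 0.5
  it <- 0L
  for (it in seq_len(max_iter)) {
    g <- gradient(w)
    gn <- sqrt(sum(g^2))
    if (gn < 1e-8) break
    improved <- FALSE
    s <- step
    gain <- 0
    for (half in 1:20) {
      w_new <- w + s * g
      obj_new <- objective(w_new)
      if (obj_new > obj) {
        gain <- obj_new - obj
        w <- w_new; obj <- obj_new; step <- s * 1.2; improved <- TRUE
        break
      }
      s <- s / 2
    }
    if (!improved || gain < tol) break
  }
  # Normalised squared weights, with a small ridge so the all-irrelevant
  # fixed point (every raw weight shrunk to ~0) reports near-uniform
  # weights instead of amplified numerical noise.
  w2 <- w^2
  weights <- (w2 + 1e-3) / sum(w2 + 1e-3)
  structure(list(weights = weights, weights_raw = w, kept = which(weights >= 0.05),
                 objective = obj, iterations = it, lambda = lambda),
            class = "vag_nca")
}

#' Select features by NCA weight
#'
#' Keeps indices with normalised weight at or above the cutoff. If nothing
#' survives, falls back to the top 3 weights with a warning.
#'
#' @param result A `vag_nca` from [nca_weights()].
#' @param threshold Weight cutoff (0.05).
#' @return Integer vector of feature indices.
#' @export
select_by_weight <- function(result, threshold = 0.05) {
  stopifnot(inherits(result, "vag_nca"))
  keep <- which(result$weights >= threshold)
  if (length(keep) == 0) {
    warn("No feature reaches the weight cutoff; falling back to the top 3.")
    keep <- utils::head(order(result$weights, decreasing = TRUE), 3)
  }
  sort(keep)
}

#' Metrics from a binary confusion matrix
#'
#' @param tp,fn,tn,fp Non-negative counts (positives = OA).
#' @return A tibble with `accuracy`, `sensitivity`, `specificity`,
#'   `precision`, `recall`, `f1`; ratios with zero denominators are `NaN`.
#' @export
metrics_from_confusion <- function(tp, fn, tn, fp) {
  counts <- c(tp, fn, tn, fp)
  if (any(counts < 0)) abort("Negative confusion counts.")
  total <- sum(counts)
  if (total == 0) abort("Empty confusion matrix.")
  div <- function(num, den) if (den > 0) num / den else NaN
  sens <- div(tp, tp + fn)
  prec <- div(tp, tp + fp)
  f1 <- if (is.finite(prec) && is.finite(sens) && (prec + sens) > 0) {
    2 * prec * sens / (prec + sens)
  } else NaN
  tibble::tibble(accuracy = (tp + tn) / total,
                 sensitivity = sens,
                 specificity = div(tn, tn + fp),
                 precision = prec,
                 recall = sens,
                 f1 = f1)
}

#' Trapezoidal ROC curve and AUC
#'
#' Empirical ROC over the distinct score thresholds; tied scores move the
#' curve diagonally, so the trapezoidal area equals the rank/concordance
#' estimator with ties counted 1/2.
#'
#' @param scores Numeric scores, larger = more positive.
#' @param labels Binary labels; `positive` marks the positive class.
#' @param positive Positive-class label (default `"OA"`, or the second
#'   factor level for non-VAG labels).
#' @return A list with `auc` and `roc` (tibble of `fpr`, `tpr`, `threshold`).
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  stopifnot(length(scores) == length(labels))
  labs <- as.character(labels)
  positive <- positive %||% (if ("OA" %in% labs) "OA" else sort(unique(labs))[2])
  y <- labs == positive
  if (all(y) || !any(y)) abort("Both classes must be present.")
  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]; s <- scores[ord]
  # collapse tied scores into single steps
  grp <- cumsum(!duplicated(s))
  tp_steps <- tapply(y, grp, sum)
  fp_steps <- tapply(!y, grp, sum)
  tpr <- c(0, cumsum(tp_steps) / sum(y))
  fpr <- c(0, cumsum(fp_steps) / sum(!y))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  roc <- tibble::tibble(fpr = fpr, tpr = tpr,
                        threshold = c(Inf, s[!duplicated(s)]))
  list(auc = as.numeric(auc), roc = roc)
}

# Seeded stratified fold assignment; every fold contains both classes.
stratified_folds <- function(y, k, seed) {
  y <- as.character(y)
  folds <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      if (length(idx) < k) abort(sprintf("Class '%s' has fewer than k = %d members.", cl, k))
      idx <- sample(idx)
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' RBF-SVM with stratified k-fold cross-validation
#'
#' Per fold: standardise on the training split, train an RBF-kernel SVM
#' (`e1071`), score the held-out fold with continuous decision values for
#' the ROC, and compute the confusion-matrix metric panel at the default
#' decision threshold. Positive class is OA.
#'
#' @param X Numeric feature matrix (n x p).
#' @param y Labels (`HC`/`OA`, or any two classes; the second sorted level
#'   is treated as positive unless `OA` is present).
#' @param k Number of folds (5).
#' @param cost SVM cost parameter.
#' @param gamma RBF width; `"scale"` uses `1 / (p * var)` on the
#'   standardised training data (i.e. `1/p`).
#' @param seed Integer seed for the fold assignment.
#' @return A `vag_cv_report`: tibble `folds` (per-fold metrics + AUC),
#'   `summary` (mean and sd), `roc` (per-fold ROC points), `confusion`
#'   (per-fold counts), `predictions`.
#' @export
svm_rbf_cv <- function(X, y, k = 5L, cost = 1, gamma = "scale", seed = 1L) {
  X <- as.matrix(X)
  labs <- as.character(y)
  positive <- if ("OA" %in% labs) "OA" else sort(unique(labs))[2]
  folds <- stratified_folds(labs, k, seed)
  fold_rows <- list(); roc_rows <- list(); conf_rows <- list(); pred_rows <- list()
  for (f in seq_len(k)) {
    tr <- folds != f; te <- !tr
    mu <- colMeans(X[tr, , drop = FALSE])
    sdv <- apply(X[tr, , drop = FALSE], 2, stats::sd)
    sdv[sdv == 0] <- 1
    Xtr <- sweep(sweep(X[tr, , drop = FALSE], 2, mu), 2, sdv, "/")
    Xte <- sweep(sweep(X[te, , drop = FALSE], 2, mu), 2, sdv, "/")
    g <- if (identical(gamma, "scale")) 1 / (ncol(X) * mean(apply(Xtr, 2, stats::var))) else gamma
    ytr <- factor(labs[tr], levels = c(setdiff(unique(labs), positive), positive))
    fit <- e1071::svm(Xtr, ytr, kernel = "radial", cost = cost, gamma = g,
                      scale = FALSE, probability = FALSE)
    pr <- predict(fit, Xte, decision.values = TRUE)
    # orient decision values so larger means more 'positive': the attribute
    # column is named "first/second" with larger values favouring 'first'
    dv_col <- colnames(attr(pr, "decision.values"))[1]
    first <- strsplit(dv_col, "/", fixed = TRUE)[[1]][1]
    dv <- as.numeric(attr(pr, "decision.values"))
    if (first != positive) dv <- -dv
    pred <- as.character(pr)
    truth <- labs[te]
    tp <- sum(pred == positive & truth == positive)
    fn <- sum(pred != positive & truth == positive)
    tn <- sum(pred != positive & truth != positive)
    fp <- sum(pred == positive & truth != positive)
    met <- metrics_from_confusion(tp, fn, tn, fp)
    ra <- roc_auc(dv, truth, positive = positive)
    fold_rows[[f]] <- dplyr::bind_cols(tibble::tibble(fold = f), met,
                                       tibble::tibble(auc = ra$auc))
    roc_rows[[f]] <- dplyr::mutate(ra$roc, fold = f)
    conf_rows[[f]] <- tibble::tibble(fold = f, tp = tp, fn = fn, tn = tn, fp = fp)
    pred_rows[[f]] <- tibble::tibble(fold = f, truth = truth, predicted = pred, score = dv)
  }
  fold_tbl <- dplyr::bind_rows(fold_rows)
  metric_cols <- setdiff(names(fold_tbl), "fold")
  summary <- fold_tbl |>
    tidyr::pivot_longer(dplyr::all_of(metric_cols), names_to = "metric") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                     sd = stats::sd(.data$value, na.rm = TRUE), .groups = "drop")
  structure(list(folds = fold_tbl, summary = summary,
                 roc = dplyr::bind_rows(roc_rows),
                 confusion = dplyr::bind_rows(conf_rows),
                 predictions = dplyr::bind_rows(pred_rows),
                 positive = positive, k = k, seed = seed),
            class = "vag_cv_report")
}

#' @export
print.vag_cv_report <- function(x, ...) {
  acc <- x$summary[x$summary$metric == "accuracy", ]
  auc <- x$summary[x$summary$metric == "auc", ]
  cat(sprintf("<vag_cv_report> %d-fold CV: accuracy %.3f +/- %.3f, AUC %.3f +/- %.3f (positive: %s)\n",
              x$k, acc$mean, acc$sd, auc$mean, auc$sd, x$positive))
  invisible(x)
}

#' @export
tidy.vag_cv_report <- function(x, ...) x$folds

#' @export
glance.vag_cv_report <- function(x, ...) {
  x$summary |>
    tidyr::pivot_wider(names_from = "metric", values_from = c("mean", "sd"),
                       names_glue = "{metric}_{.value}")
}

#' Plot the cross-validated ROC curves
#'
#' @param object A `vag_cv_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vag_cv_report <- function(object, ...) {
  ggplot2::ggplot(object$roc,
                  ggplot2::aes(x = .data$fpr, y = .data$tpr,
                               colour = factor(.data$fold))) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  colour = "fold") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' @export
tidy.vag_nca <- function(x, ...) {
  tibble::tibble(feature = seq_along(x$weights), weight = x$weights,
                 kept = seq_along(x$weights) %in% x$kept)
}
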