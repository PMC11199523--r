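#' ROC curve, AUC and Youden-optimal threshold
#'
#' AUC is the probability that a randomly chosen positive outscores a
#' randomly chosen negative, ties counting one half (the Mann-Whitney
#' statistic). The curve is swept over the sorted unique scores; the
#' reported operating point maximizes Youden's J = sensitivity +
#' specificity - 1.
#'
#' @param scores numeric classifier scores, larger = more positive.
#' @param labels class labels; `positive` identifies the positive class.
#' @param positive positive-class label (default: last sorted unique label,
#'   or `TRUE`/`1` for logical/binary input).
#' @return List with `curve` (tibble `threshold`, `fpr`, `tpr`), `auc`,
#'   `threshold`, `sensitivity`, `specificity`.
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  if (length(scores) != length(labels)) stop_invalid("scores and labels differ in length")
  labs <- sort(unique(as.character(labels)))
  if (length(labs) != 2) stop_invalid("need exactly two classes, got %d", length(labs))
  if (is.null(positive)) positive <- labs[2]
  pos <- as.character(labels) == as.character(positive)
  n1 <- sum(pos)
  n0 <- sum(!pos)
  rk <- rank(scores)  # midranks handle ties as 1/2
  auc <- (sum(rk[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(th, function(t) mean(scores[pos] >= t), numeric(1))
  fpr <- vapply(th, function(t) mean(scores[!pos] >= t), numeric(1))
  curve <- tibble::tibble(threshold = c(Inf, th), fpr = c(0, fpr), tpr = c(0, tpr))
  j <- which.max(curve$tpr - curve$fpr)
  list(curve = curve, auc = auc, threshold = curve$threshold[j],
       sensitivity = curve$tpr[j], specificity = 1 - curve$fpr[j])
}

#' Lasso feature selection
#'
#' L1-penalized logistic scoring at a fixed penalty; features with nonzero
#' coefficients are the selected set. Expects a standardized feature matrix
#' (the repeated-split evaluator standardizes on training data only).
#'
#' @param x numeric matrix (subjects x features), standardized.
#' @param y two-level factor or character labels.
#' @param lambda penalty (> 0).
#' @return List with `selected` (character), `weights` (named numeric,
#'   nonzero coefficients, intercept excluded).
#' @export
lasso_select <- function(x, y, lambda) {
  if (lambda <= 0) stop_invalid("lambda must be positive")
  y <- factor(y)
  if (nlevels(y) != 2) stop_invalid("need exactly two classes")
  if (min(table(y)) < 2) stop_invalid("need >= 2 subjects per class")
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 1,
                        lambda = lambda, standardize = FALSE)
  w <- as.numeric(stats::coef(fit))[-1]
  names(w) <- colnames(x)
  nz <- w[w != 0]
  list(selected = names(nz), weights = nz)
}

#' Drop near-duplicate features
#'
#' Removes one of every feature pair with absolute correlation above the
#' cutoff, preferring to keep the mean-statistic variant of a feature over
#' its max/min/SD siblings. Intended before minimal-subset searches where
#' mean/max collinearity otherwise makes selections unstable.
#'
#' @param features feature table (`subject`, `group`, feature columns).
#' @param cutoff absolute-correlation threshold (default 0.95).
#' @return The feature table with redundant columns removed.
#' @export
prune_collinear <- function(features, cutoff = 0.95) {
  meta <- c("subject", "group")
  x <- as.matrix(features[, setdiff(names(features), meta)])
  cm <- abs(cor(x, use = "pairwise.complete.obs"))
  diag(cm) <- 0
  keep <- colnames(x)
  # prefer mean-statistic columns: process non-mean columns first as drops
  pref <- grepl("_mean$", keep)
  ord <- order(pref)  # non-mean first => dropped first
  dropped <- character(0)
  for (nm in keep[ord]) {
    if (nm %in% dropped) next
    partners <- colnames(cm)[cm[nm, ] > cutoff]
    partners <- setdiff(partners, dropped)
    if (length(partners) > 0) dropped <- c(dropped, nm)
  }
  features[, c(meta, setdiff(keep, dropped))]
}

#' Classifier configuration
#'
#' @param lambda penalty grid for the lasso scan (default 20 values from
#'   0.02 to 0.4).
#' @param n_realizations number of random train/validation splits.
#' @param train_frac fraction of each class used for training.
#' @param seed integer seed controlling all splits and truncations.
#' @param positive positive-class label (default `"patient"` when present).
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(lambda = seq(0.02, 0.4, length.out = 20),
                              n_realizations = 500L,
                              train_frac = 0.7,
                              seed = 1L,
                              positive = NULL) {
  if (any(lambda <= 0)) stop_invalid("lambda must be positive")
  if (train_frac <= 0 || train_frac >= 1) stop_invalid("train_frac must be in (0, 1)")
  structure(list(lambda = sort(lambda), n_realizations = as.integer(n_realizations),
                 train_frac = train_frac, seed = as.integer(seed),
                 positive = positive),
            class = "classifier_config")
}

#' Repeated-split lasso-LDA evaluation
#'
#' For each realization: stratified random train/validation split;
#' standardization fit on the training fold only; lasso selection at every
#' penalty on the grid; ordinary linear discriminant analysis on the
#' selected features; evaluation on a validation set whose majority class
#' is randomly truncated to the minority count, fixing chance level at
#' 50%. Reports accuracy mean and SD per penalty, the pooled ROC/AUC at
#' the best penalty, the modal selected feature set, and the Youden
#' operating point.
#'
#' @param features feature table: `subject`, `group`, numeric feature
#'   columns. Features missing for more than 20% of subjects are dropped;
#'   remaining missing values are median-imputed.
#' @param config a [classifier_config()].
#' @return A list of class `classifier_report`; see Details.
#' @details The report contains `by_lambda` (tibble: `lambda`, `mean_acc`,
#'   `sd_acc`, `mean_selected`), `best_lambda`, `accuracy_mean`,
#'   `accuracy_sd` (percent), `auc`, `roc` (curve tibble), `threshold`,
#'   `sensitivity`, `specificity`, `selected_features` (modal set at the
#'   best penalty), `n_realizations_used`, `dropped_features`.
#' @export
multirealization_eval <- function(features, config = classifier_config()) {
  meta <- c("subject", "group")
  featnames <- setdiff(names(features), meta)
  y_all <- factor(features$group)
  if (nlevels(y_all) != 2) stop_invalid("need exactly two classes")
  positive <- config$positive
  if (is.null(positive)) {
    positive <- if ("patient" %in% levels(y_all)) "patient" else levels(y_all)[2]
  }

  x_all <- as.matrix(features[, featnames])
  storage.mode(x_all) <- "double"
  na_frac <- colMeans(is.na(x_all))
  dropped <- featnames[na_frac > 0.2]
  x_all <- x_all[, na_frac <= 0.2, drop = FALSE]
  for (j in seq_len(ncol(x_all))) {
    nas <- is.na(x_all[, j])
    if (any(nas)) x_all[nas, j] <- median(x_all[, j], na.rm = TRUE)
  }
  # constant columns carry no information and break standardization
  keep <- apply(x_all, 2, sd) > 0
  x_all <- x_all[, keep, drop = FALSE]

  idx_by_class <- split(seq_along(y_all), y_all)
  lambdas <- config$lambda
  acc <- matrix(NA_real_, nrow = config$n_realizations, ncol = length(lambdas))
  nsel <- matrix(NA_real_, nrow = config$n_realizations, ncol = length(lambdas))
  sel_sets <- vector("list", config$n_realizations)
  val_scores <- vector("list", config$n_realizations)
  val_labels <- vector("list", config$n_realizations)
  used <- logical(config$n_realizations)

  for (rlz in seq_len(config$n_realizations)) {
    split_seed <- derive_seed(config$seed, "split", rlz)
    parts <- with_seed(split_seed, {
      train <- unlist(lapply(idx_by_class, function(ix) {
        sample(ix, max(1, round(config$train_frac * length(ix))))
      }))
      val <- setdiff(seq_along(y_all), train)
      vy <- y_all[val]
      counts <- table(vy)
      k <- min(counts)
      bal <- unlist(lapply(split(val, vy), function(ix) sample(ix, k)))
      list(train = train, val = bal)
    })
    if (min(table(y_all[parts$val])) < 2 || min(table(y_all[parts$train])) < 2) next
    used[rlz] <- TRUE

    xtr <- x_all[parts$train, , drop = FALSE]
    mu <- colMeans(xtr)
    sg <- apply(xtr, 2, sd)
    sg[sg == 0] <- 1
    xtr <- sweep(sweep(xtr, 2, mu), 2, sg, "/")
    xva <- sweep(sweep(x_all[parts$val, , drop = FALSE], 2, mu), 2, sg, "/")
    ytr <- y_all[parts$train]
    yva <- y_all[parts$val]

    # small training folds trip glmnet's sample-size caution; degenerate
    # fits are handled explicitly below
    fit <- suppressWarnings(
      glmnet::glmnet(xtr, ytr, family = "binomial", alpha = 1,
                     lambda = lambdas, standardize = FALSE)
    )
    cf <- stats::coef(fit)
    sel_sets[[rlz]] <- vector("list", length(lambdas))
    val_scores[[rlz]] <- vector("list", length(lambdas))
    val_labels[[rlz]] <- yva

    for (li in seq_along(lambdas)) {
      # glmnet stores solutions for its (descending) lambda sequence
      col <- which(abs(fit$lambda - lambdas[li]) == min(abs(fit$lambda - lambdas[li])))[1]
      w <- as.numeric(cf[-1, col])
      sel <- colnames(xtr)[w != 0]
      # LDA needs fewer predictors than training samples
      max_p <- length(parts$train) - 3
      if (length(sel) > max_p) {
        sel <- sel[order(abs(w[w != 0]), decreasing = TRUE)[seq_len(max_p)]]
      }
      nsel[rlz, li] <- length(sel)
      sel_sets[[rlz]][[li]] <- sel
      if (length(sel) == 0) {
        acc[rlz, li] <- 0.5
        val_scores[[rlz]][[li]] <- rep(0, length(yva))
        next
      }
      lfit <- tryCatch(
        suppressWarnings(MASS::lda(xtr[, sel, drop = FALSE], grouping = ytr)),
        error = function(e) NULL
      )
      if (is.null(lfit)) {
        acc[rlz, li] <- NA_real_
        val_scores[[rlz]][[li]] <- rep(NA_real_, length(yva))
        next
      }
      pr <- predict(lfit, xva[, sel, drop = FALSE])
      acc[rlz, li] <- mean(pr$class == yva)
      val_scores[[rlz]][[li]] <- pr$posterior[, positive]
    }
  }

  if (!any(used)) stop_invalid("no usable validation realization")
  by_lambda <- tibble::tibble(
    lambda = lambdas,
    mean_acc = 100 * colMeans(acc[used, , drop = FALSE], na.rm = TRUE),
    sd_acc = 100 * apply(acc[used, , drop = FALSE], 2, sd, na.rm = TRUE),
    mean_selected = colMeans(nsel[used, , drop = FALSE], na.rm = TRUE)
  )
  best <- which.max(by_lambda$mean_acc)

  pooled_scores <- unlist(lapply(which(used), function(r) val_scores[[r]][[best]]))
  pooled_labels <- unlist(lapply(which(used), function(r) as.character(val_labels[[r]])))
  ok <- !is.na(pooled_scores)
  roc <- roc_auc(pooled_scores[ok], pooled_labels[ok], positive = positive)

  sel_tab <- sort(table(unlist(lapply(which(used), function(r) {
    unique(sel_sets[[r]][[best]])
  }))), decreasing = TRUE)
  modal_n <- round(by_lambda$mean_selected[best])
  modal <- names(sel_tab)[seq_len(min(length(sel_tab), max(modal_n, 1)))]

  structure(list(
    by_lambda = by_lambda,
    best_lambda = lambdas[best],
    accuracy_mean = by_lambda$mean_acc[best],
    accuracy_sd = by_lambda$sd_acc[best],
    auc = roc$auc,
    roc = roc$curve,
    threshold = roc$threshold,
    sensitivity = roc$sensitivity,
    specificity = roc$specificity,
    selected_features = modal,
    positive = positive,
    n_realizations_used = sum(used),
    dropped_features = dropped
  ), class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("<classifier_report> accuracy %.1f%% (SD %.1f) at lambda = %.3g; AUC = %.3f\n",
              x$accuracy_mean, x$accuracy_sd, x$best_lambda, x$auc))
  cat(sprintf("  %d modal features over %d realizations\n",
              length(x$selected_features), x$n_realizations_used))
  invisible(x)
}

# plain-list view of a report for JSON serialization
report_to_list <- function(report) {
  list(
    by_lambda = as.list(report$by_lambda),
    best_lambda = report$best_lambda,
    accuracy_mean = report$accuracy_mean,
    accuracy_sd = report$accuracy_sd,
    auc = report$auc,
    roc = as.list(report$roc),
    threshold = report$threshold,
    sensitivity = report$sensitivity,
    specificity = report$specificity,
    selected_features = report$selected_features,
    positive = report$positive,
    n_realizations_used = report$n_realizations_used,
    dropped_features = report$dropped_features
  )
}
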