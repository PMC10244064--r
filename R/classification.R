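# Decision-tree classification of epileptic-focus laterality from LI features.
# rpart provides the CART machinery; the default configuration (Gini split,
# no depth cap, minimum leaf size 1, no pruning) is fixed here and exposed
# through tree_control().

#' Default CART hyperparameters
#' @param minsplit,minbucket,cp,maxdepth passed to
#'   \code{rpart::rpart.control}
#' @return an \code{rpart.control} list
#' @export
tree_control <- function(minsplit = 2L, minbucket = 1L, cp = 0,
                         maxdepth = 30L) {
  rpart::rpart.control(minsplit = minsplit, minbucket = minbucket, cp = cp,
                       maxdepth = maxdepth, xval = 0L,
                       maxcompete = 0L, maxsurrogate = 0L)
}

# stratified k-fold assignment: class proportions preserved per fold
.stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(sample.int(k), length(idx))
  }
  fold
}

# per-tree predictor importance, the CART estimator the paper describes:
# sum over branch nodes of the primary split's improvement, attributed to
# the split feature, divided by the number of branch nodes
.tree_importance <- function(fit, feature_names) {
  imp <- stats::setNames(numeric(length(feature_names)), feature_names)
  fr <- fit$frame
  branch <- which(fr$var != "<leaf>")
  if (!length(branch) || is.null(fit$splits)) return(imp)
  ptr <- 1L
  for (i in seq_len(nrow(fr))) {
    if (fr$var[i] == "<leaf>") next
    v <- as.character(fr$var[i])
    imp[v] <- imp[v] + fit$splits[ptr, "improve"]
    ptr <- ptr + 1L + fr$ncompete[i] + fr$nsurrogate[i]
  }
  imp / length(branch)
}

#' Repeated stratified k-fold cross-validated decision-tree classification
#'
#' At each iteration a fresh stratified k-fold split is drawn; a CART tree
#' (Gini impurity, unlimited depth, minimum leaf size 1) is trained on the
#' training folds and evaluated on the held-out fold. Per-iteration accuracy,
#' sensitivity, specificity, PPV and NPV are computed from the iteration's
#' pooled confusion matrix over folds (each patient predicted exactly once
#' per iteration), with "left" focus as the positive class. With
#' \code{shuffle = TRUE} the labels are randomly permuted (class counts
#' preserved) anew at every iteration before splitting, giving the chance
#' null.
#'
#' @param features data.frame or matrix of numeric predictors (one patient
#'   per row; typically the nine sleep LI features, night 1)
#' @param labels factor or character of \code{"left"}/\code{"right"} focus
#' @param n_iter number of repetitions (paper-scale: 5000)
#' @param k number of folds (default 5)
#' @param seed master seed; spawns one seed per iteration
#' @param shuffle permute labels each iteration (the null model)
#' @param positive positive class for sensitivity/PPV (default "left")
#' @param control \code{\link{tree_control}} hyperparameters
#' @param metric_agg \code{"pooled"} (default; per-iteration metrics from the
#'   pooled fold confusion, so the contingency identities hold exactly) or
#'   \code{"fold"} (mean over folds)
#' @return object of class \code{"sleep_cvrun"}: per-iteration metric
#'   vectors (\code{accuracy}, \code{sensitivity}, \code{specificity},
#'   \code{ppv}, \code{npv}), \code{contingency} (pooled TP/FP/FN/TN over
#'   all iterations), \code{importance_raw} (n_iter x p matrix),
#'   \code{mean_accuracy}, \code{sd_accuracy}, \code{n_iter}, \code{k},
#'   \code{seed}, \code{shuffle}, \code{n}
#' @export
run_repeated_cv <- function(features, labels, n_iter = 5000L, k = 5L,
                            seed = 1L, shuffle = FALSE, positive = "left",
                            control = tree_control(),
                            metric_agg = c("pooled", "fold")) {
  metric_agg <- match.arg(metric_agg)
  n_iter <- as.integer(n_iter)
  x <- as.data.frame(features)
  if (!all(vapply(x, is.numeric, TRUE))) stop("features must be numeric")
  if (any(!is.finite(as.matrix(x)))) stop("features must be finite")
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L)
    stop("need two classes; got a single-class matrix")
  if (length(labels) != nrow(x)) stop("labels must match feature rows")
  n <- nrow(x)
  if (n < 10L) stop("at least 10 patients are required for cross-validation")
  feats <- colnames(x)
  set.seed(seed)
  iter_seeds <- sample.int(.Machine$integer.max, n_iter)
  acc <- sens <- spec <- ppv <- npv <- numeric(n_iter)
  imp <- matrix(0, n_iter, length(feats), dimnames = list(NULL, feats))
  cont <- c(TP = 0, FP = 0, FN = 0, TN = 0)
  form <- stats::as.formula(paste(".lab ~",
                                  paste(sprintf("`%s`", feats),
                                        collapse = " + ")))
  for (it in seq_len(n_iter)) {
    set.seed(iter_seeds[it])
    lab <- if (shuffle) sample(labels) else labels
    fold <- .stratified_folds(lab, k)
    itc_ <- c(TP = 0, FP = 0, FN = 0, TN = 0)
    fold_acc <- numeric(k)
    imp_it <- stats::setNames(numeric(length(feats)), feats)
    for (f in seq_len(k)) {
      tr <- fold != f; te <- !tr
      dtr <- x[tr, , drop = FALSE]
      dtr$.lab <- factor(lab[tr], levels = sort(unique(labels)))
      fit <- rpart::rpart(form, data = dtr, method = "class",
                          parms = list(split = "gini"), control = control)
      pred <- as.character(predict(fit, x[te, , drop = FALSE],
                                   type = "class"))
      truth <- lab[te]
      tp <- sum(pred == positive & truth == positive)
      fp <- sum(pred == positive & truth != positive)
      fn <- sum(pred != positive & truth == positive)
      tn <- sum(pred != positive & truth != positive)
      itc_ <- itc_ + c(tp, fp, fn, tn)
      fold_acc[f] <- (tp + tn) / length(truth)
      imp_it <- imp_it + .tree_importance(fit, feats)
    }
    cont <- cont + itc_
    imp[it, ] <- imp_it / k
    if (metric_agg == "pooled") {
      tot <- sum(itc_)
      acc[it] <- (itc_["TP"] + itc_["TN"]) / tot
    } else acc[it] <- mean(fold_acc)
    sens[it] <- itc_["TP"] / (itc_["TP"] + itc_["FN"])
    spec[it] <- itc_["TN"] / (itc_["TN"] + itc_["FP"])
    ppv[it] <- itc_["TP"] / (itc_["TP"] + itc_["FP"])
    npv[it] <- itc_["TN"] / (itc_["TN"] + itc_["FN"])
  }
  structure(list(accuracy = acc, sensitivity = sens, specificity = spec,
                 ppv = ppv, npv = npv, contingency = cont,
                 importance_raw = imp,
                 mean_accuracy = mean(acc), sd_accuracy = stats::sd(acc),
                 n_iter = n_iter, k = k, seed = seed, shuffle = shuffle,
                 positive = positive, n = n,
                 classes = sort(unique(labels))),
            class = "sleep_cvrun")
}

#' Label-shuffle null classification run
#'
#' Identical to \code{\link{run_repeated_cv}} except that the focus labels
#' are randomly permuted (class counts preserved) anew at every iteration, so
#' the run estimates chance-level performance for the same feature matrix.
#'
#' @inheritParams run_repeated_cv
#' @return a \code{sleep_cvrun} (see \code{\link{run_repeated_cv}})
#' @export
run_shuffle_null <- function(features, labels, n_iter = 5000L, k = 5L,
                             seed = 1L, positive = "left",
                             control = tree_control(),
                             metric_agg = c("pooled", "fold")) {
  run_repeated_cv(features, labels, n_iter = n_iter, k = k, seed = seed,
                  shuffle = TRUE, positive = positive, control = control,
                  metric_agg = metric_agg)
}

#' @export
print.sleep_cvrun <- function(x, ...) {
  cat(sprintf(
    "<sleep_cvrun>%s %d iterations, %d-fold CV, n = %d\n",
    if (x$shuffle) " [label-shuffle null]" else "", x$n_iter, x$k, x$n))
  cat(sprintf("  accuracy: %.1f%% (SD %.1f%%)\n", 100 * x$mean_accuracy,
              100 * x$sd_accuracy))
  invisible(x)
}

#' @export
summary.sleep_cvrun <- function(object, ...) {
  m <- function(v) c(mean = mean(v), sd = stats::sd(v))
  out <- rbind(accuracy = m(object$accuracy),
               sensitivity = m(object$sensitivity),
               specificity = m(object$specificity),
               ppv = m(object$ppv), npv = m(object$npv))
  cat(sprintf("Repeated %d-fold CV decision tree (%d iterations%s)\n",
              object$k, object$n_iter,
              if (object$shuffle) ", shuffled labels" else ""))
  print(round(out, 4))
  cat("Pooled contingency (positive class:", object$positive, "):\n")
  print(object$contingency)
  cat("Predictor importance (0 = least, 1 = most):\n")
  print(round(predictor_importance(object), 3))
  invisible(out)
}

#' Compare per-iteration accuracies across classification runs
#'
#' For two runs, an unpaired t-test on per-iteration accuracies; for three or
#' more, a one-way ANOVA followed by all pairwise contrasts using the pooled
#' residual error, with Sidak-adjusted p-values. All runs must share the same
#' number of iterations.
#'
#' @param ... named \code{sleep_cvrun} objects (at least two)
#' @return list of class \code{"cvrun_comparison"}: \code{means},
#'   \code{anova_p} (or \code{NA} for two runs), \code{contrasts}
#'   (data.frame with \code{diff}, \code{t}, \code{p}, \code{p_adj})
#' @export
compare_runs <- function(...) {
  runs <- list(...)
  if (length(runs) == 1L && is.list(runs[[1]]) &&
      !inherits(runs[[1]], "sleep_cvrun")) runs <- runs[[1]]
  if (length(runs) < 2L) stop("need at least two runs")
  if (is.null(names(runs)) || any(names(runs) == ""))
    names(runs) <- paste0("run", seq_along(runs))
  ni <- vapply(runs, function(r) as.integer(r$n_iter), 0L)
  if (length(unique(ni)) != 1L)
    stop("runs must share the same number of iterations")
  accs <- lapply(runs, function(r) r$accuracy)
  means <- vapply(accs, mean, 0)
  pairs <- utils::combn(names(runs), 2, simplify = FALSE)
  m <- length(pairs)
  if (length(runs) == 2L) {
    a <- accs[[1]]; b <- accs[[2]]
    if (isTRUE(all.equal(a, b))) {
      contrasts <- data.frame(run1 = names(runs)[1], run2 = names(runs)[2],
                              diff = 0, t = 0, p = 1, p_adj = 1)
    } else {
      tt <- stats::t.test(a, b, var.equal = TRUE)
      contrasts <- data.frame(run1 = names(runs)[1], run2 = names(runs)[2],
                              diff = mean(a) - mean(b),
                              t = unname(tt$statistic), p = tt$p.value,
                              p_adj = tt$p.value)
    }
    anova_p <- NA_real_
  } else {
    dat <- data.frame(acc = unlist(accs),
                      run = factor(rep(names(runs), times = ni)))
    av <- stats::aov(acc ~ run, data = dat)
    anova_p <- summary(av)[[1]][["Pr(>F)"]][1]
    mse <- summary(av)[[1]][["Mean Sq"]][2]
    dfres <- summary(av)[[1]][["Df"]][2]
    contrasts <- do.call(rbind, lapply(pairs, function(cp) {
      d <- means[[cp[1]]] - means[[cp[2]]]
      se <- sqrt(mse * (1 / ni[[cp[1]]] + 1 / ni[[cp[2]]]))
      tv <- d / se
      p <- 2 * stats::pt(-abs(tv), dfres)
      data.frame(run1 = cp[1], run2 = cp[2], diff = d, t = tv, p = p,
                 p_adj = 1 - (1 - p)^m, stringsAsFactors = FALSE)
    }))
  }
  rownames(contrasts) <- NULL
  structure(list(means = means, anova_p = anova_p, contrasts = contrasts),
            class = "cvrun_comparison")
}

#' @export
print.cvrun_comparison <- function(x, ...) {
  cat("Accuracy means:\n"); print(round(x$means, 4))
  if (!is.na(x$anova_p))
    cat(sprintf("One-way ANOVA p = %.3g; Sidak-adjusted contrasts:\n",
                x$anova_p))
  print(x$contrasts)
  invisible(x)
}

#' Fisher's exact test on a run's pooled contingency table
#'
#' Two-sided Fisher's exact test on the pooled 2x2 table (predicted vs true
#' class, accumulated over all folds and iterations). A table with a zero
#' margin carries no association and returns p = 1.
#'
#' @param run a \code{sleep_cvrun}, or a length-4 vector/2x2 matrix
#'   (TP, FP, FN, TN)
#' @return two-sided p-value
#' @export
contingency_significance <- function(run) {
  tab <- if (inherits(run, "sleep_cvrun")) run$contingency else run
  if (is.matrix(tab)) tab <- c(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
  m <- matrix(tab, 2, 2, byrow = TRUE)   # rows: predicted; cols: true
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) return(1)
  stats::fisher.test(m)$p.value
}

#' Predictor importance of a classification run
#'
#' Per-tree importances (split improvement summed per feature over branch
#' nodes, divided by the number of branch nodes) are averaged over folds and
#' iterations, then min-max rescaled so 0 denotes the smallest and 1 the
#' highest importance. A degenerate run in which all features tie returns
#' all zeros.
#'
#' @param run a \code{sleep_cvrun}
#' @return named numeric vector of importances in [0, 1]
#' @export
predictor_importance <- function(run) {
  raw <- colMeans(run$importance_raw)
  rng <- range(raw)
  if (diff(rng) == 0) return(raw * 0)
  (raw - rng[1]) / diff(rng)
}

#' Predictor importance within the low-IED-asymmetry subset
#'
#' Selects the patients whose absolute IED lateralization index is strictly
#' below the cohort median absolute value ("difficult-to-lateralize"
#' patients), reruns the repeated cross-validation on that subset, and
#' compares the per-iteration feature importances with a Kruskal-Wallis test
#' plus Dunn's contrasts of every feature against the IED feature.
#'
#' @param features feature data.frame including the IED column
#' @param labels focus labels
#' @param ied_col name of the IED LI column (default \code{"ied_rate"})
#' @param n_iter,k,seed as in \code{\link{run_repeated_cv}}
#' @param min_subset below this subset size the result is flagged (default 6)
#' @return list: \code{subset_idx}, \code{n_subset}, \code{run} (the subset
#'   \code{sleep_cvrun}), \code{importance}, \code{importance_test} (Dunn
#'   contrasts vs the IED feature), \code{flagged}, \code{empty}
#' @export
low_asymmetry_subset <- function(features, labels, ied_col = "ied_rate",
                                 n_iter = 500L, k = 5L, seed = 1L,
                                 min_subset = 6L) {
  x <- as.data.frame(features)
  if (!ied_col %in% names(x)) stop("feature matrix lacks column ", ied_col)
  a <- abs(x[[ied_col]])
  sel <- which(a < stats::median(a))
  if (!length(sel))
    return(list(subset_idx = integer(), n_subset = 0L, run = NULL,
                importance = NULL, importance_test = NULL, flagged = TRUE,
                empty = TRUE))
  flagged <- length(sel) < min_subset
  if (length(sel) < 10L || length(unique(labels[sel])) < 2L)
    return(list(subset_idx = sel, n_subset = length(sel), run = NULL,
                importance = NULL, importance_test = NULL, flagged = TRUE,
                empty = FALSE))
  run <- run_repeated_cv(x[sel, , drop = FALSE], labels[sel],
                         n_iter = n_iter, k = k, seed = seed)
  impm <- run$importance_raw
  long <- data.frame(imp = as.vector(impm),
                     feature = rep(colnames(impm), each = nrow(impm)))
  others <- setdiff(colnames(impm), ied_col)
  cmp <- lapply(others, function(f) c(f, ied_col))
  dt <- dunn_test(long$imp, long$feature, comparisons = cmp)
  list(subset_idx = sel, n_subset = length(sel), run = run,
       importance = predictor_importance(run), importance_test = dt,
       flagged = flagged, empty = FALSE)
}
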