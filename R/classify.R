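## SVM group classification: cubic polynomial kernel, fixed gamma, penalty
## grid search nested inside repeated stratified 75/25 cross-validation.

#' Feature set for classification
#'
#' @param name feature family, e.g. `"power"`, `"coherence"`,
#'   `"connectivity"`, `"behavior"`, `"all"`.
#' @param band `"mu"`, `"beta"` or `"both"`.
#' @param matrix subjects x features numeric matrix (no NaN).
#' @param labels two-level group factor/character, one per subject.
#' @return a `feature_set` list.
#' @export
feature_set <- function(name, band, matrix, labels) {
  matrix <- as.matrix(matrix)
  stop_if_not(all(is.finite(matrix)), "features contain non-finite values")
  labels <- factor(labels)
  stop_if_not(nlevels(labels) == 2, "labels must have exactly two levels")
  stop_if_not(length(labels) == nrow(matrix),
              "one label per subject required")
  stop_if_not(all(table(labels) >= 2), "each class needs >= 2 subjects")
  if (is.null(colnames(matrix)))
    colnames(matrix) <- paste0("f", seq_len(ncol(matrix)))
  structure(list(name = name, band = band, matrix = matrix,
                 labels = labels),
            class = "feature_set")
}

# Stratified index split: `frac` of each class for training.
stratified_split <- function(labels, frac) {
  train <- integer()
  for (lv in levels(labels)) {
    idx <- which(labels == lv)
    n_tr <- max(1L, min(length(idx) - 1L, round(frac * length(idx))))
    train <- c(train, sample(idx)[seq_len(n_tr)])
  }
  sort(train)
}

# Fit on standardized training data with one cost value; return test accuracy.
svm_split_accuracy <- function(X, y, train, cost, gamma, degree, coef0) {
  mu <- colMeans(X[train, , drop = FALSE])
  s <- apply(X[train, , drop = FALSE], 2, sd)
  s[s == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, s, "/")
  wts <- length(train) / (nlevels(y) * table(y[train]))
  fit <- e1071::svm(Xs[train, , drop = FALSE], y[train],
                    kernel = "polynomial", degree = degree, gamma = gamma,
                    coef0 = coef0, cost = cost, scale = FALSE,
                    class.weights = wts)
  pred <- predict(fit, Xs[-train, , drop = FALSE])
  mean(pred == y[-train])
}

#' SVM classification with repeated stratified cross-validation
#'
#' Cubic polynomial kernel `K(x, y) = (gamma * x'y + 1)^3` with
#' `gamma = 0.25`; the soft-margin penalty C is grid-searched over 1..10
#' inside each training portion (nested selection over inner stratified
#' splits). The outer scheme is 10 repeated stratified Monte-Carlo splits
#' with 75% training / 25% testing; features are standardized on the
#' training portion only.
#'
#' @param features a [feature_set()].
#' @param seed integer seed driving all splits.
#' @param n_splits outer splits (default 10).
#' @param train_frac training fraction (default 0.75).
#' @param cost_grid penalty values searched (default `1:10`).
#' @param gamma,degree,coef0 kernel parameters (defaults 0.25, 3, 1).
#' @param n_inner inner selection splits per outer split (default 5).
#' @return a `cv_report`: `fold_accuracies`, `mean_accuracy`, `selected_C`
#'   (per outer split), `kernel`, `seed`.
#' @export
svm_classify <- function(features, seed = NULL, n_splits = 10,
                         train_frac = 0.75, cost_grid = 1:10,
                         gamma = 0.25, degree = 3, coef0 = 1, n_inner = 5) {
  stop_if_not(inherits(features, "feature_set"),
              "`features` must be a feature_set")
  X <- features$matrix; y <- features$labels
  acc <- numeric(n_splits); sel_c <- numeric(n_splits)
  with_seed(seed, {
    for (k in seq_len(n_splits)) {
      train <- stratified_split(y, train_frac)
      if (length(unique(y[train])) < 2 ||
          length(unique(y[-train])) < 2 && length(y) - length(train) >= 2)
        stop("a class is absent from a training fold; need more subjects",
             call. = FALSE)
      # nested penalty selection inside the training portion
      best_c <- cost_grid[1]
      if (all(table(y[train]) >= 4) && length(cost_grid) > 1) {
        inner_acc <- vapply(cost_grid, function(cc) {
          mean(vapply(seq_len(n_inner), function(i) {
            itr <- stratified_split(droplevels(y[train]), train_frac)
            svm_split_accuracy(X[train, , drop = FALSE],
                               droplevels(y[train]), itr, cc,
                               gamma, degree, coef0)
          }, numeric(1)))
        }, numeric(1))
        best_c <- cost_grid[which.max(inner_acc)]
      }
      sel_c[k] <- best_c
      acc[k] <- svm_split_accuracy(X, y, train, best_c, gamma, degree, coef0)
    }
  })
  structure(list(fold_accuracies = acc, mean_accuracy = mean(acc),
                 selected_C = sel_c,
                 kernel = sprintf(
                   "polynomial degree %d, gamma %g, coef0 %g", degree,
                   gamma, coef0),
                 seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> mean accuracy %.1f%% over %d splits (%s)\n",
              100 * x$mean_accuracy, length(x$fold_accuracies), x$kernel))
  invisible(x)
}

#' Build the classification feature menu from a cohort table
#'
#' Emits one [feature_set()] per analyzed parameter and band — power,
#' coherence and connectivity alone, their per-band combination, a
#' behaviour set when behavioural columns are present, and the union across
#' both bands.
#'
#' @param dataset data.frame with a `group` column, per-band feature columns
#'   named `power_<band>`, `coherence_<band>`, `connectivity_<band>`, and
#'   optionally behavioural columns `dprime_walker`, `dprime_scramble`.
#' @param bands character vector of band names present (default
#'   `c("mu", "beta")`).
#' @return named list of `feature_set` objects; unavailable sets are skipped
#'   with a warning.
#' @export
build_feature_sets <- function(dataset, bands = c("mu", "beta")) {
  stop_if_not(nrow(dataset) > 0, "empty dataset")
  stop_if_not("group" %in% names(dataset), "dataset needs a `group` column")
  out <- list()
  add <- function(name, band, cols) {
    if (!all(cols %in% names(dataset))) {
      warning(sprintf("skipping feature set %s/%s: missing column(s) %s",
                      name, band,
                      paste(setdiff(cols, names(dataset)), collapse = ", ")))
      return(invisible(NULL))
    }
    out[[paste(name, band, sep = "_")]] <<-
      feature_set(name, band, as.matrix(dataset[, cols, drop = FALSE]),
                  dataset$group)
  }
  fams <- c("power", "coherence", "connectivity")
  for (b in bands) {
    for (fam in fams) add(fam, b, paste0(fam, "_", b))
    add("all", b, paste0(fams, "_", b))
  }
  if (all(c("dprime_walker", "dprime_scramble") %in% names(dataset)))
    add("behavior", "none", c("dprime_walker", "dprime_scramble"))
  if (length(bands) > 1)
    add("all", "both", as.vector(outer(fams, bands, paste, sep = "_")))
  out
}

#' Repeat the cross-validated classification
#'
#' Independent [svm_classify()] runs under distinct derived seeds,
#' summarizing the run-to-run spread of the mean accuracy.
#'
#' @param features a [feature_set()].
#' @param n_repeats number of runs (default 3).
#' @param seed base seed; run k uses a seed derived from it.
#' @param ... forwarded to [svm_classify()].
#' @return list with `runs` (cv_reports), `mean_accuracies`, `mean`, `sd`.
#' @export
repeat_cv <- function(features, n_repeats = 3, seed = NULL, ...) {
  runs <- lapply(seq_len(n_repeats), function(k)
    svm_classify(features, seed = derive_seed(seed, k), ...))
  means <- vapply(runs, function(r) r$mean_accuracy, numeric(1))
  list(runs = runs, mean_accuracies = means, mean = mean(means),
       sd = if (n_repeats > 1) sd(means) else 0)
}
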