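#' Train a one-vs-one linear SVM on the calibrated quantity feature
#'
#' The classifier operates on a single scalar feature per strip -- the
#' regression-approximated log quantity `x_hat = (T/C - b) / m` -- so each
#' pairwise decision function is a line `f(x) = w x + b0` and prediction is
#' a majority vote over all class pairs. Pairwise problems are solved as
#' soft-margin linear SVMs (hinge loss, penalty `cost`); for large `cost`
#' on separable data each boundary converges to the midpoint of the closest
#' opposing training points. Since the calibration map is monotone, feeding
#' T/C ratios directly is equivalent up to the boundary parameterisation.
#'
#' @param features numeric vector, one scalar per sample.
#' @param labels class labels (analyte quantities in fg, numeric).
#' @param cost soft-margin penalty C (default 1).
#' @return An object of class `lfa_svm`: `classes` (ascending quantities),
#'   `pairs` (data frame of pairwise `w`, `b`; `f(x) > 0` votes for
#'   `class_a`), and `cost`.
#' @export
train_svm <- function(features, labels, cost = 1) {
  stopifnot(length(features) == length(labels), cost > 0)
  classes <- sort(unique(labels))
  if (length(classes) < 2L) {
    stop("need at least two classes to train a classifier", call. = FALSE)
  }
  combos <- combn(length(classes), 2L)
  pairs <- lapply(seq_len(ncol(combos)), function(j) {
    a <- classes[combos[1, j]]; b <- classes[combos[2, j]]
    keep <- labels %in% c(a, b)
    x <- matrix(features[keep], ncol = 1)
    y <- factor(labels[keep], levels = c(a, b))
    wb <- tryCatch({
      m <- e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE)
      c(w = sum(m$coefs * m$SV), b = -m$rho)
    }, error = function(e) c(w = 0, b = 0))
    # a flat decision function carries no information about the pair; zero
    # its offset as well so it abstains instead of casting a constant vote
    if (wb[1] == 0) wb[2] <- 0
    # libsvm orients the decision function by label order of appearance in
    # the data; re-orient so that f(x) > 0 always votes for class_a
    f <- wb[1] * features[keep] + wb[2]
    if (mean(f[labels[keep] == a]) < mean(f[labels[keep] == b])) wb <- -wb
    data.frame(class_a = a, class_b = b, w = unname(wb[1]), b = unname(wb[2]))
  })
  structure(list(classes = classes, pairs = do.call(rbind, pairs),
                 cost = cost),
            class = "lfa_svm")
}

#' @export
print.lfa_svm <- function(x, ...) {
  cat(sprintf("<lfa_svm> %d classes (%s), C = %g, %d pairwise boundaries\n",
              length(x$classes), paste(x$classes, collapse = ", "),
              x$cost, nrow(x$pairs)))
  invisible(x)
}

#' Pairwise decision boundaries
#'
#' Feature values where each pairwise decision function crosses zero
#' (`-b / w`); `NA` for degenerate pairs with zero weight.
#'
#' @param model an `lfa_svm`.
#' @return The `pairs` data frame with an added `boundary` column.
#' @export
decision_boundaries <- function(model) {
  stopifnot(inherits(model, "lfa_svm"))
  p <- model$pairs
  p$boundary <- ifelse(p$w != 0, -p$b / p$w, NA_real_)
  p
}

#' Predict class labels
#'
#' One-vs-one majority vote. Ties are broken by the larger aggregate
#' decision margin (sum of |f(x)| over the votes the tied class won), then
#' by the lower quantity.
#'
#' @param object an `lfa_svm`.
#' @param newdata numeric vector of features.
#' @param ... unused.
#' @return Numeric vector of predicted class quantities.
#' @export
predict.lfa_svm <- function(object, newdata, ...) {
  p <- object$pairs
  vapply(newdata, function(x) {
    f <- p$w * x + p$b
    votes <- ifelse(f > 0, p$class_a, p$class_b)
    votes[p$w == 0 & p$b == 0] <- NA   # degenerate pairs abstain
    tally <- vapply(object$classes,
                    function(cl) sum(votes == cl, na.rm = TRUE), numeric(1))
    top <- object$classes[tally == max(tally)]
    if (length(top) > 1L) {
      margin <- vapply(top, function(cl) sum(abs(f)[which(votes == cl)]),
                       numeric(1))
      top <- top[margin == max(margin)]
      top <- min(top)
    }
    top
  }, numeric(1))
}

#' Confusion matrix
#'
#' Square count matrix with rows = actual class, columns = predicted class.
#'
#' @param actual,predicted label vectors of equal length.
#' @param classes class ordering for rows/columns (default: sorted union).
#' @return An integer matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(actual, predicted,
                             classes = sort(unique(c(actual, predicted)))) {
  stopifnot(length(actual) == length(predicted))
  # canonical labels: numeric 1e+05 and integer 100000 must coincide
  lab <- function(v) {
    if (is.numeric(v)) {
      vapply(v, function(x) format(x, scientific = FALSE, trim = TRUE), "")
    } else {
      as.character(v)
    }
  }
  lv <- lab(classes)
  m <- table(factor(lab(actual), levels = lv),
             factor(lab(predicted), levels = lv))
  m <- matrix(as.integer(m), nrow = length(classes),
              dimnames = list(actual = lv, predicted = lv))
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' Multiclass accuracy in percent
#'
#' `100 x (diagonal count) / (total count)`: the proportion of samples whose
#' predicted class equals the actual one, which coincides with the TP + TN
#' over TP + TN + FP + FN form aggregated over classes.
#'
#' @param cm a [confusion_matrix()] (or plain square count matrix).
#' @return Accuracy in \[0, 100\].
#' @export
accuracy <- function(cm) {
  if (sum(cm) == 0) stop("empty confusion matrix", call. = FALSE)
  100 * sum(diag(cm)) / sum(cm)
}

#' Stratified k-fold cross validation
#'
#' Samples of each class are shuffled (seeded) and dealt round-robin into
#' `k` folds, so classes stay balanced across folds even when a class has
#' fewer than `k` samples. Out-of-fold predictions from the `k` retrained
#' models are accumulated into one confusion matrix.
#'
#' @param features numeric vector of scalar features.
#' @param labels class labels (quantities in fg).
#' @param k fold count (>= 2, default 5).
#' @param cost SVM penalty passed to [train_svm()].
#' @param seed RNG seed for the shuffles.
#' @return A [confusion_matrix()] of pooled out-of-fold predictions.
#' @export
cross_validate <- function(features, labels, k = 5L, cost = 1, seed = 1L) {
  stopifnot(length(features) == length(labels))
  if (k < 2L) stop("need at least 2 folds", call. = FALSE)
  n <- length(features)
  fold <- integer(n)
  with_local_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- (seq_along(idx) - 1L) %% k + 1L
    }
  })
  actual <- c(); predicted <- c()
  classes <- sort(unique(labels))
  for (f in seq_len(k)) {
    test <- fold == f
    if (!any(test)) next
    model <- train_svm(features[!test], labels[!test], cost = cost)
    actual <- c(actual, labels[test])
    predicted <- c(predicted, predict(model, features[test]))
  }
  confusion_matrix(actual, predicted, classes = classes)
}
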