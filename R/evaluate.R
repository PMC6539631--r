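#' Train a linear-kernel multi-class SVM
#'
#' Fits a one-vs-one multi-class support vector machine with the linear
#' kernel (libsvm via e1071) on a feature tibble.  Features are used
#' unscaled.
#'
#' @inheritParams rank_features_rfe
#' @return An object of class `popm_svm` wrapping the fitted model together
#'   with the feature column names and class order, usable with
#'   [predict.popm_svm()].
#' @export
train_svm <- function(features, labels, cost = 1, id = "id") {
  parts <- feature_parts(features, id = id)
  y <- check_labels(labels, nrow(parts$x))
  fit <- e1071::svm(parts$x, y,
    kernel = "linear", cost = cost, scale = FALSE
  )
  structure(
    list(fit = fit, columns = parts$columns, classes = levels(y),
      cost = cost
    ),
    class = "popm_svm"
  )
}

#' Predict subcellular classes for new feature rows
#'
#' @param object A [train_svm()] model.
#' @param newdata A feature tibble containing at least the model's feature
#'   columns.
#' @param id Name of the id column in `newdata`.
#' @param ... Unused.
#' @return A tibble with columns `id` and `predicted`.
#' @export
predict.popm_svm <- function(object, newdata, id = "id", ...) {
  missing <- setdiff(object$columns, names(newdata))
  if (length(missing) > 0) {
    abort(paste0(
      "newdata is missing model feature column(s): ",
      paste(head(missing, 5), collapse = ", ")
    ))
  }
  x <- as.matrix(newdata[, object$columns, drop = FALSE])
  pred <- predict(object$fit, x)
  tibble(
    id = as.character(newdata[[id]]),
    predicted = as.character(pred)
  )
}

#' @export
print.popm_svm <- function(x, ...) {
  cat(sprintf(
    "<popm_svm> linear kernel, C = %g, %d features, classes: %s\n",
    x$cost, length(x$columns), paste(x$classes, collapse = ", ")
  ))
  invisible(x)
}

#' Per-class classification metrics from a confusion matrix
#'
#' Computes, for each class j, sensitivity `TP / (TP + FN)`, specificity
#' `TN / (TN + FP)`, and the Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, together with
#' the overall accuracy `sum(TP) / n` (the trace over the total).  Rows of
#' the confusion matrix are true classes, columns are predicted classes.
#' Any metric whose denominator is zero is reported as 0 and flagged in the
#' `degenerate` column rather than returned as NaN, so that sweep tables
#' stay total.
#'
#' @param confusion A square numeric matrix or `table` with identical
#'   row/column class names, true classes in rows.
#' @return An object of class `popm_eval` with elements `confusion`,
#'   `per_class` (tibble: `class`, `n`, `sens`, `spec`, `mcc`,
#'   `degenerate`), `oa`, `n`, and `settings` (empty here; filled by
#'   [jackknife_evaluate()]).
#' @examples
#' cm <- matrix(c(8, 5, 2, 85), 2, 2,
#'   dimnames = list(c("pos", "neg"), c("pos", "neg"))
#' )
#' compute_metrics(cm)
#' @export
compute_metrics <- function(confusion) {
  cm <- as.matrix(confusion)
  if (nrow(cm) != ncol(cm)) abort("confusion matrix must be square")
  if (is.null(rownames(cm)) || is.null(colnames(cm))) {
    abort("confusion matrix must carry class names")
  }
  if (!identical(rownames(cm), colnames(cm))) {
    abort("confusion row and column class names must match")
  }
  if (any(cm < 0)) abort("confusion counts must be non-negative")
  total <- sum(as.numeric(cm))
  if (total <= 0) abort("confusion matrix is empty")

  classes <- rownames(cm)
  per <- purrr::map(seq_along(classes), function(j) {
    # double arithmetic: the 4-way MCC denominator overflows 32-bit counts
    tp <- as.numeric(cm[j, j])
    fn <- sum(as.numeric(cm[j, ])) - tp
    fp <- sum(as.numeric(cm[, j])) - tp
    tn <- total - tp - fn - fp
    sens_den <- tp + fn
    spec_den <- tn + fp
    mcc_den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
    tibble(
      class = classes[j],
      n = sens_den,
      sens = if (sens_den > 0) tp / sens_den else 0,
      spec = if (spec_den > 0) tn / spec_den else 0,
      mcc = if (mcc_den > 0) (tp * tn - fp * fn) / sqrt(mcc_den) else 0,
      degenerate = sens_den == 0 || spec_den == 0 || mcc_den == 0
    )
  })
  structure(
    list(
      confusion = cm,
      per_class = dplyr::bind_rows(per),
      oa = sum(as.numeric(diag(cm))) / total,
      n = as.integer(total),
      settings = list()
    ),
    class = "popm_eval"
  )
}

#' @export
print.popm_eval <- function(x, digits = 3, ...) {
  s <- x$settings
  header <- "<popm_eval>"
  if (length(s) > 0) {
    header <- sprintf(
      "<popm_eval> jackknife, k = %s, mode = %s, C = %g",
      s$k %||% "all", s$mode %||% "-", s$cost %||% NA
    )
  }
  cat(header, "\n")
  tab <- x$per_class
  cat(sprintf(
    "%-10s %8s %8s %8s\n", "Location", "Sens (%)", "Spec (%)", "MCC"
  ))
  for (i in seq_len(nrow(tab))) {
    cat(sprintf(
      "%-10s %8.1f %8.1f %8.3f%s\n",
      tab$class[i], 100 * tab$sens[i], 100 * tab$spec[i], tab$mcc[i],
      if (tab$degenerate[i]) " *" else ""
    ))
  }
  cat(sprintf("OA = %.1f%% (n = %d)\n", 100 * x$oa, x$n))
  if (any(tab$degenerate)) {
    cat("* zero-denominator metric reported as 0\n")
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.popm_eval <- function(x, ...) x$per_class

#' @exportS3Method generics::glance
glance.popm_eval <- function(x, ...) {
  s <- x$settings
  tibble(
    oa = x$oa, n = x$n, n_classes = nrow(x$per_class),
    k = s$k %||% NA_integer_, mode = s$mode %||% NA_character_,
    cost = s$cost %||% NA_real_
  )
}

#' Leave-one-out jackknife evaluation of the full pipeline
#'
#' Each sample is held out in turn and predicted by a linear SVM trained on
#' the remaining samples; the aggregated confusion matrix is scored with
#' [compute_metrics()].  Two protocols for combining feature selection with
#' the jackknife are supported:
#'
#' * `mode = "paper"`: the RFE ranking and the top-k subset are computed
#'   once on the full matrix, before the leave-one-out loop.  This mirrors
#'   protocols that report a single ranked list per dataset, but lets the
#'   held-out sample influence feature selection: on label-free (null) data
#'   it inflates accuracy well above chance.
#' * `mode = "leak_free"`: ranking and selection are recomputed inside each
#'   fold from the n-1 training samples only.  Recommended for honest error
#'   estimates on new data.
#'
#' Fold order is the dataset order, so results are deterministic for a
#' given input; `seed` is recorded in the settings and set before the run
#' for completeness.
#'
#' @inheritParams rank_features_rfe
#' @param k Number of top-ranked features used by the classifier
#'   (default 120, the method's operating point).  Use
#'   `k = ncol(features) - 1` (all features) to bypass selection.
#' @param mode `"paper"` or `"leak_free"` (see Details).
#' @param rfe_step Elimination step size passed to [rank_features_rfe()].
#' @param seed Integer seed recorded with the run.
#' @param allow_singletons If `FALSE` (default), a class with a single
#'   member is an error, because its fold has no same-class training
#'   example.
#' @return A `popm_eval` object (see [compute_metrics()]) whose `settings`
#'   record k, mode, cost, rfe_step and seed.
#' @export
jackknife_evaluate <- function(features, labels, k = 120L,
                               mode = c("paper", "leak_free"),
                               cost = 1, rfe_step = 1L, seed = 1L,
                               id = "id", allow_singletons = FALSE) {
  mode <- match.arg(mode)
  parts <- feature_parts(features, id = id)
  y <- check_labels(labels, nrow(parts$x),
    min_per_class = if (allow_singletons) 1L else 2L
  )
  n <- nrow(parts$x)
  if (n < nlevels(y) + 1L) {
    abort("need at least one more sample than classes")
  }
  set.seed(seed)

  if (mode == "paper") {
    ranking <- rank_features_rfe(features, labels,
      cost = cost, step = rfe_step, id = id
    )
    sel <- select_top_k(features, ranking, k, id = id)
    xk <- feature_parts(sel, id = id)$x
    pred <- character(n)
    for (i in seq_len(n)) {
      fit <- e1071::svm(xk[-i, , drop = FALSE], droplevels(y[-i]),
        kernel = "linear", cost = cost, scale = FALSE
      )
      pred[i] <- as.character(predict(fit, xk[i, , drop = FALSE]))
    }
  } else {
    pred <- character(n)
    for (i in seq_len(n)) {
      train <- features[-i, , drop = FALSE]
      ytr <- droplevels(y[-i])
      ranking <- rank_features_rfe(train, ytr,
        cost = cost, step = rfe_step, id = id
      )
      sel <- select_top_k(train, ranking, k, id = id)
      cols <- setdiff(names(sel), id)
      fit <- e1071::svm(as.matrix(sel[, cols, drop = FALSE]), ytr,
        kernel = "linear", cost = cost, scale = FALSE
      )
      pred[i] <- as.character(
        predict(fit, as.matrix(features[i, cols, drop = FALSE]))
      )
    }
  }

  cm <- table(
    factor(as.character(y), levels = levels(y)),
    factor(pred, levels = levels(y))
  )
  cm <- matrix(as.integer(cm), nrow = nlevels(y),
    dimnames = list(levels(y), levels(y))
  )
  report <- compute_metrics(cm)
  report$settings <- list(
    k = as.integer(k), mode = mode, cost = cost,
    rfe_step = as.integer(rfe_step), seed = as.integer(seed)
  )
  report
}

#' Jackknife accuracy as a function of the number of selected features
#'
#' Runs [jackknife_evaluate()] for each value of k on a grid (default
#' 10, 20, ..., 300) and returns the (k, OA) curve.  The best k is the
#' argmax of OA, ties broken toward the smallest k.
#'
#' @inheritParams jackknife_evaluate
#' @param k_values Integer grid of feature counts, each in 1..n_features.
#' @return A tibble of class `topk_sweep` with columns `k` and `oa` and an
#'   attribute `best_k`.
#' @export
sweep_top_k <- function(features, labels, k_values = seq(10L, 300L, 10L),
                        mode = c("paper", "leak_free"), cost = 1,
                        rfe_step = 1L, seed = 1L, id = "id") {
  mode <- match.arg(mode)
  if (length(k_values) == 0) abort("`k_values` must be non-empty")
  oa <- purrr::map_dbl(k_values, function(k) {
    jackknife_evaluate(features, labels,
      k = k, mode = mode, cost = cost,
      rfe_step = rfe_step, seed = seed, id = id
    )$oa
  })
  out <- tibble(k = as.integer(k_values), oa = oa)
  best <- out$k[which.max(out$oa)] # which.max takes the first tie
  structure(out,
    class = c("topk_sweep", class(out)),
    best_k = best
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.topk_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$k, y = 100 * .data$oa)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::geom_vline(
      xintercept = attr(object, "best_k"), linetype = "dashed"
    ) +
    ggplot2::labs(
      x = "Top K features", y = "Overall accuracy (%)",
      title = "Jackknife accuracy vs. number of selected tri-gram features"
    ) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.popm_eval <- function(object, ...) {
  long <- tidyr::pivot_longer(object$per_class,
    cols = c("sens", "spec", "mcc"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$class, y = .data$value, fill = .data$metric)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(
      x = "Subcellular location", y = "Value",
      title = sprintf("Per-class metrics (OA = %.1f%%)", 100 * object$oa)
    ) +
    ggplot2::theme_minimal()
}
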