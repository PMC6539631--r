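#' Rank features by linear SVM recursive feature elimination
#'
#' Implements SVM-RFE: repeatedly fit linear SVMs on the surviving features,
#' score every surviving feature, and discard the `step` lowest-scoring
#' features until none remain.  The importance order is the reverse of the
#' removal order.  For more than two classes, one binary machine is fitted
#' per class pair (one-vs-one, as in libsvm's multi-class scheme) and a
#' feature's criterion is the sum over all pairs of its squared weight-vector
#' component.  Ties are broken by removing the feature with the larger
#' column position first, so rankings are fully deterministic.
#'
#' Features are used as-is (no rescaling): tri-gram features already live in
#' `[0, 1]`.
#'
#' @param features A feature tibble (id column + numeric feature columns),
#'   e.g., from [encode_trigrams()].
#' @param labels Class labels, one per row of `features` (character or
#'   factor).  At least 2 classes with at least 2 samples each.
#' @param cost SVM cost parameter C (> 0).
#' @param step Number of features eliminated per iteration (>= 1); 1 is the
#'   classical schedule, larger values trade ranking resolution for speed.
#'   When fewer than `step` features survive, all remaining features are
#'   eliminated in criterion order in the final iteration.
#' @param id Name of the id column in `features`.
#' @return An object of class `rfe_ranking` with elements
#'   `ranking` (tibble: `rank`, `feature`, `column`, `criterion` — the
#'   squared-weight score the feature had when it was eliminated),
#'   `elimination_log` (tibble: `iteration`, `feature`, `column`,
#'   `criterion`, in removal order), and `settings`.
#' @examples
#' \donttest{
#' spec <- default_benchmark_spec("zw225-like", seed = 1)
#' feats <- encode_trigrams(generate_dataset(spec))
#' # coarse schedule for illustration
#' rk <- rank_features_rfe(feats, generate_dataset(spec)$class, step = 200)
#' head(tidy(rk))
#' }
#' @export
rank_features_rfe <- function(features, labels, cost = 1, step = 1L,
                              id = "id") {
  parts <- feature_parts(features, id = id)
  y <- check_labels(labels, nrow(parts$x), min_per_class = 2L)
  if (!is.numeric(cost) || length(cost) != 1L || cost <= 0) {
    abort("`cost` must be a positive number")
  }
  step <- as.integer(step)
  if (is.na(step) || step < 1L) abort("`step` must be a positive integer")

  p <- ncol(parts$x)
  surviving <- seq_len(p)
  removal <- integer(0)
  removal_crit <- numeric(0)
  removal_iter <- integer(0)
  iter <- 0L
  while (length(surviving) > 0L) {
    iter <- iter + 1L
    crit <- pairwise_sq_weights(parts$x[, surviving, drop = FALSE], y, cost)
    n_rm <- min(step, length(surviving))
    # worst first; ties resolved toward the larger column position
    ord <- order(crit, -surviving)
    drop_local <- ord[seq_len(n_rm)]
    removal <- c(removal, surviving[drop_local])
    removal_crit <- c(removal_crit, crit[drop_local])
    removal_iter <- c(removal_iter, rep(iter, n_rm))
    surviving <- surviving[-drop_local]
  }
  order_cols <- rev(removal)
  cols <- parts$columns
  structure(
    list(
      ranking = tibble(
        rank = seq_len(p),
        feature = cols[order_cols],
        column = order_cols,
        criterion = rev(removal_crit)
      ),
      elimination_log = tibble(
        iteration = removal_iter,
        feature = cols[removal],
        column = removal,
        criterion = removal_crit
      ),
      settings = list(cost = cost, step = step, n_features = p,
        classes = levels(y)
      )
    ),
    class = "rfe_ranking"
  )
}

# sum over one-vs-one linear machines of squared weight components
pairwise_sq_weights <- function(x, y, cost) {
  crit <- numeric(ncol(x))
  pairs <- utils::combn(levels(y), 2L)
  for (k in seq_len(ncol(pairs))) {
    keep <- y %in% pairs[, k]
    fit <- e1071::svm(
      x[keep, , drop = FALSE], factor(y[keep]),
      kernel = "linear", cost = cost, scale = FALSE
    )
    w <- as.numeric(crossprod(fit$coefs, fit$SV))
    crit <- crit + w^2
  }
  crit
}

check_labels <- function(labels, n, min_per_class = 1L) {
  if (length(labels) != n) {
    abort(sprintf(
      "length of `labels` (%d) does not match number of rows (%d)",
      length(labels), n
    ))
  }
  y <- factor(as.character(labels), levels = unique(as.character(labels)))
  if (nlevels(y) < 2L) abort("at least 2 classes are required")
  small <- table(y) < min_per_class
  if (any(small)) {
    abort(sprintf(
      "class(es) with fewer than %d members: %s",
      min_per_class, paste(names(which(small)), collapse = ", ")
    ))
  }
  y
}

#' @export
print.rfe_ranking <- function(x, ...) {
  s <- x$settings
  cat(sprintf(
    "<rfe_ranking> %d features, %d classes (C = %g, step = %d)\n",
    s$n_features, length(s$classes), s$cost, s$step
  ))
  print(head(x$ranking, 5))
  cat("...\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.rfe_ranking <- function(x, ...) x$ranking

#' @exportS3Method generics::glance
glance.rfe_ranking <- function(x, ...) {
  tibble(
    n_features = x$settings$n_features,
    n_classes = length(x$settings$classes),
    cost = x$settings$cost, step = x$settings$step,
    n_iterations = max(x$elimination_log$iteration)
  )
}

#' Select the top-k ranked feature columns
#'
#' Subsets a feature tibble to the `k` highest-ranked columns of an RFE
#' ranking, preserving row order.  The operating point used throughout the
#' package defaults to k = 120.
#'
#' @param features The feature tibble the ranking refers to.
#' @param ranking An [rank_features_rfe()] result (or a tibble with columns
#'   `rank` and `feature`, e.g., read back by [read_ranking()]).
#' @param k Number of features to keep, in 1..number of ranked features.
#' @param id Name of the id column.
#' @return The feature tibble restricted to the id column plus the top-k
#'   feature columns, ordered by rank.
#' @export
select_top_k <- function(features, ranking, k, id = "id") {
  rk <- if (inherits(ranking, "rfe_ranking")) ranking$ranking else ranking
  if (!is.data.frame(rk) || !all(c("rank", "feature") %in% names(rk))) {
    abort("`ranking` must be an rfe_ranking or a tibble with rank/feature")
  }
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > nrow(rk)) {
    abort(sprintf("`k` must be in 1..%d", nrow(rk)))
  }
  keep <- rk$feature[order(rk$rank)][seq_len(k)]
  missing <- setdiff(keep, names(features))
  if (length(missing) > 0) {
    abort(paste0(
      "ranked feature(s) absent from `features`: ",
      paste(head(missing, 5), collapse = ", ")
    ))
  }
  features[, c(id, keep), drop = FALSE]
}
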