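# Independent oracles and small data generators used across the suite.

# naive triple-nested-loop evaluation of the tri-gram definition,
# independent of the vectorized implementation
naive_trigram <- function(popm) {
  m <- unclass(popm)
  l <- nrow(m)
  out <- numeric(1000)
  pos <- 0L
  for (x in 1:10) {
    for (y in 1:10) {
      for (z in 1:10) {
        pos <- pos + 1L
        acc <- 0
        for (i in seq_len(l - 2L)) {
          acc <- acc + m[i, x] * m[i + 1L, y] * m[i + 2L, z]
        }
        out[pos] <- acc / (l - 2L)
      }
    }
  }
  out
}

random_sequence <- function(len) {
  paste(
    sample(popmtrigram:::STANDARD_RESIDUES, len, replace = TRUE),
    collapse = ""
  )
}

random_confusion <- function(n_classes, max_count = 40L) {
  cls <- paste0("class", seq_len(n_classes))
  repeat {
    m <- matrix(
      sample(0:max_count, n_classes^2, replace = TRUE),
      n_classes, n_classes, dimnames = list(cls, cls)
    )
    if (sum(m) > 0 && all(rowSums(m) > 0)) return(m)
  }
}

# per-class one-vs-rest tally: collapse the multi-class confusion to a
# binary problem for class j and compute the metrics from first principles
ovr_oracle <- function(cm, j) {
  cm <- matrix(as.numeric(cm), nrow(cm)) # avoid 32-bit product overflow
  total <- sum(cm)
  tp <- cm[j, j]
  fn <- sum(cm[j, ]) - tp
  fp <- sum(cm[, j]) - tp
  tn <- total - tp - fn - fp
  sens <- if (tp + fn > 0) tp / (tp + fn) else 0
  spec <- if (tn + fp > 0) tn / (tn + fp) else 0
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den > 0) (tp * tn - fp * fn) / sqrt(den) else 0
  c(sens = sens, spec = spec, mcc = mcc)
}

# feature matrix with one planted informative column among noise
planted_feature_matrix <- function(n_per_class = 20L, p = 1000L,
                                   planted = 417L, margin = 0.6) {
  n <- 2L * n_per_class
  x <- matrix(runif(n * p), n, p)
  colnames(x) <- paste0("f", seq_len(p))
  y <- rep(c("a", "b"), each = n_per_class)
  x[, planted] <- ifelse(y == "a",
    runif(n, 1 + margin, 2), runif(n, 0, 1 - margin)
  )
  list(
    features = dplyr::bind_cols(
      tibble::tibble(id = paste0("s", seq_len(n))),
      tibble::as_tibble(x)
    ),
    labels = y,
    planted_name = paste0("f", planted)
  )
}
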