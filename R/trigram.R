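#' Tri-gram feature names and indices
#'
#' The 1000 tri-gram features are ordered lexicographically in the property
#' triple (x, y, z), 1 <= x, y, z <= 10: the zero-based flat offset is
#' (x-1)*100 + (y-1)*10 + (z-1), and the 1-based column position is that
#' offset plus one.  This ordering is deterministic and invertible, which is
#' what makes RFE rankings reproducible across runs.
#'
#' @param x,y,z Property indices in 1..10 (Polar = 1 ... Proline = 10).
#' @return `trigram_index()`: the 1-based column position in 1..1000.
#'   `trigram_feature_name()`: a stable label of the form
#'   `g_<Prop_x>_<Prop_y>_<Prop_z>`.
#' @examples
#' trigram_index(5, 6, 8) # 458 (zero-based offset 457)
#' trigram_feature_name(5, 6, 8)
#' @export
trigram_index <- function(x, y, z) {
  check_property_index(x, y, z)
  as.integer(x - 1) * 100L + as.integer(y - 1) * 10L + as.integer(z)
}

#' @rdname trigram_index
#' @export
trigram_feature_name <- function(x, y, z) {
  check_property_index(x, y, z)
  props <- taylor_property_table()$property
  paste("g", props[x], props[y], props[z], sep = "_")
}

check_property_index <- function(...) {
  for (v in list(...)) {
    if (!is.numeric(v) || any(is.na(v)) || any(v < 1) || any(v > 10) ||
      any(v != as.integer(v))) {
      abort("property indices must be integers in 1..10")
    }
  }
  invisible(TRUE)
}

# all 1000 column labels in lexicographic (x, y, z) order
trigram_feature_names <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      props <- taylor_property_table()$property
      grid <- expand.grid(z = props, y = props, x = props,
        stringsAsFactors = FALSE
      )
      cache <<- paste("g", grid$x, grid$y, grid$z, sep = "_")
    }
    cache
  }
})

#' Tri-gram feature vector of one POPM
#'
#' For each ordered property triple (x, y, z) the feature is the mean over
#' all L-2 sliding windows of the product
#' `M[i, x] * M[i + 1, y] * M[i + 2, z]` — the relative frequency with which
#' properties x, y, z co-occur at three adjacent sequence positions.  Every
#' value lies in `[0, 1]`.  Windows that contain an all-zero row (a
#' non-standard residue) contribute 0 but still count in the `L - 2`
#' denominator.
#'
#' @param popm A [build_popm()] matrix with at least 3 rows.
#' @return A named numeric vector of length 1000 in lexicographic triple
#'   order.
#' @examples
#' trigram_features(build_popm("MKLVVA"))
#' @export
trigram_features <- function(popm) {
  if (!inherits(popm, "popm")) abort("`popm` must be a popm matrix")
  l <- nrow(popm)
  if (l < 3L) {
    abort(sprintf(
      "sequence '%s' too short for tri-gram (length %d < 3)",
      attr(popm, "sequence_id"), l
    ))
  }
  m <- unclass(popm)
  a <- m[seq_len(l - 2L), , drop = FALSE]
  b <- m[seq_len(l - 2L) + 1L, , drop = FALSE]
  cc <- m[seq_len(l - 2L) + 2L, , drop = FALSE]
  # Khatri-Rao style expansion: column (x-1)*10+y of ab is A[,x]*B[,y]
  ab <- a[, rep(1:10, each = 10), drop = FALSE] *
    b[, rep(1:10, times = 10), drop = FALSE]
  g <- crossprod(ab, cc) / (l - 2L) # 100 x 10, [(x-1)*10+y, z]
  setNames(as.vector(t(g)), trigram_feature_names())
}

#' Encode a set of sequences as a tri-gram feature matrix
#'
#' Builds the POPM and the 1000-dimensional tri-gram feature vector for each
#' sequence in a data frame, returning one row per input row in input order.
#'
#' @param data A data frame with an id column and a sequence column (e.g.,
#'   from [read_fasta()] or [generate_dataset()]).
#' @param sequence,id Column names (strings) holding the residue strings and
#'   the sequence identifiers.
#' @return A tibble: first column `id`, then the 1000 named tri-gram
#'   columns in lexicographic triple order.
#' @examples
#' encode_trigrams(tibble::tibble(id = "p1", sequence = "MKLVVA"))
#' @export
encode_trigrams <- function(data, sequence = "sequence", id = "id") {
  if (!is.data.frame(data)) abort("`data` must be a data frame")
  for (col in c(id, sequence)) {
    if (!col %in% names(data)) {
      abort(sprintf("column '%s' not found in `data`", col))
    }
  }
  ids <- as.character(data[[id]])
  seqs <- as.character(data[[sequence]])
  if (anyDuplicated(ids)) {
    abort(sprintf(
      "duplicate sequence ids: %s",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ))
  }
  short <- ids[nchar(seqs) < 3L]
  if (length(short) > 0) {
    abort(paste0(
      "sequence(s) too short for tri-gram (length < 3): ",
      paste(short, collapse = ", ")
    ))
  }
  rows <- purrr::map2(seqs, ids, function(s, i) {
    trigram_features(build_popm(s, i))
  })
  mat <- do.call(rbind, rows)
  out <- as_tibble(mat)
  dplyr::bind_cols(tibble(id = ids), out)
}

# split a feature tibble into (ids, numeric matrix of feature columns)
feature_parts <- function(features, id = "id") {
  if (!is.data.frame(features)) abort("`features` must be a data frame")
  if (!id %in% names(features)) {
    abort(sprintf("column '%s' not found in `features`", id))
  }
  num <- vapply(features, is.numeric, logical(1))
  num[id] <- FALSE
  cols <- names(features)[num]
  if (length(cols) == 0) abort("no numeric feature columns found")
  x <- as.matrix(features[, cols, drop = FALSE])
  list(ids = as.character(features[[id]]), x = x, columns = cols)
}
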