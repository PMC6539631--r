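SCHEMA_VERSION <- "1"

#' Read protein sequences from a FASTA file
#'
#' Parses FASTA via Biostrings; the id is the header token before the first
#' whitespace, wrapped sequence lines are concatenated, and sequences are
#' uppercased.  Stop (`*`) and gap (`-`) characters are stripped with a
#' warning.  Duplicate ids, records with empty sequences, and files whose
#' first non-blank line is not a header are errors.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` and `sequence`, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0) abort(sprintf("empty FASTA file: %s", path))
  if (!startsWith(trimws(lines[nonblank[1]]), ">")) {
    abort(sprintf(
      "malformed FASTA: sequence before first header at line %d of %s",
      nonblank[1], path
    ))
  }
  aa <- Biostrings::readBStringSet(path)
  ids <- vapply(
    strsplit(names(aa), "\\s+"), function(x) x[1], character(1)
  )
  if (anyDuplicated(ids)) {
    abort(sprintf(
      "duplicate FASTA ids: %s",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ))
  }
  seqs <- toupper(as.character(aa))
  stripped <- gsub("[*-]", "", seqs)
  if (any(stripped != seqs)) {
    warn(sprintf(
      "stripped stop/gap characters from %d sequence(s)",
      sum(stripped != seqs)
    ))
  }
  empty <- ids[nchar(stripped) == 0]
  if (length(empty) > 0) {
    abort(paste0(
      "empty sequence record(s): ", paste(empty, collapse = ", ")
    ))
  }
  bad <- ids[!grepl("^[A-Za-z]+$", stripped)]
  if (length(bad) > 0) {
    abort(paste0(
      "non-alphabetic characters in sequence(s): ",
      paste(bad, collapse = ", ")
    ))
  }
  tibble(id = unname(ids), sequence = unname(stripped))
}

#' Write sequences to a FASTA file
#'
#' @param data A data frame with `id` and `sequence` columns.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(data, path, width = 60L) {
  set <- Biostrings::BStringSet(setNames(data$sequence, data$id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a sequence-id to class-label table
#'
#' Reads a two-column TSV (`id`, `class`).  A first row whose first field is
#' `id` (case-insensitive) is treated as a header and skipped.  Duplicate id
#' rows with conflicting classes are an error; consistent duplicates are
#' collapsed.
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `id` and `class`.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort(sprintf("empty label file: %s", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 2L)
  if (length(bad) > 0) {
    abort(sprintf(
      "label file %s: line %d does not have two tab-separated fields",
      path, bad[1]
    ))
  }
  id <- vapply(fields, function(x) trimws(x[1]), character(1))
  cls <- vapply(fields, function(x) trimws(x[2]), character(1))
  if (tolower(id[1]) == "id") {
    id <- id[-1]
    cls <- cls[-1]
  }
  dup <- unique(id[duplicated(id)])
  for (d in dup) {
    if (length(unique(cls[id == d])) > 1L) {
      abort(sprintf("conflicting classes for id '%s'", d))
    }
  }
  keep <- !duplicated(id)
  tibble(id = id[keep], class = cls[keep])
}

#' Write an id/class label table
#'
#' @param data A data frame with `id` and `class` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(data, path) {
  readr::write_tsv(data[, c("id", "class")], path)
  invisible(path)
}

#' Join sequences with class labels into a validated labeled dataset
#'
#' Every record must have exactly one label and every label must refer to an
#' existing record; offenders are listed by id.  Class order is
#' first-appearance order in the label table.  Per-class counts are reported
#' as a message.
#'
#' As a fallback for FASTA files without a sidecar label table, headers of
#' the form `>id|CLASS` can be split upstream (see [read_fasta()]; the id
#' token keeps the full header token, so split on `|` before calling this).
#'
#' @param records A tibble with `id` and `sequence` (e.g., [read_fasta()]).
#' @param labels A tibble with `id` and `class` (e.g., [read_labels()]), or
#'   a named character vector id -> class.
#' @return A tibble with columns `id`, `sequence`, `class`; attribute
#'   `class_counts` holds the per-class tally.
#' @export
assemble_dataset <- function(records, labels) {
  if (is.character(labels) && !is.null(names(labels))) {
    labels <- tibble(id = names(labels), class = unname(labels))
  }
  if (anyDuplicated(records$id)) {
    abort(paste0(
      "duplicate record ids: ",
      paste(unique(records$id[duplicated(records$id)]), collapse = ", ")
    ))
  }
  unlabeled <- setdiff(records$id, labels$id)
  if (length(unlabeled) > 0) {
    abort(paste0(
      "record(s) without a label: ", paste(unlabeled, collapse = ", ")
    ))
  }
  dangling <- setdiff(labels$id, records$id)
  if (length(dangling) > 0) {
    abort(paste0(
      "label(s) without a record: ", paste(dangling, collapse = ", ")
    ))
  }
  out <- dplyr::left_join(records, labels, by = "id")
  if (length(unique(out$class)) < 2L) {
    abort("a labeled dataset needs at least 2 classes")
  }
  counts <- table(factor(out$class, levels = unique(labels$class)))
  inform(paste0(
    "dataset: ", nrow(out), " sequences; ",
    paste(sprintf("%s: %d", names(counts), as.integer(counts)),
      collapse = ", "
    )
  ))
  structure(out, class_counts = counts)
}

#' Write / read a tri-gram feature matrix
#'
#' The matrix serializes to CSV (first column `id`, then the named feature
#' columns) at full double precision, plus a JSON sidecar
#' (`<path>.meta.json`) recording the schema version, the property-table
#' version, and any encoder settings, so that rankings and models cannot
#' silently mix incompatible encodings.
#'
#' @param features Feature tibble from [encode_trigrams()].
#' @param path Output CSV path.
#' @param metadata Named list merged into the sidecar.
#' @return `path`, invisibly (writer); the feature tibble (reader).
#' @export
write_feature_matrix <- function(features, path, metadata = list()) {
  # 17 significant digits guarantee bit-exact double round-trips
  printable <- features
  num_cols <- names(printable)[vapply(printable, is.numeric, logical(1))]
  printable[num_cols] <- lapply(
    printable[num_cols], formatC, digits = 17, format = "g"
  )
  readr::write_csv(printable, path)
  meta <- c(
    list(
      schema_version = SCHEMA_VERSION,
      property_table = "taylor_properties_v1",
      n_sequences = nrow(features),
      n_features = ncol(features) - 1L
    ),
    metadata
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  # base parser: correctly rounded doubles, so text round-trips bit-exactly
  df <- utils::read.csv(path, check.names = FALSE,
    colClasses = c(id = "character")
  )
  as_tibble(df)
}

#' Write / read an RFE feature ranking
#'
#' The ranking serializes to a TSV (`rank`, `feature`, `column`,
#' `criterion`) plus a JSON settings sidecar (`<path>.settings.json`).
#'
#' @param ranking An [rank_features_rfe()] result.
#' @param path Output TSV path.
#' @return `path`, invisibly (writer); a ranking tibble usable by
#'   [select_top_k()] (reader).
#' @export
write_ranking <- function(ranking, path) {
  if (!inherits(ranking, "rfe_ranking")) {
    abort("`ranking` must be an rfe_ranking")
  }
  readr::write_tsv(ranking$ranking, path)
  jsonlite::write_json(
    c(list(schema_version = SCHEMA_VERSION), ranking$settings),
    paste0(path, ".settings.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_ranking
#' @export
read_ranking <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    rank = readr::col_integer(), feature = readr::col_character(),
    column = readr::col_integer(), criterion = readr::col_double()
  ))
}

#' Write an evaluation report to JSON
#'
#' Serializes a [jackknife_evaluate()] / [compute_metrics()] report:
#' confusion counts (with class names), per-class metrics, overall accuracy
#' and run settings.
#'
#' @param report A `popm_eval` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  if (!inherits(report, "popm_eval")) abort("`report` must be a popm_eval")
  payload <- list(
    schema_version = SCHEMA_VERSION,
    classes = rownames(report$confusion),
    confusion = unname(apply(report$confusion, 1, as.integer,
      simplify = FALSE
    )),
    per_class = report$per_class,
    oa = report$oa,
    n = report$n,
    settings = report$settings
  )
  jsonlite::write_json(payload, path,
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(path)
}
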