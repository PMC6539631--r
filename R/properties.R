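#' Taylor's ten overlapping physicochemical property groups
#'
#' Returns the fixed table of ten overlapping amino-acid groups (Polar,
#' Positive, Negative, Charged, Hydrophobic, Aliphatic, Aromatic, Small,
#' Tiny, Proline) used to build the protein overlapping property matrix
#' (POPM).  A residue may belong to several groups; every standard residue
#' belongs to at least one.  Group order is fixed top-to-bottom and defines
#' property index j = 1..10 of the POPM columns.
#'
#' The table ships as a plain-text resource so that alternative groupings
#' can be swapped in via `file`; the default is version `v1` of the packaged
#' table.
#'
#' @param file Path to a two-column TSV (`property`, comma-separated
#'   `residues`).  Defaults to the packaged Taylor table.
#' @return A tibble with columns `property` (ordered factor levels in table
#'   order) and `residues` (list column of one-letter codes), 10 rows.
#' @examples
#' taylor_property_table()
#' @export
taylor_property_table <- function(file = NULL) {
  file <- file %||% system.file("extdata", "taylor_properties_v1.tsv",
    package = "popmtrigram", mustWork = TRUE
  )
  raw <- readr::read_tsv(file,
    col_types = readr::cols(.default = readr::col_character())
  )
  if (!identical(names(raw), c("property", "residues"))) {
    abort("property table must have columns 'property' and 'residues'")
  }
  tbl <- tibble(
    property = raw$property,
    residues = purrr::map(raw$residues, function(x) {
      toupper(trimws(strsplit(x, ",", fixed = TRUE)[[1]]))
    })
  )
  validate_property_table(tbl)
  tbl
}

validate_property_table <- function(tbl) {
  if (nrow(tbl) != 10L) {
    abort(sprintf("expected 10 property groups, found %d", nrow(tbl)))
  }
  bad <- setdiff(unlist(tbl$residues), STANDARD_RESIDUES)
  if (length(bad) > 0) {
    abort(paste0(
      "non-standard residues in property table: ",
      paste(bad, collapse = ", ")
    ))
  }
  uncovered <- setdiff(STANDARD_RESIDUES, unlist(tbl$residues))
  if (length(uncovered) > 0) {
    abort(paste0(
      "residues in no property group: ", paste(uncovered, collapse = ", ")
    ))
  }
  invisible(tbl)
}

#' Residue-by-property membership matrix
#'
#' Expands a property table into the 20 x 10 binary membership map: entry
#' (r, j) is 1 iff residue r appears in group j.  Rows cover the 20 standard
#' residues in alphabet order; columns follow the table's group order.
#'
#' @inheritParams taylor_property_table
#' @param table A property table from [taylor_property_table()]; built from
#'   the default resource when missing.
#' @return A tibble with column `residue` followed by ten 0/1 integer
#'   columns named after the property groups.
#' @examples
#' residue_membership()
#' @export
residue_membership <- function(table = NULL) {
  table <- table %||% taylor_property_table()
  bits <- vapply(
    table$residues,
    function(set) as.integer(STANDARD_RESIDUES %in% set),
    integer(length(STANDARD_RESIDUES))
  )
  colnames(bits) <- table$property
  dplyr::bind_cols(tibble(residue = STANDARD_RESIDUES), as_tibble(bits))
}

# cached 20x10 integer matrix with residue rownames, built once per session
membership_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      mem <- residue_membership()
      m <- as.matrix(mem[, -1])
      storage.mode(m) <- "integer"
      rownames(m) <- mem$residue
      cache <<- m
    }
    cache
  }
})

#' Encode one residue as a 10-bit property vector
#'
#' Maps a one-letter amino-acid code (case-insensitive) to its binary
#' membership vector over the ten property groups.  Non-standard codes
#' (B, J, O, U, X, Z) map to the all-zero vector with a warning, so that
#' positional structure is preserved for downstream tri-gram windows.
#'
#' @param residue A single one-letter character.
#' @return A named integer vector of length 10 (names are the property
#'   groups), each entry 0 or 1.
#' @examples
#' encode_residue("V") # Hydrophobic, Aliphatic, Small
#' @export
encode_residue <- function(residue) {
  if (!is.character(residue) || length(residue) != 1L ||
    nchar(residue) != 1L) {
    abort("`residue` must be a single one-letter character")
  }
  if (!grepl("^[A-Za-z]$", residue)) {
    abort(sprintf("non-alphabetic residue code: '%s'", residue))
  }
  r <- toupper(residue)
  m <- membership_matrix()
  if (r %in% rownames(m)) {
    return(m[r, ])
  }
  warn(sprintf("non-standard residue '%s' encoded as all-zero vector", r))
  setNames(integer(10L), colnames(m))
}

#' Build the protein overlapping property matrix (POPM)
#'
#' Encodes a protein sequence as an L x 10 binary matrix whose row i is the
#' property membership vector of residue i.  Rows for non-standard residue
#' codes are all-zero (one warning per sequence).
#'
#' @param sequence Residue string (length >= 1, alphabetic only; `*` and `-`
#'   are not accepted here — see [read_fasta()] which strips them).
#' @param sequence_id Identifier carried along with the matrix.
#' @return An object of class `popm`: the L x 10 integer matrix with
#'   attributes `sequence_id` and `length`.
#' @examples
#' build_popm("IVL", "toy")
#' @export
build_popm <- function(sequence, sequence_id = "seq") {
  if (!is.character(sequence) || length(sequence) != 1L ||
    nchar(sequence) == 0L) {
    abort("`sequence` must be a non-empty string")
  }
  if (!grepl("^[A-Za-z]+$", sequence)) {
    abort(sprintf(
      "sequence '%s' contains non-alphabetic characters", sequence_id
    ))
  }
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  m <- membership_matrix()
  rows <- match(chars, rownames(m))
  mat <- matrix(0L, nrow = length(chars), ncol = 10L,
    dimnames = list(NULL, colnames(m))
  )
  known <- !is.na(rows)
  mat[known, ] <- m[rows[known], , drop = FALSE]
  if (any(!known)) {
    warn(sprintf(
      "sequence '%s': %d non-standard residue(s) (%s) encoded as zero rows",
      sequence_id, sum(!known),
      paste(sort(unique(chars[!known])), collapse = ", ")
    ))
  }
  structure(mat,
    class = c("popm", class(mat)),
    sequence_id = sequence_id, length = length(chars)
  )
}

#' @export
print.popm <- function(x, ...) {
  cat(sprintf(
    "<popm> sequence '%s', %d residues x 10 properties\n",
    attr(x, "sequence_id"), attr(x, "length")
  ))
  print(unclass(x)[seq_len(min(6L, nrow(x))), , drop = FALSE])
  if (nrow(x) > 6L) cat(sprintf("... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}
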