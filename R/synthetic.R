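#' Build class-specific residue composition profiles
#'
#' Each class profile is a mixture of the uniform distribution over the 20
#' standard residues and a distribution concentrated on a class-specific
#' residue set: `p(r) = (1 - s) / 20 + s * [r in S_c] / |S_c|`, where the
#' `informative_strength` s in `[0, 1]` controls how far profiles deviate
#' from uniform.  `s = 0` gives identical (uninformative) profiles for all
#' classes — the exchangeable null; larger s concentrates composition on the
#' class set, which propagates to near-disjoint tri-gram support when the
#' sets map to distinct property groups.
#'
#' @param classes Character vector of class names.
#' @param residue_sets Named list (one entry per class) of residue vectors;
#'   defaults to property-aligned sets (aromatic, aliphatic, charged, tiny,
#'   polar-small, proline/other) recycled over classes.
#' @param informative_strength Mixture weight s in `[0, 1]`.
#' @return Named list of numeric length-20 profiles (names = residues),
#'   each summing to 1.
#' @export
class_profiles <- function(classes, residue_sets = NULL,
                           informative_strength = 0.5) {
  s <- informative_strength
  if (!is.numeric(s) || length(s) != 1L || s < 0 || s > 1) {
    abort("`informative_strength` must be a number in [0, 1]")
  }
  default_sets <- list(
    c("F", "Y", "W"), # aromatic
    c("I", "V", "L"), # aliphatic
    c("K", "R", "D", "E"), # charged
    c("A", "S", "G", "C"), # tiny
    c("N", "Q", "S", "T"), # polar small
    c("P", "H", "M") # proline / other
  )
  if (is.null(residue_sets)) {
    if (length(classes) > length(default_sets)) {
      abort(sprintf(
        "default residue sets cover at most %d classes; supply residue_sets",
        length(default_sets)
      ))
    }
    residue_sets <- setNames(default_sets[seq_along(classes)], classes)
  }
  purrr::map(setNames(residue_sets[classes], classes), function(set) {
    set <- toupper(set)
    bad <- setdiff(set, STANDARD_RESIDUES)
    if (length(bad) > 0) {
      abort(paste0("non-standard residues in set: ", paste(bad, collapse = ", ")))
    }
    p <- rep((1 - s) / 20, 20)
    names(p) <- STANDARD_RESIDUES
    p[set] <- p[set] + s / length(set)
    p
  })
}

#' Specification of a synthetic labeled sequence dataset
#'
#' Describes a dataset of i.i.d.-residue sequences whose residue
#' composition depends on the class — the minimal generative structure that
#' exercises the tri-gram pipeline, since the features depend only on
#' short-range property co-occurrence.  No positional or Markov structure,
#' homology, or redundancy is emulated.
#'
#' @param n_per_class A single count, or a named/per-class vector of counts
#'   aligned with `names(class_profiles)`.
#' @param class_profiles Named list of residue profiles from
#'   [class_profiles()] (each a length-20 non-negative vector summing to 1).
#' @param length_range Two integers `(min, max)`, min >= 3; sequence
#'   lengths are drawn uniformly from this range.  The default (50, 500)
#'   spans typical benchmark protein lengths.
#' @param seed Integer seed; generation is deterministic given the spec.
#' @param informative_strength Recorded for provenance when the profiles
#'   came from [class_profiles()].
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_per_class, class_profiles,
                           length_range = c(50L, 500L), seed = 1L,
                           informative_strength = NA_real_) {
  if (!is.list(class_profiles) || is.null(names(class_profiles))) {
    abort("`class_profiles` must be a named list of residue profiles")
  }
  classes <- names(class_profiles)
  if (length(classes) < 2L) abort("need at least 2 classes")
  for (cl in classes) {
    p <- class_profiles[[cl]]
    if (length(p) != 20L || any(p < 0) || sum(p) == 0) {
      abort(sprintf("degenerate profile for class '%s'", cl))
    }
    if (abs(sum(p) - 1) > 1e-8) {
      abort(sprintf("profile for class '%s' does not sum to 1", cl))
    }
  }
  if (length(n_per_class) == 1L) {
    n_per_class <- setNames(rep(as.integer(n_per_class), length(classes)),
      classes
    )
  } else if (is.null(names(n_per_class))) {
    if (length(n_per_class) != length(classes)) {
      abort("`n_per_class` length must match the number of classes")
    }
    n_per_class <- setNames(as.integer(n_per_class), classes)
  } else {
    n_per_class <- setNames(
      as.integer(n_per_class[classes]), classes
    )
  }
  if (any(is.na(n_per_class)) || any(n_per_class < 1L)) {
    abort("`n_per_class` must be positive for every class")
  }
  length_range <- as.integer(length_range)
  if (length(length_range) != 2L || length_range[1] < 3L ||
    length_range[2] < length_range[1]) {
    abort("`length_range` must be (min >= 3, max >= min)")
  }
  structure(
    list(
      n_per_class = n_per_class, class_profiles = class_profiles,
      length_range = length_range, seed = as.integer(seed),
      informative_strength = informative_strength
    ),
    class = "synthetic_spec"
  )
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(
    "<synthetic_spec> %d classes, %d sequences, lengths %d-%d, seed %d\n",
    length(x$n_per_class), sum(x$n_per_class),
    x$length_range[1], x$length_range[2], x$seed
  ))
  print(x$n_per_class)
  invisible(x)
}

#' Synthetic specs shaped like the apoptosis-protein benchmarks
#'
#' Returns a [synthetic_spec()] whose class count and per-class sizes
#' mirror the two standard apoptosis-protein benchmark compositions:
#' `"zw225-like"` (4 classes, sizes Nucl 41, Cyto 70, Mito 25, Memb 89;
#' total 225) or `"cl317-like"` (6 classes, sizes Cyto 112, Endo 47,
#' Memb 55, Mito 34, Nucl 52, Secr 17; total 317), with moderately
#' separated property-aligned residue profiles.  These specs exercise the
#' benchmarks' class-imbalance structure without imitating real sequences.
#'
#' @param shape `"zw225-like"` or `"cl317-like"`.
#' @param informative_strength Profile separation in `[0, 1]`
#'   (see [class_profiles()]); 0 gives the label-free null.
#' @param seed Integer seed.
#' @param length_range Passed to [synthetic_spec()].
#' @return A `synthetic_spec`.
#' @export
default_benchmark_spec <- function(shape = c("zw225-like", "cl317-like"),
                                   informative_strength = 0.5, seed = 1L,
                                   length_range = c(50L, 500L)) {
  shape <- match.arg(shape)
  sizes <- switch(shape,
    "zw225-like" = c(Nucl = 41L, Cyto = 70L, Mito = 25L, Memb = 89L),
    "cl317-like" = c(
      Cyto = 112L, Endo = 47L, Memb = 55L, Mito = 34L, Nucl = 52L,
      Secr = 17L
    )
  )
  synthetic_spec(
    n_per_class = sizes,
    class_profiles = class_profiles(names(sizes),
      informative_strength = informative_strength
    ),
    length_range = length_range, seed = seed,
    informative_strength = informative_strength
  )
}

#' Generate a labeled synthetic sequence dataset
#'
#' Draws, for each class, `n_per_class` sequences with lengths uniform in
#' `length_range` and residues i.i.d. from the class profile.  Output is
#' deterministic given the spec (including its seed).
#'
#' @param spec A [synthetic_spec()].
#' @return A labeled dataset tibble (`id`, `sequence`, `class`) that passes
#'   [assemble_dataset()] validation.
#' @export
generate_dataset <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) {
    abort("`spec` must be a synthetic_spec")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  rows <- purrr::imap(spec$n_per_class, function(n, cl) {
    p <- spec$class_profiles[[cl]]
    lens <- sample(
      seq(spec$length_range[1], spec$length_range[2]), n, replace = TRUE
    )
    seqs <- vapply(lens, function(l) {
      paste(
        sample(STANDARD_RESIDUES, l, replace = TRUE, prob = p),
        collapse = ""
      )
    }, character(1))
    tibble(
      id = sprintf("%s_%04d", cl, seq_len(n)),
      sequence = seqs,
      class = cl
    )
  })
  dplyr::bind_rows(rows)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
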