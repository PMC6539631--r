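test_that("feature indexing is lexicographic in the property triple", {
  expect_identical(trigram_index(1, 1, 1), 1L) # zero-based offset 0
  expect_identical(trigram_index(10, 10, 10), 1000L) # zero-based 999
  expect_identical(trigram_index(5, 6, 8), 458L) # zero-based 457
  expect_identical(
    trigram_feature_name(5, 6, 8), "g_Hydrophobic_Aliphatic_Small"
  )
  expect_error(trigram_index(0, 1, 1), "1..10")
  expect_error(trigram_index(1, 11, 1), "1..10")
})

test_that("single-window sequences reproduce hand-derived tri-grams", {
  # M is Hydrophobic only: one window, a single unit feature at (5,5,5)
  f <- trigram_features(build_popm("MMM"))
  expect_identical(which(f != 0), setNames(trigram_index(5, 5, 5),
    trigram_feature_name(5, 5, 5)
  ))
  expect_equal(unname(f[trigram_index(5, 5, 5)]), 1)

  # IVL: x in {5,6}, y in {5,6,8}, z in {5,6} -> 12 unit entries
  f2 <- trigram_features(build_popm("IVL"))
  expect_identical(sum(f2 == 1), 12L)
  expect_equal(sum(f2), 12)
  on <- expand.grid(z = c(5, 6), y = c(5, 6, 8), x = c(5, 6))
  expect_setequal(
    which(f2 != 0),
    trigram_index(on$x, on$y, on$z)
  )
})

test_that("a repeated residue with k properties gives k^3 unit features", {
  for (r in c("M", "V", "K", "P")) {
    k <- sum(encode_residue(r))
    f <- trigram_features(build_popm(strrep(r, 10)))
    expect_identical(sum(f == 1), as.integer(k^3))
    expect_identical(sum(f != 0), as.integer(k^3))
  }
})

test_that("vectorized features equal the naive triple-loop oracle", {
  set.seed(93)
  for (rep in 1:30) {
    s <- random_sequence(sample(3:60, 1))
    p <- build_popm(s)
    expect_equal(unname(trigram_features(p)), naive_trigram(p),
      tolerance = 1e-12
    )
  }
})

test_that("total feature mass factorizes over window row sums", {
  set.seed(94)
  for (rep in 1:20) {
    s <- random_sequence(sample(3:120, 1))
    p <- build_popm(s)
    l <- nrow(p)
    ns <- rowSums(p)
    expected <- sum(ns[1:(l - 2)] * ns[2:(l - 1)] * ns[3:l]) / (l - 2)
    expect_equal(sum(trigram_features(p)), expected, tolerance = 1e-10)
  }
})

test_that("features stay in [0, 1] up to benchmark-extreme lengths", {
  set.seed(95)
  for (len in c(76L, 3037L, 5000L)) {
    f <- trigram_features(build_popm(random_sequence(len)))
    expect_length(f, 1000L)
    expect_true(all(f >= 0 & f <= 1))
  }
})

test_that("windows spanning a non-standard residue count in the denominator", {
  suppressWarnings({
    fx <- trigram_features(build_popm("MXMMM")) # L-2 = 3, zero row at 2
    fm <- trigram_features(build_popm("MMMMM"))
  })
  # only the window clear of the zero row contributes for MXMMM... windows
  # (M,X,M),(X,M,M),(M,M,M): one in three is all-hydrophobic
  expect_equal(unname(fx[trigram_index(5, 5, 5)]), 1 / 3)
  expect_equal(unname(fm[trigram_index(5, 5, 5)]), 1)
})

test_that("encode_trigrams returns one ordered row per sequence", {
  d <- tibble::tibble(
    id = c("a", "b"), sequence = c("MMM", "IVL")
  )
  feats <- encode_trigrams(d)
  expect_identical(dim(feats), c(2L, 1001L))
  expect_identical(feats$id, c("a", "b"))
  expect_identical(names(feats)[-1], popmtrigram:::trigram_feature_names())
  expect_equal(unname(rowSums(feats[, -1])), c(1, 12))

  expect_error(
    encode_trigrams(tibble::tibble(id = "short1", sequence = "MM")),
    "short1"
  )
  expect_error(
    encode_trigrams(tibble::tibble(id = c("x", "x"),
      sequence = c("MMM", "MMM")
    )),
    "duplicate"
  )
})

test_that("feature matrices round-trip through CSV at full precision", {
  set.seed(96)
  d <- tibble::tibble(
    id = paste0("s", 1:3),
    sequence = vapply(sample(10:40, 3), random_sequence, character(1))
  )
  feats <- encode_trigrams(d)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_matrix(feats, path, metadata = list(note = "test"))
  back <- read_feature_matrix(path)
  expect_equal(as.data.frame(back), as.data.frame(feats), tolerance = 0)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"))
  expect_identical(meta$n_features, 1000L)
  expect_identical(meta$property_table, "taylor_properties_v1")
})
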