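# Modified cosine scoring, network construction, molecular families,
# node annotation and MGF round-tripping.

test_that("modified cosine handles the canonical cases", {
  p <- network_params(min_matched_peaks = 1L)
  s <- fragment_spectrum("s", 500, cbind(c(100, 200, 300), c(10, 40, 20)))
  expect_equal(modified_cosine(s, s, p)$score, 1, tolerance = 1e-12)
  # precursor-shifted analogue peaks pair under the offset
  s1 <- fragment_spectrum("a", 200, cbind(c(100, 150), c(1, 1)))
  s2 <- fragment_spectrum("b", 210, cbind(c(100, 160), c(1, 1)))
  mc <- modified_cosine(s1, s2, p)
  expect_equal(mc$score, 1, tolerance = 1e-12)
  expect_equal(mc$n_matched, 2L)
  # nothing pairable under either offset
  s3 <- fragment_spectrum("c", 777, cbind(c(50, 60), c(1, 1)))
  expect_equal(modified_cosine(s1, s3, p)$score, 0)
})

test_that("modified cosine is exactly symmetric", {
  set.seed(31)
  p <- network_params(min_matched_peaks = 1L)
  for (i in 1:20) {
    a <- random_spectrum(sprintf("a%d", i))
    b <- random_spectrum(sprintf("b%d", i))
    expect_identical(modified_cosine(a, b, p)$score,
                     modified_cosine(b, a, p)$score)
  }
})

test_that("greedy pairing agrees with the exhaustive assignment oracle", {
  set.seed(13)
  p <- network_params(min_matched_peaks = 1L, fragment_tol = 0.3)
  for (i in 1:50) {
    a <- random_spectrum(sprintf("a%d", i), max_peaks = 8L)
    b <- random_spectrum(sprintf("b%d", i), max_peaks = 8L)
    g <- modified_cosine(a, b, p, method = "greedy")$score
    o <- modified_cosine(a, b, p, method = "optimal")$score
    expect_lte(abs(g - o), 1e-9)
  }
})

test_that("network edges obey threshold and matched-peak rules", {
  set.seed(41)
  peaks <- cbind(seq(80, 220, by = 20), runif(8, 10, 100))
  same <- lapply(1:4, function(i)
    fragment_spectrum(sprintf("s%d", i), 400, peaks))
  net <- build_network(same, network_params())
  expect_equal(length(net$families), 1)
  expect_equal(nrow(net$edges), choose(4, 2))  # identical spectra: a clique
  # a strict threshold of 1.0 silences noisy pairs
  noisy <- lapply(1:4, function(i) random_spectrum(sprintf("n%d", i)))
  net2 <- build_network(noisy, network_params(cosine_threshold = 1.0,
                                              min_matched_peaks = 1L))
  expect_equal(nrow(net2$edges), 0)
  expect_equal(length(net2$singletons), 4)
})

test_that("edge sets are invariant to spectrum input order", {
  set.seed(51)
  peaks <- cbind(seq(80, 220, by = 20), runif(8, 10, 100))
  sp <- c(
    lapply(1:3, function(i) fragment_spectrum(sprintf("s%d", i), 400 + i, peaks)),
    lapply(4:6, function(i) random_spectrum(sprintf("s%d", i)))
  )
  key <- function(net) {
    e <- net$edges
    sort(paste(pmin(e$source, e$target), pmax(e$source, e$target)))
  }
  expect_identical(key(build_network(sp)), key(build_network(rev(sp))))
})

test_that("analogue spectra from a shared scaffold link above threshold", {
  scaffold <- cbind(seq(60, 180, by = 15), rep(50, 9))
  base <- generate_spectrum(300, scaffold, 0, 0, spectrum_id = "base")
  ch2 <- generate_spectrum(314.0157, scaffold, 14.0157, 0, spectrum_id = "ch2")
  mc <- modified_cosine(base, ch2, network_params())
  expect_gt(mc$score, 0.7)
  expect_gte(mc$n_matched, 6)
  # unrelated scaffolds stay below the linking range
  set.seed(61)
  other <- generate_spectrum(410, cbind(sort(runif(9, 60, 350)), rep(50, 9)),
                             0, 0, spectrum_id = "other")
  expect_lt(modified_cosine(base, other, network_params())$score, 0.3)
  # zero shift and no noise reproduces the scaffold exactly
  expect_equal(unname(base$peaks[, 1]), scaffold[, 1])
  expect_equal(unname(base$peaks[, 2]), scaffold[, 2])
})

test_that("planted molecular families come out as single components", {
  w <- small_world()
  net <- build_network(w$spectra, network_params())
  fam_of <- stats::setNames(rep(names(net$families), lengths(net$families)),
                            unlist(net$families))
  for (cl in w$ledger$clusters) {
    ids <- sprintf("MSMS_%s", cl$linked_features)
    if (length(ids) < 2) next
    expect_equal(length(unique(fam_of[ids])), 1)
    expect_false(any(is.na(fam_of[ids])))
  }
})

test_that("node annotation labels core, shared and unique features", {
  rows <- rbind(
    raw_rows(300.15, 4, strain = "S1"), raw_rows(300.15, 4, strain = "S2"),
    raw_rows(450.25, 7, strain = "S1"), raw_rows(450.25, 7, strain = "S2"),
    raw_rows(450.25, 7, strain = "S3"),
    raw_rows(600.35, 9, strain = "S3")
  )
  ft <- align_features(rows)
  mz <- function(m) m + 1.00727646
  peaks <- cbind(c(90, 120), c(5, 9))
  sp <- list(
    fragment_spectrum("core", mz(450.25), peaks, strain_id = "S1"),
    fragment_spectrum("shared", mz(300.15), peaks, strain_id = "S1"),
    fragment_spectrum("unique", mz(600.35), peaks, strain_id = "S3"),
    fragment_spectrum("lost", mz(999.99), peaks, strain_id = "S1")
  )
  net <- build_network(sp, network_params(min_matched_peaks = 1L))
  expect_warning(net <- annotate_nodes(net, ft), "no feature match")
  lab <- stats::setNames(net$nodes$label, net$nodes$spectrum_id)
  expect_equal(unname(lab[c("core", "shared", "unique", "lost")]),
               c("core", "shared", "unique", "unknown"))
})

test_that("MGF files round-trip", {
  sp <- list(
    fragment_spectrum("one", 321.1234, cbind(c(100.5, 200.25), c(10, 20)),
                      rt = 5.5, strain_id = "ST01", feature_id = "TM0001"),
    fragment_spectrum("two", 654.4321, cbind(150.125, 33))
  )
  tmp <- tempfile(fileext = ".mgf")
  write_mgf(sp, tmp)
  back <- read_mgf(tmp)
  expect_equal(length(back), 2)
  expect_equal(back[[1]]$spectrum_id, "one")
  expect_equal(back[[1]]$precursor_mz, 321.1234, tolerance = 1e-6)
  expect_equal(back[[1]]$rt, 5.5, tolerance = 1e-6)
  expect_equal(back[[1]]$strain_id, "ST01")
  expect_equal(back[[1]]$feature_id, "TM0001")
  expect_equal(unname(back[[1]]$peaks[, 1]), c(100.5, 200.25), tolerance = 1e-6)
  expect_true(is.na(back[[2]]$strain_id))
  # a missing file errors (readLines also warns about it first)
  suppressWarnings(expect_error(read_mgf(tempfile()), "cannot open"))
})
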