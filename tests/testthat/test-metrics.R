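# Metric arithmetic against counting/sorting oracles, toolkit profiling,
# good ranges, and activity classes.

test_that("valid fraction counts parse failures only", {
  vf <- valid_fraction(c("CCO", "c1ccccc1", "CC(", "CCN"))
  expect_equal(as.numeric(vf), 0.75)
  expect_length(attr(vf, "valid_set"), 3L)
  expect_equal(as.numeric(valid_fraction(rep("CCO", 5))), 1) # dups ignored
  expect_error(valid_fraction(character()), "empty")
})

test_that("unique fraction deduplicates a seeded subsample", {
  expect_equal(unique_fraction(c("CCO", "CCO", "CCN"), c = 3, seed = 1), 2 / 3)
  expect_equal(unique_fraction(letters, c = 26, canonical = TRUE), 1)
  expect_error(unique_fraction(c("C", "N"), c = 10), "2 molecules")
  # counting oracle: 100 distinct molecules, 10 duplicated once
  set.seed(9)
  base <- sprintf("%s%d", "C", 1:100) # opaque keys; canonical = TRUE path
  s <- c(base, base[1:10])
  expect_equal(unique_fraction(s, c = 110, canonical = TRUE),
               length(unique(s)) / 110)
})

test_that("unique fraction canonicalizes aliased spellings", {
  expect_equal(unique_fraction(c("OCC", "CCO", "C(C)O"), c = 3, seed = 2),
               1 / 3)
})

test_that("novel fraction is a canonical set difference", {
  expect_equal(novel_fraction(c("CCO", "CCN", "CCC"), "CCN",
                              canonical = TRUE), 2 / 3)
  expect_equal(novel_fraction(c("CCO", "CCN"), c("CCO", "CCN", "CCC"),
                              canonical = TRUE), 0)
  expect_equal(novel_fraction(c("CCO", "CCN"), "CCC", canonical = TRUE), 1)
  expect_error(novel_fraction(character(), "C"), "empty")
  # aliasing invariance: same molecules spelled differently on both sides
  expect_equal(novel_fraction(c("OCC", "c1ccccc1"),
                              c("CCO", "C1=CC=CC=C1")), 0)
})

test_that("wasserstein distance satisfies its metric properties", {
  expect_equal(wasserstein_1d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(wasserstein_1d(0, 3), 3) # translation of point masses
  expect_equal(wasserstein_1d(c(0, 0), c(5, 5)), 5)
  set.seed(12)
  a <- rnorm(40); b <- rexp(25)
  expect_equal(wasserstein_1d(a, b), wasserstein_1d(b, a))
  # translation additivity for point masses
  expect_equal(wasserstein_1d(2, 7), wasserstein_1d(0, 5))
})

test_that("wasserstein matches the sorted-difference oracle", {
  set.seed(13)
  a <- rnorm(50); b <- rnorm(50, mean = 1)
  expect_equal(wasserstein_1d(a, b), mean(abs(sort(a) - sort(b))))
  # unequal sizes: replicate each sample to the common refinement
  a2 <- rnorm(12); b2 <- runif(18)
  oracle <- mean(abs(sort(rep(a2, each = 3)) - sort(rep(b2, each = 2))))
  expect_equal(wasserstein_1d(a2, b2), oracle)
})

test_that("property profiles match textbook molecules", {
  pr <- property_profile(c("CCO", "c1ccccc1"))
  expect_equal(pr$mw[1], 46.07, tolerance = 1e-3)
  expect_identical(pr$hbd[1], 1)
  expect_identical(pr$hba[1], 1)
  expect_identical(pr$hbd[2], 0)
  expect_identical(pr$hba[2], 0)
  expect_true(all(pr$qed >= 0 & pr$qed <= 1))
  expect_true(all(pr$sa >= 1 & pr$sa <= 10))
  expect_identical(property_profile("CCO"), property_profile("CCO"))
  expect_error(property_profile("CC("), "unparsable")
})

test_that("good-range report computes closed-interval percentages", {
  inside <- tibble::tibble(mw = 350, tpsa = 60, logp = 2, hbd = 1, hba = 3,
                           qed = 0.6, sa = 3)
  rep1 <- good_range_report(inside)
  expect_true(all(rep1$percent_in_range == 100))
  heavy <- dplyr::mutate(inside, mw = 600)
  expect_equal(
    good_range_report(heavy)$percent_in_range[
      good_range_report(heavy)$property == "mw"], 0)
  ten <- dplyr::bind_rows(lapply(1:10, function(i) {
    dplyr::mutate(inside, mw = ifelse(i <= 7, 350, 600))
  }))
  r10 <- good_range_report(ten)
  expect_equal(r10$percent_in_range[r10$property == "mw"], 70)
  expect_true(all(r10$percent_in_range >= 0 & r10$percent_in_range <= 100))
})

test_that("activity classes use left-closed 6/7/8 boundaries", {
  x <- classify_activity(c(5.9, 6, 6.5, 7, 7.5, 8, 8.1))
  expect_identical(as.character(x),
                   c("low", "middle", "middle", "high", "high",
                     "ultra-high", "ultra-high"))
  expect_error(classify_activity(c(5, NA)), "finite")
})

test_that("evaluation report assembles all metrics coherently", {
  gen <- tibble::tibble(smiles = c("CCO", "CCN", "CCC", "CCO", "c1ccccc1",
                                   "CCOC", "CCCC", "CC=C", "C#N", "CCS"))
  train <- tibble::tibble(smiles = c("CCO", "CCN"))
  rep <- evaluate_generation(gen, train, unique_k = 5L, seed = 2)
  expect_s3_class(rep, "mg_report")
  expect_equal(rep$valid, 1)
  expect_equal(rep$novel, 0.7)
  expect_true(all(tidy(rep)$value[tidy(rep)$metric %in%
                                    c("valid", "novel")] <= 1))
  expect_identical(nrow(rep$good_ranges), 7L)
  expect_true(all(c("mw", "qed") %in% names(rep$wasserstein)))
})
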