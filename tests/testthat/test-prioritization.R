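test_that("activity calls use strict viability thresholding", {
  act <- call_activity(table1_viability())
  expect_true(act$active[act$sample_id == "S1"])
  # S3 sits at 51% viability: below a 50%-decrease cutoff, hence inactive
  # under the strict rule even though the study counted it cytotoxic
  expect_false(act$active[act$sample_id == "S3"])
  expect_setequal(act$sample_id[act$active],
                  c("S1", "S2", "S4", "S5", "S6", "S7", "S8"))
  one <- call_activity(data.frame(sample_id = "X", viability_percent = 100))
  expect_false(one$active)
  edge <- call_activity(data.frame(sample_id = "X", viability_percent = 51))
  expect_false(edge$active)
  expect_error(call_activity(data.frame(sample_id = "X",
                                        viability_percent = -1)), "viability")
})

test_that("viability computes as percent of averaged control", {
  expect_equal(compute_viability(0.08, 1.00), 8.0)
  expect_equal(compute_viability(1.0, 1.0), 100.0)
  expect_equal(compute_viability(c(0.30, 0.32, 0.31), c(1, 1, 1)), 31.0)
  expect_error(compute_viability(0.5, 0), "control")
})

test_that("normalization performs sum, log10 and unit-variance steps", {
  withr::with_seed(11, {
    x <- matrix(rlnorm(5 * 20, 8, 1), nrow = 5,
                dimnames = list(paste0("S", 1:5), paste0("F", 1:20)))
  })
  nm <- normalize_table(x)
  expect_equal(colMeans(nm), rep(0, ncol(nm)), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(apply(nm, 2, sd), rep(1, ncol(nm)), tolerance = 1e-10,
               ignore_attr = TRUE)
  # sum-normalization makes scaling one sample's row a no-op
  x2 <- x
  x2[2, ] <- x2[2, ] * 7.3
  expect_equal(normalize_table(x2), nm, tolerance = 1e-10, ignore_attr = TRUE)
  # a feature with constant share across samples is dropped with a warning
  xc <- rbind(S1 = c(2, 3, 5), S2 = c(2, 5, 3), S3 = c(2, 1, 7))
  colnames(xc) <- c("const", "a", "b")
  expect_warning(nmc <- normalize_table(xc), "constant")
  expect_false("const" %in% colnames(nmc))
  xz <- x
  xz[3, ] <- 0
  expect_error(normalize_table(xz), "S3")
})

test_that("pca matches the covariance eigendecomposition oracle", {
  toy <- rbind(c(1, 0), c(0, 1), c(-1, -1))
  p <- pca(toy)
  oracle <- brute_force_pca(toy)
  expect_equal(p$explained_variance_fraction, oracle$fractions,
               tolerance = 1e-10)
  expect_equal(p$explained_variance_fraction[1], 0.75, tolerance = 1e-10)
  # random small matrices: loadings and scores agree up to sign
  withr::with_seed(4, {
    for (i in 1:5) {
      n <- sample(4:10, 1)
      pp <- sample(3:10, 1)
      x <- matrix(rnorm(n * pp), n, pp)
      rownames(x) <- paste0("S", 1:n)
      colnames(x) <- paste0("F", 1:pp)
      res <- pca(x)
      orc <- brute_force_pca(x)
      k <- ncol(res$scores)
      for (j in seq_len(k)) {
        expect_equal(abs(res$loadings[, j]), abs(orc$loadings[, j]),
                     tolerance = 1e-8, ignore_attr = TRUE)
        expect_equal(abs(res$scores[, j]), abs(orc$scores[, j]),
                     tolerance = 1e-8, ignore_attr = TRUE)
      }
      expect_equal(sum(res$explained_all), 1, tolerance = 1e-8)
      # loadings columns are orthonormal
      expect_equal(crossprod(res$loadings), diag(k), tolerance = 1e-8,
                   ignore_attr = TRUE)
      # explained fractions are non-increasing
      expect_true(all(diff(res$explained_variance_fraction) <= 1e-12))
    }
  })
  dup <- rbind(A = c(1, 2, 3), B = c(1, 2, 3), C = c(4, 0, 1))
  pd <- pca(dup)
  expect_equal(pd$scores["A", ], pd$scores["B", ], tolerance = 1e-10)
  expect_error(pca(matrix(1, 1, 3)), "at least 2")
})

test_that("the cohort pipeline recovers the alkaloid-bearing specimens", {
  co <- simulate_cohort(small_cohort_spec(seed = 31))
  ft <- build_feature_table(co$runs)
  nm <- suppressWarnings(normalize_table(ft))
  p <- pca(nm, 5)
  act <- call_activity(co$bioactivity)
  pr <- prioritize_cluster(p, act)
  expect_setequal(pr$candidates, c("S1", "S5", "S8"))
  expect_true(1 %in% pr$components)
  # driver features are injected alkaloid ions that match the library
  pf <- prioritize_features(p, ft$features, curated_library(),
                            components = pr$components)
  matched <- pf[!is.na(pf$compound), ]
  expect_gt(nrow(matched), 5)
  truth_mz <- unique(co$truth$mz[co$truth$fn == 1])
  good <- vapply(matched$mz, function(m)
    any(abs(m - truth_mz) / m * 1e6 < 15), logical(1))
  expect_gte(mean(good), 0.9)
  # degenerate tolerance matches nothing
  pf0 <- prioritize_features(p, ft$features, curated_library(),
                             components = pr$components, ppm_tol = 0)
  expect_true(all(is.na(pf0$compound)))
  expect_error(prioritize_cluster(p, act[-1, ]), "cover")
})

test_that("signal-free cohorts yield no candidate cluster", {
  co <- simulate_cohort(small_cohort_spec(seed = 32,
                                          apa_sample_ids = character()))
  ft <- build_feature_table(co$runs)
  p <- pca(suppressWarnings(normalize_table(ft)), 5)
  pr <- prioritize_cluster(p, call_activity(co$bioactivity))
  expect_length(pr$candidates, 0)
  pf_bg <- prioritize_features(p, ft$features, curated_library(),
                               components = 1L, top_k = 30)
  expect_lte(sum(!is.na(pf_bg$compound)), 2) # at most chance-level matches
})

test_that("the abundance matrix reflects the injected compound profiles", {
  co <- simulate_cohort(small_cohort_spec(seed = 33))
  lib <- curated_library()
  anns <- do.call(rbind, lapply(c("S1", "S5", "S8"), function(id)
    annotate_run(co$runs[[id]], lib)))
  m <- abundance_heatmap(anns)
  expect_true(all(c("S1", "S5", "S8") %in% colnames(m)))
  # S1 injected with twice the cyclostellettamine Q content of S5
  expect_gt(m["Cyclostellettamine Q", "S1"], m["Cyclostellettamine Q", "S5"])
  z <- abundance_heatmap(anns, scaling = "zscore")
  rs <- rowMeans(z)
  expect_equal(unname(rs), rep(0, nrow(z)), tolerance = 1e-10)
  one <- anns[anns$sample_id == "S1", ]
  expect_warning(abundance_heatmap(one, scaling = "zscore"), "disabled")
  expect_error(abundance_heatmap(anns[0, ]), "no annotations")
})
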