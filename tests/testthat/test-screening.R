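lib <- curated_library()

test_that("diagnostic EICs light up only for the matching moiety", {
  hc <- lib$entries[["Haliclamine C"]]
  run <- simulate_mse_run(list(hc), 1, noise_free_spec(), "S1")
  thp <- extract_eic(run, 2, 98.0970, 10)
  expect_gt(max(thp$intensity), 0)
  rt_hot <- thp$rt[which.max(thp$intensity)]
  expect_lt(abs(rt_hot - apascreen:::compound_rt("Haliclamine C")), 0.2)
  # all signal concentrated at the compound's elution
  expect_equal(sum(thp$intensity[abs(thp$rt - rt_hot) > 0.5]), 0)
  pyr <- extract_eic(run, 2, 106.0657, 10)
  expect_equal(max(pyr$intensity), 0)
  # widening the window can only add intensity
  wide <- extract_eic(run, 2, 98.0970, 20)
  expect_true(all(wide$intensity >= thp$intensity))
  expect_error(extract_eic(run, 3, 98.0970, 10), "function")
  expect_error(extract_eic(run, 2, 98.0970, 0), "ppm_tol")
})

test_that("EIC peak detection finds isolated elution peaks", {
  p <- lib$entries[["Cyclostellettamine P"]] # rt ~11.4
  q <- lib$entries[["Cyclostellettamine Q"]] # rt ~6.1
  run <- simulate_mse_run(list(p, q), c(1, 1), noise_free_spec(), "S1")
  trace <- extract_eic(run, 2, 106.0657, 10)
  peaks <- detect_eic_peaks(trace)
  expect_equal(nrow(peaks), 2)
  expect_true(all(peaks$rt_lo <= peaks$rt_apex & peaks$rt_apex <= peaks$rt_hi))
  zero <- trace
  zero$intensity <- 0
  expect_equal(nrow(detect_eic_peaks(zero)), 0)
  one <- simulate_mse_run(list(p), 1, noise_free_spec(), "S1")
  pk1 <- detect_eic_peaks(extract_eic(one, 2, 106.0657, 10))
  expect_equal(nrow(pk1), 1)
  expect_lt(abs(pk1$rt_apex - apascreen:::compound_rt(p$name)), 0.15)
})

test_that("charge states verify through the isotope spacing", {
  pat <- simulate_isotope_pattern("C30H48N2", 2, 3)
  spectrum <- list(rt = 5, fn = 1, mz = pat$mz, intensity = pat$intensity)
  expect_true(charge_from_isotopes(spectrum, pat$mz[1], 2))
  expect_false(charge_from_isotopes(spectrum, pat$mz[1], 1))
  lone <- list(rt = 5, fn = 1, mz = 218.1909, intensity = 1)
  for (z in 1:3) expect_false(charge_from_isotopes(lone, 218.1909, z))
})

test_that("precursor search matches the library within tolerance only", {
  p <- lib$entries[["Cyclostellettamine P"]]
  rt_p <- apascreen:::compound_rt(p$name)
  run <- simulate_mse_run(list(p), 1, noise_free_spec(), "S1")
  hits <- find_precursors(run, rt_p + c(-0.3, 0.3), lib, 10)
  hit_p <- hits[hits$compound == "Cyclostellettamine P" &
                  hits$ion_label == "[M]2+", ]
  expect_gt(nrow(hit_p), 0)
  expect_equal(max(abs(hit_p$ppm_error)), 0, tolerance = 1e-6)
  expect_true(all(hit_p$isotope_confirmed))
  expect_true(any(hits$compound == "Cyclostellettamine P" &
                    abs(hits$mz_expected - 437.3896) < 1e-3))
  # a 20 ppm displacement must not match at 10 ppm
  run2 <- run
  run2$spectra <- lapply(run2$spectra, function(s) {
    s$mz <- s$mz * (1 + 20e-6)
    s
  })
  expect_equal(nrow(find_precursors(run2, rt_p + c(-0.3, 0.3), lib, 10)), 0)
})

test_that("fragment confirmation returns the predicted fragment subset", {
  hd <- lib$entries[["Haliclamine D"]]
  rt_d <- apascreen:::compound_rt(hd$name)
  run <- simulate_mse_run(list(hd), 1, noise_free_spec(), "S1")
  fr <- confirm_fragments(run, rt_d + c(-0.3, 0.3), hd, 10)
  expect_setequal(fr$formula[fr$role %in% c("F1", "F2")],
                  c("C15H28N", "C16H30N"))
  # absent compound: nothing to confirm
  hp <- lib$entries[["Cyclostellettamine P"]]
  fr0 <- confirm_fragments(run, rt_d + c(-0.3, 0.3), hp, 10)
  expect_equal(nrow(fr0[fr0$role %in% c("F1", "F2"), ]), 0)
  # Pyr compound: diagnostic 106.0657 and both onium fragments
  runp <- simulate_mse_run(list(hp), 1, noise_free_spec(), "S1")
  rt_p <- apascreen:::compound_rt(hp$name)
  frp <- confirm_fragments(runp, rt_p + c(-0.3, 0.3), hp, 10)
  expect_true(any(frp$role == "diagnostic" & abs(frp$mz - 106.0657) < 1e-3))
  expect_setequal(round(frp$mz[frp$role %in% c("F1", "F2")], 4),
                  c(204.1752, 232.2065))
})

test_that("a full synthetic run annotates all thirteen compounds", {
  run <- simulate_mse_run(lib$entries, rep(1, 13), cohort_spec(seed = 5),
                          "S1", seed = 5)
  ann <- annotate_run(run, lib)
  expect_setequal(unique(ann$compound), names(lib$entries))
  bg <- simulate_mse_run(list(), numeric(), cohort_spec(seed = 5), "B", 6)
  expect_equal(nrow(annotate_run(bg, lib)), 0)
})

test_that("haliclamine-only runs are reached via the THP trace, A also via Pyr", {
  hal <- lib$entries[grep("^Haliclamine", names(lib$entries))]
  run <- simulate_mse_run(hal, rep(1, length(hal)), noise_free_spec(), "S1")
  thp_peaks <- detect_eic_peaks(extract_eic(run, 2, 98.0970, 10))
  pyr_peaks <- detect_eic_peaks(extract_eic(run, 2, 106.0657, 10))
  expect_equal(nrow(thp_peaks), 5) # every haliclamine carries 98.0970
  expect_equal(nrow(pyr_peaks), 1) # only A carries pyridinium fragments
  expect_lt(abs(pyr_peaks$rt_apex - apascreen:::compound_rt("Haliclamine A")),
            0.15)
  ann <- annotate_run(run, lib)
  expect_setequal(unique(ann$compound), names(hal))
})

test_that("annotation equals the brute-force matcher on small runs", {
  cases <- list(
    lib$entries["Cyclostellettamine P"],
    lib$entries["Haliclamine C"],
    lib$entries[c("Cyclostellettamine Q", "Haliclamine D")]
  )
  for (cmp in cases) {
    run <- simulate_mse_run(cmp, rep(1, length(cmp)), noise_free_spec(), "S1")
    expect_lte(count_peaks(run), 200)
    oracle <- brute_force_compounds(run, lib, 10)
    ann <- annotate_run(run, lib)
    expect_setequal(unique(ann$compound), oracle)
  }
})

test_that("annotations grow monotonically with ppm tolerance", {
  run <- simulate_mse_run(lib$entries, rep(1, 13), cohort_spec(seed = 77),
                          "S1", seed = 77)
  sets <- lapply(c(4, 10, 20), function(tol)
    unique(annotate_run(run, lib, annotate_params(ppm_tol = tol))$compound))
  expect_true(all(sets[[1]] %in% sets[[2]]))
  expect_true(all(sets[[2]] %in% sets[[3]]))
})

test_that("scores follow the weighted evidence formula", {
  mk <- function(ppm, nd, nf, np, iso)
    data.frame(ppm_error = ppm, n_diagnostic = nd, n_fragments = nf,
               n_fragments_predicted = np, isotope_confirmed = iso)
  expect_equal(score_annotation(mk(0, 1, 2, 2, TRUE), ppm_tol = 10), 4)
  expect_equal(score_annotation(mk(10, 0, 0, 2, FALSE), ppm_tol = 10), 0)
  expect_equal(score_annotation(mk(5, 1, 2, 2, TRUE), ppm_tol = 10), 3.5)
  expect_error(score_annotation(mk(0, 1, 2, 2, TRUE), weights = c(-1, 1, 1, 1)),
               "weights")
  # jitter-free data reports zero ppm error
  p <- lib$entries["Cyclostellettamine P"]
  run <- simulate_mse_run(p, 1, noise_free_spec(), "S1")
  ann <- annotate_run(run, lib)
  expect_true(all(abs(ann$ppm_error) < 1e-6))
})
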