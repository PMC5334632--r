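# Shared fixtures and independent oracles. Everything is generated in code;
# no binary fixtures.

# noise-free cohort spec: no background, no jitter, no shot noise
noise_free_spec <- function(seed = 1L, ...) {
  cohort_spec(n_background_features = 0, mz_jitter_ppm_sd = 0,
              noise_peak_rate = 0, rt_jitter_sd = 0, seed = seed, ...)
}

# small cohort spec for fast multivariate tests
small_cohort_spec <- function(seed = 1L, ...) {
  cohort_spec(n_background_features = 300, seed = seed, ...)
}

all_run_peaks <- function(run, fn) {
  sp <- Filter(function(s) s$fn == fn, run$spectra)
  do.call(rbind, lapply(sp, function(s)
    if (length(s$mz)) data.frame(rt = s$rt, mz = s$mz, intensity = s$intensity)))
}

count_peaks <- function(run) {
  sum(vapply(run$spectra, function(s) length(s$mz), numeric(1)))
}

# Brute-force annotation oracle: tests every (function-1 peak, library
# precursor ion) pair; a compound is reported if a precursor matches and at
# least one diagnostic and one F1/F2 fragment of that compound are present
# in function 2 within +/- 0.3 min of the precursor peak.
brute_force_compounds <- function(run, lib, ppm_tol = 10, rt_win = 0.3) {
  p1 <- all_run_peaks(run, 1)
  p2 <- all_run_peaks(run, 2)
  if (is.null(p1) || is.null(p2)) return(character())
  idx <- lib$index[lib$index$kind == "precursor", ]
  found <- character()
  for (i in seq_len(nrow(p1))) {
    for (j in seq_len(nrow(idx))) {
      if (abs(p1$mz[i] - idx$mz[j]) > idx$mz[j] * ppm_tol * 1e-6) next
      cmp <- lib$entries[[idx$name[j]]]
      near <- p2[abs(p2$rt - p1$rt[i]) <= rt_win, , drop = FALSE]
      if (!nrow(near)) next
      match_frag <- function(mzs) {
        vapply(mzs, function(m)
          any(abs(near$mz - m) <= m * ppm_tol * 1e-6), logical(1))
      }
      fr <- cmp$fragments
      n_diag <- sum(match_frag(fr$mz[fr$role == "diagnostic"]))
      n_f <- sum(match_frag(fr$mz[fr$role %in% c("F1", "F2")]))
      if (n_diag >= 1 && n_f >= 1) found <- union(found, cmp$name)
    }
  }
  found
}

# Brute-force PCA oracle: covariance eigendecomposition.
brute_force_pca <- function(x) {
  xc <- sweep(x, 2, colMeans(x), "-")
  ev <- eigen(stats::cov(xc), symmetric = TRUE)
  scores <- xc %*% ev$vectors
  list(eigenvalues = ev$values, loadings = ev$vectors, scores = scores,
       fractions = ev$values / sum(ev$values))
}
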