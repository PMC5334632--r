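# MSE screening: diagnostic-fragment extracted ion chromatograms, precursor
# matching against the 3-APA library, fragment confirmation and scoring.
#
# The screening gate mirrors the published workflow: a compound is annotated
# at a retention-time peak of a moiety-diagnostic EIC only if a library
# precursor matches in the low-energy function AND at least one diagnostic
# AND at least one F1/F2 fragment are confirmed in the high-energy function
# (both requirements configurable).

#' Screening parameters
#'
#' @param ppm_tol Precursor/fragment match tolerance in ppm (the curated
#'   compounds' reported deviations reach 10 ppm).
#' @param eic_ppm_tol EIC extraction window in ppm.
#' @param min_intensity Minimum EIC apex intensity for peak detection.
#' @param min_prominence_fraction Minimum peak prominence as a fraction of
#'   the apex. The default 0.05 resolves coeluting homologs whose EIC
#'   valleys are shallow.
#' @param require_diagnostic Require >= 1 matched diagnostic fragment.
#' @param require_fragment Require >= 1 matched F1/F2 fragment.
#' @param use_printed Match literature-printed m/z instead of recomputed.
#' @param check_isotopes Verify the claimed charge by the isotope spacing.
#' @param iso_ratio_bounds Accepted intensity ratio (first isotope over
#'   monoisotopic) when confirming a charge state.
#' @param weights Score weights (ppm, diagnostic, fragment, isotope).
#' @return List of parameters for [annotate_run()].
#' @export
annotate_params <- function(ppm_tol = 10, eic_ppm_tol = 10,
                            min_intensity = 1000,
                            min_prominence_fraction = 0.05,
                            require_diagnostic = TRUE,
                            require_fragment = TRUE,
                            use_printed = FALSE,
                            check_isotopes = TRUE,
                            iso_ratio_bounds = c(0.01, 1.5),
                            weights = c(ppm = 1, diag = 1, frag = 1, iso = 1)) {
  list(ppm_tol = ppm_tol, eic_ppm_tol = eic_ppm_tol,
       min_intensity = min_intensity,
       min_prominence_fraction = min_prominence_fraction,
       require_diagnostic = require_diagnostic,
       require_fragment = require_fragment,
       use_printed = use_printed, check_isotopes = check_isotopes,
       iso_ratio_bounds = iso_ratio_bounds, weights = weights)
}

#' Extract an ion chromatogram
#'
#' Per retention-time point, the summed intensity of peaks within the ppm
#' window around the target m/z in the requested function.
#'
#' @param run An `mse_run`.
#' @param fn Acquisition function (1 low energy, 2 high energy).
#' @param target_mz Target m/z.
#' @param ppm_tol Window half-width in ppm (> 0).
#' @return An `eic_trace`: data frame (rt, intensity) with attributes
#'   `target_mz`, `ppm_tol`, `fn`.
#' @export
extract_eic <- function(run, fn, target_mz, ppm_tol) {
  if (ppm_tol <= 0) stop("ppm_tol must be > 0")
  if (!fn %in% run_functions(run))
    stop("function ", fn, " not present in run")
  tol <- ppm_to_da(target_mz, ppm_tol)
  sp <- Filter(function(s) s$fn == fn, run$spectra)
  rt <- vapply(sp, `[[`, numeric(1), "rt")
  o <- order(rt)
  sp <- sp[o]
  y <- vapply(sp, function(s) {
    if (!length(s$mz)) return(0)
    lo <- findInterval(target_mz - tol, s$mz)
    hi <- findInterval(target_mz + tol, s$mz)
    if (hi <= lo) 0 else sum(s$intensity[(lo + 1L):hi])
  }, numeric(1))
  trace <- data.frame(rt = rt[o], intensity = y)
  attr(trace, "target_mz") <- target_mz
  attr(trace, "ppm_tol") <- ppm_tol
  attr(trace, "fn") <- fn
  class(trace) <- c("eic_trace", "data.frame")
  trace
}

#' Detect peaks in an EIC trace
#'
#' Local maxima above `min_intensity` with prominence (apex minus the higher
#' of the two bounding minima) at least `min_prominence_fraction` of the
#' apex; integration bounds at the nearest flanking minima.
#'
#' @param trace An `eic_trace` (or data frame with rt, intensity).
#' @param min_intensity Minimum apex intensity.
#' @param min_prominence_fraction Minimum prominence as fraction of apex.
#' @return Data frame (rt_apex, intensity_apex, rt_lo, rt_hi).
#' @export
detect_eic_peaks <- function(trace, min_intensity = 1000,
                             min_prominence_fraction = 0.05) {
  if (min_intensity < 0 || min_prominence_fraction < 0)
    stop("thresholds must be >= 0")
  y <- trace$intensity
  rt <- trace$rt
  n <- length(y)
  empty <- data.frame(rt_apex = numeric(), intensity_apex = numeric(),
                      rt_lo = numeric(), rt_hi = numeric())
  if (n < 3) return(empty)
  is_max <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  out <- lapply(is_max, function(i) {
    if (y[i] < min_intensity) return(NULL)
    # bounds at the nearest flanking minima, clipped at zero intensity so a
    # baseline plateau does not extend the window to the next peak's foot
    l <- i
    while (l > 1 && y[l - 1] <= y[l] && y[l] > 0) l <- l - 1
    r <- i
    while (r < n && y[r + 1] <= y[r] && y[r] > 0) r <- r + 1
    prominence <- y[i] - max(y[l], y[r])
    if (prominence < min_prominence_fraction * y[i]) return(NULL)
    data.frame(rt_apex = rt[i], intensity_apex = y[i], rt_lo = rt[l],
               rt_hi = rt[r])
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty else out
}

#' Verify a charge state from the isotope spacing
#'
#' TRUE iff a peak exists at `mz + 1.003355 / claimed_charge` within the ppm
#' tolerance, its intensity relative to the monoisotopic peak lies within
#' `ratio_bounds`, and no peak sits at the tighter spacing of a higher
#' charge state (which would indicate the envelope belongs to a more highly
#' charged ion).
#'
#' @param spectrum One spectrum (list with mz, intensity).
#' @param mz Monoisotopic peak m/z.
#' @param claimed_charge Charge to verify (1, 2 or 3).
#' @param ppm_tol Tolerance in ppm.
#' @param ratio_bounds Accepted first-isotope / monoisotopic intensity ratio.
#' @return Logical.
#' @export
charge_from_isotopes <- function(spectrum, mz, claimed_charge, ppm_tol = 10,
                                 ratio_bounds = c(0.01, 1.5)) {
  if (!claimed_charge %in% 1:3) stop("claimed_charge must be 1, 2 or 3")
  if (!length(spectrum$mz)) return(FALSE)
  tol <- ppm_to_da(mz, ppm_tol)
  mono <- which(abs(spectrum$mz - mz) <= tol)
  if (!length(mono)) return(FALSE)
  mono <- mono[which.max(spectrum$intensity[mono])]
  target <- mz + C13_SPACING / claimed_charge
  iso <- which(abs(spectrum$mz - target) <= tol)
  if (!length(iso)) return(FALSE)
  ratio <- max(spectrum$intensity[iso]) / spectrum$intensity[mono]
  if (ratio < ratio_bounds[1] || ratio > ratio_bounds[2]) return(FALSE)
  for (z2 in seq_len(3)[-seq_len(claimed_charge)]) {
    tighter <- mz + C13_SPACING / z2
    if (any(abs(spectrum$mz - tighter) <= tol)) return(FALSE)
  }
  TRUE
}

#' Find library precursor matches in a retention-time window
#'
#' Every function-1 peak within the window is compared against all library
#' precursor ions; each match is reported with its signed ppm error and
#' isotope-based charge confirmation, sorted by absolute ppm error.
#'
#' @param run An `mse_run`.
#' @param rt_window Numeric length-2 window (min).
#' @param library A `mass_library`.
#' @param ppm_tol Match tolerance in ppm (> 0).
#' @param use_printed Match printed instead of recomputed m/z.
#' @param check_isotopes Verify charge states by isotope spacing.
#' @param iso_ratio_bounds See [charge_from_isotopes()].
#' @return Data frame of precursor hits.
#' @export
find_precursors <- function(run, rt_window, library, ppm_tol = 10,
                            use_printed = FALSE, check_isotopes = TRUE,
                            iso_ratio_bounds = c(0.01, 1.5)) {
  if (ppm_tol <= 0) stop("ppm_tol must be > 0")
  idx <- library$index[library$index$kind == "precursor", , drop = FALSE]
  ref <- if (use_printed) idx$mz_printed else idx$mz
  ok <- !is.na(ref)
  idx <- idx[ok, , drop = FALSE]
  ref <- ref[ok]
  sp <- Filter(function(s) s$fn == 1 & s$rt >= rt_window[1] &
                 s$rt <= rt_window[2], run$spectra)
  hits <- list()
  for (s in sp) {
    if (!length(s$mz)) next
    tol <- ppm_to_da(ref, ppm_tol)
    lo <- findInterval(ref - tol, s$mz)
    hi <- findInterval(ref + tol, s$mz)
    matched <- which(hi > lo)
    for (j in matched) {
      pk <- (lo[j] + 1L):hi[j]
      best <- pk[which.max(s$intensity[pk])]
      iso_ok <- if (check_isotopes)
        charge_from_isotopes(s, s$mz[best], idx$charge[j], ppm_tol,
                             iso_ratio_bounds) else NA
      hits[[length(hits) + 1L]] <- data.frame(
        compound = idx$name[j], ion_label = idx$label[j],
        charge = idx$charge[j], mz_expected = ref[j],
        observed_mz = s$mz[best], rt = s$rt,
        intensity = s$intensity[best],
        ppm_error = ppm_deviation(s$mz[best], ref[j]),
        isotope_confirmed = iso_ok, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, hits)
  if (is.null(out))
    out <- data.frame(compound = character(), ion_label = character(),
                      charge = integer(), mz_expected = numeric(),
                      observed_mz = numeric(), rt = numeric(),
                      intensity = numeric(), ppm_error = numeric(),
                      isotope_confirmed = logical(),
                      stringsAsFactors = FALSE)
  out[order(abs(out$ppm_error)), , drop = FALSE]
}

#' Confirm predicted fragments of a compound in the high-energy function
#'
#' Searches function 2 within the retention-time window for the compound's
#' diagnostic and F1/F2 fragment ions.
#'
#' @param run An `mse_run`.
#' @param rt_window Numeric length-2 window (min).
#' @param compound An `apa_compound`.
#' @param ppm_tol Tolerance in ppm.
#' @param use_printed Match printed instead of recomputed m/z.
#' @return The matched subset of the compound's fragment table, with
#'   observed m/z, ppm error and intensity.
#' @export
confirm_fragments <- function(run, rt_window, compound, ppm_tol = 10,
                              use_printed = FALSE) {
  fr <- compound$fragments
  ref <- if (use_printed) ifelse(is.na(fr$mz_printed), fr$mz, fr$mz_printed)
  else fr$mz
  sp <- Filter(function(s) s$fn == 2 & s$rt >= rt_window[1] &
                 s$rt <= rt_window[2], run$spectra)
  best_obs <- rep(NA_real_, nrow(fr))
  best_int <- rep(-Inf, nrow(fr))
  for (s in sp) {
    if (!length(s$mz)) next
    tol <- ppm_to_da(ref, ppm_tol)
    lo <- findInterval(ref - tol, s$mz)
    hi <- findInterval(ref + tol, s$mz)
    matched <- which(hi > lo)
    for (j in matched) {
      pk <- (lo[j] + 1L):hi[j]
      b <- pk[which.max(s$intensity[pk])]
      if (s$intensity[b] > best_int[j]) {
        best_int[j] <- s$intensity[b]
        best_obs[j] <- s$mz[b]
      }
    }
  }
  found <- which(!is.na(best_obs))
  out <- fr[found, , drop = FALSE]
  out$observed_mz <- best_obs[found]
  out$intensity <- best_int[found]
  out$ppm_error <- ppm_deviation(best_obs[found], ref[found])
  rownames(out) <- NULL
  out
}

#' Score an annotation
#'
#' `score = w_ppm * (1 - |ppm_error| / tol) + w_diag * n_diagnostic +
#' w_frag * n_fragments / n_fragments_predicted + w_iso * isotope_confirmed`.
#' A perfect noise-free match with default weights scores 4.
#'
#' @param annotations Data frame with columns ppm_error, n_diagnostic,
#'   n_fragments, n_fragments_predicted, isotope_confirmed (as produced by
#'   [annotate_run()]).
#' @param weights Non-negative weights (ppm, diag, frag, iso).
#' @param ppm_tol The tolerance the ppm term is scaled by.
#' @return Numeric score vector.
#' @export
score_annotation <- function(annotations,
                             weights = c(ppm = 1, diag = 1, frag = 1, iso = 1),
                             ppm_tol = 10) {
  if (any(weights < 0)) stop("weights must be >= 0")
  frag_frac <- ifelse(annotations$n_fragments_predicted > 0,
                      annotations$n_fragments / annotations$n_fragments_predicted,
                      0)
  unname(weights[1] * pmax(0, 1 - abs(annotations$ppm_error) / ppm_tol) +
           weights[2] * annotations$n_diagnostic +
           weights[3] * frag_frac +
           weights[4] * as.numeric(annotations$isotope_confirmed %in% TRUE))
}

#' Annotate one MSE run against a 3-APA library
#'
#' Pipeline: extract the two moiety-diagnostic EICs in the high-energy
#' function, detect their retention-time peaks, search function 1 within
#' each peak's bounds for library precursor ions, confirm diagnostic and
#' F1/F2 fragments in function 2, apply the acceptance rule and score. One
#' annotation per (compound, retention-time peak); when several library
#' entries match one peak all are kept, ranked by score then ppm error.
#'
#' @param run An `mse_run`.
#' @param library A `mass_library`.
#' @param params See [annotate_params()].
#' @return Data frame of annotations (possibly zero rows), sorted by score.
#' @export
annotate_run <- function(run, library, params = annotate_params()) {
  diag <- diagnostic_fragments()
  cand <- list()
  for (d in seq_len(nrow(diag))) {
    trace <- extract_eic(run, 2, diag$mz[d], params$eic_ppm_tol)
    peaks <- detect_eic_peaks(trace, params$min_intensity,
                              params$min_prominence_fraction)
    for (p in seq_len(nrow(peaks))) {
      window <- c(peaks$rt_lo[p], peaks$rt_hi[p])
      hits <- find_precursors(run, window, library, params$ppm_tol,
                              params$use_printed, params$check_isotopes,
                              params$iso_ratio_bounds)
      if (!nrow(hits)) next
      for (cname in unique(hits$compound)) {
        cmp <- library$entries[[cname]]
        fr <- confirm_fragments(run, window, cmp, params$ppm_tol,
                                params$use_printed)
        n_diag <- sum(fr$role == "diagnostic")
        n_frag <- sum(fr$role %in% c("F1", "F2"))
        n_pred <- sum(cmp$fragments$role %in% c("F1", "F2"))
        if (params$require_diagnostic && n_diag < 1) next
        if (params$require_fragment && n_frag < 1 && n_pred > 0) next
        h <- hits[hits$compound == cname, , drop = FALSE]
        # report the apex hit (most intense matched peak of the compound)
        best <- h[which.max(h$intensity), , drop = FALSE]
        cand[[length(cand) + 1L]] <- data.frame(
          sample_id = run$sample_id, compound = cname,
          rt = peaks$rt_apex[p], ion_label = best$ion_label,
          charge = best$charge, observed_mz = best$observed_mz,
          intensity = best$intensity, ppm_error = best$ppm_error,
          n_diagnostic = n_diag, n_fragments = n_frag,
          n_fragments_predicted = n_pred,
          isotope_confirmed = best$isotope_confirmed %in% TRUE,
          stringsAsFactors = FALSE)
      }
    }
  }
  empty <- data.frame(sample_id = character(), compound = character(),
                      rt = numeric(), ion_label = character(),
                      charge = integer(), observed_mz = numeric(),
                      intensity = numeric(), ppm_error = numeric(),
                      n_diagnostic = integer(), n_fragments = integer(),
                      n_fragments_predicted = integer(),
                      isotope_confirmed = logical(), score = numeric(),
                      stringsAsFactors = FALSE)
  if (!length(cand)) return(empty)
  ann <- do.call(rbind, cand)
  ann$score <- score_annotation(ann, params$weights, params$ppm_tol)
  ann <- ann[order(-ann$score, abs(ann$ppm_error)), , drop = FALSE]
  # deduplicate co-located detections of the same compound found through
  # both diagnostic traces
  keep <- rep(TRUE, nrow(ann))
  for (i in seq_len(nrow(ann))) {
    if (!keep[i]) next
    dup <- which(keep & seq_len(nrow(ann)) > i &
                   ann$compound == ann$compound[i] &
                   abs(ann$rt - ann$rt[i]) < 0.3)
    keep[dup] <- FALSE
  }
  ann <- ann[keep, , drop = FALSE]
  rownames(ann) <- NULL
  ann
}
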