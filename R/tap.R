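# Pseudo-MS3 by time-aligned parallel (TAP) fragmentation: primary fragments
# separated by ion-mobility drift time, secondary spectra keyed by drift
# bin. Resolves coeluting isobaric species (e.g. the two gas-phase forms of
# a doubly charged macrocycle at m/z 218.19) and classifies them by their
# secondary fragmentation.

#' Drift-time profile (driftogram) of an m/z window
#'
#' @param tap A `tap_run`.
#' @param mz Target m/z.
#' @param mz_tol_da Window half-width in Da (> 0).
#' @return Data frame (drift_time, intensity) over the run's drift grid.
#' @export
driftogram <- function(tap, mz, mz_tol_da) {
  if (mz_tol_da <= 0) stop("mz_tol_da must be > 0")
  p <- tap$primary
  sel <- abs(p$mz - mz) <= mz_tol_da
  grid <- seq(0, max(p$drift_time), by = tap$drift_step %||% 0.1)
  y <- numeric(length(grid))
  if (any(sel)) {
    idx <- round(p$drift_time[sel] / (tap$drift_step %||% 0.1)) + 1L
    for (i in seq_along(idx))
      y[idx[i]] <- y[idx[i]] + p$intensity[sel][i]
  }
  data.frame(drift_time = grid, intensity = y)
}

#' Detect peaks in a driftogram
#'
#' Local maxima above `min_intensity`, at least `min_separation_ms` apart
#' (the stronger apex wins within the separation window); bounds at the
#' nearest flanking minima.
#'
#' @param trace Data frame (drift_time, intensity) from [driftogram()].
#' @param min_intensity Minimum apex intensity.
#' @param min_separation_ms Minimum apex separation in ms.
#' @return Data frame (drift_apex, intensity, drift_lo, drift_hi).
#' @export
detect_drift_peaks <- function(trace, min_intensity = 1000,
                               min_separation_ms = 0.5) {
  if (min_intensity < 0 || min_separation_ms < 0)
    stop("thresholds must be >= 0")
  y <- trace$intensity
  x <- trace$drift_time
  n <- length(y)
  empty <- data.frame(drift_apex = numeric(), intensity = numeric(),
                      drift_lo = numeric(), drift_hi = numeric())
  if (n < 3) return(empty)
  cand <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  cand <- cand[y[cand] >= min_intensity]
  if (!length(cand)) return(empty)
  cand <- cand[order(-y[cand])]
  kept <- integer()
  for (i in cand)
    if (!length(kept) || all(abs(x[i] - x[kept]) >= min_separation_ms))
      kept <- c(kept, i)
  kept <- sort(kept)
  out <- lapply(kept, function(i) {
    l <- i
    while (l > 1 && y[l - 1] <= y[l] && y[l - 1] > 0) l <- l - 1
    r <- i
    while (r < n && y[r + 1] <= y[r] && y[r + 1] > 0) r <- r + 1
    data.frame(drift_apex = x[i], intensity = y[i], drift_lo = x[l],
               drift_hi = x[r])
  })
  do.call(rbind, out)
}

#' Assemble the pseudo-MS3 spectrum of a drift peak
#'
#' Union of all secondary spectra whose drift bins fall within the parent
#' peak's drift bounds, intensity-summed per m/z within a 0.01 Da merge
#' width.
#'
#' @param tap A `tap_run`.
#' @param parent One row of [detect_drift_peaks()] output (needs `drift_lo`,
#'   `drift_hi`).
#' @param merge_width_da m/z merge width in Da.
#' @return Data frame (mz, intensity) sorted by m/z (possibly empty).
#' @export
associate_secondary <- function(tap, parent, merge_width_da = 0.01) {
  sel <- Filter(function(s) s$drift_time >= parent$drift_lo &
                  s$drift_time <= parent$drift_hi, tap$secondary)
  if (!length(sel))
    return(data.frame(mz = numeric(), intensity = numeric()))
  all <- do.call(rbind, lapply(sel, `[[`, "peaks"))
  all <- all[order(all$mz), , drop = FALSE]
  grp <- cumsum(c(TRUE, diff(all$mz) > merge_width_da))
  data.frame(
    mz = as.numeric(tapply(all$mz * all$intensity, grp, sum) /
                      tapply(all$intensity, grp, sum)),
    intensity = as.numeric(tapply(all$intensity, grp, sum))
  )
}

#' Resolve coeluting isobars at an m/z by drift time
#'
#' Builds the driftogram, detects drift peaks, assembles each peak's
#' pseudo-MS3 spectrum, and classifies each isobar:
#' * `"ring-opened"` if the spectrum contains the macrocycle-opening
#'   neutral-loss signature, a fragment at `2 * mz + m(H) - m(C2H6N)`
#'   (loss of the C2H6N iminium from the singly charged species);
#' * `"compact/onium"` if it contains both onium fragment m/z of the best
#'   library precursor match;
#' * `"unclassified"` otherwise.
#'
#' @param tap A `tap_run`.
#' @param mz Target m/z (e.g. 218.19).
#' @param mz_tol_da Driftogram window half-width in Da.
#' @param params List: `min_intensity`, `min_separation_ms`,
#'   `class_tol_da` (signature match window, default 0.02),
#'   `min_rel_intensity` (a signature peak must reach this fraction of the
#'   spectrum's base peak, default 0.05, so tails of neighbouring drift
#'   populations leaking into a window's edge bins do not classify),
#'   `library` (defaults to [curated_library()]), `library_ppm` (precursor
#'   match tolerance against the library, default 200 ppm to absorb
#'   two-decimal reporting of TAP m/z values).
#' @return List with one element per drift peak: `drift_peak` (one-row data
#'   frame), `spectrum` (pseudo-MS3 spectrum), `classification` (string).
#' @export
resolve_isobars <- function(tap, mz, mz_tol_da = 0.05, params = list()) {
  min_int <- params$min_intensity %||% 1000
  min_sep <- params$min_separation_ms %||% 0.5
  class_tol <- params$class_tol_da %||% 0.02
  min_rel <- params$min_rel_intensity %||% 0.05
  lib <- params$library %||% curated_library()
  lib_ppm <- params$library_ppm %||% 200
  trace <- driftogram(tap, mz, mz_tol_da)
  peaks <- detect_drift_peaks(trace, min_int, min_sep)
  ring_target <- 2 * mz + element_masses()[["H"]] -
    monoisotopic_mass(parse_formula("C2H6N"))
  match <- library_match(lib, mz, lib_ppm, kind = "precursor")
  onium <- numeric()
  if (nrow(match)) {
    cmp <- lib$entries[[match$name[1]]]
    onium <- cmp$fragments$mz[cmp$fragments$role %in% c("F1", "F2")]
  }
  lapply(seq_len(nrow(peaks)), function(i) {
    spec <- associate_secondary(tap, peaks[i, ])
    floor_int <- if (nrow(spec)) min_rel * max(spec$intensity) else 0
    has <- function(target, tol)
      any(abs(spec$mz - target) <= tol & spec$intensity >= floor_int)
    classification <- if (nrow(spec) && has(ring_target, class_tol)) {
      "ring-opened"
    } else if (length(onium) >= 2 && nrow(spec) &&
                 all(vapply(onium, has, logical(1), tol = class_tol))) {
      "compact/onium"
    } else {
      "unclassified"
    }
    list(drift_peak = peaks[i, ], spectrum = spec,
         classification = classification)
  })
}
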