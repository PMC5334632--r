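# Cross-run feature table construction: greedy m/z / retention-time binning
# of low-energy (function 1) centroids with a simple isotope-position
# deisotoping rule. This intentionally replaces vendor feature detection
# with a transparent, testable rule.

#' Build a samples x features intensity table from MSE runs
#'
#' Function-1 peaks are clustered greedily across runs: peaks are sorted by
#' m/z and split where the gap exceeds the ppm window, then split again
#' along retention time where the gap exceeds `rt_bin`. Peaks sitting at an
#' isotope position (m/z - k * 1.003355 / z, z in 1..3, k >= 1) of a
#' stronger co-eluting peak are removed first when `deisotope` is TRUE.
#' Features are ordered by median intensity (descending).
#'
#' Features detected in fewer than `min_samples` samples are discarded,
#' mirroring the reproducible-occurrence requirement of real feature
#' detection (transient one-sample spikes are not features).
#'
#' @param runs List of `mse_run` objects.
#' @param mz_bin_ppm m/z clustering window in ppm.
#' @param rt_bin Retention-time clustering window in minutes.
#' @param deisotope Remove isotope peaks before clustering.
#' @param min_samples Minimum number of samples a feature must occur in;
#'   default 2 for multi-run inputs, 1 for a single run.
#' @return A `feature_table`: list with `features` (feature_id, mz, rt) and
#'   `matrix` (samples x features, intensity-summed).
#' @export
build_feature_table <- function(runs, mz_bin_ppm = 15, rt_bin = 0.4,
                                deisotope = TRUE, min_samples = NULL) {
  if (!length(runs)) stop("at least one run is required")
  if (mz_bin_ppm <= 0 || rt_bin <= 0) stop("bins must be positive")
  sample_ids <- vapply(runs, `[[`, character(1), "sample_id")
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids across runs")
  pooled <- do.call(rbind, lapply(runs, function(run) {
    p <- if (deisotope) deisotope_run_peaks(run, mz_bin_ppm) else
      run_peaks(run, 1)
    if (nrow(p)) p$sample_id <- run$sample_id
    p
  }))
  if (!nrow(pooled)) stop("runs contain no function-1 peaks")
  o <- order(pooled$mz)
  pooled <- pooled[o, , drop = FALSE]
  gap <- diff(pooled$mz) > ppm_to_da(pooled$mz[-nrow(pooled)], mz_bin_ppm)
  mz_cluster <- cumsum(c(TRUE, gap))
  # split each m/z cluster along rt
  feat_id <- integer(nrow(pooled))
  nf <- 0L
  for (rows in split(seq_len(nrow(pooled)), mz_cluster)) {
    ro <- rows[order(pooled$rt[rows])]
    rgap <- diff(pooled$rt[ro]) > rt_bin
    sub <- cumsum(c(TRUE, rgap))
    feat_id[ro] <- nf + sub
    nf <- nf + max(sub)
  }
  wsum <- function(v) tapply(v * pooled$intensity, feat_id, sum) /
    tapply(pooled$intensity, feat_id, sum)
  f_mz <- wsum(pooled$mz)
  f_rt <- wsum(pooled$rt)
  mat <- matrix(0, nrow = length(runs), ncol = nf,
                dimnames = list(sample_ids, NULL))
  agg <- tapply(pooled$intensity,
                list(factor(pooled$sample_id, levels = sample_ids),
                     factor(feat_id, levels = seq_len(nf))), sum)
  agg[is.na(agg)] <- 0
  mat[, ] <- agg
  min_samples <- min_samples %||% (if (length(runs) > 1) 2L else 1L)
  present <- colSums(mat > 0) >= min_samples
  mat <- mat[, present, drop = FALSE]
  f_mz <- f_mz[present]
  f_rt <- f_rt[present]
  nf <- sum(present)
  if (!nf) stop("no feature occurs in at least ", min_samples, " samples")
  med <- apply(mat, 2, stats::median)
  o2 <- order(med, decreasing = TRUE)
  ids <- sprintf("F%05d", seq_len(nf))
  features <- data.frame(feature_id = ids, mz = as.numeric(f_mz[o2]),
                         rt = as.numeric(f_rt[o2]), stringsAsFactors = FALSE)
  mat <- mat[, o2, drop = FALSE]
  colnames(mat) <- ids
  out <- list(features = features, matrix = mat, sample_ids = sample_ids)
  class(out) <- "feature_table"
  out
}

# Remove function-1 peaks lying at an isotope position of a stronger peak in
# the same spectrum (co-eluting by construction of the centroid grid).
deisotope_run_peaks <- function(run, ppm_tol) {
  sp <- Filter(function(s) s$fn == 1, run$spectra)
  shifts <- as.vector(outer(1:2, 1:3, function(k, z) k * C13_SPACING / z))
  parts <- lapply(sp, function(s) {
    n <- length(s$mz)
    if (!n) return(NULL)
    ns <- length(shifts)
    # candidate monoisotopic positions for every (peak, shift) pair; the
    # spectrum is sorted, so the nearest peaks bracket each target
    tv <- rep(s$mz, times = ns) - rep(shifts, each = n)
    tol <- rep(ppm_to_da(s$mz, ppm_tol), times = ns)
    own_int <- rep(s$intensity, times = ns)
    pos <- findInterval(tv, s$mz)
    lo <- pmax(pos, 1L)
    hi <- pmin(pos + 1L, n)
    hit <- (pos >= 1L & abs(s$mz[lo] - tv) <= tol &
              s$intensity[lo] > own_int) |
      (abs(s$mz[hi] - tv) <= tol & s$intensity[hi] > own_int)
    keep <- rowSums(matrix(hit, nrow = n, ncol = ns)) == 0
    if (!any(keep)) return(NULL)
    data.frame(rt = s$rt, mz = s$mz[keep], intensity = s$intensity[keep])
  })
  out <- do.call(rbind, parts)
  if (is.null(out))
    out <- data.frame(rt = numeric(), mz = numeric(), intensity = numeric())
  out
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d samples x %d features\n",
              nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}
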