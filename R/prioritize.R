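# Bioactivity-aligned prioritization: viability calls, feature-table
# normalization (sum -> log10 -> unit variance), PCA via singular value
# decomposition, k-means candidate-cluster selection gated on the active
# fraction, library matching of the driving features, and the per-compound
# abundance matrix behind the heat map.

#' Call cytotoxic activity from viability
#'
#' An extract is active when it reduced cell viability by more than the
#' threshold, i.e. viability strictly below `threshold_percent`. Note the
#' reported cytotoxic set includes one extract at 51% viability; the strict
#' rule is kept and the threshold left configurable.
#'
#' @param bioactivity Data frame with `sample_id` and `viability_percent`.
#' @param threshold_percent Viability threshold (default 50).
#' @return The input with `active` (logical) and `threshold_used` appended.
#' @export
call_activity <- function(bioactivity, threshold_percent = 50) {
  if (any(bioactivity$viability_percent < 0, na.rm = TRUE) ||
      any(is.na(bioactivity$viability_percent)))
    stop("viability must be present and >= 0")
  bioactivity$active <- bioactivity$viability_percent < threshold_percent
  bioactivity$threshold_used <- threshold_percent
  bioactivity
}

#' Percent viability from assay absorbances
#'
#' Replicate absorbances are averaged before the ratio to the solvent
#' control.
#'
#' @param absorbance_sample Numeric absorbance(s) of the treated wells.
#' @param absorbance_control Numeric absorbance(s) of control wells.
#' @return Viability as percent of control.
#' @export
compute_viability <- function(absorbance_sample, absorbance_control) {
  ctrl <- mean(absorbance_control)
  if (!is.finite(ctrl) || ctrl <= 0) stop("control absorbance must be > 0")
  100 * mean(absorbance_sample) / ctrl
}

#' Normalize a feature table for multivariate analysis
#'
#' Three steps: (1) each sample is divided by its total intensity; (2) zeros
#' are replaced by half the smallest positive normalized value, then log10;
#' (3) each feature is centered and scaled to unit variance. Features with
#' zero variance are dropped with a warning.
#'
#' @param ft A `feature_table` (or a samples x features matrix).
#' @return Normalized samples x features matrix; dropped feature ids in
#'   `attr(, "dropped_features")`.
#' @export
normalize_table <- function(ft) {
  x <- if (inherits(ft, "feature_table")) ft$matrix else as.matrix(ft)
  if (any(x < 0)) stop("intensities must be >= 0")
  rs <- rowSums(x)
  if (any(rs == 0))
    stop("all-zero sample(s): ",
         paste(rownames(x)[rs == 0], collapse = ", "))
  x <- x / rs
  minpos <- min(x[x > 0])
  x[x == 0] <- minpos / 2
  x <- log10(x)
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  drop <- sdv == 0
  dropped <- colnames(x)[drop]
  if (any(drop))
    warning(sum(drop), " constant feature(s) dropped: ",
            paste(utils::head(dropped, 5), collapse = ", "))
  x <- sweep(x[, !drop, drop = FALSE], 2, mu[!drop], "-")
  x <- sweep(x, 2, sdv[!drop], "/")
  attr(x, "dropped_features") <- dropped
  x
}

#' Principal component analysis by singular value decomposition
#'
#' Columns are centered; explained variance fractions are squared singular
#' values over their total (summing to 1 over all `min(n - 1, p)` informative
#' components). Sign convention: each loading vector's largest-magnitude
#' entry is positive.
#'
#' @param x Normalized samples x features matrix.
#' @param n_components Number of components to keep (default all
#'   informative ones).
#' @return An `apa_pca`: list with `scores` (samples x k), `loadings`
#'   (features x k, orthonormal columns) and `explained_variance_fraction`.
#' @export
pca <- function(x, n_components = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2) stop("PCA requires at least 2 samples")
  k_max <- min(n - 1L, ncol(x))
  k <- as.integer(n_components %||% k_max)
  if (k < 1 || k > k_max)
    stop("n_components must be in 1..", k_max)
  xc <- sweep(x, 2, colMeans(x), "-")
  sv <- svd(xc)
  expl <- sv$d^2 / sum(sv$d^2)
  u <- sv$u[, seq_len(k), drop = FALSE]
  v <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) {
      v[, j] <- -v[, j]
      u[, j] <- -u[, j]
    }
  }
  scores <- u %*% diag(sv$d[seq_len(k)], nrow = k)
  rownames(scores) <- rownames(x)
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(v) <- colnames(x)
  colnames(v) <- paste0("PC", seq_len(k))
  out <- list(scores = scores, loadings = v,
              explained_variance_fraction = expl[seq_len(k)],
              explained_all = expl, d = sv$d)
  class(out) <- "apa_pca"
  out
}

#' @export
print.apa_pca <- function(x, ...) {
  cat(sprintf("<apa_pca> %d samples, %d components; PC1 %.1f%%, PC2 %.1f%%\n",
              nrow(x$scores), ncol(x$scores),
              100 * x$explained_variance_fraction[1],
              if (length(x$explained_variance_fraction) > 1)
                100 * x$explained_variance_fraction[2] else NA))
  invisible(x)
}

#' Select a bioactivity-aligned candidate cluster from PCA scores
#'
#' k-means with k = 2 (20 restarts, seeded) on the first two score
#' dimensions. The smaller cluster becomes the candidate set only if its
#' active fraction exceeds the other cluster's AND reaches
#' `min_active_fraction`; otherwise the candidate set is empty. The gate
#' keeps chance splits of signal-free cohorts (where actives scatter among
#' inactives) from producing candidates. Separating components are those
#' whose share of the between-cluster variance (over the two dimensions
#' used) reaches `min_share`.
#'
#' @param pca_result An `apa_pca`.
#' @param activity Output of [call_activity()] covering all samples.
#' @param params List: `min_share` (default 0.5), `min_active_fraction`
#'   (default 0.8), `kmeans_restarts` (20), `kmeans_seed` (17).
#' @return List: `candidates` (sample ids, possibly empty), `components`
#'   (separating component indices), `cluster` (assignments),
#'   `active_fraction` (per cluster).
#' @export
prioritize_cluster <- function(pca_result, activity, params = list()) {
  min_share <- params$min_share %||% 0.5
  min_active <- params$min_active_fraction %||% 0.8
  restarts <- params$kmeans_restarts %||% 20
  km_seed <- params$kmeans_seed %||% 17
  scores <- pca_result$scores[, seq_len(min(2, ncol(pca_result$scores))),
                              drop = FALSE]
  ids <- rownames(scores)
  if (!setequal(ids, activity$sample_id))
    stop("activity calls must cover exactly the scored samples")
  act <- activity$active[match(ids, activity$sample_id)]
  km <- withr::with_seed(derive_seed(km_seed, "kmeans"),
                         stats::kmeans(scores, centers = 2,
                                       nstart = restarts))
  sizes <- tabulate(km$cluster, 2)
  frac <- vapply(1:2, function(k) mean(act[km$cluster == k]), numeric(1))
  small <- if (sizes[1] != sizes[2]) which.min(sizes) else which.max(frac)
  other <- 3L - small
  candidates <- if (isTRUE(frac[small] > frac[other]) &&
                      isTRUE(frac[small] >= min_active))
    ids[km$cluster == small] else character()
  # between-cluster variance share per score dimension
  comp <- integer()
  if (length(candidates)) {
    b <- vapply(seq_len(ncol(scores)), function(j) {
      m <- mean(scores[, j])
      sum(vapply(1:2, function(k)
        sizes[k] * (mean(scores[km$cluster == k, j]) - m)^2, numeric(1)))
    }, numeric(1))
    share <- b / sum(b)
    comp <- which(share >= min_share)
    if (!length(comp)) comp <- which.max(share)
  }
  list(candidates = candidates, components = comp, cluster = km$cluster,
       active_fraction = frac)
}

#' Rank and identify the features driving a candidate cluster
#'
#' Features are ranked by loading magnitude on the separating components;
#' the top `top_k` are matched against the library's precursor ions.
#'
#' @param pca_result An `apa_pca`.
#' @param features Feature metadata (`feature_id`, `mz`, `rt`), e.g.
#'   `ft$features`.
#' @param library A `mass_library`.
#' @param components Separating component indices (from
#'   [prioritize_cluster()]).
#' @param ppm_tol Library match tolerance in ppm.
#' @param top_k Number of features to keep.
#' @return Data frame in descending loading magnitude with the best library
#'   match per feature (`compound`, `ion_label`, `match_ppm`; NA when
#'   unmatched) and `n_matches`.
#' @export
prioritize_features <- function(pca_result, features, library,
                                components = 1L, ppm_tol = 10, top_k = 50) {
  ld <- pca_result$loadings[, components, drop = FALSE]
  mag <- sqrt(rowSums(ld^2))
  o <- order(-mag)
  keep <- utils::head(o, top_k)
  fid <- rownames(pca_result$loadings)[keep]
  fm <- features[match(fid, features$feature_id), , drop = FALSE]
  res <- data.frame(feature_id = fid, mz = fm$mz, rt = fm$rt,
                    loading = mag[keep],
                    compound = NA_character_, ion_label = NA_character_,
                    match_ppm = NA_real_, n_matches = 0L,
                    stringsAsFactors = FALSE)
  if (ppm_tol > 0) {
    for (i in seq_len(nrow(res))) {
      m <- library_match(library, res$mz[i], ppm_tol, kind = "precursor")
      if (nrow(m)) {
        res$compound[i] <- m$name[1]
        res$ion_label[i] <- m$label[1]
        res$match_ppm[i] <- m$ppm_error[1]
        res$n_matches[i] <- nrow(m)
      }
    }
  }
  rownames(res) <- NULL
  res
}

#' Per-compound abundance matrix across samples (heat-map table)
#'
#' Takes the apex (maximum) precursor-hit intensity of each annotated
#' compound per sample, so a compound detected at several overlapping
#' chromatographic windows is not double-counted. Optional per-compound
#' z-scoring (disabled with a warning when only one sample is annotated).
#'
#' @param annotations Row-bound [annotate_run()] outputs across samples.
#' @param scaling `"raw"` or `"zscore"`.
#' @return Compounds x samples matrix with attribute `scaling`.
#' @export
abundance_heatmap <- function(annotations, scaling = c("raw", "zscore")) {
  scaling <- match.arg(scaling)
  if (!nrow(annotations)) stop("no annotations to tabulate")
  m <- tapply(annotations$intensity,
              list(annotations$compound, annotations$sample_id), max)
  m[is.na(m)] <- 0
  m <- m[rowSums(m) > 0, , drop = FALSE]
  if (scaling == "zscore") {
    if (ncol(m) < 2) {
      warning("z-scoring disabled: need at least 2 annotated samples")
      scaling <- "raw"
    } else {
      sdv <- apply(m, 1, stats::sd)
      mu <- rowMeans(m)
      m <- (m - mu) / ifelse(sdv > 0, sdv, 1)
    }
  }
  attr(m, "scaling") <- scaling
  m
}
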