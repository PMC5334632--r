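# Synthetic two-function MSE cohorts, TAP drift-time datasets and
# bioactivity tables. Every simulator is a pure function of (spec, seed):
# identical inputs give byte-identical serialized output.

#' Specification of a synthetic sponge cohort
#'
#' Defaults emulate the study conditions of the screen the package
#' implements: 28 specimens of which 3 carry the thirteen curated 3-APA
#' compounds, roughly 2100 shared log-normal background features, 3 ppm mass
#' jitter, a 21-minute gradient, and an acquired mass range of 50-1200.
#'
#' @param n_samples Number of specimens.
#' @param apa_sample_ids Sample ids carrying 3-APA compounds.
#' @param abundance_profiles Compounds x APA-samples matrix of relative
#'   abundances; defaults to [default_abundance_profiles()].
#' @param n_background_features Shared background features per run.
#' @param background_meanlog,background_sdlog Log-normal parameters of the
#'   shared background feature intensities.
#' @param sample_noise_sd SD of per-sample multiplicative (log-scale)
#'   intensity noise on background features.
#' @param mz_jitter_ppm_sd Gaussian m/z jitter in ppm applied per peak.
#' @param rt_jitter_sd Per-sample retention-time jitter SD in minutes.
#' @param noise_peak_rate Expected random shot-noise peaks per spectrum.
#' @param base_intensity Monoisotopic intensity of a compound's main ion at
#'   relative abundance 1.
#' @param run_length_min Gradient length in minutes.
#' @param rt_step_min Retention-time grid step in minutes.
#' @param mass_range Acquired m/z range.
#' @param seed Integer seed; all randomness derives from it.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_samples = 28L,
                        apa_sample_ids = c("S1", "S5", "S8"),
                        abundance_profiles = default_abundance_profiles(),
                        n_background_features = 2100L,
                        background_meanlog = 10,
                        background_sdlog = 1,
                        sample_noise_sd = 0.2,
                        mz_jitter_ppm_sd = 3,
                        rt_jitter_sd = 0.02,
                        noise_peak_rate = 2,
                        base_intensity = 1e6,
                        run_length_min = 21,
                        rt_step_min = 0.1,
                        mass_range = c(50, 1200),
                        seed = 1L) {
  stopifnot(n_samples >= 1, n_background_features >= 0,
            mz_jitter_ppm_sd >= 0, rt_jitter_sd >= 0, noise_peak_rate >= 0,
            base_intensity > 0, rt_step_min > 0)
  spec <- list(n_samples = as.integer(n_samples),
               apa_sample_ids = apa_sample_ids,
               abundance_profiles = abundance_profiles,
               n_background_features = as.integer(n_background_features),
               background_meanlog = background_meanlog,
               background_sdlog = background_sdlog,
               sample_noise_sd = sample_noise_sd,
               mz_jitter_ppm_sd = mz_jitter_ppm_sd,
               rt_jitter_sd = rt_jitter_sd,
               noise_peak_rate = noise_peak_rate,
               base_intensity = base_intensity,
               run_length_min = run_length_min,
               rt_step_min = rt_step_min,
               mass_range = mass_range,
               seed = as.integer(seed))
  class(spec) <- "cohort_spec"
  spec
}

#' Default per-specimen 3-APA abundance profiles
#'
#' Ordinal mimic of the reported compound distribution across the three
#' alkaloid-bearing specimens: S1 and S5 share a similar profile with S1
#' richer in cyclostellettamine Q and the haliclamines; S8 is divergent,
#' richer in most compounds except cyclostellettamines N and P, haliclamine
#' E, viscosaline B2 and viscosamine C.
#'
#' @return Matrix (13 compounds x 3 samples) of relative abundances.
#' @export
default_abundance_profiles <- function() {
  cmp <- c("Cyclostellettamine P", "Cyclostellettamine Q",
           "Cyclostellettamine N", "Cyclostellettamine G",
           "Cyclostellettamine A", "Haliclamine A", "Haliclamine C",
           "Haliclamine D", "Haliclamine E", "Haliclamine H",
           "Viscosamine C", "Viscosaline B2", "Viscosaline C")
  m <- cbind(
    S1 = c(1.5, 2.0, 1.0, 0.8, 0.6, 1.5, 1.5, 1.5, 1.2, 1.3, 0.8, 0.9, 0.6),
    S5 = c(1.4, 1.0, 0.9, 0.7, 0.6, 0.9, 0.9, 0.9, 0.7, 0.8, 0.7, 0.8, 0.6),
    S8 = c(0.4, 2.5, 0.3, 2.0, 2.0, 2.2, 2.3, 2.4, 0.3, 2.2, 0.3, 0.3, 1.8)
  )
  rownames(m) <- cmp
  m
}

#' Reported cell-viability table of the eight cytotoxic extracts
#'
#' The MTS viability values (% of solvent control at 33 ug/mL) of the eight
#' cytotoxic sponge extracts, used to seed the synthetic bioactivity table.
#'
#' @return Data frame with columns `sample_id`, `viability_percent`,
#'   `species`.
#' @export
table1_viability <- function() {
  data.frame(
    sample_id = paste0("S", 1:8),
    viability_percent = c(8, 29, 51, 18, 31, 31, 13, 22),
    species = c("Haliclona rosea", "Halichondria sitiens",
                "Myxilla incrustans", "Halichondria panicea",
                "Haliclona rosea", "Lissodendoryx fragilis",
                "Halichondria panicea", "Haliclona rosea"),
    stringsAsFactors = FALSE
  )
}

#' Simulate an isotope envelope for an ion
#'
#' Peaks at `mz + k * 1.003355 / charge`, k = 0..n_peaks-1, with relative
#' intensities from a binomial model over the formula's carbon count with
#' per-carbon heavy-isotope probability 0.0107 (N/O heavy isotopes are below
#' matching tolerance and ignored).
#'
#' @param ion_formula Formula of the charged species.
#' @param charge Positive integer charge.
#' @param n_peaks Number of isotope peaks (>= 1).
#' @return Data frame (mz, intensity) with the monoisotopic peak at
#'   intensity 1.
#' @export
simulate_isotope_pattern <- function(ion_formula, charge, n_peaks = 3L) {
  if (n_peaks < 1) stop("n_peaks must be >= 1")
  f <- as_formula(ion_formula)
  n_c <- if ("C" %in% names(f)) unclass(f)[["C"]] else 0L
  k <- seq_len(n_peaks) - 1L
  rel <- stats::dbinom(k, size = n_c, prob = C13_ABUNDANCE)
  rel <- rel / rel[1]
  data.frame(mz = ion_mz(f, charge) + k * C13_SPACING / charge,
             intensity = rel)
}

# Deterministic retention time of a compound on the 2-16 min window of the
# gradient: reproducibility without modeling chromatography.
compound_rt <- function(name, lo = 2, hi = 16) {
  lo + (stable_hash(name) %% 100000L) / 99999 * (hi - lo)
}

# Chromatographic profile weights over grid offsets (Gaussian peak shape).
rt_profile <- function(rt_step, peak_sd = 0.12) {
  half <- max(1L, ceiling(3 * peak_sd / rt_step))
  off <- (-half):half
  w <- exp(-0.5 * (off * rt_step / peak_sd)^2)
  sel <- w > 0.01
  list(offsets = off[sel], weights = w[sel])
}

# Placement of a compound set in one sample: one row per (fn, ion/fragment,
# isotope peak) at its apex, before chromatographic spreading and jitter.
# Used both by the run builder and by the cohort ground-truth table.
compound_placement <- function(compounds, abundances, spec, sample_id, seed) {
  rows <- vector("list", length(compounds) * 4L)
  ri <- 0L
  for (i in seq_along(compounds)) {
    cmp <- compounds[[i]]
    ab <- abundances[i]
    if (ab <= 0) next
    rt_c <- compound_rt(cmp$name) +
      withr::with_seed(derive_seed(seed, paste0("rt:", sample_id, ":", cmp$name)),
                       stats::rnorm(1, 0, spec$rt_jitter_sd))
    ions <- cmp$ions[!is.na(cmp$ions$mz), , drop = FALSE]
    ion_w <- c(1, rep(0.4, max(0, nrow(ions) - 1L)))
    for (j in seq_len(nrow(ions))) {
      iso <- simulate_isotope_pattern(ions$formula[j], ions$charge[j], 3L)
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        compound = cmp$name, kind = ions$label[j], fn = 1L, rt = rt_c,
        mz = iso$mz,
        intensity = spec$base_intensity * ab * ion_w[j] * iso$intensity,
        stringsAsFactors = FALSE)
      # attenuated unfragmented precursor survives into the high-energy fn
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        compound = cmp$name, kind = paste0(ions$label[j], " (survivor)"),
        fn = 2L, rt = rt_c, mz = iso$mz[1],
        intensity = spec$base_intensity * ab * ion_w[j] * 0.2,
        stringsAsFactors = FALSE)
    }
    fr <- cmp$fragments
    fr_w <- ifelse(fr$role == "diagnostic", 0.6, 0.5)
    ri <- ri + 1L
    rows[[ri]] <- data.frame(
      compound = cmp$name, kind = fr$role, fn = 2L, rt = rt_c, mz = fr$mz,
      intensity = spec$base_intensity * ab * fr_w,
      stringsAsFactors = FALSE)
  }
  if (ri == 0L)
    return(data.frame(compound = character(), kind = character(),
                      fn = integer(), rt = numeric(), mz = numeric(),
                      intensity = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, rows[seq_len(ri)])
}

# Shared background features: identical across samples apart from
# per-sample multiplicative noise. Drawn from the spec seed only.
background_features <- function(spec) {
  if (spec$n_background_features == 0L)
    return(data.frame(mz = numeric(), rt = numeric(), base = numeric()))
  withr::with_seed(derive_seed(spec$seed, "background"), {
    n <- spec$n_background_features
    data.frame(
      mz = stats::runif(n, spec$mass_range[1], spec$mass_range[2]),
      rt = stats::runif(n, 1, spec$run_length_min - 2),
      base = stats::rlnorm(n, spec$background_meanlog, spec$background_sdlog)
    )
  })
}

#' Simulate one two-function MSE run
#'
#' Places each compound at a reproducible retention time; the low-energy
#' function receives its ion species with isotope envelopes, the high-energy
#' function its diagnostic and predicted F1/F2 fragments plus an attenuated
#' precursor at the same retention time. Shared background features,
#' Gaussian ppm jitter and shot noise are added per the spec. Identical
#' (spec, seed, sample_id) give identical runs.
#'
#' @param compounds List of `apa_compound` objects (may be empty).
#' @param abundances Numeric relative abundances, one per compound.
#' @param spec A [cohort_spec()].
#' @param sample_id Sample identifier.
#' @param seed Seed; defaults to `spec$seed`.
#' @return An `mse_run`.
#' @export
simulate_mse_run <- function(compounds = list(), abundances = numeric(),
                             spec = cohort_spec(), sample_id = "S1",
                             seed = spec$seed) {
  if (length(compounds) != length(abundances))
    stop("compounds and abundances must have equal length")
  if (any(abundances < 0)) stop("abundances must be >= 0")
  rt_grid <- seq(0, spec$run_length_min, by = spec$rt_step_min)
  prof <- rt_profile(spec$rt_step_min)
  apex <- compound_placement(compounds, abundances, spec, sample_id, seed)
  bg <- background_features(spec)
  parts <- list()
  withr::with_seed(derive_seed(seed, paste0("run:", sample_id)), {
    if (nrow(bg)) {
      fac <- exp(stats::rnorm(nrow(bg), 0, spec$sample_noise_sd))
      parts$bg <- data.frame(fn = 1L, rt = bg$rt, mz = bg$mz,
                             intensity = bg$base * fac)
    }
    if (nrow(apex))
      parts$apa <- apex[c("fn", "rt", "mz", "intensity")]
    # shot noise in both functions
    if (spec$noise_peak_rate > 0) {
      n_noise <- stats::rpois(1, spec$noise_peak_rate * length(rt_grid) * 2)
      if (n_noise > 0)
        parts$noise <- data.frame(
          fn = sample(1:2, n_noise, replace = TRUE),
          rt = sample(rt_grid, n_noise, replace = TRUE),
          mz = stats::runif(n_noise, spec$mass_range[1], spec$mass_range[2]),
          intensity = stats::rlnorm(n_noise, 6, 1))
    }
    peaks <- do.call(rbind, parts)
    if (is.null(peaks) || !nrow(peaks)) {
      peaks <- data.frame(fn = integer(), rt = numeric(), mz = numeric(),
                          intensity = numeric())
    } else {
      # chromatographic spreading onto the grid
      apex_idx <- pmin(pmax(round(peaks$rt / spec$rt_step_min) + 1L, 1L),
                       length(rt_grid))
      noff <- length(prof$offsets)
      idx <- rep(apex_idx, each = noff) + rep(prof$offsets, nrow(peaks))
      keep <- idx >= 1L & idx <= length(rt_grid)
      peaks <- data.frame(
        fn = rep(peaks$fn, each = noff)[keep],
        rt = rt_grid[idx[keep]],
        mz = rep(peaks$mz, each = noff)[keep],
        intensity = (rep(peaks$intensity, each = noff) *
                       rep(prof$weights, nrow(peaks)))[keep])
      # per-peak Gaussian mass error
      if (spec$mz_jitter_ppm_sd > 0)
        peaks$mz <- peaks$mz *
          (1 + stats::rnorm(nrow(peaks), 0, spec$mz_jitter_ppm_sd) * 1e-6)
      peaks <- peaks[peaks$mz >= spec$mass_range[1] &
                       peaks$mz <= spec$mass_range[2], , drop = FALSE]
    }
  })
  new_mse_run(sample_id, peaks, rt_grid, spec)
}

new_mse_run <- function(sample_id, peaks, rt_grid, spec) {
  spectra <- vector("list", 2L * length(rt_grid))
  si <- 0L
  for (fn in 1:2) {
    sel <- peaks$fn == fn
    p <- peaks[sel, , drop = FALSE]
    grp <- split(seq_len(nrow(p)), factor(match(p$rt, rt_grid),
                                          levels = seq_along(rt_grid)))
    for (g in seq_along(rt_grid)) {
      rows <- grp[[g]]
      si <- si + 1L
      if (length(rows)) {
        mz <- p$mz[rows]
        int <- p$intensity[rows]
        o <- order(mz)
        mz <- mz[o]; int <- int[o]
        # merge exactly coincident centroids to keep mz strictly ascending
        if (anyDuplicated(mz)) {
          int <- as.numeric(tapply(int, factor(mz, levels = unique(mz)), sum))
          mz <- unique(mz)
        }
        spectra[[si]] <- list(rt = rt_grid[g], fn = fn, mz = mz,
                              intensity = int)
      } else {
        spectra[[si]] <- list(rt = rt_grid[g], fn = fn, mz = numeric(),
                              intensity = numeric())
      }
    }
  }
  run <- list(sample_id = sample_id,
              metadata = list(run_length_min = spec$run_length_min,
                              rt_step_min = spec$rt_step_min,
                              mass_range = spec$mass_range),
              spectra = spectra)
  class(run) <- "mse_run"
  run
}

#' @export
print.mse_run <- function(x, ...) {
  np <- sum(vapply(x$spectra, function(s) length(s$mz), numeric(1)))
  cat(sprintf("<mse_run> %s: %d spectra (2 functions), %d centroid peaks\n",
              x$sample_id, length(x$spectra), np))
  invisible(x)
}

# flat data.frame of all peaks of one function, in rt order
run_peaks <- function(run, fn) {
  sp <- Filter(function(s) s$fn == fn, run$spectra)
  n <- vapply(sp, function(s) length(s$mz), integer(1))
  data.frame(rt = rep(vapply(sp, `[[`, numeric(1), "rt"), n),
             mz = unlist(lapply(sp, `[[`, "mz")),
             intensity = unlist(lapply(sp, `[[`, "intensity")))
}

run_functions <- function(run) {
  sort(unique(vapply(run$spectra, `[[`, numeric(1), "fn")))
}

#' Simulate a full cohort of MSE runs with bioactivity and ground truth
#'
#' APA-carrying samples receive the thirteen curated compounds scaled by
#' their abundance profiles; all samples share the same log-normal
#' background. Viability values are seeded from the reported cytotoxicity
#' table for S1-S8 (APA samples are always active) and drawn near control
#' level for the remaining specimens.
#'
#' @param spec A [cohort_spec()].
#' @return List with `runs` (list of `mse_run`), `bioactivity` (data frame
#'   sample_id, viability_percent) and `truth` (one row per injected ion
#'   with true m/z, apex retention time and apex intensity).
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  ids <- paste0("S", seq_len(spec$n_samples))
  if (!all(spec$apa_sample_ids %in% ids))
    stop("apa_sample_ids not in cohort: ",
         paste(setdiff(spec$apa_sample_ids, ids), collapse = ", "))
  lib <- curated_library()
  profiles <- spec$abundance_profiles
  runs <- vector("list", length(ids))
  truth_parts <- list()
  for (i in seq_along(ids)) {
    id <- ids[i]
    if (id %in% spec$apa_sample_ids) {
      col <- match(id, spec$apa_sample_ids)
      col <- ((col - 1L) %% ncol(profiles)) + 1L
      cmp_names <- rownames(profiles)
      compounds <- lib$entries[cmp_names]
      ab <- profiles[, col]
      runs[[i]] <- simulate_mse_run(compounds, ab, spec, id)
      tr <- compound_placement(compounds, ab, spec, id, spec$seed)
      if (nrow(tr)) {
        tr$sample_id <- id
        truth_parts[[id]] <- tr[c("sample_id", "compound", "kind", "fn",
                                  "mz", "rt", "intensity")]
      }
    } else {
      runs[[i]] <- simulate_mse_run(list(), numeric(), spec, id)
    }
  }
  names(runs) <- ids
  truth <- if (length(truth_parts)) do.call(rbind, truth_parts) else
    data.frame(sample_id = character(), compound = character(),
               kind = character(), fn = integer(), mz = numeric(),
               rt = numeric(), intensity = numeric())
  rownames(truth) <- NULL
  bio <- cohort_bioactivity(ids, spec)
  out <- list(runs = runs, bioactivity = bio, truth = truth, spec = spec)
  class(out) <- "apa_cohort"
  out
}

cohort_bioactivity <- function(ids, spec) {
  t1 <- table1_viability()
  via <- withr::with_seed(derive_seed(spec$seed, "viability"), {
    v <- numeric(length(ids))
    for (i in seq_along(ids)) {
      id <- ids[i]
      if (id %in% t1$sample_id) {
        v[i] <- t1$viability_percent[match(id, t1$sample_id)]
      } else {
        v[i] <- round(min(120, max(60, stats::rnorm(1, 95, 8))))
      }
      # APA-bearing extracts are always cytotoxic
      if (id %in% spec$apa_sample_ids && v[i] >= 50)
        v[i] <- round(stats::runif(1, 5, 45))
    }
    v
  })
  data.frame(sample_id = ids, viability_percent = via,
             stringsAsFactors = FALSE)
}

#' @export
print.apa_cohort <- function(x, ...) {
  cat(sprintf("<apa_cohort> %d runs, %d APA-bearing, %d ground-truth ions\n",
              length(x$runs), length(x$spec$apa_sample_ids), nrow(x$truth)))
  invisible(x)
}

#' Simulate a TAP (pseudo-MS3) dataset with two coeluting isobars
#'
#' Emulates the drift-time experiment on the doubly charged macrocyclic
#' precursor at m/z 218.19: two primary drift populations at that m/z with
#' distinct drift times; the lower-drift population's secondary spectrum
#' carries the ring-opening fragment at m/z 393.33, the higher-drift
#' population's the two onium fragments at m/z 204.17 and 232.20. Primary
#' fragments at 393.33, 204.17 and 232.20 have their own drift times and
#' secondary spectra.
#'
#' @param seed Integer seed.
#' @param drift_low,drift_high Drift-time apexes (ms) of the two isobar
#'   populations.
#' @param drift_sd Gaussian drift peak SD in ms.
#' @param drift_step Drift grid step in ms.
#' @param mz_jitter_sd Absolute m/z jitter SD in Da.
#' @return A `tap_run`.
#' @export
simulate_tap_isobars <- function(seed = 1L, drift_low = 4.0,
                                 drift_high = 5.5, drift_sd = 0.25,
                                 drift_step = 0.1, mz_jitter_sd = 0.001) {
  # species table: primary m/z values as reported at two-decimal precision
  species <- list(
    list(mz = 218.19, drift = drift_low, int = 8e4,
         secondary = data.frame(mz = c(393.33, 204.17, 106.07),
                                intensity = c(5e4, 2.5e4, 1.5e4))),
    list(mz = 218.19, drift = drift_high, int = 1e5,
         secondary = data.frame(mz = c(204.17, 232.20, 106.07),
                                intensity = c(6e4, 5.5e4, 2e4))),
    list(mz = 393.33, drift = 7.0, int = 4e4,
         secondary = data.frame(mz = c(204.17, 106.07),
                                intensity = c(2e4, 1e4))),
    list(mz = 204.17, drift = 2.8, int = 5e4,
         secondary = data.frame(mz = 106.07, intensity = 2e4)),
    list(mz = 232.20, drift = 3.2, int = 4.5e4,
         secondary = data.frame(mz = 106.07, intensity = 1.8e4))
  )
  grid <- seq(0, 12, by = drift_step)
  primary <- list()
  sec_bins <- vector("list", length(grid))
  withr::with_seed(derive_seed(seed, "tap"), {
    for (sp in species) {
      w <- exp(-0.5 * ((grid - sp$drift) / drift_sd)^2)
      keep <- which(w > 0.01)
      primary[[length(primary) + 1L]] <- data.frame(
        mz = sp$mz + stats::rnorm(length(keep), 0, mz_jitter_sd),
        drift_time = grid[keep],
        intensity = sp$int * w[keep])
      for (g in keep) {
        s <- sp$secondary
        s$intensity <- s$intensity * w[g]
        s$mz <- s$mz + stats::rnorm(nrow(s), 0, mz_jitter_sd)
        sec_bins[[g]] <- rbind(sec_bins[[g]], s)
      }
    }
  })
  secondary <- list()
  for (g in seq_along(grid)) {
    if (is.null(sec_bins[[g]])) next
    s <- sec_bins[[g]]
    s <- s[order(s$mz), , drop = FALSE]
    secondary[[length(secondary) + 1L]] <-
      list(drift_time = grid[g],
           peaks = data.frame(mz = s$mz, intensity = s$intensity))
  }
  run <- list(precursor_mz = 218.19,
              primary = do.call(rbind, primary),
              secondary = secondary,
              drift_step = drift_step)
  class(run) <- "tap_run"
  run
}

#' @export
print.tap_run <- function(x, ...) {
  cat(sprintf("<tap_run> precursor m/z %.2f, %d primary peaks, %d secondary drift bins\n",
              x$precursor_mz, nrow(x$primary), length(x$secondary)))
  invisible(x)
}
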