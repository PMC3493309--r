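#' Specification of one synthetic spectrum stream
#'
#' Describes the acquisition grid and noise model for one chip x mass-range
#' stream of synthetic SELDI-like spectra. The m/z grid is log-uniform between
#' the mass bounds; peaks are Gaussian with a full width at half maximum
#' proportional to m/z (constant relative resolution, as in TOF instruments);
#' the chemical/matrix baseline decays exponentially from the low-mass end.
#'
#' @param mass_range_bounds Length-2 numeric, increasing positive (Da).
#' @param grid_size Number of grid points (>= 100).
#' @param baseline_amplitude Baseline intensity at the low-mass bound.
#' @param baseline_decay Exponential decay scale of the baseline (Da).
#' @param noise_sd SD of additive white Gaussian noise.
#' @param resolution_fwhm_rel Peak FWHM as a fraction of peak m/z, in (0, 0.05].
#' @param mz_jitter_rel SD of the per-sample relative m/z calibration shift.
#' @param tic_scale_sd Log-SD of the per-spectrum multiplicative intensity
#'   scale (spot-to-spot ionization variability).
#' @return An object of class `spectrum_spec`.
#' @export
spectrum_spec <- function(mass_range_bounds, grid_size = 2000,
                          baseline_amplitude = 20, baseline_decay = NULL,
                          noise_sd = 0.5, resolution_fwhm_rel = 0.003,
                          mz_jitter_rel = 0.001, tic_scale_sd = 0.1) {
  stopifnot(length(mass_range_bounds) == 2)
  if (any(mass_range_bounds <= 0) || diff(mass_range_bounds) <= 0) {
    stop("mass_range_bounds must be positive and increasing", call. = FALSE)
  }
  if (grid_size < 100) stop("grid_size must be >= 100", call. = FALSE)
  if (noise_sd < 0 || mz_jitter_rel < 0 || tic_scale_sd < 0) {
    stop("standard deviations must be >= 0", call. = FALSE)
  }
  if (resolution_fwhm_rel <= 0 || resolution_fwhm_rel > 0.05) {
    stop("resolution_fwhm_rel must lie in (0, 0.05]", call. = FALSE)
  }
  if (is.null(baseline_decay)) baseline_decay <- diff(mass_range_bounds) / 4
  structure(
    list(mass_range_bounds = as.numeric(mass_range_bounds),
         grid_size = as.integer(grid_size),
         baseline_amplitude = baseline_amplitude,
         baseline_decay = baseline_decay, noise_sd = noise_sd,
         resolution_fwhm_rel = resolution_fwhm_rel,
         mz_jitter_rel = mz_jitter_rel, tic_scale_sd = tic_scale_sd),
    class = "spectrum_spec")
}

#' A planted (ground-truth) peak
#'
#' @param mz Peak location (Da).
#' @param base_intensity Peak apex height in the negative class (> 0).
#' @param effect_size Log-fold intensity shift in the positive class: positive
#'   samples have this peak's height multiplied by `exp(effect_size)`.
#' @param cv Biological coefficient of variation of the height across samples
#'   (log-normal, sdlog = cv).
#' @return An object of class `planted_peak`.
#' @export
planted_peak <- function(mz, base_intensity, effect_size = 0, cv = 0.15) {
  if (base_intensity <= 0) stop("base_intensity must be > 0", call. = FALSE)
  if (cv < 0) stop("cv must be >= 0", call. = FALSE)
  structure(list(mz = mz, base_intensity = base_intensity,
                 effect_size = effect_size, cv = cv),
            class = "planted_peak")
}

# log-uniform acquisition grid for a stream
spec_grid <- function(spec) {
  exp(seq(log(spec$mass_range_bounds[1]), log(spec$mass_range_bounds[2]),
          length.out = spec$grid_size))
}

# run code with a temporary RNG state; leaves the caller's RNG untouched
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate one synthetic spectrum
#'
#' The trace is
#' `sample_scale * (baseline + sum of Gaussian peaks) + noise`, where the
#' baseline decays exponentially from the low-mass bound, each peak is a
#' unit-height Gaussian scaled by its planted height with FWHM equal to
#' `resolution_fwhm_rel * mz`, the whole peak pattern is shifted by the
#' sample's relative m/z calibration error, and the noise is white Gaussian.
#' Intensities are reported as generated and may be slightly negative where
#' noise undershoots; preprocessing is responsible for baseline handling.
#'
#' @param spec A [spectrum_spec()].
#' @param peaks List of [planted_peak()]; all locations must lie inside the
#'   mass bounds.
#' @param sample_scale Positive multiplicative intensity scale.
#' @param mz_shift_rel Relative m/z shift applied to all peak locations.
#' @param seed Integer seed; the trace is bit-reproducible given the seed.
#' @param ... Metadata passed to [ms_spectrum()] (sample_id, chip, ...).
#' @return An `ms_spectrum`.
#' @export
generate_spectrum <- function(spec, peaks = list(), sample_scale = 1,
                              mz_shift_rel = 0, seed = 1L, ...) {
  if (sample_scale <= 0) stop("sample_scale must be > 0", call. = FALSE)
  bounds <- spec$mass_range_bounds
  for (p in peaks) {
    if (p$mz < bounds[1] || p$mz > bounds[2]) {
      stop(sprintf("planted peak at m/z %.1f outside bounds [%g, %g]",
                   p$mz, bounds[1], bounds[2]), call. = FALSE)
    }
  }
  m <- spec_grid(spec)
  signal <- spec$baseline_amplitude * exp(-(m - bounds[1]) / spec$baseline_decay)
  for (p in peaks) {
    centre <- p$mz * (1 + mz_shift_rel)
    fwhm <- spec$resolution_fwhm_rel * p$mz
    sdv <- fwhm / (2 * sqrt(2 * log(2)))
    # evaluate only near the peak; beyond 6 sd the contribution is negligible
    idx <- which(abs(m - centre) < 6 * sdv)
    if (length(idx)) {
      signal[idx] <- signal[idx] +
        p$base_intensity * exp(-(m[idx] - centre)^2 / (2 * sdv^2))
    }
  }
  eps <- if (spec$noise_sd > 0) {
    with_seed(seed, stats::rnorm(length(m), 0, spec$noise_sd))
  } else numeric(length(m))
  ms_spectrum(m, sample_scale * signal + eps, ...)
}

#' Default stream definitions emulating the study design
#'
#' Four streams (CM10 and IMAC30 chips, each acquired over a low < 10 kDa and
#' a high 10-100 kDa mass range), with a fixed panel of planted peaks per
#' stream. One peak, at m/z 2698.9 on IMAC30 low, carries a class-dependent
#' log-fold shift (`effect_size`); all other peaks are non-discriminatory.
#' All planted peaks in a stream are separated by well over 1% in m/z, so the
#' default 0.1% calibration jitter leaves them alignable.
#'
#' @param effect_size Log-fold shift of the discriminatory peak (default 3).
#' @param marker_cv Biological CV of the discriminatory peak (default 0.05).
#' @param grid_size Grid points per stream (default 2000); smaller values give
#'   proportionally faster, coarser cohorts.
#' @param noise_sd Additive noise SD (default 0.5).
#' @return A named list of streams, each a list with elements `chip`,
#'   `mass_range`, `spec` and `peaks`.
#' @export
default_streams <- function(effect_size = 3, marker_cv = 0.05,
                            grid_size = 2000, noise_sd = 0.5) {
  low <- function(...) spectrum_spec(c(1000, 10000), baseline_amplitude = 20,
                                     baseline_decay = 2500,
                                     grid_size = grid_size,
                                     noise_sd = noise_sd, ...)
  high <- function(...) spectrum_spec(c(10000, 100000), baseline_amplitude = 10,
                                      baseline_decay = 25000,
                                      grid_size = grid_size,
                                      noise_sd = noise_sd, ...)
  pk <- planted_peak
  list(
    CM10_low = list(chip = "CM10", mass_range = "low", spec = low(),
      peaks = list(pk(1532.1, 40), pk(2044.7, 30), pk(3224.3, 55),
                   pk(3953.2, 70), pk(5210.0, 35), pk(7432.0, 25))),
    CM10_high = list(chip = "CM10", mass_range = "high", spec = high(),
      peaks = list(pk(11700, 30), pk(12802.8, 45), pk(28400, 25),
                   pk(66430, 20))),
    IMAC30_low = list(chip = "IMAC30", mass_range = "low", spec = low(),
      peaks = list(pk(1627.3, 35), pk(1979.5, 25),
                   pk(2698.9, 4, effect_size = effect_size, cv = marker_cv),
                   pk(4783.5, 45), pk(6120.0, 30))),
    IMAC30_high = list(chip = "IMAC30", mass_range = "high", spec = high(),
      peaks = list(pk(15254.8, 40), pk(23100, 30), pk(78294.9, 20),
                   pk(94029.3, 25))))
}

#' Generate a synthetic cohort of spectra with known ground truth
#'
#' Emulates the study design: `n_pos` positive and `n_neg` negative samples,
#' each analysed in duplicate on every stream. Per sample and stream, a
#' relative m/z calibration shift and log-normal biological peak heights are
#' drawn once and shared by both replicates; replicates differ only in their
#' additive noise and a fresh multiplicative spot scale. Positive samples have
#' every discriminatory peak's height multiplied by `exp(effect_size)`.
#'
#' @param n_pos,n_neg Samples per class (each >= 2); defaults 12 and 48.
#' @param streams Stream list as produced by [default_streams()].
#' @param n_replicates Replicate spots per sample and stream (default 2).
#' @param seed Integer master seed.
#' @return A list with `spectra` (list of `ms_spectrum`) and `truth`, a list
#'   holding per-sample labels (+1/-1), the discriminatory m/z per stream, the
#'   planted peak table, and the replicate map.
#' @export
generate_cohort <- function(n_pos = 12, n_neg = 48,
                            streams = default_streams(),
                            n_replicates = 2, seed = 1L) {
  if (n_pos < 2 || n_neg < 2) stop("need >= 2 samples per class", call. = FALSE)
  if (length(streams) == 0) stop("empty stream list", call. = FALSE)
  n <- n_pos + n_neg
  sample_ids <- sprintf("S%02d", seq_len(n))
  labels <- c(rep(1L, n_pos), rep(-1L, n_neg))
  names(labels) <- sample_ids

  planted <- do.call(rbind, lapply(names(streams), function(nm) {
    st <- streams[[nm]]
    do.call(rbind, lapply(st$peaks, function(p) data.frame(
      stream = nm, chip = st$chip, mass_range = st$mass_range, mz = p$mz,
      base_intensity = p$base_intensity, effect_size = p$effect_size,
      cv = p$cv, stringsAsFactors = FALSE)))
  }))

  spectra <- list()
  with_seed(seed, {
    for (nm in names(streams)) {
      st <- streams[[nm]]
      for (i in seq_len(n)) {
        shift <- stats::rnorm(1, 0, st$spec$mz_jitter_rel)
        heights <- vapply(st$peaks, function(p) {
          h <- p$base_intensity * exp(stats::rnorm(1, 0, p$cv))
          if (labels[i] > 0) h <- h * exp(p$effect_size)
          h
        }, numeric(1))
        bio_peaks <- lapply(seq_along(st$peaks), function(k) {
          planted_peak(st$peaks[[k]]$mz, heights[k])
        })
        for (r in seq_len(n_replicates)) {
          scale <- exp(stats::rnorm(1, 0, st$spec$tic_scale_sd))
          sseed <- sample.int(.Machine$integer.max - 1L, 1L)
          spectra[[length(spectra) + 1L]] <- generate_spectrum(
            st$spec, bio_peaks, sample_scale = scale, mz_shift_rel = shift,
            seed = sseed, sample_id = sample_ids[i],
            replicate_id = sprintf("r%d", r),
            chip = st$chip, mass_range = st$mass_range)
        }
      }
    }
  })

  disc <- planted[planted$effect_size != 0, c("stream", "mz")]
  truth <- list(
    labels = labels,
    discriminatory_mz = disc,
    planted = planted,
    n_replicates = n_replicates,
    replicate_map = spectra_manifest(spectra)[, c("spectrum_id", "sample_id",
                                                 "replicate", "chip",
                                                 "mass_range")])
  list(spectra = spectra, truth = truth)
}

#' Generate a pooled-serum QC measurement series
#'
#' Simulates the weekly pooled-serum control runs: independent Gaussian
#' measurements around `mean`, with optional deterministic shifts (in SD
#' units) injected at chosen indices to provoke Westgard rule violations.
#'
#' @param n Number of control runs (>= 10).
#' @param mean,sd In-control mean and SD (`sd > 0`).
#' @param injected_shifts Optional data.frame or list of `c(index, offset)`
#'   pairs; `offset` is in SD units and is added to the sampled value.
#' @param seed Integer seed.
#' @return Numeric vector of control values (class `qc_values`).
#' @export
generate_qc_series <- function(n, mean = 100, sd = 5,
                               injected_shifts = list(), seed = 1L) {
  if (n < 10) stop("need n >= 10 control runs", call. = FALSE)
  if (sd <= 0) stop("sd must be > 0", call. = FALSE)
  values <- with_seed(seed, stats::rnorm(n, mean, sd))
  for (sh in injected_shifts) {
    idx <- sh[[1]]
    if (idx < 1 || idx > n) stop("injected shift index out of range",
                                 call. = FALSE)
    values[idx] <- values[idx] + sh[[2]] * sd
  }
  values
}
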