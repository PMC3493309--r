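# running minimum over a centred window of 2*half_window+1 points,
# truncated at the edges; vectorized as pmin over shifted copies
running_min <- function(x, half_window) {
  n <- length(x)
  out <- x
  for (off in seq_len(half_window)) {
    out <- pmin(out, c(x[-seq_len(off)], rep(Inf, off)),
                c(rep(Inf, off), x[seq_len(n - off)]))
  }
  out
}

# running mean over the same truncated window, via cumulative sums
running_mean <- function(x, half_window) {
  n <- length(x)
  cs <- cumsum(x)
  hi <- pmin(n, seq_len(n) + half_window)
  lo <- pmax(1L, seq_len(n) - half_window)
  (cs[hi] - cs[lo] + x[lo]) / (hi - lo + 1L)
}

#' Subtract the baseline from a spectrum
#'
#' The baseline is estimated morphologically: a running minimum over windows
#' of `2 * half_window + 1` points (the lower envelope) followed by a running
#' mean of the same width (smoothing the envelope). The estimate is clipped to
#' be non-negative after subtraction. The window must be wider than the peaks
#' it should pass under; with the default synthetic resolution a peak spans a
#' handful of grid points, so the default is generous.
#'
#' @param s An `ms_spectrum`.
#' @param half_window Half-width in grid points (>= 1, < length/2).
#' @return The spectrum with baseline-subtracted, non-negative intensities.
#' @export
subtract_baseline <- function(s, half_window = 25) {
  n <- length(s$intensity)
  if (half_window < 1) stop("half_window must be >= 1", call. = FALSE)
  if (half_window >= n / 2) {
    stop("half_window must be < length(spectrum)/2", call. = FALSE)
  }
  baseline <- running_mean(running_min(s$intensity, half_window), half_window)
  s$intensity <- pmax(s$intensity - baseline, 0)
  s
}

#' Normalize spectra to the mean total ion current of their stream
#'
#' The total ion current (TIC) of a spectrum is the sum of its intensities.
#' Each spectrum is divided by its normalization factor
#' `factor_i = TIC_i / mean(TIC)`, after which every spectrum in the stream
#' carries the same TIC (the stream mean). Factors are recorded on the
#' spectra; they feed the 2-SD outlier rule of [flag_outlier_spectra()].
#'
#' @param spectra List of `ms_spectrum` from one chip x mass-range stream.
#' @return A list with `spectra` (normalized) and `factors`.
#' @export
normalize_tic <- function(spectra) {
  if (length(spectra) < 2) stop("need >= 2 spectra", call. = FALSE)
  keys <- vapply(spectra, stream_key, character(1))
  if (length(unique(keys)) != 1L) {
    stop("all spectra must belong to one chip/mass-range stream",
         call. = FALSE)
  }
  tic <- vapply(spectra, function(s) sum(s$intensity), numeric(1))
  bad <- which(tic <= 0)
  if (length(bad)) {
    stop("non-positive total ion current for spectrum ",
         spectrum_id(spectra[[bad[1]]]), call. = FALSE)
  }
  factors <- tic / mean(tic)
  spectra <- lapply(seq_along(spectra), function(i) {
    s <- spectra[[i]]
    s$intensity <- s$intensity / factors[i]
    s$normalization_factor <- factors[i]
    s
  })
  list(spectra = spectra, factors = factors)
}

#' Flag outlier spectra by their TIC normalization factor
#'
#' A spectrum is flagged when its normalization factor deviates from the mean
#' factor of its stream by more than two standard deviations (sample SD,
#' denominator n - 1). Flagged spectra are excluded from replicate averaging
#' and all downstream peak work.
#'
#' @param factors Numeric vector of normalization factors (>= 3 values).
#' @return Logical vector, `TRUE` = outlier.
#' @export
flag_outlier_spectra <- function(factors) {
  if (length(factors) < 3) stop("need >= 3 factors", call. = FALSE)
  s <- stats::sd(factors)
  if (s == 0) return(rep(FALSE, length(factors)))
  abs(factors - mean(factors)) > 2 * s
}

#' Average replicate spectra within each sample and stream
#'
#' Produces one spectrum per sample and stream whose intensity is the
#' pointwise mean of the surviving (non-outlier) replicates. If every
#' replicate of a sample was flagged the sample is dropped from that stream
#' with a warning. Replicates must share an identical m/z grid.
#'
#' @param spectra List of `ms_spectrum` from one stream.
#' @param outlier Logical vector parallel to `spectra` (default: none).
#' @return List of averaged `ms_spectrum`, one per surviving sample, in order
#'   of first appearance.
#' @export
average_replicates <- function(spectra, outlier = NULL) {
  if (is.null(outlier)) outlier <- rep(FALSE, length(spectra))
  stopifnot(length(outlier) == length(spectra))
  sample_ids <- vapply(spectra, function(s) s$sample_id, character(1))
  out <- list()
  for (sid in unique(sample_ids)) {
    idx <- which(sample_ids == sid & !outlier)
    if (!length(idx)) {
      warning("all replicates of sample ", sid,
              " flagged as outliers; sample dropped", call. = FALSE)
      next
    }
    ref <- spectra[[idx[1]]]
    for (j in idx[-1]) {
      if (!isTRUE(all.equal(spectra[[j]]$mz, ref$mz))) {
        stop("replicates of sample ", sid, " have mismatched m/z grids",
             call. = FALSE)
      }
    }
    avg <- rowMeans(vapply(idx, function(j) spectra[[j]]$intensity,
                           numeric(length(ref$mz))))
    ref$intensity <- avg
    ref$replicate_id <- "avg"
    out[[length(out) + 1L]] <- ref
  }
  out
}

#' Preprocess a cohort of raw spectra
#'
#' Per stream: baseline subtraction, TIC normalization, 2-SD outlier
#' flagging, replicate averaging. Convenience wrapper used by the pipeline.
#'
#' @param spectra List of raw `ms_spectrum`.
#' @param baseline_half_window Window half-width for [subtract_baseline()].
#' @return A list with `spectra` (averaged, one per sample and stream),
#'   `manifest` (per input spectrum, with normalization factor and outlier
#'   flag), in stream order.
#' @export
preprocess_cohort <- function(spectra, baseline_half_window = 25) {
  keys <- vapply(spectra, stream_key, character(1))
  out <- list()
  man <- list()
  for (k in unique(keys)) {
    idx <- which(keys == k)
    strm <- lapply(spectra[idx], subtract_baseline,
                   half_window = baseline_half_window)
    norm <- normalize_tic(strm)
    flags <- flag_outlier_spectra(norm$factors)
    m <- spectra_manifest(norm$spectra)
    m$outlier <- flags
    man[[k]] <- m
    out <- c(out, average_replicates(norm$spectra, flags))
  }
  list(spectra = out, manifest = do.call(rbind, c(man, make.row.names = FALSE)))
}
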