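#' Detect peaks by sign changes of the first derivative
#'
#' The intensity is lightly smoothed by a running mean of width
#' `2 * smooth_half_window + 1`; candidate apexes are the indices where the
#' discrete first derivative of the smoothed trace changes sign from positive
#' to negative. Plateaus (zero-derivative runs between a rise and a fall)
#' report their midpoint. The reported apex intensity is the unsmoothed
#' intensity at the apex index.
#'
#' @param s A preprocessed `ms_spectrum`.
#' @param smooth_half_window Smoothing half-width in grid points (0 = none).
#' @return A data.frame of peaks: `mz`, `intensity`, `index`, `sample_id`,
#'   `chip`, `mass_range`.
#' @export
detect_peaks <- function(s, smooth_half_window = 2) {
  n <- length(s$intensity)
  if (n < 2 * smooth_half_window + 1) {
    stop("spectrum shorter than the smoothing window", call. = FALSE)
  }
  sm <- if (smooth_half_window > 0) {
    running_mean(s$intensity, smooth_half_window)
  } else s$intensity
  d <- sign(diff(sm))
  r <- rle(d)
  ends <- cumsum(r$lengths)
  # apex for a strict peak: end of the rise + 1; a zero-derivative run of
  # length L between rise and fall spans x-indices (end+1)..(end+L+1), and
  # its midpoint end+1+L%/%2 is reported
  apex <- integer(0)
  for (j in seq_along(r$values)) {
    if (r$values[j] != -1) next
    prev <- j - 1L
    plateau <- 0L
    if (prev >= 1L && r$values[prev] == 0) {
      plateau <- r$lengths[prev]
      prev <- prev - 1L
    }
    if (prev >= 1L && r$values[prev] == 1) {
      apex <- c(apex, ends[prev] + 1L + plateau %/% 2L)
    }
  }
  if (smooth_half_window > 0 && length(apex)) {
    # smoothing can displace the derivative sign change by a grid step or
    # two on narrow peaks: snap each apex to the unsmoothed local maximum
    # within the smoothing window
    apex <- vapply(apex, function(a) {
      lo <- max(1L, as.integer(a - smooth_half_window))
      hi <- min(n, as.integer(a + smooth_half_window))
      lo + which.max(s$intensity[lo:hi]) - 1L
    }, integer(1))
    apex <- sort(unique(apex))
  }
  data.frame(mz = s$mz[apex], intensity = s$intensity[apex], index = apex,
             sample_id = rep(s$sample_id, length(apex)),
             chip = rep(s$chip, length(apex)),
             mass_range = rep(s$mass_range, length(apex)),
             stringsAsFactors = FALSE)
}

#' Filter peaks against a local noise threshold
#'
#' A peak is kept if and only if its apex intensity strictly exceeds
#' `median(w) + 5 * MAD(w)`, where `w` is the spectrum intensity in a window
#' of `2 * noise_half_window + 1` grid points centred on the apex (clipped at
#' the spectrum edges) and MAD is the unscaled median absolute deviation,
#' `median(|w - median(w)|)` — no 1.4826 consistency factor.
#'
#' @param peaks Data.frame from [detect_peaks()] for spectrum `s`.
#' @param s The spectrum the peaks came from.
#' @param noise_half_window Window half-width in grid points (default 100,
#'   i.e. 201-point windows).
#' @return The subset of `peaks` passing the threshold.
#' @export
filter_peaks <- function(peaks, s, noise_half_window = 100) {
  if (!nrow(peaks)) return(peaks)
  n <- length(s$intensity)
  keep <- vapply(seq_len(nrow(peaks)), function(i) {
    idx <- peaks$index[i]
    w <- s$intensity[max(1L, idx - noise_half_window):
                       min(n, idx + noise_half_window)]
    med <- stats::median(w)
    mad_u <- stats::median(abs(w - med))
    peaks$intensity[i] > med + 5 * mad_u
  }, logical(1))
  peaks[keep, , drop = FALSE]
}

#' Align peaks across samples by 1-D complete-linkage clustering
#'
#' Agglomerative complete-linkage clustering on the peak m/z values of one
#' stream. In one dimension, complete-linkage clusters are contiguous
#' intervals of the sorted m/z axis and the complete-linkage distance between
#' two adjacent intervals is the span of their union. At each step the pair
#' of adjacent clusters with the smallest span relative to its tolerance
#' budget (`rel_tolerance * midpoint m/z of the union`) is merged; merging
#' stops when no pair fits within its budget, so every output cluster's
#' diameter is at most `rel_tolerance * consensus_mz`. If one sample
#' contributes several peaks to a cluster, only its most intense peak is
#' kept. Clusters are sorted by consensus m/z (the median member m/z).
#'
#' @param all_peaks Data.frame of peaks from one stream (columns `mz`,
#'   `intensity`, `sample_id`, and optionally `chip`, `mass_range`).
#' @param rel_tolerance Relative m/z tolerance (> 0, default 0.008: it must
#'   exceed the full per-sample m/z scatter, i.e. the span of the calibration
#'   jitter across the cohort plus one grid step).
#' @param min_support Minimum number of distinct samples a cluster must
#'   contain to be reported (default 1 = keep all clusters).
#' @return An object of class `peak_clusters`: a list with `clusters` (one
#'   row per cluster: `cluster_id`, `consensus_mz`, `diameter`, `n_samples`)
#'   and `members` (one row per kept member peak).
#' @export
cluster_peaks <- function(all_peaks, rel_tolerance = 0.008, min_support = 1) {
  if (rel_tolerance <= 0) stop("rel_tolerance must be > 0", call. = FALSE)
  chip <- if (nrow(all_peaks)) all_peaks$chip[1] else NA_character_
  mrange <- if (nrow(all_peaks)) all_peaks$mass_range[1] else NA_character_
  empty <- function() {
    structure(list(
      clusters = data.frame(cluster_id = integer(0), consensus_mz = numeric(0),
                            diameter = numeric(0), n_samples = integer(0),
                            chip = character(0), mass_range = character(0)),
      members = all_peaks[0, ], rel_tolerance = rel_tolerance),
      class = "peak_clusters")
  }
  if (!nrow(all_peaks)) return(empty())
  ord <- order(all_peaks$mz)
  pk <- all_peaks[ord, , drop = FALSE]
  # contiguous-interval agglomeration: lo/hi bound each current cluster,
  # assignment tracked via a membership index per sorted peak
  memb <- seq_len(nrow(pk))
  lo <- pk$mz
  hi <- pk$mz
  repeat {
    if (length(lo) < 2L) break
    span <- hi[-1] - lo[-length(lo)]                  # union span, adjacent
    mid <- (lo[-length(lo)] + hi[-1]) / 2
    ratio <- span / (rel_tolerance * mid)
    j <- which.min(ratio)
    if (ratio[j] > 1) break
    # merge clusters j and j+1
    hi[j] <- hi[j + 1]
    lo <- lo[-(j + 1)]
    hi <- hi[-(j + 1)]
    memb[memb > j] <- memb[memb > j] - 1L
  }
  pk$cluster_id <- memb
  # one peak per sample per cluster: keep the most intense
  keep <- unlist(lapply(split(seq_len(nrow(pk)),
                              list(pk$cluster_id, pk$sample_id), drop = TRUE),
                        function(ii) ii[which.max(pk$intensity[ii])]))
  pk <- pk[sort(keep), , drop = FALSE]
  cl <- do.call(rbind, lapply(split(pk, pk$cluster_id), function(g) {
    data.frame(consensus_mz = stats::median(g$mz),
               diameter = max(g$mz) - min(g$mz),
               n_samples = length(unique(g$sample_id)))
  }))
  o <- order(cl$consensus_mz)
  cl <- cl[o, , drop = FALSE]
  old_ids <- as.integer(rownames(cl))
  cl$cluster_id <- seq_len(nrow(cl))
  pk$cluster_id <- match(pk$cluster_id, old_ids)
  keep_ids <- cl$cluster_id[cl$n_samples >= min_support]
  if (!length(keep_ids)) return(empty())
  cl <- cl[cl$cluster_id %in% keep_ids, , drop = FALSE]
  pk <- pk[pk$cluster_id %in% keep_ids, , drop = FALSE]
  remap <- stats::setNames(seq_along(keep_ids), keep_ids)
  cl$cluster_id <- unname(remap[as.character(cl$cluster_id)])
  pk$cluster_id <- unname(remap[as.character(pk$cluster_id)])
  cl$chip <- chip
  cl$mass_range <- mrange
  rownames(cl) <- NULL
  structure(list(clusters = cl[, c("cluster_id", "consensus_mz", "diameter",
                                   "n_samples", "chip", "mass_range")],
                 members = pk, rel_tolerance = rel_tolerance),
            class = "peak_clusters")
}

#' @export
print.peak_clusters <- function(x, ...) {
  cat(sprintf("<peak_clusters> %d clusters from %d member peaks (%s/%s)\n",
              nrow(x$clusters), nrow(x$members),
              x$clusters$chip[1], x$clusters$mass_range[1]))
  invisible(x)
}

#' Build the samples x peak-clusters intensity matrix for one stream
#'
#' Entries are the member-peak apex intensities. Where a sample contributed
#' no peak to a cluster, its entry is re-quantified locally: the sample's
#' preprocessed trace value at the grid point nearest the cluster consensus
#' m/z (never zero-filled, which would fabricate class separation for rare
#' peaks). Entries are clipped at zero.
#'
#' @param clusters A `peak_clusters` object.
#' @param spectra The (averaged, preprocessed) spectra of the same stream,
#'   one per sample.
#' @return An object of class `peak_matrix`: list with `intensity` (matrix,
#'   rows = samples, columns = clusters, dimnames set) and `clusters` (the
#'   cluster annotation table, with a `column` id "chip_massrange_mz").
#' @export
build_peak_matrix <- function(clusters, spectra) {
  cl <- clusters$clusters
  sample_ids <- vapply(spectra, function(s) s$sample_id, character(1))
  if (anyDuplicated(sample_ids)) {
    stop("expected one (averaged) spectrum per sample", call. = FALSE)
  }
  member_sids <- unique(clusters$members$sample_id)
  missing_sp <- setdiff(member_sids, sample_ids)
  if (length(missing_sp)) {
    stop("no spectrum in stream for sample(s): ",
         paste(missing_sp, collapse = ", "), call. = FALSE)
  }
  mat <- matrix(NA_real_, nrow = length(spectra), ncol = nrow(cl),
                dimnames = list(sample_ids, sprintf(
                  "%s_%s_%.2f", cl$chip, cl$mass_range, cl$consensus_mz)))
  m <- clusters$members
  if (nrow(m)) {
    mat[cbind(match(m$sample_id, sample_ids), m$cluster_id)] <- m$intensity
  }
  for (j in seq_len(ncol(mat))) {
    miss <- which(is.na(mat[, j]))
    for (i in miss) {
      s <- spectra[[i]]
      gi <- which.min(abs(s$mz - cl$consensus_mz[j]))
      mat[i, j] <- s$intensity[gi]
    }
  }
  mat[mat < 0] <- 0
  cl$column <- colnames(mat)
  structure(list(intensity = mat, clusters = cl), class = "peak_matrix")
}

#' Run detection, filtering, alignment and quantification for a cohort
#'
#' Convenience wrapper: per stream, detects and noise-filters peaks on every
#' averaged spectrum, aligns them by complete-linkage clustering, and builds
#' the peak matrix. The pipeline default keeps clusters supported by at least
#' `min_support_frac` of the stream's samples.
#'
#' @param spectra Averaged preprocessed spectra (all streams together).
#' @param smooth_half_window,noise_half_window,rel_tolerance See the
#'   stage functions.
#' @param min_support_frac Minimum fraction of samples supporting a reported
#'   cluster (default 0.25).
#' @return Named list (by stream) of `peak_matrix` objects.
#' @export
detect_cohort_peaks <- function(spectra, smooth_half_window = 2,
                                noise_half_window = 100, rel_tolerance = 0.008,
                                min_support_frac = 0.25) {
  keys <- vapply(spectra, stream_key, character(1))
  out <- list()
  for (k in unique(keys)) {
    strm <- spectra[keys == k]
    pks <- do.call(rbind, lapply(strm, function(s) {
      filter_peaks(detect_peaks(s, smooth_half_window), s, noise_half_window)
    }))
    min_support <- max(1L, ceiling(min_support_frac * length(strm)))
    cls <- cluster_peaks(pks, rel_tolerance, min_support = min_support)
    out[[k]] <- build_peak_matrix(cls, strm)
  }
  out
}
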