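#' Construct a mass spectrum
#'
#' A spectrum is a single (m/z, intensity) trace plus acquisition metadata:
#' which serum sample it came from, which replicate spot, which chip surface
#' (CM10 weak cation exchange or IMAC30 immobilized metal affinity) and which
#' acquisition mass range (low, < 10 kDa; high, 10-100 kDa).
#'
#' @param mz Strictly increasing numeric vector of m/z values (Da).
#' @param intensity Numeric vector of intensities, same length as `mz`.
#' @param sample_id Sample identifier.
#' @param replicate_id Replicate (spot) identifier within the sample.
#' @param chip Chip surface, one of `"CM10"`, `"IMAC30"`.
#' @param mass_range Acquisition range, one of `"low"`, `"high"`.
#' @param normalization_factor TIC normalization factor, `NA` until
#'   [normalize_tic()] has been applied.
#' @return An object of class `ms_spectrum`.
#' @export
ms_spectrum <- function(mz, intensity, sample_id = NA_character_,
                        replicate_id = NA_character_,
                        chip = c("CM10", "IMAC30"),
                        mass_range = c("low", "high"),
                        normalization_factor = NA_real_) {
  chip <- match.arg(chip)
  mass_range <- match.arg(mass_range)
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) < 2L || length(mz) != length(intensity)) {
    stop("'mz' and 'intensity' must have equal length >= 2", call. = FALSE)
  }
  if (any(diff(mz) <= 0)) {
    stop("'mz' must be strictly increasing", call. = FALSE)
  }
  structure(
    list(mz = mz, intensity = intensity,
         sample_id = as.character(sample_id),
         replicate_id = as.character(replicate_id),
         chip = chip, mass_range = mass_range,
         normalization_factor = normalization_factor),
    class = "ms_spectrum")
}

#' @export
print.ms_spectrum <- function(x, ...) {
  cat(sprintf(
    "<ms_spectrum> sample %s rep %s | %s/%s | %d points, m/z %.1f-%.1f\n",
    x$sample_id, x$replicate_id, x$chip, x$mass_range,
    length(x$mz), min(x$mz), max(x$mz)))
  invisible(x)
}

# stream key "CHIP_range", e.g. "CM10_low"; streams are processed separately
stream_key <- function(s) paste(s$chip, s$mass_range, sep = "_")

#' Spectrum identifier used in manifests and file names
#' @param s An `ms_spectrum`.
#' @return A character scalar.
#' @export
spectrum_id <- function(s) {
  paste(s$sample_id, stream_key(s), s$replicate_id, sep = "_")
}

#' Build a manifest table for a list of spectra
#'
#' @param spectra List of `ms_spectrum` objects.
#' @return A data.frame with one row per spectrum: spectrum_id, sample_id,
#'   replicate, chip, mass_range and the recorded normalization factor.
#' @export
spectra_manifest <- function(spectra) {
  data.frame(
    spectrum_id = vapply(spectra, spectrum_id, character(1)),
    sample_id = vapply(spectra, function(s) s$sample_id, character(1)),
    replicate = vapply(spectra, function(s) s$replicate_id, character(1)),
    chip = vapply(spectra, function(s) s$chip, character(1)),
    mass_range = vapply(spectra, function(s) s$mass_range, character(1)),
    normalization_factor = vapply(spectra,
      function(s) s$normalization_factor, numeric(1)),
    stringsAsFactors = FALSE)
}

#' Write spectra as one CSV per spectrum plus a manifest CSV
#'
#' Mirrors the study workflow of exporting numeric data to csv files for
#' downstream biostatistics: each trace is a two-column (mz, intensity) CSV
#' named after its spectrum id, and `manifest.csv` records the metadata.
#'
#' @param spectra List of `ms_spectrum` objects.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest data.frame.
#' @export
write_spectra <- function(spectra, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in spectra) {
    data.table::fwrite(data.frame(mz = s$mz, intensity = s$intensity),
                       file.path(dir, paste0(spectrum_id(s), ".csv")))
  }
  man <- spectra_manifest(spectra)
  data.table::fwrite(man, file.path(dir, "manifest.csv"))
  invisible(man)
}

#' Read spectra written by [write_spectra()]
#'
#' @param dir Directory containing per-spectrum CSVs and `manifest.csv`.
#' @return List of `ms_spectrum` objects in manifest order.
#' @export
read_spectra <- function(dir) {
  man_path <- file.path(dir, "manifest.csv")
  if (!file.exists(man_path)) stop("no manifest.csv in ", dir, call. = FALSE)
  man <- as.data.frame(data.table::fread(man_path))
  lapply(seq_len(nrow(man)), function(i) {
    tr <- as.data.frame(data.table::fread(
      file.path(dir, paste0(man$spectrum_id[i], ".csv"))))
    ms_spectrum(tr$mz, tr$intensity,
                sample_id = man$sample_id[i], replicate_id = man$replicate[i],
                chip = man$chip[i], mass_range = man$mass_range[i],
                normalization_factor =
                  if ("normalization_factor" %in% names(man))
                    man$normalization_factor[i] else NA_real_)
  })
}
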