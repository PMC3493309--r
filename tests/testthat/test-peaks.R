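grid_spec <- function(intensity, ...) ms_spectrum(seq_along(intensity),
                                                  intensity, ...)

test_that("first-derivative detection finds hand-constructed apexes", {
  pk <- detect_peaks(grid_spec(c(0, 1, 2, 1, 0)), smooth_half_window = 0)
  expect_equal(pk$index, 3)
  expect_equal(pk$intensity, 2)
  expect_equal(nrow(detect_peaks(grid_spec(1:50), 0)), 0)   # monotone
  # plateau between rise and fall reports the midpoint
  pk2 <- detect_peaks(grid_spec(c(0, 1, 2, 2, 2, 1, 0)), 0)
  expect_equal(pk2$index, 4)
  expect_error(detect_peaks(grid_spec(c(0, 1)), smooth_half_window = 3),
               "shorter")
})

test_that("well-separated noise-free Gaussians are each recovered on-grid", {
  sp <- spectrum_spec(c(1000, 10000), grid_size = 1200,
                      baseline_amplitude = 0, noise_sd = 0)
  s <- generate_spectrum(sp, list(planted_peak(2000, 60),
                                  planted_peak(6000, 40)), seed = 1)
  pk <- detect_peaks(s, smooth_half_window = 1)
  expect_equal(nrow(pk), 2)
  expect_lt(abs(pk$mz[1] - 2000) / 2000, 2 * diff(log(range(s$mz))) / 1200)
  expect_lt(abs(pk$mz[2] - 6000) / 6000, 2 * diff(log(range(s$mz))) / 1200)
})

test_that("the median + 5*MAD filter matches hand-computed thresholds", {
  # window (1,2,3,4,5,6,100): median 4, unscaled MAD 2, threshold 14
  s <- grid_spec(c(1, 2, 3, 4, 5, 6, 100))
  pk <- data.frame(mz = 7, intensity = 100, index = 7, sample_id = "a",
                   chip = "CM10", mass_range = "low")
  expect_equal(nrow(filter_peaks(pk, s, noise_half_window = 6)), 1)
  s2 <- grid_spec(c(1, 2, 3, 4, 5, 6, 12))
  pk2 <- transform(pk, intensity = 12)
  expect_equal(nrow(filter_peaks(pk2, s2, noise_half_window = 6)), 0)
  # flat window: MAD 0, threshold = c, strict > removes an apex equal to c
  s3 <- grid_spec(rep(5, 50))
  pk3 <- data.frame(mz = 25, intensity = 5, index = 25, sample_id = "a",
                    chip = "CM10", mass_range = "low")
  expect_equal(nrow(filter_peaks(pk3, s3, noise_half_window = 10)), 0)
  # 100-point unit window with a 10x apex: median 1, MAD 0, kept
  x <- rep(1, 101); x[51] <- 10
  pk4 <- data.frame(mz = 51, intensity = 10, index = 51, sample_id = "a",
                    chip = "CM10", mass_range = "low")
  expect_equal(nrow(filter_peaks(pk4, grid_spec(x), noise_half_window = 50)), 1)
})

test_that("clustering reproduces hand-worked complete-linkage fixtures", {
  one <- data.frame(mz = 1500, intensity = 1, sample_id = "a",
                    chip = "CM10", mass_range = "low")
  cl1 <- cluster_peaks(one, 0.003)
  expect_equal(nrow(cl1$clusters), 1)
  expect_equal(cl1$clusters$diameter, 0)

  three <- data.frame(mz = c(1000, 1000.5, 2000), intensity = 1,
                      sample_id = c("a", "b", "c"),
                      chip = "CM10", mass_range = "low")
  cl3 <- cluster_peaks(three, 0.003)
  expect_equal(partition_of(cl3), list(c(1000, 1000.5), 2000))

  # chain where the allowed diameter is ~4 Da: complete linkage yields two
  # 2-member clusters, never one 4-member cluster of diameter 6
  chain <- data.frame(mz = c(1000, 1002, 1004, 1006), intensity = 1,
                      sample_id = letters[1:4],
                      chip = "CM10", mass_range = "low")
  clc <- cluster_peaks(chain, 4 / 1003)
  expect_equal(partition_of(clc), list(c(1000, 1002), c(1004, 1006)))

  expect_equal(nrow(cluster_peaks(one[0, ], 0.003)$clusters), 0)
})

test_that("clustering equals brute-force complete linkage on random small sets", {
  set.seed(42)
  for (rep in 1:30) {
    n <- sample(2:10, 1)
    base <- exp(runif(1, log(1000), log(90000)))
    mz <- sort(base * (1 + cumsum(runif(n, 0, 0.004))))
    tol <- runif(1, 0.001, 0.01)
    pk <- data.frame(mz = mz, intensity = 1,
                     sample_id = paste0("s", seq_len(n)),
                     chip = "CM10", mass_range = "low")
    expect_equal(partition_of(cluster_peaks(pk, tol)),
                 brute_complete_linkage(mz, tol),
                 info = sprintf("case %d", rep))
  }
})

test_that("raising the tolerance never increases the cluster count", {
  set.seed(9)
  mz <- sort(exp(runif(40, log(1000), log(10000))))
  pk <- data.frame(mz = mz, intensity = 1,
                   sample_id = paste0("s", seq_along(mz)),
                   chip = "CM10", mass_range = "low")
  counts <- sapply(c(0.001, 0.003, 0.01, 0.03, 0.1),
                   function(t) nrow(cluster_peaks(pk, t)$clusters))
  expect_true(all(diff(counts) <= 0))
})

test_that("peak input order does not change the partition", {
  set.seed(10)
  mz <- exp(runif(25, log(1000), log(10000)))
  pk <- data.frame(mz = mz, intensity = runif(25),
                   sample_id = paste0("s", seq_along(mz)),
                   chip = "CM10", mass_range = "low")
  a <- cluster_peaks(pk, 0.01)
  b <- cluster_peaks(pk[sample(nrow(pk)), ], 0.01)
  expect_equal(a$clusters$consensus_mz, b$clusters$consensus_mz)
  expect_equal(partition_of(a), partition_of(b))
})

test_that("duplicate sample peaks in a cluster keep the most intense; support filter works", {
  pk <- data.frame(mz = c(1000, 1000.5, 1300), intensity = c(2, 9, 1),
                   sample_id = c("a", "a", "b"),
                   chip = "CM10", mass_range = "low")
  cl <- cluster_peaks(pk, 0.003)
  expect_equal(nrow(cl$clusters), 2)
  expect_equal(cl$members$intensity[cl$members$sample_id == "a"], 9)
  cl2 <- cluster_peaks(pk, 0.003, min_support = 2)
  expect_equal(nrow(cl2$clusters), 0)   # both clusters are single-sample
})

test_that("peak matrix entries follow the detection/re-quantification rule", {
  s1 <- grid_spec(c(0, 1, 5, 1, 0, 0, 2, 0.5, 0), sample_id = "A")
  s2 <- grid_spec(c(0, 1, 4, 1, 0, 0, 0.3, 0.2, 0), sample_id = "B")
  pk <- rbind(
    data.frame(mz = 3, intensity = 5, sample_id = "A", chip = "CM10",
               mass_range = "low"),
    data.frame(mz = 7, intensity = 2, sample_id = "A", chip = "CM10",
               mass_range = "low"),
    data.frame(mz = 3, intensity = 4, sample_id = "B", chip = "CM10",
               mass_range = "low"))
  cl <- cluster_peaks(pk, rel_tolerance = 0.1)
  pm <- build_peak_matrix(cl, list(s1, s2))
  expect_equal(dim(pm$intensity), c(2, 2))
  expect_equal(unname(pm$intensity["A", ]), c(5, 2))
  # sample B contributed no peak at m/z 7: local re-quantification from trace
  expect_equal(unname(pm$intensity["B", ]), c(4, 0.3))
  expect_error(build_peak_matrix(cl, list(s1)), "no spectrum")
})

test_that("a noise-free cohort yields exactly one matrix column per planted peak", {
  co <- small_cohort(seed = 2, noise_sd = 0)
  pp <- preprocess_cohort(co$spectra, baseline_half_window = 25)
  mats <- detect_cohort_peaks(pp$spectra, noise_half_window = 50)
  expect_equal(ncol(mats$CM10_low$intensity), 3)
  expect_equal(ncol(mats$IMAC30_low$intensity), 3)
  # consensus m/z within the alignment tolerance of the planted locations
  mz_found <- sort(mats$IMAC30_low$clusters$consensus_mz)
  expect_equal(mz_found, c(1500, 2700, 5000), tolerance = 0.01)
})
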