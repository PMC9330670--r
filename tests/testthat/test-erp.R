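test_that("noiseless waveforms round-trip to the planted peak parameters", {
  co <- extract_cohort_features(generate_waveforms(narrow_wave_config()),
                                min_epochs = 1)
  tp <- co$truth$waveform_params
  dt <- 1000 / 250
  for (i in seq_len(nrow(tp))) {
    r <- tp[i, ]
    row <- co$features[co$features$subject == r$subject, ]
    expect_lt(abs(row[[paste0(r$component, "_lat_", r$condition)]] - r$latency),
              dt / 2 + 1e-9)
    expect_lt(abs(row[[paste0(r$component, "_amp_", r$condition)]] - r$amplitude),
              0.05)
  }
})

test_that("scaling planted amplitudes scales extracted amplitudes", {
  cfgA <- narrow_wave_config(seed = 8)
  cfgB <- narrow_wave_config(seed = 8)
  cfgB$component_params$amplitude <- cfgB$component_params$amplitude * 2
  cfgB$component_params$amp_sd <- cfgB$component_params$amp_sd * 2
  fA <- extract_cohort_features(generate_waveforms(cfgA), min_epochs = 1)$features
  fB <- extract_cohort_features(generate_waveforms(cfgB), min_epochs = 1)$features
  cols <- grep("_amp_(FD|FA|F|N|SD|SA)$", names(fA), value = TRUE)
  expect_equal(as.matrix(fB[, cols]), 2 * as.matrix(fA[, cols]),
               tolerance = 0.02)
})

test_that("artifact rejection removes spikes and flags depleted sets", {
  co <- generate_waveforms(narrow_wave_config(n_epochs = 20))
  es <- co$epochs[[1]][[1]]
  clean <- reject_artifacts(es, 200, min_epochs = 10)
  expect_identical(dim(clean$data)[1], 20L) # all within threshold
  expect_identical(clean$flag, "ok")

  es$data[3, 1, 60] <- 500 # spike on a designated channel
  dropped <- reject_artifacts(es, 200, min_epochs = 10)
  expect_identical(dim(dropped$data)[1], 19L)

  es2 <- co$epochs[[2]][[1]]
  es2$data[1:12, 2, 10] <- 400 # 12 of 20 epochs exceed threshold
  flagged <- reject_artifacts(es2, 200, min_epochs = 10)
  expect_identical(dim(flagged$data)[1], 8L)
  expect_identical(flagged$flag, "too-few-epochs")

  empty <- es; empty$data <- es$data[0, , , drop = FALSE]
  expect_error(reject_artifacts(empty), "empty")
})

test_that("epoch averaging is the baseline-corrected pointwise mean", {
  time <- seq(-200, 800, by = 4)
  nt <- length(time)
  one <- array(rnorm(2 * nt), c(1, 2, nt))
  es1 <- epoch_set(one, time, 1)
  avg1 <- average_epochs(es1)
  manual <- one[1, , ] - rowMeans(one[1, , time <= 0])
  expect_equal(unclass(avg1)[, ], manual, ignore_attr = TRUE)

  x <- matrix(rnorm(2 * nt), 2, nt)
  x <- x - rowMeans(x[, time <= 0, drop = FALSE])
  sym <- array(0, c(2, 2, nt)); sym[1, , ] <- x; sym[2, , ] <- -x
  avg0 <- average_epochs(epoch_set(sym, time, 1))
  expect_lt(max(abs(avg0)), 1e-12)

  es0 <- epoch_set(sym, time, 1)
  es0$data <- es0$data[0, , , drop = FALSE]
  expect_error(average_epochs(es0), "epoch")
})

test_that("peak detection honors polarity, ties, windows and edge runs", {
  time <- seq(-200, 800, by = 4)
  bump <- 5 * exp(-0.5 * ((time - 120) / 20)^2)
  avg <- rbind(bump, bump)
  attr(avg, "time") <- time; attr(avg, "ot_channels") <- 1:2
  pk <- detect_peak(avg, component_windows()[1, ])
  expect_equal(pk$latency, 120)
  expect_equal(pk$amplitude, 5)
  expect_identical(pk$flag, "ok")

  mono <- rbind(time / 100, time / 100)
  attr(mono, "time") <- time; attr(mono, "ot_channels") <- 1:2
  expect_identical(detect_peak(mono, component_windows()[1, ])$flag, "no-peak")

  two <- matrix(0, 2, length(time))
  two[, time == 112] <- 5; two[, time == 132] <- 5
  attr(two, "time") <- time; attr(two, "ot_channels") <- 1:2
  expect_equal(detect_peak(two, component_windows()[1, ])$latency, 112)

  w <- component_windows()[1, ]; w$lo <- -300
  expect_error(detect_peak(avg, w), "window")

  # negative polarity picks the minimum
  navg <- -avg
  attr(navg, "time") <- time; attr(navg, "ot_channels") <- 1:2
  wn <- component_windows()[2, ]; wn$lo <- 70; wn$hi <- 170
  pkn <- detect_peak(navg, wn)
  expect_equal(pkn$amplitude, -5)
})

test_that("feature extraction propagates flags and computes exact contrasts", {
  co <- generate_waveforms(narrow_wave_config(seed = 13))
  windows <- component_windows()
  averages <- lapply(co$epochs[[1]], average_epochs)

  # identical toward/away averages zero every TvA contrast
  averages2 <- averages
  averages2$SA <- averages2$SD
  row <- extract_features(averages2, windows)
  expect_true(all(row[grep("TvA", names(row))] == 0))

  # flagged noise condition wipes the face-noise contrasts
  averages3 <- averages
  averages3$N <- NA
  row3 <- extract_features(averages3, windows)
  expect_true(all(is.na(row3[grep("FvN", names(row3))])))
  expect_true(all(is.na(row3[grep("_N$", names(row3))])))
  expect_false(anyNA(row3[grep("_FD$", names(row3))]))

  # contrast consistency under noise
  cfg <- narrow_wave_config(noise_sd = 3, n_epochs = 10, seed = 17)
  f <- extract_cohort_features(generate_waveforms(cfg), min_epochs = 1)$features
  expect_equal(f$N290_lat_FvN, f$N290_lat_F - f$N290_lat_N)
  expect_equal(f$P400_amp_DvA, f$P400_amp_FD - f$P400_amp_FA)
})

test_that("averaging epochs attenuates latency noise", {
  lat_err <- function(n_epochs, seed) {
    cfg <- narrow_wave_config(n_per_group = c("TL" = 3, "EL-noASD" = 0, "EL-ASD" = 0),
                              noise_sd = 5, n_epochs = n_epochs, seed = seed)
    co <- extract_cohort_features(generate_waveforms(cfg), min_epochs = 1)
    tp <- co$truth$waveform_params
    errs <- vapply(seq_len(nrow(tp)), function(i) {
      r <- tp[i, ]
      abs(co$features[co$features$subject == r$subject,
                      paste0(r$component, "_lat_", r$condition)] - r$latency)
    }, numeric(1))
    mean(errs)
  }
  few <- mean(vapply(1:3, function(s) lat_err(4, s), numeric(1)))
  many <- mean(vapply(1:3, function(s) lat_err(50, s), numeric(1)))
  expect_lte(many, few + 0.5)
})
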