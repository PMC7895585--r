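sineRecording <- function(freqs, fs = 250, secs = 10,
                          labels = c("C3", "C4")) {
  t <- seq(0, secs - 1 / fs, by = 1 / fs)
  data <- do.call(rbind, lapply(freqs, function(f)
    if (f == 0) rep(1, length(t)) else sin(2 * pi * f * t)))
  new("Recording", data = data, labels = labels, fs = fs)
}

test_that("recordings round-trip through CSV and EDF", {
  rec <- simulateTrial(tinyConfig(), "RH")
  csv <- tempfile(fileext = ".csv")
  writeRecording(rec, csv, format = "csv")
  back <- readRecording(csv, fs = samplingRate(rec))
  expect_equal(channelLabels(back), channelLabels(rec))
  expect_equal(recData(back), recData(rec), tolerance = 1e-7)
  expect_equal(dim(recData(back)), c(60, 2500))

  edf <- tempfile(fileext = ".edf")
  writeRecording(rec, edf, format = "edf")
  backE <- readRecording(edf)
  expect_equal(channelLabels(backE), channelLabels(rec))
  expect_equal(samplingRate(backE), 250)
  expect_equal(taskLabel(backE), "RH")
  # 16-bit quantisation: error bounded by one digital step per channel
  step <- apply(recData(rec), 1, function(x) diff(range(x))) / 65535
  err <- abs(recData(backE) - recData(rec))
  expect_true(all(err <= step + 1e-9))
})

test_that("reading rejects labels outside the montage", {
  bad <- tempfile(fileext = ".csv")
  writeLines(c("C3,XX9", "1,2,3", "4,5,6"), bad)
  expect_error(readRecording(bad, fs = 250), "XX9")
  expect_error(readRecording(tempfile(fileext = ".csv"), fs = 250),
               "not found")
  ok <- tempfile(fileext = ".csv")
  writeLines(c("C3,C4", "1,2,3", "4,5,6"), ok)
  expect_error(readRecording(ok), "fs")
})

test_that("mu band-pass keeps 10 Hz, rejects 40 Hz and DC", {
  rec <- sineRecording(c(10, 40, 0), labels = c("C3", "C4", "Cz"))
  out <- bandpassMu(rec)
  trim <- 126:2375  # discard 0.5 s of edge transient each side
  inRms <- apply(recData(rec)[, trim], 1, function(x) sqrt(mean(x^2)))
  outRms <- apply(recData(out)[, trim], 1, function(x) sqrt(mean(x^2)))
  expect_equal(outRms[1] / inRms[1], 1, tolerance = 0.05)  # passband
  expect_lt(outRms[2] / inRms[2], 0.10)                    # stopband
  expect_lt(outRms[3], 1e-3)                               # DC removed
  expect_equal(dim(recData(out)), dim(recData(rec)))
  expect_error(bandpassMu(rec, 8, 200), "infeasible band")
})

test_that("stopband rejection matches the designed filter response", {
  # forward-backward filtering applies |H(f)|^2; compare measured
  # attenuation just above the band with the designed Butterworth
  # magnitude (deeper in the stopband, edge transients dominate the
  # residual and the steady-state response is unobservable)
  fs <- 250
  bf <- signal::butter(4, c(8, 13) / (fs / 2), type = "pass")
  H <- signal::freqz(bf$b, bf$a, Fs = fs)
  trim <- 126:2375
  for (f0 in c(15, 16)) {
    expected <- Mod(H$h[which.min(abs(H$f - f0))])^2
    rec <- sineRecording(f0, labels = "C3")
    out <- bandpassMu(rec)
    measured <- sqrt(mean(recData(out)[1, trim]^2)) /
      sqrt(mean(recData(rec)[1, trim]^2))
    expect_lt(abs(log10(measured / expected)), 0.15)
  }
})

test_that("stage extraction slices half-open windows and keeps labels", {
  rec <- simulateTrial(tinyConfig(), "S")
  expect_equal(ncol(recData(extractStage(rec, "imagery"))), 1000)
  expect_equal(ncol(recData(extractStage(rec, "rest"))), 500)
  expect_equal(ncol(recData(extractStage(rec, "preparation"))), 750)
  whole <- extractStage(rec, c(0, 10))
  expect_equal(recData(whole), recData(rec))
  expect_equal(channelLabels(extractStage(rec, "imagery")),
               channelLabels(rec))
  expect_error(extractStage(rec, c(8, 12)), "outside")
  expect_error(extractStage(rec, "warmup"), "unknown stage")
})

test_that("the pipeline order is filter first, then slice", {
  rec <- simulateTrial(tinyConfig(), "S")
  seg <- extractStage(bandpassMu(rec), "imagery")
  h <- processingHistory(seg)
  expect_lt(grep("bandpass", h), grep("slice", h))
})

test_that("artifact hook defaults to identity", {
  rec <- simulateTrial(tinyConfig(), "S")
  expect_identical(recData(removeArtifacts(rec)), recData(rec))
  flip <- function(r) { r@data <- -r@data; r }
  expect_identical(recData(removeArtifacts(rec, flip)), -recData(rec))
})
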