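test_that("noise-free isobaric simulation encodes inhibition exactly", {
  pe <- simulateIsobaricPsms(tinyDesign(), tinyTruth(c(0.75, 0.9)),
                             noiselessModel(), seed = 1)
  snr <- assay(pe, "snr")
  expect_true(all(snr[, "c1"] == snr[, "c2"]))
  expect_equal(snr[, "t1"], 0.25 * snr[, "c1"], tolerance = 1e-12)
  expect_equal(snr[, "t2"], 0.10 * snr[, "c1"], tolerance = 1e-12)
})

test_that("generators are pure functions of parameters and seed", {
  d <- tinyDesign(); tr <- tinyTruth()
  a <- simulateIsobaricPsms(d, tr, noiseModel(), seed = 42)
  b <- simulateIsobaricPsms(d, tr, noiseModel(), seed = 42)
  expect_equal(assay(a, "snr"), assay(b, "snr"))
  expect_false(isTRUE(all.equal(
    assay(a, "snr"),
    assay(simulateIsobaricPsms(d, tr, noiseModel(), seed = 43), "snr"))))
  r1 <- simulateDimethylRatios(data.frame(protein = "P", ratio = 4),
                               seed = 9)
  r2 <- simulateDimethylRatios(data.frame(protein = "P", ratio = 4),
                               seed = 9)
  expect_equal(r1, r2)
  # the caller's RNG stream is untouched
  set.seed(123); before <- runif(1)
  set.seed(123)
  invisible(simulateIsobaricPsms(d, tr, noiseModel(), seed = 42))
  expect_equal(runif(1), before)
})

test_that("simulation requires control channels", {
  bad <- experimentDesign(c("a", "b"), c("control", "treatment"),
                          c(NA, 1e-6))
  expect_error(simulateIsobaricPsms(bad, tinyTruth()), "control channels")
})

test_that("spectra round-trip through extraction at zero jitter", {
  pe <- simulateIsobaricPsms(tinyDesign(), tinyTruth(), noiselessModel(),
                             seed = 2)
  pk <- simulateSpectra(pe, jitterSd = 0, decoyDensity = 0, seed = 3)
  back <- psmExperimentFromPeaks(
    pk, as.data.frame(rowData(pe)), tinyDesign())
  expect_equal(assay(back, "snr"), assay(pe, "snr"), tolerance = 1e-12)
  expect_equal(assay(back, "intensity"), assay(pe, "intensity"),
               tolerance = 1e-12)
})

test_that("decoys outside the window do not perturb extraction", {
  pe <- simulateIsobaricPsms(tinyDesign(), tinyTruth(), noiselessModel(),
                             seed = 2)
  pk <- simulateSpectra(pe, jitterSd = 0, decoyDensity = 0, seed = 3)
  id <- pk$spectrum_id[1]
  # a decoy 0.005 Th from the first reporter: outside +/- 0.001
  far <- rbind(pk, data.frame(spectrum_id = id,
                              mz = tinyDesign()$reporter_mz[1] + 0.005,
                              intensity = 1e9, noise = 1))
  back <- psmExperimentFromPeaks(far, as.data.frame(rowData(pe)),
                                 tinyDesign())
  expect_equal(assay(back, "snr"), assay(pe, "snr"), tolerance = 1e-12)
})

test_that("an in-window, more intense decoy is picked by design", {
  pe <- simulateIsobaricPsms(tinyDesign(), tinyTruth(), noiselessModel(),
                             seed = 2)
  pk <- simulateSpectra(pe, jitterSd = 0, decoyDensity = 0, seed = 3)
  id <- rowData(pe)$spectrum_id[1]
  mz1 <- tinyDesign()$reporter_mz[1]
  true_int <- assay(pe, "intensity")[1, 1]
  near <- rbind(pk, data.frame(spectrum_id = id, mz = mz1 + 0.0009,
                               intensity = 10 * true_int, noise = 1))
  back <- psmExperimentFromPeaks(near, as.data.frame(rowData(pe)),
                                 tinyDesign())
  expect_equal(assay(back, "intensity")[1, 1], 10 * true_int)
})

test_that("zero-sigma dimethyl ratios equal the truth", {
  tr <- data.frame(protein = c("A", "B"), ratio = c(4, 0.5))
  out <- simulateDimethylRatios(tr, nPeptides = 5, sigma = 0, seed = 1)
  expect_equal(out$ratio, rep(c(4, 0.5), each = 5))
  expect_true(all(out$unique))
})

test_that("zero-sigma dose-response data sit exactly on the curve", {
  p <- list(bottom = 0, top = 100, hill = 1, ic50 = 1.6e-9)
  conc <- 10^seq(-10.5, -6.5, length.out = 8)
  y <- simulateDoseResponse(p, conc, sigmaAbs = 0, seed = 1)
  expect_equal(y$response_percent,
               100 / (1 + 10^((log10(1.6e-9) - log10(conc)) * 1)),
               tolerance = 1e-12)
})

test_that("zero-sigma MRM batches invert exactly and spike amount cancels", {
  ta <- data.frame(sample = "s1", species = c("9-PAHSA", "12-OAHSA"),
                   family = c("PAHSA", "OAHSA"), amount_pmol = c(5, 2))
  sp <- data.frame(sample = "s1",
                   standard = c("13C16-9-PAHSA", "13C18-12-OAHSA"),
                   family = c("PAHSA", "OAHSA"), amount_pmol = c(10, 10))
  sm <- data.frame(sample = "s1", normalizer = 1, unit = "mg")
  rf <- c(PAHSA = 2000, OAHSA = 1500)
  batch <- simulateMrmBatch(ta, sp, rf, sm, sigma = 0, seed = 1)
  got <- quantifyLipids(batch$measurements, batch$spikes, batch$samples)
  expect_equal(got$amount, c(5, 2), tolerance = 1e-12)
  # doubling the spike amount doubles IS area too: amounts are invariant
  sp2 <- sp; sp2$amount_pmol <- sp$amount_pmol * 2
  batch2 <- simulateMrmBatch(ta, sp2, rf, sm, sigma = 0, seed = 1)
  got2 <- quantifyLipids(batch2$measurements, batch2$spikes,
                         batch2$samples)
  expect_equal(got2$amount, got$amount, tolerance = 1e-12)
})
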