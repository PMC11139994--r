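test_that("channel normalization equalizes summed SNR to the grand mean", {
  snr <- matrix(c(10, 40, 50,    # channel sums: 100, 200
                  40, 60, 100), ncol = 2)
  d <- experimentDesign(c("a", "b"), c("control", "treatment"),
                        c(NA, 1e-6))
  pe <- peFromSnr(snr, d, peptide = sprintf("PEP%d", 1:3))
  out <- assay(normalizeChannels(pe), "snr")
  expect_equal(colSums(out), c(a = 150, b = 150))
  expect_equal(out[, "a"], snr[, 1] * 1.5)
  expect_equal(out[, "b"], snr[, 2] * 0.75)
  # already-equal sums: identity transform
  eq <- peFromSnr(matrix(c(1, 2, 2, 1), ncol = 2), d,
                  peptide = c("P1", "P2"))
  expect_equal(assay(normalizeChannels(eq), "snr"), assay(eq, "snr"))
})

test_that("normalization is idempotent and exact on random tables", {
  set.seed(31)
  for (i in 1:5) {
    snr <- matrix(rlnorm(80, 3, 1), ncol = 4)
    pe <- peFromSnr(snr)
    once <- normalizeChannels(pe)
    sums <- colSums(assay(once, "snr"))
    expect_lt(max(abs(sums - mean(colSums(snr)))) /
                mean(colSums(snr)), 1e-9)
    expect_equal(assay(normalizeChannels(once), "snr"),
                 assay(once, "snr"), tolerance = 1e-12)
  }
  zero <- peFromSnr(matrix(c(0, 0, 1, 1, 1, 1, 1, 1), ncol = 4))
  expect_error(normalizeChannels(zero), "c1")
})

test_that("PSM filters remove exactly the CV and mean-SNR violations", {
  # controls (10, 30): sample sd 14.142, mean 20 -> CV 0.707 > 0.5
  snr <- rbind(
    c(10, 30, 100, 100),   # removed: control CV
    c(1.9, 1.9, 1.9, 1.9), # removed: mean SNR 1.9 < 2
    c(100, 100, 50, 50),   # kept: CV 0, mean 75
    c(20, 20, 1, 1))       # kept: CV 0, mean 10.5
  pe <- peFromSnr(snr)
  out <- filterPsms(pe)
  expect_equal(nrow(out), 2)
  log <- metadata(out)$rejections
  expect_setequal(log$rule, c("cv", "mean_snr"))
  expect_equal(log$spectrum_id[log$rule == "cv"], "S001")
  # hand CV check against the documented n-1 convention
  expect_equal(sd(c(10, 30)) / mean(c(10, 30)), 0.7071068,
               tolerance = 1e-6)
})

test_that("protein rollup divides mean control sum by channel sums", {
  d <- tinyDesign()
  # single PSM: controls (100, 100), treatment 25 -> ratio 4
  pe <- peFromSnr(matrix(c(100, 100, 25, 100), nrow = 1), d)
  r <- proteinRatios(pe)
  expect_equal(r$raw_ratio[r$channel == "t1"], 4)
  # 3 PSMs with control sums (120, 80), treatment sum 50 -> 100/50 = 2
  snr <- rbind(c(60, 30, 20, 10), c(40, 30, 20, 10), c(20, 20, 10, 10))
  pe <- peFromSnr(snr, d, peptide = sprintf("PEP%d", 1:3))
  r <- proteinRatios(pe)
  expect_equal(r$raw_ratio[r$channel == "t1"], 100 / 50)
  # zero treatment channel -> infinite raw ratio
  pe <- peFromSnr(matrix(c(10, 10, 0, 10), nrow = 1), d)
  expect_equal(proteinRatios(pe)$raw_ratio[1], Inf)
})

test_that("rollup matches a brute-force recomputation on random tables", {
  set.seed(77)
  d <- tinyDesign()
  snr <- matrix(rlnorm(120, 3, 1), ncol = 4)
  prot <- sample(c("A", "B", "C"), 30, replace = TRUE)
  pe <- peFromSnr(snr, d, protein = prot,
                  peptide = sprintf("PEP%02d", 1:30))
  r <- proteinRatios(pe)
  for (p in c("A", "B", "C")) {
    sub <- snr[prot == p, , drop = FALSE]
    ctrlFig <- mean(c(sum(sub[, 1]), sum(sub[, 2])))
    expect_equal(r$raw_ratio[r$protein == p & r$channel == "t1"],
                 ctrlFig / sum(sub[, 3]), tolerance = 1e-12)
    expect_equal(r$raw_ratio[r$protein == p & r$channel == "t2"],
                 ctrlFig / sum(sub[, 4]), tolerance = 1e-12)
  }
})

test_that("capping and percent conversion follow the stated convention", {
  out <- capAndPercent(c(1, 4, 32, 100, Inf))
  expect_equal(out$capped_ratio, c(1, 4, 32, 32, 32))
  expect_equal(out$percent_competition,
               c(0, 75, 96.875, 96.875, 96.875))
  # sub-unity ratios clip at 0 percent
  expect_equal(capAndPercent(0.5)$percent_competition, 0)
  # monotone: ordered ratios give ordered percents
  r <- sort(rlnorm(50, 0, 1.5))
  expect_false(is.unsorted(capAndPercent(r)$percent_competition))
})

test_that("reporting rule and exception list behave as specified", {
  res <- data.frame(
    protein = c("P2u", "P3n", "P3y", "AIG1"),
    n_peptides = c(2, 3, 3, 1), n_unique = c(2, 0, 1, 1),
    stringsAsFactors = FALSE)
  out <- reportingFilter(res, exceptions = "AIG1")
  expect_equal(out$reported, c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(out$exception, c(FALSE, FALSE, FALSE, TRUE))
})

test_that("noise-free end-to-end recovery is exact: percent = 100 * phi", {
  phis <- c(0.1, 0.5, 0.75, 0.9, 1 - 1 / 32)
  d <- experimentDesign(
    c("c1", "c2", paste0("t", seq_along(phis))),
    c("control", "control", rep("treatment", length(phis))),
    c(NA, NA, 10^seq(-9, -5, length.out = length(phis))))
  pe <- simulateIsobaricPsms(
    d, groundTruth(
      data.frame(protein = "P1", n_peptides = 5, psms_per_peptide = 2L,
                 unique_fraction = 1),
      inhibition = matrix(phis, nrow = 1)),
    noiselessModel(), seed = 1)
  res <- proteinCompetition(pe, normalize = FALSE)
  expect_equal(res$percent_competition,
               100 * phis, tolerance = 1e-9)
  # capping engages exactly at ratio 32: phi beyond 1 - 1/32 saturates
  pe2 <- simulateIsobaricPsms(
    d, groundTruth(
      data.frame(protein = "P1", n_peptides = 5, psms_per_peptide = 2L,
                 unique_fraction = 1),
      inhibition = matrix(c(0.97, 0.99, 1, 1, 1), nrow = 1)),
    noiselessModel(), seed = 1)
  res2 <- proteinCompetition(pe2, normalize = FALSE)
  expect_true(all(res2$capped_ratio == 32))
  expect_true(all(res2$percent_competition == 96.875))
})

test_that("stochastic recovery stays within the calibrated tolerance", {
  # log-normal sigma 0.3, 10 peptides x 3 PSMs, phi = 0.9:
  # the pipeline should land within +/- 5 percent-competition points
  d <- tinyDesign()
  errs <- vapply(1:25, function(s) {
    pe <- simulateIsobaricPsms(
      d, groundTruth(
        data.frame(protein = "P1", n_peptides = 10,
                   psms_per_peptide = 3L, unique_fraction = 1),
        inhibition = matrix(c(0.9, 0.9), nrow = 1)),
      noiseModel(psmSigma = 1, channelSigma = 0.3), seed = s)
    res <- proteinCompetition(pe, normalize = FALSE)
    mean(abs(res$percent_competition - 90))
  }, numeric(1))
  expect_lte(median(errs), 5)
})
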