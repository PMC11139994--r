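# run code under a fixed RNG state, restoring the caller's state after,
# so every generator is a pure function of (parameters, seed)
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Construct a ground truth for simulated competition experiments
#'
#' @param proteins data.frame with columns \code{protein},
#'   \code{n_peptides}, \code{psms_per_peptide}, \code{unique_fraction}
#'   and, when no inhibition matrix is given, \code{ic50} (molar) and
#'   \code{hill}. Missing bookkeeping columns get defaults (3 PSMs per
#'   peptide, all peptides unique).
#' @param inhibition Optional matrix (protein x treatment channel) of true
#'   fractional inhibition in [0, 1]; overrides ic50 curves.
#' @return A [GroundTruth-class] object.
#' @export
groundTruth <- function(proteins, inhibition = NULL) {
  if (is.null(proteins$psms_per_peptide)) proteins$psms_per_peptide <- 3L
  if (is.null(proteins$unique_fraction)) proteins$unique_fraction <- 1
  if (is.null(inhibition)) inhibition <- matrix(numeric(0), 0, 0)
  new("GroundTruth", proteins = proteins, inhibition = inhibition)
}

#' @describeIn groundTruth True fractional inhibition per protein and
#'   treatment channel, either the stored matrix or logistic curves
#'   \code{1 / (1 + (ic50 / conc)^hill)} evaluated at each treatment
#'   channel's concentration (ic50 = NA means a fully unaffected protein).
#' @param truth A [GroundTruth-class] object.
#' @param design An [experimentDesign()] data.frame.
#' @export
inhibitionMatrix <- function(truth, design) {
  trt <- design[design$role == "treatment", , drop = FALSE]
  p <- truth@proteins
  if (length(truth@inhibition)) {
    m <- truth@inhibition
    stopifnot(ncol(m) == nrow(trt))
  } else {
    m <- t(vapply(seq_len(nrow(p)), function(i) {
      if (is.na(p$ic50[i])) return(rep(0, nrow(trt)))
      1 / (1 + (p$ic50[i] / trt$concentration_M)^p$hill[i])
    }, numeric(nrow(trt))))
  }
  dimnames(m) <- list(p$protein, trt$channel)
  m
}

#' Construct a reporter noise model
#'
#' @param psmSigma Log-normal sigma of per-PSM base abundance (how spread
#'   peptide signals are; default 1, a realistic order-of-magnitude spread).
#' @param channelSigma Log-normal sigma of per-measurement multiplicative
#'   noise (default 0.3, typical of MS3 reporter scatter).
#' @param baseMeanlog Mean log base intensity (default log(2e4)).
#' @param noiseMeanlog,noiseSigma Reporter noise-floor log-normal
#'   parameters (defaults log(100), 0.25).
#' @param channelBias Per-channel loading factors (default 1 = equal
#'   loading).
#' @return A [NoiseModel-class] object. \code{noiseModel(0, 0, noiseSigma
#'   = 0)} is the exactly noise-free model used for round-trip identities.
#' @export
noiseModel <- function(psmSigma = 1, channelSigma = 0.3,
                       baseMeanlog = log(2e4), noiseMeanlog = log(100),
                       noiseSigma = 0.25, channelBias = 1) {
  new("NoiseModel", psmSigma = psmSigma, channelSigma = channelSigma,
      baseMeanlog = baseMeanlog, noiseMeanlog = noiseMeanlog,
      noiseSigma = noiseSigma, channelBias = channelBias)
}

#' Simulate an isobaric competition PSM table
#'
#' Generates PSM-level reporter intensities with known ground truth. Per
#' PSM p and channel c:
#' \deqn{intensity = base_p \times bias_c \times (1 - \phi_{prot(p),c})
#'   \times e^{\epsilon}, \quad \epsilon \sim N(0, channelSigma^2)}
#' with \eqn{\phi = 0} in control channels, base abundance log-normal
#' around \code{baseMeanlog}, reporter noise values drawn from the noise
#' floor, and SNR = intensity / noise. Deterministic for a fixed seed.
#'
#' @param design [experimentDesign()] data.frame with >= 2 control
#'   channels.
#' @param truth A [GroundTruth-class] object.
#' @param noise A [NoiseModel-class] object.
#' @param seed Integer seed.
#' @return A [PsmExperiment-class] with assays \code{intensity},
#'   \code{noise}, \code{snr}; the truth and design are kept in
#'   \code{metadata()}.
#' @export
simulateIsobaricPsms <- function(design, truth, noise = noiseModel(),
                                 seed = 1) {
  stopifnot(is(truth, "GroundTruth"), is(noise, "NoiseModel"))
  if (sum(design$role == "control") < 2)
    stop("design must have at least 2 control channels")
  p <- truth@proteins
  inh <- inhibitionMatrix(truth, design)
  nch <- nrow(design)
  bias <- rep_len(noise@channelBias, nch)

  rows <- do.call(rbind, lapply(seq_len(nrow(p)), function(i) {
    npep <- p$n_peptides[i]
    nuniq <- round(p$unique_fraction[i] * npep)
    pep <- sprintf("%s_PEP%02d", p$protein[i], seq_len(npep))
    data.frame(
      protein = p$protein[i],
      peptide = rep(pep, each = p$psms_per_peptide[i]),
      unique = rep(seq_len(npep) <= nuniq, each = p$psms_per_peptide[i]),
      stringsAsFactors = FALSE)
  }))
  rows$spectrum_id <- sprintf("SPEC%05d", seq_len(nrow(rows)))
  npsm <- nrow(rows)

  # survival fraction per PSM x channel: 1 for controls, 1 - phi otherwise
  surv <- matrix(1, npsm, nch, dimnames = list(NULL, design$channel))
  surv[, colnames(inh)] <- inh[rows$protein, , drop = FALSE]
  surv[, colnames(inh)] <- 1 - surv[, colnames(inh)]

  withSeed(seed, {
    base <- rlnorm(npsm, noise@baseMeanlog, noise@psmSigma)
    eps <- matrix(rlnorm(npsm * nch, 0, noise@channelSigma), npsm, nch)
    intensity <- base * sweep(surv * eps, 2, bias, "*")
    nz <- matrix(rlnorm(npsm * nch, noise@noiseMeanlog, noise@noiseSigma),
                 npsm, nch)
    dimnames(intensity) <- dimnames(nz) <- list(NULL, design$channel)
    pe <- PsmExperiment(snr = intensity / nz, rowData = rows,
                        design = design, intensity = intensity, noise = nz)
    metadata(pe)$truth <- truth
    pe
  })
}

#' Named selectivity archetypes for demonstration truths
#'
#' A qualitative mouse-brain-like selectivity table: one high-potency
#' primary target (an AIG1-like hydrolase, low-nM IC50, few peptides — the
#' reason the reporting-filter exception exists), a handful of partially
#' inhibited off-targets (an ABHD6-like hydrolase and homologous
#' carboxylesterases, as carbamates typically show), and an unaffected
#' background proteome. Illustrative structure only; no measured values.
#'
#' @param nBackground Number of unaffected background proteins.
#' @return A [GroundTruth-class] object with ic50/hill curves.
#' @export
selectivityTruth <- function(nBackground = 20) {
  targets <- data.frame(
    protein = c("AIG1", "ABHD6", "CES1C", "CES1D"),
    n_peptides = c(2L, 8L, 10L, 9L),
    psms_per_peptide = 3L,
    unique_fraction = c(1, 1, 0.8, 0.8),
    ic50 = c(2e-9, 5e-7, 2e-6, 5e-6),
    hill = 1, stringsAsFactors = FALSE)
  bg <- data.frame(
    protein = sprintf("BG%03d", seq_len(nBackground)),
    n_peptides = 6L, psms_per_peptide = 3L, unique_fraction = 1,
    ic50 = NA_real_, hill = 1, stringsAsFactors = FALSE)
  groundTruth(rbind(targets, bg))
}

#' Simulate centroided MS3 peak lists from a PSM table
#'
#' Writes one peak list per PSM: a reporter peak per channel at the
#' channel's expected m/z plus Gaussian jitter, carrying the table's
#' intensity and noise values, plus uniformly scattered decoy peaks.
#' Running [extractReporters()] on the output with matching windows
#' reproduces the input SNR table whenever decoys fall outside windows.
#'
#' @param pe A [PsmExperiment-class] with \code{intensity} and \code{noise}
#'   assays and \code{reporter_mz} in its design.
#' @param jitterSd Gaussian m/z jitter SD in Th (keep below 0.001 Th so
#'   true peaks stay inside a 0.002 Th-wide window).
#' @param decoyDensity Expected decoy peaks per Th across the reporter
#'   region.
#' @param mzRange Reporter region covered by decoys.
#' @param seed Integer seed.
#' @return data.frame with \code{spectrum_id}, \code{mz},
#'   \code{intensity}, \code{noise}, sorted by spectrum then m/z.
#' @export
simulateSpectra <- function(pe, jitterSd = 0, decoyDensity = 0,
                            mzRange = c(125.5, 135.0), seed = 1) {
  stopifnot(is(pe, "PsmExperiment"),
            all(c("intensity", "noise") %in% assayNames(pe)))
  d <- psmDesign(pe)
  if (any(is.na(d$reporter_mz)))
    stop("design lacks reporter_mz for some channels")
  ids <- rowData(pe)$spectrum_id
  inten <- assay(pe, "intensity"); nz <- assay(pe, "noise")
  withSeed(seed, {
    n <- length(ids) * nrow(d)
    rep_pk <- data.frame(
      spectrum_id = rep(ids, times = nrow(d)),
      mz = rep(d$reporter_mz, each = length(ids)) + rnorm(n, 0, jitterSd),
      intensity = as.vector(inten), noise = as.vector(nz),
      stringsAsFactors = FALSE)
    pk <- rep_pk
    if (decoyDensity > 0) {
      lam <- decoyDensity * diff(mzRange)
      ndec <- rpois(length(ids), lam)
      if (sum(ndec) > 0) {
        dec <- data.frame(
          spectrum_id = rep(ids, ndec),
          mz = runif(sum(ndec), mzRange[1], mzRange[2]),
          intensity = rlnorm(sum(ndec), log(500), 1),
          noise = rlnorm(sum(ndec), log(100), 0.25),
          stringsAsFactors = FALSE)
        pk <- rbind(pk, dec)
      }
    }
    pk <- pk[order(pk$spectrum_id, pk$mz), , drop = FALSE]
    rownames(pk) <- NULL
    pk
  })
}

#' Simulate a dimethyl (light/heavy) peptide-ratio table
#'
#' Peptide-level heavy-vs-light ratios around each protein's true ratio
#' under multiplicative log-normal noise.
#'
#' @param truth data.frame with columns \code{protein}, \code{ratio}
#'   (true fold change, > 0).
#' @param nPeptides Peptides per protein.
#' @param uniqueFraction Fraction of peptides flagged unique.
#' @param sigma Log-normal sigma of peptide-level scatter.
#' @param seed Integer seed.
#' @return data.frame(\code{protein}, \code{peptide}, \code{unique},
#'   \code{ratio}).
#' @export
simulateDimethylRatios <- function(truth, nPeptides = 10,
                                   uniqueFraction = 1, sigma = 0.25,
                                   seed = 1) {
  stopifnot(all(truth$ratio > 0))
  withSeed(seed, {
    rows <- do.call(rbind, lapply(seq_len(nrow(truth)), function(i) {
      nuniq <- round(uniqueFraction * nPeptides)
      data.frame(
        protein = truth$protein[i],
        peptide = sprintf("%s_PEP%02d", truth$protein[i],
                          seq_len(nPeptides)),
        unique = seq_len(nPeptides) <= nuniq,
        ratio = truth$ratio[i] * rlnorm(nPeptides, 0, sigma),
        stringsAsFactors = FALSE)
    }))
    rownames(rows) <- NULL
    rows
  })
}

#' Simulate a densitometry dose-response series
#'
#' Evaluates the four-parameter logistic at each concentration and adds
#' Gaussian noise on the percent-activity scale (additive, as gel
#' densitometry noise is; values may dip slightly below zero as real gels
#' do).
#'
#' @param params Named list/vector with \code{bottom}, \code{top},
#'   \code{hill}, \code{ic50} (molar).
#' @param concentrations Molar concentrations (> 0).
#' @param sigmaAbs Gaussian SD in percent-activity units.
#' @param seed Integer seed.
#' @return data.frame(\code{concentration_M}, \code{response_percent}).
#' @export
simulateDoseResponse <- function(params, concentrations, sigmaAbs = 0,
                                 seed = 1) {
  stopifnot(all(concentrations > 0))
  y <- fourPL(concentrations, params[["bottom"]], params[["top"]],
              params[["hill"]], params[["ic50"]])
  withSeed(seed, data.frame(
    concentration_M = concentrations,
    response_percent = y + rnorm(length(y), 0, sigmaAbs)))
}

#' Simulate an MRM peak-area batch with internal-standard spikes
#'
#' Peak area = amount x family response factor x log-normal noise, for
#' endogenous species (amount = true pmol in the processed sample) and for
#' spiked isotope-labeled standards, which share their family's response
#' factor — the stated assumption behind single-point internal-standard
#' quantification.
#'
#' @param trueAmounts data.frame(\code{sample}, \code{species},
#'   \code{family}, \code{amount_pmol}).
#' @param spikes data.frame(\code{sample}, \code{standard}, \code{family},
#'   \code{amount_pmol}).
#' @param responseFactors Named numeric vector, area units per pmol, by
#'   family.
#' @param samples data.frame(\code{sample}, \code{normalizer},
#'   \code{unit}) — mg protein, g tissue or mL serum per sample.
#' @param sigma Log-normal sigma of area noise.
#' @param seed Integer seed.
#' @return list with \code{measurements}, \code{spikes} (areas appended)
#'   and \code{samples}.
#' @export
simulateMrmBatch <- function(trueAmounts, spikes, responseFactors,
                             samples, sigma = 0.2, seed = 1) {
  stopifnot(all(trueAmounts$family %in% names(responseFactors)),
            all(spikes$family %in% names(responseFactors)))
  withSeed(seed, {
    meas <- trueAmounts
    meas$area <- meas$amount_pmol * responseFactors[meas$family] *
      rlnorm(nrow(meas), 0, sigma)
    sp <- spikes
    sp$area <- sp$amount_pmol * responseFactors[sp$family] *
      rlnorm(nrow(sp), 0, sigma)
    list(measurements = meas[, c("sample", "species", "family", "area")],
         spikes = sp, samples = samples)
  })
}

fourPL <- function(conc, bottom, top, hill, ic50)
  bottom + (top - bottom) / (1 + 10^((log10(ic50) - log10(conc)) * hill))
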