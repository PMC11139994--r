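# shared fixtures built in code; all randomness is seeded at the call site

suppressPackageStartupMessages(library(SummarizedExperiment))

# small 4-channel design: 2 controls + 2 treatment channels
tinyDesign <- function() {
  experimentDesign(
    channels = c("c1", "c2", "t1", "t2"),
    roles = c("control", "control", "treatment", "treatment"),
    concentrations = c(NA, NA, 1e-8, 1e-6),
    reporter_mz = tmtproChannels()$mz[1:4])
}

# PsmExperiment straight from an SNR matrix (one spectrum per row)
peFromSnr <- function(snr, design = tinyDesign(),
                      protein = rep("P1", nrow(snr)),
                      peptide = sprintf("PEP%02d", seq_len(nrow(snr))),
                      unique = TRUE) {
  PsmExperiment(
    snr = snr,
    rowData = data.frame(
      spectrum_id = sprintf("S%03d", seq_len(nrow(snr))),
      protein = protein, peptide = peptide,
      unique = rep_len(unique, nrow(snr)), stringsAsFactors = FALSE),
    design = design)
}

# exactly noise-free reporter model: constant base, constant noise floor
noiselessModel <- function() {
  noiseModel(psmSigma = 0, channelSigma = 0, baseMeanlog = log(1000),
             noiseMeanlog = log(10), noiseSigma = 0)
}

# truth with explicit per-channel inhibition for the tiny design
tinyTruth <- function(phi = c(0.75, 0.9), nPeptides = 4,
                      proteins = "P1") {
  m <- matrix(rep(phi, each = length(proteins)),
              nrow = length(proteins))
  groundTruth(
    data.frame(protein = proteins, n_peptides = nPeptides,
               psms_per_peptide = 2L, unique_fraction = 1,
               stringsAsFactors = FALSE),
    inhibition = m)
}
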