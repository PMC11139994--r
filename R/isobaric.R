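#' Per-channel SNR normalization
#'
#' Scales every channel so its summed SNR equals the pre-normalization
#' grand mean of per-channel summed SNRs: channel scale factor =
#' mean(channel sums) / channel sum. Corrects unequal channel loading; the
#' operation is idempotent.
#'
#' @param pe A [PsmExperiment-class] object.
#' @return The PsmExperiment with a rescaled \code{snr} assay.
#' @export
normalizeChannels <- function(pe) {
  stopifnot(is(pe, "PsmExperiment"))
  snr <- assay(pe, "snr")
  sums <- colSums(snr)
  if (any(sums == 0))
    stop("channel(s) with zero total SNR: ",
         paste(colnames(snr)[sums == 0], collapse = ", "))
  assay(pe, "snr") <- sweep(snr, 2, mean(sums) / sums, "*")
  pe
}

#' PSM quality filters
#'
#' Removes a PSM when the coefficient of variation of its control-channel
#' SNRs exceeds \code{cvMax}, or when its mean SNR across all channels
#' falls below \code{minMeanSnr}. CV uses the sample (n-1) standard
#' deviation divided by the mean; a PSM whose control mean is zero has
#' undefined CV and is treated as CV = Inf (removed). Each removal is
#' recorded with the rule that fired.
#'
#' @param pe A [PsmExperiment-class] object.
#' @param cvMax Maximum allowed control-channel CV (default 0.5).
#' @param minMeanSnr Minimum mean SNR across all channels (default 2).
#' @return The filtered PsmExperiment; the rejection log (a data.frame
#'   with \code{spectrum_id}, \code{protein}, \code{peptide},
#'   \code{rule}) is appended to \code{metadata()$rejections}.
#' @export
filterPsms <- function(pe, cvMax = 0.5, minMeanSnr = 2) {
  stopifnot(is(pe, "PsmExperiment"))
  snr <- assay(pe, "snr")
  ctrl <- controlChannels(pe)
  if (length(ctrl) < 2)
    stop("at least 2 control channels are needed to compute a CV")
  cm <- rowMeans(snr[, ctrl, drop = FALSE])
  csd <- apply(snr[, ctrl, drop = FALSE], 1, sd)
  cv <- ifelse(cm > 0, csd / cm, Inf)
  meanAll <- rowMeans(snr)
  badCv <- cv > cvMax
  badSnr <- meanAll < minMeanSnr
  drop <- badCv | badSnr
  rd <- rowData(pe)
  log <- data.frame(
    spectrum_id = rd$spectrum_id[drop], protein = rd$protein[drop],
    peptide = rd$peptide[drop],
    rule = ifelse(badCv[drop],
                  ifelse(badSnr[drop], "cv+mean_snr", "cv"),
                  "mean_snr"),
    stringsAsFactors = FALSE)
  out <- pe[!drop, ]
  metadata(out)$rejections <-
    rbind(metadata(pe)$rejections, log)
  out
}

#' Protein-level competition ratios
#'
#' Groups PSMs by protein accession (as given; no protein inference),
#' sums SNR per channel over the protein's PSMs, takes the mean of the
#' control-channel sums as the control figure, and divides it by the
#' protein's summed SNR in every treatment channel. A treatment channel
#' with zero protein SNR yields an infinite raw ratio (capped at the next
#' stage). Proteins with a zero control figure cannot form ratios and are
#' excluded with a log entry.
#'
#' @param pe A normalized, filtered [PsmExperiment-class].
#' @return Long data.frame: \code{protein}, \code{channel},
#'   \code{concentration_M}, \code{raw_ratio}, \code{n_peptides}
#'   (distinct post-filter peptide sequences), \code{n_unique}. Excluded
#'   proteins are listed in \code{attr(, "excluded")}.
#' @export
proteinRatios <- function(pe) {
  stopifnot(is(pe, "PsmExperiment"))
  snr <- assay(pe, "snr")
  rd <- as.data.frame(rowData(pe), stringsAsFactors = FALSE)
  d <- psmDesign(pe)
  ctrl <- controlChannels(pe); trt <- treatmentChannels(pe)
  prot <- factor(rd$protein, levels = unique(rd$protein))
  sums <- rowsum(snr, prot)                      # protein x channel
  ctrlFigure <- rowMeans(sums[, ctrl, drop = FALSE])
  keep <- ctrlFigure > 0
  excluded <- rownames(sums)[!keep]
  pepCount <- tapply(rd$peptide, prot, function(x) length(unique(x)))
  uniqCount <- tapply(seq_len(nrow(rd)), prot, function(i)
    length(unique(rd$peptide[i][rd$unique[i]])))
  res <- do.call(rbind, lapply(which(keep), function(i) {
    data.frame(
      protein = rownames(sums)[i], channel = trt,
      concentration_M = d$concentration_M[match(trt, d$channel)],
      raw_ratio = ifelse(sums[i, trt] > 0,
                         ctrlFigure[i] / sums[i, trt], Inf),
      n_peptides = pepCount[[i]], n_unique = uniqCount[[i]],
      stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  attr(res, "excluded") <- excluded
  res
}

#' Cap competition ratios and convert to percent competition
#'
#' Ratios are capped between -32 and 32 (the negative bound cannot bind
#' for ratios of non-negative SNR sums and is retained for fidelity to the
#' capping rule), then mapped to percent competition by
#' \code{100 * (1 - 1 / capped)}, clipped to [0, 100] — the standard
#' competitive-ABPP convention in which ratio 1 is 0% competition and the
#' 32 cap is 96.875%.
#'
#' @param raw Numeric vector of raw ratios (positive or infinite).
#' @param cap Cap magnitude (default 32).
#' @return data.frame(\code{capped_ratio}, \code{percent_competition}).
#' @examples
#' capAndPercent(c(1, 4, 100, Inf))
#' @export
capAndPercent <- function(raw, cap = 32) {
  capped <- pmin(pmax(raw, -cap), cap)
  pct <- pmin(pmax(100 * (1 - 1 / capped), 0), 100)
  data.frame(capped_ratio = capped, percent_competition = pct)
}

#' Reporting filter with exception list
#'
#' A protein is reported when it has at least \code{minPeptides}
#' quantified peptides (distinct post-filter sequences) and at least
#' \code{minUnique} unique quantified peptides. Proteins on the exception
#' list (e.g. a low-coverage primary target such as AIG1) are always
#' reported and carry an exception flag.
#'
#' @param results data.frame with \code{protein}, \code{n_peptides},
#'   \code{n_unique} columns.
#' @param minPeptides,minUnique Reporting thresholds (defaults 3 and 1).
#' @param exceptions Character vector of always-reported accessions.
#' @return \code{results} with logical \code{reported} and
#'   \code{exception} columns appended.
#' @export
reportingFilter <- function(results, minPeptides = 3, minUnique = 1,
                            exceptions = character()) {
  passes <- results$n_peptides >= minPeptides &
    results$n_unique >= minUnique
  results$exception <- results$protein %in% exceptions
  results$reported <- passes | results$exception
  results
}

#' Isobaric competition pipeline
#'
#' Runs the full TMTpro competition analysis on a PSM table:
#' per-channel normalization (optional; normalization corrects loading
#' bias and can be disabled when channels are known to be equally
#' loaded), PSM quality filters, protein rollup to raw ratios, capping
#' and percent-competition conversion, and the reporting filter.
#'
#' @param pe A [PsmExperiment-class] object.
#' @param normalize Apply [normalizeChannels()] first (default TRUE).
#' @param cvMax,minMeanSnr Passed to [filterPsms()].
#' @param cap Passed to [capAndPercent()].
#' @param minPeptides,minUnique,exceptions Passed to [reportingFilter()].
#' @return Long per-protein, per-treatment-channel data.frame with raw and
#'   capped ratios, percent competition, peptide counts and reporting
#'   flags; rejection and exclusion logs in attributes \code{"rejections"}
#'   and \code{"excluded"}.
#' @export
proteinCompetition <- function(pe, normalize = TRUE, cvMax = 0.5,
                               minMeanSnr = 2, cap = 32, minPeptides = 3,
                               minUnique = 1, exceptions = "AIG1") {
  if (normalize) pe <- normalizeChannels(pe)
  pe <- filterPsms(pe, cvMax = cvMax, minMeanSnr = minMeanSnr)
  res <- proteinRatios(pe)
  cp <- capAndPercent(res$raw_ratio, cap = cap)
  res$capped_ratio <- cp$capped_ratio
  res$percent_competition <- cp$percent_competition
  res <- reportingFilter(res, minPeptides = minPeptides,
                         minUnique = minUnique, exceptions = exceptions)
  attr(res, "rejections") <- metadata(pe)$rejections
  res
}
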