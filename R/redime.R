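#' Protein ratios from dimethyl peptide ratios (median rollup)
#'
#' The protein competition ratio is the median of all its peptide-level
#' ratio entries. All entries are used by default — duplicate sequences
#' (multiple quantification events of the same peptide) are retained; set
#' \code{collapsePeptides = TRUE} to first collapse each distinct sequence
#' to its own median. An even number of entries yields the arithmetic mean
#' of the central pair (the usual median convention).
#'
#' @param peptideRatios data.frame(\code{protein}, \code{peptide},
#'   \code{unique}, \code{ratio}) with ratios > 0 (heavy-vs-light fold).
#' @param collapsePeptides Collapse duplicate sequences first (default
#'   FALSE).
#' @return data.frame(\code{protein}, \code{ratio}, \code{n_peptides},
#'   \code{n_unique}) — peptide counts are distinct sequences.
#' @examples
#' pr <- data.frame(protein = "P1", peptide = c("a", "b", "c"),
#'                  unique = TRUE, ratio = c(2, 4, 8))
#' proteinMedianRatio(pr)  # ratio 4
#' @export
proteinMedianRatio <- function(peptideRatios, collapsePeptides = FALSE) {
  stopifnot(all(peptideRatios$ratio > 0))
  if (collapsePeptides) {
    agg <- aggregate(ratio ~ protein + peptide + unique,
                     data = peptideRatios, FUN = median)
    peptideRatios <- agg
  }
  prot <- factor(peptideRatios$protein,
                 levels = unique(peptideRatios$protein))
  data.frame(
    protein = levels(prot),
    ratio = as.numeric(tapply(peptideRatios$ratio, prot, median)),
    n_peptides = as.integer(tapply(peptideRatios$peptide, prot,
                                   function(x) length(unique(x)))),
    n_unique = as.integer(tapply(seq_len(nrow(peptideRatios)), prot,
      function(i) length(unique(peptideRatios$peptide[i][
        peptideRatios$unique[i]])))),
    stringsAsFactors = FALSE)
}

#' Per-sample median normalization of protein ratios
#'
#' Divides every protein ratio by the sample-wide median protein ratio, so
#' the post-normalization median is exactly 1. Idempotent and invariant to
#' a global rescaling of the input ratios.
#'
#' @param proteinRatios data.frame with a \code{ratio} column.
#' @return The data.frame with \code{ratio} normalized and the applied
#'   \code{norm_factor} recorded as an attribute.
#' @export
normalizeSample <- function(proteinRatios) {
  stopifnot(nrow(proteinRatios) >= 1)
  f <- median(proteinRatios$ratio)
  proteinRatios$ratio <- proteinRatios$ratio / f
  attr(proteinRatios, "norm_factor") <- f
  proteinRatios
}

#' ReDiMe competition pipeline
#'
#' Light/heavy dimethyl competition analysis: protein ratio = median of
#' all peptide ratios, per-sample median normalization to 1, capping at
#' +/- 32 (applied after normalization, so ratios enter percent space only
#' once), percent-competition conversion, and the reporting filter with
#' exception list. By default light = vehicle and heavy = treated; set
#' \code{heavyIsControl = TRUE} when the labels were swapped, which
#' inverts the ratios before rollup.
#'
#' @param peptideRatios data.frame(\code{protein}, \code{peptide},
#'   \code{unique}, \code{ratio}).
#' @param heavyIsControl Invert ratios first (default FALSE).
#' @param collapsePeptides Passed to [proteinMedianRatio()].
#' @param cap Passed to [capAndPercent()].
#' @param minPeptides,minUnique,exceptions Passed to [reportingFilter()].
#' @return Per-protein data.frame with normalized ratio, capped ratio,
#'   percent competition, peptide counts and reporting flags; the
#'   normalization factor is kept in \code{attr(, "norm_factor")}.
#' @export
redimeCompetition <- function(peptideRatios, heavyIsControl = FALSE,
                              collapsePeptides = FALSE, cap = 32,
                              minPeptides = 3, minUnique = 1,
                              exceptions = "AIG1") {
  if (heavyIsControl) peptideRatios$ratio <- 1 / peptideRatios$ratio
  res <- proteinMedianRatio(peptideRatios,
                            collapsePeptides = collapsePeptides)
  res <- normalizeSample(res)
  nf <- attr(res, "norm_factor")
  cp <- capAndPercent(res$ratio, cap = cap)
  res$capped_ratio <- cp$capped_ratio
  res$percent_competition <- cp$percent_competition
  res <- reportingFilter(res, minPeptides = minPeptides,
                         minUnique = minUnique, exceptions = exceptions)
  attr(res, "norm_factor") <- nf
  res
}
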