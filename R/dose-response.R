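#' Percent-of-control activity from band densitometry
#'
#' Integrated gel-band intensities expressed as percent of the
#' vehicle-control band: \code{100 * intensity / reference}.
#'
#' @param intensities Numeric vector of integrated band intensities.
#' @param reference The control intensity (> 0), or the name of the
#'   control entry when \code{intensities} is named.
#' @return Numeric vector of percent-of-control activities.
#' @export
relativeActivity <- function(intensities, reference) {
  if (is.character(reference)) {
    stopifnot(reference %in% names(intensities))
    reference <- intensities[[reference]]
  }
  if (!is.numeric(reference) || length(reference) != 1 || reference <= 0)
    stop("reference intensity must be a single positive number")
  100 * intensities / reference
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Fits \deqn{y(c) = bottom + (top - bottom) / (1 + 10^{(\log_{10} IC50 -
#' \log_{10} c)\, hill})} to percent-activity responses by ordinary
#' nonlinear least squares on semi-log-transformed concentrations
#' (Levenberg-Marquardt, via \pkg{minpack.lm}). Initialization is
#' deterministic: bottom = min response, top = max response, |hill| = 1
#' with sign from the response trend, log10 IC50 = the x value whose
#' response is nearest the half-range; bounds constrain hill to [-10, 10]
#' and log10 IC50 to the data range +/- 3 decades. Responses with no
#' variance are flagged non-identifiable, and optimizer failure returns a
#' flagged result rather than a silent answer.
#'
#' @param concentrations Molar concentrations (> 0, >= 4 distinct values).
#' @param responses Percent-activity responses, same length.
#' @param weights Optional observation weights (default unweighted, the
#'   usual densitometry practice).
#' @return A [DoseResponseFit-class] object.
#' @examples
#' conc <- 10^seq(-10, -6, length.out = 8)
#' y <- simulateDoseResponse(list(bottom = 0, top = 100, hill = 1,
#'                                ic50 = 1.6e-9), conc)
#' fit4PL(y$concentration_M, y$response_percent)
#' @export
fit4PL <- function(concentrations, responses, weights = NULL) {
  stopifnot(length(concentrations) == length(responses),
            all(concentrations > 0))
  if (length(unique(concentrations)) < 4)
    stop("at least 4 distinct concentrations are required")
  x <- log10(concentrations)
  y <- responses
  fail <- function(msg) new("DoseResponseFit",
    bottom = NA_real_, top = NA_real_, hill = NA_real_, ic50 = NA_real_,
    rss = NA_real_, converged = FALSE, se = numeric(0), message = msg)
  if (var(y) == 0) return(fail("degenerate input: all responses equal"))

  bottom0 <- min(y); top0 <- max(y)
  hill0 <- if (suppressWarnings(stats::cor(x, y)) >= 0) 1 else -1
  mid <- (top0 + bottom0) / 2
  logIC0 <- x[which.min(abs(y - mid))]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ bottom + (top - bottom) / (1 + 10^((logIC50 - x) * hill)),
      start = list(bottom = bottom0, top = top0, hill = hill0,
                   logIC50 = logIC0),
      lower = c(-Inf, -Inf, -10, min(x) - 3),
      upper = c(Inf, Inf, 10, max(x) + 3),
      weights = weights %||% rep(1, length(y)),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(fail("optimizer failed to converge"))
  cf <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) numeric(0))
  new("DoseResponseFit",
      bottom = unname(cf["bottom"]), top = unname(cf["top"]),
      hill = unname(cf["hill"]), ic50 = unname(10^cf["logIC50"]),
      rss = sum(resid(fit)^2), converged = TRUE,
      se = if (length(se)) setNames(as.numeric(se), names(cf)) else
        numeric(0),
      message = "")
}

#' @describeIn fit4PL Evaluate a fitted curve at concentrations.
#' @param fit A [DoseResponseFit-class] object.
#' @export
predict4PL <- function(fit, concentrations) {
  stopifnot(is(fit, "DoseResponseFit"), fit@converged)
  fourPL(concentrations, fit@bottom, fit@top, fit@hill, fit@ic50)
}

setMethod("show", "DoseResponseFit", function(object) {
  if (!object@converged) {
    cat("DoseResponseFit: NOT converged (", object@message, ")\n",
        sep = "")
  } else {
    cat(sprintf(
      "DoseResponseFit: IC50 %.3g M, hill %.3g, bottom %.3g, top %.3g (RSS %.4g)\n",
      object@ic50, object@hill, object@bottom, object@top, object@rss))
  }
})
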