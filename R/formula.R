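#' Parse a molecular formula string
#'
#' Accepts the usual element-count grammar (\code{"C21H23N4O4S"}) with
#' optional bracketed isotope tokens for labeled atoms
#' (\code{"[13C]16C18H65O4"} is hexadeca-13C palmitic-hydroxystearic
#' PAHSA). A missing count means 1. The empty string parses to the empty
#' formula.
#'
#' @param text Formula string.
#' @return A [MolecularFormula-class] object. Parsing then writing with
#'   [formulaString()] canonicalizes; re-parsing the canonical string gives
#'   back an identical formula.
#' @examples
#' parseFormula("C21H23N4O4S")
#' parseFormula("[13C]16C18H65O4")
#' @export
parseFormula <- function(text) {
  stopifnot(is.character(text), length(text) == 1, !is.na(text))
  text <- gsub("[[:space:]]", "", text)
  if (!nzchar(text)) return(molecularFormula(numeric(0)))
  pat <- "\\[([0-9]+)([A-Z][a-z]?)\\]([0-9]*)|([A-Z][a-z]?)([0-9]*)"
  m <- gregexpr(pat, text, perl = TRUE)[[1]]
  toks <- regmatches(text, gregexpr(pat, text, perl = TRUE))[[1]]
  # the matches must tile the whole string; anything skipped is a bad token
  covered <- paste0(toks, collapse = "")
  if (!identical(covered, text)) {
    ends <- m + attr(m, "match.length") - 1L
    pos <- setdiff(seq_len(nchar(text)), unlist(mapply(seq, m, ends)))
    stop("cannot parse formula near '",
         substr(text, min(pos), min(pos) + 3), "' in '", text, "'")
  }
  counts <- numeric(0)
  for (tok in toks) {
    iso <- regmatches(tok, regexec(pat, tok, perl = TRUE))[[1]]
    if (nzchar(iso[2])) {          # bracketed isotope token
      sym <- paste0(iso[2], iso[3])
      n <- if (nzchar(iso[4])) as.numeric(iso[4]) else 1
    } else {
      sym <- iso[5]
      n <- if (nzchar(iso[6])) as.numeric(iso[6]) else 1
    }
    if (!sym %in% names(.ISOTOPE_MASSES))
      stop("unknown element or unsupported isotope '", sym,
           "' in formula '", text, "'")
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0) + n
  }
  molecularFormula(counts)
}

#' Construct a MolecularFormula from a count vector
#'
#' @param counts Named numeric vector of non-negative atom counts; zero
#'   counts are dropped.
#' @return A [MolecularFormula-class] object.
#' @export
molecularFormula <- function(counts = numeric(0)) {
  counts <- counts[counts != 0]
  if (length(counts)) counts <- counts[base::order(names(counts))]
  new("MolecularFormula", counts = counts)
}

#' Canonical formula writer
#'
#' Writes in Hill order (C, then H, then other elements alphabetically);
#' within an element the unlabeled isotope precedes bracketed heavy
#' isotopes. \code{parseFormula(formulaString(f))} is the identity.
#'
#' @param f A [MolecularFormula-class] object.
#' @return A single formula string (\code{""} for the empty formula).
#' @export
formulaString <- function(f) {
  stopifnot(is(f, "MolecularFormula"))
  cnt <- f@counts
  if (!length(cnt)) return("")
  base <- sub("^[0-9]+", "", names(cnt))
  iso <- sub("([A-Z].*)$", "", names(cnt))  # mass-number prefix or ""
  ord <- order(match(base, c("C", "H"), nomatch = 3L), base,
               nzchar(iso), as.numeric(ifelse(nzchar(iso), iso, "0")))
  out <- vapply(ord, function(i) {
    sym <- if (nzchar(iso[i])) paste0("[", names(cnt)[i], "]") else base[i]
    n <- cnt[[i]]
    paste0(sym, if (n != 1 || nzchar(iso[i])) n else "")
  }, character(1))
  paste0(out, collapse = "")
}

#' @describeIn monoisotopicMass Number of atoms in a formula.
#' @export
atomCount <- function(f) sum(f@counts)

#' Monoisotopic mass of a formula
#'
#' Sum of count x isotope monoisotopic mass over all atoms; additive over
#' formula addition; 0 for the empty formula. Masses come from the pinned
#' [isotopeMasses()] table.
#'
#' @param f A [MolecularFormula-class] object.
#' @return Mass in Da.
#' @examples
#' monoisotopicMass(parseFormula("C16H31O2"))  # palmitate anion, 255.2324
#' @export
monoisotopicMass <- function(f) {
  stopifnot(is(f, "MolecularFormula"))
  cnt <- f@counts
  if (!length(cnt)) return(0)
  sum(cnt * .ISOTOPE_MASSES[names(cnt)])
}

setMethod("show", "MolecularFormula", function(object) {
  cat("MolecularFormula: ", formulaString(object),
      "  (", format(monoisotopicMass(object), digits = 10), " Da)\n",
      sep = "")
})

#' @rdname MolecularFormula-class
#' @param e1,e2 MolecularFormula objects.
#' @export
setMethod("+", signature("MolecularFormula", "MolecularFormula"),
  function(e1, e2) {
    cnt <- e1@counts
    for (sym in names(e2@counts))
      cnt[sym] <- (if (sym %in% names(cnt)) cnt[[sym]] else 0) +
        e2@counts[[sym]]
    molecularFormula(cnt)
  })

#' @rdname MolecularFormula-class
#' @export
setMethod("-", signature("MolecularFormula", "MolecularFormula"),
  function(e1, e2) {
    cnt <- e1@counts
    for (sym in names(e2@counts)) {
      have <- if (sym %in% names(cnt)) cnt[[sym]] else 0
      if (have < e2@counts[[sym]])
        stop("cannot remove ", e2@counts[[sym]], " x ", sym,
             " from ", formulaString(e1))
      cnt[sym] <- have - e2@counts[[sym]]
    }
    molecularFormula(cnt)
  })

.ADDUCT_REGISTRY <- list(
  "[M+H]+"     = list(add = "H",  remove = "",     charge = +1),
  "[M-H]-"     = list(add = "",   remove = "H",    charge = -1),
  # Boc/tBu loss: isobutylene (C4H8) elimination, then protonation
  "[M-tBu+H]+" = list(add = "H",  remove = "C4H8", charge = +1)
)

#' Construct an adduct
#'
#' Built-in names: \code{"[M+H]+"}, \code{"[M-H]-"}, \code{"[M-tBu+H]+"}
#' (ASCII hyphens; Unicode minus is normalized). Custom adducts can be
#' built by supplying \code{add}, \code{remove} and \code{charge}.
#'
#' @param name Adduct name.
#' @param add,remove Formula strings of atoms gained/lost (custom adducts).
#' @param charge Signed integer charge (custom adducts).
#' @return An [Adduct-class] object.
#' @export
adduct <- function(name, add = NULL, remove = NULL, charge = NULL) {
  key <- gsub("−", "-", name)
  if (is.null(add) && is.null(remove) && is.null(charge)) {
    spec <- .ADDUCT_REGISTRY[[key]]
    if (is.null(spec))
      stop("unknown adduct '", name, "'; built-ins: ",
           paste(names(.ADDUCT_REGISTRY), collapse = ", "))
    add <- spec$add; remove <- spec$remove; charge <- spec$charge
  }
  new("Adduct", name = key, add = parseFormula(add %||% ""),
      remove = parseFormula(remove %||% ""), charge = charge)
}

setMethod("show", "Adduct", function(object) {
  cat("Adduct ", object@name, " (charge ",
      sprintf("%+d", as.integer(object@charge)), ")\n", sep = "")
})

#' m/z of an ionized formula
#'
#' Applies an adduct to a neutral formula and returns
#' \code{monoisotopicMass(neutral + add - remove) / |charge|}. No
#' electron-mass correction is applied: this is the convention under which
#' synthesis-paper "calcd" values are printed (e.g. the [M+H]+ of
#' C21H22N4O4S prints 427.1440; with electron subtraction it would be
#' 427.1435).
#'
#' @param neutral A [MolecularFormula-class] (or formula string) of the
#'   neutral molecule.
#' @param add An [Adduct-class] object or adduct name.
#' @return m/z in Th.
#' @examples
#' adductMz("C4H7N3O2S", "[M+H]+")   # 162.03 -> prints as 162
#' adductMz("C16H32O2", "[M-H]-")    # palmitate, 255.2324
#' @export
adductMz <- function(neutral, add) {
  if (is.character(neutral)) neutral <- parseFormula(neutral)
  if (is.character(add)) add <- adduct(add)
  ion <- (neutral + add@add) - add@remove
  monoisotopicMass(ion) / abs(add@charge)
}

#' Move atoms between isotopes (isotope labeling)
#'
#' Converts \code{n} atoms of isotope \code{from} into isotope \code{to},
#' e.g. building the 13C16-labeled palmitic chain of an internal-standard
#' PAHSA. The mass shifts by exactly \code{n * (mass(to) - mass(from))}.
#'
#' @param f A [MolecularFormula-class] object.
#' @param n Number of atoms to substitute (0 returns \code{f} unchanged).
#' @param from,to Isotope symbols present in [isotopeMasses()].
#' @return The labeled [MolecularFormula-class].
#' @examples
#' pahsa <- parseFormula("C34H66O4")
#' applyIsotopeLabel(pahsa, 16, "C", "13C")
#' @export
applyIsotopeLabel <- function(f, n, from = "C", to = "13C") {
  stopifnot(is(f, "MolecularFormula"), n >= 0, n == round(n))
  if (n == 0) return(f)
  for (sym in c(from, to))
    if (!sym %in% names(.ISOTOPE_MASSES))
      stop("unknown isotope symbol '", sym, "'")
  cnt <- f@counts
  have <- if (from %in% names(cnt)) cnt[[from]] else 0
  if (have < n)
    stop("formula ", formulaString(f), " has only ", have, " x ", from,
         "; cannot label ", n)
  cnt[from] <- have - n
  cnt[to] <- (if (to %in% names(cnt)) cnt[[to]] else 0) + n
  molecularFormula(cnt)
}

#' Round an m/z for reporting at printed precision
#'
#' Round-half-even (IEC 60559, R's \code{round}) at the stated number of
#' decimal places — 4 dp for HRMS values, 1 or 0 dp for low-resolution MS
#' and MRM transition lists. Applied only at the reporting boundary; all
#' internal arithmetic is full precision.
#'
#' @param mz Numeric m/z value(s).
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
roundMz <- function(mz, digits = 4) round(mz, digits)

`%||%` <- function(a, b) if (is.null(a)) b else a
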