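# independent mass oracle used by the derived-value checks below:
# a plain lookup-and-sum over a regex token walk, no package machinery
bruteMass <- function(text) {
  tab <- isotopeMasses()
  toks <- regmatches(text, gregexpr(
    "\\[[0-9]+[A-Z][a-z]?\\][0-9]*|[A-Z][a-z]?[0-9]*", text))[[1]]
  sum(vapply(toks, function(tk) {
    sym <- gsub("[][0-9]*$|^\\[|\\]", "", tk)
    if (grepl("^\\[", tk)) sym <- sub("^\\[([0-9]+[A-Z][a-z]?)\\].*$",
                                      "\\1", tk)
    n <- sub("^.*?([0-9]*)$", "\\1", sub("^\\[[^]]*\\]", "", tk))
    if (grepl("^\\[", tk)) n <- sub("^\\[[^]]*\\]", "", tk)
    n <- if (nzchar(n)) as.numeric(n) else 1
    tab[[sym]] * n
  }, numeric(1)))
}

test_that("formula parsing matches the element-count grammar", {
  f <- parseFormula("C21H23N4O4S")
  expect_equal(f@counts[c("C", "H", "N", "O", "S")],
               c(C = 21, H = 23, N = 4, O = 4, S = 1))
  expect_length(parseFormula("")@counts, 0)
  expect_equal(parseFormula("C16H31O2")@counts,
               c(C = 16, H = 31, O = 2))
  lab <- parseFormula("[13C]16C18H65O4")
  expect_equal(lab@counts[["13C"]], 16)
  expect_equal(lab@counts[["C"]], 18)
  expect_error(parseFormula("C21Xx3"), "Xx")
  expect_error(parseFormula("[99Q]2H4"), "99Q")
})

test_that("formula writing canonicalizes and round-trips", {
  cases <- c("C21H23N4O4S", "H2O", "C16H31O2", "[13C]16C18H65O4", "")
  for (s in cases) {
    f <- parseFormula(s)
    w <- formulaString(f)
    expect_identical(parseFormula(w)@counts, f@counts)
    expect_identical(formulaString(parseFormula(w)), w)
  }
  # canonical Hill order with C and H first, labeled isotopes bracketed
  expect_identical(formulaString(parseFormula("O4C34H66")), "C34H66O4")
  expect_identical(formulaString(parseFormula("[13C]16C18H65O4")),
                   "C18[13C]16H65O4")
})

test_that("monoisotopic mass is an additive sum over the pinned table", {
  expect_equal(monoisotopicMass(parseFormula("")), 0)
  expect_equal(monoisotopicMass(parseFormula("C16H31O2")),
               16 * 12 + 31 * 1.00782503207 + 2 * 15.99491461956,
               tolerance = 1e-12)
  expect_equal(roundMz(monoisotopicMass(parseFormula("C16H31O2")), 4),
               255.2324)
  # additivity over random compositions
  set.seed(42)
  syms <- c("C", "H", "N", "O", "S", "13C", "2H", "P")
  for (i in 1:25) {
    a <- molecularFormula(setNames(sample(0:20, 4), sample(syms, 4)))
    b <- molecularFormula(setNames(sample(0:20, 4), sample(syms, 4)))
    expect_equal(monoisotopicMass(a + b),
                 monoisotopicMass(a) + monoisotopicMass(b),
                 tolerance = 1e-9)
  }
})

test_that("printed synthesis-route calcd ion masses reproduce exactly", {
  hrms <- function(s) roundMz(monoisotopicMass(parseFormula(s)), 4)
  lowres <- function(s, dp) roundMz(monoisotopicMass(parseFormula(s)), dp)
  expect_identical(hrms("C21H23N4O4S"), 427.1440)
  expect_identical(hrms("C20H21N4O4S"), 413.1284)
  expect_identical(lowres("C9H16N3O4S", 0), 262)
  expect_identical(lowres("C4H8N3O2S", 0), 162)
  expect_identical(lowres("C16H16NO3", 1), 270.1)
  expect_identical(lowres("C15H16NO", 0), 226)
})

test_that("adduct m/z follows the no-electron-correction convention", {
  # neutral-molecule routes to the same printed ions
  expect_equal(roundMz(adductMz("C21H22N4O4S", "[M+H]+"), 4), 427.1440)
  expect_equal(roundMz(adductMz("C4H7N3O2S", "[M+H]+"), 0), 162)
  expect_equal(roundMz(adductMz("C20H23NO3", "[M-tBu+H]+"), 1), 270.1)
  # [M+H]+ minus [M-H]- is exactly two hydrogens for any neutral
  for (s in c("C34H66O4", "C16H32O2", "C6H12O6")) {
    gap <- adductMz(s, "[M+H]+") - adductMz(s, "[M-H]-")
    expect_equal(gap, 2 * isotopeMasses()[["H"]], tolerance = 1e-9)
  }
  expect_error(adductMz("C4H8", "[M-H]-"), NA)
  expect_error(adductMz("O2", "[M-tBu+H]+"), "remove")
  expect_error(adduct("[M+2H]2+"), "unknown adduct")
})

test_that("isotope labeling moves atoms and shifts mass exactly", {
  pahsa <- parseFormula("C34H66O4")
  lab <- applyIsotopeLabel(pahsa, 16, "C", "13C")
  dC <- isotopeMasses()[["13C"]] - isotopeMasses()[["C"]]
  expect_equal(monoisotopicMass(lab) - monoisotopicMass(pahsa),
               16 * dC, tolerance = 1e-9)
  expect_equal(roundMz(adductMz(lab, "[M-H]-"), 1), 553.5)
  oahsa <- applyIsotopeLabel(parseFormula("C36H68O4"), 18, "C", "13C")
  expect_equal(roundMz(adductMz(oahsa, "[M-H]-"), 1), 581.6)
  # identity and error branches
  expect_identical(applyIsotopeLabel(pahsa, 0)@counts, pahsa@counts)
  expect_error(applyIsotopeLabel(parseFormula("C2H4"), 3, "C", "13C"),
               "only 2")
  # random label shifts stay exact
  set.seed(7)
  for (i in 1:20) {
    n <- sample(1:30, 1)
    f <- molecularFormula(c(C = 30, H = 50, N = 3))
    expect_equal(monoisotopicMass(applyIsotopeLabel(f, n, "C", "13C")) -
                   monoisotopicMass(f), n * dC, tolerance = 1e-9)
  }
})

test_that("derived hand-sums agree with an independent brute-force oracle", {
  for (s in c("C21H23N4O4S", "C34H66O4", "[13C]16C18H65O4", "C16H31O2"))
    expect_equal(monoisotopicMass(parseFormula(s)), bruteMass(s),
                 tolerance = 1e-9)
})

test_that("formula subtraction errors when atoms are absent", {
  expect_error(parseFormula("CH4") - parseFormula("O"), "cannot remove")
  expect_identical((parseFormula("C2H6O") - parseFormula("H2O"))@counts,
                   c(C = 2, H = 4))
})
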