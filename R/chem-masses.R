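#' @import methods
#' @importFrom stats setNames
NULL

## Monoisotopic atomic masses (CODATA/IUPAC values commonly used in MS).
.ELEMENTS <- c(
  C = 12.000000,
  H = 1.0078250319,
  N = 14.0030740052,
  O = 15.9949146221,
  P = 30.97376151,
  S = 31.97207069
)

## Mass of a proton; used for [M+H]+ rather than the H-atom mass, following
## standard MS convention (the electron is carried away with the charge).
.PROTON_MASS <- 1.0072765

#' Construct an elemental formula
#'
#' An elemental formula is represented as a named integer vector over the
#' elements C, H, N, O, P, S. Counts must be non-negative.
#'
#' @param ... element counts, e.g. `elementalFormula(C = 10, H = 13, N = 5, O = 4)`.
#' @return named integer vector with one entry per supported element.
#' @examples
#' adenosine <- elementalFormula(C = 10, H = 13, N = 5, O = 4)
#' formulaMass(adenosine)
#' @export
elementalFormula <- function(...) {
  counts <- c(...)
  if (length(counts) == 0) {
    return(setNames(integer(length(.ELEMENTS)), names(.ELEMENTS)))
  }
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("all element counts must be named")
  }
  unknown <- setdiff(names(counts), names(.ELEMENTS))
  if (length(unknown)) {
    stop("unsupported element(s): ", paste(unknown, collapse = ", "))
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("element counts must be non-negative integers")
  }
  out <- setNames(integer(length(.ELEMENTS)), names(.ELEMENTS))
  out[names(counts)] <- as.integer(counts)
  out
}

#' Parse a Hill-style formula string such as "C10H13N5O4"
#'
#' @param x a formula string restricted to the elements C, H, N, O, P, S.
#' @return an elemental formula (named integer vector).
#' @export
parseFormula <- function(x) {
  stopifnot(is.character(x), length(x) == 1L, nzchar(x))
  tokens <- gregexpr("([A-Z][a-z]?)([0-9]*)", x)[[1]]
  parts <- regmatches(x, gregexpr("([A-Z][a-z]?)([0-9]*)", x))[[1]]
  if (!nzchar(paste(parts, collapse = "")) ||
      nchar(paste(parts, collapse = "")) != nchar(x)) {
    stop("cannot parse formula string: ", x)
  }
  els <- sub("[0-9]*$", "", parts)
  ns <- sub("^[A-Z][a-z]?", "", parts)
  ns <- ifelse(nzchar(ns), as.integer(ns), 1L)
  counts <- tapply(ns, els, sum)
  do.call(elementalFormula, as.list(counts))
}

#' Add or subtract elemental formulas
#'
#' Addition and subtraction are element-wise; subtraction that would produce
#' a negative count is an error (you cannot remove atoms that are not there).
#'
#' @param a,b elemental formulas.
#' @return an elemental formula.
#' @export
addFormula <- function(a, b) {
  out <- elementalFormula()
  out[names(.ELEMENTS)] <- as.integer(.asFormula(a) + .asFormula(b))
  out
}

#' @rdname addFormula
#' @export
subtractFormula <- function(a, b) {
  res <- .asFormula(a) - .asFormula(b)
  if (any(res < 0)) {
    stop("formula subtraction would yield a negative element count")
  }
  out <- elementalFormula()
  out[names(.ELEMENTS)] <- as.integer(res)
  out
}

.asFormula <- function(x) {
  if (is.character(x)) return(parseFormula(x))
  out <- setNames(integer(length(.ELEMENTS)), names(.ELEMENTS))
  out[names(x)] <- as.integer(x)
  if (any(out < 0)) stop("invalid formula: negative element count")
  out
}

#' Monoisotopic mass of an elemental formula
#'
#' @param formula an elemental formula (named integer vector or a Hill string).
#' @return monoisotopic mass in Da.
#' @examples
#' formulaMass("H2O")   # 18.0106
#' @export
formulaMass <- function(formula) {
  f <- .asFormula(formula)
  sum(f * .ELEMENTS[names(f)])
}

## ---------------------------------------------------------------------------
## Built-in amino-acid and modification tables
## ---------------------------------------------------------------------------

.AA_FORMULAS <- c(
  A = "C3H7NO2",  R = "C6H14N4O2", N = "C4H8N2O3",  D = "C4H7NO4",
  C = "C3H7NO2S", E = "C5H9NO4",   Q = "C5H10N2O3", G = "C2H5NO2",
  H = "C6H9N3O2", I = "C6H13NO2",  L = "C6H13NO2",  K = "C6H14N2O2",
  M = "C5H11NO2S", F = "C9H11NO2", P = "C5H9NO2",   S = "C3H7NO3",
  T = "C4H9NO3",  W = "C11H12N2O2", Y = "C9H11NO3", V = "C5H11NO2"
)

.AA_NAMES <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", E = "Glu",
  Q = "Gln", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
  M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
  Y = "Tyr", V = "Val"
)

## Net formula change on the alpha-amino group. Acetylation and formylation
## are condensations (acid minus water); Fmoc carbamoylation adds the
## fluorenylmethyloxycarbonyl group.
.MOD_DELTAS <- list(
  none   = elementalFormula(),
  acetyl = parseFormula("C2H2O"),
  formyl = parseFormula("CO"),
  Fmoc   = parseFormula("C15H10O2")
)

.ADENOSINE <- "C10H13N5O4"
.WATER <- "H2O"
.PHOSPHATE_HPO3 <- "HPO3"

#' The canonical amino-acid table
#'
#' All 20 canonical amino acids with the elemental formula of the free amino
#' acid and its monoisotopic mass. Leucine and isoleucine are structural
#' isomers and share a formula.
#'
#' @return data.frame with columns `name`, `code`, `formula`,
#'   `monoisotopic_mass`.
#' @export
aminoAcidTable <- function() {
  codes <- names(.AA_FORMULAS)
  data.frame(
    name = unname(.AA_NAMES[codes]),
    code = codes,
    formula = unname(.AA_FORMULAS[codes]),
    monoisotopic_mass = vapply(.AA_FORMULAS[codes], formulaMass, numeric(1),
                               USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
}

#' The alpha-amino modification table
#'
#' @return data.frame with columns `name`, `delta_formula`, `delta_mass`.
#' @export
modificationTable <- function() {
  deltas <- vapply(.MOD_DELTAS, formulaMass, numeric(1))
  fm <- vapply(.MOD_DELTAS, .formulaString, character(1))
  data.frame(name = names(.MOD_DELTAS), delta_formula = unname(fm),
             delta_mass = unname(deltas), stringsAsFactors = FALSE)
}

.formulaString <- function(f) {
  f <- .asFormula(f)
  f <- f[f > 0]
  if (!length(f)) return("")
  paste0(names(f), ifelse(f > 1, f, ""), collapse = "")
}

## ---------------------------------------------------------------------------
## Digest products
## ---------------------------------------------------------------------------

#' Build a derivatized aminoacyl-adenosine digestion product
#'
#' Complete RNase I digestion of aminoacyl-tRNA releases the aminoacylated
#' 3'-terminal adenosine (aminoacyl-adenosine, no phosphate); Nuclease P1
#' digestion releases the 5'-monophosphate form (aminoacyl-AMP). The amino
#' acid is joined to adenosine by a single ester condensation (one water is
#' lost); the 2' vs 3' ester position does not change the mass. The alpha-amino
#' group may carry a modification (acetyl, formyl or Fmoc).
#'
#' @param aa one-letter amino-acid code.
#' @param mod modification, one of `"none"`, `"acetyl"`, `"formyl"`, `"Fmoc"`.
#' @param digestion `"RNaseI"` (aminoacyl-adenosine) or `"NucleaseP1"`
#'   (aminoacyl-AMP).
#' @return a `DigestProduct` object (see [DigestProduct-class]) holding the
#'   derived formula, neutral monoisotopic mass and \[M+H\]+ m/z.
#' @examples
#' buildProduct("P", "Fmoc", "RNaseI")   # Fmoc-Pro-adenosine, m/z 587.22
#' buildProduct("M", "formyl", "RNaseI") # fMet-adenosine, m/z 427.13
#' @export
buildProduct <- function(aa, mod = c("none", "acetyl", "formyl", "Fmoc"),
                         digestion = c("RNaseI", "NucleaseP1")) {
  mod <- match.arg(mod)
  digestion <- match.arg(digestion)
  if (!aa %in% names(.AA_FORMULAS)) {
    stop("unknown amino-acid code: ", aa)
  }
  f <- addFormula(.AA_FORMULAS[[aa]], .ADENOSINE)
  f <- subtractFormula(f, .WATER)
  f <- addFormula(f, .MOD_DELTAS[[mod]])
  if (digestion == "NucleaseP1") {
    f <- addFormula(f, .PHOSPHATE_HPO3)
  }
  mass <- formulaMass(f)
  stopifnot(mass > 0)
  new("DigestProduct", aminoAcid = aa, modification = mod,
      digestion = digestion, formula = f, neutralMass = mass,
      mzMH = mass + .PROTON_MASS)
}

#' DigestProduct: a derivatized aminoacyl-(phospho)adenosine species
#'
#' The nuclease digestion product of a (modified) aminoacyl-tRNA, built by
#' [buildProduct].
#'
#' @slot aminoAcid one-letter amino-acid code.
#' @slot modification alpha-amino modification name.
#' @slot digestion nuclease context (`RNaseI` or `NucleaseP1`).
#' @slot formula derived elemental formula.
#' @slot neutralMass neutral monoisotopic mass (Da).
#' @slot mzMH \[M+H\]+ m/z (Th).
#' @exportClass DigestProduct
setClass("DigestProduct",
  representation(aminoAcid = "character", modification = "character",
                 digestion = "character", formula = "integer",
                 neutralMass = "numeric", mzMH = "numeric"),
  validity = function(object) {
    if (object@neutralMass <= 0) return("neutral mass must be positive")
    if (object@mzMH <= object@neutralMass) return("[M+H]+ must exceed neutral mass")
    TRUE
  })

setMethod("show", "DigestProduct", function(object) {
  cat(sprintf("%s%s-%s (%s): %s  M = %.4f Da  [M+H]+ = %.4f\n",
              ifelse(object@modification == "none", "",
                     paste0(object@modification, "-")),
              .AA_NAMES[[object@aminoAcid]],
              ifelse(object@digestion == "RNaseI", "adenosine", "AMP"),
              object@digestion, .formulaString(object@formula),
              object@neutralMass, object@mzMH))
})

#' Accessors for DigestProduct
#'
#' @param x a `DigestProduct`.
#' @return `neutralMass()` the neutral monoisotopic mass in Da; `mzMH()` the
#'   \[M+H\]+ m/z in Th; `productFormula()` the elemental formula.
#' @export
neutralMass <- function(x) x@neutralMass

#' @rdname neutralMass
#' @export
mzMH <- function(x) x@mzMH

#' @rdname neutralMass
#' @export
productFormula <- function(x) x@formula

#' Enumerate digestion products
#'
#' Builds the full table of derivatized aminoacyl-(phospho)adenosine species
#' for a digestion context and a set of modifications, with isobar group ids.
#'
#' @param digestion `"RNaseI"` or `"NucleaseP1"`.
#' @param mods character vector of modifications to enumerate.
#' @param tolerancePpm isobar-grouping tolerance in ppm.
#' @return data.frame with columns `amino_acid`, `code`, `modification`,
#'   `digestion`, `formula`, `neutral_mass`, `mz_mh`, `isobar_group`.
#' @export
digestProductTable <- function(digestion = c("RNaseI", "NucleaseP1"),
                               mods = c("none", "acetyl"),
                               tolerancePpm = 5) {
  digestion <- match.arg(digestion)
  prods <- list()
  for (mod in mods) {
    for (aa in names(.AA_FORMULAS)) {
      prods[[length(prods) + 1L]] <- buildProduct(aa, mod, digestion)
    }
  }
  groups <- findIsobars(prods, tolerancePpm)
  gid <- integer(length(prods))
  for (i in seq_along(groups)) gid[groups[[i]]] <- i
  data.frame(
    amino_acid = vapply(prods, function(p) .AA_NAMES[[p@aminoAcid]], ""),
    code = vapply(prods, function(p) p@aminoAcid, ""),
    modification = vapply(prods, function(p) p@modification, ""),
    digestion = digestion,
    formula = vapply(prods, function(p) .formulaString(p@formula), ""),
    neutral_mass = vapply(prods, neutralMass, numeric(1)),
    mz_mh = vapply(prods, mzMH, numeric(1)),
    isobar_group = gid,
    stringsAsFactors = FALSE
  )
}

#' Group digestion products into isobars
#'
#' Partitions products into maximal groups whose neutral masses agree within
#' a ppm tolerance, using the transitive closure of the pairwise relation
#' (adequate and deterministic for the ~100 species this chemistry yields).
#' Glutamyl and N-acetyl-seryl products are the canonical isobaric pair;
#' leucyl and isoleucyl products are identical formulas.
#'
#' @param products list of `DigestProduct` objects.
#' @param tolerancePpm mass tolerance in parts per million (> 0).
#' @return list of integer vectors, each the indices of one isobar group,
#'   ordered by increasing group mass. Singleton groups are allowed.
#' @export
findIsobars <- function(products, tolerancePpm = 5) {
  stopifnot(length(products) > 0, tolerancePpm > 0)
  masses <- vapply(products, neutralMass, numeric(1))
  n <- length(masses)
  parent <- seq_len(n)
  findRoot <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      tol <- tolerancePpm * 1e-6 * max(masses[i], masses[j])
      if (abs(masses[i] - masses[j]) <= tol) {
        parent[findRoot(j)] <- findRoot(i)
      }
    }
  }
  roots <- vapply(seq_len(n), findRoot, integer(1))
  groups <- split(seq_len(n), roots)
  ord <- order(vapply(groups, function(g) min(masses[g]), numeric(1)))
  unname(groups[ord])
}

#' Truncate a value at a number of decimal places
#'
#' Mass values quoted at two decimals in instrument reports are truncations,
#' not roundings (e.g. 427.1394 is reported as 427.13); this helper reproduces
#' that dialect when comparing computed masses against quoted ones.
#'
#' @param x numeric vector.
#' @param digits decimal places to keep.
#' @export
truncateAt <- function(x, digits = 2) {
  floor(x * 10^digits) / 10^digits
}

#' Write the built-in amino-acid table to CSV
#'
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeAminoAcidTable <- function(path) {
  utils::write.csv(aminoAcidTable(), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
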