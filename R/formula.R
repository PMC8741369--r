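## Molecular-formula algebra: the unit every other module computes with.
## A formula is a named integer vector (element symbol -> count), e.g.
## c(C = 39, H = 50, O = 19). Elements with count 0 are dropped, so two
## formulas are equal iff identical after sorting names.

## Monoisotopic masses (Da), IUPAC 2021 atomic-mass evaluation, >= 6 decimals.
## Single authoritative table used by all modules.
.MONO_MASS <- c(
  C  = 12.000000000,
  H  = 1.0078250319,
  N  = 14.0030740052,
  O  = 15.9949146221,
  P  = 30.97376151,
  S  = 31.97207069,
  Na = 22.98976928,
  K  = 38.96370649,
  Cl = 34.96885268,
  F  = 18.99840316,
  Br = 78.9183376,
  I  = 126.904473,
  Si = 27.9769265
)

.ELECTRON_MASS <- 0.00054857990
## proton taken as m(1H) - m(e-) so that (de)protonation is exactly the
## neutral-atom/electron arithmetic used for every other adduct; differs from
## the CODATA free proton by the 1.5e-8 Da H binding energy, i.e. ~0.02 ppb
.PROTON_MASS   <- 1.0078250319 - 0.00054857990

#' Mass constants used throughout the package
#'
#' Returns the single authoritative table of monoisotopic element masses plus
#' the proton and electron masses, all in Da. Every m/z computed by the
#' package derives from these values.
#'
#' @return A list with components `elements` (named numeric vector of
#'   monoisotopic masses), `proton` and `electron`.
#' @examples
#' massConstants()$elements[["O"]]
#' @export
massConstants <- function() {
  list(elements = .MONO_MASS, proton = .PROTON_MASS, electron = .ELECTRON_MASS)
}

.canonFormula <- function(counts) {
  counts <- counts[counts != 0]
  if (length(counts) == 0L) {
    counts <- integer(0)
    names(counts) <- character(0)
    return(counts)
  }
  ## Hill order for display stability: C, H, then alphabetical.
  el <- names(counts)
  ord <- order(match(el, c("C", "H"), nomatch = 3L), el)
  storage.mode(counts) <- "integer"
  counts[ord]
}

#' Parse a molecular formula string
#'
#' Accepts plain formulas (`"C39H50O19"`) and the markdown-mangled dialect
#' found in typeset tables (`"C_39_H_50_O_19_"`): underscores, asterisks and
#' whitespace are stripped before parsing. Each element symbol may be followed
#' by an optional positive integer count.
#'
#' @param text Character scalar, the formula.
#' @return Named integer vector mapping element symbol to count.
#' @examples
#' parseFormula("C_39_H_50_O_19_")
#' parseFormula("H2O")
#' @export
parseFormula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("formula must be a single character string")
  clean <- gsub("[_*[:space:]]", "", text)
  if (!nzchar(clean)) stop("cannot parse an empty formula string")
  m <- gregexpr("[A-Z][a-z]?[0-9]*", clean)[[1]]
  tokens <- regmatches(clean, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(clean))
    stop("unparseable characters in formula '", text, "'")
  counts <- integer(0)
  for (tok in tokens) {
    sym <- sub("[0-9]+$", "", tok)
    numtxt <- substring(tok, nchar(sym) + 1L)
    if (!sym %in% names(.MONO_MASS))
      stop("unknown element symbol '", sym, "' in formula '", text, "'")
    n <- if (nzchar(numtxt)) as.integer(numtxt) else 1L
    if (is.na(n) || n <= 0L)
      stop("invalid count '", numtxt, "' for element '", sym, "'")
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + n
  }
  .canonFormula(counts)
}

#' Format a formula back to text
#'
#' Inverse of [parseFormula()]: writes counts in Hill order (C, H, then
#' alphabetical), omitting the count when it is 1.
#'
#' @param f Named integer vector as returned by [parseFormula()].
#' @return Character scalar.
#' @export
formatFormula <- function(f) {
  f <- .canonFormula(f)
  if (length(f) == 0L) return("")
  paste0(names(f), ifelse(f == 1L, "", f), collapse = "")
}

.assertFormula <- function(f) {
  if (is.character(f) && length(f) == 1L) return(parseFormula(f))
  if (!is.numeric(f) || is.null(names(f)) ||
      (length(f) > 0L && (any(is.na(f)) || any(f < 0) || any(f != round(f)))))
    stop("not a molecular formula: expected named non-negative integer counts")
  bad <- setdiff(names(f), names(.MONO_MASS))
  if (length(bad))
    stop("element(s) missing from the mass table: ", paste(bad, collapse = ", "))
  .canonFormula(f)
}

#' Monoisotopic mass of a formula
#'
#' @param f A formula (named count vector or formula string).
#' @return Mass in Da; 0 for the empty formula.
#' @examples
#' formulaMass("H2O")     # 18.010565
#' formulaMass("C39H50O19")
#' @export
formulaMass <- function(f) {
  f <- .assertFormula(f)
  if (length(f) == 0L) return(0)
  sum(.MONO_MASS[names(f)] * as.numeric(f))
}

#' Add two molecular formulas elementwise
#'
#' @param a,b Formulas (named count vectors or strings).
#' @return The elementwise sum, canonicalised.
#' @examples
#' addFormulas("C27H44O7", "H2O")
#' @export
addFormulas <- function(a, b) {
  a <- .assertFormula(a); b <- .assertFormula(b)
  el <- union(names(a), names(b))
  out <- vapply(el, function(e) {
    (if (e %in% names(a)) a[[e]] else 0L) + (if (e %in% names(b)) b[[e]] else 0L)
  }, integer(1))
  .canonFormula(out)
}

#' Subtract one formula from another
#'
#' Errors when any element of `b` exceeds its count in `a` — used upstream to
#' prune chemically impossible neutral losses and transformation chains.
#'
#' @param a,b Formulas (named count vectors or strings).
#' @return The elementwise difference, canonicalised.
#' @examples
#' subtractFormulas("C33H40O15", "C6H10O4")  # icariin minus a rhamnosyl residue
#' @export
subtractFormulas <- function(a, b) {
  a <- .assertFormula(a); b <- .assertFormula(b)
  el <- union(names(a), names(b))
  out <- vapply(el, function(e) {
    (if (e %in% names(a)) a[[e]] else 0L) - (if (e %in% names(b)) b[[e]] else 0L)
  }, integer(1))
  if (any(out < 0L)) {
    bad <- names(out)[out < 0L]
    stop("infeasible subtraction: '", formatFormula(.canonFormula(pmax(b, 0))),
         "' removes more ", paste(bad, collapse = ", "),
         " than present in '", formatFormula(a), "'")
  }
  .canonFormula(out)
}

## TRUE when b <= a elementwise (subtraction would succeed).
.formulaContains <- function(a, b) {
  all(vapply(names(b), function(e) {
    (if (e %in% names(a)) a[[e]] else 0L) >= b[[e]]
  }, logical(1)))
}
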