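## Adduct ion m/z and ppm mass error.
##
## An adduct registry is a data.frame with one row per ionisation recipe:
##   label     e.g. "[M+H]+"
##   polarity  "+" or "-"
##   delta     formula string added to (or, for "[M-H]-", removed from) the
##             neutral molecule; "" for none
##   sign      +1 when delta is added, -1 when removed
##   charge    +1 or -1 (singly charged species only)
## The m/z of a charged species includes the electron correction: a cation is
## lighter than its atoms by one electron mass, an anion heavier.

#' Default ESI adduct registry
#'
#' The six singly charged adducts of the screening method: positive-mode
#' \[M+H\]+, \[M+Na\]+, \[M+K\]+ and negative-mode \[M-H\]-, \[M+HCOO\]-,
#' \[M+Cl\]-. Users may rbind further rows (e.g. \[M+NH4\]+) with the same
#' columns.
#'
#' @return data.frame with columns `label`, `polarity`, `delta`, `sign`,
#'   `charge`.
#' @export
defaultAdducts <- function() {
  data.frame(
    label    = c("[M+H]+", "[M+Na]+", "[M+K]+", "[M-H]-", "[M+HCOO]-", "[M+Cl]-"),
    polarity = c("+", "+", "+", "-", "-", "-"),
    delta    = c("H", "Na", "K", "H", "CHO2", "Cl"),
    sign     = c(1L, 1L, 1L, -1L, 1L, 1L),
    charge   = c(1L, 1L, 1L, -1L, -1L, -1L),
    stringsAsFactors = FALSE
  )
}

## Normalise bracket notation so fixture strings with unicode minus or
## spaces ("[M - H]-", "[M−H]−") resolve against the registry.
.normAdductLabel <- function(x) {
  x <- gsub("[−–—]", "-", x)
  gsub("[[:space:]]", "", x)
}

.adductRow <- function(adduct, registry = defaultAdducts()) {
  if (is.data.frame(adduct)) {
    stopifnot(nrow(adduct) == 1L)
    return(adduct)
  }
  lab <- .normAdductLabel(adduct)
  hit <- which(.normAdductLabel(registry$label) == lab)
  if (length(hit) != 1L)
    stop("adduct '", adduct, "' is not in the registry")
  registry[hit, , drop = FALSE]
}

#' Theoretical m/z of an adduct ion
#'
#' Computes the m/z of the singly charged species formed from a neutral
#' molecule: the neutral monoisotopic mass plus/minus the adduct delta, with
#' the electron mass subtracted for cations and added for anions (so
#' \[M+H\]+ = M + proton and \[M-H\]- = M - proton exactly).
#'
#' @param f Neutral molecular formula (named counts or string).
#' @param adduct Adduct label (e.g. `"[M+Na]+"`) or a one-row registry
#'   data.frame.
#' @param registry Adduct registry used to resolve labels.
#' @return Theoretical m/z in Da.
#' @examples
#' adductMz("C39H50O19", "[M+H]+")   # 823.301906
#' adductMz("C48H76O19", "[M-H]-")   # 955.490804
#' @export
adductMz <- function(f, adduct, registry = defaultAdducts()) {
  f <- .assertFormula(f)
  a <- .adductRow(adduct, registry)
  m <- formulaMass(f)
  if (a$sign < 0L) {
    delta <- parseFormula(a$delta)
    if (!.formulaContains(f, delta))
      stop("cannot form ", a$label, " from ", formatFormula(f),
           ": formula lacks the atoms to remove")
    m <- m - formulaMass(delta)
  } else if (nzchar(a$delta)) {
    m <- m + formulaMass(a$delta)
  }
  ## charged-species mass: remove an electron per positive charge, add one
  ## per negative charge
  m - a$charge * .ELECTRON_MASS
}

#' Signed ppm mass error
#'
#' `1e6 * (observed - theoretical) / theoretical`. Filtering always uses the
#' unrounded value; report columns round half-away-from-zero to 1 decimal via
#' [roundHalfUp()].
#'
#' @param observed,theoretical m/z values (Da); `theoretical` must be > 0.
#' @return Signed error in parts-per-million (vectorised).
#' @examples
#' ppmError(823.3014, adductMz("C39H50O19", "[M+H]+"))
#' @export
ppmError <- function(observed, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical m/z must be positive")
  1e6 * (observed - theoretical) / theoretical
}

#' Round half away from zero
#'
#' Table-style rounding for report columns (R's `round()` rounds half to
#' even, which never prints -0.6 from -0.55).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
roundHalfUp <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
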