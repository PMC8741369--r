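## S4 containers for the two record types the screening stage consumes.
## Both wrap a validated data.frame; accessors return plain vectors so
## downstream code never touches slots directly.

#' @importFrom methods new validObject setClass setGeneric setMethod is
#' @importFrom methods representation setValidity show
NULL

setClass("CompoundLibrary", representation(compounds = "data.frame"))

setValidity("CompoundLibrary", function(object) {
  df <- object@compounds
  need <- c("name", "formula", "class", "origin", "standard_confirmed")
  miss <- setdiff(need, names(df))
  if (length(miss))
    return(paste("missing column(s):", paste(miss, collapse = ", ")))
  if (any(!nzchar(df$name) | is.na(df$name))) return("empty compound name")
  if (anyDuplicated(df$name))
    return(paste("duplicate compound name:", df$name[duplicated(df$name)][1]))
  bad <- NULL
  for (i in seq_len(nrow(df))) {
    ok <- tryCatch({ parseFormula(df$formula[i]); TRUE }, error = function(e) FALSE)
    if (!ok) { bad <- i; break }
  }
  if (!is.null(bad))
    return(paste0("row ", bad, ": unparseable formula '", df$formula[bad], "'"))
  TRUE
})

#' Compound library
#'
#' A validated table of screenable compounds. Required columns: `name`
#' (unique, nonempty), `formula` (parseable), `class` (free-text structure
#' class), `origin` (semicolon-joined source codes), `standard_confirmed`
#' (logical; identity confirmed against a reference standard). An optional
#' `rt_min` column supplies reference retention times, enabling RT-windowed
#' screening (see [matchPeaks()]).
#'
#' @param compounds data.frame with the columns above.
#' @return A `CompoundLibrary` object.
#' @examples
#' lib <- CompoundLibrary(data.frame(
#'   name = "ecdysterone", formula = "C27H44O7", class = "Steroids",
#'   origin = "NX", standard_confirmed = TRUE))
#' compoundNames(lib)
#' @export
CompoundLibrary <- function(compounds) {
  compounds <- as.data.frame(compounds, stringsAsFactors = FALSE)
  compounds$standard_confirmed <- as.logical(compounds$standard_confirmed)
  rownames(compounds) <- NULL
  new("CompoundLibrary", compounds = compounds)
}

setClass("PeakList", representation(peaks = "data.frame"))

setValidity("PeakList", function(object) {
  df <- object@peaks
  need <- c("rt_min", "mz", "polarity")
  miss <- setdiff(need, names(df))
  if (length(miss))
    return(paste("missing column(s):", paste(miss, collapse = ", ")))
  if (any(is.na(df$mz)) || any(df$mz <= 0)) return("m/z must be positive")
  if (any(is.na(df$rt_min)) || any(df$rt_min < 0))
    return("retention time must be >= 0")
  if (!all(df$polarity %in% c("+", "-")))
    return("polarity must be '+' or '-'")
  TRUE
})

#' LC-MS peak list
#'
#' A validated table of observed peaks. Required columns: `rt_min` (retention
#' time, minutes, >= 0), `mz` (observed m/z, Da, > 0), `polarity` (`"+"` or
#' `"-"`). An optional `fragments` column holds semicolon-joined fragment m/z
#' strings; further columns are carried through untouched.
#'
#' @param peaks data.frame with the columns above.
#' @return A `PeakList` object.
#' @export
PeakList <- function(peaks) {
  peaks <- as.data.frame(peaks, stringsAsFactors = FALSE)
  rownames(peaks) <- NULL
  new("PeakList", peaks = peaks)
}

#' @describeIn CompoundLibrary Compound names, in library order.
#' @param x A `CompoundLibrary`.
#' @export
compoundNames <- function(x) {
  stopifnot(is(x, "CompoundLibrary"))
  x@compounds$name
}

#' Coerce package containers to data.frame
#'
#' @param x A `CompoundLibrary` or `PeakList`.
#' @param row.names,optional,... Ignored; present for generic consistency.
#' @return The underlying data.frame.
#' @name as.data.frame-phytoms
NULL

#' @rdname as.data.frame-phytoms
#' @export
as.data.frame.CompoundLibrary <- function(x, row.names = NULL,
                                          optional = FALSE, ...) x@compounds

#' @rdname as.data.frame-phytoms
#' @export
as.data.frame.PeakList <- function(x, row.names = NULL,
                                   optional = FALSE, ...) x@peaks

setMethod("length", "CompoundLibrary", function(x) nrow(x@compounds))
setMethod("length", "PeakList", function(x) nrow(x@peaks))

setMethod("[", "CompoundLibrary", function(x, i, j, ..., drop = FALSE)
  CompoundLibrary(x@compounds[i, , drop = FALSE]))
setMethod("[", "PeakList", function(x, i, j, ..., drop = FALSE)
  PeakList(x@peaks[i, , drop = FALSE]))

setMethod("show", "CompoundLibrary", function(object) {
  df <- object@compounds
  cat("CompoundLibrary with", nrow(df), "compounds\n")
  tab <- sort(table(df$class), decreasing = TRUE)
  cat("  classes:", paste0(names(tab), " (", tab, ")", collapse = ", "), "\n")
  if (any(df$standard_confirmed, na.rm = TRUE))
    cat("  standard-confirmed:", sum(df$standard_confirmed, na.rm = TRUE), "\n")
  invisible(NULL)
})

setMethod("show", "PeakList", function(object) {
  df <- object@peaks
  cat("PeakList with", nrow(df), "peaks (",
      sum(df$polarity == "+"), "positive /", sum(df$polarity == "-"),
      "negative )\n")
  cat(sprintf("  rt %.2f-%.2f min, m/z %.4f-%.4f\n",
              min(df$rt_min), max(df$rt_min), min(df$mz), max(df$mz)))
  invisible(NULL)
})

#' Screening settings
#'
#' Bundle of the screening-stage parameters: the ppm tolerance (default
#' +/-10 ppm), the analysis time window (default 1-65 min), the mass window
#' (default 50-1500 Da), the adduct registry (default [defaultAdducts()]),
#' and an optional retention-time tolerance. `rtTolerance` (minutes) is `NA`
#' by default — RT then carries no identity information; when set, a library
#' compound is only eligible for a peak if the library has an `rt_min`
#' reference within the window (used for serum prototype screening, where the
#' reference RTs come from the annotated in vitro run).
#'
#' @param ppmTolerance Positive ppm tolerance.
#' @param rtRange Length-2 numeric, analysis time window in minutes.
#' @param mzRange Length-2 numeric, mass window in Da.
#' @param adducts Adduct registry data.frame.
#' @param rtTolerance Optional RT window half-width in minutes (`NA` = off).
#' @return A `ScreenSettings` object.
#' @export
ScreenSettings <- function(ppmTolerance = 10, rtRange = c(1, 65),
                           mzRange = c(50, 1500), adducts = defaultAdducts(),
                           rtTolerance = NA_real_) {
  new("ScreenSettings", ppmTolerance = as.numeric(ppmTolerance),
      rtRange = as.numeric(rtRange), mzRange = as.numeric(mzRange),
      adducts = adducts, rtTolerance = as.numeric(rtTolerance))
}

setClass("ScreenSettings", representation(
  ppmTolerance = "numeric", rtRange = "numeric", mzRange = "numeric",
  adducts = "data.frame", rtTolerance = "numeric"))

setValidity("ScreenSettings", function(object) {
  if (length(object@ppmTolerance) != 1L || object@ppmTolerance <= 0)
    return("ppmTolerance must be a single positive number")
  if (length(object@rtRange) != 2L || diff(object@rtRange) < 0)
    return("rtRange must be a nonempty [lo, hi] window")
  if (length(object@mzRange) != 2L || diff(object@mzRange) < 0)
    return("mzRange must be a nonempty [lo, hi] window")
  need <- c("label", "polarity", "delta", "sign", "charge")
  if (!all(need %in% names(object@adducts)))
    return("adduct registry lacks required columns")
  TRUE
})

setMethod("show", "ScreenSettings", function(object) {
  cat(sprintf(paste0("ScreenSettings: +/-%g ppm, rt %g-%g min, ",
                     "m/z %g-%g Da, %d adducts"),
              object@ppmTolerance, object@rtRange[1], object@rtRange[2],
              object@mzRange[1], object@mzRange[2], nrow(object@adducts)))
  if (!is.na(object@rtTolerance))
    cat(sprintf(", rt window +/-%g min", object@rtTolerance))
  cat("\n")
  invisible(NULL)
})
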