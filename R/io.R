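## Delimited-table readers/writers and the packaged reference tables.
##
## All fixtures live under inst/extdata as UTF-8 CSV, hand-curated from the
## printed identification tables of the Gushuling study (93 in vitro
## constituents, 20 serum prototypes, 42 serum metabolites). Every deviation
## from the literal print (typeset typos, formula corrections forced by the
## printed m/z arithmetic) is recorded in the row's `provenance` column.

#' @importFrom utils read.csv write.csv
NULL

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "phytoms")
  if (!nzchar(path)) stop("packaged fixture not found: ", file)
  path
}

#' Read a compound library from CSV
#'
#' Expected header: `name,formula,class,origin,standard_confirmed` (`origin`
#' semicolon-joined; extra columns such as `rt_min` or `provenance` are kept).
#' Malformed rows — missing columns, unparseable formulas, duplicate names —
#' error at load time with the offending row number.
#'
#' @param path CSV file path.
#' @return A [CompoundLibrary()].
#' @export
readCompoundLibrary <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("name", "formula", "class", "origin", "standard_confirmed")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("library file lacks column(s): ", paste(miss, collapse = ", "))
  for (i in seq_len(nrow(df))) {
    ok <- tryCatch({ parseFormula(df$formula[i]); TRUE },
                   error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) stop("library row ", i, ": ", ok)
  }
  dup <- which(duplicated(df$name))
  if (length(dup)) stop("library row ", dup[1], ": duplicate name '",
                        df$name[dup[1]], "'")
  CompoundLibrary(df)
}

#' Read a peak list from CSV
#'
#' Expected header: `rt_min,mz,polarity` with optional `fragments`
#' (semicolon-joined m/z) and any further columns. Rows failing validation
#' (non-positive m/z, negative RT, bad polarity) error with the row number.
#'
#' @param path CSV file path.
#' @return A [PeakList()].
#' @export
readPeakList <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("rt_min", "mz", "polarity")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("peak file lacks column(s): ", paste(miss, collapse = ", "))
  bad <- which(is.na(df$mz) | df$mz <= 0)
  if (length(bad)) stop("peak row ", bad[1], ": m/z must be positive")
  bad <- which(is.na(df$rt_min) | df$rt_min < 0)
  if (length(bad)) stop("peak row ", bad[1], ": rt_min must be >= 0")
  bad <- which(!df$polarity %in% c("+", "-"))
  if (length(bad)) stop("peak row ", bad[1], ": polarity must be '+' or '-'")
  PeakList(df)
}

#' Write / read an annotation table
#'
#' CSV round-trip for the output of [matchPeaks()] / [matchMetabolites()].
#'
#' @param annotations Annotation data.frame.
#' @param path Output CSV path.
#' @return `writeAnnotations` returns `path` invisibly; `readAnnotations`
#'   returns the data.frame.
#' @export
writeAnnotations <- function(annotations, path) {
  write.csv(annotations, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname writeAnnotations
#' @export
readAnnotations <- function(path) {
  read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
}

#' Packaged Gushuling reference tables
#'
#' Curated fixtures from the printed identification tables of the Gushuling
#' (GSL) UPLC-Q-TOF/MS study:
#' \describe{
#'   \item{`gslLibrary()`}{the 93 in vitro constituents (name, formula,
#'     structure class, herb origin codes YYH/NX/HQ, standard-confirmed flag,
#'     and the observed in vitro RT usable as a reference RT).}
#'   \item{`gslPeaksInVitro()`}{the in vitro peak rows (one per printed
#'     table line; several compounds have one positive- and one
#'     negative-mode row) with observed RT, m/z, polarity, printed adducts,
#'     fragments and printed ppm error.}
#'   \item{`gslPeaksSerum()`}{the serum prototype peak rows (20 compounds).}
#'   \item{`gslPeaksMetabolites()`}{the 42 serum metabolite peaks with the
#'     printed prototype, transformation chain, formula and ppm error.}
#' }
#' Rows curated around a printed inconsistency carry a `provenance` note.
#'
#' @return `gslLibrary()` a [CompoundLibrary()]; the others [PeakList()]s.
#' @examples
#' gslLibrary()
#' @export
gslLibrary <- function() readCompoundLibrary(.extdata("gsl_library.csv"))

#' @rdname gslLibrary
#' @export
gslPeaksInVitro <- function() readPeakList(.extdata("gsl_peaks_invitro.csv"))

#' @rdname gslLibrary
#' @export
gslPeaksSerum <- function() readPeakList(.extdata("gsl_peaks_serum.csv"))

#' @rdname gslLibrary
#' @export
gslPeaksMetabolites <- function() readPeakList(.extdata("gsl_peaks_metabolites.csv"))

#' Serum screening library: the annotated in vitro results
#'
#' The serum prototype screen uses the annotated in vitro compounds as its
#' database, including their observed retention times as reference RTs (the
#' original workflow compares retention time as well as accurate mass when
#' screening serum). Equivalent to `gslLibrary()`, whose `rt_min` column is
#' the first observed in vitro RT of each compound.
#'
#' @return A [CompoundLibrary()] with an `rt_min` reference column.
#' @export
gslSerumLibrary <- function() gslLibrary()
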