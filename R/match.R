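## Library screening: annotate observed peaks against a compound library
## under polarity-specific adduct sets, a ppm tolerance and time/mass windows.

## Theoretical m/z for every (compound, adduct) pair; NA where the adduct
## cannot form (e.g. deprotonating an H-free molecule). Matrix layout keeps
## the per-adduct columns sorted-searchable; with the library sizes in play a
## vectorised sweep over columns is already index-grade.
.theoreticalGrid <- function(formulas, adducts) {
  fl <- lapply(formulas, parseFormula)
  grid <- matrix(NA_real_, nrow = length(fl), ncol = nrow(adducts),
                 dimnames = list(NULL, adducts$label))
  for (j in seq_len(nrow(adducts))) {
    a <- adducts[j, , drop = FALSE]
    grid[, j] <- vapply(fl, function(f) {
      tryCatch(adductMz(f, a), error = function(e) NA_real_)
    }, numeric(1))
  }
  grid
}

.emptyAnnotations <- function(extra = NULL) {
  out <- data.frame(peak = integer(0), rt_min = numeric(0), mz = numeric(0),
                    polarity = character(0), compound = character(0),
                    adduct = character(0), theoretical_mz = numeric(0),
                    ppm_error = numeric(0), stringsAsFactors = FALSE)
  if (!is.null(extra)) for (nm in extra) out[[nm]] <- vector(mode = "integer")
  out
}

#' Screen peaks against a compound library
#'
#' For every peak inside the analysis time and mass windows, reports each
#' (compound, adduct) pair of matching polarity whose theoretical m/z lies
#' within the ppm tolerance of the observed m/z. A peak may receive zero, one
#' or many annotations; rows are sorted per peak by |ppm error| ascending,
#' ties broken by library order. Mass-isomeric library entries are therefore
#' all reported — resolving them is the "manual review" step of the original
#' workflow, which this function surfaces rather than automates.
#'
#' When `settings@rtTolerance` is set and the library carries an `rt_min`
#' column, a compound is additionally required to have its reference RT
#' within that window of the peak's RT (serum prototype screening).
#'
#' @param peaks A [PeakList()] (or data.frame coercible to one).
#' @param library A [CompoundLibrary()] (or data.frame coercible to one).
#' @param settings A [ScreenSettings()] object.
#' @return data.frame with columns `peak` (row index into `peaks`), `rt_min`,
#'   `mz`, `polarity`, `compound`, `adduct`, `theoretical_mz`, `ppm_error`.
#' @examples
#' lib <- gslLibrary()
#' pk  <- gslPeaksInVitro()
#' ann <- matchPeaks(pk, lib)
#' length(unique(ann$compound))
#' @export
matchPeaks <- function(peaks, library, settings = ScreenSettings()) {
  if (!is(peaks, "PeakList")) peaks <- PeakList(peaks)
  if (!is(library, "CompoundLibrary")) library <- CompoundLibrary(library)
  stopifnot(is(settings, "ScreenSettings"))
  pk <- as.data.frame(peaks)
  lib <- as.data.frame(library)
  if (nrow(lib) == 0L) stop("compound library is empty")
  if (nrow(pk) == 0L) return(.emptyAnnotations())

  adducts <- settings@adducts
  grid <- .theoreticalGrid(lib$formula, adducts)
  useRt <- !is.na(settings@rtTolerance) && "rt_min" %in% names(lib)
  tol <- settings@ppmTolerance

  res <- vector("list", nrow(pk))
  for (i in seq_len(nrow(pk))) {
    if (pk$rt_min[i] < settings@rtRange[1] || pk$rt_min[i] > settings@rtRange[2])
      next
    if (pk$mz[i] < settings@mzRange[1] || pk$mz[i] > settings@mzRange[2])
      next
    jj <- which(adducts$polarity == pk$polarity[i])
    if (!length(jj)) next
    sub <- grid[, jj, drop = FALSE]
    ppm <- 1e6 * (pk$mz[i] - sub) / sub
    hit <- which(!is.na(ppm) & abs(ppm) <= tol, arr.ind = TRUE)
    if (!nrow(hit)) next
    comp <- hit[, 1L]
    if (useRt) {
      keep <- !is.na(lib$rt_min[comp]) &
        abs(lib$rt_min[comp] - pk$rt_min[i]) <= settings@rtTolerance
      hit <- hit[keep, , drop = FALSE]
      if (!nrow(hit)) next
      comp <- hit[, 1L]
    }
    adj <- jj[hit[, 2L]]
    ann <- data.frame(
      peak = i, rt_min = pk$rt_min[i], mz = pk$mz[i],
      polarity = pk$polarity[i], compound = lib$name[comp],
      adduct = adducts$label[adj],
      theoretical_mz = grid[cbind(comp, adj)],
      ppm_error = ppm[hit], stringsAsFactors = FALSE)
    ord <- order(abs(ann$ppm_error), comp, adj)
    res[[i]] <- ann[ord, , drop = FALSE]
  }
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out)) return(.emptyAnnotations())
  rownames(out) <- NULL
  out
}

#' Default structure-class grouping
#'
#' Maps the free-text structure classes of the packaged library onto the
#' summary groups used when reporting screening results: flavonoids,
#' terpenoids (including mono- and triterpenoids), phenylpropanoids, steroids,
#' and an "Others" bucket for everything else (saccharides, organic acids,
#' anthraquinones, ...).
#'
#' @return Named character vector: class pattern (regular expression, matched
#'   case-insensitively against the class text) -> group name.
#' @export
defaultClassGroups <- function() {
  c("flavonoid" = "Flavonoids",
    "terpenoid" = "Terpenoids",
    "phenylpropanoid" = "Phenylpropanoids",
    "steroid" = "Steroids")
}

#' Summarise annotations by structure class
#'
#' Counts distinct annotated compounds per summary group; a compound is
#' counted once however many peaks or adducts matched it.
#'
#' @param annotations Output of [matchPeaks()].
#' @param library The [CompoundLibrary()] the annotations refer to (source of
#'   the `class` column).
#' @param groups Pattern -> group map, see [defaultClassGroups()].
#' @return Named integer vector of compound counts per group (plus "Others").
#' @export
summarizeByClass <- function(annotations, library,
                             groups = defaultClassGroups()) {
  if (!is(library, "CompoundLibrary")) library <- CompoundLibrary(library)
  lib <- as.data.frame(library)
  cmp <- unique(annotations$compound)
  if (!length(cmp)) return(setNames(integer(0), character(0)))
  cls <- lib$class[match(cmp, lib$name)]
  grp <- rep("Others", length(cls))
  for (pat in names(groups))
    grp[grepl(pat, cls, ignore.case = TRUE)] <- groups[[pat]]
  counts <- table(factor(grp, levels = c(unname(groups), "Others")))
  out <- as.integer(counts)
  names(out) <- names(counts)
  out[out > 0 | names(out) %in% c(unname(groups), "Others")]
}
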