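## Neutral-loss explanation of fragment ions: a fragment m/z is explained as
## the precursor ion minus a multiset of neutral losses whose summed mass
## matches (precursor - fragment) within a mDa budget. Charge is retained on
## the residual ion; losses are neutral. Radical losses (CH3., CH2OH., COOH.)
## are permitted but flagged.

#' Default neutral-loss registry
#'
#' The loss vocabulary of glycosylated natural products: sugar residues
#' (Glc 162.0528, Rha 146.0579, the O-linked Rha-Rha disaccharide residue),
#' the 120 Da C-glycoside cross-ring loss (C4H8O4), water, CO, CO2, prenyl
#' C4H8, C4H10O, ketene C2H2O, C2H4O2, CH2O, and the radicals CH3, CH2OH,
#' COOH. Extend by rbinding rows with the same columns.
#'
#' @return data.frame with columns `label`, `formula`, `radical`, `mass`.
#' @examples
#' lr <- defaultLossRegistry()
#' lr[lr$label == "Glc", ]
#' @export
defaultLossRegistry <- function() {
  df <- data.frame(
    label = c("H2O", "CO", "CO2", "CH3", "Glc", "Rha", "ORha-Rha",
              "C4H8O4", "C4H8", "C4H10O", "C2H2O", "C2H4O2", "CH2O",
              "CH2OH", "COOH", "OH"),
    formula = c("H2O", "CO", "CO2", "CH3", "C6H10O5", "C6H10O4", "C12H20O9",
                "C4H8O4", "C4H8", "C4H10O", "C2H2O", "C2H4O2", "CH2O",
                "CH3O", "CHO2", "HO"),
    radical = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE,
                FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  df$mass <- vapply(df$formula, formulaMass, numeric(1))
  df
}

## All multisets of registry rows of size 0..maxLosses, as a list of integer
## count vectors (length nrow(registry)). Enumerated by nondecreasing row
## index so each multiset appears once.
.lossMultisets <- function(n, maxLosses) {
  out <- list(integer(n))
  frontier <- list(list(counts = integer(n), last = 1L))
  for (k in seq_len(maxLosses)) {
    nxt <- list()
    for (node in frontier) {
      for (j in seq(node$last, n)) {
        cnt <- node$counts
        cnt[j] <- cnt[j] + 1L
        nxt[[length(nxt) + 1L]] <- list(counts = cnt, last = j)
        out[[length(out) + 1L]] <- cnt
      }
    }
    frontier <- nxt
  }
  out
}

#' Explain fragment ions by neutral-loss arithmetic
#'
#' For each fragment m/z, enumerates every multiset of registry losses of
#' total multiplicity `<= maxLosses` whose summed mass equals
#' `precursorMz - fragment` within `budgetMDa` mDa, ranked by absolute
#' deviation. When the precursor's neutral formula is supplied, loss multisets
#' that would remove more atoms than the precursor contains are pruned.
#' A fragment with no qualifying multiset is reported once with `NA` losses —
#' unexplained, surfaced rather than forced.
#'
#' @param precursorMz Precursor ion m/z.
#' @param fragments Numeric vector of fragment m/z values.
#' @param losses Loss registry, see [defaultLossRegistry()].
#' @param maxLosses Maximum total loss multiplicity per assignment.
#' @param budgetMDa Mass-deviation budget in mDa.
#' @param precursorFormula Optional neutral formula of the precursor for
#'   feasibility pruning.
#' @return data.frame with columns `fragment_mz`, `losses` (label multiset,
#'   `"2xH2O"`-style, `+`-joined; `NA` when unexplained), `n_losses`,
#'   `predicted_mz`, `deviation_mda`, `radical`.
#' @examples
#' explainFragments(677.2433, c(531.1851, 369.1321, 313.0698))
#' @export
explainFragments <- function(precursorMz, fragments,
                             losses = defaultLossRegistry(),
                             maxLosses = 3L, budgetMDa = 5,
                             precursorFormula = NULL) {
  stopifnot(length(precursorMz) == 1L, precursorMz > 0, maxLosses >= 1L)
  if (!is.null(precursorFormula))
    precursorFormula <- .assertFormula(precursorFormula)
  sets <- .lossMultisets(nrow(losses), as.integer(maxLosses))
  setMass <- vapply(sets, function(cnt) sum(cnt * losses$mass), numeric(1))
  setFeasible <- rep(TRUE, length(sets))
  if (!is.null(precursorFormula)) {
    lossF <- lapply(losses$formula, parseFormula)
    setFeasible <- vapply(sets, function(cnt) {
      tot <- integer(0); names(tot) <- character(0)
      for (j in which(cnt > 0L))
        for (r in seq_len(cnt[j])) tot <- addFormulas(tot, lossF[[j]])
      .formulaContains(precursorFormula, tot)
    }, logical(1))
  }

  out <- vector("list", length(fragments))
  for (i in seq_along(fragments)) {
    fr <- fragments[i]
    if (fr > precursorMz + budgetMDa / 1000) {
      out[[i]] <- data.frame(fragment_mz = fr, losses = NA_character_,
                             n_losses = NA_integer_, predicted_mz = NA_real_,
                             deviation_mda = NA_real_, radical = NA,
                             flag = "fragment above precursor",
                             stringsAsFactors = FALSE)
      next
    }
    target <- precursorMz - fr
    dev <- abs(setMass - target) * 1000
    hit <- which(dev <= budgetMDa & setFeasible)
    if (!length(hit)) {
      out[[i]] <- data.frame(fragment_mz = fr, losses = NA_character_,
                             n_losses = NA_integer_, predicted_mz = NA_real_,
                             deviation_mda = NA_real_, radical = NA,
                             flag = "unexplained", stringsAsFactors = FALSE)
      next
    }
    hit <- hit[order(dev[hit])]
    lab <- vapply(hit, function(h) {
      cnt <- sets[[h]]
      j <- which(cnt > 0L)
      if (!length(j)) return("")
      paste0(ifelse(cnt[j] > 1L, paste0(cnt[j], "x"), ""), losses$label[j],
             collapse = " + ")
    }, character(1))
    rad <- vapply(hit, function(h) any(sets[[h]] > 0L & losses$radical),
                  logical(1))
    out[[i]] <- data.frame(
      fragment_mz = fr, losses = lab,
      n_losses = vapply(hit, function(h) sum(sets[[h]]), integer(1)),
      predicted_mz = precursorMz - setMass[hit],
      deviation_mda = dev[hit],
      radical = rad, flag = "", stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
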