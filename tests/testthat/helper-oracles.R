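## Independent oracles the tests compare the implementation against.

## Independently typed monoisotopic masses (IUPAC atomic-mass evaluation).
## Deliberately a separate table from the package's constants.
ORACLE_MASS <- c(C = 12, H = 1.00782503, N = 14.00307401, O = 15.99491462,
                 P = 30.97376151, S = 31.97207069, Na = 22.98976928,
                 K = 38.96370649, Cl = 34.96885268)

## Per-element hand sum from a count vector.
oracleMass <- function(counts) {
  if (!length(counts)) return(0)
  sum(ORACLE_MASS[names(counts)] * as.numeric(counts))
}

## Brute-force screening oracle: exhaustive loop over every
## (peak, compound, adduct) triple, no indexing, no vectorisation.
bruteForceMatch <- function(peaks, library, settings = ScreenSettings()) {
  pk <- as.data.frame(peaks)
  lib <- as.data.frame(library)
  adducts <- settings@adducts
  rows <- list()
  for (i in seq_len(nrow(pk))) {
    if (pk$rt_min[i] < settings@rtRange[1] || pk$rt_min[i] > settings@rtRange[2]) next
    if (pk$mz[i] < settings@mzRange[1] || pk$mz[i] > settings@mzRange[2]) next
    cand <- list()
    for (c in seq_len(nrow(lib))) {
      for (a in seq_len(nrow(adducts))) {
        if (adducts$polarity[a] != pk$polarity[i]) next
        th <- tryCatch(adductMz(lib$formula[c], adducts[a, , drop = FALSE]),
                       error = function(e) NA_real_)
        if (is.na(th)) next
        ppm <- 1e6 * (pk$mz[i] - th) / th
        if (abs(ppm) > settings@ppmTolerance) next
        cand[[length(cand) + 1L]] <- data.frame(
          peak = i, rt_min = pk$rt_min[i], mz = pk$mz[i],
          polarity = pk$polarity[i], compound = lib$name[c],
          adduct = adducts$label[a], theoretical_mz = th, ppm_error = ppm,
          c = c, a = a, stringsAsFactors = FALSE)
      }
    }
    if (!length(cand)) next
    cand <- do.call(rbind, cand)
    cand <- cand[order(abs(cand$ppm_error), cand$c, cand$a), ]
    rows[[length(rows) + 1L]] <- cand[, setdiff(names(cand), c("c", "a"))]
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## Brute-force neutral-loss multiset enumeration over a small registry:
## all count vectors with total <= maxLosses, via expand.grid.
bruteForceLossSets <- function(masses, target, maxLosses, budgetMDa) {
  grids <- expand.grid(lapply(masses, function(x) 0:maxLosses))
  grids <- grids[rowSums(grids) <= maxLosses, , drop = FALSE]
  dev <- abs(as.matrix(grids) %*% masses - target) * 1000
  grids[dev <= budgetMDa, , drop = FALSE]
}

## Random plausible formula for property tests.
randomFormula <- function() {
  f <- c(C = sample(1:60, 1), H = sample(1:90, 1), O = sample(0:25, 1),
         N = sample(0:4, 1), S = sample(0:2, 1), P = sample(0:1, 1))
  f[f > 0]
}
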