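## Seeded synthetic peak lists with planted ground truth. Emulates what the
## acquisition hands to the screening stage: each true peak is a library
## compound ionised under a polarity-consistent adduct with Gaussian
## ppm-scale mass error (instrument error scales with m/z, so the noise is
## multiplicative in ppm, not additive in Da); decoy peaks are uniform in the
## mass window, kept away from every theoretical library m/z.

#' @importFrom stats rnorm runif setNames sd qnorm
NULL

#' Simulate a peak list from a compound library
#'
#' Draws `nPeaks` peaks: a fraction `decoyFraction` are decoys placed
#' uniformly in the m/z window at `>= 3 * sigmaPpm` ppm from every
#' theoretical (compound, adduct) m/z of the same polarity; the rest are true
#' peaks from a uniformly chosen compound and polarity-consistent adduct,
#' with sampled m/z = theoretical * (1 + e/1e6), e ~ Normal(0, sigmaPpm).
#' Retention times are uniform in `rtRange` and carry no identity
#' information. Fully reproducible under `seed`.
#'
#' @param library A [CompoundLibrary()].
#' @param nPeaks Number of peaks to generate.
#' @param sigmaPpm Standard deviation of the ppm mass error (>= 0).
#' @param decoyFraction Fraction of decoy peaks in `[0, 1)`.
#' @param rtRange Retention-time range (minutes).
#' @param mzRange Mass window for decoys (Da).
#' @param polarityMix Probability a peak is positive mode.
#' @param adducts Adduct registry.
#' @param seed Integer seed.
#' @return List with `peaks` (a [PeakList()]) and `truth` (data.frame with
#'   per-peak `compound`, `adduct`, `decoy`, `true_mz`, plus the generator
#'   settings as attributes).
#' @export
simulatePeaks <- function(library, nPeaks = 1000L, sigmaPpm = 2,
                          decoyFraction = 0.2, rtRange = c(1, 65),
                          mzRange = c(50, 1500), polarityMix = 0.5,
                          adducts = defaultAdducts(), seed = 1L) {
  if (!is(library, "CompoundLibrary")) library <- CompoundLibrary(library)
  stopifnot(sigmaPpm >= 0, decoyFraction >= 0, decoyFraction < 1)
  lib <- as.data.frame(library)
  if (nrow(lib) == 0L && decoyFraction < 1)
    stop("cannot draw true peaks from an empty library")
  grid <- .theoreticalGrid(lib$formula, adducts)

  set.seed(as.integer(seed))
  nDecoy <- as.integer(round(nPeaks * decoyFraction))
  nTrue <- nPeaks - nDecoy
  isDecoy <- rep(c(FALSE, TRUE), c(nTrue, nDecoy))

  compound <- rep(NA_character_, nPeaks)
  adduct <- rep(NA_character_, nPeaks)
  trueMz <- rep(NA_real_, nPeaks)
  mz <- numeric(nPeaks)
  polarity <- ifelse(runif(nPeaks) < polarityMix, "+", "-")

  for (i in which(!isDecoy)) {
    jj <- which(adducts$polarity == polarity[i])
    ok <- which(!is.na(grid[, jj, drop = FALSE]), arr.ind = TRUE)
    pick <- ok[sample.int(nrow(ok), 1L), ]
    ci <- pick[1L]; ai <- jj[pick[2L]]
    compound[i] <- lib$name[ci]
    adduct[i] <- adducts$label[ai]
    trueMz[i] <- grid[ci, ai]
    mz[i] <- trueMz[i] * (1 + rnorm(1L, 0, sigmaPpm) / 1e6)
  }
  if (nDecoy > 0L) {
    guard <- 3 * max(sigmaPpm, 1e-3)   # ppm stand-off from any library ion
    for (i in which(isDecoy)) {
      jj <- which(adducts$polarity == polarity[i])
      theo <- grid[, jj]
      theo <- theo[!is.na(theo)]
      repeat {
        x <- runif(1L, mzRange[1], mzRange[2])
        if (!length(theo) ||
            min(abs(1e6 * (x - theo) / theo)) >= guard) break
      }
      mz[i] <- x
    }
  }
  rt <- runif(nPeaks, rtRange[1], rtRange[2])
  peaks <- PeakList(data.frame(rt_min = rt, mz = mz, polarity = polarity,
                               stringsAsFactors = FALSE))
  truth <- data.frame(peak = seq_len(nPeaks), compound = compound,
                      adduct = adduct, decoy = isDecoy, true_mz = trueMz,
                      stringsAsFactors = FALSE)
  attr(truth, "sigma_ppm") <- sigmaPpm
  attr(truth, "seed") <- as.integer(seed)
  list(peaks = peaks, truth = truth)
}

#' Simulate a serum metabolome peak list
#'
#' Each peak derives from a random prototype and a random feasible rule
#' multiset of total multiplicity `<= maxSteps` (a fraction
#' `prototypeFraction` keep the empty chain, i.e. circulate unchanged),
#' ionised under a random polarity-consistent adduct with Gaussian ppm noise
#' as in [simulatePeaks()]. The truth table records the applied chain.
#'
#' @param prototypes A [CompoundLibrary()] of prototype compounds.
#' @param registry Rule registry, see [defaultRuleRegistry()].
#' @param nPeaks,sigmaPpm,rtRange,polarityMix,adducts,seed As in
#'   [simulatePeaks()].
#' @param maxSteps Maximum chain length.
#' @param prototypeFraction Fraction of peaks with an empty chain.
#' @return List with `peaks` (a [PeakList()]) and `truth` (data.frame with
#'   `prototype`, `rules`, `formula`, `adduct`, `true_mz`).
#' @export
simulateMetabolome <- function(prototypes, registry = defaultRuleRegistry(),
                               nPeaks = 500L, maxSteps = 3L, sigmaPpm = 2,
                               prototypeFraction = 0.2, rtRange = c(1, 65),
                               polarityMix = 0.5, adducts = defaultAdducts(),
                               seed = 1L) {
  if (!is(prototypes, "CompoundLibrary")) prototypes <- CompoundLibrary(prototypes)
  proto <- as.data.frame(prototypes)
  stopifnot(nrow(proto) > 0L, maxSteps >= 1L, sigmaPpm >= 0)
  cand <- enumerateCandidates(prototypes, registry, maxSteps)

  set.seed(as.integer(seed))
  rows <- vector("list", nPeaks)
  for (i in seq_len(nPeaks)) {
    if (runif(1L) < prototypeFraction) {
      p <- sample.int(nrow(proto), 1L)
      nm <- proto$name[p]; rules <- ""; f <- proto$formula[p]; src <- nm
    } else {
      k <- sample.int(nrow(cand), 1L)
      nm <- cand$name[k]; rules <- cand$rules[k]; f <- cand$formula[k]
      src <- cand$prototype[k]
    }
    polarity <- if (runif(1L) < polarityMix) "+" else "-"
    jj <- which(adducts$polarity == polarity)
    theo <- NA_real_
    while (is.na(theo)) {
      ai <- jj[sample.int(length(jj), 1L)]
      theo <- tryCatch(adductMz(f, adducts[ai, , drop = FALSE]),
                       error = function(e) NA_real_)
    }
    rows[[i]] <- data.frame(
      peak = i, prototype = src, rules = rules, formula = f,
      adduct = adducts$label[ai], true_mz = theo, polarity = polarity,
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, rows)
  truth$mz <- truth$true_mz * (1 + rnorm(nPeaks, 0, sigmaPpm) / 1e6)
  truth$rt_min <- runif(nPeaks, rtRange[1], rtRange[2])
  peaks <- PeakList(truth[, c("rt_min", "mz", "polarity")])
  attr(truth, "sigma_ppm") <- sigmaPpm
  attr(truth, "seed") <- as.integer(seed)
  list(peaks = peaks, truth = truth[, c("peak", "prototype", "rules",
                                        "formula", "adduct", "true_mz",
                                        "polarity", "mz", "rt_min")])
}
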