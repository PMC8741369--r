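## Biotransformation-rule enumeration: candidate metabolite formulas are a
## prototype compound's formula with a multiset of rule deltas applied
## (additions and eliminations), then matched to serum peaks by exact mass
## like any other library.

#' Default biotransformation-rule registry
#'
#' The nine-rule vocabulary of serum metabolite screening: reduction (+H2),
#' oxidation (+O), hydration (+H2O), phosphorylation (+HPO3), glucuronidation
#' (+C6H8O6), acetylcysteine conjugation (+C5H7NO3S), glutathione
#' S-conjugation (+C10H15N3O6S), dehydration (-H2O), and decarboxylation
#' (-COO, i.e. the CO2 atom multiset). Phase-II conjugations default to at
#' most one occurrence per candidate (`max_per_candidate`); the small phase-I
#' shifts may repeat up to the chain-length cap.
#'
#' @return data.frame with columns `code`, `direction` (`"add"`/`"subtract"`),
#'   `delta` (formula string), `label`, `max_per_candidate`.
#' @export
defaultRuleRegistry <- function() {
  data.frame(
    code = c("+H2", "+O", "+H2O", "+HPO3", "+C6H8O6", "+C5H7NO3S",
             "+C10H15N3O6S", "-H2O", "-COO"),
    direction = c(rep("add", 7), "subtract", "subtract"),
    delta = c("H2", "O", "H2O", "HPO3", "C6H8O6", "C5H7NO3S",
              "C10H15N3O6S", "H2O", "CO2"),
    label = c("reduction", "oxidation", "hydration", "phosphorylation",
              "glucuronidation", "acetylcysteine conjugation",
              "glutathione S-conjugation", "dehydration", "decarboxylation"),
    max_per_candidate = c(NA, NA, NA, 1L, 1L, 1L, 1L, NA, NA),
    stringsAsFactors = FALSE)
}

.normRuleCode <- function(x) {
  x <- gsub("[−–—]", "-", x)
  x <- gsub("[_*[:space:]]", "", x)
  ## the registry writes additions with an explicit "+"
  ifelse(grepl("^[+-]", x), x, paste0("+", x))
}

## rule codes (character vector, repeats = multiplicity) -> registry rows
.ruleIdx <- function(codes, registry) {
  idx <- match(.normRuleCode(codes), .normRuleCode(registry$code))
  if (anyNA(idx))
    stop("unknown transformation rule(s): ",
         paste(codes[is.na(idx)], collapse = ", "))
  idx
}

#' Apply a multiset of transformation rules to a prototype
#'
#' Computes the candidate formula (prototype plus all additive deltas minus
#' all subtractive deltas, checked for elementwise feasibility) and the
#' canonical derived name, e.g. `"Ecdysterone + 2x(+O) + HPO3"`: rules in
#' registry order, multiplicity `k` written `kx(...)`, subtractions with a
#' leading minus.
#'
#' @param prototype Either a formula (string/named counts) or a one-row
#'   data.frame with `name` and `formula` columns.
#' @param rules Character vector of rule codes; repeats encode multiplicity
#'   (e.g. `c("+O", "+O", "+HPO3")`).
#' @param registry Rule registry, see [defaultRuleRegistry()].
#' @return List with `formula` (named counts), `formula_text`, `name`
#'   (derived identification string), `n_steps`.
#' @examples
#' applyRules(data.frame(name = "Ecdysterone", formula = "C27H44O7"), "+H2O")
#' @export
applyRules <- function(prototype, rules, registry = defaultRuleRegistry()) {
  if (is.data.frame(prototype)) {
    protoName <- prototype$name[1]
    f0 <- parseFormula(prototype$formula[1])
  } else {
    f0 <- .assertFormula(prototype)
    protoName <- formatFormula(f0)
  }
  idx <- .ruleIdx(rules, registry)
  add <- integer(0); names(add) <- character(0)
  sub <- add
  for (i in idx) {
    d <- parseFormula(registry$delta[i])
    if (registry$direction[i] == "add") add <- addFormulas(add, d)
    else sub <- addFormulas(sub, d)
  }
  f1 <- addFormulas(f0, add)
  f1 <- subtractFormulas(f1, sub)   # errors when infeasible
  cnt <- table(factor(idx, levels = seq_len(nrow(registry))))
  parts <- character(0)
  for (i in which(cnt > 0)) {
    code <- registry$code[i]
    k <- cnt[[i]]
    body <- if (k > 1L) paste0(k, "x(", code, ")")
            else if (startsWith(code, "+")) substring(code, 2L)
            else code
    parts <- c(parts,
               if (startsWith(code, "-") && k == 1L) paste("-", substring(body, 2L))
               else paste("+", body))
  }
  nm <- if (length(parts)) paste(protoName, paste(parts, collapse = " "))
        else protoName
  list(formula = f1, formula_text = formatFormula(f1), name = nm,
       n_steps = length(idx))
}

#' Parse a derived candidate name back into prototype and rules
#'
#' Inverse of the naming convention of [applyRules()] (and of the printed
#' identification strings in the packaged metabolite table): tolerates
#' unicode minus signs, underscores and loose spacing, expands `"kx(...)"`
#' multiplicities, and — because compound names themselves may contain `+`
#' and `-` — accepts a split point only when everything after it parses as a
#' sequence of registry rule terms.
#'
#' @param name Identification string, e.g. `"Ecdysterone + 2x(+O) + HPO3"`.
#' @param registry Rule registry the codes must resolve against.
#' @return List with `prototype` (name string) and `rules` (character vector
#'   of rule codes with repeats).
#' @export
parseCandidateName <- function(name, registry = defaultRuleRegistry()) {
  x <- gsub("[−–—]", "-", name)
  x <- gsub("_", "", x)
  chars <- strsplit(x, "")[[1]]
  depth <- 0L
  cut <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] %in% c("(", "[", "{")) depth <- depth + 1L
    if (chars[i] %in% c(")", "]", "}")) depth <- depth - 1L
    if (depth == 0L && chars[i] %in% c("+", "-") && i > 1L)
      cut <- c(cut, i)
  }
  known <- .normRuleCode(registry$code)
  parseTerm <- function(seg) {
    ## one "op body" segment -> expanded rule codes, or NULL if not a rule
    op <- substring(seg, 1L, 1L)
    body <- trimws(substring(seg, 2L))
    mult <- 1L
    mm <- regmatches(body, regexec("^([0-9]+)[xX]\\((.*)\\)$", body))[[1]]
    if (length(mm) == 3L) {
      mult <- as.integer(mm[2])
      body <- trimws(mm[3])
      if (grepl("^[+-]", body)) {
        op <- substring(body, 1L, 1L)
        body <- trimws(substring(body, 2L))
      }
    }
    code <- .normRuleCode(paste0(op, body))
    if (!code %in% known) return(NULL)
    rep(code, mult)
  }
  for (k in seq_along(cut)) {
    bounds <- cut[k:length(cut)]
    starts <- bounds
    ends <- c(bounds[-1] - 1L, length(chars))
    segs <- mapply(function(s, e) trimws(paste(chars[s:e], collapse = "")),
                   starts, ends)
    terms <- lapply(segs, parseTerm)
    if (any(vapply(terms, is.null, logical(1)))) next
    proto <- trimws(paste(chars[seq_len(cut[k] - 1L)], collapse = ""))
    return(list(prototype = proto, rules = unlist(terms)))
  }
  list(prototype = trimws(x), rules = character(0))
}

## multisets of rules with per-rule caps; returns list of count vectors
.ruleMultisets <- function(registry, maxSteps) {
  caps <- registry$max_per_candidate
  caps[is.na(caps)] <- maxSteps
  n <- nrow(registry)
  out <- list()
  frontier <- list(list(counts = integer(n), last = 1L))
  for (k in seq_len(maxSteps)) {
    nxt <- list()
    for (node in frontier) {
      for (j in seq(node$last, n)) {
        cnt <- node$counts
        if (cnt[j] + 1L > caps[j]) next
        cnt[j] <- cnt[j] + 1L
        nxt[[length(nxt) + 1L]] <- list(counts = cnt, last = j)
        out[[length(out) + 1L]] <- cnt
      }
    }
    frontier <- nxt
  }
  out
}

#' Enumerate metabolite candidates from prototype compounds
#'
#' Generates every (prototype, rule multiset) pair with total multiplicity
#' between 1 and `maxSteps`, subject to per-rule caps
#' (`registry$max_per_candidate`) and elementwise feasibility of the
#' resulting formula. Candidates are deduplicated on (prototype, formula):
#' the first (fewest-step, registry-order) chain is kept and mass-equivalent
#' alternatives are recorded — chains such as +O +H2 versus +H2O yield the
#' same formula and are indistinguishable by exact mass.
#'
#' @param prototypes A [CompoundLibrary()] or data.frame with `name` and
#'   `formula` columns.
#' @param registry Rule registry, see [defaultRuleRegistry()].
#' @param maxSteps Maximum total rule multiplicity per candidate.
#' @return data.frame with columns `prototype`, `rules` (`;`-joined codes),
#'   `name`, `formula`, `n_steps`, `n_alternatives`.
#' @export
enumerateCandidates <- function(prototypes, registry = defaultRuleRegistry(),
                                maxSteps = 3L) {
  stopifnot(maxSteps >= 1L)
  if (is(prototypes, "CompoundLibrary")) prototypes <- as.data.frame(prototypes)
  sets <- .ruleMultisets(registry, as.integer(maxSteps))
  deltas <- lapply(registry$delta, parseFormula)
  ## net delta per multiset, as (add formula, subtract formula)
  setAdd <- vector("list", length(sets))
  setSub <- vector("list", length(sets))
  empty <- integer(0); names(empty) <- character(0)
  for (s in seq_along(sets)) {
    add <- empty; sub <- empty
    cnt <- sets[[s]]
    for (j in which(cnt > 0L)) {
      d <- deltas[[j]]
      for (r in seq_len(cnt[j])) {
        if (registry$direction[j] == "add") add <- addFormulas(add, d)
        else sub <- addFormulas(sub, d)
      }
    }
    setAdd[[s]] <- add; setSub[[s]] <- sub
  }
  codesOf <- function(cnt) rep(registry$code, cnt)

  rows <- vector("list", nrow(prototypes))
  for (p in seq_len(nrow(prototypes))) {
    f0 <- parseFormula(prototypes$formula[p])
    seen <- new.env(parent = emptyenv())
    recs <- list()
    for (s in seq_along(sets)) {
      fAdd <- addFormulas(f0, setAdd[[s]])
      if (!.formulaContains(fAdd, setSub[[s]])) next
      f1 <- subtractFormulas(fAdd, setSub[[s]])
      key <- formatFormula(f1)
      prev <- if (exists(key, envir = seen)) get(key, envir = seen) else NULL
      if (is.null(prev)) {
        codes <- codesOf(sets[[s]])
        res <- applyRules(prototypes[p, , drop = FALSE], codes, registry)
        recs[[length(recs) + 1L]] <- data.frame(
          prototype = prototypes$name[p],
          rules = paste(codes, collapse = ";"),
          name = res$name, formula = key,
          n_steps = sum(sets[[s]]), n_alternatives = 0L,
          stringsAsFactors = FALSE)
        assign(key, length(recs), envir = seen)
      } else {
        recs[[prev]]$n_alternatives <- recs[[prev]]$n_alternatives + 1L
      }
    }
    rows[[p]] <- do.call(rbind, recs)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Match serum peaks against enumerated metabolite candidates
#'
#' Same matching contract as [matchPeaks()] with candidates in place of
#' library compounds; per-peak annotations are ranked by |ppm error|, ties
#' broken by fewest rule steps then enumeration order.
#'
#' @param candidates Output of [enumerateCandidates()].
#' @param peaks A [PeakList()] of serum peaks.
#' @param settings A [ScreenSettings()].
#' @return data.frame like [matchPeaks()] output plus `prototype`, `rules`,
#'   `n_steps`, `formula` columns; `compound` holds the derived name.
#' @export
matchMetabolites <- function(candidates, peaks, settings = ScreenSettings()) {
  if (!nrow(candidates))
    return(.emptyAnnotations())
  lib <- CompoundLibrary(data.frame(
    name = candidates$name, formula = candidates$formula,
    class = "Metabolite", origin = candidates$prototype,
    standard_confirmed = FALSE, stringsAsFactors = FALSE))
  ann <- matchPeaks(peaks, lib, settings)
  if (!nrow(ann)) return(ann)
  i <- match(ann$compound, candidates$name)
  ann$prototype <- candidates$prototype[i]
  ann$rules <- candidates$rules[i]
  ann$n_steps <- candidates$n_steps[i]
  ann$formula <- candidates$formula[i]
  ## re-rank within peak: |ppm|, then fewest steps, then enumeration order
  ord <- order(ann$peak, abs(ann$ppm_error), ann$n_steps, i)
  ann <- ann[ord, , drop = FALSE]
  rownames(ann) <- NULL
  ann
}
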