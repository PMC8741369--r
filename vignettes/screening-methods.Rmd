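---
title: "Exact-mass screening and metabolite annotation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact-mass screening and metabolite annotation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phytoms)
```

# The model

All three stages of the workflow — library screening, fragment explanation,
metabolite enumeration — reduce to arithmetic on molecular formulas. A
formula is a map from element symbols to non-negative integer counts; its
monoisotopic mass is the sum of per-element monoisotopic masses from a
single authoritative table (`massConstants()`, IUPAC values to at least six
decimals). Two conventions matter and are worth stating explicitly:

* **Charged-species masses include the electron.** A singly charged cation
  is lighter than the sum of its atoms by one electron mass (0.000549 Da),
  an anion heavier. At m/z 500–1200 this is a 0.5–1 ppm effect, large enough
  to matter against a ±10 ppm filter. So
  `[M+Na]+ = M + m(Na) − m(e)` and `[M+Cl]− = M + m(Cl) + m(e)`.
* **The proton is taken as `m(H) − m(e)`.** This makes protonation and
  deprotonation exactly the same neutral-atom/electron arithmetic as every
  other adduct, and makes the identity
  `mz[M+H]+ − mz[M−H]− = 2 m_p` hold to machine precision. The difference
  from the CODATA free-proton mass is the hydrogen binding energy,
  1.5e-8 Da (~0.02 ppb) — far below instrument precision.

The ppm mass error is `1e6 (m_obs − m_theo)/m_theo`, signed. Filtering always
uses the unrounded value; report columns round half-away-from-zero to one
decimal (`roundHalfUp()`), matching how screening software prints errors
(R's default half-to-even rounding would print −0.5 where platforms print
−0.6 from −0.55).

# Library screening

`matchPeaks()` reports every (peak, compound, adduct) triple with matching
polarity, the peak inside the analysis time and mass windows, and |ppm| at
or below tolerance, sorted per peak by |ppm| with ties broken by library
order. The defaults mirror the acquisition method the packaged tables come
from:

| parameter | default | unit | rationale |
|---|---|---|---|
| `ppmTolerance` | 10 | ppm | the screening platform's "quality allowable error range" |
| `rtRange` | 1–65 | min | the analysis time range of the gradient |
| `mzRange` | 50–1500 | Da | the screening mass range (the instrument scan range was 50–1200; the screening stage was configured wider, and the wider setting is what the annotation tables were produced with, so it is the default; both ends are plain arguments) |
| adducts | H⁺, Na⁺, K⁺ / −H⁺, HCOO⁻, Cl⁻ | — | the positive/negative adduct sets of the method; registry extensible |
| `rtTolerance` | `NA` (off) | min | see below |

Two deliberate behaviours:

* **All mass-isomers are reported.** Compounds with identical formulas
  (e.g. ecdysterone/inokosterone, wogonin/calycosin) are indistinguishable
  by exact mass; the matcher surfaces all of them, ranked, rather than
  guessing. Resolving such ties was a manual-review step in the original
  workflow and stays out of scope here.
* **Retention time is not an identity criterion by default** because a
  literature-derived compound library has no reference RTs. The serum
  prototype screen is the exception: its database is the *annotated in
  vitro result set*, which does carry observed RTs, and the original
  workflow compared retention time as well as accurate mass at that stage.
  With `rtTolerance = 0.5` min (the largest in vitro/serum RT shift across
  the packaged tables is 0.41 min, and sub-minute run-to-run RT
  reproducibility is typical for UPLC) the serum screen recovers exactly
  the 20 published prototypes; by mass alone it would also pull in three
  mass-isomeric in vitro compounds whose RTs are 5–18 min away.

Matching is vectorised over a per-adduct theoretical-mass grid; tests pin
its behaviour to an exhaustive triple-loop oracle, so the implementation is
free to change shape without changing meaning.

# Fragment explanation

`explainFragments()` enumerates all multisets of registry neutral losses of
total multiplicity ≤ `maxLosses` (default 3) whose summed mass equals
(precursor − fragment) within `budgetMDa` (default 5 mDa), ranked by
deviation. The defaults follow the worked fragmentations in the source
tables: every consistent step there resolves within ~0.5 mDa, and 5 mDa
absorbs the observed-fragment measurement error while staying far from the
14 mDa gap between, say, Rha and Glc − O. Losses are neutral and charge is
retained on the residual ion; radical losses (CH₃·, CH₂OH·, COOH·) are
allowed but flagged. When the precursor formula is known, multisets that
would remove more atoms than the precursor contains are pruned.

Unexplainable fragments are reported as such, never forced. Three printed
fragment assignments in the source tables are arithmetically inconsistent,
and the package keeps them that way:

* the 515.1931 → 369.1322 step is a 146.06 Da (rhamnosyl) loss although the
  running text calls it a glucosyl loss;
* ginsenoside Ro's 631.2021 is 180 mDa away from the stated double glucosyl
  loss from 955.4884 (the co-eluting ikarisoside F ion at exactly 631.2021
  is the likely culprit);
* ecdysterone's 371.2244 is 5.3 mDa from 2×H₂O + C₄H₁₀O — just outside the
  default budget; a 6 mDa budget recovers it, and the tests document both.

Glc + Rha and the O-linked Rha–Rha disaccharide residue are the same atom
multiset, hence exactly isobaric; both are reported when either fits.

# Metabolite enumeration

`enumerateCandidates()` applies every multiset of the nine-rule registry
with total multiplicity 1–3 to each prototype. Choices:

* **Chain length ≤ 3** (counting multiplicity, so "2×(+O) + HPO₃" is three
  steps): the deepest chain in the published metabolite table uses three.
* **Phase-II conjugations (glucuronide, acetylcysteine, glutathione,
  phosphate) at most once per candidate** — no published candidate carries
  two bulky conjugates, and double conjugation within a three-step budget
  is biologically implausible; the cap is per-rule configurable
  (`max_per_candidate`).
* **"−COO" decarboxylation is the CO₂ atom multiset**; feasibility is
  checked elementwise on the aggregate delta, so chain order cannot
  manufacture or destroy feasibility.
* **Deduplication on (prototype, formula)**: +H₂ +O and +H₂O are
  mass-identical; the shortest chain is kept and alternatives counted
  (`n_alternatives`), because exact mass cannot distinguish them — a
  limitation inherited from the method itself, not an implementation
  choice.

Derived names follow the published notation ("Ecdysterone + 2×(+O) +
HPO₃"), rules in registry order; `parseCandidateName()` inverts it, and
accepts a split point only where the whole tail parses as rule terms, so
compound names containing `+`/`-` (e.g. "2,15-Hexadecanedione") do not
confuse it.

# The synthetic generator

`simulatePeaks()` emulates exactly what the screening stage consumes: each
true peak is a uniformly chosen (compound, polarity-consistent adduct) with
multiplicative Gaussian mass noise — ppm-scaled, not Da-scaled, because
TOF mass error grows with m/z and ppm is the error currency of the whole
workflow. Decoys are uniform in the mass window, kept ≥ 3σ (ppm) from every
same-polarity theoretical library ion. `simulateMetabolome()` plants random
feasible rule chains instead. Retention times are uniform and carry no
signal. Everything is reproducible from a single integer seed.

What the generator does **not** emulate — chromatographic peak shape,
intensity, isotope envelopes, in-source fragmentation, co-elution — bounds
what passing recovery tests show: they validate the matching and
enumeration arithmetic under calibrated mass noise, not peak picking or
spectral deconvolution on real raw data.

Problem sizes used by the test suite: oracle-equivalence runs use 25-compound
libraries and ~100 peaks; the recovery and noise-calibration checks use
10,000 peaks at σ = 2 ppm against the full 93-compound library (recall
≥ 99.9 % expected from the Normal tail: P(|ε| > 5σ) ≈ 6e-7), with the σ
estimate checked against a 99 % χ² confidence interval.

# Fixture curation

The packaged tables transcribe the printed identification tables; a
`provenance` column records every curated deviation:

* epimedin A is stored as C₃₉H₅₀O₂₀ (the print duplicates epimedin C's
  C₃₉H₅₀O₁₉, which is inconsistent with all three printed m/z values for
  epimedin A and with its printed dehydration metabolite);
* epimedin B is stored as C₃₈H₄₈O₁₉ (print says O₁₈, inconsistent the same
  way);
* a handful of adduct cells with impossible polarity signs or adducts
  inconsistent with the printed m/z (e.g. a formate adduct printed with a
  positive charge) are normalised, with notes;
* one printed mass error (icariside B1, −6.6 ppm) recomputes to −7.6 ppm
  under any plausible constant set; it is kept as printed and flagged —
  every other row recomputes within 0.8 ppm of the printed value, the slack
  expected from unpublished vendor mass tables.

# Known limitations

Exact-mass screening cannot separate isomers (by design); fragment
explanation is combinatorial over a user-extensible registry, not a
structure-aware predictor; RDA and other ring cleavages are representable
only as tabulated formula losses; multiply charged ions, dimers and isotope
patterns are out of scope; and the serum RT window assumes run-to-run RT
stability, which holds within these tables but must be re-checked for other
instruments.
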