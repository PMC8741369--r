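# phytoms

Qualitative annotation of LC–MS peak lists from complex herbal preparations,
in the style of vendor screening platforms (UNIFI-like workflows): exact-mass
library screening, neutral-loss fragment explanation, and serum-metabolite
identification by biotransformation-rule enumeration.

## The problem

Untargeted UPLC-Q-TOF/MS runs on a multi-herb preparation yield hundreds of
peaks. Qualitative identification proceeds in three stages, each of which is
plain mass arithmetic once the compound library and the observed peak table
are in hand:

1. **Library screening.** For a peak with observed m/z *m* and an adduct *A*
   of a candidate compound with neutral monoisotopic mass *M*, the
   theoretical ion mass is e.g. `[M+H]+ = M + m_p`, `[M+Na]+ = M + m_Na − m_e`,
   `[M+HCOO]− = M + m_HCOO + m_e` (singly charged species; the electron mass
   is included). The signed mass error is

       ppm = 1e6 × (m_obs − m_theo) / m_theo

   and a match requires |ppm| ≤ 10 within the analysis time window
   (1–65 min) and mass window (50–1500 Da), under polarity-specific adduct
   sets (+: H⁺, Na⁺, K⁺; −: deprotonation, HCOO⁻, Cl⁻).
2. **Fragment explanation.** An MS/MS fragment at m/z *f* of a precursor at
   *p* is explained by a multiset *L* of neutral losses (Glc 162.0528 Da,
   Rha 146.0579 Da, H₂O, CO₂, radical CH₃, ...) when
   `|p − f − Σ_{l∈L} mass(l)| ≤ 5 mDa`, with at most 3 losses.
3. **Metabolite enumeration.** Serum metabolites of absorbed prototype
   compounds are candidate formulas `proto ± Σ deltas` over a nine-rule
   registry (+H₂ reduction, +O oxidation, +H₂O hydration, +HPO₃
   phosphorylation, +C₆H₈O₆ glucuronidation, +C₅H₇NO₃S acetylcysteine
   conjugation, +C₁₀H₁₅N₃O₆S glutathione conjugation, −H₂O dehydration,
   −COO decarboxylation), chains of total length ≤ 3, matched to serum peaks
   exactly like a library.

The package implements all three stages over a small molecular-formula
algebra (parse/format, add/subtract, monoisotopic mass), ships curated
reference tables for the Gushuling (GSL) preparation — 93 in vitro
constituents, 20 serum prototypes, 42 serum metabolites — and provides a
seeded synthetic peak-list generator (Gaussian ppm noise, decoys, random
rule chains) so the whole pipeline is testable end to end with known ground
truth.

## Worked example

Screen one positive-mode peak against the packaged library:

```r
library(phytoms)
lib <- gslLibrary()                      # CompoundLibrary with 93 compounds
pk  <- PeakList(data.frame(rt_min = 18.93, mz = 823.3014, polarity = "+"))
matchPeaks(pk, lib)
#>   peak rt_min       mz polarity   compound adduct theoretical_mz  ppm_error
#> 1    1  18.93 823.3014        + Epimedin C [M+H]+       823.3019 -0.6144367
```

The peak is annotated as protonated epimedin C (C₃₉H₅₀O₁₉) with a −0.6 ppm
mass error — the error the original study reports for this ion. Its
fragments are explained as neutral losses from the precursor:

```r
fa <- explainFragments(823.3014, c(531.1852, 515.1931, 369.1322, 313.0699),
                       precursorFormula = "C39H50O19")
fa[!duplicated(fa$fragment_mz), c("fragment_mz", "losses", "deviation_mda")]
#>   fragment_mz                losses deviation_mda
#> 1    531.1852                 2xRha     0.3823852
#> 2    515.1931              ORha-Rha     2.4322369
#> 5    369.1322        Rha + ORha-Rha     0.5589557
#> 7    313.0699 Rha + ORha-Rha + C4H8     0.2587005
```

i.e. successive losses of rhamnosyl residues, the O-linked
rhamnosyl-rhamnose group, and the prenyl C₄H₈ — the published fragmentation
pathway of epimedin C. Metabolite candidates derive from prototypes by rule
chains:

```r
applyRules(data.frame(name = "Ecdysterone", formula = "C27H44O7"),
           c("+O", "+O", "+HPO3"))$name
#> [1] "Ecdysterone + 2x(+O) + HPO3"     # formula C27H45O12P
```

A thin command-line wrapper over the same functions is installed at
`system.file("scripts", "phytoms", package = "phytoms")`, with subcommands
`match`, `fragments`, `metabolites` and `simulate`.

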