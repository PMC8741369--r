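test_that("transformation rules reproduce the printed metabolite formulas", {
  ec <- data.frame(name = "Ecdysterone", formula = "C27H44O7")
  expect_identical(applyRules(ec, "+H2O")$formula_text, "C27H46O8")
  expect_identical(applyRules(ec, "+H2O")$name, "Ecdysterone + H2O")
  ru <- data.frame(name = "Rutin", formula = "C27H30O16")
  got <- applyRules(ru, c("+H2", "+C10H15N3O6S"))
  expect_identical(got$formula_text, "C37H47N3O22S")
  ## multiplicity and registry-order normalisation in derived names
  got2 <- applyRules(ec, c("+HPO3", "+O", "+O"))
  expect_identical(got2$name, "Ecdysterone + 2x(+O) + HPO3")
  expect_identical(got2$formula_text, "C27H45O12P")
  ## decarboxylation is a CO2 subtraction
  rb <- data.frame(name = "Rubschisantherin", formula = "C25H30O8")
  expect_identical(applyRules(rb, "-COO")$formula_text, "C24H30O6")
  expect_identical(applyRules(rb, c("-COO", "-COO"))$name,
                   "Rubschisantherin + 2x(-COO)")
  ## empty rule set leaves the prototype untouched
  expect_identical(applyRules(ec, character(0))$formula_text, "C27H44O7")
  ## infeasible chains error
  expect_error(applyRules(data.frame(name = "x", formula = "CH4"), "-H2O"),
               "infeasible")
  expect_error(applyRules(ec, "+XYZ"), "unknown transformation")
})

test_that("enumeration count matches the closed-form multiset count", {
  ## nine addition rules, no caps, a prototype large enough that nothing is
  ## pruned: sum_{k=1..3} C(9+k-1, k) = 9 + 45 + 165
  reg <- data.frame(code = paste0("+R", 1:9), direction = "add",
                    delta = c("O", "H2", "H2O", "CO2", "CH2", "NH", "S",
                              "C2H4", "PH"),
                    label = letters[1:9], max_per_candidate = NA)
  cand <- enumerateCandidates(
    data.frame(name = "big", formula = "C100H200O50"), reg, maxSteps = 3)
  ## distinct formulas can collide (e.g. H2+O vs H2O); total enumerated
  ## chains = kept + alternatives
  expect_identical(nrow(cand) + sum(cand$n_alternatives), 219L)
})

test_that("candidates deduplicate mass-equivalent chains per prototype", {
  reg <- defaultRuleRegistry()
  cand <- enumerateCandidates(
    data.frame(name = "Ecdysterone", formula = "C27H44O7"), reg, 2)
  ## +H2O and (+H2, +O) give the same formula: one row, one alternative
  row <- cand[cand$formula == "C27H46O8", ]
  expect_identical(nrow(row), 1L)
  expect_identical(row$n_steps, 1L)        # the shorter chain is kept
  expect_gte(row$n_alternatives, 1L)
  ## phase-II conjugations appear at most once per candidate
  expect_false(any(grepl("C10H15N3O6S;C10H15N3O6S", cand$rules)))
})

test_that("derived names round-trip through the parser", {
  proto <- data.frame(name = c("Ecdysterone", "Rubschisantherin"),
                      formula = c("C27H44O7", "C25H30O8"))
  cand <- enumerateCandidates(proto, maxSteps = 3)
  set.seed(5)
  for (i in sample(nrow(cand), 40)) {
    parsed <- parseCandidateName(cand$name[i])
    expect_identical(parsed$prototype, cand$prototype[i])
    p <- proto[proto$name == parsed$prototype, ]
    expect_identical(applyRules(p, parsed$rules)$formula_text, cand$formula[i])
  }
  ## names with hyphens and glued rule operators still parse
  parsed <- parseCandidateName("Rubschisantherin-COO + C10H15N3O6S")
  expect_identical(parsed$prototype, "Rubschisantherin")
  expect_identical(sort(parsed$rules), c("+C10H15N3O6S", "-COO"))
  parsed2 <- parseCandidateName("2,15-Hexadecanedione + 2x(+H2O)")
  expect_identical(parsed2$prototype, "2,15-Hexadecanedione")
  expect_identical(parsed2$rules, c("+H2O", "+H2O"))
})

test_that("every printed identification string maps to its printed formula", {
  met <- as.data.frame(gslPeaksMetabolites())
  lib <- as.data.frame(gslLibrary())
  for (i in seq_len(nrow(met))) {
    parsed <- parseCandidateName(met$identification[i])
    expect_identical(parsed$prototype, met$prototype[i])
    p <- lib[lib$name == parsed$prototype, c("name", "formula")]
    expect_identical(applyRules(p, parsed$rules)$formula_text,
                     formatFormula(parseFormula(met$formula[i])),
                     info = met$no[i])
  }
})

test_that("serum metabolite peaks are annotated with the printed errors", {
  lib <- as.data.frame(gslLibrary())
  proto <- lib[lib$name %in% c("Ecdysterone", "Linolenic acid"), ]
  cand <- enumerateCandidates(proto[, c("name", "formula")], maxSteps = 3)
  met <- gslPeaksMetabolites()
  ann <- matchMetabolites(cand, met)
  m <- as.data.frame(met)
  ## M15: ecdysterone + H2O, [M-H]-, printed error 2.2 ppm
  i15 <- which(m$no == "M15")
  a15 <- ann[ann$peak == i15 & ann$formula == "C27H46O8", ]
  expect_gte(nrow(a15), 1L)
  expect_identical(a15$adduct[1], "[M-H]-")
  expect_equal(roundHalfUp(a15$ppm_error[1], 1), 2.2)
  ## M4: ecdysterone + 2 oxidations + phosphorylation, printed error 9.3 ppm
  i4 <- which(m$no == "M4")
  a4 <- ann[ann$peak == i4 & ann$formula == "C27H45O12P", ]
  expect_gte(nrow(a4), 1L)
  expect_equal(roundHalfUp(a4$ppm_error[1], 1), 9.3)
  ## empty candidate set -> empty annotation table
  expect_identical(nrow(matchMetabolites(cand[0, ], met)), 0L)
})
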