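test_that("the default loss registry carries the glycoside vocabulary", {
  lr <- defaultLossRegistry()
  expect_equal(lr$mass[lr$label == "Glc"], 162.0528, tolerance = 1e-4)
  expect_equal(lr$mass[lr$label == "Rha"], 146.0579, tolerance = 1e-4)
  expect_equal(lr$mass[lr$label == "C4H8O4"], 120.0423, tolerance = 1e-4)
  expect_true(all(c("H2O", "CO", "CO2", "CH3", "ORha-Rha", "C4H8",
                    "C4H10O", "C2H2O", "CH2OH", "COOH") %in% lr$label))
  expect_true(lr$radical[lr$label == "CH3"])
  expect_true(all(lr$mass > 0))
})

test_that("the icariin fragment cascade is explained within 1 mDa per step", {
  steps <- list(c(677.2433, 531.1851, "Rha"),
                c(531.1851, 369.1321, "Glc"),
                c(369.1321, 313.0698, "C4H8"))
  for (s in steps) {
    fa <- explainFragments(as.numeric(s[1]), as.numeric(s[2]), maxLosses = 1)
    expect_identical(fa$losses[1], s[3])
    expect_lt(fa$deviation_mda[1], 1)
  }
  ## full chain from the precursor; note Glc + Rha is isobaric with the
  ## ORha-Rha disaccharide residue (same atoms), so assert membership
  fa <- explainFragments(677.2433, c(531.1851, 369.1321, 313.0698),
                         precursorFormula = "C33H40O15")
  expect_true("Rha" %in% fa$losses[fa$fragment_mz == 531.1851])
  expect_true(all(c("Glc + Rha", "ORha-Rha") %in%
                    fa$losses[fa$fragment_mz == 369.1321]))
  expect_true("Glc + Rha + C4H8" %in% fa$losses[fa$fragment_mz == 313.0698])
  expect_true(all(fa$deviation_mda < 1.5))
})

test_that("ecdysterone loses two waters within 1 mDa", {
  fa <- explainFragments(481.3134, 445.2923)
  expect_identical(fa$losses[1], "2xH2O")
  expect_lt(fa$deviation_mda[1], 1)
  expect_equal(fa$predicted_mz[1], 445.2923, tolerance = 1e-3)
})

test_that("a fragment equal to the precursor gets the empty loss multiset", {
  fa <- explainFragments(500.1234, 500.1234)
  expect_identical(fa$losses[1], "")
  expect_identical(fa$n_losses[1], 0L)
  expect_equal(fa$deviation_mda[1], 0)
  ## above the precursor -> flagged, not fatal
  fa2 <- explainFragments(500, 600)
  expect_identical(fa2$flag, "fragment above precursor")
})

test_that("printed fragmentation inconsistencies are surfaced, not forced", {
  ## the 515.1931 -> 369.1322 step is arithmetically a rhamnosyl loss,
  ## not the glucosyl loss the running text claims
  fa <- explainFragments(515.1931, 369.1322, maxLosses = 1)
  expect_identical(fa$losses[1], "Rha")
  expect_false("Glc" %in% fa$losses)
  ## ginsenoside Ro 631.2021 is 180 mDa away from a double glucosyl loss
  fa <- explainFragments(955.4884, 631.2021)
  expect_identical(fa$flag[1], "unexplained")
  ## ecdysterone 371.2244 sits 5.3 mDa from 2xH2O + C4H10O: outside the
  ## default 5 mDa budget, inside a 6 mDa one
  fa5 <- explainFragments(481.3134, 371.2244)
  expect_identical(fa5$flag[1], "unexplained")
  fa6 <- explainFragments(481.3134, 371.2244, budgetMDa = 6)
  expect_identical(fa6$losses[1], "2xH2O + C4H10O")
  expect_equal(fa6$deviation_mda[1], 5.3, tolerance = 0.1)
})

test_that("multiset enumeration equals exhaustive search on small registries", {
  lr <- defaultLossRegistry()
  small <- lr[lr$label %in% c("H2O", "CO", "CO2", "Glc", "Rha", "C4H8"), ]
  set.seed(21)
  for (r in 1:10) {
    k <- sample(0:3, 1)
    target <- sum(sample(small$mass, k, replace = TRUE)) +
      rnorm(1, 0, 0.002)
    prec <- 900
    fa <- explainFragments(prec, prec - target, losses = small,
                           maxLosses = 3, budgetMDa = 5)
    oracle <- bruteForceLossSets(small$mass, target, 3, 5)
    nGot <- if (all(is.na(fa$losses))) 0L else nrow(fa)
    expect_identical(nGot, nrow(oracle))
  }
})

test_that("larger budgets and deeper searches never drop assignments", {
  key <- function(fa) paste(fa$fragment_mz, fa$losses)
  frags <- c(531.1851, 369.1321, 445.2923, 313.0698)
  a <- explainFragments(677.2433, frags, maxLosses = 2, budgetMDa = 3)
  b <- explainFragments(677.2433, frags, maxLosses = 3, budgetMDa = 6)
  keep <- !is.na(a$losses)
  expect_true(all(key(a)[keep] %in% key(b)))
})

test_that("a supplied precursor formula prunes impossible losses", {
  ## precursor with no oxygen cannot lose water even if the mass fits
  fa <- explainFragments(100.1126, 100.1126 - 18.0106,
                         precursorFormula = "C7H14",
                         losses = defaultLossRegistry(), maxLosses = 1)
  expect_identical(fa$flag[1], "unexplained")
  fa2 <- explainFragments(100.1126, 100.1126 - 18.0106, maxLosses = 1)
  expect_identical(fa2$losses[1], "H2O")
})
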