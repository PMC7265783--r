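# Deconvolution into sample scores and pathway-level aggregation.

fit_small <- function(n = 80, p = 5, seed = 3, density = 0.3) {
  net <- simulateNetwork(p, density, seed)
  ls <- lineage_study(net, n, c(0.15, 0.7, 0.15), 2, seed + 1)
  list(net = fitCancerNetwork(ls$study, mcmc = mcmcSettings(
         iterations = 3000L, burnin = 500L, seed = seed + 2)),
       study = ls$study, status = ls$status)
}

test_that("probability triples live on the simplex", {
  f <- fit_small()
  sc <- scoreSamples(f$net, f$study)
  s <- sc@pPlus + sc@pZero + sc@pMinus
  expect_lt(max(abs(s - 1)), 1e-8)
  expect_gte(min(sc@pPlus, sc@pZero, sc@pMinus), 0)
  expect_lte(max(sc@pPlus, sc@pZero, sc@pMinus), 1)
})

test_that("a sample at the training center scores symmetrically neutral", {
  f <- fit_small()
  center <- matrix(f$net@center, 1,
                   dimnames = list("S0", f$net@proteins))
  sc <- scoreSamples(f$net, center)
  expect_equal(sc@pPlus[1, ], sc@pMinus[1, ])
  expect_true(all(sc@pZero[1, ] > sc@pPlus[1, ]))
})

test_that("a +5 predictive-sd excursion on one protein is called activated", {
  f <- fit_small()
  x <- matrix(f$net@center, 1, dimnames = list("S0", f$net@proteins))
  i <- 2L
  x[1, i] <- x[1, i] + 5 * f$net@residScale[i] * f$net@scale[i]
  sc <- scoreSamples(f$net, x)
  expect_gt(sc@pPlus[1, i], 0.95)
})

test_that("cross-system scoring is the identity on the training slice", {
  f <- fit_small()
  a <- scoreSamples(f$net, f$study)
  b <- scoreCrossSystem(f$net, f$study)
  expect_identical(a@pPlus, b@pPlus)
  expect_identical(a@pMinus, b@pMinus)
  # shifting a neutral sample moves mass from p0 to p+
  x <- exprMatrix(f$study)[1, , drop = FALSE]
  xs <- x + 1.5 * f$net@scale
  s0 <- scoreSamples(f$net, x)
  s1 <- scoreSamples(f$net, xs)
  expect_true(all(s1@pPlus > s0@pPlus))
  expect_true(mean(s1@pZero) < mean(s0@pZero) ||
                mean(s0@pPlus) > 0.9)
  expect_error(scoreSamples(f$net, exprMatrix(f$study)[, -1]),
               "missing protein")
})

test_that("pathway aggregation averages triples and resolves ties to neutral", {
  mk <- function(pp, p0, pm)
    new("SampleScores", lineage = "l", pathway = "pw",
        sampleIds = paste0("S", seq_len(nrow(pp))),
        proteins = paste0("P", seq_len(ncol(pp))),
        pPlus = pp, pZero = p0, pMinus = pm,
        delta = numeric(nrow(pp)))
  one <- mk(matrix(0.2), matrix(0.5), matrix(0.3))
  t1 <- scoreTable(aggregatePathwayScores(one))
  expect_equal(unlist(t1[, c("k_plus", "k_zero", "k_minus")]),
               c(k_plus = 0.2, k_zero = 0.5, k_minus = 0.3))
  expect_identical(t1$status, "neutral")

  two <- mk(matrix(c(1, 0), 1), matrix(c(0, 1), 1), matrix(c(0, 0), 1))
  t2 <- scoreTable(aggregatePathwayScores(two))
  expect_equal(t2$k_plus, 0.5)
  expect_identical(t2$status, "neutral")    # tie resolves to neutral

  expect_error(aggregatePathwayScores(
    mk(matrix(0, 0, 1), matrix(0, 0, 1), matrix(0, 0, 1))), "empty")
})

test_that("aggregated triples sum to one and the aberration identity is exact", {
  f <- fit_small()
  ps <- aggregatePathwayScores(scoreSamples(f$net, f$study))
  df <- scoreTable(ps)
  expect_lt(max(abs(df$k_plus + df$k_zero + df$k_minus - 1)), 1e-8)
  expect_identical(df$aberration, 1 - df$k_zero)
  expect_lt(max(abs(df$aberration - (df$k_plus + df$k_minus))), 1e-12)
})
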