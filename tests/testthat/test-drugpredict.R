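# BART drug-sensitivity models: binarization, eligibility, CV, import.

pw12 <- paste0("pw", sprintf("%02d", 1:12))

unif_ab <- function(n, seed) {
  set.seed(seed)
  matrix(runif(n * 12), n, 12,
         dimnames = list(sprintf("C%03d", seq_len(n)), pw12))
}

fast_bart <- bartSettings(draws = 800L, burnin = 200L, keepEvery = 5L)

test_that("continuous panels binarize at the strict per-drug median", {
  v <- matrix(c(1:5, rep(2, 5)), 5, 2,
              dimnames = list(paste0("C", 1:5), c("dA", "dflat")))
  panel <- DrugResponsePanel(v, "continuous")
  expect_warning(bin <- binarizeResponse(panel), "constant")
  expect_identical(colnames(responseMatrix(bin)), "dA")
  expect_identical(unname(responseMatrix(bin)[, "dA"]),
                   c(1, 1, 0, 0, 0))   # median 3 itself is resistant
  # binary panels pass through unchanged
  b <- DrugResponsePanel(matrix(c(0, 1, NA, 1), 2, 2,
                                dimnames = list(c("C1", "C2"),
                                                c("d1", "d2"))),
                         "binary")
  expect_identical(binarizeResponse(b), b)
})

test_that("eligibility rules skip small or single-class inputs", {
  A <- unif_ab(30, 1)
  y <- rep(c(0, 1), 15)
  expect_message(
    m <- fitDrugModel(A[1:9, ], y[1:9], lineage = "l", drug = "d"),
    "need >= 10")
  expect_null(m)
  expect_message(
    m2 <- fitDrugModel(A[1:12, ], rep(1, 12), lineage = "l", drug = "d"),
    "single-class")
  expect_null(m2)
  # missing responses do not count as profiles
  y2 <- y; y2[10:30] <- NA
  expect_message(
    expect_null(fitDrugModel(A, y2, lineage = "l", drug = "d")),
    "only 9")
})

test_that("importance is a normalized, seed-reproducible distribution", {
  A <- unif_ab(60, 2)
  panel <- simulateDrugResponse(A, setNames(c(3, rep(0, 11)), pw12),
                                0.5, seed = 4)
  y <- responseMatrix(panel)[, 1]
  m <- fitDrugModel(A, y, seed = 9, settings = fast_bart, cv = FALSE,
                    lineage = "l", drug = "d")
  imp <- pathwayImportance(m)
  expect_equal(sum(imp), 1, tolerance = 1e-8)
  expect_true(all(imp >= 0))
  expect_identical(names(which.max(imp)), "pw01")
  m2 <- fitDrugModel(A, y, seed = 9, settings = fast_bart, cv = FALSE,
                     lineage = "l", drug = "d")
  expect_identical(imp, pathwayImportance(m2))
  # permuting predictor columns permutes importance (within MCMC noise)
  perm <- c(4:12, 1:3)
  m3 <- fitDrugModel(A[, perm], y, seed = 9, settings = fast_bart,
                     cv = FALSE, lineage = "l", drug = "d")
  expect_identical(names(which.max(pathwayImportance(m3))), "pw01")
  expect_lt(max(abs(pathwayImportance(m3)[pw12] - imp[pw12])), 0.08)
})

test_that("cross-validated AUC tracks the planted signal strength", {
  A <- unif_ab(60, 3)
  # perfectly separable response
  ysep <- as.integer(A[, 5] > median(A[, 5]))
  expect_gte(cvAUC(A, ysep, seed = 11, settings = fast_bart), 0.95)
  # null response
  y0 <- responseMatrix(simulateDrugResponse(A, rep(0, 12), 1,
                                            seed = 21))[, 1]
  auc0 <- cvAUC(A, y0, seed = 13, settings = fast_bart)
  expect_gte(auc0, 0.3)
  expect_lte(auc0, 0.7)
})

test_that("top-predictor and synergy summaries filter and count correctly", {
  mkmodel <- function(drug, imp, auc, n = 20L)
    new("DrugModel", lineage = "l", drug = drug, nProfiles = n,
        cvAuc = auc, importance = imp / sum(imp), forest = list(),
        pathways = names(imp), seed = 1L, meta = list())
  imp1 <- setNames(c(5, 3, 1), c("hormone", "apoptosis", "emt"))
  imp2 <- setNames(c(4, 5, 1), c("hormone", "apoptosis", "emt"))
  models <- list(mkmodel("d1", imp1, 0.9), mkmodel("d2", imp1, 0.95),
                 mkmodel("d3", imp2, 0.84),   # below the AUC cutoff
                 mkmodel("d4", imp2, NA_real_))     # no CV run
  tops <- topPredictorSummary(models)
  expect_identical(tops$n_top[tops$pathway == "hormone"], 2L)
  expect_equal(tops$proportion[tops$pathway == "hormone"], 1)
  expect_equal(tops$log1_proportion[tops$pathway == "hormone"], log(2))
  expect_identical(nrow(topPredictorSummary(list())), 0L)

  syn <- pathwayPairSynergy(models)
  expect_identical(sum(syn$count), 2L)
  expect_identical(syn$pathway_a, "apoptosis")
  expect_identical(syn$pathway_b, "hormone")
  # importance ties break by pathway name order
  tied <- mkmodel("d5", setNames(c(1, 1, 1), c("c", "a", "b")), 0.9)
  syn2 <- pathwayPairSynergy(list(tied))
  expect_identical(c(syn2$pathway_a, syn2$pathway_b), c("a", "b"))
})

test_that("patient prediction is bounded, train-consistent and driver-monotone", {
  A <- unif_ab(60, 6)
  panel <- simulateDrugResponse(A, setNames(c(0, 3, rep(0, 10)), pw12),
                                0.3, seed = 7)
  y <- responseMatrix(panel)[, 1]
  m <- fitDrugModel(A, y, seed = 15, settings = fast_bart, cv = FALSE,
                    lineage = "ovary_cl", drug = "d")
  pat <- new("AberrationMatrix", values = A[1:20, ],
             annotations = data.frame(sample_id = rownames(A)[1:20],
                                      system = "patient",
                                      lineage = "ovary"))
  out <- predictPatients(m, pat, c(ovary = "ovary_cl"))
  expect_true(all(out$predictions$probability >= 0 &
                    out$predictions$probability <= 1))
  expect_gte(out$responseRate, 0)
  expect_lte(out$responseRate, 1)
  # a patient identical to a training cell line scores alike
  trainProb <- PanPathNet:::.bart_probit_predict(
    m@forest$forests, m@forest$offset, A[1:20, ])
  expect_equal(out$predictions$probability, as.numeric(trainProb),
               tolerance = 1e-12)
  # monotone in the planted driver along a 1-D sweep
  sweepX <- matrix(0.5, 40, 12, dimnames = list(NULL, pw12))
  sweepX[, 2] <- seq(0, 1, length.out = 40)
  pr <- PanPathNet:::.bart_probit_predict(m@forest$forests,
                                          m@forest$offset, sweepX)
  expect_gt(pr[40] - pr[1], 0.3)
  expect_lt(max(head(pr, -1) - tail(pr, -1)), 0.02)
  expect_error(predictPatients(m, pat, c(ovary = "other")),
               "no patient lineage maps")
  patBad <- pat
  colnames(patBad@values) <- paste0("x", 1:12)
  expect_error(predictPatients(m, patBad, c(ovary = "ovary_cl")),
               "pathway mismatch")
})
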