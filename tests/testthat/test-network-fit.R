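# Bayesian graphical regression: Gibbs sampler, exact oracle, edges.

chain_study <- function(n = 300, seed = 11) {
  # 3-protein chain A-B-C with partial correlations 0.5
  Om <- matrix(c(1.5, -0.75, 0, -0.75, 1.5, -0.75, 0, -0.75, 1.5), 3, 3)
  Sig <- solve(Om)
  set.seed(seed)
  vals <- matrix(rnorm(n * 3), n, 3) %*% chol(Sig)
  dimnames(vals) <- list(sprintf("S%03d", seq_len(n)), c("A", "B", "C"))
  ann <- data.frame(sample_id = rownames(vals), system = "patient",
                    lineage = "ovary")
  ProteinExpressionStudy(vals, ann)
}

test_that("Gibbs PPIs recover a chain and agree with the exact oracle", {
  study <- chain_study()
  mc <- mcmcSettings(iterations = 20000L, burnin = 5000L, seed = 42)
  net <- fitCancerNetwork(study, mcmc = mc)
  P <- ppiMatrix(net)
  expect_gt(P["A", "B"], 0.9)
  expect_gt(P["B", "C"], 0.9)
  expect_lt(P["A", "C"], 0.5)
  oracle <- exactPosteriorOracle(study, mc)
  expect_lt(max(abs(P - oracle)), 0.05)
})

test_that("on independent noise the sampler matches the oracle and calls no edges", {
  study <- tiny_study(n = 300, p = 4, seed = 19)
  mc <- mcmcSettings(iterations = 20000L, burnin = 5000L, seed = 3)
  net <- fitCancerNetwork(study, mcmc = mc)
  oracle <- exactPosteriorOracle(study, mc)
  expect_lt(max(abs(ppiMatrix(net) - oracle)), 0.05)
  expect_true(all(ppiMatrix(net) < 0.5))
  expect_identical(nrow(callEdges(net)), 0L)
})

test_that("the exact oracle handles degenerate and saturated cases", {
  expect_equal(exactPosteriorOracle(matrix(rnorm(20), 20, 1)),
               matrix(0, 1, 1), ignore_attr = TRUE)
  set.seed(4)
  x <- rnorm(100)
  XX <- cbind(A = x, B = x + rnorm(100, sd = 1e-3))
  expect_gt(exactPosteriorOracle(XX)[1, 2], 0.99)
  expect_error(exactPosteriorOracle(matrix(rnorm(60), 10, 6)),
               "limited to 5")
})

test_that("fitting is deterministic in the seed and validates inputs", {
  study <- tiny_study(n = 40, p = 4, seed = 5)
  mc <- mcmcSettings(iterations = 2000L, burnin = 500L, seed = 13)
  n1 <- fitCancerNetwork(study, mcmc = mc)
  n2 <- fitCancerNetwork(study, mcmc = mc)
  expect_identical(ppiMatrix(n1), ppiMatrix(n2))
  expect_identical(n1@coef, n2@coef)

  expect_error(fitCancerNetwork(tiny_study(n = 5, p = 3), mcmc = mc),
               "insufficient samples")
  vals <- exprMatrix(study)
  vals[, "P2"] <- 1
  flat <- ProteinExpressionStudy(vals, data.frame(
    sample_id = rownames(vals), system = "patient", lineage = "ovary"))
  expect_error(fitCancerNetwork(flat, mcmc = mc),
               "zero-variance protein: P2")
})

test_that("callEdges applies strict PPI > threshold semantics", {
  P <- matrix(0, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  P["A", "B"] <- P["B", "A"] <- 0.51
  P["B", "C"] <- P["C", "B"] <- 0.50
  ed <- callEdges(P, 0.5)
  expect_identical(nrow(ed), 1L)
  expect_identical(ed$protein_a, "A")
  expect_identical(nrow(callEdges(matrix(0, 3, 3), 0.5)), 0L)
  expect_error(callEdges(P, 1.5), "threshold")
})

test_that("symmetrization rules bound the directed probabilities", {
  study <- chain_study(n = 80, seed = 2)
  base <- mcmcSettings(iterations = 3000L, burnin = 500L, seed = 1)
  pmaxr <- ppiMatrix(fitCancerNetwork(study, mcmc = base))
  andr <- mcmcSettings(iterations = 3000L, burnin = 500L, seed = 1,
                       symmetrize = "and")
  meanr <- mcmcSettings(iterations = 3000L, burnin = 500L, seed = 1,
                        symmetrize = "mean")
  pand <- ppiMatrix(fitCancerNetwork(study, mcmc = andr))
  pmean <- ppiMatrix(fitCancerNetwork(study, mcmc = meanr))
  expect_true(all(pand <= pmean + 1e-12))
  expect_true(all(pmean <= pmaxr + 1e-12))
})
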