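# Ground-truth generator: networks, lineages, drug response, bundles.

test_that("simulateNetwork spans empty to complete supports", {
  empty <- simulateNetwork(6, 0, seed = 1)
  expect_identical(sum(empty$adjacency), 0L)
  expect_equal(empty$precision, diag(6), ignore_attr = TRUE)
  full <- simulateNetwork(6, 1, seed = 1)
  expect_identical(sum(full$adjacency[upper.tri(full$adjacency)]), 15L)
  expect_identical(simulateNetwork(6, 0.4, seed = 9),
                   simulateNetwork(6, 0.4, seed = 9))
  expect_error(simulateNetwork(2, 0.5, seed = 1), ">= 3")
})

test_that("generated precisions are positive definite and match the support", {
  for (s in 1:8) {
    net <- simulateNetwork(7, 0.3, seed = s)
    ev <- eigen(net$precision, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 1e-8)
    off <- net$partialCor[upper.tri(net$partialCor)]
    onn <- net$adjacency[upper.tri(net$adjacency)] == 1L
    if (any(onn)) expect_true(all(abs(off[onn]) >= 0.05))
    if (any(!onn)) expect_true(all(off[!onn] == 0))
  }
})

test_that("empirical partial correlations at n = 2000 match the truth", {
  net <- simulateNetwork(6, 0.35, seed = 4)
  sl <- simulateLineage(net, 2000, c(0, 1, 0), 0, seed = 5)
  pcEmp <- -stats::cov2cor(solve(stats::cov(sl$values)))
  diag(pcEmp) <- 1
  expect_lt(max(abs(pcEmp - net$partialCor)), 0.1)
})

test_that("simulateLineage applies shifts per planted status", {
  net <- simulateNetwork(5, 0.2, seed = 2)
  expect_error(simulateLineage(net, 10, c(0.5, 0.6, 0), 1, seed = 1),
               "summing to 1")
  expect_error(simulateLineage(net, 10, c(0, 1, 0), -1, seed = 1),
               ">= 0")
  allAct <- simulateLineage(net, 500, c(1, 0, 0), 3, seed = 3)
  expect_true(all(abs(colMeans(allAct$values) - 3) < 0.5))
  expect_identical(simulateLineage(net, 50, c(0.2, 0.6, 0.2), 2, seed = 8),
                   simulateLineage(net, 50, c(0.2, 0.6, 0.2), 2, seed = 8))
})

test_that("zero shift makes the status groups distributionally identical", {
  net <- simulateNetwork(4, 0.2, seed = 6)
  hits <- 0L
  for (s in 1:100) {
    sl <- simulateLineage(net, 60, c(1 / 3, 1 / 3, 1 / 3), 0, seed = s)
    a <- sl$values[sl$status == "activated", 1]
    n <- sl$values[sl$status == "neutral", 1]
    if (length(a) > 2 && length(n) > 2 &&
        stats::t.test(a, n)$p.value < 0.01) hits <- hits + 1L
  }
  expect_lte(hits, 5L)
})

test_that("drug response thresholds the latent score at the cohort median", {
  ab <- matrix(runif(40 * 3), 40, 3,
               dimnames = list(sprintf("C%02d", 1:40), paste0("pw", 1:3)))
  # single unit weight, zero noise: label = indicator above median
  panel <- simulateDrugResponse(ab, c(0, 1, 0), noiseSd = 0, seed = 2)
  expect_identical(unname(responseMatrix(panel)[, 1]),
                   as.numeric(ab[, 2] > median(ab[, 2])))
  expect_identical(simulateDrugResponse(ab, c(1, 0, 2), 0.5, seed = 4),
                   simulateDrugResponse(ab, c(1, 0, 2), 0.5, seed = 4))
  expect_error(simulateDrugResponse(ab, c(1, 0), 0.5, seed = 1),
               "match the number of pathways")
})

test_that("fixture bundles validate, are pure in (config, seed), warn when underpowered", {
  b <- makeFixtureStudy(seed = 3)
  expect_true(validObject(b$study))
  expect_true(validObject(b$catalog))
  expect_true(validObject(b$panel))
  expect_length(unmatchedProteins(b$catalog, b$study), 0)
  expect_setequal(unique(sampleSystems(b$study)),
                  c("patient", "cell_line"))

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeFixtureBundle(b, d1)
  writeFixtureBundle(makeFixtureStudy(seed = 3), d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)

  expect_warning(
    makeFixtureStudy(fixtureConfig(nPerLineage = 12L), seed = 1),
    "identifiability")
})

test_that("heavy-tailed noise switch keeps unit variance", {
  net <- simulateNetwork(4, 0, seed = 1)
  sl <- simulateLineage(net, 4000, c(0, 1, 0), 0, seed = 2, noise = "t5")
  expect_true(all(abs(apply(sl$values, 2, sd) - 1) < 0.15))
})
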