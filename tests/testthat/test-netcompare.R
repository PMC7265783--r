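# Edge consistency, conservation classes, connectivity score and null.

sym <- function(p, pairs) {
  P <- matrix(0, p, p,
              dimnames = list(paste0("P", 1:p), paste0("P", 1:p)))
  for (pr in pairs) {
    P[pr[[1]], pr[[2]]] <- P[pr[[2]], pr[[1]]] <- pr[[3]]
  }
  P
}

test_that("edge consistency counts lineages per system with strict > 0.5", {
  nets <- list(
    fake_network(sym(3, list(list(1, 2, 0.6), list(2, 3, 0.5))),
                 "ovary", "apoptosis", "patient"),
    fake_network(sym(3, list(list(1, 2, 0.7), list(2, 3, 0.5))),
                 "lung", "apoptosis", "patient"),
    fake_network(sym(3, list(list(1, 2, 0.9))),
                 "breast", "apoptosis", "patient"),
    fake_network(sym(3, list(list(1, 2, 0.4))),
                 "ovary_cl", "apoptosis", "cell_line"))
  tab <- edgeConsistency(nets)
  e12 <- tab[tab$protein_a == "P1" & tab$protein_b == "P2", ]
  expect_identical(e12$patient_count, 3L)
  expect_identical(e12$cellline_count, 0L)
  # PPI exactly 0.5 never counts
  e23 <- tab[tab$protein_a == "P2" & tab$protein_b == "P3", ]
  expect_identical(e23$patient_count, 0L)

  expect_error(edgeConsistency(list()), "empty")
  bad <- fake_network(sym(4, list()), "x", "apoptosis", "patient")
  expect_error(edgeConsistency(c(nets, list(bad))), "inconsistent")
})

test_that("conserved edges are categorized against both cutoffs", {
  tab <- data.frame(pathway = "pw", protein_a = "A", protein_b = "B",
                    patient_count = c(17L, 20L, 0L, 5L),
                    cellline_count = c(10L, 0L, 0L, 9L))
  out <- classifyConservedEdges(tab, patientCutoff = 8L,
                                celllineCutoff = 8L)
  expect_identical(out$category,
                   c("both", "patients_only", "neither",
                     "celllines_only"))
  expect_error(classifyConservedEdges(tab, 0L, 8L), ">= 1")
})

test_that("connectivity score is the exact edge fraction", {
  ed <- data.frame(protein_a = c("P1", "P2", "P1", "P3"),
                   protein_b = c("P2", "P3", "P4", "P5"))
  expect_equal(connectivityScore(ed, 5), 0.4)
  expect_equal(connectivityScore(ed[0, ], 5), 0)
  # complete graph
  all6 <- t(combn(paste0("P", 1:6), 2))
  expect_equal(connectivityScore(
    data.frame(protein_a = all6[, 1], protein_b = all6[, 2]), 6), 1)
  expect_error(connectivityScore(ed, 5, proteins = paste0("P", 1:4)),
               "unknown protein: P5")
  expect_error(connectivityScore(ed, 1), ">= 2")
})

test_that("connectivity score equals brute force and is edge-monotone", {
  for (s in 1:10) {
    set.seed(s)
    p <- sample(4:8, 1)
    P <- matrix(0, p, p)
    idx <- which(upper.tri(P))
    P[idx] <- runif(length(idx))
    P <- pmax(P, t(P))
    colnames(P) <- rownames(P) <- paste0("P", 1:p)
    ed <- callEdges(P, 0.5)
    brute <- sum(P[upper.tri(P)] > 0.5) / choose(p, 2)
    expect_identical(connectivityScore(ed, p), brute)
    # adding one absent edge never decreases the score
    if (nrow(ed) < choose(p, 2)) {
      ed2 <- rbind(ed[, c("protein_a", "protein_b")],
                   setdiff(data.frame(protein_a = rownames(P)[1],
                                      protein_b = rownames(P)[2]),
                           ed[, 1:2]))
      expect_gte(connectivityScore(unique(ed2), p),
                 connectivityScore(ed, p))
    }
  }
})

test_that("the permutation null reports tie-conservative proportions", {
  study <- tiny_study(n = 40, p = 8, seed = 21)
  mc <- mcmcSettings(iterations = 1000L, burnin = 200L)
  res0 <- randomCSNull(study, "ovary", 4, paste0("P", 1:8), nReps = 20,
                       seed = 5, mcmc = mc, observedCS = 2)
  expect_identical(res0$proportion, 0)      # observed beats every null
  expect_identical(res0$exceedance, 1)
  res1 <- randomCSNull(study, "ovary", 4, paste0("P", 1:8), nReps = 20,
                       seed = 5, mcmc = mc, observedCS = -1)
  expect_identical(res1$proportion, 1)      # observed at/below them all
  expect_length(res1$randomCS, 20)
  expect_error(randomCSNull(study, "ovary", 9, paste0("P", 1:8),
                            nReps = 5, seed = 1, mcmc = mc),
               "pool smaller")
})

test_that("lineage linking demands strict exceedance on both sides", {
  res <- data.frame(
    lineage = c("ovary", "ovary_cl", "lung", "lung_cl"),
    system = c("patient", "cell_line", "patient", "cell_line"),
    pathway = "apoptosis",
    exceedance = c(0.92, 0.95, 0.85, 0.99))
  out <- linkLineages(res, cutoff = 0.9)
  expect_identical(nrow(out), 2L)   # both cell lines link to ovary only
  expect_setequal(out$patient_lineage, "ovary")
  # strictness: exactly at the cutoff does not pass
  res$exceedance <- c(0.9, 0.95, 0.9, 0.9)
  expect_identical(nrow(linkLineages(res, cutoff = 0.9)), 0L)
  # row order invariance
  res2 <- data.frame(
    lineage = c("a", "b", "c_cl"), system = c("patient", "patient",
                                              "cell_line"),
    pathway = "pw", exceedance = c(0.95, 0.99, 0.93))
  expect_identical(linkLineages(res2, 0.9),
                   linkLineages(res2[c(3, 1, 2), ], 0.9))
})
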