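# Aberration scores, avatar matching and gap-statistic clustering.

test_that("aberration scores carry the exact identity and demand completeness", {
  df <- data.frame(sample_id = rep(c("S1", "S2"), each = 2),
                   pathway = rep(c("a", "b"), 2),
                   k_plus = c(0.2, 1, 0, 0.3),
                   k_zero = c(0.5, 0, 1, 0.4),
                   k_minus = c(0.3, 0, 0, 0.3),
                   status = c("neutral", "activated", "neutral",
                              "neutral"))
  df$aberration <- 1 - df$k_zero
  ps <- new("PathwayScores", scores = df)
  ann <- data.frame(sample_id = c("S1", "S2"), system = "patient",
                    lineage = "ovary")
  ab <- aberrationScores(ps, ann)
  V <- aberrationValues(ab)
  expect_equal(V["S1", "a"], 0.5)
  expect_equal(V["S1", "b"], 1)    # k_plus = 1
  expect_equal(V["S2", "a"], 0)    # k_zero = 1
  incomplete <- new("PathwayScores", scores = df[-4, ])
  expect_error(aberrationScores(incomplete, ann), "missing sample")
})

test_that("pairwise correlations flag constant vectors and check pathways", {
  pat <- fake_aberration(list(c(0.1, 0.5, 0.9), c(0.9, 0.5, 0.1),
                              c(0.4, 0.4, 0.4)), "ovary", "patient")
  cel <- fake_aberration(list(c(0.1, 0.5, 0.9)), "ovary_cl", "cell_line")
  R <- pairwiseCorrelations(pat, cel)
  expect_equal(R[1, 1], 1)
  expect_equal(R[2, 1], -1)
  expect_true(is.na(R[3, 1]))
  expect_identical(attr(R, "nUndefined"), 1L)
  bad <- cel
  colnames(bad@values) <- c("x", "y", "z")
  expect_error(pairwiseCorrelations(pat, bad), "pathway")
})

test_that("avatar links require more than the pair fraction, strictly", {
  v <- c(0.9, 0.1, 0.8, 0.2, 0.7, 0.1)
  ortho <- c(0.01, 0.21, 0.91, 0.61, 0.38, 0.44)  # |r| vs v ~ 0.01
  # 8 of 10 pairs at |r| ~ 1: 4 matching patients x 2 cell lines
  pat8 <- fake_aberration(c(replicate(4, v, simplify = FALSE),
                            list(ortho)), "ovary", "patient")
  cel2 <- fake_aberration(list(v, v + 0.01), "ovary_cl", "cell_line")
  out <- avatarLinks(pat8, cel2)
  expect_equal(out$percent, 80)
  expect_true(out$link)
  # 7 of 10: no link ("more than 75%" is strict)
  pat7 <- fake_aberration(c(replicate(7, v, simplify = FALSE),
                            replicate(3, ortho, simplify = FALSE)),
                          "ovary", "patient")
  cel1 <- fake_aberration(list(v), "ovary_cl", "cell_line")
  out7 <- avatarLinks(pat7, cel1)
  expect_equal(out7$percent, 70)
  expect_false(out7$link)
  # anti-correlated profiles count through the magnitude
  patneg <- fake_aberration(list(1 - v), "ovary", "patient")
  expect_lt(cor(1 - v, v), -0.9)
  outneg <- avatarLinks(patneg, cel1)
  expect_equal(outneg$percent, 100)
  # constant vectors leave the denominator
  patc <- fake_aberration(list(v, rep(0.5, 6)), "ovary", "patient")
  outc <- avatarLinks(patc, cel1)
  expect_identical(outc$n_defined, 1L)
  expect_equal(outc$percent, 100)
  expect_error(avatarLinks(pat8, cel2, rThreshold = 1.2), "thresholds")
})

test_that("avatar links are symmetric in which system provides rows", {
  set.seed(9)
  mk <- function(lin, sys, n, base)
    fake_aberration(lapply(seq_len(n), function(i)
      base + runif(6, -0.03, 0.03)), lin, sys)
  pat <- mk("ovary", "patient", 5, c(0.9, 0.1, 0.8, 0.1, 0.9, 0.2))
  cel <- mk("ovary_cl", "cell_line", 4, c(0.9, 0.1, 0.8, 0.1, 0.9, 0.2))
  a <- avatarLinks(pat, cel)
  b <- avatarLinks(cel, pat)
  expect_identical(a$link, b$link)
  expect_equal(a$percent, b$percent)
})

test_that("planted partitions are recovered with the gap-chosen K", {
  set.seed(31)
  centers <- matrix(rnorm(3 * 8, sd = 3), 3, 8)
  V <- do.call(rbind, lapply(1:3, function(g)
    matrix(rnorm(15 * 8, mean = rep(centers[g, ], each = 15), sd = 1),
           15, 8)))
  rownames(V) <- sprintf("S%02d", seq_len(nrow(V)))
  truth <- rep(1:3, each = 15)
  cl <- clusterSamples(V, kMax = 6, gapB = 30, seed = 7)
  expect_identical(cl@K, 3L)
  expect_equal(length(unique(paste(clusterLabels(cl),
                                   truth[match(names(clusterLabels(cl)),
                                               rownames(V))]))), 3L)
  # determinism and order invariance
  cl2 <- clusterSamples(V[sample(nrow(V)), ], kMax = 6, gapB = 30,
                        seed = 7)
  expect_identical(clusterLabels(cl), clusterLabels(cl2))
})

test_that("near-identical samples collapse to a single cluster", {
  set.seed(2)
  base <- c(0.2, 0.8, 0.5, 0.9)
  V <- matrix(rep(base, each = 10), 10, 4) +
    matrix(runif(40, 0, 1e-7), 10, 4)
  rownames(V) <- sprintf("S%02d", 1:10)
  cl <- clusterSamples(V, kMax = 4, gapB = 10, seed = 1)
  expect_identical(cl@K, 1L)
})

test_that("cluster composition fractions are coherent", {
  lab <- setNames(c(1L, 1L, 1L, 1L, 2L, 2L), paste0("S", 1:6))
  res <- new("ClusterResult", labels = lab, K = 2L,
             gapCurve = data.frame(), hclust = NULL, seed = 1L)
  ann <- data.frame(sample_id = paste0("S", 1:6),
                    system = c(rep("patient", 4), "cell_line",
                               "cell_line"),
                    lineage = c(rep("ovary", 5), "lung"))
  comp <- clusterComposition(res, ann)
  sys1 <- comp$bySystem[comp$bySystem$cluster == 1, ]
  expect_equal(sys1$fraction[sys1$system == "patient"], 1)
  expect_equal(sys1$fraction[sys1$system == "cell_line"], 0)
  # fractions per lineage sum to 1 across clusters
  sums <- tapply(comp$byLineage$fraction, comp$byLineage$lineage, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("status contrasts between clusters behave like a chi-square test", {
  mkps <- function(statuses) {
    kp <- ifelse(statuses == "activated", 0.8, 0.1)
    k0 <- ifelse(statuses == "neutral", 0.8, 0.1)
    new("PathwayScores", scores = data.frame(
      sample_id = sprintf("S%03d", seq_along(statuses)), pathway = "pw",
      k_plus = kp, k_zero = k0, k_minus = 1 - kp - k0,
      aberration = 1 - k0, status = statuses))
  }
  n <- 100
  lab <- setNames(rep(c(1L, 2L), each = n / 2), sprintf("S%03d", 1:n))
  res <- new("ClusterResult", labels = lab, K = 2L,
             gapCurve = data.frame(), hclust = NULL, seed = 1L)
  same <- mkps(rep(c("activated", "neutral"), n / 2))
  out <- statusContrast(same, res, "pw", c(1L, 2L))
  expect_lt(out$statistic, 1e-6)
  expect_gt(out$p.value, 0.99)
  expect_true(all(abs(colSums(out$percent) - 100) < 1e-9))
  opp <- mkps(rep(c("suppressed", "activated"), each = n / 2))
  out2 <- statusContrast(opp, res, "pw", c(1L, 2L))
  expect_lt(out2$p.value, 1e-6)
  expect_error(statusContrast(same, res, "pw", c(1L, 3L)), "empty")
})

test_that("dendrograms serialize to Newick", {
  set.seed(5)
  V <- matrix(runif(40), 10, 4,
              dimnames = list(sprintf("S%02d", 1:10), NULL))
  cl <- clusterSamples(V, kMax = 3, gapB = 5, seed = 2)
  f <- withr::local_tempfile(fileext = ".nwk")
  exportDendrogram(cl, f)
  tree <- ape::read.tree(f)
  expect_setequal(tree$tip.label, rownames(V))
})
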