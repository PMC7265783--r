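## Pan-cancer stratification: aberration scores, patient/cell-line
## correlation, avatar lineage links, and gap-statistic clustering.

#' Build the sample x pathway network aberration matrix
#'
#' The aberration score of a sample in a pathway is k+ + k- = 1 - k0,
#' its total departure from neutral pathway activity.
#'
#' @param scores a [PathwayScores-class] covering every sample x
#'   pathway combination
#' @param annotations data.frame with columns sample_id, system,
#'   lineage (or a [ProteinExpressionStudy-class] to take them from)
#' @return an [AberrationMatrix-class]
#' @export
aberrationScores <- function(scores, annotations) {
  df <- scoreTable(scores)
  samples <- unique(df$sample_id)
  pathways <- unique(df$pathway)
  if (nrow(df) != length(samples) * length(pathways))
    stop("missing sample x pathway combination: expected ",
         length(samples) * length(pathways), " rows, found ", nrow(df))
  V <- matrix(NA_real_, length(samples), length(pathways),
              dimnames = list(samples, pathways))
  V[cbind(match(df$sample_id, samples), match(df$pathway, pathways))] <-
    df$aberration
  if (anyNA(V)) stop("missing sample x pathway combination")
  if (is(annotations, "ProteinExpressionStudy"))
    annotations <- data.frame(sample_id = colnames(annotations),
                              system = sampleSystems(annotations),
                              lineage = sampleLineages(annotations))
  ann <- annotations[match(samples, annotations$sample_id), ]
  if (anyNA(ann$sample_id))
    stop("annotations missing for scored samples")
  rownames(ann) <- NULL
  new("AberrationMatrix", values = V, annotations = ann)
}

#' Pearson correlations between patient and cell-line samples
#'
#' Correlates each patient sample's aberration vector (across the
#' shared pathway axis) with each cell-line sample's.  Pairs where
#' either vector is constant get `NA` (flagged, excluded from
#' downstream percentages).
#'
#' @param patients,celllines [AberrationMatrix-class] objects with
#'   identical pathway sets and order
#' @return patients x cell-lines correlation matrix; the number of
#'   undefined pairs is attached as attribute `"nUndefined"`
#' @export
pairwiseCorrelations <- function(patients, celllines) {
  A <- aberrationValues(patients)
  B <- aberrationValues(celllines)
  if (!identical(colnames(A), colnames(B)))
    stop("pathway sets/order differ between the two matrices")
  constA <- apply(A, 1, sd) < 1e-12
  constB <- apply(B, 1, sd) < 1e-12
  R <- suppressWarnings(cor(t(A), t(B)))
  R[constA, ] <- NA_real_
  R[, constB] <- NA_real_
  attr(R, "nUndefined") <- sum(is.na(R))
  R
}

#' Avatar links between patient and cell-line lineages
#'
#' For each (patient lineage, cell-line lineage) pair, computes the
#' percentage of sample pairs whose aberration-score correlation has
#' magnitude at least `rThreshold`; a link is emitted iff that
#' percentage strictly exceeds `pairFraction`.  Undefined correlations
#' are excluded from the denominator.
#'
#' @param patients,celllines [AberrationMatrix-class] objects
#' @param rThreshold absolute correlation threshold (default 0.9)
#' @param pairFraction required fraction of qualifying pairs
#'   (default 0.75)
#' @return data.frame with columns patient_lineage, cellline_lineage,
#'   n_pairs, n_defined, percent, link
#' @export
avatarLinks <- function(patients, celllines, rThreshold = 0.9,
                        pairFraction = 0.75) {
  if (rThreshold <= 0 || rThreshold >= 1 ||
      pairFraction <= 0 || pairFraction >= 1)
    stop("thresholds must lie in (0,1)")
  R <- pairwiseCorrelations(patients, celllines)
  pl <- aberrationAnnotations(patients)$lineage
  cl <- aberrationAnnotations(celllines)$lineage
  rows <- list()
  for (p in unique(pl))
    for (c in unique(cl)) {
      sub <- R[pl == p, cl == c, drop = FALSE]
      def <- !is.na(sub)
      nq <- sum(abs(sub[def]) >= rThreshold)
      pct <- if (any(def)) 100 * nq / sum(def) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        patient_lineage = p, cellline_lineage = c,
        n_pairs = length(sub), n_defined = sum(def), percent = pct,
        link = !is.na(pct) && pct > 100 * pairFraction)
    }
  out <- do.call(rbind, rows)
  out <- out[order(out$patient_lineage, out$cellline_lineage), ]
  rownames(out) <- NULL
  out
}

## gap statistic on an arbitrary dissimilarity ------------------------

# pooled within-cluster dispersion W_k = sum_r sum_{i<j in C_r} d_ij/n_r
.within_dispersion <- function(D, labels) {
  w <- 0
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) > 1L)
      w <- w + sum(D[idx, idx][upper.tri(D[idx, idx])]) / length(idx)
  }
  w
}

.cor_dist <- function(V, distance) {
  R <- suppressWarnings(cor(t(V)))
  R[!is.finite(R)] <- 0
  if (distance == "abscor") 1 - abs(R) else 1 - R
}

#' Cluster samples on aberration-score correlations
#'
#' Complete-linkage hierarchical clustering with distance 1 - Pearson
#' correlation between sample aberration vectors (`"abscor"` uses
#' 1 - |r|; `onCorrelationMatrix = TRUE` clusters the rows of the
#' sample x sample correlation matrix itself, with Euclidean
#' distance).  The number of clusters is chosen by the gap statistic
#' with `gapB` uniform reference datasets drawn over the bounding box
#' of the aberration matrix and the first-SE-max rule.
#'
#' Samples are processed in sorted sample-ID order, making the result
#' invariant to input row order; constant-vector samples are removed
#' with a warning before clustering.
#'
#' @param aberration an [AberrationMatrix-class] (or plain samples x
#'   pathways matrix)
#' @param kMax largest candidate K (must be < number of samples)
#' @param gapB number of uniform reference datasets (default 50)
#' @param seed integer seed for the reference draws
#' @param distance `"cor"` (default) or `"abscor"`
#' @param onCorrelationMatrix cluster the correlation matrix rows
#'   instead of the aberration vectors (default FALSE)
#' @return a [ClusterResult-class]
#' @export
clusterSamples <- function(aberration, kMax = 10L, gapB = 50L,
                           seed = 1L, distance = c("cor", "abscor"),
                           onCorrelationMatrix = FALSE) {
  distance <- match.arg(distance)
  V <- if (is(aberration, "AberrationMatrix"))
    aberrationValues(aberration) else as.matrix(aberration)
  if (nrow(V) < 3L) stop("need >= 3 samples to cluster")
  if (is.null(rownames(V))) rownames(V) <- paste0("S", seq_len(nrow(V)))
  V <- V[order(rownames(V)), , drop = FALSE]
  const <- apply(V, 1, sd) < 1e-12
  if (any(const)) {
    warning("removed ", sum(const),
            " constant-vector sample(s) before clustering")
    V <- V[!const, , drop = FALSE]
  }
  n <- nrow(V)
  if (kMax >= n) stop("kMax must be smaller than the number of samples")

  dmat <- function(M) {
    if (onCorrelationMatrix) {
      R <- suppressWarnings(cor(t(M))); R[!is.finite(R)] <- 0
      as.matrix(dist(R))
    } else .cor_dist(M, distance)
  }
  D <- dmat(V)

  hc <- hclust(as.dist(D), method = "complete")
  ks <- seq_len(kMax)
  if (max(D) < 1e-8) {
    labels <- setNames(rep(1L, n), rownames(V))
    return(new("ClusterResult", labels = labels, K = 1L,
               gapCurve = data.frame(k = 1L, logW = NA_real_,
                                     ElogW = NA_real_, gap = NA_real_,
                                     se = NA_real_),
               hclust = hc, seed = as.integer(seed)))
  }

  cuts <- cutree(hc, k = ks)
  logW <- vapply(ks, function(k)
    log(max(.within_dispersion(D, cuts[, k]), 1e-12)), numeric(1))

  lo <- apply(V, 2, min); hi <- apply(V, 2, max)
  set.seed(as.integer(seed))
  refW <- matrix(NA_real_, gapB, kMax)
  for (b in seq_len(gapB)) {
    Vb <- sapply(seq_along(lo), function(j) runif(n, lo[j], hi[j]))
    Db <- dmat(Vb)
    hb <- hclust(as.dist(Db), method = "complete")
    cb <- cutree(hb, k = ks)
    refW[b, ] <- vapply(ks, function(k)
      log(max(.within_dispersion(Db, cb[, k]), 1e-12)), numeric(1))
  }
  ElogW <- colMeans(refW)
  gap <- ElogW - logW
  se <- apply(refW, 2, sd) * sqrt(1 + 1 / gapB)

  K <- kMax
  for (k in seq_len(kMax - 1L))
    if (gap[k] >= gap[k + 1L] - se[k + 1L]) { K <- k; break }

  raw <- cuts[, K]
  labels <- setNames(match(raw, unique(raw)), rownames(V))
  new("ClusterResult", labels = as.integer(labels) |>
        setNames(rownames(V)), K = as.integer(K),
      gapCurve = data.frame(k = ks, logW = logW, ElogW = ElogW,
                            gap = gap, se = se),
      hclust = hc, seed = as.integer(seed))
}

#' Cluster composition by lineage and system
#'
#' @param result a [ClusterResult-class]
#' @param annotations data.frame with sample_id, system, lineage
#' @return list of two data.frames: `bySystem` (cluster, system, n,
#'   fraction of the cluster) and `byLineage` (cluster, lineage, n,
#'   fraction of that lineage's samples falling in the cluster)
#' @export
clusterComposition <- function(result, annotations) {
  lab <- clusterLabels(result)
  ann <- annotations[match(names(lab), annotations$sample_id), ]
  if (anyNA(ann$sample_id))
    stop("annotations missing for clustered samples")
  bySys <- as.data.frame(table(cluster = lab, system = ann$system),
                         responseName = "n")
  tot <- tapply(bySys$n, bySys$cluster, sum)
  bySys$fraction <- bySys$n / as.numeric(tot[as.character(bySys$cluster)])
  byLin <- as.data.frame(table(cluster = lab, lineage = ann$lineage),
                         responseName = "n")
  ltot <- tapply(byLin$n, byLin$lineage, sum)
  byLin$fraction <- byLin$n /
    as.numeric(ltot[as.character(byLin$lineage)])
  list(bySystem = bySys, byLineage = byLin)
}

#' Status contrast between two clusters for one pathway
#'
#' Builds the 3 x 2 contingency of pathway status (activated, neutral,
#' suppressed) against cluster membership and runs a chi-square test.
#'
#' @param scores a [PathwayScores-class]
#' @param result a [ClusterResult-class]
#' @param pathway pathway name
#' @param clusters length-2 vector of cluster IDs to contrast
#' @return list with `counts`, `percent` (column percentages),
#'   `statistic` and `p.value`
#' @export
statusContrast <- function(scores, result, pathway, clusters) {
  df <- scoreTable(scores)
  df <- df[df$pathway == pathway, ]
  lab <- clusterLabels(result)
  df$cluster <- lab[df$sample_id]
  df <- df[!is.na(df$cluster) & df$cluster %in% clusters, ]
  for (cl in clusters)
    if (!any(df$cluster == cl))
      stop("cluster ", cl, " is empty for pathway '", pathway, "'")
  counts <- table(factor(df$status, levels = c("activated", "neutral",
                                               "suppressed")),
                  factor(df$cluster, levels = clusters))
  if (all(counts == 0)) stop("expected cell count 0 in every cell")
  pct <- sweep(counts, 2, colSums(counts), "/") * 100
  used <- counts[rowSums(counts) > 0, , drop = FALSE]
  if (nrow(used) < 2L) {
    stat <- 0; pval <- 1
  } else {
    ct <- suppressWarnings(chisq.test(used, correct = FALSE))
    stat <- unname(ct$statistic); pval <- unname(ct$p.value)
  }
  list(counts = counts, percent = pct, statistic = stat,
       p.value = pval)
}

#' Export a clustering dendrogram in Newick format
#'
#' @param result a [ClusterResult-class]
#' @param path output file
#' @return invisibly, `path`
#' @export
exportDendrogram <- function(result, path) {
  ape::write.tree(ape::as.phylo(result@hclust), file = path)
  invisible(path)
}
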