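## Comparing fitted networks across lineages and model systems: edge
## consistency, conservation categories, connectivity score and its
## permutation null, and cross-system lineage linking.

#' Edge consistency across lineages and systems
#'
#' For every unordered protein pair within a pathway, counts how many
#' patient lineages and how many cell-line lineages hold the edge with
#' PPI strictly above the threshold.
#'
#' @param networks list of [CancerNetwork-class] across lineages and
#'   systems; all networks of a pathway must share the protein set
#' @param threshold inclusion-probability threshold (default 0.5)
#' @return data.frame with columns pathway, protein_a, protein_b,
#'   patient_count, cellline_count
#' @export
edgeConsistency <- function(networks, threshold = 0.5) {
  if (!length(networks)) stop("empty network collection")
  pws <- unique(vapply(networks, function(n) n@pathway, character(1)))
  out <- list()
  for (pw in pws) {
    nets <- Filter(function(n) n@pathway == pw, networks)
    prot <- nets[[1L]]@proteins
    for (n in nets)
      if (!identical(n@proteins, prot))
        stop("inconsistent protein sets for pathway '", pw, "'")
    idx <- which(upper.tri(diag(length(prot))), arr.ind = TRUE)
    pat <- cel <- integer(nrow(idx))
    for (n in nets) {
      held <- n@ppi[idx] > threshold
      if (n@system == "patient") pat <- pat + held else cel <- cel + held
    }
    out[[pw]] <- data.frame(pathway = pw,
                            protein_a = prot[idx[, 1L]],
                            protein_b = prot[idx[, 2L]],
                            patient_count = pat, cellline_count = cel)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify conserved edges into sharing categories
#'
#' An edge is `both` when its patient and cell-line lineage counts meet
#' the respective cutoffs, `patients_only` / `celllines_only` when
#' exactly one side qualifies, and `neither` otherwise.  Defaults
#' mirror the "highly conserved" reading: shared by more than 20
#' patient lineages, more than 8 cell-line lineages.
#'
#' @param table output of [edgeConsistency()]
#' @param patientCutoff,celllineCutoff minimum lineage counts (>= 1)
#' @return the table with an added `category` column
#' @export
classifyConservedEdges <- function(table, patientCutoff = 21L,
                                   celllineCutoff = 9L) {
  if (patientCutoff < 1L || celllineCutoff < 1L)
    stop("cutoffs must be >= 1")
  p <- table$patient_count >= patientCutoff
  c <- table$cellline_count >= celllineCutoff
  table$category <- ifelse(p & c, "both",
                    ifelse(p, "patients_only",
                    ifelse(c, "celllines_only", "neither")))
  table
}

#' Connectivity score of a pathway network
#'
#' The ratio of observed edges to all possible undirected edges over
#' the pathway's proteins.
#'
#' @param edges edge set: a data.frame with columns protein_a,
#'   protein_b (e.g. from [callEdges()]) or an edge count
#' @param nProteins number of proteins in the pathway (>= 2)
#' @param proteins optional protein IDs; when given, edges referencing
#'   unknown proteins are an error
#' @return fraction in [0, 1]
#' @export
connectivityScore <- function(edges, nProteins, proteins = NULL) {
  if (nProteins < 2L) stop("nProteins must be >= 2")
  if (is.data.frame(edges)) {
    if (!is.null(proteins)) {
      bad <- setdiff(c(edges$protein_a, edges$protein_b), proteins)
      if (length(bad))
        stop("edge references unknown protein: ", bad[1L])
    }
    nEdges <- nrow(edges)
  } else nEdges <- as.integer(edges)
  nEdges / (nProteins * (nProteins - 1) / 2)
}

# lightweight CS for a protein subset of a standardized lineage matrix
.quick_cs <- function(Z, mcmc, threshold) {
  fit <- .gibbs_network_fit(Z, mcmc$iterations, mcmc$burnin,
                            mcmc$piIncl, mcmc$tau2, mcmc$a0, mcmc$b0)
  P <- .symmetrize_ppi(fit$ppi, mcmc$symmetrize)
  sum(P[upper.tri(P)] > threshold) / (ncol(Z) * (ncol(Z) - 1) / 2)
}

#' Permutation null for the connectivity score
#'
#' For each replicate, draws `pathwaySize` proteins uniformly without
#' replacement from the all-pathway pool, refits the network for the
#' same lineage on that protein set (with reduced sampler settings by
#' default) and records its connectivity score.  The reported
#' `proportion` is the fraction of null values at or above the observed
#' CS (ties count against significance); `exceedance = 1 - proportion`
#' is the fraction of null values the observed CS strictly beats.
#' `pit` is the tie-randomized probability-integral transform of the
#' observed CS within the null ensemble, exactly uniform under
#' exchangeability and used for calibration diagnostics of the
#' discrete CS statistic.
#'
#' @param study a [ProteinExpressionStudy-class]
#' @param lineage lineage to refit on
#' @param pathwaySize number of proteins per replicate
#' @param proteinPool candidate proteins (>= pathwaySize), normally the
#'   union over all pathways
#' @param nReps number of replicates (default 1000)
#' @param seed integer seed
#' @param mcmc reduced [mcmcSettings()] for the refits
#' @param threshold edge-calling threshold (default 0.5)
#' @param observedCS optional observed connectivity score; when given,
#'   `proportion`, `exceedance` and `pit` are filled in
#' @return list with fields lineage, cs, randomCS, proportion,
#'   exceedance, pit, nReps, seed
#' @export
randomCSNull <- function(study, lineage, pathwaySize, proteinPool,
                         nReps = 1000L, seed = 1L,
                         mcmc = mcmcSettings(iterations = 2000L,
                                             burnin = 500L),
                         threshold = 0.5, observedCS = NULL) {
  if (length(proteinPool) < pathwaySize)
    stop("protein pool smaller than the pathway size")
  if (nReps < 1L) stop("nReps must be >= 1")
  slice <- sliceStudy(study, lineage = lineage, proteins = proteinPool)
  X <- exprMatrix(slice)
  scl <- apply(X, 2, sd)
  if (any(scl < 1e-12))
    stop("zero-variance protein: ", colnames(X)[which(scl < 1e-12)[1L]])
  Z <- sweep(sweep(X, 2, colMeans(X)), 2, scl, "/")
  set.seed(as.integer(seed))
  null <- vapply(seq_len(nReps), function(r) {
    pick <- sample(ncol(Z), pathwaySize)
    .quick_cs(Z[, pick, drop = FALSE], mcmc, threshold)
  }, numeric(1))
  res <- list(lineage = lineage, cs = observedCS, randomCS = null,
              proportion = NA_real_, exceedance = NA_real_,
              pit = NA_real_, nReps = as.integer(nReps),
              seed = as.integer(seed))
  if (!is.null(observedCS)) {
    res$proportion <- mean(null >= observedCS)
    res$exceedance <- 1 - res$proportion
    nTie <- sum(null == observedCS)
    res$pit <- (sum(null > observedCS) + runif(1) * (nTie + 1)) /
      (nReps + 1)
  }
  res
}

#' Observed CS and permutation null for every fitted network
#'
#' @param networks named list from [fitNetworks()]
#' @param study the study the networks were fitted on
#' @param catalog the [PathwayCatalog-class] (defines the protein pool)
#' @param nReps null replicates per network (default 1000)
#' @param seed integer seed
#' @param mcmc reduced [mcmcSettings()] for the null refits
#' @param threshold edge-calling threshold (default 0.5)
#' @return data.frame with columns lineage, system, pathway, cs,
#'   proportion, exceedance, pit
#' @export
connectivityTable <- function(networks, study, catalog,
                              nReps = 1000L, seed = 1L,
                              mcmc = mcmcSettings(iterations = 2000L,
                                                  burnin = 500L),
                              threshold = 0.5) {
  pool <- unique(unlist(catalog@pathways, use.names = FALSE))
  pool <- intersect(pool, rownames(study))
  rows <- list()
  for (k in seq_along(networks)) {
    net <- networks[[k]]
    obs <- connectivityScore(callEdges(net, threshold),
                             length(net@proteins), net@proteins)
    nl <- randomCSNull(study, net@lineage, length(net@proteins), pool,
                       nReps = nReps,
                       seed = (seed + 17L * k) %% 2147483647L,
                       mcmc = mcmc, threshold = threshold,
                       observedCS = obs)
    rows[[k]] <- data.frame(lineage = net@lineage, system = net@system,
                            pathway = net@pathway, cs = obs,
                            proportion = nl$proportion,
                            exceedance = nl$exceedance, pit = nl$pit)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Link cell-line and patient lineages through shared pathway
#' cross-signaling
#'
#' A (cell-line lineage, pathway, patient lineage) triplet is emitted
#' when both lineages individually show an observed CS strictly
#' exceeding `cutoff` of their null CS values for that pathway
#' (`exceedance > cutoff`; e.g. cutoff 0.9 demands more than 900 of
#' 1000 random CS values beaten).
#'
#' @param results data.frame from [connectivityTable()] (columns
#'   lineage, system, pathway, exceedance)
#' @param cutoff required null-exceedance fraction (0.9 or 0.8 in the
#'   standard analyses)
#' @return data.frame with columns cellline_lineage, pathway,
#'   patient_lineage, sorted; invariant to input row order
#' @export
linkLineages <- function(results, cutoff) {
  pass <- results[!is.na(results$exceedance) &
                  results$exceedance > cutoff, ]
  cl <- pass[pass$system == "cell_line", c("lineage", "pathway")]
  pa <- pass[pass$system == "patient", c("lineage", "pathway")]
  out <- merge(cl, pa, by = "pathway",
               suffixes = c("_cellline", "_patient"))
  out <- data.frame(cellline_lineage = out$lineage_cellline,
                    pathway = out$pathway,
                    patient_lineage = out$lineage_patient)
  out <- out[order(out$cellline_lineage, out$pathway,
                   out$patient_lineage), ]
  rownames(out) <- NULL
  out
}
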