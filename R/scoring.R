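## Deconvolving a fitted lineage network into sample-specific pathway
## scores.
##
## Each sample's standardized profile z_j is modelled as a latent
## pathway shift delta_j shared by all member proteins plus network
## noise:  z_j = delta_j 1 + eps_j,  eps_j ~ N(0, Sigma-hat).  delta_j
## is the GLS estimate through the fitted precision, and each protein's
## departure t_ij = z_ij - B(z_j - delta_j 1)_i (its value minus the
## network prediction from the de-shifted neighbours) is scored against
## a robust residual scale:  p+ = P(N(t/s, 1) > c), p- = P(N(t/s, 1) <
## -c), p0 the remainder, with tail cutoff c = 1 by default.

#' Score samples against a fitted cancer network
#'
#' Computes the per-sample, per-protein activation / neutral /
#' suppression probability triples (see the package vignette for the
#' deconvolution model).  The training slice's centering, scale and
#' residual scale are reused verbatim, so any sample set measured on
#' the same proteins can be scored, including samples from the other
#' model system.
#'
#' @param network a [CancerNetwork-class]
#' @param study a [ProteinExpressionStudy-class] (or samples x proteins
#'   matrix) covering the network's proteins
#' @param cCut tail cutoff c in predictive standard deviations
#'   (default 1)
#' @return a [SampleScores-class]
#' @export
scoreSamples <- function(network, study, cCut = 1) {
  X <- if (is(study, "ProteinExpressionStudy")) exprMatrix(study)
       else as.matrix(study)
  miss <- setdiff(network@proteins, colnames(X))
  if (length(miss))
    stop("missing protein in study: ", paste(miss, collapse = ", "))
  X <- X[, network@proteins, drop = FALSE]
  Z <- sweep(sweep(X, 2, network@center), 2, network@scale, "/")
  delta <- .pathway_shift(Z)
  Tm <- Z - (Z - delta) %*% t(network@coef)
  Zs <- sweep(Tm, 2, network@residScale, "/")
  pPlus <- pnorm(Zs - cCut)
  pMinus <- pnorm(-Zs - cCut)
  pZero <- 1 - pPlus - pMinus
  new("SampleScores", lineage = network@lineage,
      pathway = network@pathway, sampleIds = rownames(X),
      proteins = network@proteins, pPlus = pPlus, pZero = pZero,
      pMinus = pMinus, delta = delta)
}

#' Score samples from the other model system against a network
#'
#' Identical computation to [scoreSamples()]; provided as the explicit
#' cross-system entry point (e.g. scoring cell lines against a patient
#' lineage's network).  Scoring the training slice reproduces
#' [scoreSamples()] exactly.
#'
#' @inheritParams scoreSamples
#' @param otherStudy sample set from the other model system
#' @return a [SampleScores-class]
#' @export
scoreCrossSystem <- function(network, otherStudy, cCut = 1) {
  scoreSamples(network, otherStudy, cCut = cCut)
}

.status_call <- function(kp, k0, km) {
  ifelse(kp > k0 & kp > km, "activated",
         ifelse(km > k0 & km > kp, "suppressed", "neutral"))
}

#' Aggregate protein-level scores into pathway scores
#'
#' k^s_j is the mean over pathway proteins of p^s_ij for each status s;
#' k0 is stored as 1 - (k+ + k-) so that the aberration identity
#' aberration = k+ + k- = 1 - k0 holds exactly.  The derived status is
#' the argmax of the triple, with any tie resolved to neutral.
#'
#' @param scores a [SampleScores-class]
#' @return a [PathwayScores-class] with one row per sample
#' @export
aggregatePathwayScores <- function(scores) {
  if (nrow(scores@pPlus) == 0L) stop("empty scores")
  kp <- rowMeans(scores@pPlus)
  km <- rowMeans(scores@pMinus)
  k0 <- 1 - (kp + km)
  ab <- 1 - k0   # bitwise-exact aberration = 1 - k0 identity
  df <- data.frame(sample_id = scores@sampleIds,
                   pathway = scores@pathway,
                   k_plus = kp, k_zero = k0, k_minus = km,
                   aberration = ab,
                   status = .status_call(kp, k0, km),
                   row.names = NULL)
  new("PathwayScores", scores = df)
}

#' Combine pathway score tables
#'
#' @param ... [PathwayScores-class] objects (or one list of them)
#' @return a single [PathwayScores-class]
#' @export
combinePathwayScores <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && is.list(xs[[1L]]) && !is(xs[[1L]], "PathwayScores"))
    xs <- xs[[1L]]
  df <- do.call(rbind, lapply(xs, scoreTable))
  rownames(df) <- NULL
  new("PathwayScores", scores = df)
}

#' Score every sample of a study under its own lineage's networks
#'
#' Each sample is scored against the network fitted for its lineage,
#' one pathway at a time, and the protein-level triples are aggregated
#' into pathway scores.
#'
#' @param networks named list from [fitNetworks()]
#' @param study the [ProteinExpressionStudy-class] the networks were
#'   fitted on (or any study with the same lineages/proteins)
#' @param cCut tail cutoff (default 1)
#' @return a [PathwayScores-class] covering all samples x pathways
#' @export
scoreStudy <- function(networks, study, cCut = 1) {
  parts <- lapply(networks, function(net) {
    slice <- sliceStudy(study, lineage = net@lineage,
                        proteins = net@proteins)
    aggregatePathwayScores(scoreSamples(net, slice, cCut = cCut))
  })
  combinePathwayScores(parts)
}
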