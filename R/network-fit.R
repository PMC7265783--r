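## Fitting the lineage x pathway Bayesian graphical regression.
##
## Node-wise spike-and-slab linear model on the standardized slice:
##   x_i = sum_{k != i} gamma_ik beta_ik x_k + eps_i
##   gamma_ik ~ Bernoulli(piIncl), beta_ik | in ~ N(0, tau2 sigma2),
##   sigma2 ~ IG(a0, b0)
## PPI(i,k) = posterior inclusion frequency; the undirected PPI is the
## max (configurable) over the two directions.

#' Sampler settings for the graphical regression
#'
#' @param iterations total Gibbs iterations (default 20000)
#' @param burnin burn-in iterations discarded (default 5000)
#' @param seed integer seed
#' @param piIncl prior edge-inclusion probability (default 0.2)
#' @param tau2 slab variance multiplier (slab variance = tau2 * sigma2)
#' @param a0,b0 Inverse-Gamma prior on the residual variance
#' @param symmetrize `"max"` (default), `"mean"` or `"and"` (min) rule
#'   combining the two directed inclusion probabilities
#' @return a settings list
#' @export
mcmcSettings <- function(iterations = 20000L, burnin = 5000L, seed = 1L,
                         piIncl = 0.2, tau2 = 1, a0 = 2, b0 = 1,
                         symmetrize = c("max", "mean", "and")) {
  symmetrize <- match.arg(symmetrize)
  if (iterations <= burnin) stop("iterations must exceed burnin")
  list(iterations = as.integer(iterations), burnin = as.integer(burnin),
       seed = as.integer(seed), piIncl = piIncl, tau2 = tau2,
       a0 = a0, b0 = b0, symmetrize = symmetrize)
}

.symmetrize_ppi <- function(P, rule) {
  switch(rule,
         max = pmax(P, t(P)),
         mean = (P + t(P)) / 2,
         and = pmin(P, t(P)))
}

# Core fit on a plain samples x proteins matrix.
.fit_network_core <- function(X, mcmc, lineage, pathway, system) {
  n <- nrow(X); p <- ncol(X)
  if (n < 10L) stop("insufficient samples (n = ", n, ", need >= 10)")
  center <- colMeans(X)
  scl <- apply(X, 2, sd)
  zero <- which(scl < 1e-12)
  if (length(zero))
    stop("zero-variance protein: ", colnames(X)[zero[1L]])
  Z <- sweep(sweep(X, 2, center), 2, scl, "/")
  set.seed(mcmc$seed)
  fit <- .gibbs_network_fit(Z, mcmc$iterations, mcmc$burnin,
                            mcmc$piIncl, mcmc$tau2, mcmc$a0, mcmc$b0)
  ppi <- .symmetrize_ppi(fit$ppi, mcmc$symmetrize)
  diag(ppi) <- 0
  dimnames(ppi) <- dimnames(fit$coef) <- dimnames(fit$coefCond) <-
    list(colnames(X), colnames(X))

  # precision implied by the node-wise regressions (symmetrized), used
  # by the latent-shift deconvolution in scoreSamples()
  Dinv <- diag(1 / pmax(fit$sigma2, 1e-10), p)
  Or <- Dinv %*% (diag(p) - fit$coef)
  omega <- (Or + t(Or)) / 2
  dimnames(omega) <- dimnames(ppi)

  # neutral reference scale of the deconvolution departure t = delta + e:
  # robust (MAD) spread of the de-shifted conditional residual e, plus
  # an estimate of the shift-estimation noise for a neutral sample;
  # both are free of contamination by genuinely aberrant samples
  delta <- .pathway_shift(Z)
  Tm <- Z - (Z - delta) %*% t(fit$coef)
  E <- Tm - delta
  madE <- apply(E, 2, mad)
  seDelta2 <- mean(madE^2) / p
  residScale <- pmax(sqrt(madE^2 + seDelta2), 1e-8)

  new("CancerNetwork", lineage = lineage, pathway = pathway,
      system = system, proteins = colnames(X), ppi = ppi,
      coef = fit$coef, coefCond = fit$coefCond,
      sigma2 = as.numeric(fit$sigma2), omega = omega,
      center = center, scale = scl,
      residScale = as.numeric(residScale), nSamples = as.integer(n),
      samplerMeta = mcmc)
}

# Per-sample latent pathway-shift estimate: the mean standardized
# value over pathway proteins.  An equal-weight estimator is used
# (rather than GLS through the fitted precision) because a strongly
# shifted cohort biases the fitted graph toward absorbing the shift
# direction, which would make a precision-weighted estimator
# degenerate exactly when the shift matters most.
.pathway_shift <- function(Z) rowMeans(Z)

#' Fit a cancer-specific pathway network for one lineage
#'
#' Restricts the study to one lineage and one pathway's proteins,
#' standardizes each protein to mean 0 / sd 1 within the slice, and
#' runs the node-wise spike-and-slab Gibbs sampler.
#'
#' @param study a [ProteinExpressionStudy-class]; either already
#'   restricted to one lineage/pathway or restricted here via
#'   `lineage`, `pathway` + `catalog` (or `proteins`)
#' @param lineage optional lineage label to slice on
#' @param pathway optional pathway name (requires `catalog`)
#' @param catalog optional [PathwayCatalog-class]
#' @param proteins optional explicit protein set
#' @param mcmc [mcmcSettings()]
#' @return a [CancerNetwork-class]
#' @export
fitCancerNetwork <- function(study, lineage = NULL, pathway = NULL,
                             catalog = NULL, proteins = NULL,
                             mcmc = mcmcSettings()) {
  if (!is.null(pathway)) {
    if (is.null(proteins)) {
      if (is.null(catalog))
        stop("pathway slicing requires a catalog or explicit proteins")
      proteins <- pathwayMembers(catalog, pathway)
    }
  }
  slice <- sliceStudy(study, lineage = lineage, proteins = proteins)
  lin <- unique(sampleLineages(slice))
  if (length(lin) != 1L)
    stop("slice must contain exactly one lineage (found: ",
         paste(lin, collapse = ", "), ")")
  sys <- unique(sampleSystems(slice))
  sys <- if (length(sys) == 1L) sys else "mixed"
  .fit_network_core(exprMatrix(slice), mcmc, lin,
                    if (is.null(pathway)) "all" else pathway, sys)
}

#' Fit networks for every lineage x pathway combination
#'
#' @param study a [ProteinExpressionStudy-class]
#' @param catalog a [PathwayCatalog-class]
#' @param mcmc [mcmcSettings()]; per-fit seeds are derived
#'   deterministically from `mcmc$seed`
#' @param lineages optional subset of lineages (default: all)
#' @return named list of [CancerNetwork-class], names
#'   `"<lineage>|<pathway>"`
#' @export
fitNetworks <- function(study, catalog, mcmc = mcmcSettings(),
                        lineages = NULL) {
  if (is.null(lineages)) lineages <- unique(sampleLineages(study))
  nets <- list()
  k <- 0L
  for (lin in lineages)
    for (pw in pathwayNames(catalog)) {
      k <- k + 1L
      m <- mcmc
      m$seed <- (mcmc$seed + 13L * k) %% 2147483647L
      nets[[paste(lin, pw, sep = "|")]] <-
        fitCancerNetwork(study, lineage = lin, pathway = pw,
                         catalog = catalog, mcmc = m)
    }
  nets
}

#' Exact posterior edge-inclusion probabilities by subset enumeration
#'
#' Independent test oracle for [fitCancerNetwork()]: for each node it
#' enumerates all predictor subsets, computes the closed-form conjugate
#' marginal likelihood under the identical prior, and returns exact
#' posterior inclusion probabilities, symmetrized by the same rule.
#' Limited to 5 proteins (16 subsets per node).
#'
#' @param study a [ProteinExpressionStudy-class] slice or a plain
#'   samples x proteins matrix (max 5 proteins)
#' @param mcmc [mcmcSettings()] (only the prior fields are used)
#' @return exact symmetric PPI matrix
#' @export
exactPosteriorOracle <- function(study, mcmc = mcmcSettings()) {
  X <- if (is(study, "ProteinExpressionStudy")) exprMatrix(study)
       else as.matrix(study)
  p <- ncol(X)
  if (p > 5L)
    stop("exact enumeration is limited to 5 proteins (got ", p, ")")
  Z <- scale(X)
  ppi <- matrix(0, p, p, dimnames = list(colnames(X), colnames(X)))
  if (p < 2L) return(ppi)
  for (i in seq_len(p)) {
    preds <- setdiff(seq_len(p), i)
    m <- length(preds)
    subsets <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), m)))
    lw <- apply(subsets, 1L, function(g) {
      kk <- sum(g)
      .log_marginal(Z[, i], Z[, preds[g], drop = FALSE],
                    mcmc$tau2, mcmc$a0, mcmc$b0) +
        kk * log(mcmc$piIncl) + (m - kk) * log(1 - mcmc$piIncl)
    })
    w <- exp(lw - max(lw)); w <- w / sum(w)
    for (k in seq_len(m))
      ppi[i, preds[k]] <- sum(w[subsets[, k]])
  }
  .symmetrize_ppi(ppi, mcmc$symmetrize)
}

# log marginal likelihood of y under the conjugate spike-and-slab
# regression with sigma2 integrated out (Inverse-Gamma(a0, b0)) and
# slab variance tau2 * sigma2
.log_marginal <- function(y, X, tau2, a0, b0) {
  n <- length(y)
  yy <- sum(y * y)
  if (is.null(dim(X)) || ncol(X) == 0L) {
    ldet <- 0; quad <- yy
  } else {
    m <- ncol(X)
    M <- diag(m) + tau2 * crossprod(X)
    Xty <- crossprod(X, y)
    ldet <- as.numeric(determinant(M, logarithm = TRUE)$modulus)
    quad <- yy - tau2 * drop(crossprod(Xty, solve(M, Xty)))
  }
  lgamma(a0 + n / 2) - lgamma(a0) + a0 * log(b0) -
    (n / 2) * log(2 * pi) - 0.5 * ldet -
    (a0 + n / 2) * log(b0 + 0.5 * quad)
}

#' Call edges from a fitted network
#'
#' An unordered protein pair is an edge iff its posterior inclusion
#' probability strictly exceeds the threshold (default 0.5).
#'
#' @param network a [CancerNetwork-class] (or a symmetric PPI matrix)
#' @param threshold inclusion-probability threshold in (0, 1)
#' @return data.frame with columns protein_a, protein_b, ppi, sign
#' @export
callEdges <- function(network, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie in (0,1)")
  if (is(network, "CancerNetwork")) {
    P <- network@ppi
    sgn <- sign(network@coefCond + t(network@coefCond))
    prot <- network@proteins
  } else {
    P <- network
    sgn <- matrix(0, nrow(P), ncol(P))
    prot <- if (is.null(colnames(P))) paste0("P", seq_len(ncol(P)))
            else colnames(P)
  }
  idx <- which(upper.tri(P) & P > threshold, arr.ind = TRUE)
  data.frame(protein_a = prot[idx[, 1L]], protein_b = prot[idx[, 2L]],
             ppi = P[idx], sign = as.integer(sgn[idx]))
}
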