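## S4 classes for the PanPathNet data model.

#' ProteinExpressionStudy: annotated sample x protein expression
#'
#' Thin subclass of [SummarizedExperiment::SummarizedExperiment] holding
#' one assay `"exprs"` (proteins in rows, samples in columns) and
#' per-sample annotations `system` (`"patient"` or `"cell_line"`) and
#' `lineage` (tissue-of-origin label) in `colData`.
#'
#' @slot .. see `SummarizedExperiment`; no extra slots.
#' @export
setClass("ProteinExpressionStudy", contains = "SummarizedExperiment")

.validProteinExpressionStudy <- function(object) {
  msg <- character()
  cd <- colData(object)
  if (!all(c("system", "lineage") %in% colnames(cd)))
    msg <- c(msg, "colData must contain 'system' and 'lineage'")
  else {
    bad <- setdiff(unique(cd$system), c("patient", "cell_line"))
    if (length(bad))
      msg <- c(msg, paste0("unknown system label(s): ",
                           paste(bad, collapse = ", ")))
    if (anyNA(cd$system) || anyNA(cd$lineage))
      msg <- c(msg, "every sample must have a system and a lineage")
  }
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, paste0("duplicate sample ID ",
                         colnames(object)[duplicated(colnames(object))][1L]))
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, paste0("duplicate protein ID ",
                         rownames(object)[duplicated(rownames(object))][1L]))
  if (length(SummarizedExperiment::assays(object)) &&
      anyNA(assay(object)))
    msg <- c(msg, "expression matrix contains missing values")
  if (length(msg)) msg else TRUE
}
setValidity("ProteinExpressionStudy", .validProteinExpressionStudy)

#' PathwayCatalog: named protein membership lists
#'
#' @slot pathways named list; each element a character vector of protein
#'   IDs (>= 3 unique members per pathway).
#' @export
setClass("PathwayCatalog", representation(pathways = "list"))

setValidity("PathwayCatalog", function(object) {
  pw <- object@pathways
  msg <- character()
  if (!length(pw)) msg <- c(msg, "catalog is empty")
  if (is.null(names(pw)) || any(names(pw) == ""))
    msg <- c(msg, "all pathways must be named")
  if (anyDuplicated(names(pw)))
    msg <- c(msg, "duplicate pathway names")
  for (nm in names(pw)) {
    m <- pw[[nm]]
    if (!is.character(m) || length(unique(m)) < 3L)
      msg <- c(msg, paste0("pathway too small: '", nm,
                           "' has fewer than 3 proteins"))
    if (anyDuplicated(m))
      msg <- c(msg, paste0("pathway '", nm, "' lists a protein twice"))
  }
  if (length(msg)) msg else TRUE
})

#' DrugResponsePanel: cell line x drug response values
#'
#' @slot values numeric matrix, cell lines in rows, drugs in columns;
#'   `NA` marks missing profiles.
#' @slot mode `"continuous"` (potency, e.g. log-IC50) or `"binary"`
#'   (1 = sensitive, 0 = resistant).
#' @export
setClass("DrugResponsePanel",
         representation(values = "matrix", mode = "character"))

setValidity("DrugResponsePanel", function(object) {
  msg <- character()
  v <- object@values
  if (!is.numeric(v)) msg <- c(msg, "values must be numeric")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "values must carry cell-line rownames and drug colnames")
  if (!object@mode %in% c("continuous", "binary"))
    msg <- c(msg, "mode must be 'continuous' or 'binary'")
  if (identical(object@mode, "binary")) {
    obs <- v[!is.na(v)]
    if (length(obs) && !all(obs %in% c(0, 1)))
      msg <- c(msg, "binary panel contains values outside {0,1}")
  }
  if (length(msg)) msg else TRUE
})

#' CancerNetwork: fitted Bayesian graphical regression for one
#' lineage x pathway
#'
#' @slot lineage,pathway,system labels of the fitted slice.
#' @slot proteins protein IDs, fixing matrix order.
#' @slot ppi symmetric posterior edge-inclusion probability matrix.
#' @slot coef model-averaged regression coefficients (row i = node-wise
#'   regression of protein i on the others); used for deconvolution.
#' @slot coefCond posterior mean of the slab coefficient conditional on
#'   inclusion; its symmetrized sign labels edges.
#' @slot sigma2 posterior mean residual variances per node.
#' @slot omega symmetrized precision estimate implied by the node-wise
#'   regressions.
#' @slot center,scale per-protein centering/scaling of the training
#'   slice (reused verbatim for cross-system scoring).
#' @slot residScale robust (MAD) scale of the training deconvolution
#'   residuals, the reference scale for tail scores.
#' @slot nSamples training sample count.
#' @slot samplerMeta list: iterations, burnin, seed, piIncl, tau2, a0,
#'   b0, symmetrize.
#' @export
setClass("CancerNetwork",
         representation(lineage = "character", pathway = "character",
                        system = "character", proteins = "character",
                        ppi = "matrix", coef = "matrix",
                        coefCond = "matrix", sigma2 = "numeric",
                        omega = "matrix", center = "numeric",
                        scale = "numeric", residScale = "numeric",
                        nSamples = "integer", samplerMeta = "list"))

setValidity("CancerNetwork", function(object) {
  msg <- character()
  p <- length(object@proteins)
  P <- object@ppi
  if (!all(dim(P) == c(p, p))) msg <- c(msg, "ppi dimension mismatch")
  else {
    if (max(abs(P - t(P))) > 1e-12) msg <- c(msg, "ppi must be symmetric")
    if (any(diag(P) != 0)) msg <- c(msg, "ppi diagonal must be zero")
    if (any(P < 0 | P > 1)) msg <- c(msg, "ppi entries must lie in [0,1]")
  }
  if (!all(is.finite(object@coef))) msg <- c(msg, "coef must be finite")
  if (length(msg)) msg else TRUE
})

#' SampleScores: per-sample, per-protein status probability triples
#'
#' For sample j and pathway protein i the triple
#' (p+_ij, p0_ij, p-_ij) gives the posterior probabilities of the
#' protein being in the activated / neutral / suppressed tail of its
#' deconvolved predictive distribution.  Each triple sums to 1.
#'
#' @slot lineage,pathway labels inherited from the scoring network.
#' @slot sampleIds,proteins dimension names of the three matrices.
#' @slot pPlus,pZero,pMinus samples x proteins probability matrices.
#' @slot delta per-sample latent pathway-shift estimates (GLS).
#' @export
setClass("SampleScores",
         representation(lineage = "character", pathway = "character",
                        sampleIds = "character", proteins = "character",
                        pPlus = "matrix", pZero = "matrix",
                        pMinus = "matrix", delta = "numeric"))

setValidity("SampleScores", function(object) {
  msg <- character()
  s <- object@pPlus + object@pZero + object@pMinus
  if (length(s) && max(abs(s - 1)) > 1e-8)
    msg <- c(msg, "probability triples must sum to 1")
  for (nm in c("pPlus", "pZero", "pMinus")) {
    v <- slot(object, nm)
    if (length(v) && (min(v) < -1e-12 || max(v) > 1 + 1e-12))
      msg <- c(msg, paste0(nm, " outside [0,1]"))
  }
  if (length(msg)) msg else TRUE
})

#' PathwayScores: aggregated per-sample pathway score triples
#'
#' Long-format table with one row per sample x pathway: the aggregated
#' triple (k+, k0, k-), the derived status (argmax; ties resolve to
#' neutral) and the network aberration score k+ + k-.
#'
#' @slot scores data.frame with columns sample_id, pathway, k_plus,
#'   k_zero, k_minus, aberration, status.
#' @export
setClass("PathwayScores", representation(scores = "data.frame"))

setValidity("PathwayScores", function(object) {
  df <- object@scores
  need <- c("sample_id", "pathway", "k_plus", "k_zero", "k_minus",
            "aberration", "status")
  if (!all(need %in% colnames(df)))
    return(paste("scores must have columns:", paste(need, collapse = ", ")))
  msg <- character()
  s <- df$k_plus + df$k_zero + df$k_minus
  if (nrow(df) && max(abs(s - 1)) > 1e-8)
    msg <- c(msg, "k triples must sum to 1")
  if (nrow(df) && any(df$aberration != 1 - df$k_zero))
    msg <- c(msg, "aberration must equal 1 - k_zero")
  if (nrow(df) &&
      max(abs(df$aberration - (df$k_plus + df$k_minus))) > 1e-12)
    msg <- c(msg, "aberration must equal k_plus + k_minus")
  if (!all(df$status %in% c("activated", "neutral", "suppressed")))
    msg <- c(msg, "invalid status label")
  if (anyDuplicated(df[c("sample_id", "pathway")]))
    msg <- c(msg, "duplicate sample x pathway rows")
  if (length(msg)) msg else TRUE
})

#' AberrationMatrix: sample x pathway network aberration scores
#'
#' Entry (j, g) is the aberration score k+ + k- = 1 - k0 of sample j in
#' pathway g, in [0, 1].
#'
#' @slot values samples x pathways numeric matrix.
#' @slot annotations data.frame with columns sample_id, system, lineage
#'   aligned with the rows of `values`.
#' @export
setClass("AberrationMatrix",
         representation(values = "matrix", annotations = "data.frame"))

setValidity("AberrationMatrix", function(object) {
  msg <- character()
  v <- object@values
  if (length(v) && (min(v) < -1e-10 || max(v) > 1 + 1e-10))
    msg <- c(msg, "aberration scores must lie in [0,1]")
  a <- object@annotations
  if (!all(c("sample_id", "system", "lineage") %in% colnames(a)))
    msg <- c(msg, "annotations need sample_id, system, lineage")
  else if (!identical(as.character(a$sample_id), rownames(v)))
    msg <- c(msg, "annotations must align with matrix rows")
  if (length(msg)) msg else TRUE
})

#' ClusterResult: gap-statistic-selected complete-linkage clustering
#'
#' @slot labels named integer cluster labels, one per sample.
#' @slot K chosen number of clusters.
#' @slot gapCurve data.frame with columns k, logW, ElogW, gap, se.
#' @slot hclust the dendrogram (class `hclust`).
#' @slot seed integer seed used for the reference draws.
#' @export
setClass("ClusterResult",
         representation(labels = "integer", K = "integer",
                        gapCurve = "data.frame", hclust = "ANY",
                        seed = "integer"))

setValidity("ClusterResult", function(object) {
  msg <- character()
  if (length(unique(object@labels)) != object@K)
    msg <- c(msg, "K must equal the number of distinct labels")
  if (is.null(names(object@labels)))
    msg <- c(msg, "labels must be named by sample ID")
  if (length(msg)) msg else TRUE
})

#' DrugModel: fitted BART classifier for one lineage x drug
#'
#' @slot lineage,drug labels.
#' @slot nProfiles number of cell lines with a non-missing response.
#' @slot cvAuc pooled five-fold cross-validation AUC (NA if not run).
#' @slot importance named per-pathway posterior splitting-rule
#'   proportions; non-negative, sums to 1.
#' @slot forest opaque, reloadable posterior tree-ensemble state.
#' @slot pathways predictor order the model was trained with.
#' @slot seed integer seed.
#' @slot meta list of sampler settings.
#' @export
setClass("DrugModel",
         representation(lineage = "character", drug = "character",
                        nProfiles = "integer", cvAuc = "numeric",
                        importance = "numeric", forest = "list",
                        pathways = "character", seed = "integer",
                        meta = "list"))

setValidity("DrugModel", function(object) {
  msg <- character()
  if (object@nProfiles < 10L)
    msg <- c(msg, "models require >= 10 response profiles")
  if (!is.na(object@cvAuc) && (object@cvAuc < 0 || object@cvAuc > 1))
    msg <- c(msg, "cvAuc must lie in [0,1]")
  imp <- object@importance
  if (any(imp < -1e-12) || abs(sum(imp) - 1) > 1e-8)
    msg <- c(msg, "importance must be non-negative and sum to 1")
  if (length(msg)) msg else TRUE
})
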