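## Generics and accessors.

#' @name accessors
#' @title Accessors for PanPathNet classes
#' @description Small accessor generics: `exprMatrix` returns the
#'   samples x proteins expression matrix, `sampleSystems` /
#'   `sampleLineages` the per-sample annotations, `pathwayNames` /
#'   `pathwayMembers` the catalog content, `ppiMatrix` / `edgeCoefs` /
#'   `networkProteins` the fitted network content, `responseMatrix` /
#'   `drugProfileCounts` the drug panel content, `scoreTable` the
#'   aggregated pathway score table and `aberrationValues` /
#'   `aberrationAnnotations` the aberration matrix content.
#' @param x an object of the documented class
#' @param name a pathway name (for `pathwayMembers`)
#' @return the documented component
NULL

#' @rdname accessors
#' @export
setGeneric("exprMatrix", function(x) standardGeneric("exprMatrix"))
#' @rdname accessors
#' @export
setMethod("exprMatrix", "ProteinExpressionStudy",
          function(x) t(assay(x, "exprs")))

#' @rdname accessors
#' @export
setGeneric("sampleSystems", function(x) standardGeneric("sampleSystems"))
#' @rdname accessors
#' @export
setMethod("sampleSystems", "ProteinExpressionStudy", function(x)
  setNames(as.character(colData(x)$system), colnames(x)))

#' @rdname accessors
#' @export
setGeneric("sampleLineages", function(x) standardGeneric("sampleLineages"))
#' @rdname accessors
#' @export
setMethod("sampleLineages", "ProteinExpressionStudy", function(x)
  setNames(as.character(colData(x)$lineage), colnames(x)))

#' @rdname accessors
#' @export
setGeneric("pathwayNames", function(x) standardGeneric("pathwayNames"))
#' @rdname accessors
#' @export
setMethod("pathwayNames", "PathwayCatalog", function(x) names(x@pathways))

#' @rdname accessors
#' @export
setGeneric("pathwayMembers", function(x, name)
  standardGeneric("pathwayMembers"))
#' @rdname accessors
#' @export
setMethod("pathwayMembers", "PathwayCatalog", function(x, name) {
  if (!name %in% names(x@pathways))
    stop("unknown pathway: ", name)
  x@pathways[[name]]
})

#' @rdname accessors
#' @export
setGeneric("ppiMatrix", function(x) standardGeneric("ppiMatrix"))
#' @rdname accessors
#' @export
setMethod("ppiMatrix", "CancerNetwork", function(x) x@ppi)

#' @rdname accessors
#' @export
setGeneric("edgeCoefs", function(x) standardGeneric("edgeCoefs"))
#' @rdname accessors
#' @export
setMethod("edgeCoefs", "CancerNetwork", function(x) x@coefCond)

#' @rdname accessors
#' @export
setGeneric("networkProteins", function(x) standardGeneric("networkProteins"))
#' @rdname accessors
#' @export
setMethod("networkProteins", "CancerNetwork", function(x) x@proteins)

#' @rdname accessors
#' @export
setGeneric("responseMatrix", function(x) standardGeneric("responseMatrix"))
#' @rdname accessors
#' @export
setMethod("responseMatrix", "DrugResponsePanel", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("drugProfileCounts", function(x)
  standardGeneric("drugProfileCounts"))
#' @rdname accessors
#' @export
setMethod("drugProfileCounts", "DrugResponsePanel", function(x) {
  n <- colSums(!is.na(x@values))
  setNames(as.integer(n), names(n))
})

#' @rdname accessors
#' @export
setGeneric("scoreTable", function(x) standardGeneric("scoreTable"))
#' @rdname accessors
#' @export
setMethod("scoreTable", "PathwayScores", function(x) x@scores)

#' @rdname accessors
#' @export
setGeneric("aberrationValues", function(x)
  standardGeneric("aberrationValues"))
#' @rdname accessors
#' @export
setMethod("aberrationValues", "AberrationMatrix", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("aberrationAnnotations", function(x)
  standardGeneric("aberrationAnnotations"))
#' @rdname accessors
#' @export
setMethod("aberrationAnnotations", "AberrationMatrix",
          function(x) x@annotations)

#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))
#' @rdname accessors
#' @export
setMethod("clusterLabels", "ClusterResult", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("pathwayImportance", function(x)
  standardGeneric("pathwayImportance"))
#' @rdname accessors
#' @export
setMethod("pathwayImportance", "DrugModel", function(x) x@importance)

## show methods -------------------------------------------------------

setMethod("show", "PathwayCatalog", function(object) {
  pw <- object@pathways
  cat("PathwayCatalog with", length(pw), "pathways\n")
  sizes <- vapply(pw, length, integer(1))
  cat("  sizes:", paste0(names(sizes), "=", sizes, collapse = ", "), "\n")
})

setMethod("show", "DrugResponsePanel", function(object) {
  cat("DrugResponsePanel (", object@mode, "): ",
      nrow(object@values), " cell lines x ", ncol(object@values),
      " drugs\n", sep = "")
  cat("  non-missing profiles per drug:",
      paste0(colnames(object@values), "=",
             colSums(!is.na(object@values)), collapse = ", "), "\n")
})

setMethod("show", "CancerNetwork", function(object) {
  ut <- upper.tri(object@ppi)
  cat("CancerNetwork: lineage '", object@lineage, "' (",
      object@system, "), pathway '", object@pathway, "'\n", sep = "")
  cat("  ", length(object@proteins), " proteins, ",
      sum(object@ppi[ut] > 0.5), " edges at PPI > 0.5, n = ",
      object@nSamples, " samples\n", sep = "")
})

setMethod("show", "SampleScores", function(object) {
  cat("SampleScores: ", length(object@sampleIds), " samples x ",
      length(object@proteins), " proteins (lineage '", object@lineage,
      "', pathway '", object@pathway, "')\n", sep = "")
})

setMethod("show", "PathwayScores", function(object) {
  df <- object@scores
  cat("PathwayScores:", length(unique(df$sample_id)), "samples x",
      length(unique(df$pathway)), "pathways\n")
  print(table(df$status))
})

setMethod("show", "AberrationMatrix", function(object) {
  cat("AberrationMatrix:", nrow(object@values), "samples x",
      ncol(object@values), "pathways\n")
  cat("  systems:", paste(names(table(object@annotations$system)),
                          table(object@annotations$system),
                          collapse = ", "), "\n")
})

setMethod("show", "ClusterResult", function(object) {
  cat("ClusterResult: K =", object@K, "clusters over",
      length(object@labels), "samples (gap statistic)\n")
})

setMethod("show", "DrugModel", function(object) {
  cat("DrugModel: drug '", object@drug, "' in lineage '",
      object@lineage, "', n = ", object@nProfiles, " profiles\n",
      sep = "")
  if (!is.na(object@cvAuc))
    cat("  5-fold CV AUC:", round(object@cvAuc, 3), "\n")
  top <- names(sort(object@importance, decreasing = TRUE))[1L]
  cat("  top predictor:", top, "\n")
})
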