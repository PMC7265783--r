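## Readers, writers and constructors for the external table formats.
## All tables are tab-separated UTF-8 with a header row; numeric values
## are written with a fixed "%.17g" format (full double precision) so
## that write/read round trips are exact and repeated runs are
## byte-identical.

.fmt <- function(x) sprintf("%.17g", x)

.write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], .fmt)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
}

#' Construct a ProteinExpressionStudy
#'
#' @param values numeric matrix, samples in rows, proteins in columns,
#'   with sample IDs as rownames and protein IDs as colnames.
#' @param annotations data.frame with columns `sample_id`, `system`
#'   (`"patient"` or `"cell_line"`) and `lineage`, covering every
#'   sample in `values`.
#' @return a validated [ProteinExpressionStudy-class] object.
#' @export
ProteinExpressionStudy <- function(values, annotations) {
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must carry sample rownames and protein colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample ID ",
         rownames(values)[duplicated(rownames(values))][1L])
  if (anyDuplicated(colnames(values)))
    stop("duplicate protein ID ",
         colnames(values)[duplicated(colnames(values))][1L])
  miss <- setdiff(rownames(values), annotations$sample_id)
  if (length(miss))
    stop("sample missing from annotations: ", miss[1L])
  ann <- annotations[match(rownames(values), annotations$sample_id), ]
  se <- SummarizedExperiment(
    assays = list(exprs = t(values)),
    colData = DataFrame(system = as.character(ann$system),
                        lineage = as.character(ann$lineage),
                        row.names = rownames(values)))
  new("ProteinExpressionStudy", se)
}

#' Read an expression study from a matrix TSV and an annotation TSV
#'
#' The matrix file holds samples in rows (first column = sample ID,
#' header row = protein IDs).  The annotation file is keyed by
#' `sample_id` with columns `system` and `lineage`.  Missing values are
#' handled by the package's missing policy: proteins with more than
#' `maxMissing` missing in a lineage are flagged as dropped for that
#' lineage (recorded in `metadata(study)$droppedProteins` and honoured
#' by [sliceStudy()]); all remaining missing values are imputed by the
#' protein's lineage median.
#'
#' @param path matrix TSV path
#' @param annotationPath annotation TSV path
#' @param maxMissing per-lineage missing fraction above which a protein
#'   is dropped for that lineage (default 0.2)
#' @return a [ProteinExpressionStudy-class]
#' @export
readExpressionStudy <- function(path, annotationPath, maxMissing = 0.2) {
  raw <- read.delim(path, check.names = FALSE, colClasses = "character",
                    na.strings = c("", "NA"))
  if (!ncol(raw) >= 2L) stop("expression matrix needs >= 1 protein column")
  ids <- raw[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate sample ID ", ids[duplicated(ids)][1L])
  prot <- colnames(raw)[-1L]
  vals <- matrix(NA_real_, nrow(raw), length(prot),
                 dimnames = list(ids, prot))
  for (k in seq_along(prot)) {
    col <- raw[[k + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(!is.na(col) & is.na(num))
    if (length(bad))
      stop("non-numeric value at row ", bad[1L], ", column '",
           prot[k], "': '", col[bad[1L]], "'")
    vals[, k] <- num
  }
  ann <- read.delim(annotationPath, check.names = FALSE,
                    colClasses = "character")
  if (!all(c("sample_id", "system", "lineage") %in% colnames(ann)))
    stop("annotations need columns sample_id, system, lineage")
  miss <- setdiff(ids, ann$sample_id)
  if (length(miss)) stop("sample missing from annotations: ", miss[1L])
  ann <- ann[match(ids, ann$sample_id), ]

  dropped <- list()
  if (anyNA(vals)) {
    for (lin in unique(ann$lineage)) {
      rows <- which(ann$lineage == lin)
      fr <- colMeans(is.na(vals[rows, , drop = FALSE]))
      drop <- prot[fr > maxMissing]
      if (length(drop)) dropped[[lin]] <- drop
      for (k in which(fr > 0)) {
        med <- median(vals[rows, k], na.rm = TRUE)
        if (is.na(med)) med <- median(vals[, k], na.rm = TRUE)
        vals[rows[is.na(vals[rows, k])], k] <- med
      }
    }
    if (anyNA(vals))
      vals[is.na(vals)] <- median(vals, na.rm = TRUE)
  }
  study <- ProteinExpressionStudy(vals, ann)
  metadata(study)$droppedProteins <- dropped
  study
}

#' Write an expression study
#'
#' Inverse of [readExpressionStudy()]; round trips reproduce values
#' exactly (full-precision float format).
#'
#' @param study a [ProteinExpressionStudy-class]
#' @param path,annotationPath output TSV paths
#' @return invisibly, the two paths
#' @export
writeExpressionStudy <- function(study, path, annotationPath) {
  m <- exprMatrix(study)
  df <- data.frame(sample_id = rownames(m), check.names = FALSE)
  for (p in colnames(m)) df[[p]] <- m[, p]
  .write_tsv(df, path)
  ann <- data.frame(sample_id = colnames(study),
                    system = sampleSystems(study),
                    lineage = sampleLineages(study))
  .write_tsv(ann, annotationPath)
  invisible(c(path, annotationPath))
}

#' Restrict a study to a lineage, system and/or protein set
#'
#' Slicing to a single lineage honours the per-lineage dropped-protein
#' record left by the missing-value policy of [readExpressionStudy()].
#'
#' @param study a [ProteinExpressionStudy-class]
#' @param lineage,system optional labels to select samples
#' @param proteins optional protein IDs to select (order preserved)
#' @return a [ProteinExpressionStudy-class] slice
#' @export
sliceStudy <- function(study, lineage = NULL, system = NULL,
                       proteins = NULL) {
  keep <- rep(TRUE, ncol(study))
  if (!is.null(lineage)) keep <- keep & sampleLineages(study) %in% lineage
  if (!is.null(system)) keep <- keep & sampleSystems(study) %in% system
  out <- study[, keep]
  if (!is.null(proteins)) {
    miss <- setdiff(proteins, rownames(out))
    if (length(miss))
      stop("protein not present in study: ", paste(miss, collapse = ", "))
    if (!is.null(lineage) && length(lineage) == 1L) {
      dp <- metadata(study)$droppedProteins[[lineage]]
      proteins <- setdiff(proteins, dp)
    }
    out <- out[proteins, ]
  }
  new("ProteinExpressionStudy", out)
}

#' Construct a PathwayCatalog
#'
#' @param pathways named list of character vectors (>= 3 unique
#'   proteins each)
#' @return a validated [PathwayCatalog-class]
#' @export
PathwayCatalog <- function(pathways) {
  pathways <- lapply(pathways, function(m) unique(as.character(m)))
  new("PathwayCatalog", pathways = pathways)
}

#' Read a pathway catalog from a GMT file
#'
#' Standard GMT: one pathway per line, fields name, description and
#' tab-separated members.  Duplicated members within a pathway are
#' stored once (with a warning); a pathway with fewer than 3 distinct
#' members is an error.
#'
#' @param path GMT file path
#' @return a [PathwayCatalog-class]
#' @export
readPathwayCatalog <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty pathway file: ", path)
  pw <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("malformed GMT line (need name, description, members): ", ln)
    name <- f[1L]
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning("pathway '", name, "' lists a protein twice; stored once")
      members <- unique(members)
    }
    if (length(members) < 3L)
      stop("pathway too small: '", name, "' has fewer than 3 proteins")
    pw[[name]] <- members
  }
  PathwayCatalog(pw)
}

#' Write a pathway catalog as GMT
#'
#' @param catalog a [PathwayCatalog-class]
#' @param path output path
#' @param descriptions optional named descriptions (defaults to "na")
#' @return invisibly, `path`
#' @export
writePathwayCatalog <- function(catalog, path, descriptions = NULL) {
  nms <- pathwayNames(catalog)
  desc <- if (is.null(descriptions)) setNames(rep("na", length(nms)), nms)
          else descriptions
  lines <- vapply(nms, function(nm)
    paste(c(nm, desc[[nm]], pathwayMembers(catalog, nm)), collapse = "\t"),
    character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Check catalog proteins against a study
#'
#' @param catalog a [PathwayCatalog-class]
#' @param study a [ProteinExpressionStudy-class]
#' @return character vector of catalog proteins absent from the study
#'   (empty when all match); matching is exact and case-sensitive
#' @export
unmatchedProteins <- function(catalog, study) {
  all_members <- unique(unlist(catalog@pathways, use.names = FALSE))
  setdiff(all_members, rownames(study))
}

#' Construct a DrugResponsePanel
#'
#' @param values numeric matrix, cell lines x drugs, `NA` = missing
#' @param mode `"continuous"` or `"binary"`
#' @return a validated [DrugResponsePanel-class]
#' @export
DrugResponsePanel <- function(values, mode = c("continuous", "binary")) {
  mode <- match.arg(mode)
  new("DrugResponsePanel", values = values, mode = mode)
}

#' Read a cell line x drug response table
#'
#' Tab-separated, first column cell-line ID, header row drug names,
#' blank cells mark missing profiles.  In binary mode any value outside
#' {0, 1, blank} is an error.
#'
#' @param path TSV path
#' @param mode `"continuous"` or `"binary"`
#' @return a [DrugResponsePanel-class]
#' @export
readDrugPanel <- function(path, mode = c("continuous", "binary")) {
  mode <- match.arg(mode)
  raw <- read.delim(path, check.names = FALSE, colClasses = "character",
                    na.strings = c("", "NA"))
  ids <- raw[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate cell line ID ", ids[duplicated(ids)][1L])
  drugs <- colnames(raw)[-1L]
  vals <- matrix(NA_real_, nrow(raw), length(drugs),
                 dimnames = list(ids, drugs))
  for (k in seq_along(drugs)) {
    col <- raw[[k + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(!is.na(col) & is.na(num))
    if (length(bad))
      stop("non-numeric value at row ", bad[1L], ", drug '", drugs[k], "'")
    if (mode == "binary") {
      off <- which(!is.na(num) & !num %in% c(0, 1))
      if (length(off))
        stop("binary panel contains value ", num[off[1L]], " for drug '",
             drugs[k], "' (only 0, 1 or blank allowed)")
    }
    vals[, k] <- num
  }
  DrugResponsePanel(vals, mode)
}

#' Write a drug response panel
#'
#' @param panel a [DrugResponsePanel-class]
#' @param path output TSV path
#' @return invisibly, `path`
#' @export
writeDrugPanel <- function(panel, path) {
  v <- responseMatrix(panel)
  df <- data.frame(cell_line = rownames(v), check.names = FALSE)
  for (d in colnames(v)) df[[d]] <- v[, d]
  .write_tsv(df, path)
  invisible(path)
}

#' Write fitted networks as an edge-list TSV
#'
#' One row per unordered protein pair per network with columns pathway,
#' lineage, system, protein_a, protein_b, ppi, sign.
#'
#' @param networks a list of [CancerNetwork-class] objects
#' @param path output TSV path
#' @return invisibly, `path`
#' @export
writeNetworkEdges <- function(networks, path) {
  if (is(networks, "CancerNetwork")) networks <- list(networks)
  rows <- lapply(networks, function(net) {
    p <- length(net@proteins)
    idx <- which(upper.tri(net@ppi), arr.ind = TRUE)
    sgn <- sign(net@coefCond + t(net@coefCond))
    data.frame(pathway = net@pathway, lineage = net@lineage,
               system = net@system,
               protein_a = net@proteins[idx[, 1L]],
               protein_b = net@proteins[idx[, 2L]],
               ppi = net@ppi[idx],
               sign = as.integer(sgn[idx]))
  })
  .write_tsv(do.call(rbind, rows), path)
  invisible(path)
}

#' Read an edge-list TSV written by [writeNetworkEdges()]
#'
#' @param path TSV path
#' @return data.frame with columns pathway, lineage, system, protein_a,
#'   protein_b, ppi, sign
#' @export
readNetworkEdges <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  need <- c("pathway", "lineage", "system", "protein_a", "protein_b",
            "ppi", "sign")
  if (!all(need %in% colnames(df)))
    stop("edge list must have columns: ", paste(need, collapse = ", "))
  df
}

#' Write / read aggregated pathway scores
#'
#' Long TSV with columns sample_id, pathway, k_plus, k_zero, k_minus,
#' aberration, status.
#'
#' @param scores a [PathwayScores-class]
#' @param path TSV path
#' @return `writePathwayScores` invisibly returns `path`;
#'   `readPathwayScores` a [PathwayScores-class]
#' @export
writePathwayScores <- function(scores, path) {
  .write_tsv(scoreTable(scores), path)
  invisible(path)
}

#' @rdname writePathwayScores
#' @export
readPathwayScores <- function(path) {
  df <- read.delim(path, check.names = FALSE,
                   colClasses = c(sample_id = "character",
                                  pathway = "character",
                                  status = "character"))
  # restore the exact aberration identity lost to text rounding
  df$aberration <- 1 - df$k_zero
  new("PathwayScores", scores = df)
}
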