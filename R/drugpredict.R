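## BART drug-response prediction from pathway aberration scores.

#' BART sampler settings
#'
#' @param trees number of trees (default 50)
#' @param draws posterior draws kept (default 2000)
#' @param burnin burn-in sweeps (default 500)
#' @param keepEvery thinning for the stored forests used in prediction
#'   (default 10)
#' @param alpha,beta depth prior: p(split at depth d) =
#'   alpha (1+d)^-beta (defaults 0.95, 2)
#' @param k leaf-shrinkage factor; leaf sd = 3 / (k sqrt(trees))
#' @param numCut cutpoints per predictor (default 100)
#' @return a settings list
#' @export
bartSettings <- function(trees = 50L, draws = 2000L, burnin = 500L,
                         keepEvery = 10L, alpha = 0.95, beta = 2,
                         k = 2, numCut = 100L) {
  list(trees = as.integer(trees), draws = as.integer(draws),
       burnin = as.integer(burnin), keepEvery = as.integer(keepEvery),
       alpha = alpha, beta = beta, k = k, numCut = as.integer(numCut))
}

#' Binarize a continuous drug response panel
#'
#' A cell line is called sensitive (1) iff its potency value (e.g.
#' log-IC50) is strictly below the per-drug median across cell lines
#' with a profile; values at or above the median are resistant (0).
#' Drugs with a constant response column are dropped with a warning.
#' A panel that is already binary passes through unchanged.
#'
#' @param panel a [DrugResponsePanel-class]
#' @return a binary [DrugResponsePanel-class]
#' @export
binarizeResponse <- function(panel) {
  if (panel@mode == "binary") return(panel)
  v <- responseMatrix(panel)
  keep <- logical(ncol(v))
  out <- v
  for (d in seq_len(ncol(v))) {
    obs <- v[, d][!is.na(v[, d])]
    if (length(unique(obs)) < 2L) {
      warning("drug '", colnames(v)[d],
              "' has a constant response; dropped")
      next
    }
    keep[d] <- TRUE
    med <- median(obs)
    out[, d] <- as.numeric(v[, d] < med)
  }
  DrugResponsePanel(out[, keep, drop = FALSE], mode = "binary")
}

.aberration_input <- function(aberration) {
  if (is(aberration, "AberrationMatrix")) aberrationValues(aberration)
  else as.matrix(aberration)
}

#' Fit a BART drug-sensitivity model for one lineage x drug
#'
#' Probit sum-of-trees classifier of binary response from the pathway
#' aberration scores.  Pathway importance is the posterior proportion
#' of splitting rules using each pathway.  Ineligible inputs (fewer
#' than 10 profiles, or a single response class) are skipped: the
#' function messages the reason and returns `NULL`, so batch training
#' can log and continue.
#'
#' @param aberration samples x pathways matrix (or
#'   [AberrationMatrix-class]) for one lineage's cell lines
#' @param response binary response vector aligned with the rows
#'   (`NA` = no profile)
#' @param seed integer seed
#' @param settings [bartSettings()]
#' @param lineage,drug labels stored on the model
#' @param cv run [cvAUC()] and store the result (default TRUE)
#' @param folds CV folds (default 5)
#' @return a [DrugModel-class], or `NULL` if skipped
#' @export
fitDrugModel <- function(aberration, response, seed = 1L,
                         settings = bartSettings(), lineage = "all",
                         drug = "drug", cv = TRUE, folds = 5L) {
  A <- .aberration_input(aberration)
  ok <- !is.na(response)
  A <- A[ok, , drop = FALSE]
  y <- as.integer(response[ok])
  if (length(y) < 10L) {
    message("skipping ", lineage, " x ", drug, ": only ", length(y),
            " response profiles (need >= 10)")
    return(invisible(NULL))
  }
  if (length(unique(y)) < 2L) {
    message("skipping ", lineage, " x ", drug,
            ": single-class response")
    return(invisible(NULL))
  }
  auc <- NA_real_
  if (cv)
    auc <- cvAUC(A, y, folds = folds, seed = seed, settings = settings)
  set.seed(as.integer(seed))
  fit <- .bart_probit_fit(A, y, settings$trees, settings$draws,
                          settings$burnin, settings$keepEvery,
                          settings$alpha, settings$beta, settings$k,
                          settings$numCut)
  imp <- as.numeric(fit$importance)
  imp <- imp / sum(imp)
  names(imp) <- colnames(A)
  new("DrugModel", lineage = lineage, drug = drug,
      nProfiles = length(y), cvAuc = auc, importance = imp,
      forest = list(forests = fit$forests, offset = fit$offset),
      pathways = colnames(A), seed = as.integer(seed),
      meta = settings)
}

.stratified_folds <- function(y, folds, seed) {
  set.seed(as.integer(seed))
  f <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    f[idx] <- rep_len(seq_len(folds), length(idx))
  }
  f
}

#' Pooled cross-validation AUC of the BART classifier
#'
#' Stratified folds; out-of-fold predicted sensitivity probabilities
#' are pooled and a single AUC is computed on the pooled predictions.
#' A fold assignment that loses a class in some training split is
#' redrawn (new derived seed, up to 10 attempts) before giving up.
#'
#' @param aberration samples x pathways predictor matrix
#' @param response binary response vector (no missing values)
#' @param folds number of folds (default 5)
#' @param seed integer seed
#' @param settings [bartSettings()]
#' @return AUC in [0, 1] (NA if folding failed)
#' @export
cvAUC <- function(aberration, response, folds = 5L, seed = 1L,
                  settings = bartSettings()) {
  A <- .aberration_input(aberration)
  y <- as.integer(response)
  for (attempt in 0:9) {
    f <- .stratified_folds(y, folds, seed + 1000L * attempt)
    ok <- all(vapply(seq_len(folds), function(k)
      length(unique(y[f != k])) == 2L, logical(1)))
    if (ok) break
    if (attempt == 9L) return(NA_real_)
  }
  pred <- numeric(length(y))
  for (k in seq_len(folds)) {
    tr <- f != k
    set.seed(as.integer(seed) + k)
    fit <- .bart_probit_fit(A[tr, , drop = FALSE], y[tr],
                            settings$trees, settings$draws,
                            settings$burnin, settings$keepEvery,
                            settings$alpha, settings$beta, settings$k,
                            settings$numCut)
    pred[!tr] <- .bart_probit_predict(fit$forests, fit$offset,
                                      A[!tr, , drop = FALSE])
  }
  as.numeric(pROC::auc(pROC::roc(response = y, predictor = pred,
                                 levels = c(0, 1), direction = "<",
                                 quiet = TRUE)))
}

#' Train drug models for every lineage x drug combination
#'
#' @param aberration an [AberrationMatrix-class] covering the cell
#'   lines (lineage taken from its annotations)
#' @param panel a binary [DrugResponsePanel-class]
#' @param seed integer seed
#' @param settings [bartSettings()]
#' @param folds CV folds
#' @return list of fitted [DrugModel-class] objects (skips omitted),
#'   with a `skipped` attribute naming lineage x drug pairs not fitted
#' @export
trainDrugModels <- function(aberration, panel, seed = 1L,
                            settings = bartSettings(), folds = 5L) {
  ann <- aberrationAnnotations(aberration)
  V <- aberrationValues(aberration)
  resp <- responseMatrix(panel)
  models <- list()
  skipped <- character()
  k <- 0L
  for (lin in unique(ann$lineage)) {
    rows <- ann$sample_id[ann$lineage == lin]
    rows <- intersect(rows, rownames(resp))
    for (d in colnames(resp)) {
      k <- k + 1L
      y <- resp[rows, d]
      m <- suppressMessages(
        fitDrugModel(V[rows, , drop = FALSE], y,
                     seed = (seed + 31L * k) %% 2147483647L,
                     settings = settings, lineage = lin, drug = d,
                     folds = folds))
      if (is.null(m)) skipped <- c(skipped, paste(lin, d, sep = "|"))
      else models[[paste(lin, d, sep = "|")]] <- m
    }
  }
  attr(models, "skipped") <- skipped
  models
}

.qualifying <- function(models, aucCutoff) {
  Filter(function(m) m@nProfiles >= 10L && !is.na(m@cvAuc) &&
           m@cvAuc >= aucCutoff, models)
}

#' Top-predictor proportions over qualifying drug models
#'
#' Filters models to those with >= 10 profiles and CV AUC at or above
#' `aucCutoff`, finds each model's top pathway by importance, and
#' reports the per-pathway proportion of qualifying drugs topped by it
#' together with the log(1 + proportion) transform used for radar
#' displays.
#'
#' @param models list of [DrugModel-class]
#' @param aucCutoff AUC eligibility threshold (default 0.85)
#' @return data.frame with columns pathway, n_top, proportion,
#'   log1_proportion (empty when nothing qualifies)
#' @export
topPredictorSummary <- function(models, aucCutoff = 0.85) {
  q <- .qualifying(models, aucCutoff)
  if (!length(q))
    return(data.frame(pathway = character(), n_top = integer(),
                      proportion = numeric(),
                      log1_proportion = numeric()))
  pws <- names(q[[1L]]@importance)
  top <- vapply(q, function(m) {
    imp <- m@importance
    names(imp)[order(-imp, names(imp))][1L]
  }, character(1))
  n <- vapply(pws, function(p) sum(top == p), integer(1))
  data.frame(pathway = pws, n_top = as.integer(n),
             proportion = n / length(q),
             log1_proportion = log1p(n / length(q)),
             row.names = NULL)
}

#' Pathway pair synergy counts
#'
#' For each qualifying model (same filter as [topPredictorSummary()]),
#' takes the two highest-importance pathways (ties broken by pathway
#' name order) and counts unordered pairs.
#'
#' @param models list of [DrugModel-class]
#' @param aucCutoff AUC eligibility threshold (default 0.85)
#' @return data.frame with columns pathway_a, pathway_b, count;
#'   counts sum to the number of qualifying models
#' @export
pathwayPairSynergy <- function(models, aucCutoff = 0.85) {
  q <- .qualifying(models, aucCutoff)
  if (!length(q))
    return(data.frame(pathway_a = character(), pathway_b = character(),
                      count = integer()))
  pairs <- vapply(q, function(m) {
    imp <- m@importance
    top2 <- sort(names(imp)[order(-imp, names(imp))][1:2])
    paste(top2, collapse = "\r")
  }, character(1))
  tab <- table(pairs)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  data.frame(pathway_a = vapply(parts, `[`, "", 1L),
             pathway_b = vapply(parts, `[`, "", 2L),
             count = as.integer(tab), row.names = NULL)
}

#' Predict patient drug sensitivity in a matched lineage
#'
#' Applies a cell-line drug model to patient aberration scores from
#' the patient lineage mapped to the model's training lineage.
#'
#' @param model a [DrugModel-class]
#' @param patientAberration an [AberrationMatrix-class] of patient
#'   samples
#' @param lineageMap named character vector: patient lineage ->
#'   cell-line lineage
#' @param threshold responder probability cutoff (default 0.5)
#' @return list with `predictions` (data.frame sample_id, lineage,
#'   probability, responder) and `responseRate`
#' @export
predictPatients <- function(model, patientAberration, lineageMap,
                            threshold = 0.5) {
  ann <- aberrationAnnotations(patientAberration)
  V <- aberrationValues(patientAberration)
  matched <- names(lineageMap)[lineageMap == model@lineage]
  if (!length(matched))
    stop("no patient lineage maps to model lineage '", model@lineage,
         "'")
  keep <- ann$lineage %in% matched
  if (!any(keep))
    stop("no patient samples in mapped lineage(s): ",
         paste(matched, collapse = ", "))
  miss <- setdiff(model@pathways, colnames(V))
  if (length(miss))
    stop("pathway mismatch: ", paste(miss, collapse = ", "))
  X <- V[keep, model@pathways, drop = FALSE]
  prob <- as.numeric(.bart_probit_predict(model@forest$forests,
                                          model@forest$offset, X))
  pred <- data.frame(sample_id = ann$sample_id[keep],
                     lineage = ann$lineage[keep],
                     probability = prob,
                     responder = prob > threshold)
  list(predictions = pred, responseRate = mean(pred$responder))
}
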