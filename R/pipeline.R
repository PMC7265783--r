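## Pipeline orchestration: one validated config drives
## simulate -> fit-networks -> score-samples -> compare-networks ->
## stratify -> train-drugs -> predict-patients, with per-stage seeds
## and a manifest recording every parameter and output.

.default_config <- function() {
  list(
    seed = 1L,
    outdir = "panpathnet_out",
    inputs = list(expression = NULL, annotations = NULL,
                  pathways = NULL, drug_panel = NULL,
                  drug_panel_mode = "binary"),
    simulate = list(enabled = TRUE, n_per_lineage = 60L,
                    n_proteins_per_pathway = 8L, shift = 2.5,
                    noise = "gaussian"),
    mcmc = list(iterations = 5000L, burnin = 1000L,
                null_iterations = 2000L, null_burnin = 500L,
                pi_incl = 0.2, tau2 = 1, a0 = 2, b0 = 1,
                symmetrize = "max"),
    scoring = list(c_cut = 1),
    thresholds = list(ppi = 0.5, avatar_r = 0.9,
                      avatar_fraction = 0.75, link_cutoff = 0.8,
                      auc_cutoff = 0.85, min_profiles = 10L),
    compare = list(n_reps = 200L),
    cluster = list(k_max = 8L, gap_b = 50L, distance = "cor"),
    bart = list(trees = 50L, draws = 2000L, burnin = 500L,
                folds = 5L),
    lineage_map = NULL)
}

.num <- function(x) suppressWarnings(as.numeric(x))

.check_range <- function(x, nm, lo, hi, open = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop("config: ", nm, " must be a number")
  bad <- if (open) x <= lo || x >= hi else x < lo || x > hi
  if (bad)
    stop("config: ", nm, " = ", x, " outside its domain (",
         lo, ", ", hi, ")")
  x
}

#' Validate a pipeline configuration
#'
#' Reads a YAML or JSON config (or takes a list), rejects unknown keys,
#' fills documented defaults and range-checks every threshold.
#'
#' @param config path to a YAML/JSON file, or a config list
#' @return the validated config list with all defaults filled
#' @export
validateConfig <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a file path or a list")
  def <- .default_config()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown))
    stop("unknown config key: ", paste(unknown, collapse = ", "))
  for (sec in names(config)) {
    if (is.list(def[[sec]]) && !is.null(names(def[[sec]]))) {
      bad <- setdiff(names(config[[sec]]), names(def[[sec]]))
      if (length(bad))
        stop("unknown config key: ", sec, ".",
             paste(bad, collapse = ", "))
    }
  }
  cfg <- modifyList(def, config)
  th <- cfg$thresholds
  th$ppi <- .check_range(.num(th$ppi), "thresholds.ppi", 0, 1)
  th$avatar_r <- .check_range(.num(th$avatar_r),
                              "thresholds.avatar_r", 0, 1)
  th$avatar_fraction <- .check_range(.num(th$avatar_fraction),
                                     "thresholds.avatar_fraction", 0, 1)
  th$link_cutoff <- .check_range(.num(th$link_cutoff),
                                 "thresholds.link_cutoff", 0, 1)
  th$auc_cutoff <- .check_range(.num(th$auc_cutoff),
                                "thresholds.auc_cutoff", 0, 1, open = FALSE)
  if (th$min_profiles < 1) stop("config: min_profiles must be >= 1")
  cfg$thresholds <- th
  cfg$seed <- as.integer(cfg$seed)
  if (!cfg$simulate$enabled) {
    for (f in c("expression", "annotations", "pathways")) {
      if (is.null(cfg$inputs[[f]]))
        stop("config: inputs.", f, " required when simulate is disabled")
      if (!file.exists(cfg$inputs[[f]]))
        stop("config: missing input file ", cfg$inputs[[f]])
    }
  }
  cfg
}

.stage_seed <- function(seed, stage)
  (seed + 1000L * stage) %% 2147483647L

#' Run the full pipeline
#'
#' Executes simulate (or load), fit-networks, score-samples,
#' compare-networks, stratify, train-drugs and predict-patients in
#' order, writing each stage's tables to `outdir` and recording
#' parameters and outputs in `manifest.json`.  Identical config + seed
#' reproduce byte-identical numeric tables.
#'
#' @param config a config list or path (see [validateConfig()])
#' @param outdir output directory (overrides the config's)
#' @param seed base seed (overrides the config's); per-stage seeds are
#'   derived as seed + 1000 * stage
#' @return invisibly, the manifest list
#' @export
runPipeline <- function(config = list(), outdir = NULL, seed = NULL) {
  cfg <- validateConfig(config)
  if (!is.null(outdir)) cfg$outdir <- outdir
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  out <- cfg$outdir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = cfg, stages = list())
  t0 <- Sys.time()
  record <- function(stage, params, files) {
    manifest$stages[[stage]] <<- list(
      params = params, outputs = files,
      elapsed_s = round(as.numeric(Sys.time() - t0, units = "secs"), 2))
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = 12, pretty = TRUE,
                         force = TRUE, null = "null")
  }

  ## stage 1: simulate or load ---------------------------------------
  if (cfg$simulate$enabled) {
    fc <- fixtureConfig(nPerLineage = cfg$simulate$n_per_lineage,
                        nProteinsPerPathway =
                          cfg$simulate$n_proteins_per_pathway,
                        shift = cfg$simulate$shift,
                        noise = cfg$simulate$noise)
    bundle <- makeFixtureStudy(fc, seed = .stage_seed(cfg$seed, 1L))
    writeFixtureBundle(bundle, out)
    study <- bundle$study
    catalog <- bundle$catalog
    panel <- bundle$panel
    lineage_map <- setNames(as.character(fc$celllineLineages),
                            fc$patientLineages)
  } else {
    study <- readExpressionStudy(cfg$inputs$expression,
                                 cfg$inputs$annotations)
    catalog <- readPathwayCatalog(cfg$inputs$pathways)
    panel <- if (!is.null(cfg$inputs$drug_panel))
      readDrugPanel(cfg$inputs$drug_panel,
                    mode = cfg$inputs$drug_panel_mode) else NULL
    lineage_map <- unlist(cfg$lineage_map)
  }
  record("simulate", cfg$simulate,
         c("expression.tsv", "annotations.tsv", "pathways.gmt"))

  ## stage 2: fit networks -------------------------------------------
  mc <- mcmcSettings(iterations = cfg$mcmc$iterations,
                     burnin = cfg$mcmc$burnin,
                     seed = .stage_seed(cfg$seed, 2L),
                     piIncl = cfg$mcmc$pi_incl, tau2 = cfg$mcmc$tau2,
                     a0 = cfg$mcmc$a0, b0 = cfg$mcmc$b0,
                     symmetrize = cfg$mcmc$symmetrize)
  networks <- fitNetworks(study, catalog, mcmc = mc)
  writeNetworkEdges(networks, file.path(out, "networks.tsv"))
  saveRDS(networks, file.path(out, "networks.rds"))
  record("fit_networks", mc, "networks.tsv")

  ## stage 3: score samples ------------------------------------------
  scores <- scoreStudy(networks, study, cCut = cfg$scoring$c_cut)
  writePathwayScores(scores, file.path(out, "scores.tsv"))
  record("score_samples", cfg$scoring, "scores.tsv")

  ## stage 4: compare networks ---------------------------------------
  cons <- classifyConservedEdges(
    edgeConsistency(networks, threshold = cfg$thresholds$ppi),
    patientCutoff = max(1L, length(unique(sampleLineages(
      sliceStudy(study, system = "patient")))) - 1L),
    celllineCutoff = max(1L, length(unique(sampleLineages(
      sliceStudy(study, system = "cell_line")))) - 1L))
  .write_tsv(cons, file.path(out, "edge_consistency.tsv"))
  nullmc <- mcmcSettings(iterations = cfg$mcmc$null_iterations,
                         burnin = cfg$mcmc$null_burnin,
                         piIncl = cfg$mcmc$pi_incl,
                         tau2 = cfg$mcmc$tau2, a0 = cfg$mcmc$a0,
                         b0 = cfg$mcmc$b0,
                         symmetrize = cfg$mcmc$symmetrize)
  conn <- connectivityTable(networks, study, catalog,
                            nReps = cfg$compare$n_reps,
                            seed = .stage_seed(cfg$seed, 4L),
                            mcmc = nullmc,
                            threshold = cfg$thresholds$ppi)
  .write_tsv(conn, file.path(out, "connectivity.tsv"))
  trip <- linkLineages(conn, cutoff = cfg$thresholds$link_cutoff)
  .write_tsv(trip, file.path(out, "triplets.tsv"))
  record("compare_networks",
         list(n_reps = cfg$compare$n_reps,
              link_cutoff = cfg$thresholds$link_cutoff),
         c("edge_consistency.tsv", "connectivity.tsv", "triplets.tsv"))

  ## stage 5: stratify -----------------------------------------------
  ab <- aberrationScores(scores, study)
  abdf <- data.frame(sample_id = rownames(aberrationValues(ab)),
                     as.data.frame(aberrationValues(ab)),
                     check.names = FALSE)
  .write_tsv(abdf, file.path(out, "aberration.tsv"))
  pat <- subsetBySystem(ab, "patient")
  cel <- subsetBySystem(ab, "cell_line")
  av <- avatarLinks(pat, cel, rThreshold = cfg$thresholds$avatar_r,
                    pairFraction = cfg$thresholds$avatar_fraction)
  .write_tsv(av, file.path(out, "avatar_links.tsv"))
  cl <- clusterSamples(ab, kMax = cfg$cluster$k_max,
                       gapB = cfg$cluster$gap_b,
                       seed = .stage_seed(cfg$seed, 5L),
                       distance = cfg$cluster$distance)
  .write_tsv(data.frame(sample_id = names(clusterLabels(cl)),
                        cluster = clusterLabels(cl)),
             file.path(out, "clusters.tsv"))
  .write_tsv(cl@gapCurve, file.path(out, "gap_curve.tsv"))
  exportDendrogram(cl, file.path(out, "dendrogram.nwk"))
  record("stratify",
         c(cfg$cluster, list(avatar_r = cfg$thresholds$avatar_r,
                             avatar_fraction =
                               cfg$thresholds$avatar_fraction)),
         c("aberration.tsv", "avatar_links.tsv", "clusters.tsv",
           "gap_curve.tsv", "dendrogram.nwk"))

  ## stage 6: train drugs --------------------------------------------
  models <- list()
  if (!is.null(panel)) {
    bs <- bartSettings(trees = cfg$bart$trees, draws = cfg$bart$draws,
                       burnin = cfg$bart$burnin)
    models <- trainDrugModels(cel, binarizeResponse(panel),
                              seed = .stage_seed(cfg$seed, 6L),
                              settings = bs, folds = cfg$bart$folds)
    aucdf <- do.call(rbind, lapply(models, function(m)
      data.frame(lineage = m@lineage, drug = m@drug,
                 n_profiles = m@nProfiles, cv_auc = m@cvAuc)))
    if (is.null(aucdf))
      aucdf <- data.frame(lineage = character(), drug = character(),
                          n_profiles = integer(), cv_auc = numeric())
    .write_tsv(aucdf, file.path(out, "drug_auc.tsv"))
    impdf <- do.call(rbind, lapply(models, function(m)
      data.frame(lineage = m@lineage, drug = m@drug,
                 pathway = names(m@importance),
                 importance = as.numeric(m@importance))))
    if (!is.null(impdf)) .write_tsv(impdf, file.path(out, "importance.tsv"))
    syn <- pathwayPairSynergy(models,
                              aucCutoff = cfg$thresholds$auc_cutoff)
    .write_tsv(syn, file.path(out, "synergy_pairs.tsv"))
    tops <- topPredictorSummary(models,
                                aucCutoff = cfg$thresholds$auc_cutoff)
    .write_tsv(tops, file.path(out, "top_predictors.tsv"))
  }
  record("train_drugs", cfg$bart,
         c("drug_auc.tsv", "importance.tsv", "synergy_pairs.tsv",
           "top_predictors.tsv"))

  ## stage 7: predict patients ---------------------------------------
  if (length(models) && length(lineage_map)) {
    preds <- list()
    for (m in models) {
      matched <- names(lineage_map)[lineage_map == m@lineage]
      if (!length(matched)) next
      pr <- predictPatients(m, pat, lineage_map)
      pr$predictions$drug <- m@drug
      pr$predictions$model_lineage <- m@lineage
      preds[[paste(m@lineage, m@drug, sep = "|")]] <- pr$predictions
    }
    pdf <- do.call(rbind, preds)
    if (!is.null(pdf)) {
      rownames(pdf) <- NULL
      .write_tsv(pdf, file.path(out, "patient_predictions.tsv"))
    }
  }
  record("predict_patients", list(lineage_map = as.list(lineage_map)),
         "patient_predictions.tsv")
  invisible(manifest)
}

#' Subset an aberration matrix by model system
#'
#' @param ab an [AberrationMatrix-class]
#' @param system `"patient"` or `"cell_line"`
#' @return an [AberrationMatrix-class] with only that system's samples
#' @export
subsetBySystem <- function(ab, system) {
  ann <- aberrationAnnotations(ab)
  keep <- ann$system == system
  new("AberrationMatrix",
      values = aberrationValues(ab)[keep, , drop = FALSE],
      annotations = ann[keep, , drop = FALSE] |>
        (\(d) { rownames(d) <- NULL; d })())
}
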