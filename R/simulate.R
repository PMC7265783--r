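## Synthetic-study generator with known ground truth: sparse
## partial-correlation networks, per-sample pathway status shifts and
## drug response driven by a known subset of pathway aberrations.

#' Simulate a sparse ground-truth pathway network
#'
#' Draws an Erdos-Renyi edge support at the requested density, assigns
#' off-diagonal precision entries +/-u with u ~ Uniform(0.3, 0.6) on the
#' support, enforces positive definiteness by minimal diagonal
#' dominance (diagonal = max(1, 1.05 * sum of absolute off-diagonals))
#' and rescales the implied covariance to unit marginal variances.
#'
#' @param nProteins number of proteins (>= 3)
#' @param density edge density in [0, 1]
#' @param seed integer seed
#' @param proteins optional protein IDs (default P1..Pn)
#' @return list with elements `adjacency` (binary symmetric),
#'   `precision`, `partialCor` (implied partial correlations),
#'   `sigma` (unit-variance covariance) and `proteins`
#' @export
simulateNetwork <- function(nProteins, density, seed, proteins = NULL) {
  if (nProteins < 3L) stop("nProteins must be >= 3")
  if (density < 0 || density > 1) stop("density must lie in [0,1]")
  if (is.null(proteins)) proteins <- paste0("P", seq_len(nProteins))
  set.seed(as.integer(seed))
  p <- nProteins
  A <- matrix(0L, p, p, dimnames = list(proteins, proteins))
  pairs <- which(upper.tri(A), arr.ind = TRUE)
  on <- runif(nrow(pairs)) < density
  Om <- diag(p)
  for (r in which(on)) {
    i <- pairs[r, 1L]; j <- pairs[r, 2L]
    A[i, j] <- A[j, i] <- 1L
    u <- runif(1, 0.3, 0.6) * sample(c(-1, 1), 1L)
    Om[i, j] <- Om[j, i] <- u
  }
  for (i in seq_len(p))
    Om[i, i] <- max(1, 1.05 * sum(abs(Om[i, -i])))
  pc <- -Om / sqrt(tcrossprod(diag(Om)))
  diag(pc) <- 1
  nReq <- sum(on)
  if (nReq > 0) {
    erased <- sum(abs(pc[upper.tri(pc)][on]) < 0.05)
    if (erased > 0.1 * nReq)
      stop("positive-definiteness repair erased more than 10% of ",
           "requested edges; use a lower density")
  }
  Sig <- solve(Om)
  D <- 1 / sqrt(diag(Sig))
  Sig <- Sig * tcrossprod(D)
  dimnames(Om) <- dimnames(pc) <- dimnames(Sig) <-
    list(proteins, proteins)
  list(adjacency = A, precision = Om, partialCor = pc, sigma = Sig,
       proteins = proteins)
}

#' Simulate expression for one lineage from a ground-truth network
#'
#' Samples zero-mean Gaussians (optionally unit-variance t with 5 df)
#' with the network's covariance; "activated" samples receive `+shift`
#' on every pathway protein, "suppressed" `-shift`, "neutral" none.
#'
#' @param network output of [simulateNetwork()]
#' @param nSamples number of samples
#' @param statusFractions length-3 fractions (activated, neutral,
#'   suppressed) summing to 1
#' @param shift non-negative mean shift applied to non-neutral samples
#' @param seed integer seed
#' @param noise `"gaussian"` (default) or `"t5"` (heavy-tailed,
#'   variance-matched)
#' @return list with `values` (nSamples x nProteins matrix) and
#'   `status` (character vector of planted labels)
#' @export
simulateLineage <- function(network, nSamples, statusFractions, shift,
                            seed, noise = c("gaussian", "t5")) {
  noise <- match.arg(noise)
  if (shift < 0) stop("shift must be >= 0")
  if (length(statusFractions) != 3L ||
      abs(sum(statusFractions) - 1) > 1e-9)
    stop("statusFractions must be three fractions summing to 1")
  set.seed(as.integer(seed))
  p <- length(network$proteins)
  status <- sample(c("activated", "neutral", "suppressed"), nSamples,
                   replace = TRUE, prob = statusFractions)
  E <- if (noise == "gaussian") matrix(rnorm(nSamples * p), nSamples, p)
       else matrix(rt(nSamples * p, df = 5) / sqrt(5 / 3), nSamples, p)
  X <- E %*% chol(network$sigma)
  X <- X + shift * ((status == "activated") - (status == "suppressed"))
  colnames(X) <- network$proteins
  list(values = X, status = status)
}

#' Simulate binary drug response driven by pathway aberrations
#'
#' Latent sensitivity = `aberration %*% weights` + Gaussian noise; a
#' sample is labelled sensitive (1) iff its latent value strictly
#' exceeds the cohort median of latent values.
#'
#' @param aberration samples x pathways matrix (or
#'   [AberrationMatrix-class]) of aberration scores
#' @param weights per-pathway weight vector, or a drugs x pathways
#'   matrix with drug rownames for a multi-drug panel
#' @param noiseSd Gaussian noise standard deviation
#' @param seed integer seed
#' @return a binary [DrugResponsePanel-class] over the aberration
#'   matrix's samples
#' @export
simulateDrugResponse <- function(aberration, weights, noiseSd, seed) {
  if (is(aberration, "AberrationMatrix"))
    aberration <- aberrationValues(aberration)
  if (is.null(dim(weights))) {
    if (length(weights) != ncol(aberration))
      stop("weights length must match the number of pathways")
    weights <- matrix(weights, nrow = 1L,
                      dimnames = list("drug1", colnames(aberration)))
  }
  if (ncol(weights) != ncol(aberration))
    stop("weights length must match the number of pathways")
  set.seed(as.integer(seed))
  n <- nrow(aberration)
  labels <- matrix(NA_real_, n, nrow(weights),
                   dimnames = list(rownames(aberration), rownames(weights)))
  for (d in seq_len(nrow(weights))) {
    latent <- as.vector(aberration %*% weights[d, ]) +
      rnorm(n, sd = noiseSd)
    labels[, d] <- as.numeric(latent > median(latent))
  }
  DrugResponsePanel(labels, mode = "binary")
}

#' Default configuration for [makeFixtureStudy()]
#'
#' The defaults define a two-system, four-lineage study: patient
#' lineages `ovary` and `lung`, cell-line lineages `ovary_cl` and
#' `lung_cl`.  `ovary` and `ovary_cl` are the planted avatar pair: they
#' share every pathway network and the per-pathway status process.
#' `lung` and `lung_cl` are the planted non-match: independent networks
#' and disjoint aberrant-pathway profiles.  The first pathway
#' (`apoptosis`) is generated denser than the rest for the avatar pair
#' only, planting a cross-system connectivity link.  One low-shift
#' "mixed" pathway (`ras_mapk`) varies per sample within the non-avatar
#' cell-line lineage and drives the synthetic drug response, so that
#' per-lineage drug models have learnable within-lineage signal.
#'
#' @param nPerLineage samples per lineage (default 60)
#' @param nProteinsPerPathway proteins per pathway (default 8)
#' @param pathways pathway names
#' @param densities named per-pathway edge densities
#' @param shift mean shift for non-neutral samples in aberrant
#'   pathways (default 4)
#' @param aberrantFractions status fractions (activated, neutral,
#'   suppressed) in a lineage's aberrant pathways; the default
#'   (0.5, 0, 0.5) makes the lineage's aberration profile a stable
#'   signature of the lineage, as avatar matching requires
#' @param quietFractions status fractions in its quiet pathways
#' @param aberrantPathways named list: lineage -> aberrant pathway set
#' @param mixedPathways pathways with per-sample mixed status in
#'   non-avatar cell-line lineages (the drug-response drivers; the
#'   avatar cell-line lineage is kept clean so its aberration
#'   signature stays matched to its patient counterpart)
#' @param mixedFractions status fractions in mixed pathways
#' @param mixedShift mean shift in mixed pathways (kept small so the
#'   mixed coordinate does not mask the lineage signature)
#' @param drugWeights drugs x pathways weight matrix for the cell-line
#'   drug panel
#' @param drugNoiseSd latent noise of the drug response
#' @param noise `"gaussian"` or `"t5"` expression noise
#' @return a config list understood by [makeFixtureStudy()]
#' @export
fixtureConfig <- function(nPerLineage = 60L,
                          nProteinsPerPathway = 8L,
                          pathways = c("apoptosis", "cell_cycle",
                                       "dna_damage", "emt",
                                       "ras_mapk", "tsc_mtor"),
                          densities = NULL,
                          shift = 4,
                          aberrantFractions = c(0.5, 0, 0.5),
                          quietFractions = c(0, 1, 0),
                          aberrantPathways = NULL,
                          mixedPathways = "ras_mapk",
                          mixedFractions = c(0.35, 0.3, 0.35),
                          mixedShift = 1.2,
                          drugWeights = NULL,
                          drugNoiseSd = 0.5,
                          noise = "gaussian") {
  if (is.null(densities))
    densities <- setNames(rep(0, length(pathways)), pathways)
  if (is.null(aberrantPathways))
    aberrantPathways <- list(
      ovary = pathways[c(1L, 3L, 6L)], ovary_cl = pathways[c(1L, 3L, 6L)],
      lung = pathways[2L], lung_cl = pathways[min(4L, length(pathways))])
  mixedPathways <- intersect(mixedPathways, pathways)
  if (is.null(drugWeights)) {
    drugWeights <- matrix(0, 3L, length(pathways),
                          dimnames = list(c("drug_a", "drug_b",
                                            "drug_null"), pathways))
    drv <- if (length(mixedPathways)) mixedPathways[1L] else pathways[1L]
    drugWeights["drug_a", drv] <- 3
    drugWeights["drug_b", drv] <- 3
  }
  list(nPerLineage = as.integer(nPerLineage),
       nProteinsPerPathway = as.integer(nProteinsPerPathway),
       pathways = pathways, densities = densities, shift = shift,
       aberrantFractions = aberrantFractions,
       quietFractions = quietFractions,
       aberrantPathways = aberrantPathways,
       mixedPathways = mixedPathways,
       mixedFractions = mixedFractions, mixedShift = mixedShift,
       linkPathway = pathways[1L], linkDensity = 0.5,
       patientLineages = c("ovary", "lung"),
       celllineLineages = c("ovary_cl", "lung_cl"),
       avatarPair = c(patient = "ovary", cellline = "ovary_cl"),
       nonMatchPair = c(patient = "lung", cellline = "lung_cl"),
       drugWeights = drugWeights, drugNoiseSd = drugNoiseSd,
       noise = noise)
}

.seed_mix <- function(seed, k) (as.integer(seed) * 101L + k * 7919L) %% 2147483647L

#' Generate a complete synthetic study bundle with ground truth
#'
#' Produces an expression study across patient and cell-line lineages,
#' a pathway catalog, a binary drug-response panel for the cell lines
#' and the generating ground truth (networks, per-sample statuses, drug
#' weights, the planted avatar pair and non-match).  A pure function of
#' `(config, seed)`.
#'
#' @param config a [fixtureConfig()] list
#' @param seed integer seed
#' @return list with elements `study`
#'   ([ProteinExpressionStudy-class]), `catalog`
#'   ([PathwayCatalog-class]), `panel` (binary
#'   [DrugResponsePanel-class]) and `truth` (list: `networks`,
#'   `status`, `drugWeights`, `avatarPair`, `nonMatchPair`)
#' @export
makeFixtureStudy <- function(config = fixtureConfig(), seed = 1L) {
  cfg <- config
  lineages <- c(cfg$patientLineages, cfg$celllineLineages)
  systems <- setNames(rep(c("patient", "cell_line"),
                          c(length(cfg$patientLineages),
                            length(cfg$celllineLineages))), lineages)
  if (length(cfg$patientLineages) < 2L || length(cfg$celllineLineages) < 2L)
    stop("config must name >= 2 lineages per system")
  if (length(cfg$pathways) < 2L) stop("config must name >= 2 pathways")
  if (cfg$nPerLineage < 3L * cfg$nProteinsPerPathway)
    warning("fewer samples per lineage than 3x pathway size; ",
            "network identifiability may suffer")

  pw <- cfg$pathways
  prot <- lapply(seq_along(pw), function(g)
    paste0(toupper(substr(pw[g], 1, 3)), g, "_", seq_len(cfg$nProteinsPerPathway)))
  names(prot) <- pw
  catalog <- PathwayCatalog(prot)

  # one network per lineage x pathway; the avatar pair shares objects
  av <- cfg$avatarPair
  networks <- list()
  k <- 0L
  for (lin in lineages) {
    networks[[lin]] <- list()
    for (g in seq_along(pw)) {
      k <- k + 1L
      if (lin == av[["cellline"]]) {
        networks[[lin]][[pw[g]]] <- networks[[av[["patient"]]]][[pw[g]]]
      } else {
        # the planted link pathway is dense only for the avatar pair,
        # so high cross-signaling there is a property of the pair, not
        # of the pathway
        dens <- if (!is.null(cfg$linkPathway) &&
                    pw[g] == cfg$linkPathway && lin == av[["patient"]])
          cfg$linkDensity else cfg$densities[[pw[g]]]
        networks[[lin]][[pw[g]]] <- simulateNetwork(
          cfg$nProteinsPerPathway, dens,
          .seed_mix(seed, k), proteins = prot[[pw[g]]])
      }
    }
  }

  # expression + planted statuses
  vals <- list(); ann <- list(); status_rows <- list()
  for (lin in lineages) {
    ids <- sprintf("%s_S%03d", lin, seq_len(cfg$nPerLineage))
    blocks <- list()
    for (g in seq_along(pw)) {
      k <- k + 1L
      mixed <- pw[g] %in% cfg$mixedPathways &&
        systems[[lin]] == "cell_line" &&
        lin != cfg$avatarPair[["cellline"]]
      fr <- if (pw[g] %in% cfg$aberrantPathways[[lin]])
        cfg$aberrantFractions
      else if (mixed) cfg$mixedFractions else cfg$quietFractions
      sh <- if (mixed) cfg$mixedShift else cfg$shift
      sl <- simulateLineage(networks[[lin]][[pw[g]]], cfg$nPerLineage,
                            fr, sh, .seed_mix(seed, k),
                            noise = cfg$noise)
      blocks[[pw[g]]] <- sl$values
      status_rows[[length(status_rows) + 1L]] <- data.frame(
        sample_id = ids, pathway = pw[g], status = sl$status)
    }
    X <- do.call(cbind, blocks)
    rownames(X) <- ids
    # overlapping pathways: first listing wins
    X <- X[, !duplicated(colnames(X)), drop = FALSE]
    vals[[lin]] <- X
    ann[[lin]] <- data.frame(sample_id = ids, system = systems[[lin]],
                             lineage = lin)
  }
  allprot <- unique(unlist(prot, use.names = FALSE))
  vals <- lapply(vals, function(X) X[, allprot, drop = FALSE])
  study <- ProteinExpressionStudy(do.call(rbind, vals),
                                  do.call(rbind, ann))
  trueStatus <- do.call(rbind, status_rows)
  rownames(trueStatus) <- NULL

  # binary drug panel for cell lines, driven by the true aberration
  # indicator (1 iff the sample's planted status is non-neutral)
  cl_ids <- unlist(lapply(lineages[systems == "cell_line"], function(l)
    ann[[l]]$sample_id), use.names = FALSE)
  ab_true <- matrix(0, length(cl_ids), length(pw),
                    dimnames = list(cl_ids, pw))
  st_cl <- trueStatus[trueStatus$sample_id %in% cl_ids, ]
  ab_true[cbind(match(st_cl$sample_id, cl_ids),
                match(st_cl$pathway, pw))] <-
    as.numeric(st_cl$status != "neutral")
  panel <- simulateDrugResponse(ab_true, cfg$drugWeights,
                                cfg$drugNoiseSd, .seed_mix(seed, k + 1L))

  truth <- list(networks = networks, status = trueStatus,
                trueAberration = ab_true,
                drugWeights = cfg$drugWeights,
                avatarPair = cfg$avatarPair,
                nonMatchPair = cfg$nonMatchPair,
                systems = systems)
  list(study = study, catalog = catalog, panel = panel, truth = truth)
}

#' Write a fixture bundle to a directory
#'
#' Writes expression.tsv, annotations.tsv, pathways.gmt,
#' drug_panel.tsv and ground_truth.json in the package's standard
#' formats.  Repeated calls with the same bundle are byte-identical.
#'
#' @param bundle output of [makeFixtureStudy()]
#' @param dir output directory (created if absent)
#' @return invisibly, `dir`
#' @export
writeFixtureBundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeExpressionStudy(bundle$study, file.path(dir, "expression.tsv"),
                       file.path(dir, "annotations.tsv"))
  writePathwayCatalog(bundle$catalog, file.path(dir, "pathways.gmt"))
  writeDrugPanel(bundle$panel, file.path(dir, "drug_panel.tsv"))
  tr <- bundle$truth
  gt <- list(
    status = tr$status,
    drugWeights = tr$drugWeights,
    avatarPair = as.list(tr$avatarPair),
    nonMatchPair = as.list(tr$nonMatchPair),
    adjacency = lapply(tr$networks, function(ns)
      lapply(ns, function(n) n$adjacency)))
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       digits = 12, pretty = TRUE)
  invisible(dir)
}
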