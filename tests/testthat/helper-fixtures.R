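# shared fixture builders (everything generated in code; no data files)

tiny_study <- function(n = 12, p = 4, seed = 1, lineage = "ovary",
                       system = "patient", prefix = "S") {
  set.seed(seed)
  vals <- matrix(rnorm(n * p), n, p,
                 dimnames = list(sprintf("%s%02d", prefix, seq_len(n)),
                                 paste0("P", seq_len(p))))
  ann <- data.frame(sample_id = rownames(vals), system = system,
                    lineage = lineage)
  ProteinExpressionStudy(vals, ann)
}

# a CancerNetwork with hand-set PPI, for the comparison operations
fake_network <- function(ppi, lineage, pathway, system = "patient",
                         coef = NULL) {
  p <- ncol(ppi)
  prot <- colnames(ppi)
  if (is.null(prot)) prot <- paste0("P", seq_len(p))
  dimnames(ppi) <- list(prot, prot)
  z <- matrix(0, p, p, dimnames = dimnames(ppi))
  if (is.null(coef)) coef <- z
  new("CancerNetwork", lineage = lineage, pathway = pathway,
      system = system, proteins = prot, ppi = ppi, coef = coef,
      coefCond = coef, sigma2 = rep(1, p), omega = diag(p),
      center = rep(0, p), scale = rep(1, p), residScale = rep(1, p),
      nSamples = 50L, samplerMeta = list())
}

# aberration matrix from explicit per-sample vectors
fake_aberration <- function(vectors, lineage, system) {
  V <- do.call(rbind, vectors)
  rownames(V) <- sprintf("%s_%02d", lineage, seq_len(nrow(V)))
  colnames(V) <- paste0("pw", seq_len(ncol(V)))
  ann <- data.frame(sample_id = rownames(V), system = system,
                    lineage = lineage)
  new("AberrationMatrix", values = V, annotations = ann)
}

# standardized study slice from a simulated lineage
lineage_study <- function(net, n, fractions, shift, seed,
                          lineage = "ovary", system = "patient") {
  sl <- simulateLineage(net, n, fractions, shift, seed)
  rownames(sl$values) <- sprintf("%s_S%03d", lineage, seq_len(n))
  ann <- data.frame(sample_id = rownames(sl$values), system = system,
                    lineage = lineage)
  list(study = ProteinExpressionStudy(sl$values, ann),
       status = sl$status)
}
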