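## End-to-end orchestration over simulated inputs: simulate -> synteny ->
## karyotype -> subgenome -> ks -> screen, with a run manifest.

#' Default pipeline configuration
#'
#' Returns the full set of recognized configuration keys with their
#' defaults. \code{runPipeline()} rejects unknown keys, so configs stay
#' in sync with the implementation.
#'
#' @return named list.
#' @export
defaultPipelineConfig <- function() {
  list(
    out_dir = "karyotrace_run",
    seed = 1L,
    ## simulator
    n_blocks = 22L, genes_per_block = 50L,
    spacing_bp = 10000, gene_length_bp = 2000,
    fuse = c("ACK6", "ACK8"),
    loss_rate = 0.05, bias_mean = 0, bias_sd = 0.5,
    ## synteny
    flank_window = 20L, min_support = 2L,
    max_gene_gap = 50L, max_bp_gap = 300000,
    ## karyotype
    min_genes_per_call = 5L, min_fraction = 0.10,
    ## subgenome
    window = 100L, step = 50L, thresholds_max = 8L, pseudocount = 0.1,
    ## molecular evolution
    ks_pairs = 500L, ks_codons = 300L, true_ks = 0.12,
    ## screen
    n_decoy_proteins = 50L, n_planted = 3L,
    planted_slope = 0.05, planted_noise_sd = 0.5,
    r_min = 0.75, p_max = 1e-05, differential_ratio = 4.0,
    tetra_glucosides = c(Q3G = 450, Q7G = 175, `Q3,7G` = 125,
                         quercetin = 2.8),
    diploid_glucosides = c(Q3G = 6.9, Q7G = 2.9, `Q3,7G` = 0.7,
                           quercetin = 1.5))
}

.loadConfig <- function(config) {
  def <- defaultPipelineConfig()
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  for (k in names(config)) {
    v <- config[[k]]
    if (!is.null(names(def[[k]])) && is.list(v)) v <- unlist(v)
    def[[k]] <- v
  }
  def
}

.writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline on simulated data
#'
#' Simulates an ancestral karyotype and its diploid and tetraploid
#' descendants, then runs every analysis stage and writes one TSV per
#' result under \code{out_dir}, finishing with an atomically-written
#' \code{manifest.json} recording the configuration, per-stage record
#' counts and wall-clock, and the md5 checksum of every written file.
#' Identical configurations reproduce identical stage outputs.
#'
#' @param config a named list overriding \code{\link{defaultPipelineConfig}}
#'   entries, or the path of a YAML file with the same keys; unknown keys
#'   are an error.
#' @return the manifest, invisibly.
#' @export
runPipeline <- function(config = list()) {
  cfg <- .loadConfig(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$out_dir, f)
  stages <- list()
  files <- character(0)
  tic <- function() proc.time()[["elapsed"]]
  stage <- function(name, nrec, t0) {
    stages[[name]] <<- list(records = nrec, seconds = round(tic() - t0, 3))
    message("[", name, "] ", nrec, " records (",
            stages[[name]]$seconds, "s)")
  }

  ## --- simulate -----------------------------------------------------------
  t0 <- tic()
  anc <- buildAncestralKaryotype(cfg$n_blocks, cfg$genes_per_block,
                                 cfg$spacing_bp, cfg$gene_length_bp)
  dip <- applyScenario(anc, diploidScenario(cfg$fuse, seed = cfg$seed),
                       genomeId = "diploid")
  tet <- applyScenario(anc,
                       tetraploidScenario(cfg$fuse, lossRate = cfg$loss_rate,
                                          biasMean = cfg$bias_mean,
                                          biasSd = cfg$bias_sd,
                                          seed = cfg$seed),
                       genomeId = "tetraploid")
  gbT <- gbDefinitionTable(anc)
  files <- c(files,
             writeAnnotation(anc, out("ancestor.gff3")),
             writeAnnotation(dip, out("diploid.gff3")),
             writeAnnotation(tet, out("tetraploid.gff3")),
             writeGBTable(gbT, out("gb_table.tsv")))
  stage("simulate", length(anc) + length(dip) + length(tet), t0)

  ## --- synteny ------------------------------------------------------------
  t0 <- tic()
  homDip <- makeHomologyTable(dip, anc)
  homTet <- makeHomologyTable(tet, anc)
  homSelf <- makeHomologyTable(tet, tet)
  pairsDip <- detectSyntenicPairs(dip, anc, homDip,
                                  cfg$flank_window, cfg$min_support)
  pairsTet <- detectSyntenicPairs(tet, anc, homTet,
                                  cfg$flank_window, cfg$min_support)
  pairsSelf <- detectSyntenicPairs(tet, tet, homSelf,
                                   cfg$flank_window, cfg$min_support)
  fragsDip <- chainFragments(pairsDip, cfg$max_gene_gap, cfg$max_bp_gap)
  fragsTet <- chainFragments(pairsTet, cfg$max_gene_gap, cfg$max_bp_gap)
  files <- c(files,
             .writeTsv(homDip, out("homology_diploid_ancestor.tsv")),
             .writeTsv(pairsDip, out("syntenic_pairs_diploid.tsv")),
             .writeTsv(pairsTet, out("syntenic_pairs_tetraploid.tsv")),
             .writeTsv(fragments(fragsDip), out("fragments_diploid.tsv")),
             .writeTsv(fragments(fragsTet), out("fragments_tetraploid.tsv")))
  stage("synteny", nrow(pairsDip) + nrow(pairsTet) + nrow(pairsSelf), t0)

  ## --- karyotype ----------------------------------------------------------
  t0 <- tic()
  projDip <- projectGenomicBlocks(fragsDip, gbT, cfg$min_genes_per_call,
                                  cfg$max_gene_gap, cfg$max_bp_gap)
  projTet <- projectGenomicBlocks(fragsTet, gbT, cfg$min_genes_per_call,
                                  cfg$max_gene_gap, cfg$max_bp_gap)
  cnDip <- gbCopyNumber(projDip, gbT)
  cnTet <- gbCopyNumber(projTet, gbT)
  assoc <- extractGBAssociations(projDip)
  ancAssoc <- gbTableAssociations(gbT)
  recov <- associationRecoveryFraction(assoc, ancAssoc)
  evDip <- inferChromosomeEvents(projDip, gbT, cfg$min_fraction)
  files <- c(files,
             .writeTsv(projDip, out("gb_projections_diploid.tsv")),
             .writeTsv(projTet, out("gb_projections_tetraploid.tsv")),
             .writeTsv(cnDip, out("gb_copy_number_diploid.tsv")),
             .writeTsv(cnTet, out("gb_copy_number_tetraploid.tsv")),
             .writeTsv(assoc, out("gb_associations_diploid.tsv")),
             .writeTsv(evDip$events, out("chromosome_events_diploid.tsv")),
             .writeTsv(data.frame(association_recovery = recov),
                       out("association_recovery.tsv")))
  stage("karyotype", nrow(projDip) + nrow(projTet), t0)

  ## --- subgenome ----------------------------------------------------------
  t0 <- tic()
  pairing <- pairHomoeologousChromosomes(pairsSelf, tet)
  partition <- assignSubgenomesByDensity(pairing, tet)
  reten <- subgenomeRetention(anc, pairsTet, partition,
                              window = cfg$window, step = cfg$step)
  design <- sampleDesign(genotype = "tetra")
  metabTet <- simulateMetabolites(design, glucosides = cfg$tetra_glucosides,
                                  seed = cfg$seed)
  hits <- NULL
  gtTet <- geneTable(tet)
  plantIds <- head(gtTet$gene_id[order(gtTet$gene_id)], cfg$n_planted)
  planted <- data.frame(gene_id = plantIds, compound = "Q3G+Q7G",
                        slope = cfg$planted_slope, intercept = 0,
                        noise_sd = cfg$planted_noise_sd,
                        stringsAsFactors = FALSE)
  se <- simulateExpression(tet, design, planted = planted,
                           metabolites = metabTet, seed = cfg$seed + 1L)
  homPairs <- pairsSelf[, c("gene_a", "gene_b")]
  dom <- expressionDominance(tet, homPairs, partition, se,
                             thresholds = seq_len(cfg$thresholds_max),
                             pseudocount = cfg$pseudocount)
  retenTab <- data.frame(subgenome = names(reten),
                         global_retention = vapply(reten, `[[`, 0, "global"))
  files <- c(files,
             .writeTsv(pairing, out("homoeolog_chromosome_pairs.tsv")),
             .writeTsv(partition, out("subgenome_partition.tsv")),
             .writeTsv(retenTab, out("retention_global.tsv")),
             .writeTsv(reten$DsA$windows, out("retention_windows_DsA.tsv")),
             .writeTsv(reten$DsB$windows, out("retention_windows_DsB.tsv")),
             .writeTsv(dom, out("expression_dominance.tsv")),
             writeExpressionMatrix(se, out("expression_tpm.tsv")))
  stage("subgenome", nrow(partition) + nrow(dom), t0)

  ## --- molecular evolution ------------------------------------------------
  t0 <- tic()
  sim <- simulateCodonDivergence(cfg$ks_pairs, cfg$ks_codons, cfg$true_ks,
                                 seed = cfg$seed + 2L)
  est <- ng86Batch(sim$a, sim$b, sim$pair_id)
  pk <- ksDistributionPeak(est$Ks)
  files <- c(files,
             .writeTsv(est, out("ks_estimates.tsv")),
             .writeTsv(data.frame(peak = pk$peak, bandwidth = pk$bandwidth,
                                  n = pk$n),
                       out("ks_peak.tsv")))
  stage("ks", nrow(est), t0)

  ## --- candidate screen ---------------------------------------------------
  t0 <- tic()
  decoys <- sprintf("decoyP%03d", seq_len(cfg$n_decoy_proteins))
  protIds <- c(plantIds, decoys)
  prots <- simulateProteins(protIds, motifIds = plantIds,
                            seed = cfg$seed + 3L)
  hits <- scanPSPG(prots)
  exprGenes <- intersect(unique(hits$protein_id), rownames(se))
  total <- colSums(metabTet[c("Q3G", "Q7G"), , drop = FALSE])
  screen <- if (length(exprGenes))
    correlationScreen(se, total, exprGenes, cfg$r_min, cfg$p_max)
  else data.frame()
  designDip <- sampleDesign(genotype = "dip")
  metabDip <- simulateMetabolites(designDip,
                                  glucosides = cfg$diploid_glucosides,
                                  seed = cfg$seed + 4L)
  common <- intersect(rownames(metabTet), rownames(metabDip))
  folds <- metaboliteFolds(cbind(metabTet[common, ], metabDip[common, ]),
                           design$sample_id, designDip$sample_id,
                           cfg$differential_ratio)
  files <- c(files,
             writeFasta(prots, out("proteins.faa"), type = "aa"),
             .writeTsv(hits, out("pspg_hits.tsv")),
             .writeTsv(screen, out("correlation_screen.tsv")),
             .writeTsv(folds, out("metabolite_folds.tsv")),
             writeMetaboliteTable(metabTet, out("metabolites_tetra.tsv")),
             writeMetaboliteTable(metabDip, out("metabolites_diploid.tsv")))
  stage("screen", nrow(hits) + nrow(folds), t0)

  ## --- manifest -----------------------------------------------------------
  manifest <- list(
    tool = "KaryoTrace",
    version = as.character(utils::packageVersion("KaryoTrace")),
    config = cfg,
    stages = stages,
    files = lapply(setNames(nm = basename(files)), function(f)
      unname(tools::md5sum(file.path(cfg$out_dir, f)))))
  tmp <- tempfile(tmpdir = cfg$out_dir)
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  file.rename(tmp, out("manifest.json"))
  invisible(manifest)
}
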