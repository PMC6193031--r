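## pipeline_cli: end-to-end orchestration of the synthetic analysis
## (simulate -> quantify -> normalize -> classify -> genesets -> mnase ->
## stats) under a single config, with a machine-readable run manifest.

#' Pipeline run configuration
#'
#' Bundles the per-module configurations and the output layout. Every
#' default that encodes an analysis constant (scaling target 1e7,
#' pseudo-count 1, 30th-percentile H3K27me3 baseline, RPKM 15/5/1,
#' |log2FC| < 2, FDR 0.05/0.2, 140 bp fragment cutoff, the window grid,
#' 500 bp promoter flank) lives in the respective module config.
#'
#' @param sim a [SimConfig-class] (its seed drives all randomness).
#' @param outDir output directory (created if needed).
#' @param scalingTarget autosomal scaling target for ChIP tracks.
#' @param transform from [transformConfig()].
#' @param rules from [setRuleConfig()].
#' @param mnase from [mnaseConfig()]; set `windowGrid` shorter for quick
#'   runs.
#' @param chipCellTypes,marks which ChIP tracks to simulate and process.
#' @param mnaseCellTypes,mnaseReplicates MNase samples to simulate.
#' @return validated config list.
#' @export
runConfig <- function(sim = simConfig(), outDir = tempfile("multimark_run_"),
                      scalingTarget = 1e7,
                      transform = transformConfig(),
                      rules = setRuleConfig(),
                      mnase = mnaseConfig(),
                      chipCellTypes = c("sperm", "embryo"),
                      marks = MARKS,
                      mnaseCellTypes = c("sperm", "embryo"),
                      mnaseReplicates = 2) {
  stopifnot(is(sim, "SimConfig"))
  stopifnot(all(chipCellTypes %in% CELL_TYPES), all(marks %in% MARKS))
  list(sim = sim, outDir = outDir, scalingTarget = scalingTarget,
       transform = transform, rules = rules, mnase = mnase,
       chipCellTypes = chipCellTypes, marks = marks,
       mnaseCellTypes = mnaseCellTypes, mnaseReplicates = mnaseReplicates)
}

#' Run the synthetic end-to-end analysis
#'
#' Simulates a genome with planted classes, ChIP tracks, expression counts
#' and MNase fragments from `config$sim`, then runs the full downstream
#' analysis: autosomal scaling, gene/promoter quantification,
#' log2/z-normalization, quadrant and multivalency classification with
#' per-class summaries, RPKM/FDR gene-set construction with
#' genotype-intersection, multi-scale MNase window occupancy with
#' low-coverage exclusion and X/A summaries, and the overlap/shift
#' statistics comparing recovered to planted gene sets. All outputs are
#' written as plain text under `config$outDir`; a JSON manifest with
#' parameters, md5 checksums of every output, and the headline summary
#' metrics is written last. Deterministic given the config seed: re-running
#' reproduces all output files byte-identically (the manifest differs only
#' in its timestamp).
#'
#' @param config from [runConfig()].
#' @return the manifest, invisibly.
#' @export
runPipeline <- function(config = runConfig()) {
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  outfile <- function(...) file.path(config$outDir, ...)
  manifest <- list(
    package_version = as.character(utils::packageVersion("multiMark")),
    generated = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$sim@seed,
    parameters = list(
      scaling_target = config$scalingTarget,
      pseudo_count = config$transform$pseudoCount,
      rules = config$rules[setdiff(names(config$rules), "reduce")],
      min_fragment_length = config$mnase$minFragmentLength,
      exclusion_min_coverage = config$mnase$exclusionMinCoverage),
    outputs = list(), summary = list(), partial = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      manifest$failed_stage <<- name
      jsonlite::write_json(manifest, outfile("manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  ## simulate
  sim <- stage("simulate", {
    g <- simulateGenome(config$sim)
    bed <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                   as.character(seqnames(g$genes)),
                   BiocGenerics::start(g$genes) - 1L,
                   BiocGenerics::end(g$genes), g$genes$gene_id,
                   as.character(strand(g$genes)))
    writeLines(bed, outfile("genes.bed"))
    writeTSV(data.frame(gene = names(plantedClass(g$truth)),
                        class = plantedClass(g$truth)),
             outfile("ground_truth.tsv"))
    g
  })

  ## quantify + normalize + classify, per ChIP cell type
  quadrantSummaries <- list(); calls <- list()
  for (ct in config$chipCellTypes) {
    z <- stage(paste0("chip_", ct), {
      ztabs <- list()
      for (mk in config$marks) {
        track <- simulateChipTracks(sim$genes, sim$truth, config$sim, ct, mk)
        writeBedGraph(track, outfile(sprintf("chip_%s_%s.bedgraph", ct, mk)))
        scaled <- scaleToAutosomalTarget(track, config$scalingTarget)
        tab <- geneMeanCoverage(
          scaled, sim$genes,
          window = if (mk == "H3K4me3") "promoter" else "gene_body",
          mark = mk)
        ztabs[[mk]] <- zscoreAgainstAutosomes(
          logTransform(tab, config$transform), config$transform)
      }
      ztabs
    })
    cl <- stage(paste0("classify_", ct), {
      qc <- classifyQuadrants(z$H3K36me3, z$H3K27me3)
      writeTSV(data.frame(gene = geneIds(qc),
                          quadrant = as.character(quadrantLabels(qc)),
                          multivalent = isMultivalent(qc)),
               outfile(sprintf("quadrants_%s.tsv", ct)))
      classSets <- split(names(plantedClass(sim$truth)),
                         plantedClass(sim$truth))
      qs <- summarizeClassMarking(qc, classSets)
      writeTSV(qs, outfile(sprintf("class_marking_%s.tsv", ct)))
      list(qc = qc, qs = qs)
    })
    calls[[ct]] <- cl$qc
    quadrantSummaries[[ct]] <- cl$qs
  }

  ## expression + gene sets
  genesets <- stage("genesets", {
    expr <- simulateExpression(sim$genes, sim$truth, config$sim)
    writeCounts(expr, outfile("counts.tsv"), outfile("samples.json"))
    expr <- computeRPKM(expr)
    cd <- SummarizedExperiment::colData(expr)
    oog <- rownames(cd)[cd$germline_type == "oogenic"]
    genotypes <- unique(cd$genotype[cd$germline_type == "spermatogenic"])
    de <- lapply(genotypes, function(g) {
      sp <- rownames(cd)[cd$germline_type == "spermatogenic" &
                           cd$genotype == g]
      nbTwoGroupTest(expr, groupA = oog, groupB = sp)
    })
    names(de) <- genotypes
    for (g in genotypes)
      exportDETable(de[[g]], outfile(sprintf("de_%s_vs_oogenic.tsv", g)))
    sperm <- buildSpermatogenesisSet(expr, de, config$rules)
    sexind <- buildSexIndependentSet(expr, de, config$rules)
    writeGeneList(sperm$final, outfile("set_spermatogenesis_specific.txt"))
    writeGeneList(sexind$final, outfile("set_sex_independent.txt"))
    list(expr = expr, de = de, sperm = sperm$final, sexind = sexind$final)
  })

  ## mnase occupancy
  mnase <- stage("mnase", {
    fragsList <- list()
    for (ct in config$mnaseCellTypes)
      for (r in seq_len(config$mnaseReplicates)) {
        fr <- simulateMnase(sim$genes, config$sim, ct, replicate = r)
        nm <- sprintf("%s_r%d", ct, r)
        fragsList[[nm]] <- fr
        writeFragments(fr, outfile(sprintf("mnase_%s.bed", nm)))
      }
    tabs <- mnaseOccupancyAnalysis(fragsList, .chromLens(sim$genes),
                                   config$mnase)
    dens <- occupancyDensitySummary(tabs[[1]])
    writeTSV(dens$summary, outfile("mnase_density_summary.tsv"))
    list(tabs = tabs, dens = dens)
  })

  ## stats: recovered vs planted spermatogenesis set
  overlap <- stage("stats", {
    universe <- Reduce(intersect, lapply(genesets$de, function(d)
      deTable(d)$gene[deTable(d)$tested]))
    planted <- names(which(plantedClass(sim$truth) ==
                             "spermatogenesis_specific"))
    ov <- hypergeometricOverlap(universe,
                                intersect(geneIds(genesets$sperm), universe),
                                intersect(planted, universe))
    lfc <- deTable(genesets$de[[1]])
    lfcAll <- lfc$log2_fold_change[lfc$tested]
    lfcSet <- lfc$log2_fold_change[lfc$tested &
                                     lfc$gene %in% geneIds(genesets$sperm)]
    sh <- mannWhitneyShift(lfcSet, lfcAll, alternative = "greater")
    writeTSV(data.frame(test = c("overlap", "shift"),
                        statistic = c(ov$statistic, sh$statistic),
                        p_value = c(ov$p.value, sh$p.value)),
             outfile("stats.tsv"))
    list(overlap = ov, shift = sh)
  })

  ## manifest
  manifest$summary <- list(
    quadrant_percentages = quadrantSummaries,
    gene_set_sizes = list(
      spermatogenesis_specific = length(genesets$sperm),
      sex_independent = length(genesets$sexind)),
    planted_class_recovery = local({
      planted <- names(which(plantedMultivalent(sim$truth)))
      called <- names(which(isMultivalent(calls[[1]])))
      list(sensitivity = length(intersect(called, planted)) / length(planted),
           precision = if (length(called))
             length(intersect(called, planted)) / length(called) else NA)
    }),
    excluded_window_fraction = mnase$tabs[[1]]@params$exclusion,
    median_xa_ratio = as.list(mnase$dens$median_xa_ratio),
    overlap_log10_p = overlap$overlap$log10_p,
    shift_p = overlap$shift$p.value)
  files <- setdiff(list.files(config$outDir), "manifest.json")
  manifest$outputs <- as.list(tools::md5sum(
    file.path(config$outDir, files)))
  names(manifest$outputs) <- files
  manifest$partial <- FALSE
  jsonlite::write_json(manifest, outfile("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
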