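#' Run the end-to-end analysis pipeline
#'
#' Orchestrates the stages \code{simulate} (write a synthetic proteome,
#' PSM tables, annotation and gold scenes), \code{infer} (parsimony
#' protein grouping from the written artifacts), \code{quantify}
#' (apportioned spectral counts and percent of total), \code{profile}
#' (clustering with CDT/GTR export, enrichment calls, abundance ranking,
#' category rollup) and \code{goldcount} (band histogram, reference band,
#' zonal distribution), writing every artifact plus a machine-readable
#' manifest (inputs, parameters, seed, package version and the counts at
#' every filter step) into \code{outDir}. Later stages read the files
#' earlier stages wrote, so any stage can be re-run against existing
#' artifacts. All randomness derives from \code{seed} via [childSeed()];
#' a rerun with the same seed produces byte-identical artifacts.
#'
#' @param outDir output directory (created if needed).
#' @param seed top-level integer seed.
#' @param stages character vector of stage names, or \code{"all"}.
#' @param nProteins,nFamilies synthetic proteome size (defaults 30 and 3).
#' @param depth expected spectra per replicate (default 2000).
#' @param replicates replicates per fraction (default 3).
#' @param minConfidence PSM confidence threshold (default 0.95).
#' @param foldThreshold enrichment fold threshold (default 2).
#' @param bandNm reference band half-width, nm (default 36).
#' @param coverage coverage used when re-deriving the band (default 0.95).
#' @param apportion apportionment mode (\code{"spectra"} or
#'   \code{"peptides"}).
#' @param goldFractions generating compartment proportions for the
#'   synthetic scenes (default: the flattened-cisternae-dominated
#'   composition 0.21 / 0.67 / 0.12 over plasma membrane / cisternae /
#'   flagellum).
#' @param nParticles,nMicrographs gold scene sizes (defaults 200 and 6).
#' @param jitterSd gold localization jitter, nm (default 10).
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(outDir, seed = 1L, stages = "all",
                        nProteins = 30L, nFamilies = 3L, depth = 2000,
                        replicates = 3L, minConfidence = 0.95,
                        foldThreshold = 2, bandNm = 36, coverage = 0.95,
                        apportion = c("spectra", "peptides"),
                        goldFractions = c(plasma_membrane = 0.21,
                                          cisternae = 0.67,
                                          flagellum = 0.12),
                        nParticles = 200L, nMicrographs = 6L,
                        jitterSd = 10) {
  apportion <- match.arg(apportion)
  allStages <- c("simulate", "infer", "quantify", "profile", "goldcount")
  if (identical(stages, "all")) stages <- allStages
  bad <- setdiff(stages, allStages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outDir, "psm"), showWarnings = FALSE)
  dir.create(file.path(outDir, "scenes"), showWarnings = FALSE)
  manifest <- list(package = "SpectroGold",
                   version = as.character(utils::packageVersion(
                     "SpectroGold")),
                   seed = as.integer(seed), stages = stages,
                   parameters = list(
                     nProteins = nProteins, nFamilies = nFamilies,
                     depth = depth, replicates = replicates,
                     minConfidence = minConfidence,
                     foldThreshold = foldThreshold, bandNm = bandNm,
                     coverage = coverage, apportion = apportion,
                     goldFractions = as.list(goldFractions),
                     nParticles = nParticles,
                     nMicrographs = nMicrographs, jitterSd = jitterSd),
                   counts = list(), files = character(0))
  addFile <- function(p) manifest$files <<- c(manifest$files,
                                              basename(p))

  if ("simulate" %in% stages) {
    gp <- generateProteome(nProteins, nFamilies, seed = seed)
    writeProteinFasta(gp, file.path(outDir, "proteome.fasta"))
    addFile("proteome.fasta")
    n1 <- ceiling(nProteins / 3)
    n2 <- ceiling((nProteins - n1) / 2)
    plant <- plantedAbundance(names(gp$proteins), nEnriched = n1,
                              nReference = n2,
                              nFlat = nProteins - n1 - n2, seed = seed)
    design <- fractionDesign(plant$abundance, replicates = replicates,
                             depth = depth, seed = seed)
    tabs <- generatePSMTables(gp, design)
    for (nm in names(tabs)) {
      p <- file.path(outDir, "psm", paste0(nm, ".tsv"))
      writePSMTable(tabs[[nm]], p)
      addFile(file.path("psm", basename(p)))
    }
    writeTSV(data.frame(accession = names(plant$truth),
                        truth = plant$truth),
             file.path(outDir, "planted_truth.tsv"))
    addFile("planted_truth.tsv")
    writeTSV(randomAnnotation(names(gp$proteins), seed = seed),
             file.path(outDir, "annotation.tsv"))
    addFile("annotation.tsv")
    gd <- goldDesign(goldFractions, nParticles = nParticles,
                     nMicrographs = nMicrographs, jitterSd = jitterSd,
                     seed = seed)
    for (sc in generateGoldScenes(gd)) {
      p <- file.path(outDir, "scenes", paste0(sc@sceneId, ".json"))
      writeGoldScene(sc, p)
      addFile(file.path("scenes", basename(p)))
    }
    manifest$counts$simulatedProteins <- nProteins
    manifest$counts$simulatedPSMs <- sum(vapply(tabs, nrow, integer(1)))
    manifest$counts$simulatedScenes <- gd$nMicrographs +
      round(gd$controlFraction * gd$nMicrographs)
  }

  psms <- NULL
  groups <- NULL
  if (any(c("infer", "quantify", "profile") %in% stages)) {
    db <- readProteinFasta(file.path(outDir, "proteome.fasta"))
    files <- sort(list.files(file.path(outDir, "psm"),
                             full.names = TRUE))
    if (!length(files)) stop("no PSM tables under ",
                             file.path(outDir, "psm"), call. = FALSE)
    read <- lapply(files, readPSMTable, minConfidence = minConfidence)
    manifest$counts$psmsDropped <- sum(vapply(read, function(x)
      attr(x, "dropped"), integer(1)))
    psms <- do.call(rbind, read)
    manifest$counts$psmsRetained <- nrow(psms)
    pmap <- mapPeptides(unique(psms$peptide), db)
    manifest$counts$orphanPeptides <- length(orphanPeptides(pmap))
    groups <- inferMinimalSet(pmap)
    manifest$counts$proteinGroups <- length(groups)
    gdf <- data.frame(
      representative = representatives(groups),
      members = vapply(groupMembers(groups), paste, character(1),
                       collapse = ";"),
      nUniquePeptides = lengths(uniquePeptides(groups)),
      nSharedPeptides = lengths(sharedPeptides(groups)))
    writeTSV(gdf, file.path(outDir, "groups.tsv"))
    addFile("groups.tsv")
  }

  fq <- NULL
  if (any(c("quantify", "profile") %in% stages)) {
    fq <- quantifySpectra(psms, groups, method = apportion)
    manifest$counts$quantifiedGroups <- nrow(fq)
    writeMatrixTSV(SummarizedExperiment::assay(fq, "apportioned"),
                   file.path(outDir, "quant_apportioned.tsv"))
    writeMatrixTSV(SummarizedExperiment::assay(fq, "percent"),
                   file.path(outDir, "quant_percent.tsv"))
    prof <- fractionProfile(fq)
    writeMatrixTSV(prof$mean, file.path(outDir, "profile_mean.tsv"))
    writeMatrixTSV(prof$sd, file.path(outDir, "profile_sd.tsv"))
    for (f in c("quant_apportioned.tsv", "quant_percent.tsv",
                "profile_mean.tsv", "profile_sd.tsv")) addFile(f)
  }

  if ("profile" %in% stages) {
    prof <- fractionProfile(fq)
    cl <- clusterProfiles(prof$mean)
    writeCdtGtr(cl, file.path(outDir, "cluster"))
    addFile("cluster.cdt"); addFile("cluster.gtr")
    target <- colnames(prof$mean)[1L]
    refs <- colnames(prof$mean)[-1L]
    enr <- classifyEnrichment(prof$mean, target, refs,
                              foldThreshold = foldThreshold)
    writeTSV(enr, file.path(outDir, "enrichment.tsv"))
    addFile("enrichment.tsv")
    manifest$counts$enrichmentExcluded <- length(attr(enr, "excluded"))
    writeTSV(data.frame(rank = seq_len(nrow(prof$mean)),
                        accession = rankByAbundance(prof$mean, target)),
             file.path(outDir, "ranking.tsv"))
    addFile("ranking.tsv")
    annPath <- file.path(outDir, "annotation.tsv")
    if (!file.exists(annPath))
      stop("annotation table not found: ", annPath, call. = FALSE)
    roll <- categoryRollup(prof$mean, readCategoryTable(annPath))
    writeMatrixTSV(roll, file.path(outDir, "rollup.tsv"))
    addFile("rollup.tsv")
  }

  if ("goldcount" %in% stages) {
    files <- sort(list.files(file.path(outDir, "scenes"),
                             full.names = TRUE))
    if (!length(files)) stop("no scene files under ",
                             file.path(outDir, "scenes"), call. = FALSE)
    scenes <- lapply(files, readGoldScene)
    labelled <- Filter(function(s) !isControl(s), scenes)
    hist <- bandHistogram(labelled[[1L]])
    writeTSV(data.frame(lowerEdgeNm = as.numeric(names(hist$bins)),
                        count = as.integer(hist$bins)),
             file.path(outDir, "gold_band_histogram.tsv"))
    addFile("gold_band_histogram.tsv")
    manifest$counts$derivedBandSpanNm <-
      2 * referenceBand(hist, coverage = coverage)
    zones <- do.call(rbind, lapply(labelled, function(sc) {
      cbind(sceneId = sc@sceneId, classifyParticles(sc, bandNm))
    }))
    writeTSV(zones, file.path(outDir, "gold_zones.tsv"))
    addFile("gold_zones.tsv")
    zd <- zoneDistribution(scenes, bandHalfWidth = bandNm)
    writeTSV(zd$summary, file.path(outDir, "gold_distribution.tsv"))
    addFile("gold_distribution.tsv")
    writeTSV(zd$controls, file.path(outDir, "gold_controls.tsv"))
    addFile("gold_controls.tsv")
    manifest$counts$goldParticlesAssigned <- zd$nParticles
    manifest$counts$goldParticlesUnassigned <- zd$nUnassigned
    manifest$counts$controlParticles <- sum(zd$controls$nParticles)
  }

  manifest$files <- sort(unique(manifest$files))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
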