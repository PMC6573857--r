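# End-to-end annealing-temperature-gradient experiment driver:
# simulate -> demultiplex -> trim/filter -> PUP extraction -> rarefaction ->
# diversity -> Bray-Curtis -> MDS -> ANOSIM -> regression, with TSV outputs
# and a provenance record.

#' Derive a stage seed from a master seed
#'
#' Deterministic per-stage seed derivation so that any pipeline stage can be
#' re-run independently: a small polynomial hash of the stage label mixed
#' with the master seed, reduced modulo 2^31 - 1.
#'
#' @param master integer master seed
#' @param stage character stage label
#' @return integer seed in [1, 2^31 - 1]
#' @export
deriveSeed <- function(master, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 1000003
  as.integer((abs(as.numeric(master)) %% 65011 * 32003 + h * 97 + 1) %%
               2147483646 + 1)
}

#' Construct an experiment configuration
#'
#' Describes the full condition grid of a temperature-gradient experiment:
#' both amplification modes across a set of annealing temperatures with
#' technical replicates, plus the downstream filtering, rarefaction and
#' permutation settings.
#'
#' @param modes amplification modes to run; default both
#' @param temperatures annealing temperatures (deg C); default
#'   c(40, 45, 50, 55, 60)
#' @param replicates technical replicates per condition; default 5
#' @param inputNg input gDNA per sample (ng); default 10
#' @param readsPerNg expected reads per ng; default 300
#' @param errorRate per-base substitution rate; default 0.001
#' @param annealing an \linkS4class{AnnealingModel}
#' @param nTaxa community size; default 40
#' @param filters a \linkS4class{FilterParams}
#' @param rarefactionDepth subsampling depth; default 1800
#' @param permutations ANOSIM permutation count; default 999
#' @param masterSeed master seed from which all stage seeds derive
#' @return a list of class "ExperimentConfig"
#' @export
experimentConfig <- function(modes = c("TAS", "DePCR"),
                             temperatures = c(40, 45, 50, 55, 60),
                             replicates = 5L, inputNg = 10,
                             readsPerNg = 300, errorRate = 0.001,
                             annealing = annealingModel(), nTaxa = 40L,
                             filters = filterParams(),
                             rarefactionDepth = 1800L,
                             permutations = 999L, masterSeed = 1L) {
  if (replicates < 1L) stop("replicates must be >= 1")
  if (!length(modes) || !length(temperatures)) stop("empty condition grid")
  structure(list(
    modes = modes, temperatures = temperatures,
    replicates = as.integer(replicates), inputNg = inputNg,
    readsPerNg = readsPerNg, errorRate = errorRate, annealing = annealing,
    nTaxa = as.integer(nTaxa), filters = filters,
    rarefactionDepth = as.integer(rarefactionDepth),
    permutations = as.integer(permutations),
    masterSeed = as.integer(masterSeed)), class = "ExperimentConfig")
}

.stageLog <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the annealing-temperature-gradient experiment
#'
#' Simulates one template community amplified under every (mode,
#' temperature) condition with technical replicates, pools and
#' demultiplexes the reads, quality-trims and length-filters them, extracts
#' primer utilization profiles, rarefies, and computes alpha diversity,
#' Bray-Curtis dissimilarities, a classical MDS ordination, one-way (mode)
#' and two-way crossed (mode x temperature) ANOSIM tests, a quadratic fit
#' of DePCR Shannon index on temperature and a linear fit for the TAS arm.
#' All per-stage seeds derive from the master seed. If \code{outputDir} is
#' given, TSV outputs and a provenance file are written; outputs already
#' produced are kept on a later-stage failure.
#'
#' @param config an \code{\link{experimentConfig}} list
#' @param outputDir optional output directory
#' @return invisibly, a list with the PupExperiment (raw and rarefied),
#'   alpha-diversity table, distance matrix, ordination, ANOSIM results and
#'   regression fits
#' @export
runTemperatureGradient <- function(config = experimentConfig(),
                                   outputDir = NULL) {
  if (!is.null(outputDir) && !dir.exists(outputDir))
    dir.create(outputDir, recursive = TRUE)
  pool <- expandDegenerate(IUPAC_806R, name = "806R")
  community <- simulateCommunity(
    pool, nTaxa = config$nTaxa,
    seed = deriveSeed(config$masterSeed, "community"))
  nCond <- length(config$modes) * length(config$temperatures)
  barcodeSet <- designBarcodes(
    nCond * config$replicates, width = 10L, minDistance = 3L,
    seed = deriveSeed(config$masterSeed, "barcodes"))

  .stageLog("simulate", "%d conditions x %d replicates", nCond,
            config$replicates)
  sims <- list()
  bcOffset <- 0L
  for (mode in config$modes) {
    for (temp in config$temperatures) {
      cond <- sprintf("%s_%g", mode, temp)
      cfg <- simulationConfig(
        mode = mode, annealingTempC = temp,
        nSamples = config$replicates, inputNg = config$inputNg,
        readsPerNg = config$readsPerNg, errorRate = config$errorRate,
        annealing = config$annealing,
        seed = deriveSeed(config$masterSeed, paste0("sim_", cond)))
      bcs <- new("BarcodeSet",
                 barcodes = barcodes(barcodeSet)[bcOffset + seq_len(config$replicates)],
                 width = barcodeSet@width,
                 minDistance = barcodeSet@minDistance)
      sims[[cond]] <- simulateReads(
        community, pool, bcs, cfg,
        sampleIds = sprintf("%s_r%d", cond, seq_len(config$replicates)))
      bcOffset <- bcOffset + config$replicates
    }
  }

  # pool everything and demultiplex against the full barcode map
  allReads <- do.call(c, unname(lapply(sims, simReads)))
  allQuals <- unlist(lapply(sims, function(s) as.character(simQualities(s))),
                     use.names = FALSE)
  allBc <- unlist(lapply(sims, simBarcodes), use.names = FALSE)
  sampleTab <- do.call(rbind, lapply(sims, simSamples))
  rownames(sampleTab) <- NULL
  bm <- setNames(sampleTab$barcode, sampleTab$sampleId)
  assign <- demultiplexReads(allBc, bm, maxMismatch = 1L)
  .stageLog("demux", "%d reads in, %d assigned, %d unassigned",
            length(allReads), sum(!is.na(assign)), sum(is.na(assign)))

  keep <- which(!is.na(assign))
  trimmed <- qualityTrim(allReads[keep], allQuals[keep], config$filters)
  lf <- lengthFilter(trimmed$reads, config$filters)
  .stageLog("filter", "%d kept, %d discarded (quality), %d short, %d long",
            lf$kept, trimmed$discarded, lf$tooShort, lf$tooLong)

  readIds <- names(lf$reads)
  assignKept <- assign[keep][match(readIds, names(allReads[keep]))]
  readsBySample <- lapply(split(seq_along(lf$reads), assignKept),
                          function(i) lf$reads[i])
  readsBySample <- readsBySample[sampleTab$sampleId[
    sampleTab$sampleId %in% names(readsBySample)]]
  meta <- sampleTab[match(names(readsBySample), sampleTab$sampleId), ]
  pe <- buildPupExperiment(readsBySample, pool, sampleData = meta)
  .stageLog("pup", "%d samples profiled", ncol(pupCounts(pe)))

  peRare <- rarefyCounts(pe, depth = config$rarefactionDepth,
                         seed = deriveSeed(config$masterSeed, "rarefy"))
  .stageLog("rarefy", "%d samples at depth %d", ncol(pupCounts(peRare)),
            config$rarefactionDepth)

  sd <- as.data.frame(sampleData(peRare))
  alpha <- data.frame(
    sampleId = colnames(pupCounts(peRare)),
    mode = sd$mode, annealingTempC = sd$annealingTempC,
    shannon = shannonIndex(peRare), richness = richness(peRare),
    evenness = pielouEvenness(peRare), row.names = NULL)

  d <- brayCurtis(peRare)
  ord <- classicalMds(d, k = 2L)
  anosimMode <- anosimOneWay(
    d, sd$mode, permutations = config$permutations,
    seed = deriveSeed(config$masterSeed, "anosim1"))
  anosimTwoWay <- tryCatch(
    anosimTwoWayCrossed(
      d, sd$mode, factor(sd$annealingTempC),
      permutations = config$permutations,
      seed = deriveSeed(config$masterSeed, "anosim2")),
    error = function(e) {
      warning("two-way ANOSIM skipped: ", conditionMessage(e))
      NULL
    })

  fits <- list()
  for (mode in config$modes) {
    rows <- alpha$mode == mode
    byTemp <- tapply(alpha$shannon[rows], alpha$annealingTempC[rows], mean)
    x <- as.numeric(names(byTemp))
    fits[[mode]] <- if (mode == "DePCR" && length(x) >= 3L)
      quadraticFit(x, as.numeric(byTemp))
    else if (length(x) >= 2L)
      linearFit(x, as.numeric(byTemp))
  }

  result <- list(pup = pe, pupRarefied = peRare, alpha = alpha,
                 distance = d, ordination = ord, anosimMode = anosimMode,
                 anosimTwoWay = anosimTwoWay, fits = fits,
                 samples = sampleTab, config = config)
  if (!is.null(outputDir)) {
    writeCountTable(peRare, file.path(outputDir, "pup_counts.tsv"))
    write.table(alpha, file.path(outputDir, "alpha_diversity.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    dm <- as.matrix(d)
    write.table(data.frame(sampleId = rownames(dm), dm, check.names = FALSE),
                file.path(outputDir, "distance_matrix.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    op <- ordinationPoints(ord)
    write.table(data.frame(sampleId = rownames(op), op, check.names = FALSE),
                file.path(outputDir, "ordination.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    an <- data.frame(
      design = c("one-way mode",
                 if (!is.null(anosimTwoWay)) "two-way mode|temperature"),
      R = c(anosimR(anosimMode),
            if (!is.null(anosimTwoWay)) anosimR(anosimTwoWay)),
      p = c(anosimP(anosimMode),
            if (!is.null(anosimTwoWay)) anosimP(anosimTwoWay)))
    write.table(an, file.path(outputDir, "anosim.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    reg <- do.call(rbind, lapply(names(fits), function(m) {
      f <- fits[[m]]
      data.frame(mode = m, model = f@model,
                 term = names(f@coefficients),
                 estimate = unname(f@coefficients),
                 rSquared = f@rSquared)
    }))
    write.table(reg, file.path(outputDir, "regression.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    prov <- c(
      sprintf("depcr version: %s",
              as.character(utils::packageVersion("depcr"))),
      sprintf("R version: %s", R.version.string),
      sprintf("masterSeed: %d", config$masterSeed),
      sprintf("stage seeds: community=%d barcodes=%d rarefy=%d anosim1=%d anosim2=%d",
              deriveSeed(config$masterSeed, "community"),
              deriveSeed(config$masterSeed, "barcodes"),
              deriveSeed(config$masterSeed, "rarefy"),
              deriveSeed(config$masterSeed, "anosim1"),
              deriveSeed(config$masterSeed, "anosim2")),
      sprintf("modes: %s", paste(config$modes, collapse = ",")),
      sprintf("temperatures: %s",
              paste(config$temperatures, collapse = ",")),
      sprintf("replicates: %d", config$replicates),
      sprintf("rarefactionDepth: %d", config$rarefactionDepth),
      sprintf("errorRate: %g", config$errorRate))
    writeLines(prov, file.path(outputDir, "provenance.txt"))
  }
  invisible(result)
}
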