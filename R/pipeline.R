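#' Configuration for an end-to-end pipeline run
#'
#' Bundles the inputs, thresholds and design parameters of one reproducible
#' run. When \code{vcf} is NA the run starts by simulating its own inputs
#' (reference, cohort VCF and a validation genotype matrix) under
#' \code{seed}.
#'
#' @param outputDir directory for the output bundle (created if needed).
#' @param reference path to a reference FASTA, or NA to simulate.
#' @param vcf path to a cohort VCF, or NA to simulate.
#' @param genotypes path to a genotype TSV for the diversity report, or NA
#'   to simulate one from panel allele frequencies.
#' @param screen a \linkS4class{ScreenConfig}.
#' @param panelSize panel target size.
#' @param panelMode "proportional" or "equal" quota allocation.
#' @param bodyLength,reverseOffset,reverseLength assay geometry, see
#'   \code{\link{designKaspPrimers}}.
#' @param hweMethod HWE method for the diversity report.
#' @param nValidation individuals in the simulated validation cohort.
#' @param seed integer seed for every stochastic stage.
#' @return a list of class "RunConfig".
#' @export
runConfig <- function(outputDir,
                      reference = NA_character_, vcf = NA_character_,
                      genotypes = NA_character_,
                      screen = screenConfig(),
                      panelSize = 50, panelMode = "proportional",
                      bodyLength = 22, reverseOffset = 30,
                      reverseLength = 22,
                      hweMethod = "chi2", nValidation = 30, seed = 1) {
  structure(list(outputDir = outputDir, reference = reference, vcf = vcf,
                 genotypes = genotypes, screen = screen,
                 panelSize = panelSize, panelMode = panelMode,
                 bodyLength = bodyLength, reverseOffset = reverseOffset,
                 reverseLength = reverseLength, hweMethod = hweMethod,
                 nValidation = nValidation, seed = seed),
            class = "RunConfig")
}

#' Run the full marker-development pipeline
#'
#' Simulate (or load) inputs, screen the cohort VCF to a candidate table,
#' subsample an evenly distributed panel, design KASP assays, genotype-level
#' diversity statistics, and write every artifact plus a manifest (input
#' md5 hashes, seed, package version, stage counts). Reruns with an
#' identical config are bit-identical except the manifest timestamp.
#'
#' @param config a \code{\link{runConfig}}.
#' @return invisibly, a list with candidates, panel, assays, stats and the
#'   manifest.
#' @examples
#' \donttest{
#' cfg <- runConfig(tempfile("run"), panelSize = 10, seed = 3)
#' bundle <- runPipeline(cfg)
#' bundle$manifest$counts
#' }
#' @export
runPipeline <- function(config) {
  dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$outputDir, f)
  stages <- character()
  simulated <- is.na(config$vcf)

  if (simulated) {
    reference <- simulateReference(
      c(Chr01 = 4e5, Chr02 = 3e5, Chr03 = 2e5), seed = config$seed)
    writeReferenceFasta(reference, out("reference.fa"))
    vset <- simulateCohortVcf(reference, nSamples = 12,
                              seed = config$seed + 1)
    writeCohortVcf(vset, out("cohort.vcf"), reference)
    stages <- c(stages, "simulate")
  } else {
    reference <- readReferenceFasta(config$reference)
    vset <- readCohortVcf(config$vcf)
  }

  scr <- screenCandidates(vset, config$screen)
  writeCandidateTable(scr$candidates, out("candidates.tsv"))
  jsonlite::write_json(as.list(scr$counts), out("stage_counts.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  stages <- c(stages, "screen")
  if (!nrow(scr$candidates)) stop("screen stage produced no candidates")

  lens <- stats::setNames(as.numeric(Biostrings::width(reference)),
                          names(reference))
  size <- min(config$panelSize, nrow(scr$candidates))
  spec <- panelSpec(size, lens, seed = config$seed + 2,
                    mode = config$panelMode)
  panel <- sampleEvenPanel(scr$candidates, spec)
  writeCandidateTable(panel, out("panel.tsv"))
  stages <- c(stages, "select-panel")

  assays <- designPanelAssays(panel, reference,
                              bodyLength = config$bodyLength,
                              reverseOffset = config$reverseOffset,
                              reverseLength = config$reverseLength)
  writeAssaySheet(assays, out("assays.csv"))
  writeAssayJson(assays, out("assays.json"))
  stages <- c(stages, "design-kasp")

  gm <- if (!is.na(config$genotypes)) {
    readGenotypeTsv(config$genotypes)
  } else {
    g <- simulateGenotypeMatrix(config$nValidation, maf = panel$maf,
                                nLoci = nrow(panel),
                                seed = config$seed + 3)
    m <- g@calls
    rownames(m) <- panel$locus_id
    genotypeMatrix(m)
  }
  stats <- panelSummary(gm, hweMethod = config$hweMethod)
  writeDiversityReport(stats, out("diversity.tsv"))
  stages <- c(stages, "stats")

  files <- c("candidates.tsv", "panel.tsv", "assays.csv", "assays.json",
             "diversity.tsv", "stage_counts.json")
  if (simulated) files <- c("reference.fa", "cohort.vcf", files)
  manifest <- list(
    package = "kaspanel",
    version = as.character(utils::packageVersion("kaspanel")),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = config$seed,
    stages = stages,
    counts = as.list(scr$counts),
    thresholds = list(
      qdMin = config$screen@qdMin, qualMin = config$screen@qualMin,
      fsMax = config$screen@fsMax, mqMin = config$screen@mqMin,
      mqRankSumMin = config$screen@mqRankSumMin,
      readPosRankSumMin = config$screen@readPosRankSumMin,
      qualHighConf = config$screen@qualHighConf,
      isolationWindow = config$screen@isolationWindow,
      mafMin = config$screen@mafMin,
      maxMissing = config$screen@maxMissing,
      hweAlpha = config$screen@hweAlpha,
      picBand = c(config$screen@picMin, config$screen@picMax)),
    files = stats::setNames(
      as.list(unname(tools::md5sum(file.path(config$outputDir, files)))),
      files))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(candidates = scr$candidates, panel = panel,
                 assays = assays, stats = stats, manifest = manifest))
}
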