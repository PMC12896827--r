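#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Thresholds for the SNP screening pipeline
#'
#' Holds every threshold used between a joint-genotyped cohort VCF and the
#' final candidate SNP table: the two GATK-style hard-filter stages, the
#' isolation window, the VCFtools-style population-genetic prefilter, and
#' the PIC informativeness band. Defaults are the values used to develop
#' the published 19-marker Yangtze finless porpoise panel.
#'
#' @slot qdMin minimum QD (quality by depth), default 2.0.
#' @slot qualMin minimum site QUAL for the initial hard filter, default 30.
#' @slot fsMax maximum FS (Phred strand bias), default 60.
#' @slot mqMin minimum RMS mapping quality MQ, default 40.
#' @slot mqRankSumMin minimum MQRankSum, default -12.5.
#' @slot readPosRankSumMin minimum ReadPosRankSum, default -8.0.
#' @slot qualHighConf QUAL required for the high-confidence ("FIRSTOK")
#'   stage, default 1000.
#' @slot isolationWindow exclusion distance in bp: a SNP is dropped if any
#'   other variant lies at distance <= this value, default 100.
#' @slot mafMin minimum minor allele frequency (VCFtools \code{--maf}),
#'   default 0.05.
#' @slot maxMissing maximum fraction of missing genotypes per site
#'   (VCFtools \code{--max-missing 1} means 0 here), default 0.
#' @slot hweAlpha Hardy-Weinberg exclusion level (VCFtools \code{--hwe}),
#'   default 0.001.
#' @slot hweMethod "exact" or "chi2".
#' @slot picMin,picMax inclusive PIC band, defaults 0.2 and 0.5.
#' @exportClass ScreenConfig
setClass("ScreenConfig",
  representation(
    qdMin = "numeric", qualMin = "numeric", fsMax = "numeric",
    mqMin = "numeric", mqRankSumMin = "numeric",
    readPosRankSumMin = "numeric", qualHighConf = "numeric",
    isolationWindow = "numeric", mafMin = "numeric",
    maxMissing = "numeric", hweAlpha = "numeric", hweMethod = "character",
    picMin = "numeric", picMax = "numeric"
  ),
  prototype(
    qdMin = 2.0, qualMin = 30.0, fsMax = 60.0, mqMin = 40.0,
    mqRankSumMin = -12.5, readPosRankSumMin = -8.0, qualHighConf = 1000.0,
    isolationWindow = 100, mafMin = 0.05, maxMissing = 0,
    hweAlpha = 0.001, hweMethod = "exact", picMin = 0.2, picMax = 0.5
  )
)

setValidity("ScreenConfig", function(object) {
  msg <- character()
  if (object@picMin < 0 || object@picMax > 1 || object@picMin > object@picMax)
    msg <- c(msg, "PIC band must satisfy 0 <= picMin <= picMax <= 1")
  if (object@isolationWindow < 0)
    msg <- c(msg, "isolationWindow must be >= 0")
  if (object@mafMin < 0 || object@mafMin > 0.5)
    msg <- c(msg, "mafMin must be in [0, 0.5]")
  if (object@maxMissing < 0 || object@maxMissing > 1)
    msg <- c(msg, "maxMissing must be in [0, 1]")
  if (!object@hweMethod %in% c("exact", "chi2"))
    msg <- c(msg, "hweMethod must be 'exact' or 'chi2'")
  if (length(msg)) msg else TRUE
})

#' Construct a ScreenConfig
#'
#' @param ... named slot overrides; unnamed defaults follow the published
#'   pipeline (QD >= 2, QUAL >= 30, FS <= 60, MQ >= 40, MQRankSum >= -12.5,
#'   ReadPosRankSum >= -8; QUAL >= 1000 for the high-confidence tag;
#'   100 bp isolation; maf 0.05 / max-missing 1 / hwe 0.001; PIC 0.2-0.5).
#' @return a \linkS4class{ScreenConfig}.
#' @examples
#' screenConfig()
#' screenConfig(hweMethod = "chi2", picMax = 0.45)
#' @export
screenConfig <- function(...) new("ScreenConfig", ...)

#' A set of cohort variant calls
#'
#' A compact container for joint-genotyped SNP calls: one row per site with
#' position, alleles, QUAL, the GATK annotations used for hard filtering
#' (QD, FS, MQ, MQRankSum, ReadPosRankSum; any may be NA when undefined at a
#' site), filter tags, and a per-sample genotype matrix in "a/b" notation
#' with "./." for missing.
#'
#' @slot variants data.frame with columns id, chrom, pos, ref, alt (comma
#'   separated when multiallelic), qual, qd, fs, mq, mqRankSum,
#'   readPosRankSum, tags (semicolon separated, "" when none).
#' @slot geno character matrix, rows matching \code{variants}, columns the
#'   cohort samples.
#' @exportClass VariantSet
setClass("VariantSet",
  representation(variants = "data.frame", geno = "matrix"))

setValidity("VariantSet", function(object) {
  v <- object@variants
  need <- c("id", "chrom", "pos", "ref", "alt", "qual", "qd", "fs", "mq",
            "mqRankSum", "readPosRankSum", "tags")
  msg <- character()
  if (!all(need %in% names(v)))
    msg <- c(msg, paste("variants lacks columns:",
                        paste(setdiff(need, names(v)), collapse = ", ")))
  else {
    if (nrow(v) != nrow(object@geno))
      msg <- c(msg, "geno rows must match variants rows")
    if (nrow(v) && any(v$pos < 1)) msg <- c(msg, "positions must be >= 1")
    if (nrow(v)) {
      alts <- strsplit(v$alt, ",", fixed = TRUE)
      if (any(mapply(function(r, a) r %in% a, v$ref, alts)))
        msg <- c(msg, "ref allele must differ from every alt allele")
    }
    if (anyDuplicated(v$id)) msg <- c(msg, "variant ids must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a VariantSet
#'
#' @param variants data.frame of site-level fields (see
#'   \linkS4class{VariantSet}); a missing \code{id} column is filled with
#'   "chrom_pos" locus ids and a missing \code{tags} column with "".
#' @param geno character genotype matrix ("0/0", "0/1", ..., "./.") with
#'   one row per variant and one column per sample.
#' @return a \linkS4class{VariantSet}.
#' @export
VariantSet <- function(variants, geno) {
  variants <- as.data.frame(variants)
  if (is.null(variants$id))
    variants$id <- paste(variants$chrom, variants$pos, sep = "_")
  if (is.null(variants$tags)) variants$tags <- ""
  for (col in c("qd", "fs", "mq", "mqRankSum", "readPosRankSum"))
    if (is.null(variants[[col]])) variants[[col]] <- NA_real_
  rownames(variants) <- NULL
  if (is.null(colnames(geno)))
    colnames(geno) <- sprintf("S%02d", seq_len(ncol(geno)))
  new("VariantSet", variants = variants, geno = geno)
}

#' Biallelic genotype calls for a set of loci and individuals
#'
#' Calls are coded as copies of the minor allele (0, 1, 2) with NA for
#' missing data, rows = loci, columns = individuals.
#'
#' @slot calls integer matrix with dimnames (loci, samples).
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix", representation(calls = "matrix"))

setValidity("GenotypeMatrix", function(object) {
  m <- object@calls
  msg <- character()
  if (!is.numeric(m)) msg <- c(msg, "calls must be numeric")
  else if (!all(m[!is.na(m)] %in% 0:2))
    msg <- c(msg, "calls must be 0, 1, 2 or NA")
  if (is.null(rownames(m))) msg <- c(msg, "loci must be named (rownames)")
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param calls numeric/integer matrix of minor-allele dosages (0/1/2, NA
#'   missing), loci in rows. Unnamed rows/columns get "LocusNN"/"SNN" ids.
#' @return a \linkS4class{GenotypeMatrix}.
#' @export
genotypeMatrix <- function(calls) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(rownames(calls)))
    rownames(calls) <- sprintf("Locus%02d", seq_len(nrow(calls)))
  if (is.null(colnames(calls)))
    colnames(calls) <- sprintf("S%02d", seq_len(ncol(calls)))
  new("GenotypeMatrix", calls = calls)
}

#' Reference context around a SNP
#'
#' Up to 150 bp of sequence either side of a target SNP, as used for
#' genotyping assay design. When both flanks are full length the variant
#' base sits at position 151 of the 301-bp window.
#'
#' @slot chrom chromosome name.
#' @slot pos 1-based position of the SNP.
#' @slot left,right flanking sequence (5' and 3' of the site, plus strand).
#' @slot refBase the reference base at \code{pos}.
#' @exportClass FlankContext
setClass("FlankContext",
  representation(chrom = "character", pos = "numeric",
                 left = "character", refBase = "character",
                 right = "character"))

setValidity("FlankContext", function(object) {
  ok <- grepl("^[ACGT]*$", c(object@left, object@right)) &
    c(TRUE, TRUE)
  if (!all(ok) || !grepl("^[ACGT]$", object@refBase))
    "flank sequences must be over {A,C,G,T} and refBase a single base"
  else if (object@pos < 1) "pos must be >= 1"
  else TRUE
})

#' A KASP assay definition for one SNP
#'
#' Two allele-specific forward primers (F1 carrying the universal FAM tail,
#' F2 the VIC tail; their untailed bodies are identical except the 3'
#' terminal base, which is the discriminating allele) plus one common
#' reverse primer on the opposite strand downstream of the SNP. Primer
#' premix is mixed F1:F2:R = 1:1:3 by volume.
#'
#' @slot locusId locus identifier ("Chr_Pos").
#' @slot chrom,pos genomic location.
#' @slot alleles the two alleles; alleles[1] (the reference base) reports
#'   through FAM, alleles[2] through VIC.
#' @slot f1,f2 tailed allele-specific forward primer sequences.
#' @slot reverse common reverse primer sequence.
#' @slot premix integer volume parts for F1, F2, R (1, 1, 3).
#' @exportClass KaspAssay
setClass("KaspAssay",
  representation(locusId = "character", chrom = "character",
                 pos = "numeric", alleles = "character",
                 f1 = "character", f2 = "character", reverse = "character",
                 premix = "numeric"))

setValidity("KaspAssay", function(object) {
  msg <- character()
  if (length(object@alleles) != 2 ||
      !all(grepl("^[ACGT]$", object@alleles)) ||
      object@alleles[1] == object@alleles[2])
    msg <- c(msg, "alleles must be two distinct single bases")
  if (!startsWith(object@f1, kaspTails()[["FAM"]]))
    msg <- c(msg, "F1 must begin with the FAM tail")
  if (!startsWith(object@f2, kaspTails()[["VIC"]]))
    msg <- c(msg, "F2 must begin with the VIC tail")
  if (!all(grepl("^[ACGT]+$", c(object@f1, object@f2, object@reverse))))
    msg <- c(msg, "primer sequences must be over {A,C,G,T}")
  if (length(msg)) msg else TRUE
})

#' Specification for evenly distributed panel subsampling
#'
#' @slot targetSize number of SNPs to select.
#' @slot chromLengths named numeric vector of chromosome lengths (bp).
#' @slot seed integer seed; mandatory so published panels are reproducible.
#' @slot mode quota allocation: "proportional" (to chromosome length) or
#'   "equal" (same quota per chromosome).
#' @exportClass PanelSpec
setClass("PanelSpec",
  representation(targetSize = "numeric", chromLengths = "numeric",
                 seed = "numeric", mode = "character"))

setValidity("PanelSpec", function(object) {
  msg <- character()
  if (object@targetSize < 1) msg <- c(msg, "targetSize must be >= 1")
  if (is.null(names(object@chromLengths)) || any(object@chromLengths <= 0))
    msg <- c(msg, "chromLengths must be named and positive")
  if (!object@mode %in% c("proportional", "equal"))
    msg <- c(msg, "mode must be 'proportional' or 'equal'")
  if (length(msg)) msg else TRUE
})

#' Construct a PanelSpec
#'
#' @param targetSize panel size.
#' @param chromLengths named chromosome lengths in bp.
#' @param seed integer seed (required).
#' @param mode "proportional" or "equal".
#' @return a \linkS4class{PanelSpec}.
#' @export
panelSpec <- function(targetSize, chromLengths, seed,
                      mode = c("proportional", "equal")) {
  mode <- match.arg(mode)
  new("PanelSpec", targetSize = targetSize, chromLengths = chromLengths,
      seed = as.numeric(seed), mode = mode)
}
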