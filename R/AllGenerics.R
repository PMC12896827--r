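#' @rdname VariantSet-class
#' @param x,object a \linkS4class{VariantSet} or \linkS4class{GenotypeMatrix}.
#' @export
setGeneric("variantTable", function(x) standardGeneric("variantTable"))

#' @rdname VariantSet-class
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname VariantSet-class
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))

#' @rdname VariantSet-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("genotypeCalls", function(x) standardGeneric("genotypeCalls"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("lociIds", function(x) standardGeneric("lociIds"))

#' Site-level table of a VariantSet
#' @param x a \linkS4class{VariantSet}.
#' @return \code{variantTable}: the site-level data.frame;
#'   \code{genotypes}: the character genotype matrix; \code{nVariants}:
#'   the record count; \code{sampleIds}: cohort sample names.
#' @aliases genotypes nVariants variantTable
#' @name VariantSet-accessors
NULL

setMethod("variantTable", "VariantSet", function(x) x@variants)
setMethod("genotypes", "VariantSet", function(x) x@geno)
setMethod("nVariants", "VariantSet", function(x) nrow(x@variants))
setMethod("sampleIds", "VariantSet", function(x) colnames(x@geno))

setMethod("genotypeCalls", "GenotypeMatrix", function(x) x@calls)
setMethod("lociIds", "GenotypeMatrix", function(x) rownames(x@calls))
setMethod("sampleIds", "GenotypeMatrix", function(x) colnames(x@calls))

#' Subset a VariantSet by record index
#' @param x a \linkS4class{VariantSet}.
#' @param i integer or logical index over records.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "VariantSet", function(x, i, j, ..., drop = FALSE) {
  v <- x@variants[i, , drop = FALSE]
  rownames(v) <- NULL
  new("VariantSet", variants = v, geno = x@geno[i, , drop = FALSE])
})

setMethod("show", "VariantSet", function(object) {
  v <- object@variants
  cat("VariantSet:", nrow(v), "records,", ncol(object@geno), "samples\n")
  if (nrow(v)) {
    cat("  chromosomes:", paste(unique(v$chrom), collapse = ", "), "\n")
    cat("  tagged FIRSTOK:", sum(grepl("\\bFIRSTOK\\b", v$tags)), "\n")
  }
})

setMethod("show", "GenotypeMatrix", function(object) {
  m <- object@calls
  cat("GenotypeMatrix:", nrow(m), "loci x", ncol(m), "samples; ",
      sprintf("%.1f%% missing\n", 100 * mean(is.na(m))))
})

setMethod("show", "ScreenConfig", function(object) {
  cat("ScreenConfig\n")
  cat(sprintf("  stage 1: QD>=%.1f QUAL>=%.1f FS<=%.1f MQ>=%.1f MQRankSum>=%.1f ReadPosRankSum>=%.1f\n",
              object@qdMin, object@qualMin, object@fsMax, object@mqMin,
              object@mqRankSumMin, object@readPosRankSumMin))
  cat(sprintf("  high-confidence QUAL>=%.1f; isolation window %d bp\n",
              object@qualHighConf, as.integer(object@isolationWindow)))
  cat(sprintf("  prefilter: maf>=%.3f, missing<=%.2f, hwe alpha %.4g (%s)\n",
              object@mafMin, object@maxMissing, object@hweAlpha,
              object@hweMethod))
  cat(sprintf("  PIC band [%.2f, %.2f]\n", object@picMin, object@picMax))
})

setMethod("show", "KaspAssay", function(object) {
  cat("KaspAssay", object@locusId, paste(object@alleles, collapse = "/"), "\n")
  cat("  F1 (FAM):", object@f1, "\n  F2 (VIC):", object@f2, "\n")
  cat("  R       :", object@reverse, "  premix",
      paste(object@premix, collapse = ":"), "\n")
})
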