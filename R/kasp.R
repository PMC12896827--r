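#' Universal KASP tail sequences
#'
#' The constant 5' tails that couple each allele-specific forward primer to
#' a fluorophore through the master mix: FAM reads through
#' GAAGGTGACCAAGTTCATGCT and VIC through GAAGGTCGGAGTCAACGGATT.
#'
#' @return named character vector with elements "FAM" and "VIC".
#' @export
kaspTails <- function() c(FAM = "GAAGGTGACCAAGTTCATGCT",
                          VIC = "GAAGGTCGGAGTCAACGGATT")

#' Extract flanking sequence around a SNP
#'
#' Pulls up to \code{flank} bp either side of a position from the
#' reference, the context used for genotyping-assay design. Flanks are
#' truncated (with a warning) at chromosome ends.
#'
#' @param reference a \link[Biostrings]{DNAStringSet}.
#' @param chrom chromosome name.
#' @param pos 1-based SNP position.
#' @param flank bases per side (default 150, giving a 301 bp window with
#'   the SNP at position 151 when both flanks are full).
#' @return a \linkS4class{FlankContext}.
#' @examples
#' ref <- simulateReference(c(Chr01 = 400), seed = 1)
#' fc <- extractFlanks(ref, "Chr01", 200)
#' nchar(fc@left)
#' @export
extractFlanks <- function(reference, chrom, pos, flank = 150) {
  if (!chrom %in% names(reference)) stop("unknown chromosome: ", chrom)
  L <- Biostrings::width(reference)[match(chrom, names(reference))]
  if (pos < 1 || pos > L)
    stop("position ", pos, " outside ", chrom, " (length ", L, ")")
  seq <- as.character(reference[[match(chrom, names(reference))]])
  lStart <- max(1, pos - flank)
  rEnd <- min(L, pos + flank)
  left <- if (pos > 1) substring(seq, lStart, pos - 1) else ""
  right <- if (pos < L) substring(seq, pos + 1, rEnd) else ""
  if (nchar(left) < flank || nchar(right) < flank)
    warning("flank truncated at chromosome end for ", chrom, ":", pos)
  new("FlankContext", chrom = chrom, pos = pos, left = left,
      refBase = substring(seq, pos, pos), right = right)
}

#' Design a KASP primer set for one SNP
#'
#' Builds the two tailed allele-specific forward primers and the common
#' reverse primer. The allele-specific body is the last
#' \code{bodyLength - 1} bases of the left flank followed by the allele
#' base, placing the discriminating base at the 3' terminus, where a
#' mismatch blocks extension. F1 gets the FAM tail and the first allele
#' (the reference base, plus strand); F2 gets the VIC tail and the
#' alternate allele. The common reverse primer is the reverse complement
#' of the reference window beginning \code{reverseOffset} bases 3' of the
#' SNP. Body length and reverse-primer geometry are configuration: no
#' melting-temperature optimization is attempted.
#'
#' @param context a \linkS4class{FlankContext}.
#' @param alleles two single bases, reference allele first.
#' @param bodyLength allele-specific body length incl. the allele base
#'   (default 22).
#' @param reverseOffset gap in bases between the SNP and the start of the
#'   reverse-primer window (default 30).
#' @param reverseLength reverse primer length (default 22).
#' @return a \linkS4class{KaspAssay} with premix parts F1:F2:R = 1:1:3.
#' @examples
#' ref <- simulateReference(c(Chr01 = 400), seed = 1)
#' fc <- extractFlanks(ref, "Chr01", 200)
#' designKaspPrimers(fc, c(fc@refBase, setdiff(c("A","C","G","T"),
#'                                             fc@refBase)[1]))
#' @export
designKaspPrimers <- function(context, alleles, bodyLength = 22,
                              reverseOffset = 30, reverseLength = 22) {
  if (length(alleles) != 2 || !all(grepl("^[ACGT]$", alleles)))
    stop("alleles must be two single bases")
  left <- context@left
  if (nchar(left) < bodyLength - 1)
    stop("left flank too short (", nchar(left), " bp) for body length ",
         bodyLength)
  stub <- substring(left, nchar(left) - bodyLength + 2, nchar(left))
  bodies <- paste0(stub, alleles)
  right <- context@right
  if (nchar(right) < reverseOffset + reverseLength)
    stop("right flank too short for reverse primer geometry")
  window <- substring(right, reverseOffset + 1,
                      reverseOffset + reverseLength)
  rev <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(window)))
  tails <- kaspTails()
  new("KaspAssay",
      locusId = paste(context@chrom, context@pos, sep = "_"),
      chrom = context@chrom, pos = context@pos, alleles = alleles,
      f1 = paste0(tails[["FAM"]], bodies[1]),
      f2 = paste0(tails[["VIC"]], bodies[2]),
      reverse = rev, premix = c(1, 1, 3))
}

#' Design assays for every SNP of a panel
#'
#' @param panel data.frame with chrom, pos, ref, alt columns (a panel or
#'   candidate table).
#' @param reference a \link[Biostrings]{DNAStringSet}.
#' @param ... passed to \code{\link{designKaspPrimers}}.
#' @return list of \linkS4class{KaspAssay}.
#' @export
designPanelAssays <- function(panel, reference, ...) {
  lapply(seq_len(nrow(panel)), function(i) {
    fc <- extractFlanks(reference, panel$chrom[i], panel$pos[i])
    designKaspPrimers(fc, c(panel$ref[i], panel$alt[i]), ...)
  })
}

#' Write an orderable assay sheet
#'
#' One row per primer (three per assay: F1, F2, R) with locus, role, dye,
#' allele, sequence and premix volume part (1:1:3).
#'
#' @param assays list of \linkS4class{KaspAssay}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeAssaySheet <- function(assays, path) {
  if (!length(assays)) stop("assay list is empty")
  ids <- vapply(assays, function(a) a@locusId, "")
  if (anyDuplicated(ids))
    stop("duplicate locus ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  rows <- do.call(rbind, lapply(assays, function(a) data.frame(
    locus = a@locusId, chrom = a@chrom, pos = a@pos,
    role = c("F1", "F2", "R"),
    dye = c("FAM", "VIC", ""),
    allele = c(a@alleles, ""),
    sequence = c(a@f1, a@f2, a@reverse),
    premix_part = a@premix,
    stringsAsFactors = FALSE)))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an assay sheet back into KaspAssay objects
#'
#' @param path CSV written by \code{\link{writeAssaySheet}}.
#' @return list of \linkS4class{KaspAssay}.
#' @export
readAssaySheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(allele = "character"))
  lapply(split(df, factor(df$locus, levels = unique(df$locus))),
         function(g) {
    g <- g[match(c("F1", "F2", "R"), g$role), ]
    new("KaspAssay", locusId = g$locus[1], chrom = g$chrom[1],
        pos = g$pos[1], alleles = g$allele[1:2],
        f1 = g$sequence[1], f2 = g$sequence[2], reverse = g$sequence[3],
        premix = as.numeric(g$premix_part))
  })
}

#' Serialize assays as JSON
#'
#' @param assays list of \linkS4class{KaspAssay}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeAssayJson <- function(assays, path) {
  obj <- lapply(assays, function(a) list(
    locus = a@locusId, chrom = a@chrom, pos = a@pos,
    alleles = as.list(a@alleles),
    dyes = list(FAM = a@alleles[1], VIC = a@alleles[2]),
    f1 = a@f1, f2 = a@f2, reverse = a@reverse,
    premix = paste(a@premix, collapse = ":")))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
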