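#' Simulate a reference genome
#'
#' Generates random chromosome sequences with a target GC content, standing
#' in for a chromosome-level assembly so that variant screening and assay
#' design can be exercised without downloading sequencing accessions.
#'
#' @param chromLengths named numeric vector of chromosome lengths in bp.
#' @param gc target GC fraction in [0, 1]; bases are drawn i.i.d. with
#'   P(G) = P(C) = gc/2.
#' @param seed integer seed; identical seeds give byte-identical sequences.
#' @return a \link[Biostrings]{DNAStringSet}, one entry per chromosome.
#' @examples
#' ref <- simulateReference(c(Chr01 = 5000, Chr02 = 3000), seed = 1)
#' Biostrings::width(ref)
#' @export
simulateReference <- function(chromLengths, gc = 0.41, seed = 1) {
  if (is.null(names(chromLengths)))
    names(chromLengths) <- sprintf("Chr%02d", seq_along(chromLengths))
  if (any(chromLengths <= 0)) stop("chromosome lengths must be positive")
  if (gc < 0 || gc > 1) stop("gc must be in [0, 1]")
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- withSeed(seed, lapply(chromLengths, function(L) {
    paste(sample(names(probs), L, replace = TRUE, prob = probs),
          collapse = "")
  }))
  Biostrings::DNAStringSet(unlist(seqs))
}

#' Write a reference to FASTA
#'
#' @param reference a \link[Biostrings]{DNAStringSet}.
#' @param path output FASTA path.
#' @return \code{path}, invisibly.
#' @export
writeReferenceFasta <- function(reference, path) {
  Biostrings::writeXStringSet(reference, path, width = 70L)
  invisible(path)
}

#' Read a reference FASTA
#'
#' @param path FASTA path.
#' @return a \link[Biostrings]{DNAStringSet}.
#' @export
readReferenceFasta <- function(path) Biostrings::readDNAStringSet(path)
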