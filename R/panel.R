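#' Allocate per-chromosome panel quotas
#'
#' Distributes the panel target over chromosomes by largest-remainder
#' rounding of either chromosome-length weights ("proportional") or equal
#' weights ("equal"). Quotas are capped at the number of candidates
#' available on each chromosome, with any deficit redistributed to
#' chromosomes with spare candidates; when the target is at least the
#' number of represented chromosomes, every chromosome holding a candidate
#' receives at least one slot.
#'
#' @param candidates candidate data.frame with \code{chrom} and \code{pos}
#'   columns (as from \code{\link{screenCandidates}}).
#' @param spec a \linkS4class{PanelSpec}.
#' @return data.frame with columns chrom, available, quota; quotas sum to
#'   the target.
#' @export
allocateQuotas <- function(candidates, spec) {
  avail <- table(candidates$chrom)
  chroms <- names(avail)
  target <- spec@targetSize
  if (target > nrow(candidates))
    stop("panel target (", target, ") exceeds the ", nrow(candidates),
         " available candidates")
  w <- if (spec@mode == "proportional") {
    if (!all(chroms %in% names(spec@chromLengths)))
      stop("chromLengths lacks: ",
           paste(setdiff(chroms, names(spec@chromLengths)), collapse = ", "))
    spec@chromLengths[chroms]
  } else stats::setNames(rep(1, length(chroms)), chroms)

  largestRemainder <- function(weights, total, cap) {
    raw <- weights / sum(weights) * total
    q <- pmin(floor(raw), cap)
    # distribute the remainder by descending fractional part, capped
    while (sum(q) < total) {
      room <- cap - q
      frac <- raw - floor(raw)
      frac[room <= 0] <- -Inf
      pick <- which.max(frac)   # ties: first chromosome
      if (!is.finite(frac[pick])) break  # cannot happen when total <= sum(cap)
      q[pick] <- q[pick] + 1
      raw[pick] <- floor(raw[pick])   # consume its fractional part
    }
    q
  }
  q <- largestRemainder(w, target, as.numeric(avail))
  # guarantee representation when feasible
  if (target >= length(chroms)) {
    while (any(q == 0)) {
      z <- which(q == 0)[1]
      donor <- which.max(q)
      q[donor] <- q[donor] - 1
      q[z] <- q[z] + 1
    }
  }
  data.frame(chrom = chroms, available = as.integer(avail),
             quota = as.integer(q), stringsAsFactors = FALSE)
}

#' Sample an evenly distributed SNP panel
#'
#' "Evenly distributed" is operationalized positionally: within each
#' chromosome the candidate span is cut into quota-many equal-width bins
#' and one candidate is drawn uniformly (seeded) from each; empty bins are
#' backfilled from the nearest bins that still hold unselected candidates.
#' The output size equals the target whenever enough candidates exist.
#'
#' @param candidates candidate data.frame (\code{chrom}, \code{pos}, plus
#'   any other columns, which are carried through).
#' @param spec a \linkS4class{PanelSpec}; its seed makes the panel
#'   reproducible.
#' @return the selected rows, sorted by (chrom, pos), with a \code{bin}
#'   column giving each pick's bin index.
#' @examples
#' cand <- data.frame(chrom = "Chr01", pos = seq(1000, 99000, by = 700))
#' spec <- panelSpec(20, c(Chr01 = 1e5), seed = 11)
#' nrow(sampleEvenPanel(cand, spec))
#' @export
sampleEvenPanel <- function(candidates, spec) {
  quotas <- allocateQuotas(candidates, spec)
  withSeed(spec@seed, {
    picks <- lapply(seq_len(nrow(quotas)), function(k) {
      ch <- quotas$chrom[k]; q <- quotas$quota[k]
      if (q == 0) return(NULL)
      rows <- which(candidates$chrom == ch)
      pos <- candidates$pos[rows]
      span <- range(pos)
      breaks <- seq(span[1], span[2], length.out = q + 1)
      bin <- if (q == 1) rep(1L, length(pos)) else
        pmin(q, findInterval(pos, breaks, rightmost.closed = TRUE))
      sel <- integer(0); selBin <- integer(0)
      taken <- rep(FALSE, length(rows))
      for (b in seq_len(q)) {
        inBin <- which(bin == b & !taken)
        if (length(inBin)) {
          j <- if (length(inBin) == 1) inBin else sample(inBin, 1)
          taken[j] <- TRUE
          sel <- c(sel, rows[j]); selBin <- c(selBin, b)
        }
      }
      # backfill deficits from the nearest bins with spare candidates
      deficit <- q - length(sel)
      emptyBins <- setdiff(seq_len(q), selBin)
      while (deficit > 0) {
        b <- emptyBins[1]; emptyBins <- emptyBins[-1]
        free <- which(!taken)
        if (!length(free)) break
        nearest <- free[order(abs(bin[free] - b))]
        cands <- nearest[abs(bin[nearest] - b) == abs(bin[nearest[1]] - b)]
        j <- if (length(cands) == 1) cands else sample(cands, 1)
        taken[j] <- TRUE
        sel <- c(sel, rows[j]); selBin <- c(selBin, bin[j])
        deficit <- deficit - 1
      }
      out <- candidates[sel, , drop = FALSE]
      out$bin <- selBin
      out
    })
    panel <- do.call(rbind, picks)
    panel <- panel[order(panel$chrom, panel$pos), , drop = FALSE]
    rownames(panel) <- NULL
    panel
  })
}
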