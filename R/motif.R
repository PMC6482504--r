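# Trinucleotide motif enrichment around SNP sites. A motif is the
# reference-strand 5'-N X N-3' context of the polymorphic site combined with
# the SNP's (unordered) substitution type: 16 flank pairs x 6 types = 96
# classes, written e.g. "A[C/T]G". Enrichment is called against an empirical
# null built from randomly resampled flanking sites.

#' All 96 motif class labels
#'
#' @return character vector of 96 labels "L[type]R" in a fixed order.
#' @export
motif_classes <- function() {
  out <- character(0)
  for (tp in SUBSTITUTION_TYPES) {
    for (l in DNA_BASES) {
      for (r in DNA_BASES) {
        out <- c(out, paste0(l, "[", tp, "]", r))
      }
    }
  }
  out
}

#' @noRd
motif_label <- function(left, type, right) {
  paste0(left, "[", type, "]", right)
}

#' Trinucleotide context at a SNP position
#'
#' Reference-strand bases at pos-1, pos, pos+1. Chromosome-end positions and
#' contexts containing N are excluded (NA).
#'
#' @inheritParams genome_base
#' @return character vector of 3-mers (NA = excluded).
#' @export
motif_at <- function(genome, chrom, pos) {
  genome_context(genome, chrom, pos)
}

#' Motif frequency spectrum of a SNP set
#'
#' Each classifiable SNP (context available, see [motif_at()]) contributes to
#' exactly one of the 96 classes; frequencies sum to 1.
#'
#' @param snps SNP table.
#' @param genome named character vector of chromosome sequences.
#' @return named numeric vector of 96 class frequencies with attributes
#'   \code{n_classified} and \code{n_excluded}.
#' @export
motif_spectrum <- function(snps, genome) {
  ctx <- motif_at(genome, snps$chrom, snps$pos)
  ok <- !is.na(ctx)
  if (!any(ok)) stop("no classifiable SNPs (all contexts excluded)")
  type <- classify_substitution(snps$ref[ok], snps$alt[ok])
  lab <- motif_label(substring(ctx[ok], 1, 1), type, substring(ctx[ok], 3, 3))
  counts <- table(factor(lab, levels = motif_classes()))
  freq <- as.numeric(counts) / sum(counts)
  names(freq) <- motif_classes()
  attr(freq, "n_classified") <- sum(ok)
  attr(freq, "n_excluded") <- sum(!ok)
  freq
}

#' One random-flanking-site replicate spectrum
#'
#' For each SNP one position is drawn uniformly from its +/- \code{flank} bp
#' window excluding the SNP position itself, clipped to the chromosome. The
#' random site contributes its own flanking bases while keeping the SNP's
#' substitution type, making this a pure local-sequence-composition null.
#' Sites whose context is excluded (chromosome end, N) are skipped in the
#' replicate.
#'
#' @inheritParams motif_spectrum
#' @param flank half-width of the sampling window in bp (default 1000).
#' @return named numeric vector of 96 class frequencies.
#' @export
random_site_spectrum <- function(snps, genome, flank = 1000) {
  lens <- chrom_lengths(genome)
  lo <- pmax(1L, snps$pos - flank)
  hi <- pmin(lens[snps$chrom], snps$pos + flank)
  # uniform over [lo, hi] \ {pos}: draw over hi-lo values, skip past pos
  r <- lo + floor(runif(nrow(snps)) * (hi - lo))
  r <- ifelse(r >= snps$pos, r + 1L, r)
  ctx <- genome_context(genome, snps$chrom, as.integer(r))
  ok <- !is.na(ctx)
  if (!any(ok)) stop("no classifiable random sites")
  type <- classify_substitution(snps$ref[ok], snps$alt[ok])
  lab <- motif_label(substring(ctx[ok], 1, 1), type, substring(ctx[ok], 3, 3))
  counts <- table(factor(lab, levels = motif_classes()))
  freq <- as.numeric(counts) / sum(counts)
  names(freq) <- motif_classes()
  freq
}

#' Empirical null: per-class 95th percentile over random-site replicates
#'
#' Runs [random_site_spectrum()] \code{n_reps} times and takes, per motif
#' class, the 95th percentile of the replicate frequencies (the empirical
#' threshold an observed frequency must beat).
#'
#' @inheritParams random_site_spectrum
#' @param n_reps number of random replicates (default 100).
#' @param seed RNG seed.
#' @param probs percentile to extract (default 0.95).
#' @return named numeric vector of 96 per-class thresholds.
#' @export
null_spectrum <- function(snps, genome, n_reps = 100, flank = 1000, seed,
                          probs = 0.95) {
  set.seed(seed)
  reps <- vapply(seq_len(n_reps),
                 function(i) random_site_spectrum(snps, genome, flank),
                 numeric(96))
  apply(reps, 1, quantile, probs = probs, names = FALSE)
}

#' Call motif enrichment against the empirical null
#'
#' A motif is enriched when the ratio of its observed frequency at SNP sites
#' over the 95th-percentile frequency at random sites is strictly greater
#' than 1 and its observed frequency exceeds the uniform expectation 1/96.
#' A zero null threshold yields an infinite ratio; enrichment then still
#' requires observed > 1/96.
#'
#' @param observed named 96-vector from [motif_spectrum()].
#' @param null95 named 96-vector from [null_spectrum()].
#' @return data.frame with motif, type, observed, null95, ratio, enriched
#'   and uv (solar-UV-signature motif flag).
#' @export
call_enrichment <- function(observed, null95) {
  stopifnot(length(observed) == 96, length(null95) == 96)
  ratio <- ifelse(null95 > 0, observed / null95,
                  ifelse(observed > 0, Inf, NA))
  type <- sub("^.\\[(.*)\\].$", "\\1", names(observed))
  uv <- uv_motifs()
  data.frame(motif = names(observed), type = type,
             observed = as.numeric(observed), null95 = as.numeric(null95),
             ratio = ratio,
             enriched = !is.na(ratio) & ratio > 1 & observed > 1 / 96,
             uv = names(observed) %in% uv$motif,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' The four motifs related to the solar-UV signature
#'
#' C/T-type SNPs in 5'-C_G-3' and 5'-T_G-3' contexts (PyCG -> PyTG under the
#' UV-induced CPD mechanism) and their reverse complements, A/G-type SNPs in
#' 5'-C_G-3' and 5'-C_A-3' contexts.
#'
#' @return data.frame with columns type and motif (4 rows).
#' @export
uv_motifs <- function() {
  data.frame(type = c("C/T", "C/T", "A/G", "A/G"),
             motif = c(motif_label("C", "C/T", "G"),
                       motif_label("T", "C/T", "G"),
                       motif_label("C", "A/G", "G"),
                       motif_label("C", "A/G", "A")),
             stringsAsFactors = FALSE)
}

#' UV-signature motif frequencies per genomic stratum
#'
#' Computes [motif_spectrum()] restricted to each stratum of a SNP partition
#' and reports the four UV-signature motif frequencies per stratum. Empty
#' strata are flagged absent (NA frequencies).
#'
#' @param snps SNP table.
#' @param genome named character vector of chromosome sequences.
#' @param strata named list of logical vectors (or index vectors) over
#'   \code{snps} rows defining the strata.
#' @return data.frame with stratum, n_snps and one column per UV motif.
#' @export
conditional_uv_frequencies <- function(snps, genome, strata) {
  uv <- uv_motifs()
  rows <- lapply(names(strata), function(s) {
    sel <- strata[[s]]
    if (is.logical(sel)) sel <- which(sel)
    out <- data.frame(stratum = s, n_snps = length(sel),
                      stringsAsFactors = FALSE)
    if (length(sel) == 0) {
      out[, uv$motif] <- NA_real_
    } else {
      sp <- motif_spectrum(snps[sel, , drop = FALSE], genome)
      out[, uv$motif] <- as.numeric(sp[uv$motif])
    }
    out
  })
  do.call(rbind, rows)
}
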