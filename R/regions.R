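# Genomic-region strata (pericentromere, TE, sweeps, methylation) and the
# correlation of windowed [AT]-difference with recombination/crossover rate.

#' Classify 100-bp methylation windows into methylated/unmethylated regions
#'
#' A window is methylated when its CG-methylation percentage is strictly
#' greater than \code{cutoff} (default 40); windows with no CG sites (NA
#' percentage) count as unmethylated. Adjacent same-state windows are merged
#' into intervals.
#'
#' @param meth value-carrying interval track: chrom, start, end (0-based
#'   half-open, non-overlapping windows aligned to multiples of 100 from the
#'   chromosome start) and value = CG-methylation percentage in [0, 100].
#' @param cutoff methylation percentage threshold (default 40, strict >).
#' @return list with interval tracks \code{methylated} and
#'   \code{unmethylated}.
#' @export
methylated_regions <- function(meth, cutoff = 40) {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(meth)))
  v <- meth$value
  if (any(!is.na(v) & (v < 0 | v > 100))) {
    stop("methylation percentages must lie in [0, 100]")
  }
  if (any(meth$start %% 100 != 0)) {
    stop("methylation windows must start at multiples of 100")
  }
  for (cn in unique(meth$chrom)) {
    m <- meth[meth$chrom == cn, ]
    m <- m[order(m$start), ]
    if (nrow(m) > 1 && any(m$start[-1] < m$end[-nrow(m)])) {
      stop("overlapping methylation windows on ", cn)
    }
  }
  is_meth <- !is.na(v) & v > cutoff
  list(methylated = interval_track(meth[is_meth, c("chrom", "start", "end")],
                                   label = "methylated", merge = TRUE),
       unmethylated = interval_track(meth[!is_meth,
                                          c("chrom", "start", "end")],
                                     label = "unmethylated", merge = TRUE))
}

#' Pericentromeric intervals from centromere positions
#'
#' The pericentromere is the centromere plus a flank (default 40 Mb, the
#' maize rule) on each side, clipped to the chromosome; the centromere itself
#' is included. Pre-computed pericentromere coordinates (e.g. from a genome
#' browser) can instead be supplied directly as a BED track downstream.
#'
#' @param centromeres interval track with exactly one record per chromosome.
#' @param lens named chromosome lengths; every chromosome in \code{lens}
#'   must have a centromere record.
#' @param flank flank size in bp (default 4e7).
#' @return interval track of pericentromeric regions.
#' @export
pericentromere <- function(centromeres, lens, flank = 4e7) {
  missing <- setdiff(names(lens), centromeres$chrom)
  if (length(missing)) {
    stop("chromosome(s) without a centromere record: ",
         paste(missing, collapse = ", "))
  }
  cen <- centromeres[centromeres$chrom %in% names(lens), , drop = FALSE]
  if (anyDuplicated(cen$chrom)) stop("multiple centromere records per chromosome")
  interval_track(data.frame(chrom = cen$chrom,
                            start = pmax(0, cen$start - flank),
                            end = pmin(unname(lens[cen$chrom]),
                                       cen$end + flank),
                            stringsAsFactors = FALSE),
                 label = "pericentromere")
}

#' Membership of SNPs in an interval track
#'
#' A SNP at 1-based position pos is inside a 0-based half-open interval
#' [start, end) when pos - 1 falls in it.
#'
#' @param snps SNP table.
#' @param track interval track.
#' @return logical vector over \code{snps} rows.
#' @export
snps_in_track <- function(snps, track) {
  if (nrow(track) == 0 || nrow(snps) == 0) return(rep(FALSE, nrow(snps)))
  snp_gr <- GenomicRanges::GRanges(snps$chrom,
                                   IRanges::IRanges(snps$pos, snps$pos))
  GenomicRanges::countOverlaps(snp_gr, track_granges(track)) > 0
}

#' Partition SNPs by an interval track
#'
#' @inheritParams snps_in_track
#' @return list with \code{inside} and \code{outside} SNP tables and the
#'   logical membership vector \code{member}; the partition is complete and
#'   disjoint.
#' @export
stratify_snps <- function(snps, track) {
  member <- snps_in_track(snps, track)
  inside <- snps[member, , drop = FALSE]
  outside <- snps[!member, , drop = FALSE]
  rownames(inside) <- rownames(outside) <- NULL
  list(inside = inside, outside = outside, member = member)
}

#' Group-mean [AT] and [AT]-difference per stratum
#'
#' For each stratum the wild and domesticated (landrace + improved) group
#' means of [AT] computed over the stratum's SNPs, and their difference.
#' Empty strata are flagged absent.
#'
#' @param geno accession x site genotype matrix.
#' @param snps SNP table aligned to the matrix columns.
#' @param groups per-accession factor.
#' @param strata named list of logical/index vectors over \code{snps} rows.
#' @return data.frame with stratum, n_snps, at_wild, at_dom, at_diff, defined.
#' @export
stratified_at_difference <- function(geno, snps, groups, strata) {
  wild <- groups == "wild"
  dom <- groups %in% c("landrace", "improved")
  rows <- lapply(names(strata), function(s) {
    sel <- strata[[s]]
    if (is.logical(sel)) sel <- which(sel)
    if (length(sel) == 0) {
      return(data.frame(stratum = s, n_snps = 0L, at_wild = NA_real_,
                        at_dom = NA_real_, at_diff = NA_real_,
                        defined = FALSE, stringsAsFactors = FALSE))
    }
    at <- compute_at(geno[, sel, drop = FALSE], snps[sel, , drop = FALSE])$at
    aw <- mean(at[wild], na.rm = TRUE)
    ad <- mean(at[dom], na.rm = TRUE)
    data.frame(stratum = s, n_snps = length(sel), at_wild = aw, at_dom = ad,
               at_diff = ad - aw, defined = TRUE, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Correlate windowed [AT]-difference with a rate track, per chromosome
#'
#' Windows are matched on (chrom, start, end); masked/NA windows are dropped
#' pairwise. Pearson correlation by default. Chromosomes with fewer than 3
#' complete pairs are flagged undefined.
#'
#' @param at_diff data.frame with chrom, start, end and at_diff (e.g. from
#'   [windowed_at_difference()]).
#' @param rate value-carrying interval track with matching windows.
#' @param method correlation method passed to [stats::cor.test()].
#' @return data.frame with chrom, n_windows, r, p.value, defined.
#' @export
rate_correlation <- function(at_diff, rate, method = "pearson") {
  key_a <- paste(at_diff$chrom, at_diff$start, at_diff$end)
  key_r <- paste(rate$chrom, rate$start, rate$end)
  m <- match(key_a, key_r)
  merged <- data.frame(chrom = at_diff$chrom, d = at_diff$at_diff,
                       v = rate$value[m])
  rows <- lapply(unique(merged$chrom), function(cn) {
    sub <- merged[merged$chrom == cn & complete.cases(merged), ]
    if (nrow(sub) < 3) {
      return(data.frame(chrom = cn, n_windows = nrow(sub), r = NA_real_,
                        p.value = NA_real_, defined = FALSE,
                        stringsAsFactors = FALSE))
    }
    ct <- cor.test(sub$d, sub$v, method = method, exact = FALSE)
    data.frame(chrom = cn, n_windows = nrow(sub), r = unname(ct$estimate),
               p.value = ct$p.value, defined = TRUE, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-window mean minor allele frequency
#'
#' MAF per site is computed over non-missing calls; windows without SNPs are
#' masked.
#'
#' @param geno accession x site genotype matrix.
#' @param snps SNP table aligned to the matrix columns.
#' @param windows data.frame with chrom, start, end (1-based inclusive,
#'   e.g. from [make_windows()]).
#' @return \code{windows} with added n_snps, mean_maf, masked.
#' @export
windowed_maf <- function(geno, snps, windows) {
  n_nonmiss <- colSums(!is.na(geno))
  p <- ifelse(n_nonmiss > 0, colSums(geno, na.rm = TRUE) / n_nonmiss, NA)
  maf <- pmin(p, 1 - p)
  windows$n_snps <- 0L
  windows$mean_maf <- NA_real_
  for (w in seq_len(nrow(windows))) {
    sel <- snps$chrom == windows$chrom[w] &
      snps$pos >= windows$start[w] & snps$pos <= windows$end[w]
    windows$n_snps[w] <- sum(sel)
    if (any(sel)) windows$mean_maf[w] <- mean(maf[sel], na.rm = TRUE)
  }
  windows$masked <- windows$n_snps == 0L
  windows
}
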