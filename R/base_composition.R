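# Per-accession base composition across polymorphic sites: the [AT] genome
# phenotype, its substitution-type decomposition, window tracks and group
# separation tests.

SUBSTITUTION_TYPES <- c("A/C", "A/G", "A/T", "C/G", "C/T", "G/T")

#' Classify the substitution type of bi-allelic SNPs
#'
#' The unordered allele pair: (C,T) and (T,C) are both "C/T". Six types
#' exist; no ancestral polarity is implied.
#'
#' @param ref,alt character vectors of single-base alleles.
#' @return character vector of type labels.
#' @export
#' @examples
#' classify_substitution(c("C", "T", "G"), c("T", "C", "T"))
classify_substitution <- function(ref, alt) {
  stopifnot(length(ref) == length(alt),
            all(ref %in% DNA_BASES), all(alt %in% DNA_BASES),
            all(ref != alt))
  paste(pmin(ref, alt), pmax(ref, alt), sep = "/")
}

#' Filter a common SNP panel on MAF and missing rate
#'
#' Keeps sites with minor allele frequency >= \code{maf_min} (computed over
#' non-missing calls) and missing-call fraction <= \code{missing_max};
#' monomorphic sites are dropped.
#'
#' @param snps SNP table.
#' @param geno accession x site genotype matrix (0/1/NA).
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @param missing_max maximum missing fraction (default 0.20).
#' @return list with filtered \code{snps}, \code{geno} and logical
#'   \code{kept} over the input sites.
#' @export
filter_common <- function(snps, geno, maf_min = 0.05, missing_max = 0.20) {
  stopifnot(ncol(geno) == nrow(snps))
  n_nonmiss <- colSums(!is.na(geno))
  n_alt <- colSums(geno, na.rm = TRUE)
  miss_frac <- 1 - n_nonmiss / nrow(geno)
  p_alt <- ifelse(n_nonmiss > 0, n_alt / n_nonmiss, NA)
  maf <- pmin(p_alt, 1 - p_alt)
  kept <- !is.na(maf) & maf >= maf_min & maf > 0 & miss_frac <= missing_max
  if (!any(kept)) warning("all sites removed by the MAF/missing filter")
  list(snps = {
         s <- snps[kept, , drop = FALSE]; rownames(s) <- NULL; s
       },
       geno = geno[, kept, drop = FALSE],
       kept = kept)
}

#' @noRd
base_counts_per_accession <- function(geno, snps) {
  is_ref <- !is.na(geno) & geno == 0L
  is_alt <- !is.na(geno) & geno == 1L
  counts <- sapply(DNA_BASES, function(b) {
    rowSums(is_ref[, snps$ref == b, drop = FALSE]) +
      rowSums(is_alt[, snps$alt == b, drop = FALSE])
  })
  if (nrow(geno) == 1) counts <- matrix(counts, nrow = 1,
                                        dimnames = list(rownames(geno),
                                                        DNA_BASES))
  counts
}

#' Per-accession base composition across polymorphic sites
#'
#' For each accession the allele carried at every non-missing site is
#' resolved to its base; the fractions of A, C, G and T among those bases are
#' returned together with \code{at = [A] + [T]}, the genome phenotype. The
#' denominator is the accession's own non-missing site count. Accessions with
#' zero non-missing sites get NA fractions and are flagged.
#'
#' @param geno accession x site genotype matrix (0 = REF, 1 = ALT, NA).
#' @param snps SNP table aligned to the matrix columns.
#' @return data.frame with accession, A, C, G, T, at, n_sites, defined.
#' @export
compute_at <- function(geno, snps) {
  stopifnot(ncol(geno) == nrow(snps))
  counts <- base_counts_per_accession(geno, snps)
  n <- rowSums(counts)
  frac <- counts / ifelse(n > 0, n, NA)
  data.frame(accession = rownames(geno) %||% as.character(seq_len(nrow(geno))),
             A = frac[, "A"], C = frac[, "C"],
             G = frac[, "G"], T = frac[, "T"],
             at = frac[, "A"] + frac[, "T"],
             n_sites = n, defined = n > 0,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Base composition conditional on substitution type
#'
#' Splits the sites into the six substitution types and computes, per
#' accession and type, the non-missing site count, the type's share of the
#' accession's non-missing sites, the conditional base fractions (which sum
#' to 1 within a type) and the conditional [AT]. Types with zero sites for an
#' accession are flagged undefined.
#'
#' @inheritParams compute_at
#' @return long data.frame (accession x type rows).
#' @export
composition_by_type <- function(geno, snps) {
  stopifnot(ncol(geno) == nrow(snps))
  type <- classify_substitution(snps$ref, snps$alt)
  total <- rowSums(!is.na(geno))
  res <- lapply(SUBSTITUTION_TYPES, function(tp) {
    sel <- type == tp
    bc <- compute_at(geno[, sel, drop = FALSE],
                     snps[sel, , drop = FALSE])
    bc$type <- tp
    bc$share <- bc$n_sites / ifelse(total > 0, total, NA)
    bc
  })
  out <- do.call(rbind, res)
  out[order(out$accession, out$type),
      c("accession", "type", "n_sites", "share",
        "A", "C", "G", "T", "at", "defined")]
}

#' Genome windows for a moving-average track
#'
#' Window k (k = 0, 1, ...) covers 1-based positions
#' \code{[1 + k*step, k*step + window]}, truncated at the chromosome end;
#' windows are emitted while their start lies inside the chromosome.
#'
#' @param lens named vector of chromosome lengths.
#' @param window window size in bp.
#' @param step step size in bp.
#' @return data.frame with chrom, start, end (1-based inclusive).
#' @export
make_windows <- function(lens, window, step) {
  if (window <= 0 || step <= 0) stop("window and step must be positive")
  out <- lapply(names(lens), function(cn) {
    starts <- as.integer(seq(1L, lens[[cn]], by = as.integer(step)))
    data.frame(chrom = cn, start = starts,
               end = as.integer(pmin(starts + window - 1, lens[[cn]])),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Sliding-window [AT] track
#'
#' Computes per-accession [AT] within moving windows (default the 5-Mb
#' window / 4-Mb step moving average; with step < window each SNP contributes
#' to every covering window). Windows with fewer than \code{min_snps} SNPs
#' are emitted but masked.
#'
#' @inheritParams compute_at
#' @param lens named chromosome lengths.
#' @param window,step window and step sizes in bp.
#' @param min_snps minimum SNP count for an unmasked window (default 100).
#' @return list with \code{windows} (chrom, start, end, n_snps, masked) and
#'   \code{at}, a windows x accessions matrix of [AT] values (NA when an
#'   accession has no non-missing call in the window).
#' @export
windowed_at <- function(geno, snps, lens, window = 5e6, step = 4e6,
                        min_snps = 100) {
  validate_snp_table(snps)
  win <- make_windows(lens, window, step)
  at <- matrix(NA_real_, nrow(win), nrow(geno),
               dimnames = list(NULL, rownames(geno)))
  n_snps <- integer(nrow(win))
  for (w in seq_len(nrow(win))) {
    sel <- snps$chrom == win$chrom[w] &
      snps$pos >= win$start[w] & snps$pos <= win$end[w]
    n_snps[w] <- sum(sel)
    if (n_snps[w] > 0) {
      at[w, ] <- compute_at(geno[, sel, drop = FALSE],
                            snps[sel, , drop = FALSE])$at
    }
  }
  win$n_snps <- n_snps
  win$masked <- n_snps < min_snps
  list(windows = win, at = at)
}

#' Per-window group-mean [AT] and [AT]-difference
#'
#' @param wat result of [windowed_at()].
#' @param groups per-accession factor (wild/landrace/improved) aligned to the
#'   columns of \code{wat$at}.
#' @return data.frame of windows with wild and domesticated mean [AT] and
#'   their difference (domesticated - wild); masked windows carry NA.
#' @export
windowed_at_difference <- function(wat, groups) {
  wild <- groups == "wild"
  dom <- groups %in% c("landrace", "improved")
  df <- wat$windows
  df$at_wild <- rowMeans(wat$at[, wild, drop = FALSE], na.rm = TRUE)
  df$at_dom <- rowMeans(wat$at[, dom, drop = FALSE], na.rm = TRUE)
  df$at_diff <- df$at_dom - df$at_wild
  df$at_wild[df$masked] <- NA
  df$at_dom[df$masked] <- NA
  df$at_diff[df$masked] <- NA
  df
}

#' Test the wild vs domesticated separation in [AT]
#'
#' Difference of group means (domesticated - wild, domesticated pooling
#' landraces and improved cultivars) with a two-sided two-sample location
#' test: Welch's unequal-variance t by default, or a Wilcoxon rank-sum test.
#'
#' @param at_values numeric per-accession [AT] values.
#' @param groups per-accession factor with levels wild/landrace/improved.
#' @param test "welch" or "wilcoxon".
#' @return list with \code{difference}, \code{statistic}, \code{p.value},
#'   and the two group means.
#' @export
group_separation <- function(at_values, groups, test = c("welch", "wilcoxon")) {
  test <- match.arg(test)
  wild <- at_values[groups == "wild"]
  dom <- at_values[groups %in% c("landrace", "improved")]
  if (length(wild) < 2 || length(dom) < 2) {
    stop("each compared group needs at least 2 accessions")
  }
  diff <- mean(dom) - mean(wild)
  if (length(unique(c(wild, dom))) == 1) {
    # identical constant values in both groups: no separation by definition
    return(list(difference = 0, statistic = 0, p.value = 1,
                mean_wild = mean(wild), mean_domesticated = mean(dom)))
  }
  ht <- if (test == "welch") {
    t.test(dom, wild, var.equal = FALSE)
  } else {
    wilcox.test(dom, wild, exact = FALSE)
  }
  list(difference = diff, statistic = unname(ht$statistic),
       p.value = ht$p.value,
       mean_wild = mean(wild), mean_domesticated = mean(dom))
}
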