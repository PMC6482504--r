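# Polarized mutation spectra of population-private SNP sets. Mutations are
# typed as B5' BA B3' -> B5' BD B3' and strand-collapsed so the ancestral
# base is a pyrimidine: 6 pyrimidine-ancestral substitutions x 16 contexts =
# 96 classes, written e.g. "TCG>TTG".

#' All 96 strand-collapsed mutation class labels
#'
#' @return character vector of 96 labels "LAR>LDR" with A in {C, T}.
#' @export
mutation_classes96 <- function() {
  subs <- list(c("C", "A"), c("C", "G"), c("C", "T"),
               c("T", "A"), c("T", "C"), c("T", "G"))
  out <- character(0)
  for (s in subs) {
    for (l in DNA_BASES) {
      for (r in DNA_BASES) {
        out <- c(out, paste0(l, s[1], r, ">", l, s[2], r))
      }
    }
  }
  out
}

#' Polarize SNPs with outgroup alleles
#'
#' The ancestral allele is the outgroup allele when it matches ref or alt;
#' SNPs with a missing or mismatching outgroup allele are excluded with a
#' logged reason.
#'
#' @param snps SNP table.
#' @param outgroup character vector of outgroup alleles aligned to
#'   \code{snps} rows (NA = missing), or a data.frame with chrom, pos,
#'   allele matched by position.
#' @return SNP table restricted to polarizable sites with added columns
#'   \code{ancestral} and \code{derived}; attribute \code{exclusions} gives
#'   counts by reason.
#' @export
polarize <- function(snps, outgroup) {
  validate_snp_table(snps)
  if (is.data.frame(outgroup)) {
    key <- paste(snps$chrom, snps$pos)
    outgroup <- outgroup$allele[match(key, paste(outgroup$chrom,
                                                 outgroup$pos))]
  }
  stopifnot(length(outgroup) == nrow(snps))
  missing <- is.na(outgroup)
  match_ref <- !missing & outgroup == snps$ref
  match_alt <- !missing & outgroup == snps$alt
  keep <- match_ref | match_alt
  excl <- c(missing_outgroup = sum(missing),
            outgroup_matches_neither = sum(!missing & !keep))
  if (sum(excl)) {
    message("polarize: excluded ", sum(excl), " SNP(s) (",
            excl[1], " missing outgroup, ", excl[2], " mismatching)")
  }
  out <- snps[keep, , drop = FALSE]
  out$ancestral <- ifelse(match_ref[keep], snps$ref[keep], snps$alt[keep])
  out$derived <- ifelse(match_ref[keep], snps$alt[keep], snps$ref[keep])
  rownames(out) <- NULL
  attr(out, "exclusions") <- excl
  out
}

#' Call population-private SNP sets
#'
#' A SNP is private to a group when it is segregating there (both alleles
#' observed among the group's non-missing calls) while every other group is
#' fixed for the ancestral allele (all non-missing calls ancestral AND group
#' call rate >= \code{min_call_rate}). Four sets are called, each directly
#' from its printed definition:
#' \describe{
#'   \item{PW}{segregating in wild; landrace and improved ancestral-fixed.}
#'   \item{PD}{segregating in the landrace or the improved group; wild
#'     ancestral-fixed. Computed independently of PL/PI, so a SNP segregating
#'     in both domesticated groups is PD but neither PL nor PI, while PL/PI
#'     members may also satisfy PD.}
#'   \item{PL}{segregating in landrace; wild and improved ancestral-fixed.}
#'   \item{PI}{segregating in improved; wild and landrace ancestral-fixed.}
#' }
#' Sites where any group is entirely missing are unassignable and excluded.
#'
#' @param geno accession x site genotype matrix (0/1/NA).
#' @param groups per-accession factor (wild/landrace/improved).
#' @param snps polarized SNP table (from [polarize()]) aligned to matrix
#'   columns.
#' @param min_call_rate per-group call-rate floor for the fixation check
#'   (default 0.8).
#' @return list with index vectors PW, PD, PL, PI over \code{snps} rows, plus
#'   \code{unassignable} and an \code{overlap} summary of the PD/PL/PI
#'   structure.
#' @export
call_private <- function(geno, groups, snps, min_call_rate = 0.8) {
  stopifnot(ncol(geno) == nrow(snps),
            all(c("ancestral", "derived") %in% names(snps)))
  anc_is_ref <- snps$ancestral == snps$ref
  stat <- function(g) {
    sub <- geno[groups == g, , drop = FALSE]
    n <- nrow(sub)
    nonmiss <- colSums(!is.na(sub))
    n_alt <- colSums(sub, na.rm = TRUE)
    n_ref <- nonmiss - n_alt
    n_anc <- ifelse(anc_is_ref, n_ref, n_alt)
    n_der <- nonmiss - n_anc
    list(seg = n_anc > 0 & n_der > 0,
         fixed_anc = n_der == 0 & nonmiss >= min_call_rate * n,
         empty = nonmiss == 0)
  }
  W <- stat("wild"); L <- stat("landrace"); I <- stat("improved")
  unassignable <- W$empty | L$empty | I$empty
  PW <- which(!unassignable & W$seg & L$fixed_anc & I$fixed_anc)
  PD <- which(!unassignable & (L$seg | I$seg) & W$fixed_anc)
  PL <- which(!unassignable & L$seg & W$fixed_anc & I$fixed_anc)
  PI <- which(!unassignable & I$seg & W$fixed_anc & L$fixed_anc)
  list(PW = PW, PD = PD, PL = PL, PI = PI,
       unassignable = which(unassignable),
       overlap = c(PL_in_PD = length(intersect(PL, PD)),
                   PI_in_PD = length(intersect(PI, PD)),
                   PD_only = length(setdiff(PD, union(PL, PI)))))
}

#' Type polarized mutations into the 96 strand-collapsed classes
#'
#' The flanking bases are read from the reference strand; when the ancestral
#' base is a purine (A or G) the context and both alleles are
#' reverse-complemented before classing, so typing a mutation and its
#' explicit reverse complement yields the same class. SNPs whose context is
#' excluded (chromosome end, N in a flank) return NA.
#'
#' @param snps polarized SNP table (columns ancestral, derived).
#' @param genome named character vector of chromosome sequences.
#' @return character vector of class labels (NA = excluded).
#' @export
mutation_type <- function(snps, genome) {
  stopifnot(all(c("ancestral", "derived") %in% names(snps)))
  ctx <- genome_context(genome, snps$chrom, snps$pos)
  l <- substring(ctx, 1, 1)
  r <- substring(ctx, 3, 3)
  anc <- snps$ancestral
  der <- snps$derived
  flip <- !is.na(ctx) & anc %in% c("A", "G")
  l2 <- ifelse(flip, complement_base(r), l)
  r2 <- ifelse(flip, complement_base(l), r)
  anc2 <- ifelse(flip, complement_base(anc), anc)
  der2 <- ifelse(flip, complement_base(der), der)
  out <- paste0(l2, anc2, r2, ">", l2, der2, r2)
  out[is.na(ctx)] <- NA
  out
}

#' 96-type mutation spectrum of a polarized SNP set
#'
#' @inheritParams mutation_type
#' @return list with \code{counts} and \code{freq} (named 96-vectors),
#'   \code{total} typed SNPs and \code{excluded} count (input = typed +
#'   excluded).
#' @export
mutation_spectrum96 <- function(snps, genome) {
  cls <- mutation_type(snps, genome)
  ok <- !is.na(cls)
  if (!any(ok)) stop("no typeable SNPs in the set")
  counts <- table(factor(cls[ok], levels = mutation_classes96()))
  counts <- setNames(as.integer(counts), mutation_classes96())
  list(counts = counts, freq = counts / sum(counts),
       total = sum(counts), excluded = sum(!ok))
}

#' Compare two mutation spectra
#'
#' Per mutation type m, the Pearson chi-square value (no continuity
#' correction) on the 2x2 table of type-m vs other counts in the two sets,
#' and the fold frequency difference (f1(m) - f2(m)) / f2(m), undefined
#' (NA, flagged) when f2(m) = 0.
#'
#' @param s1,s2 spectra from [mutation_spectrum96()].
#' @return data.frame with class, count1, count2, freq1, freq2,
#'   fold_difference, chisq, fold_defined.
#' @export
compare_spectra <- function(s1, s2) {
  stopifnot(s1$total > 0, s2$total > 0)
  a <- as.numeric(s1$counts); n1 <- s1$total
  b <- as.numeric(s2$counts); n2 <- s2$total
  # Pearson chi-square on [[a, n1-a], [b, n2-b]], vectorized over classes
  nn <- n1 + n2
  det <- a * (n2 - b) - (n1 - a) * b
  denom <- n1 * n2 * (a + b) * (nn - a - b)
  chisq <- ifelse(denom > 0, nn * det^2 / denom, 0)
  f1 <- a / n1; f2 <- b / n2
  data.frame(class = names(s1$counts), count1 = a, count2 = b,
             freq1 = f1, freq2 = f2,
             fold_difference = ifelse(f2 > 0, (f1 - f2) / f2, NA),
             chisq = chisq, fold_defined = f2 > 0,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-bin UV-signature mutation frequencies
#'
#' Partitions a position-sorted polarized SNP set into non-overlapping bins
#' of \code{bin_size} consecutive SNPs and computes f(TCG->T) and f(CCG->T)
#' (classes TCG>TTG and CCG>CTG) per bin. The final partial bin is retained
#' with its own denominator and flagged.
#'
#' @inheritParams mutation_type
#' @param bin_size SNPs per bin (default 1000).
#' @return data.frame with bin, n_snps, f_TCG, f_CCG, partial.
#' @export
bin_uv_frequencies <- function(snps, genome, bin_size = 1000) {
  if (nrow(snps) == 0) {
    return(data.frame(bin = integer(), n_snps = integer(),
                      f_TCG = numeric(), f_CCG = numeric(),
                      partial = logical()))
  }
  snps <- sort_snps(snps)
  cls <- mutation_type(snps, genome)
  bin <- (seq_len(nrow(snps)) - 1L) %/% bin_size + 1L
  n <- tapply(cls, bin, length)
  f_tcg <- tapply(cls, bin, function(x) mean(x == "TCG>TTG", na.rm = TRUE))
  f_ccg <- tapply(cls, bin, function(x) mean(x == "CCG>CTG", na.rm = TRUE))
  data.frame(bin = as.integer(names(n)), n_snps = as.integer(n),
             f_TCG = as.numeric(f_tcg), f_CCG = as.numeric(f_ccg),
             partial = as.integer(n) < bin_size,
             row.names = NULL, stringsAsFactors = FALSE)
}
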