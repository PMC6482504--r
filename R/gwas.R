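# Downstream of a genome scan for the [AT] genome phenotype: Bonferroni
# thresholding, tagging genes near significant SNPs, and the UV-related-gene
# proportion enrichment test. (The mixed-model GWAS itself is an input; a
# naive single-marker scan is provided so the pipeline runs end-to-end on
# synthetic data.)

#' Bonferroni significance threshold
#'
#' @param n_tests number of tests (> 0).
#' @param alpha family-wise error rate (default 0.05).
#' @return per-test p-value threshold alpha / n_tests.
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  if (length(n_tests) != 1 || is.na(n_tests) || n_tests < 1) {
    stop("n_tests must be a positive count")
  }
  alpha / n_tests
}

#' Naive single-marker association scan
#'
#' Per-site linear association between allele dosage (0/1) and the
#' per-accession phenotype, computed as the correlation t-test over
#' non-missing calls. Monomorphic sites (or sites with fewer than 3
#' non-missing calls) get p = 1. This is deliberately a plain scan without
#' kinship or principal components.
#'
#' @param geno accession x site genotype matrix (0/1/NA).
#' @param phenotype numeric per-accession values (e.g. [AT]).
#' @param snps optional SNP table supplying chrom/pos for the output.
#' @return association table: data.frame with chrom, pos (if supplied) and
#'   p.value per site.
#' @export
naive_scan <- function(geno, phenotype, snps = NULL) {
  stopifnot(nrow(geno) == length(phenotype))
  M <- !is.na(geno)
  X <- geno; X[!M] <- 0
  y <- phenotype
  n <- colSums(M)
  sx <- colSums(X)
  sxx <- sx  # dosage is 0/1 so x^2 = x
  sy <- colSums(M * y)
  syy <- colSums(M * y^2)
  sxy <- colSums(X * y)
  cov_xy <- sxy - sx * sy / n
  var_x <- sxx - sx^2 / n
  var_y <- syy - sy^2 / n
  r2 <- ifelse(var_x > 0 & var_y > 0, cov_xy^2 / (var_x * var_y), NA)
  r2 <- pmin(r2, 1)
  df <- n - 2
  tstat <- sqrt(ifelse(df > 0 & !is.na(r2) & r2 < 1,
                       r2 * df / (1 - r2), NA))
  p <- 2 * pt(-abs(tstat), df)
  p[!is.na(r2) & r2 >= 1 & df > 0] <- .Machine$double.xmin
  p[is.na(p)] <- 1  # monomorphic / degenerate sites
  out <- data.frame(p.value = p)
  if (!is.null(snps)) out <- cbind(snps[, c("chrom", "pos")], out)
  rownames(out) <- NULL
  out
}

#' Tag genes near significantly associated SNPs
#'
#' Each significant SNP (p below \code{threshold}) defines a window of total
#' width \code{window_size} centred on it; a gene is tagged by that SNP when
#' the gene body overlaps the window. A gene enters the tagged set only when
#' tagged by at least \code{min_snps} (default 2) distinct significant SNPs.
#'
#' @param assoc association table with chrom, pos, p.value.
#' @param threshold significance threshold (e.g. from
#'   [bonferroni_threshold()]).
#' @param genes data.frame with id, chrom, start, end (1-based gene bodies;
#'   \code{gene_models$genes} works directly).
#' @param window_size total window width in bp.
#' @param min_snps minimum tagging SNPs for a counted gene (default 2).
#' @return list with \code{counts} (data.frame id, n_tagging) and
#'   \code{tagged} (character vector of counted gene ids).
#' @export
tag_genes <- function(assoc, threshold, genes, window_size, min_snps = 2) {
  if (window_size <= 0) stop("window_size must be positive")
  sig <- assoc[assoc$p.value < threshold, , drop = FALSE]
  n_tagging <- setNames(integer(nrow(genes)), genes$id)
  if (nrow(sig) > 0 && nrow(genes) > 0) {
    half <- window_size / 2
    win_gr <- GenomicRanges::GRanges(
      sig$chrom, IRanges::IRanges(start = pmax(1, floor(sig$pos - half)),
                                  end = ceiling(sig$pos + half)))
    gene_gr <- GenomicRanges::GRanges(
      genes$chrom, IRanges::IRanges(genes$start, genes$end))
    hits <- GenomicRanges::countOverlaps(gene_gr, win_gr)
    n_tagging[] <- hits
  }
  data.frame(id = genes$id, n_tagging = unname(n_tagging),
             stringsAsFactors = FALSE) -> counts
  list(counts = counts, tagged = counts$id[counts$n_tagging >= min_snps])
}

#' One-sided two-proportion enrichment test
#'
#' Tests whether the proportion of UV-related genes tagged
#' (\code{n_uv_tagged / n_uv_total}) exceeds the genome-wide tagged
#' proportion (\code{n_all_tagged / n_all_total}) with a pooled-variance
#' one-sided z test (no continuity correction). The result is marked invalid
#' (no p-value) when fewer than \code{min_valid} UV genes are tagged, the
#' condition under which the proportion test is not applied.
#'
#' @param n_uv_tagged,n_uv_total tagged and total UV-related gene counts.
#' @param n_all_tagged,n_all_total tagged and total annotated gene counts.
#' @param min_valid validity floor on tagged UV genes (default 10).
#' @return data.frame (one row) with the counts, both proportions, the z
#'   statistic, the one-sided p-value and a validity flag.
#' @export
proportion_test <- function(n_uv_tagged, n_uv_total,
                            n_all_tagged, n_all_total, min_valid = 10) {
  if (n_uv_total <= 0 || n_all_total <= 0) stop("totals must be positive")
  if (n_uv_tagged > n_uv_total || n_all_tagged > n_all_total) {
    stop("tagged counts cannot exceed totals")
  }
  p1 <- n_uv_tagged / n_uv_total
  p2 <- n_all_tagged / n_all_total
  pooled <- (n_uv_tagged + n_all_tagged) / (n_uv_total + n_all_total)
  se <- sqrt(pooled * (1 - pooled) * (1 / n_uv_total + 1 / n_all_total))
  z <- if (se > 0) (p1 - p2) / se else 0
  valid <- n_uv_tagged >= min_valid
  data.frame(n_uv_tagged = n_uv_tagged, n_uv_total = n_uv_total,
             n_all_tagged = n_all_tagged, n_all_total = n_all_total,
             prop_uv = p1, prop_all = p2, statistic = z,
             p.value = if (valid) pnorm(z, lower.tail = FALSE) else NA_real_,
             valid = valid, stringsAsFactors = FALSE)
}

#' UV-gene enrichment across a series of window sizes
#'
#' Applies [bonferroni_threshold()], [tag_genes()] and [proportion_test()]
#' for each window size, comparing the tagged proportion among UV-related
#' genes with that among all annotated genes.
#'
#' @inheritParams tag_genes
#' @param uv_gene_ids character vector of UV-related gene ids (subset of
#'   \code{genes$id}).
#' @param window_sizes bp widths to scan (default 200 kb, 500 kb, 1 Mb,
#'   2 Mb).
#' @param alpha family-wise error rate for the Bonferroni threshold.
#' @return data.frame with one row per window size.
#' @export
uv_enrichment_scan <- function(assoc, genes, uv_gene_ids,
                               window_sizes = c(2e5, 5e5, 1e6, 2e6),
                               alpha = 0.05) {
  stopifnot(all(uv_gene_ids %in% genes$id))
  thr <- bonferroni_threshold(nrow(assoc), alpha)
  rows <- lapply(window_sizes, function(w) {
    tg <- tag_genes(assoc, thr, genes, w)
    res <- proportion_test(sum(tg$tagged %in% uv_gene_ids),
                           length(uv_gene_ids),
                           length(tg$tagged), nrow(genes))
    cbind(data.frame(window_size = w, threshold = thr), res)
  })
  do.call(rbind, rows)
}
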