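# Gene models and the seven-class SNP annotation:
# intergenic, gene_proximal, utr, synonymous, missense, intronic, other_genic.

ANNOTATION_CLASSES <- c("intergenic", "gene_proximal", "utr", "synonymous",
                        "missense", "intronic", "other_genic")
GENIC_CLASSES <- c("utr", "synonymous", "missense", "intronic", "other_genic")

#' Build gene models from a normalized feature table
#'
#' The feature table has one row per GFF3 feature with columns \code{type}
#' (gene/mRNA/exon/CDS/five_prime_UTR/three_prime_UTR), \code{chrom},
#' \code{start}, \code{end} (1-based inclusive), \code{strand}, \code{phase},
#' \code{id} and \code{parent}. One canonical transcript is chosen per gene:
#' the mRNA with the longest total CDS, ties broken by the lexicographically
#' smallest mRNA id. A gene whose phase-adjusted CDS length is not divisible
#' by 3 is flagged non-coding and classified by exon/intron structure only.
#'
#' @param feats normalized feature data.frame.
#' @return object of class \code{gene_models}: a list with a \code{genes}
#'   summary data.frame and per-gene interval lists.
#' @export
build_gene_models <- function(feats) {
  stopifnot(all(c("type", "chrom", "start", "end", "strand", "phase",
                  "id", "parent") %in% names(feats)))
  genes <- feats[feats$type == "gene", , drop = FALSE]
  mrnas <- feats[feats$type == "mRNA", , drop = FALSE]
  parts <- feats[feats$type %in% c("exon", "CDS", "five_prime_UTR",
                                   "three_prime_UTR"), , drop = FALSE]

  cds_len_by_mrna <- tapply(
    (parts$end - parts$start + 1L)[parts$type == "CDS"],
    parts$parent[parts$type == "CDS"], sum)

  out <- list(genes = NULL, exons = list(), cds = list(),
              utr = list(), cds_pos = list())
  rows <- vector("list", nrow(genes))
  for (k in seq_len(nrow(genes))) {
    g <- genes[k, ]
    tx <- mrnas[mrnas$parent == g$id, , drop = FALSE]
    if (nrow(tx) == 0) {  # gene without mRNA children: treat gene body as span
      tx <- g
      tx$parent <- g$id
    }
    lens <- cds_len_by_mrna[tx$id]
    lens[is.na(lens)] <- 0L
    best <- which(lens == max(lens))
    canonical <- tx$id[best][order(tx$id[best])][1]
    ctx <- tx[tx$id == canonical, ]

    p <- parts[parts$parent == canonical, , drop = FALSE]
    ex <- p[p$type == "exon", c("start", "end")]
    ex <- ex[order(ex$start), , drop = FALSE]
    cds <- p[p$type == "CDS", c("start", "end", "phase")]
    cds <- cds[order(cds$start), , drop = FALSE]
    utr <- p[p$type %in% c("five_prime_UTR", "three_prime_UTR"),
             c("start", "end")]

    strand <- g$strand
    tss <- if (strand == "+") ctx$start else ctx$end
    coding <- nrow(cds) > 0
    cds_pos <- integer(0)
    if (coding) {
      # genome positions of the spliced CDS in transcription order
      pos_blocks <- lapply(seq_len(nrow(cds)),
                           function(i) cds$start[i]:cds$end[i])
      if (strand == "+") {
        cds_pos <- unlist(pos_blocks)
        phase0 <- cds$phase[1]
      } else {
        cds_pos <- rev(unlist(pos_blocks))
        phase0 <- cds$phase[nrow(cds)]
      }
      if (is.na(phase0)) phase0 <- 0L
      if (phase0 > 0) cds_pos <- cds_pos[-seq_len(phase0)]
      if (length(cds_pos) %% 3 != 0) coding <- FALSE  # flagged non-coding
    }

    rows[[k]] <- data.frame(id = g$id, chrom = g$chrom, strand = strand,
                            start = ctx$start, end = ctx$end, tss = tss,
                            coding = coding, cds_len = length(cds_pos),
                            stringsAsFactors = FALSE)
    out$exons[[g$id]] <- as.matrix(ex)
    out$cds[[g$id]] <- cds
    out$utr[[g$id]] <- as.matrix(utr)
    out$cds_pos[[g$id]] <- if (coding) cds_pos else integer(0)
  }
  out$genes <- do.call(rbind, rows)
  if (is.null(out$genes)) {
    out$genes <- data.frame(id = character(), chrom = character(),
                            strand = character(), start = integer(),
                            end = integer(), tss = integer(),
                            coding = logical(), cds_len = integer())
  }
  rownames(out$genes) <- NULL
  class(out) <- "gene_models"
  out
}

#' Read gene models from GFF3
#'
#' Parses gene/mRNA/exon/CDS/UTR features (1-based inclusive coordinates) and
#' chooses one canonical transcript per gene (see [build_gene_models()]).
#'
#' @param path GFF3 file path.
#' @return \code{gene_models} object.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF3")
  md <- S4Vectors::mcols(gr)
  parent <- md$Parent
  parent <- vapply(as.list(parent),
                   function(p) if (length(p)) p[[1]] else NA_character_,
                   character(1))
  feats <- data.frame(
    type = as.character(md$type),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    phase = if ("phase" %in% names(md)) as.integer(md$phase) else NA_integer_,
    id = if ("ID" %in% names(md)) as.character(md$ID) else NA_character_,
    parent = parent,
    stringsAsFactors = FALSE)
  build_gene_models(feats)
}

#' Write a normalized feature table to GFF3
#'
#' @param feats normalized feature data.frame (see [build_gene_models()]).
#' @param path output path.
#' @export
write_gene_models_gff3 <- function(feats, path) {
  attrs <- ifelse(is.na(feats$parent),
                  paste0("ID=", feats$id),
                  ifelse(is.na(feats$id),
                         paste0("Parent=", feats$parent),
                         paste0("ID=", feats$id, ";Parent=", feats$parent)))
  lines <- paste(feats$chrom, "atgenome", feats$type, feats$start, feats$end,
                 ".", feats$strand,
                 ifelse(is.na(feats$phase), ".", feats$phase),
                 attrs, sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' @noRd
translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

#' @noRd
classify_against_gene <- function(pos, alt, gm, gene_id, genome) {
  genes <- gm$genes
  g <- genes[genes$id == gene_id, ]
  strand <- g$strand
  ex <- gm$exons[[gene_id]]
  utr <- gm$utr[[gene_id]]
  cds <- gm$cds[[gene_id]]
  cds_pos <- gm$cds_pos[[gene_id]]

  in_intervals <- function(m) {
    nrow(m) > 0 && any(pos >= m[, 1] & pos <= m[, 2])
  }

  if (g$coding && length(cds_pos)) {
    idx <- match(pos, cds_pos)
    in_cds_block <- nrow(cds) > 0 &&
      any(pos >= cds$start & pos <= cds$end)
    if (!is.na(idx)) {
      i0 <- idx - 1L
      ci <- i0 %/% 3L
      cp <- cds_pos[(3L * ci + 1L):(3L * ci + 3L)]
      if (anyNA(cp)) return("other_genic")  # incomplete terminal codon
      bases <- genome_base(genome, rep(g$chrom, 3), cp)
      alt_b <- alt
      if (strand == "-") {
        bases <- complement_base(bases)
        alt_b <- complement_base(alt)
      }
      ref_codon <- paste(bases, collapse = "")
      off <- i0 %% 3L + 1L
      bases[off] <- alt_b
      alt_codon <- paste(bases, collapse = "")
      aa_ref <- translate_codon(ref_codon)
      aa_alt <- translate_codon(alt_codon)
      if (ci == 0L && ref_codon == "ATG" && alt_codon != "ATG") {
        return("other_genic")  # start loss
      }
      if (aa_ref == "*" || aa_alt == "*") {
        if (aa_ref == aa_alt) return("synonymous")
        return("other_genic")  # stop gain/loss
      }
      if (aa_ref == aa_alt) return("synonymous")
      return("missense")
    }
    if (in_cds_block) return("other_genic")  # phase-trimmed coding edge
  }
  if (in_intervals(utr)) return("utr")
  # introns: gaps between consecutive exons; first/last 2 bp are splice sites
  if (nrow(ex) > 1) {
    for (i in seq_len(nrow(ex) - 1)) {
      istart <- ex[i, 2] + 1L
      iend <- ex[i + 1, 1] - 1L
      if (iend >= istart && pos >= istart && pos <= iend) {
        if (pos <= istart + 1L || pos >= iend - 1L) return("other_genic")
        return("intronic")
      }
    }
  }
  # inside transcript span but none of the above (e.g. exon of a gene flagged
  # non-coding, or exon sequence outside CDS/UTR)
  "other_genic"
}

#' Classify SNPs into the seven genomic annotation classes
#'
#' Precedence inside a transcript span: CDS effect (synonymous / missense /
#' other_genic for stop gain, stop loss, start loss) over UTR over splice
#' site (first/last 2 bp of an intron, absorbed into other_genic) over plain
#' intronic. Outside all transcript spans a SNP is gene_proximal when it lies
#' within \code{proximal_dist} bp upstream (5', strand-aware) of any
#' transcription start site, else intergenic. A SNP covered by several genes
#' takes the highest-severity label (missense > other_genic > synonymous >
#' utr > intronic), so genic always outranks gene-proximal.
#'
#' @param snps SNP table (ref alleles must match the genome).
#' @param models \code{gene_models} object.
#' @param genome named character vector of chromosome sequences.
#' @param proximal_dist upstream distance defining gene-proximal (default
#'   5000 bp).
#' @return factor of annotation classes aligned to \code{snps} rows.
#' @export
classify_sites <- function(snps, models, genome, proximal_dist = 5000) {
  validate_snp_table(snps)
  genome_base(genome, snps$chrom, snps$pos)  # errors on undeclared chromosome
  n <- nrow(snps)
  out <- rep("intergenic", n)
  genes <- models$genes
  if (nrow(genes)) {
    severity <- c(missense = 1, other_genic = 2, synonymous = 3,
                  utr = 4, intronic = 5)
    snp_gr <- GenomicRanges::GRanges(snps$chrom,
                                     IRanges::IRanges(snps$pos, snps$pos))
    tx_gr <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(genes$start, genes$end))
    hits <- GenomicRanges::findOverlaps(snp_gr, tx_gr)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    for (i in unique(qh)) {
      gids <- genes$id[sh[qh == i]]
      labels <- vapply(gids, function(gid) {
        classify_against_gene(snps$pos[i], snps$alt[i], models, gid, genome)
      }, character(1))
      out[i] <- labels[which.min(severity[labels])]
    }
    # gene-proximal: within proximal_dist upstream of any TSS, strand-aware
    up_start <- ifelse(genes$strand == "+",
                       pmax(1, genes$tss - proximal_dist), genes$tss + 1)
    up_end <- ifelse(genes$strand == "+",
                     genes$tss - 1, genes$tss + proximal_dist)
    ok <- up_end >= up_start
    if (any(ok)) {
      up_gr <- GenomicRanges::GRanges(genes$chrom[ok],
                                      IRanges::IRanges(up_start[ok],
                                                       up_end[ok]))
      prox <- GenomicRanges::countOverlaps(snp_gr, up_gr) > 0
      out[prox & out == "intergenic"] <- "gene_proximal"
    }
  }
  factor(out, levels = ANNOTATION_CLASSES)
}

#' Partition classified SNPs into genic and non-genic sets
#'
#' Non-genic is intergenic plus gene-proximal; genic is the other five
#' classes. The partition is complete and disjoint.
#'
#' @param classes factor from [classify_sites()].
#' @return list with logical vectors \code{genic} and \code{non_genic}.
#' @export
partition_sets <- function(classes) {
  stopifnot(!anyNA(classes))
  genic <- classes %in% GENIC_CLASSES
  list(genic = genic, non_genic = !genic)
}

#' Paired equal-size subsamples of genic and non-genic SNPs
#'
#' Each replicate draws, without replacement, min(|genic|, |non-genic|) SNPs
#' from each set, so base-composition contrasts are compared at matched SNP
#' numbers.
#'
#' @param genic_idx indices (or logical) of genic SNPs.
#' @param non_genic_idx indices (or logical) of non-genic SNPs.
#' @param n_reps number of replicates.
#' @param seed RNG seed.
#' @return list of replicates, each a list with \code{genic} and
#'   \code{non_genic} index vectors.
#' @export
balanced_subsample <- function(genic_idx, non_genic_idx, n_reps = 100, seed) {
  if (is.logical(genic_idx)) genic_idx <- which(genic_idx)
  if (is.logical(non_genic_idx)) non_genic_idx <- which(non_genic_idx)
  if (!length(genic_idx) || !length(non_genic_idx)) {
    stop("both genic and non-genic sets must be non-empty")
  }
  size <- min(length(genic_idx), length(non_genic_idx))
  set.seed(seed)
  lapply(seq_len(n_reps), function(r) {
    list(genic = sort(sample(genic_idx, size)),
         non_genic = sort(sample(non_genic_idx, size)))
  })
}
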