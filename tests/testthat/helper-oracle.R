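# Brute-force annotation oracle: rebuilds every transcript's spliced CDS
# from the genome sequence, substitutes the allele, translates both alleles
# with Biostrings and compares the proteins. Deliberately independent of the
# codon-local arithmetic inside classify_sites().

oracle_spliced_seq <- function(blocks, chrom, genome) {
  paste(vapply(seq_len(nrow(blocks)), function(i) {
    substring(genome[[chrom]], blocks[i, 1], blocks[i, 2])
  }, character(1)), collapse = "")
}

oracle_translate <- function(seq) {
  as.character(Biostrings::translate(Biostrings::DNAString(seq),
                                     if.fuzzy.codon = "X"))
}

oracle_gene_label <- function(chrom, pos, alt, models, gid, genome) {
  g <- models$genes[models$genes$id == gid, ]
  ex <- models$exons[[gid]]
  cds <- models$cds[[gid]]
  utr <- models$utr[[gid]]
  strand <- g$strand

  if (g$coding && nrow(cds) > 0 &&
      any(pos >= cds$start & pos <= cds$end)) {
    raw <- oracle_spliced_seq(as.matrix(cds[, c("start", "end")]), chrom,
                              genome)
    # raw index of pos in the ascending concatenation
    r <- 0L
    for (i in seq_len(nrow(cds))) {
      if (pos >= cds$start[i] && pos <= cds$end[i]) {
        r <- r + (pos - cds$start[i] + 1L)
        break
      }
      r <- r + (cds$end[i] - cds$start[i] + 1L)
    }
    if (strand == "+") {
      spliced <- raw
      idx <- r
      phase0 <- cds$phase[1]
      alt_b <- alt
    } else {
      spliced <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(raw)))
      idx <- nchar(raw) - r + 1L
      phase0 <- cds$phase[nrow(cds)]
      alt_b <- chartr("ACGT", "TGCA", alt)
    }
    if (is.na(phase0)) phase0 <- 0L
    if (phase0 > 0) {
      spliced <- substring(spliced, phase0 + 1L)
      idx <- idx - phase0
    }
    if (idx < 1) return("other_genic")
    usable <- nchar(spliced) - nchar(spliced) %% 3
    if (idx > usable) return("other_genic")
    spliced <- substring(spliced, 1, usable)
    mutated <- spliced
    substr(mutated, idx, idx) <- alt_b
    aa_ref <- strsplit(oracle_translate(spliced), "")[[1]]
    aa_alt <- strsplit(oracle_translate(mutated), "")[[1]]
    d <- which(aa_ref != aa_alt)
    codon_i <- (idx - 1L) %/% 3L + 1L
    ref_codon <- substring(spliced, 3 * codon_i - 2, 3 * codon_i)
    if (codon_i == 1 && ref_codon == "ATG" &&
        substring(mutated, 1, 3) != "ATG") {
      return("other_genic")
    }
    if (length(d) == 0) return("synonymous")
    if (aa_ref[d[1]] == "*" || aa_alt[d[1]] == "*") return("other_genic")
    return("missense")
  }
  if (nrow(utr) > 0 && any(pos >= utr[, 1] & pos <= utr[, 2])) return("utr")
  if (nrow(ex) > 1) {
    for (i in seq_len(nrow(ex) - 1)) {
      lo <- ex[i, 2] + 1L
      hi <- ex[i + 1, 1] - 1L
      if (hi >= lo && pos >= lo && pos <= hi) {
        if (pos - lo < 2L || hi - pos < 2L) return("other_genic")
        return("intronic")
      }
    }
  }
  "other_genic"
}

oracle_classify <- function(snps, models, genome, proximal_dist = 5000) {
  severity <- c(missense = 1, other_genic = 2, synonymous = 3,
                utr = 4, intronic = 5)
  g <- models$genes
  vapply(seq_len(nrow(snps)), function(i) {
    chrom <- snps$chrom[i]; pos <- snps$pos[i]; alt <- snps$alt[i]
    covering <- which(g$chrom == chrom & g$start <= pos & g$end >= pos)
    if (length(covering)) {
      labels <- vapply(g$id[covering], function(gid) {
        oracle_gene_label(chrom, pos, alt, models, gid, genome)
      }, character(1))
      return(labels[which.min(severity[labels])])
    }
    for (k in seq_len(nrow(g))) {
      if (g$chrom[k] != chrom) next
      if (g$strand[k] == "+" &&
          pos >= g$tss[k] - proximal_dist && pos <= g$tss[k] - 1) {
        return("gene_proximal")
      }
      if (g$strand[k] == "-" &&
          pos >= g$tss[k] + 1 && pos <= g$tss[k] + proximal_dist) {
        return("gene_proximal")
      }
    }
    "intergenic"
  }, character(1))
}
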