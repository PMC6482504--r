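# IO for the standard formats the pipeline touches. Conventions are fixed
# here once: VCF/GFF3 1-based inclusive, BED 0-based half-open, all internal
# interval tracks 0-based half-open.

#' Validate a SNP table
#'
#' A SNP table is a data.frame with columns \code{chrom}, \code{pos} (1-based),
#' \code{ref}, \code{alt} and optionally \code{id}; single-base alleles,
#' \code{ref != alt}, sorted by (chrom, pos), no duplicated positions.
#'
#' @param snps data.frame to validate.
#' @return the validated data.frame, invisibly.
#' @export
validate_snp_table <- function(snps) {
  stopifnot(is.data.frame(snps),
            all(c("chrom", "pos", "ref", "alt") %in% names(snps)))
  if (nrow(snps)) {
    stopifnot(all(snps$ref %in% DNA_BASES), all(snps$alt %in% DNA_BASES))
    if (any(snps$ref == snps$alt)) stop("ref == alt at some sites")
    o <- order(snps$chrom, snps$pos)
    if (!identical(o, seq_len(nrow(snps)))) {
      stop("SNP table not sorted by (chrom, pos)")
    }
    if (anyDuplicated(paste(snps$chrom, snps$pos))) {
      stop("duplicate (chrom, pos) in SNP table")
    }
  }
  invisible(snps)
}

#' @noRd
sort_snps <- function(snps) snps[order(snps$chrom, snps$pos), , drop = FALSE]

#' Read a sample-to-group table
#'
#' Tab-separated file with header columns \code{accession} and \code{group};
#' groups must be wild, landrace or improved.
#'
#' @param path file path.
#' @return data.frame with columns accession, group (factor).
#' @export
read_group_table <- function(path) {
  g <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("accession", "group") %in% names(g)))
  bad <- setdiff(unique(g$group), c("wild", "landrace", "improved"))
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  g$group <- factor(g$group, levels = c("wild", "landrace", "improved"))
  g
}

#' Read bi-allelic SNPs and genotype calls from a VCF
#'
#' Keeps bi-allelic single-nucleotide records only; multi-allelic and indel
#' records are skipped with a logged count. Genotype calls are coded 0 (REF),
#' 1 (ALT) and NA (missing). Heterozygous calls are set to missing: the
#' panels this pipeline targets are inbred lines and each accession
#' contributes one nucleotide per site.
#'
#' @param path VCF file path (plain text or gzipped).
#' @param groups data.frame from [read_group_table()] mapping every VCF sample
#'   to wild/landrace/improved.
#' @return list with \code{snps} (SNP table), \code{geno} (accession x site
#'   integer matrix) and \code{groups} (factor aligned to matrix rows).
#' @export
read_vcf_genotypes <- function(path, groups) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@fix) == 0) stop("empty VCF: ", path)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  keep <- fix$REF %in% DNA_BASES & fix$ALT %in% DNA_BASES
  n_skip <- sum(!keep)
  if (n_skip) message("skipped ", n_skip, " multi-allelic/non-SNP record(s)")
  if (!any(keep)) stop("no bi-allelic SNP records in VCF: ", path)
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]

  samples <- colnames(gt)
  missing_samples <- setdiff(samples, groups$accession)
  if (length(missing_samples)) {
    stop("VCF sample(s) absent from group table: ",
         paste(missing_samples, collapse = ", "))
  }

  allele <- function(s) {
    a <- sub("[/|].*$", "", s)
    b <- sub("^.*[/|]", "", s)
    out <- rep(NA_integer_, length(s))
    hom <- !is.na(s) & a == b & a %in% c("0", "1")
    out[hom] <- as.integer(a[hom])
    out  # het ("0/1" etc.) and "./." stay NA
  }
  geno <- t(apply(gt, 2, allele))  # accession x site
  colnames(geno) <- NULL
  rownames(geno) <- samples

  snps <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                     ref = fix$REF, alt = fix$ALT,
                     id = ifelse(is.na(fix$ID) | fix$ID == ".", NA, fix$ID),
                     stringsAsFactors = FALSE)
  o <- order(snps$chrom, snps$pos)
  snps <- snps[o, , drop = FALSE]
  rownames(snps) <- NULL
  geno <- geno[, o, drop = FALSE]
  validate_snp_table(snps)

  grp <- groups$group[match(samples, groups$accession)]
  names(grp) <- samples
  list(snps = snps, geno = geno, groups = grp)
}

#' Write a SNP table and genotype matrix to a minimal VCF
#'
#' Emits VCF 4.2 with GT-only genotype columns; calls 0 -> "0/0", 1 -> "1/1",
#' NA -> "./.". Round-trips exactly through [read_vcf_genotypes()].
#'
#' @param snps SNP table.
#' @param geno accession x site matrix (may be NULL for a site-only VCF).
#' @param path output path.
#' @export
write_snp_vcf <- function(snps, geno = NULL, path) {
  validate_snp_table(snps)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  header <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  id <- if ("id" %in% names(snps)) ifelse(is.na(snps$id), ".", snps$id)
        else rep(".", nrow(snps))
  body <- cbind(snps$chrom, snps$pos, id, snps$ref, snps$alt, ".", "PASS", ".")
  if (!is.null(geno)) {
    header <- c(header, "FORMAT", rownames(geno))
    code <- matrix(c("0/0", "1/1")[geno + 1L], nrow = nrow(geno))
    code[is.na(geno)] <- "./."
    body <- cbind(body, "GT", t(code))
  }
  writeLines(paste(header, collapse = "\t"), con)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a reference genome from FASTA
#'
#' @param path FASTA file path.
#' @return named character vector of uppercase chromosome sequences.
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0) stop("empty FASTA: ", path)
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm)) stop("duplicate sequence names in FASTA: ", path)
  setNames(toupper(as.character(seqs)), nm)
}

#' Write a genome to FASTA
#'
#' @param genome named character vector of chromosome sequences.
#' @param path output path.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' Read an interval track from BED
#'
#' BED is 0-based half-open, which is also the internal convention.
#' Overlapping or bookended intervals are merged on load.
#'
#' @param path BED file path.
#' @param label track name stored on the result.
#' @return data.frame with columns chrom, start, end (0-based half-open)
#'   and attribute \code{label}.
#' @export
read_bed_track <- function(path, label = basename(path)) {
  gr <- rtracklayer::import(path, format = "BED")
  interval_track(data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                            start = GenomicRanges::start(gr) - 1L,
                            end = GenomicRanges::end(gr),
                            stringsAsFactors = FALSE),
                 label = label, merge = TRUE)
}

#' Construct/normalize an interval track
#'
#' Validates 0-based half-open intervals and (optionally) merges overlaps.
#' Tracks carrying a \code{value} column are never merged.
#'
#' @param df data.frame with chrom, start, end and optional value.
#' @param label track name.
#' @param merge merge overlapping/bookended intervals (value-free tracks only).
#' @return normalized track data.frame sorted by (chrom, start).
#' @export
interval_track <- function(df, label = NULL, merge = FALSE) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) && any(df$start >= df$end)) stop("interval with start >= end")
  if (nrow(df) && any(df$start < 0)) stop("negative interval start")
  if (merge && !("value" %in% names(df)) && nrow(df)) {
    gr <- GenomicRanges::reduce(track_granges(df))
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr) - 1L,
                     end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
  }
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "label") <- label
  df
}

#' @noRd
track_granges <- function(track) {
  GenomicRanges::GRanges(track$chrom,
                         IRanges::IRanges(start = track$start + 1L,
                                          end = track$end))
}

#' Write an interval track to BED
#'
#' @param track interval track data.frame.
#' @param path output path.
#' @export
write_bed_track <- function(track, path) {
  write.table(track[, c("chrom", "start", "end")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a windowed numeric track from TSV
#'
#' Expects header columns chrom, start, end (0-based half-open) and value.
#'
#' @param path TSV path.
#' @param label track name.
#' @return value-carrying interval track.
#' @export
read_numeric_track <- function(path, label = basename(path)) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(df)))
  interval_track(df, label = label)
}

#' Write a table to TSV with a named header
#'
#' @param table data.frame.
#' @param path output path.
#' @export
write_tsv <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a flat key-value run configuration
#'
#' One \code{key = value} pair per line; \code{#} starts a comment. Values
#' are parsed as numbers where possible, otherwise kept as strings.
#'
#' @param path config file path.
#' @return named list of settings.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  if (any(lengths(kv) != 3)) stop("malformed config line(s) in ", path)
  keys <- trimws(vapply(kv, `[`, character(1), 2))
  vals <- trimws(vapply(kv, `[`, character(1), 3))
  num <- suppressWarnings(as.numeric(vals))
  out <- lapply(seq_along(vals),
                function(i) if (is.na(num[i])) vals[i] else num[i])
  setNames(out, keys)
}

#' Write a flat key-value run configuration
#'
#' @param config named list of scalar settings.
#' @param path output path.
#' @export
write_run_config <- function(config, path) {
  writeLines(paste(names(config), unlist(config), sep = " = "), path)
  invisible(path)
}

#' Cross-file consistency checks for a study
#'
#' Verifies that every SNP position falls inside its chromosome, that the
#' reference allele matches the genome base (when \code{check_ref}), that the
#' genotype matrix is aligned to the SNP table, and that every accession has
#' a group label.
#'
#' @param snps SNP table.
#' @param geno accession x site matrix.
#' @param groups per-accession factor.
#' @param genome named character vector of chromosome sequences.
#' @param check_ref verify ref allele against the genome base.
#' @return TRUE invisibly; stops on the first inconsistency.
#' @export
validate_study <- function(snps, geno, groups, genome, check_ref = TRUE) {
  validate_snp_table(snps)
  if (ncol(geno) != nrow(snps)) stop("genotype matrix not aligned to SNP table")
  if (nrow(geno) != length(groups) || any(is.na(groups))) {
    stop("every accession needs a group label")
  }
  lens <- chrom_lengths(genome)
  if (!all(snps$chrom %in% names(lens))) stop("SNP on undeclared chromosome")
  if (any(snps$pos < 1 | snps$pos > lens[snps$chrom])) {
    stop("SNP position outside chromosome")
  }
  if (check_ref) {
    gb <- genome_base(genome, snps$chrom, snps$pos)
    bad <- which(gb != snps$ref)
    if (length(bad)) {
      stop(length(bad), " SNP(s) whose ref allele mismatches the genome, ",
           "first at ", snps$chrom[bad[1]], ":", snps$pos[bad[1]])
    }
  }
  invisible(TRUE)
}
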