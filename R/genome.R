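#' @noRd
DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement a vector of DNA strings
#'
#' Plain-strand reverse complement over the A/C/G/T/N alphabet.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp(c("TCG", "CCG"))
revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(b) paste(rev(b), collapse = ""), character(1))
}

#' @noRd
complement_base <- function(x) chartr("ACGTN", "TGCAN", x)

#' Chromosome lengths of a genome
#'
#' @param genome named character vector of chromosome sequences.
#' @return named integer vector of lengths.
#' @export
chrom_lengths <- function(genome) {
  setNames(nchar(genome), names(genome))
}

#' Extract reference bases at genomic positions
#'
#' Vectorized single-base lookup. Positions outside the chromosome return NA.
#'
#' @param genome named character vector of chromosome sequences.
#' @param chrom character vector of chromosome names.
#' @param pos integer vector of 1-based positions.
#' @return character vector of bases (NA where out of range).
#' @export
genome_base <- function(genome, chrom, pos) {
  stopifnot(length(chrom) == length(pos))
  bad_chrom <- !(chrom %in% names(genome))
  if (any(bad_chrom)) {
    stop("positions on undeclared chromosome(s): ",
         paste(unique(chrom[bad_chrom]), collapse = ", "))
  }
  out <- rep(NA_character_, length(pos))
  for (cn in unique(chrom)) {
    i <- which(chrom == cn)
    p <- pos[i]
    ok <- p >= 1L & p <= nchar(genome[[cn]])
    if (any(ok)) out[i[ok]] <- substring(genome[[cn]], p[ok], p[ok])
  }
  out
}

#' Extract trinucleotide contexts centred on genomic positions
#'
#' Returns the reference-strand 3-mer at \code{pos - 1 .. pos + 1}. Positions
#' at a chromosome end, or whose 3-mer contains a base outside A/C/G/T, are
#' returned as NA (callers log/skip them).
#'
#' @inheritParams genome_base
#' @return character vector of 3-mers with NA for excluded positions.
#' @export
#' @examples
#' g <- c(chr1 = "ACGTA")
#' genome_context(g, "chr1", 3)  # "CGT"
genome_context <- function(genome, chrom, pos) {
  stopifnot(length(chrom) == length(pos))
  bad_chrom <- !(chrom %in% names(genome))
  if (any(bad_chrom)) {
    stop("positions on undeclared chromosome(s): ",
         paste(unique(chrom[bad_chrom]), collapse = ", "))
  }
  out <- rep(NA_character_, length(pos))
  for (cn in unique(chrom)) {
    i <- which(chrom == cn)
    p <- pos[i]
    ok <- p >= 2L & p <= nchar(genome[[cn]]) - 1L
    if (any(ok)) {
      ctx <- substring(genome[[cn]], p[ok] - 1L, p[ok] + 1L)
      ctx[!grepl("^[ACGT]{3}$", ctx)] <- NA_character_
      out[i[ok]] <- ctx
    }
  }
  out
}
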