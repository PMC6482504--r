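# Synthetic study generator: genome, annotation, methylation, recombination,
# three-population genotypes with a planted [AT]-difference, and
# population-private SNP sets carrying a planted solar-UV-signature mutation
# excess. Every planted parameter is echoed in a truth record so recovery can
# be scored. The generative model is deliberately statistical, not
# coalescent: sites get group-specific allele frequencies, which is the only
# structure the downstream analyses consume.

#' Configuration for the synthetic study
#'
#' Defaults mirror the magnitudes the analyses are designed around: a planted
#' wild-vs-domesticated [AT]-difference of 0.034, transition types (A/G and
#' C/T) at ~34% each, elevated mCG and reduced recombination inside the
#' pericentromere, a doubled [AT]-difference in the pericentromere and a
#' halved one in genic sequence, and a 1.5-fold excess of PyCG->PyTG
#' mutations (placed preferentially in methylated windows) in
#' domesticated-private SNP sets.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length chromosome length in bp.
#' @param gc_content genome GC fraction.
#' @param n_genes genes per chromosome (~10% placed in the pericentromere).
#' @param n_exons integer range of exons per gene.
#' @param exon_length,intron_length bp ranges.
#' @param utr_length 5'/3' UTR length in bp (< minimum exon length).
#' @param centromere_fraction centromere width as a fraction of the
#'   chromosome, centred.
#' @param pericentromere_flank flank added to each side of the centromere.
#' @param te_fraction fraction of the genome covered by transposable
#'   elements (placed ~70% inside the pericentromere).
#' @param n_sweeps,sweep_length selective-sweep intervals per genome.
#' @param n_wild,n_landrace,n_improved accessions per group.
#' @param n_common_snps size of the common panel.
#' @param n_private_snps SNPs per private set (scalar, or named vector over
#'   PW/PD/PL/PI).
#' @param delta_at planted mean domesticated-minus-wild [AT]-difference.
#' @param transition_fraction target frequency of each transition type.
#' @param peri_delta_mult,genic_delta_mult multiplicative [AT]-difference
#'   modifiers for pericentromeric and genic SNPs (overall mean is kept at
#'   \code{delta_at}).
#' @param hotspot optional list(chrom, start, end, mult) planting an extra
#'   [AT]-difference multiplier in one region.
#' @param maf_range_arm,maf_range_peri uniform MAF ranges for common sites.
#' @param uv_enrichment multiplicative excess of PyCG->PyTG mutations in
#'   domesticated-private sets (must be >= 1; 1 = null).
#' @param uv_base_rate baseline fraction of private mutations generated as
#'   UV-signature events (before enrichment).
#' @param uv_meth_weight probability a planted UV event lands in a
#'   methylated window.
#' @param private_derived_freq uniform range for the derived-allele frequency
#'   within the focal group of a private SNP.
#' @param meth_rate_arm,meth_rate_peri per-100-bp probability that a window
#'   is methylated on chromosome arms / inside pericentromere or TE.
#' @param recomb_window,recomb_arm,recomb_peri recombination-rate track:
#'   window size and uniform rate ranges (length-2) for arms and
#'   pericentromere.
#' @param outgroup_error probability an outgroup allele is misassigned.
#' @param missing_rate per-call missing probability.
#' @param min_call_rate per-group call-rate floor enforced for private sites.
#' @param seed RNG seed (always explicit).
#' @return validated config list of class \code{sim_config}.
#' @export
sim_config <- function(n_chrom = 2,
                       chrom_length = 5e6,
                       gc_content = 0.47,
                       n_genes = 150,
                       n_exons = c(2, 6),
                       exon_length = c(150, 400),
                       intron_length = c(100, 800),
                       utr_length = 60,
                       centromere_fraction = 0.04,
                       pericentromere_flank = 1e6,
                       te_fraction = 0.30,
                       n_sweeps = 3,
                       sweep_length = 2e5,
                       n_wild = 50, n_landrace = 50, n_improved = 50,
                       n_common_snps = 5e4,
                       n_private_snps = 2e4,
                       delta_at = 0.034,
                       transition_fraction = 0.34,
                       peri_delta_mult = 2,
                       genic_delta_mult = 0.5,
                       hotspot = NULL,
                       maf_range_arm = c(0.20, 0.50),
                       maf_range_peri = c(0.12, 0.40),
                       uv_enrichment = 1.5,
                       uv_base_rate = 0.08,
                       uv_meth_weight = 0.8,
                       private_derived_freq = c(0.05, 0.50),
                       meth_rate_arm = 0.25,
                       meth_rate_peri = 0.85,
                       recomb_window = 5e5,
                       recomb_arm = c(3, 7),
                       recomb_peri = c(0.1, 1),
                       outgroup_error = 0,
                       missing_rate = 0.05,
                       min_call_rate = 0.8,
                       seed = 1) {
  cfg <- as.list(environment())
  probs <- c(gc_content, te_fraction, uv_base_rate, uv_meth_weight,
             meth_rate_arm, meth_rate_peri, outgroup_error, missing_rate,
             min_call_rate, transition_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (delta_at < 0 || delta_at > 0.2) stop("delta_at must lie in [0, 0.2]")
  if (2 * transition_fraction >= 1) stop("transition_fraction must be < 0.5")
  if (uv_enrichment < 1) stop("uv_enrichment must be >= 1 (model is an excess)")
  if (is.null(seed) || is.na(seed)) stop("seed must be explicit")
  class(cfg) <- "sim_config"
  cfg
}

#' @noRd
random_chromosome <- function(len, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, len, replace = TRUE, prob = p), collapse = "")
}

# Trim `left`/`right` bp off a set of genomic blocks (matrix start,end);
# returns list(trimmed, left_part, right_part).
#' @noRd
trim_blocks <- function(blocks, left, right) {
  take_left <- function(b, k) {
    out <- NULL
    for (i in seq_len(nrow(b))) {
      w <- b[i, 2] - b[i, 1] + 1
      if (k <= 0) break
      t <- min(w, k)
      out <- rbind(out, c(b[i, 1], b[i, 1] + t - 1))
      k <- k - t
    }
    out
  }
  lp <- take_left(blocks, left)
  rp <- take_left(blocks[rev(seq_len(nrow(blocks))), , drop = FALSE][, 2:1,
                                                                    drop = FALSE] * -1,
                  right)
  if (!is.null(rp)) rp <- -rp[, 2:1, drop = FALSE]
  # remaining middle
  covered <- rbind(lp, rp)
  mid <- blocks
  if (!is.null(lp)) {
    last_l <- max(lp[, 2])
    mid[, 1] <- pmax(mid[, 1], last_l + 1)
  }
  if (!is.null(rp)) {
    first_r <- min(rp[, 1])
    mid[, 2] <- pmin(mid[, 2], first_r - 1)
  }
  mid <- mid[mid[, 1] <= mid[, 2], , drop = FALSE]
  list(mid = mid, left = lp, right = rp)
}

#' @noRd
simulate_gene_features <- function(cfg, chrom, region_start, region_end,
                                   ids) {
  n <- length(ids)
  if (n == 0) return(NULL)
  n_ex <- sample(cfg$n_exons[1]:cfg$n_exons[2], n, replace = TRUE)
  gene_rows <- vector("list", n)
  lens <- integer(n)
  structs <- vector("list", n)
  for (i in seq_len(n)) {
    ex_len <- sample(cfg$exon_length[1]:cfg$exon_length[2], n_ex[i],
                     replace = TRUE)
    in_len <- if (n_ex[i] > 1) {
      sample(cfg$intron_length[1]:cfg$intron_length[2], n_ex[i] - 1,
             replace = TRUE)
    } else integer(0)
    structs[[i]] <- list(ex = ex_len, intr = in_len)
    lens[i] <- sum(ex_len) + sum(in_len)
  }
  region_len <- region_end - region_start
  if (sum(lens) > 0.9 * region_len) {
    stop("genes do not fit the chromosome region [",
         region_start, ", ", region_end, ") on ", chrom)
  }
  slack <- region_len - sum(lens)
  gaps <- diff(c(0, sort(runif(n)), 1)) * slack
  starts <- region_start + 1 + cumsum(gaps[seq_len(n)]) +
    c(0, cumsum(lens[-n]))
  starts <- floor(starts)

  feats <- vector("list", n)
  for (i in seq_len(n)) {
    st <- structs[[i]]
    strand <- sample(c("+", "-"), 1)
    ex <- matrix(0L, length(st$ex), 2)
    p <- starts[i]
    for (e in seq_along(st$ex)) {
      ex[e, ] <- c(p, p + st$ex[e] - 1L)
      p <- ex[e, 2] + (if (e < length(st$ex)) st$intr[e] else 0L) + 1L
    }
    g_start <- ex[1, 1]; g_end <- ex[nrow(ex), 2]
    total_ex <- sum(st$ex)
    u5 <- cfg$utr_length
    u3 <- cfg$utr_length
    u3 <- u3 + (total_ex - u5 - u3) %% 3  # keep the CDS in frame
    left_trim <- if (strand == "+") u5 else u3
    right_trim <- if (strand == "+") u3 else u5
    tr <- trim_blocks(ex, left_trim, right_trim)
    cds <- tr$mid
    # phases in transcription order
    ord <- if (strand == "+") seq_len(nrow(cds)) else rev(seq_len(nrow(cds)))
    cum <- 0L
    phase <- integer(nrow(cds))
    for (b in ord) {
      phase[b] <- (3L - cum %% 3L) %% 3L
      cum <- cum + cds[b, 2] - cds[b, 1] + 1L
    }
    gid <- ids[i]; mid <- paste0(gid, ".t1")
    rows <- list(
      data.frame(type = "gene", chrom = chrom, start = g_start, end = g_end,
                 strand = strand, phase = NA_integer_, id = gid,
                 parent = NA_character_, stringsAsFactors = FALSE),
      data.frame(type = "mRNA", chrom = chrom, start = g_start, end = g_end,
                 strand = strand, phase = NA_integer_, id = mid,
                 parent = gid, stringsAsFactors = FALSE),
      data.frame(type = "exon", chrom = chrom, start = ex[, 1], end = ex[, 2],
                 strand = strand, phase = NA_integer_, id = NA_character_,
                 parent = mid, stringsAsFactors = FALSE),
      data.frame(type = "CDS", chrom = chrom, start = cds[, 1],
                 end = cds[, 2], strand = strand, phase = phase,
                 id = NA_character_, parent = mid, stringsAsFactors = FALSE))
    five <- if (strand == "+") tr$left else tr$right
    three <- if (strand == "+") tr$right else tr$left
    if (!is.null(five)) {
      rows <- c(rows, list(data.frame(type = "five_prime_UTR", chrom = chrom,
                                      start = five[, 1], end = five[, 2],
                                      strand = strand, phase = NA_integer_,
                                      id = NA_character_, parent = mid,
                                      stringsAsFactors = FALSE)))
    }
    if (!is.null(three)) {
      rows <- c(rows, list(data.frame(type = "three_prime_UTR", chrom = chrom,
                                      start = three[, 1], end = three[, 2],
                                      strand = strand, phase = NA_integer_,
                                      id = NA_character_, parent = mid,
                                      stringsAsFactors = FALSE)))
    }
    feats[[i]] <- do.call(rbind, rows)
  }
  do.call(rbind, feats)
}

#' @noRd
random_intervals_in <- function(chrom, lo, hi, budget, len_range) {
  out <- NULL
  used <- 0
  while (used < budget && hi - lo > len_range[2]) {
    w <- floor(runif(1, len_range[1], len_range[2]))
    s <- floor(runif(1, lo, hi - w))
    out <- rbind(out, data.frame(chrom = chrom, start = s, end = s + w,
                                 stringsAsFactors = FALSE))
    used <- used + w
  }
  out
}

#' Simulate the genome and its annotation tracks
#'
#' Generates i.i.d. chromosome sequences at the configured GC content,
#' non-overlapping gene models (~10% of genes inside the pericentromere,
#' emulating its low gene density), centromere/pericentromere intervals,
#' TE intervals concentrated in the pericentromere, selective-sweep
#' intervals on the arms, a per-100-bp CG-methylation track (methylation
#' elevated inside pericentromere and TEs), a windowed recombination-rate
#' track (depressed inside the pericentromere) and the pool of PyCG
#' candidate positions used to plant UV-signature mutations. Identical
#' configs (including seed) give identical output.
#'
#' @param cfg a [sim_config()].
#' @return list with genome, lens, feats (GFF3 feature table), models
#'   ([build_gene_models()] result), centromeres, peri, te, sweeps,
#'   methylation, recomb, uv_candidates and the config.
#' @export
simulate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  chroms <- paste0("chr", seq_len(cfg$n_chrom))
  genome <- setNames(vapply(chroms, function(cn) {
    random_chromosome(cfg$chrom_length, cfg$gc_content)
  }, character(1)), chroms)
  lens <- chrom_lengths(genome)

  cen_w <- round(cfg$centromere_fraction * cfg$chrom_length / 100) * 100
  cen_start <- round((cfg$chrom_length - cen_w) / 2 / 100) * 100
  centromeres <- interval_track(data.frame(chrom = chroms,
                                           start = cen_start,
                                           end = cen_start + cen_w),
                                label = "centromere")
  peri <- pericentromere(centromeres, lens,
                         flank = cfg$pericentromere_flank)

  # genes: ~10% in pericentromere, the rest split across the two arms
  feats <- NULL
  for (ci in seq_along(chroms)) {
    cn <- chroms[ci]
    p <- peri[peri$chrom == cn, ]
    arm_lens <- c(p$start, lens[[cn]] - p$end)
    n_peri <- if (sum(arm_lens) > 0) round(0.1 * cfg$n_genes) else cfg$n_genes
    n_arm <- cfg$n_genes - n_peri
    n_left <- if (sum(arm_lens) > 0) {
      round(n_arm * arm_lens[1] / sum(arm_lens))
    } else 0L
    counts <- c(left = n_left, peri = n_peri, right = n_arm - n_left)
    bounds <- list(left = c(0, p$start), peri = c(p$start, p$end),
                   right = c(p$end, lens[[cn]]))
    idx0 <- (ci - 1) * cfg$n_genes
    taken <- 0
    for (rg in names(counts)) {
      k <- counts[[rg]]
      if (k == 0) next
      ids <- sprintf("gene%05d", idx0 + taken + seq_len(k))
      taken <- taken + k
      feats <- rbind(feats,
                     simulate_gene_features(cfg, cn, bounds[[rg]][1] + 1,
                                            bounds[[rg]][2] - 1, ids))
    }
  }
  if (is.null(feats)) {
    feats <- data.frame(type = character(), chrom = character(),
                        start = integer(), end = integer(),
                        strand = character(), phase = integer(),
                        id = character(), parent = character())
  }
  feats$start <- as.integer(feats$start)
  feats$end <- as.integer(feats$end)
  feats$phase <- as.integer(feats$phase)
  models <- build_gene_models(feats)

  # transposable elements: ~70% of the TE budget inside the pericentromere
  te <- NULL
  if (cfg$te_fraction > 0) {
    for (cn in chroms) {
      p <- peri[peri$chrom == cn, ]
      budget <- cfg$te_fraction * lens[[cn]]
      te <- rbind(te,
                  random_intervals_in(cn, p$start, p$end, 0.7 * budget,
                                      c(2000, 10000)),
                  random_intervals_in(cn, 0, p$start, 0.15 * budget,
                                      c(2000, 10000)),
                  random_intervals_in(cn, p$end, lens[[cn]], 0.15 * budget,
                                      c(2000, 10000)))
    }
  }
  te <- interval_track(te %||% data.frame(chrom = character(),
                                          start = integer(),
                                          end = integer()),
                       label = "TE", merge = TRUE)

  sweeps <- NULL
  for (i in seq_len(cfg$n_sweeps)) {
    cn <- sample(chroms, 1)
    p <- peri[peri$chrom == cn, ]
    # prefer the arms; fall back to anywhere the sweep fits
    regions <- rbind(c(0, p$start), c(p$end, lens[[cn]]))
    regions <- regions[regions[, 2] - regions[, 1] > cfg$sweep_length, ,
                       drop = FALSE]
    if (nrow(regions) == 0) {
      regions <- matrix(c(0, lens[[cn]]), 1)
      if (regions[1, 2] - regions[1, 1] <= cfg$sweep_length) next
    }
    r <- regions[sample(nrow(regions), 1), ]
    s <- floor(runif(1, r[1], r[2] - cfg$sweep_length))
    sweeps <- rbind(sweeps, data.frame(chrom = cn, start = s,
                                       end = s + cfg$sweep_length))
  }
  sweeps <- interval_track(sweeps %||% data.frame(chrom = character(),
                                                  start = integer(),
                                                  end = integer()),
                           label = "sweep", merge = TRUE)

  # CG methylation per 100-bp window
  meth <- NULL
  for (cn in chroms) {
    starts <- seq(0L, lens[[cn]] - 1L, by = 100L)
    ends <- pmin(starts + 100L, lens[[cn]])
    mid <- (starts + ends) / 2
    p <- peri[peri$chrom == cn, ]
    in_peri <- mid >= p$start & mid < p$end
    w_gr <- GenomicRanges::GRanges(cn, IRanges::IRanges(starts + 1L, ends))
    in_te <- GenomicRanges::countOverlaps(
      w_gr, track_granges(te[te$chrom == cn, , drop = FALSE])) > 0
    pm <- ifelse(in_peri | in_te, cfg$meth_rate_peri, cfg$meth_rate_arm)
    is_m <- rbinom(length(starts), 1, pm) == 1
    val <- ifelse(is_m, runif(length(starts), 45, 95),
                  runif(length(starts), 0, 35))
    meth <- rbind(meth, data.frame(chrom = cn, start = starts, end = ends,
                                   value = val, stringsAsFactors = FALSE))
  }
  meth <- interval_track(meth, label = "mCG_percent")

  # recombination rate, depressed in the pericentromere
  recomb <- NULL
  for (cn in chroms) {
    starts <- seq(0L, lens[[cn]] - 1L, by = as.integer(cfg$recomb_window))
    ends <- pmin(starts + as.integer(cfg$recomb_window), lens[[cn]])
    mid <- (starts + ends) / 2
    p <- peri[peri$chrom == cn, ]
    in_peri <- mid >= p$start & mid < p$end
    val <- ifelse(in_peri,
                  runif(length(starts), cfg$recomb_peri[1],
                        cfg$recomb_peri[2]),
                  runif(length(starts), cfg$recomb_arm[1],
                        cfg$recomb_arm[2]))
    recomb <- rbind(recomb, data.frame(chrom = cn, start = starts,
                                       end = ends, value = val,
                                       stringsAsFactors = FALSE))
  }
  recomb <- interval_track(recomb, label = "recombination_rate")

  # PyCG candidate positions (either strand) for planting UV events
  uv_candidates <- NULL
  for (cn in chroms) {
    ch <- strsplit(genome[[cn]], "", fixed = TRUE)[[1]]
    n <- length(ch)
    i <- 2:(n - 1)
    l <- ch[i - 1L]; c0 <- ch[i]; r <- ch[i + 1L]
    plus <- c0 == "C" & r == "G" & l %in% c("C", "T")
    minus <- c0 == "G" & l == "C" & r %in% c("A", "G")
    pos <- c(i[plus], i[minus])
    strand <- c(rep("+", sum(plus)), rep("-", sum(minus)))
    mv <- meth$value[meth$chrom == cn][(pos - 1L) %/% 100L + 1L]
    uv_candidates <- rbind(uv_candidates,
                           data.frame(chrom = cn, pos = pos, strand = strand,
                                      methylated = mv > 40,
                                      stringsAsFactors = FALSE))
  }

  list(genome = genome, lens = lens, feats = feats, models = models,
       centromeres = centromeres, peri = peri, te = te, sweeps = sweeps,
       methylation = meth, recomb = recomb, uv_candidates = uv_candidates,
       config = cfg)
}

#' @noRd
group_vector <- function(cfg) {
  factor(c(rep("wild", cfg$n_wild), rep("landrace", cfg$n_landrace),
           rep("improved", cfg$n_improved)),
         levels = c("wild", "landrace", "improved"))
}

#' @noRd
accession_names <- function(cfg) {
  c(sprintf("wild_%03d", seq_len(cfg$n_wild)),
    sprintf("landrace_%03d", seq_len(cfg$n_landrace)),
    sprintf("improved_%03d", seq_len(cfg$n_improved)))
}

#' Simulate the common SNP panel with a planted [AT]-difference
#'
#' Sites are placed uniformly at random; the reference allele is the genome
#' base and the substitution type is drawn so transitions hit the configured
#' ~34% share each. At sites where exactly one allele is A or T, the A/T
#' allele frequency is shifted between wild and domesticated groups so the
#' mean [AT]-difference equals \code{delta_at}, with the shift doubled in the
#' pericentromere and halved in genic sequence (normalised to keep the
#' overall mean). Genotypes are per-accession Bernoulli draws (inbred-style
#' single-allele calls); a missing mask is applied, and each site is
#' guaranteed to pass the MAF >= 0.05 / missing <= 0.20 common filter.
#'
#' @param cfg a [sim_config()].
#' @param sim result of [simulate_genome()] for the same (or a compatible)
#'   config.
#' @return list with snps, geno, groups, outgroup (data.frame chrom, pos,
#'   allele) and a \code{truth} record of every planted parameter.
#' @export
simulate_common_panel <- function(cfg, sim) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  lens <- sim$lens
  total <- sum(lens - 2)
  if (cfg$n_common_snps > 0.5 * total) {
    stop("requested SNP count exceeds available positions")
  }
  # allocate sites to chromosomes proportionally to length
  alloc <- floor(cfg$n_common_snps * (lens - 2) / total)
  rem <- cfg$n_common_snps - sum(alloc)
  if (rem > 0) alloc[seq_len(rem)] <- alloc[seq_len(rem)] + 1L
  snps <- do.call(rbind, lapply(names(lens), function(cn) {
    pos <- sort(sample(2:(lens[[cn]] - 1L), alloc[[cn]]))
    data.frame(chrom = cn, pos = pos, stringsAsFactors = FALSE)
  }))
  snps$ref <- genome_base(sim$genome, snps$chrom, snps$pos)
  m <- nrow(snps)

  # substitution type per site, conditional on the reference base
  type_w <- c("A/C" = 9, "A/G" = NA, "A/T" = 8, "C/G" = 6,
              "C/T" = NA, "G/T" = 9)
  tv_total <- 1 - 2 * cfg$transition_fraction
  type_w[c("A/C", "A/T", "C/G", "G/T")] <-
    type_w[c("A/C", "A/T", "C/G", "G/T")] / 32 * tv_total
  type_w[c("A/G", "C/T")] <- cfg$transition_fraction
  types_of <- list(A = c("A/C", "A/G", "A/T"), C = c("A/C", "C/G", "C/T"),
                   G = c("A/G", "C/G", "G/T"), T = c("A/T", "C/T", "G/T"))
  type <- character(m)
  for (b in DNA_BASES) {
    i <- which(snps$ref == b)
    w <- type_w[types_of[[b]]]
    type[i] <- sample(types_of[[b]], length(i), replace = TRUE,
                      prob = w / sum(w))
  }
  both <- strsplit(type, "/", fixed = TRUE)
  snps$alt <- vapply(seq_len(m), function(i) {
    setdiff(both[[i]], snps$ref[i])[1]
  }, character(1))

  in_peri <- snps_in_track(snps, sim$peri)
  genic <- rep(FALSE, m)
  if (nrow(sim$models$genes)) {
    g <- sim$models$genes
    genic <- snps_in_track(snps, data.frame(chrom = g$chrom,
                                            start = g$start - 1L,
                                            end = g$end))
  }
  u <- rep(1, m)
  u[in_peri] <- u[in_peri] * cfg$peri_delta_mult
  u[genic] <- u[genic] * cfg$genic_delta_mult
  if (!is.null(cfg$hotspot)) {
    h <- cfg$hotspot
    in_h <- snps$chrom == h$chrom & (snps$pos - 1) >= h$start &
      (snps$pos - 1) < h$end
    u[in_h] <- u[in_h] * h$mult
  }
  ref_at <- snps$ref %in% c("A", "T")
  alt_at <- snps$alt %in% c("A", "T")
  rel <- xor(ref_at, alt_at)  # exactly one allele is A/T
  base_shift <- if (cfg$delta_at > 0) cfg$delta_at / mean(u * rel) else 0
  shift <- base_shift * u

  maf <- ifelse(in_peri,
                runif(m, cfg$maf_range_peri[1], cfg$maf_range_peri[2]),
                runif(m, cfg$maf_range_arm[1], cfg$maf_range_arm[2]))
  p0 <- ifelse(runif(m) < 0.5, maf, 1 - maf)
  n_dom <- cfg$n_landrace + cfg$n_improved
  n_tot <- cfg$n_wild + n_dom
  w_dom <- n_dom / n_tot
  clamp <- function(x) pmin(pmax(x, 0.02), 0.98)
  # AT-allele frequency per group at relevant sites; alt frequency elsewhere
  p_at_wild <- clamp(p0 - shift * w_dom)
  p_at_dom <- clamp(p0 + shift * (1 - w_dom))
  p_alt_of <- function(p_at) ifelse(rel & ref_at, 1 - p_at,
                                    ifelse(rel, p_at, p0))
  p_alt <- cbind(wild = p_alt_of(p_at_wild),
                 landrace = p_alt_of(p_at_dom),
                 improved = p_alt_of(p_at_dom))

  groups <- group_vector(cfg)
  draw_group <- function(g) {
    n <- sum(groups == g)
    gm <- matrix(rbinom(n * m, 1L, rep(p_alt[, g], each = n)), nrow = n)
    gm[matrix(runif(n * m) < cfg$missing_rate, nrow = n)] <- NA_integer_
    gm
  }
  geno <- rbind(draw_group("wild"), draw_group("landrace"),
                draw_group("improved"))
  rownames(geno) <- accession_names(cfg)

  # every emitted site must pass the common MAF/missing filter; the missing
  # side is only enforceable when the configured rate leaves it feasible
  enforce_missing <- cfg$missing_rate <= 0.15
  site_ok <- function() {
    n_nonmiss <- colSums(!is.na(geno))
    p_alt_real <- colSums(geno, na.rm = TRUE) / pmax(n_nonmiss, 1)
    ok <- pmin(p_alt_real, 1 - p_alt_real) >= 0.05
    if (enforce_missing) ok <- ok & n_nonmiss >= 0.8 * n_tot
    ok
  }
  for (attempt in 1:50) {
    bad <- which(!site_ok())
    if (!length(bad)) break
    for (j in bad) {
      col <- rbinom(n_tot, 1L, p_alt[j, as.character(groups)])
      col[runif(n_tot) < cfg$missing_rate] <- NA_integer_
      geno[, j] <- col
    }
  }
  keep <- site_ok()
  if (!all(keep)) {
    message("dropped ", sum(!keep), " site(s) that failed the common filter")
    snps <- snps[keep, , drop = FALSE]
    geno <- geno[, keep, drop = FALSE]
    type <- type[keep]; rel <- rel[keep]; u <- u[keep]
  }
  rownames(snps) <- NULL

  outgroup <- data.frame(chrom = snps$chrom, pos = snps$pos,
                         allele = ifelse(runif(nrow(snps)) <
                                           cfg$outgroup_error,
                                         snps$alt, snps$ref),
                         stringsAsFactors = FALSE)
  truth <- list(delta_at = cfg$delta_at, base_shift = base_shift,
                peri_delta_mult = cfg$peri_delta_mult,
                genic_delta_mult = cfg$genic_delta_mult,
                hotspot = cfg$hotspot,
                transition_fraction = cfg$transition_fraction,
                type_counts = table(type), n_relevant = sum(rel),
                w_dom = w_dom, seed = cfg$seed)
  snps$id <- NA_character_
  list(snps = snps[, c("chrom", "pos", "ref", "alt", "id")], geno = geno,
       groups = setNames(groups, rownames(geno)), outgroup = outgroup,
       truth = truth)
}

#' Simulate the four population-private SNP sets
#'
#' Each set (PW, PD, PL, PI) receives sites whose ancestral allele is the
#' genome base: the focal group segregates for a derived allele while every
#' other group is fixed ancestral with a per-group call rate of at least
#' \code{min_call_rate} (enforced, so every emitted SNP passes
#' [call_private()] with its own label). A fraction \code{uv_base_rate} of
#' mutations (times \code{uv_enrichment} for the domesticated-private sets
#' PD, PL and PI) are planted UV-signature events: C->T at PyCG contexts
#' (G->A on the reference strand for minus-strand contexts), placed in
#' methylated 100-bp windows with probability \code{uv_meth_weight}; the
#' remainder are background mutations with a transition share of
#' 2 x \code{transition_fraction}.
#'
#' @inheritParams simulate_common_panel
#' @return named list of sets; each has snps (polarized: ancestral/derived
#'   columns), geno, groups, outgroup; plus a shared \code{truth} record.
#' @export
simulate_private_sets <- function(cfg, sim) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$uv_enrichment < 1) stop("uv_enrichment must be >= 1")
  set.seed(cfg$seed + 2L)
  groups <- group_vector(cfg)
  acc <- accession_names(cfg)
  n_tot <- length(acc)
  lens <- sim$lens
  cand <- sim$uv_candidates
  cand_key <- paste(cand$chrom, cand$pos)
  w_cand <- ifelse(cand$methylated,
                   cfg$uv_meth_weight / max(1, sum(cand$methylated)),
                   (1 - cfg$uv_meth_weight) /
                     max(1, sum(!cand$methylated)))

  set_sizes <- cfg$n_private_snps
  if (length(set_sizes) == 1) {
    set_sizes <- setNames(rep(set_sizes, 4), c("PW", "PD", "PL", "PI"))
  }
  focal_of <- list(PW = "wild", PD = c("landrace", "improved"),
                   PL = "landrace", PI = "improved")
  used <- character(0)
  out <- list()
  truth_uv <- numeric(0)

  for (lab in c("PW", "PD", "PL", "PI")) {
    n <- set_sizes[[lab]]
    if (n == 0) {
      empty <- data.frame(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          id = character(), ancestral = character(),
                          derived = character(), stringsAsFactors = FALSE)
      out[[lab]] <- list(snps = empty,
                         geno = matrix(integer(0), n_tot, 0,
                                       dimnames = list(acc, NULL)),
                         groups = setNames(groups, acc),
                         outgroup = data.frame(chrom = character(),
                                               pos = integer(),
                                               allele = character()))
      truth_uv[lab] <- 0
      next
    }
    q_uv <- min(1, cfg$uv_base_rate *
                  (if (lab == "PW") 1 else cfg$uv_enrichment))
    n_uv <- rbinom(1, n, q_uv)
    # planted UV events at PyCG candidate positions
    free <- !(cand_key %in% used)
    uv_idx <- sample(which(free), n_uv, prob = w_cand[free])
    uv <- cand[uv_idx, , drop = FALSE]
    uv_anc <- ifelse(uv$strand == "+", "C", "G")
    uv_der <- ifelse(uv$strand == "+", "T", "A")
    uv_df <- data.frame(chrom = uv$chrom, pos = uv$pos, ancestral = uv_anc,
                        derived = uv_der, stringsAsFactors = FALSE)
    # background mutations at uniform positions
    n_bg <- n - n_uv
    bg_df <- NULL
    if (n_bg > 0) {
      avail <- lens - 2
      repeat {
        cn <- sample(names(lens), 2 * n_bg, replace = TRUE,
                     prob = avail / sum(avail))
        pos <- 2L + floor(runif(2 * n_bg) * (lens[cn] - 2))
        key <- paste(cn, pos)
        ok <- !(key %in% used) & !(key %in% paste(uv_df$chrom, uv_df$pos)) &
          !duplicated(key)
        if (sum(ok) >= n_bg) break
      }
      cn <- cn[ok][seq_len(n_bg)]; pos <- pos[ok][seq_len(n_bg)]
      anc <- genome_base(sim$genome, cn, as.integer(pos))
      transition_of <- c(A = "G", G = "A", C = "T", T = "C")
      is_ts <- runif(n_bg) < 2 * cfg$transition_fraction
      der <- ifelse(is_ts, transition_of[anc], NA)
      for (i in which(!is_ts)) {
        der[i] <- sample(setdiff(DNA_BASES, c(anc[i], transition_of[anc[i]])),
                         1)
      }
      bg_df <- data.frame(chrom = cn, pos = as.integer(pos), ancestral = anc,
                          derived = unname(der), stringsAsFactors = FALSE)
    }
    df <- rbind(uv_df, bg_df)
    df <- df[order(df$chrom, df$pos), , drop = FALSE]
    rownames(df) <- NULL
    used <- c(used, paste(df$chrom, df$pos))
    m <- nrow(df)

    focal <- groups %in% focal_of[[lab]]
    q_der <- runif(m, cfg$private_derived_freq[1],
                   cfg$private_derived_freq[2])
    geno <- matrix(0L, n_tot, m, dimnames = list(acc, NULL))
    geno[focal, ] <- matrix(rbinom(sum(focal) * m, 1L,
                                   rep(q_der, each = sum(focal))),
                            nrow = sum(focal))
    geno[matrix(runif(n_tot * m) < cfg$missing_rate, n_tot)] <- NA_integer_

    # enforce the private definition exactly per site (vectorized checks)
    check_sites <- function(g) {
      st <- lapply(levels(groups), function(gr) {
        sub <- g[groups == gr, , drop = FALSE]
        list(n = nrow(sub), nonmiss = colSums(!is.na(sub)),
             nder = colSums(sub, na.rm = TRUE))
      })
      names(st) <- levels(groups)
      seg <- function(gr) st[[gr]]$nder > 0 &
        (st[[gr]]$nonmiss - st[[gr]]$nder) > 0
      rate <- function(gr) st[[gr]]$nonmiss >= cfg$min_call_rate * st[[gr]]$n
      seg_ok <- if (lab == "PD") seg("landrace") | seg("improved")
                else seg(focal_of[[lab]])
      seg_ok & rate("wild") & rate("landrace") & rate("improved")
    }
    n_focal <- sum(focal)
    for (attempt in 1:100) {
      bad <- which(!check_sites(geno))
      if (!length(bad)) break
      nb <- length(bad)
      sub <- matrix(0L, n_tot, nb)
      sub[focal, ] <- rbinom(n_focal * nb, 1L, rep(q_der[bad],
                                                   each = n_focal))
      sub[matrix(runif(n_tot * nb) < cfg$missing_rate, n_tot)] <- NA_integer_
      geno[, bad] <- sub
    }

    snps <- data.frame(chrom = df$chrom, pos = df$pos, ref = df$ancestral,
                       alt = df$derived, id = NA_character_,
                       ancestral = df$ancestral, derived = df$derived,
                       stringsAsFactors = FALSE)
    outgroup <- data.frame(chrom = df$chrom, pos = df$pos,
                           allele = ifelse(runif(m) < cfg$outgroup_error,
                                           df$derived, df$ancestral),
                           stringsAsFactors = FALSE)
    out[[lab]] <- list(snps = snps, geno = geno,
                       groups = setNames(groups, acc), outgroup = outgroup)
    truth_uv[lab] <- n_uv
  }
  out$truth <- list(uv_enrichment = cfg$uv_enrichment,
                    uv_base_rate = cfg$uv_base_rate,
                    uv_meth_weight = cfg$uv_meth_weight,
                    n_uv_planted = truth_uv,
                    uv_classes = c("TCG>TTG", "CCG>CTG"),
                    set_sizes = set_sizes, seed = cfg$seed)
  out
}

#' Random SNPs at uniform positions (for null calibrations)
#'
#' Places \code{n} distinct positions uniformly at random on the genome;
#' the reference allele is the genome base and the alternate allele is drawn
#' uniformly from the three other bases, so substitution types follow the
#' uniform allele-pair null.
#'
#' @param genome named character vector of chromosome sequences.
#' @param n number of SNPs.
#' @param seed RNG seed (optional; omit to use the caller's RNG state).
#' @return SNP table.
#' @export
random_snps <- function(genome, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lens <- chrom_lengths(genome)
  cn <- sample(names(lens), 2 * n, replace = TRUE, prob = lens / sum(lens))
  pos <- 1L + floor(runif(2 * n) * lens[cn])
  keep <- !duplicated(paste(cn, pos))
  cn <- cn[keep][seq_len(n)]; pos <- pos[keep][seq_len(n)]
  ref <- genome_base(genome, cn, as.integer(pos))
  alt <- vapply(ref, function(b) sample(setdiff(DNA_BASES, b), 1),
                character(1), USE.NAMES = FALSE)
  sort_snps(data.frame(chrom = cn, pos = as.integer(pos), ref = ref,
                       alt = alt, id = NA_character_,
                       stringsAsFactors = FALSE))
}

#' Write a simulated study to a directory
#'
#' Emits genome.fa, genes.gff3, snps.vcf (+ genotypes), groups.tsv,
#' outgroup.tsv, centromeres.bed, te.bed, sweeps.bed, methylation.tsv,
#' recomb.tsv, private_<SET>.vcf / outgroup_<SET>.tsv, and a flat-text
#' truth.txt with every planted parameter.
#'
#' @param sim [simulate_genome()] result.
#' @param panel [simulate_common_panel()] result.
#' @param private [simulate_private_sets()] result (optional).
#' @param dir output directory (created if needed).
#' @export
write_sim_study <- function(sim, panel, private = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  write_genome_fasta(sim$genome, fp("genome.fa"))
  write_gene_models_gff3(sim$feats, fp("genes.gff3"))
  write_snp_vcf(panel$snps, panel$geno, fp("snps.vcf"))
  write_tsv(data.frame(accession = names(panel$groups),
                       group = as.character(panel$groups)),
            fp("groups.tsv"))
  write_tsv(panel$outgroup, fp("outgroup.tsv"))
  write_bed_track(sim$centromeres, fp("centromeres.bed"))
  write_bed_track(sim$te, fp("te.bed"))
  write_bed_track(sim$sweeps, fp("sweeps.bed"))
  write_tsv(sim$methylation, fp("methylation.tsv"))
  write_tsv(sim$recomb, fp("recomb.tsv"))
  truth <- panel$truth
  if (!is.null(private)) {
    for (lab in c("PW", "PD", "PL", "PI")) {
      s <- private[[lab]]
      write_snp_vcf(s$snps[, c("chrom", "pos", "ref", "alt", "id")],
                    s$geno, fp(paste0("private_", lab, ".vcf")))
      write_tsv(s$outgroup, fp(paste0("outgroup_", lab, ".tsv")))
    }
    truth <- c(truth, private$truth)
  }
  flat <- truth[!vapply(truth, is.null, logical(1))]
  flat <- lapply(flat, function(x) paste(unlist(x), collapse = ","))
  write_run_config(flat, fp("truth.txt"))
  invisible(dir)
}
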