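## Synthetic-data generator: toy genome + gene models + SINE-like repeats,
## planted A-to-I editing sites with per-region true levels, heterozygous SNP
## confounders, sequencing errors, PCR duplicates and hyper-edited reads.
## All randomness derives from SimConfig$rng_seed, so outputs are reproducible
## byte for byte.

SITE_CLASSES <- c("repeat", "intron", "CDS-recoding", "CDS-synonymous",
                  "UTR3", "UTR5")

#' Simulation configuration
#'
#' Defines the study conditions for the synthetic editing landscape: genome
#' geometry, gene architecture, repeat content, planted-site classes and
#' per-region editing-level model, sequencing depths and noise processes.
#'
#' The defaults describe the standard planted-truth fixture used throughout
#' the package: two chromosomes of 200 kb, 60 genes, a quarter of the genome
#' covered by SINE-like repeats, 500 editing sites, 50 heterozygous A/G SNPs,
#' 3 regions with 4 RNA samples each (one per animal), 100-bp strand-specific
#' RNA reads at 60x over genes, DNA at 30x per animal, 0.1% base error, 2%
#' PCR duplicates and 0.5% hyper-edited RNA molecules.
#'
#' @param rng_seed integer seed; all generator randomness derives from it.
#' @param n_chroms,chrom_length genome geometry (bp).
#' @param n_genes,exons_per_gene gene architecture; genes are split evenly
#'   across chromosomes.
#' @param exon_length,intron_length,utr5_length,utr3_length gene part sizes
#'   (bp); CDS length is trimmed to a multiple of 3.
#' @param repeat_fraction target fraction of each chromosome covered by
#'   repeat elements.
#' @param repeat_divergence per-base substitution probability applied to the
#'   subfamily consensus when stamping each repeat copy (keeps copies
#'   uniquely alignable, as aged genomic repeats are).
#' @param n_sites number of planted editing sites.
#' @param class_mix named numeric, proportions of sites per class
#'   (`repeat`, `intron`, `CDS-recoding`, `CDS-synonymous`, `UTR3`, `UTR5`).
#' @param level_model per-class specification of true editing levels; see
#'   [default_level_model()].
#' @param cluster_fraction fraction of repeat-class sites planted in spatial
#'   clusters (3 sites within 100 bp).
#' @param n_regions,samples_per_region pooling groups and RNA samples per
#'   group; each of `samples_per_region` animals contributes one sample per
#'   region, and DNA is sequenced once per animal.
#' @param n_het_snps heterozygous SNPs planted inside genes at reference-A
#'   positions of the transcribed strand (alleles A/G on that strand), the
#'   classic false-positive mimic of an editing site.
#' @param read_length read length (bp).
#' @param rna_depth,dna_depth mean fold-coverage (RNA over gene spans, DNA
#'   genome-wide).
#' @param base_error_rate per-base sequencing error probability.
#' @param low_qual_fraction fraction of bases assigned Phred 20 (below the
#'   Q30 pileup filter); the rest get Phred 40.
#' @param duplicate_rate fraction of reads duplicated as exact PCR copies.
#' @param hyper_read_fraction fraction of RNA reads drawn from hyper-edited
#'   molecules; these are emitted to the unmapped FASTQ, not the SAM.
#' @param hyper_edit_prob per-A editing probability within a hyper-edited
#'   molecule (>= 0.2 by construction).
#' @return an object of class `SimConfig`.
#' @export
sim_config <- function(rng_seed = 1L,
                       n_chroms = 2L, chrom_length = 200000L,
                       n_genes = 60L, exons_per_gene = 3L,
                       exon_length = 400L, intron_length = 1600L,
                       utr5_length = 150L, utr3_length = 250L,
                       repeat_fraction = 0.25, repeat_divergence = 0.12,
                       n_sites = 500L, class_mix = NULL,
                       level_model = default_level_model(),
                       cluster_fraction = 0.6,
                       n_regions = 3L, samples_per_region = 4L,
                       n_het_snps = 50L,
                       read_length = 100L,
                       rna_depth = 60, dna_depth = 30,
                       base_error_rate = 0.001,
                       low_qual_fraction = 0.05,
                       duplicate_rate = 0.02,
                       hyper_read_fraction = 0.005,
                       hyper_edit_prob = 0.3) {
  if (is.null(class_mix)) {
    class_mix <- c("repeat" = 0.55, intron = 0.25, "CDS-recoding" = 0.06,
                   "CDS-synonymous" = 0.03, UTR3 = 0.08, UTR5 = 0.03)
  }
  cfg <- list(rng_seed = as.integer(rng_seed),
              n_chroms = as.integer(n_chroms),
              chrom_length = as.integer(chrom_length),
              n_genes = as.integer(n_genes),
              exons_per_gene = as.integer(exons_per_gene),
              exon_length = as.integer(exon_length),
              intron_length = as.integer(intron_length),
              utr5_length = as.integer(utr5_length),
              utr3_length = as.integer(utr3_length),
              repeat_fraction = repeat_fraction,
              repeat_divergence = repeat_divergence,
              n_sites = as.integer(n_sites),
              class_mix = class_mix,
              level_model = level_model,
              cluster_fraction = cluster_fraction,
              n_regions = as.integer(n_regions),
              samples_per_region = as.integer(samples_per_region),
              n_het_snps = as.integer(n_het_snps),
              read_length = as.integer(read_length),
              rna_depth = rna_depth, dna_depth = dna_depth,
              base_error_rate = base_error_rate,
              low_qual_fraction = low_qual_fraction,
              duplicate_rate = duplicate_rate,
              hyper_read_fraction = hyper_read_fraction,
              hyper_edit_prob = hyper_edit_prob)
  counts <- c("n_chroms", "chrom_length", "n_genes", "exons_per_gene",
              "n_sites", "n_regions", "samples_per_region", "n_het_snps",
              "read_length")
  for (f in counts)
    if (cfg[[f]] < 0L) stopf("SimConfig: %s must be >= 0", f)
  props <- c("repeat_fraction", "base_error_rate", "duplicate_rate",
             "hyper_read_fraction", "low_qual_fraction", "cluster_fraction")
  for (f in props)
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stopf("SimConfig: %s must be in [0,1]", f)
  if (cfg$chrom_length < 10L * cfg$read_length)
    stopf("SimConfig: chrom_length must be >= 10 * read_length")
  if (abs(sum(class_mix) - 1) > 1e-6)
    stopf("SimConfig: class_mix must sum to 1")
  structure(cfg, class = "SimConfig")
}

#' Default per-class editing-level model
#'
#' Most planted sites are lowly edited (Beta(1,9), mean 0.1), mirroring the
#' low-level bulk of repeat and intronic editing in mammalian brain, while a
#' fraction of CDS-recoding sites is nearly fully edited (level 0.995),
#' emulating essential recoding events of the GRIA2 Q/R kind. Each class
#' entry may instead use `dist = "fixed"` with `value`, or set
#' `region_spec = "enriched"` with `enriched_level`/`background_level` to
#' plant region-specific sites (one target region per site, chosen at
#' random).
#'
#' @return named list of per-class level specifications.
#' @export
default_level_model <- function() {
  low <- list(dist = "beta", shape1 = 1, shape2 = 9)
  mid <- list(dist = "beta", shape1 = 1, shape2 = 4)
  list("repeat" = low,
       intron = low,
       "CDS-recoding" = list(dist = "mixture", high_fraction = 0.2,
                             high_level = 0.995, shape1 = 2, shape2 = 5),
       "CDS-synonymous" = mid,
       UTR3 = mid,
       UTR5 = mid)
}

#' @export
print.SimConfig <- function(x, ...) {
  cat(sprintf("SimConfig: %d chrom(s) x %d bp, %d genes, %d sites, %d regions x %d samples, seed %d\n",
              x$n_chroms, x$chrom_length, x$n_genes, x$n_sites,
              x$n_regions, x$samples_per_region, x$rng_seed))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Reference generation

REPEAT_SUBFAMS <- data.frame(
  name = c("SINE/tRNA:Pre0_SS", "SINE/tRNA:PRE1f", "SINE/tRNA:PRE1f2",
           "SINE/tRNA:PRE1g", "SINE/tRNA:PRE1e", "LINE/L1:L1_SS"),
  weight = c(0.50, 0.15, 0.08, 0.05, 0.04, 0.18),
  length = c(246L, 246L, 246L, 246L, 246L, 500L),
  stringsAsFactors = FALSE)

random_seq <- function(n) {
  if (n == 0L) return("")
  intToUtf8(utf8ToInt("ACGT")[sample.int(4L, n, replace = TRUE)])
}

## random coding sequence: ATG + non-stop codons + TAA, length divisible by 3
random_cds <- function(len) {
  stopifnot(len %% 3L == 0L, len >= 9L)
  codons <- apply(expand.grid(BASES, BASES, BASES), 1L, paste0, collapse = "")
  codons <- setdiff(codons, c("TAA", "TAG", "TGA"))
  body <- sample(codons, len / 3L - 2L, replace = TRUE)
  paste0("ATG", paste(body, collapse = ""), "TAA")
}

#' Generate a toy reference genome with gene models and repeats
#'
#' Builds random chromosome sequences, stamps protein-coding genes (UTR5 /
#' multi-exon CDS / UTR3, valid reading frame, alternating strands) onto
#' them, and tiles diverged copies of SINE/LINE-like repeat consensi over
#' non-exonic space until the configured genome fraction is covered.
#' Deterministic for a fixed `rng_seed`.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `GenomeBundle`: `genome` (named character
#'   vector of chromosome sequences), `genes`, `features` (exon/CDS/UTR
#'   intervals, 0-based half-open) and `repeats` data frames.
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$rng_seed)
  E <- config$exons_per_gene
  span <- E * config$exon_length + (E - 1L) * config$intron_length
  per_chrom <- rep(config$n_genes %/% config$n_chroms, config$n_chroms)
  extra <- config$n_genes %% config$n_chroms
  if (extra > 0L) per_chrom[seq_len(extra)] <- per_chrom[seq_len(extra)] + 1L
  if (any(per_chrom * span + (per_chrom + 1L) * 100L > config$chrom_length))
    stopf("generate_reference: %d genes of span %d bp do not fit in a %d bp chromosome",
          max(per_chrom), span, config$chrom_length)

  chrom_names <- sprintf("chr%d", seq_len(config$n_chroms))
  genome <- character(config$n_chroms)
  names(genome) <- chrom_names
  genes_l <- list(); feat_l <- list(); reps_l <- list()
  gi <- 0L

  for (ci in seq_len(config$n_chroms)) {
    genome[ci] <- random_seq(config$chrom_length)
    ng <- per_chrom[ci]
    if (ng > 0L) {
      gap <- (config$chrom_length - ng * span) %/% (ng + 1L)
      starts <- gap + (seq_len(ng) - 1L) * (span + gap)
      for (g in seq_len(ng)) {
        gi <- gi + 1L
        gid <- sprintf("G%04d", gi)
        tid <- paste0(gid, ".t1")
        strand <- if (gi %% 2L == 1L) "+" else "-"
        gs <- starts[g]
        ex_starts <- gs + (seq_len(E) - 1L) * (config$exon_length + config$intron_length)
        ex_ends <- ex_starts + config$exon_length
        ## transcript-order exon list (5' -> 3')
        ord <- if (strand == "+") seq_len(E) else rev(seq_len(E))
        exonic <- E * config$exon_length
        cds_len <- exonic - config$utr5_length - config$utr3_length
        cds_len <- cds_len - (cds_len %% 3L)
        utr3_len <- exonic - config$utr5_length - cds_len
        ## split transcript-coordinate ranges into genomic part intervals
        parts <- data.frame(type = c("UTR5", "CDS", "UTR3"),
                            tstart = c(0L, config$utr5_length,
                                       config$utr5_length + cds_len),
                            tlen = c(config$utr5_length, cds_len, utr3_len))
        off <- 0L
        for (e in ord) {
          elen <- config$exon_length
          for (p in seq_len(nrow(parts))) {
            lo <- max(parts$tstart[p], off)
            hi <- min(parts$tstart[p] + parts$tlen[p], off + elen)
            if (hi <= lo) next
            if (strand == "+") {
              s0 <- ex_starts[e] + (lo - off); e0 <- ex_starts[e] + (hi - off)
            } else {
              e0 <- ex_ends[e] - (lo - off); s0 <- ex_ends[e] - (hi - off)
            }
            feat_l[[length(feat_l) + 1L]] <- data.frame(
              chrom = chrom_names[ci], start0 = s0, end = e0, strand = strand,
              type = parts$type[p], gene_id = gid, transcript_id = tid,
              stringsAsFactors = FALSE)
          }
          off <- off + elen
        }
        for (e in seq_len(E)) {
          feat_l[[length(feat_l) + 1L]] <- data.frame(
            chrom = chrom_names[ci], start0 = ex_starts[e], end = ex_ends[e],
            strand = strand, type = "exon", gene_id = gid,
            transcript_id = tid, stringsAsFactors = FALSE)
        }
        genes_l[[length(genes_l) + 1L]] <- data.frame(
          chrom = chrom_names[ci], start0 = gs, end = gs + span,
          strand = strand, gene_id = gid, transcript_id = tid,
          stringsAsFactors = FALSE)
        ## write a valid coding sequence into the CDS intervals
        cds_seq <- random_cds(cds_len)
        cds_iv <- Filter(function(f) f$type == "CDS", feat_l)
        cds_iv <- do.call(rbind, cds_iv)
        cds_iv <- cds_iv[cds_iv$transcript_id == tid, , drop = FALSE]
        cds_iv <- cds_iv[order(if (strand == "+") cds_iv$start0 else -cds_iv$start0), ]
        off <- 0L
        for (p in seq_len(nrow(cds_iv))) {
          w <- cds_iv$end[p] - cds_iv$start0[p]
          piece <- substr(cds_seq, off + 1L, off + w)
          if (strand == "-") piece <- revcomp(piece)
          substr(genome[ci], cds_iv$start0[p] + 1L, cds_iv$end[p]) <- piece
          off <- off + w
        }
      }
    }
    ## tile repeats over non-exonic space
    if (config$repeat_fraction > 0) {
      exons <- do.call(rbind, Filter(function(f)
        f$type == "exon" && f$chrom == chrom_names[ci], feat_l))
      reps <- tile_repeats(config, chrom_names[ci], config$chrom_length, exons)
      if (!is.null(reps) && nrow(reps) > 0L) {
        for (p in seq_len(nrow(reps)))
          substr(genome[ci], reps$start0[p] + 1L, reps$end[p]) <- reps$seq[p]
        reps$seq <- NULL
        reps_l[[length(reps_l) + 1L]] <- reps
      }
    }
  }

  bundle <- list(genome = genome,
                 genes = if (length(genes_l)) do.call(rbind, genes_l) else
                   data.frame(),
                 features = if (length(feat_l)) do.call(rbind, feat_l) else
                   data.frame(),
                 repeats = if (length(reps_l)) do.call(rbind, reps_l) else
                   data.frame(chrom = character(), start0 = integer(),
                              end = integer(), strand = character(),
                              name = character(), stringsAsFactors = FALSE))
  rownames(bundle$genes) <- rownames(bundle$features) <- NULL
  if (nrow(bundle$repeats)) rownames(bundle$repeats) <- NULL
  structure(bundle, class = "GenomeBundle")
}

tile_repeats <- function(config, chrom, chrom_len, exons) {
  sub <- REPEAT_SUBFAMS
  consensi <- vapply(sub$length, random_seq, character(1))
  target <- config$repeat_fraction * chrom_len
  ## non-exonic intervals
  if (!is.null(exons) && nrow(exons) > 0L) {
    ex <- exons[order(exons$start0), ]
    free_s <- c(0L, ex$end); free_e <- c(ex$start0, chrom_len)
  } else {
    free_s <- 0L; free_e <- chrom_len
  }
  keep <- free_e - free_s > max(sub$length) + 10L
  free_s <- free_s[keep]; free_e <- free_e[keep]
  avail <- sum(free_e - free_s)
  mean_rep <- sum(sub$weight * sub$length)
  frac_needed <- min(1, target / max(avail, 1))
  mean_gap <- max(10, mean_rep * (1 / max(frac_needed, 1e-6) - 1))
  out <- list(); placed <- 0
  for (iv in seq_along(free_s)) {
    pos <- free_s[iv] + ceiling(runif(1, 0, mean_gap))
    while (placed < target) {
      fam <- sample.int(nrow(sub), 1L, prob = sub$weight)
      len <- sub$length[fam]
      if (pos + len > free_e[iv]) break
      cons <- consensi[fam]
      nmut <- rbinom(1L, len, config$repeat_divergence)
      if (nmut > 0L) {
        at <- sample.int(len, nmut)
        for (m in at) {
          old <- substr(cons, m, m)
          substr(cons, m, m) <- sample(setdiff(BASES, old), 1L)
        }
      }
      strand <- sample(c("+", "-"), 1L)
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start0 = pos, end = pos + len, strand = strand,
        name = sub$name[fam],
        seq = if (strand == "+") cons else revcomp(cons),
        stringsAsFactors = FALSE)
      placed <- placed + len
      pos <- pos + len + ceiling(runif(1, 0, 2 * mean_gap))
    }
    if (placed >= target) break
  }
  if (length(out)) do.call(rbind, out) else NULL
}

#' @export
print.GenomeBundle <- function(x, ...) {
  cat(sprintf("GenomeBundle: %d chrom(s), %s bp, %d genes, %d repeat elements\n",
              length(x$genome), format(sum(nchar(x$genome)), big.mark = ","),
              nrow(x$genes), nrow(x$repeats)))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Truth planting

## positions (0-based) of reference base `base` within [s0, e0) of chrom seq
base_positions <- function(seqstr, s0, e0, base) {
  if (e0 <= s0) return(integer())
  sub <- substr(seqstr, s0 + 1L, e0)
  m <- gregexpr(base, sub, fixed = TRUE)[[1]]
  if (m[1] == -1L) integer() else as.integer(m) - 1L + s0
}

sample_levels <- function(spec, n, n_regions) {
  dist <- spec$dist %||% "beta"
  base <- switch(dist,
    beta = rbeta(n, spec$shape1, spec$shape2),
    fixed = rep(spec$value, n),
    mixture = {
      hi <- runif(n) < spec$high_fraction
      v <- rbeta(n, spec$shape1, spec$shape2)
      v[hi] <- spec$high_level
      v
    },
    stopf("unknown level distribution '%s'", dist))
  base <- pmin(pmax(base, 0), 1)
  region_spec <- spec$region_spec %||% "shared"
  if (region_spec == "shared") {
    matrix(rep(base, n_regions), nrow = n)
  } else if (region_spec == "enriched") {
    m <- matrix(spec$background_level %||% 0.05, n, n_regions)
    tgt <- sample.int(n_regions, n, replace = TRUE)
    m[cbind(seq_len(n), tgt)] <- spec$enriched_level %||% 0.5
    m
  } else stopf("unknown region_spec '%s'", region_spec)
}

#' Plant ground-truth editing sites and SNP confounders
#'
#' Chooses reference-A positions (on the transcribed strand) for each site
#' class -- clustered sites inside intronic repeat elements, dispersed
#' intronic sites, recoding and synonymous CDS sites (verified against the
#' genetic code), UTR sites -- and draws per-region true editing levels from
#' the configured level model. Heterozygous A/G SNPs are planted at gene
#' positions disjoint from the sites. At least one CDS-recoding site is
#' guaranteed a true level >= 0.99 in all regions.
#'
#' @param bundle a [generate_reference()] result.
#' @param config the same [sim_config()] object.
#' @return an object of class `TruthSet`: `sites` (site_id, chrom, pos0,
#'   strand, class, ref_fwd), `levels` (sites x regions matrix), `het_snps`,
#'   and region names. `hyper_reads` is filled in by [simulate_reads()].
#' @export
plant_truth <- function(bundle, config) {
  stopifnot(inherits(bundle, "GenomeBundle"), inherits(config, "SimConfig"))
  set.seed(config$rng_seed + 1L)
  n_per <- round(config$class_mix * config$n_sites)
  n_per[1L] <- config$n_sites - sum(n_per[-1L])  # absorb rounding
  genes <- bundle$genes
  feats <- bundle$features

  ## candidate pools of (chrom, pos0, strand) per class
  pool <- function(class) {
    out <- list()
    for (g in seq_len(nrow(genes))) {
      strand <- genes$strand[g]
      want <- if (strand == "+") "A" else "T"
      chrom <- genes$chrom[g]
      seqstr <- bundle$genome[[chrom]]
      f <- feats[feats$gene_id == genes$gene_id[g], ]
      ex <- f[f$type == "exon", ]
      ivs <- switch(class,
        "CDS-recoding" = , "CDS-synonymous" = f[f$type == "CDS", c("start0", "end")],
        UTR3 = f[f$type == "UTR3", c("start0", "end")],
        UTR5 = f[f$type == "UTR5", c("start0", "end")],
        { # intron: gene span minus exons
          ex <- ex[order(ex$start0), ]
          data.frame(start0 = ex$end[-nrow(ex)], end = ex$start0[-1L])
        })
      for (p in seq_len(nrow(ivs))) {
        pos <- base_positions(seqstr, ivs$start0[p], ivs$end[p], want)
        if (length(pos))
          out[[length(out) + 1L]] <- data.frame(chrom = chrom, pos0 = pos,
                                                strand = strand,
                                                gene_id = genes$gene_id[g],
                                                stringsAsFactors = FALSE)
      }
    }
    if (length(out)) do.call(rbind, out) else
      data.frame(chrom = character(), pos0 = integer(), strand = character(),
                 gene_id = character(), stringsAsFactors = FALSE)
  }

  used <- character()  # "chrom:pos0" keys
  take <- function(df, n, class) {
    df <- df[!paste(df$chrom, df$pos0) %in% used, , drop = FALSE]
    if (nrow(df) < n)
      stopf("plant_truth: only %d candidate A positions for class '%s' (need %d)",
            nrow(df), class, n)
    df <- df[sample.int(nrow(df), n), , drop = FALSE]
    used <<- c(used, paste(df$chrom, df$pos0))
    df$class <- class
    df
  }

  picked <- list()

  ## repeat-class sites: inside intronic repeat elements, partly clustered
  if (n_per[["repeat"]] > 0L) {
    reps <- bundle$repeats
    intr <- pool("intron")
    key <- paste(intr$chrom, intr$pos0)
    in_rep <- rep(FALSE, nrow(intr))
    for (ci in unique(reps$chrom)) {
      ri <- reps[reps$chrom == ci, ]
      ii <- which(intr$chrom == ci)
      if (!length(ii) || !nrow(ri)) next
      ord <- order(ri$start0)
      fi <- findInterval(intr$pos0[ii], ri$start0[ord])
      ok <- fi > 0L & intr$pos0[ii] < ri$end[ord][pmax(fi, 1L)]
      in_rep[ii][ok] <- TRUE
    }
    rp <- intr[in_rep, , drop = FALSE]
    n_rep <- n_per[["repeat"]]
    n_clust3 <- floor(config$cluster_fraction * n_rep / 3)
    chosen <- list()
    if (n_clust3 > 0L) {
      ## anchor positions with >= 2 classmates within the following 100 bp
      rp_o <- rp[order(rp$chrom, rp$pos0), ]
      n_o <- nrow(rp_o)
      anchors <- if (n_o >= 3L) {
        i <- seq_len(n_o - 2L)
        i[rp_o$chrom[i] == rp_o$chrom[i + 2L] &
          rp_o$pos0[i + 2L] - rp_o$pos0[i] <= 100L]
      } else integer()
      if (length(anchors) < n_clust3)
        stopf("plant_truth: not enough clusterable repeat A positions")
      sel <- sort(sample(anchors, n_clust3))
      ## drop anchors whose triples overlap
      keep <- c(TRUE, diff(sel) >= 3L)
      sel <- sel[keep]
      idx <- unique(as.vector(outer(sel, 0:2, `+`)))
      cl1 <- rp_o[idx, , drop = FALSE]
      cl1$class <- "repeat"
      chosen[[1L]] <- cl1
      used <- c(used, paste(cl1$chrom, cl1$pos0))
    }
    n_left <- n_rep - sum(vapply(chosen, nrow, 1L))
    if (n_left > 0L) chosen[[length(chosen) + 1L]] <- take(rp, n_left, "repeat")
    rp_sites <- do.call(rbind, chosen)
    rp_sites$class <- "repeat"
    picked[["repeat"]] <- rp_sites
  }

  if (n_per[["intron"]] > 0L)
    picked[["intron"]] <- take(pool("intron"), n_per[["intron"]], "intron")

  ## CDS sites: split A positions by recoding consequence
  cds_pool <- pool("CDS-recoding")
  need_cds <- 40L * (n_per[["CDS-recoding"]] + n_per[["CDS-synonymous"]]) + 200L
  if (nrow(cds_pool) > need_cds)
    cds_pool <- cds_pool[sort(sample.int(nrow(cds_pool), need_cds)), ]
  if (nrow(cds_pool)) {
    syn <- logical(nrow(cds_pool))
    for (i in seq_len(nrow(cds_pool))) {
      eff <- recoding_effect(list(chrom = cds_pool$chrom[i],
                                  pos0 = cds_pool$pos0[i],
                                  strand = cds_pool$strand[i]),
                             bundle, cds_pool$gene_id[i])
      syn[i] <- isTRUE(eff$is_synonymous)
    }
    if (n_per[["CDS-recoding"]] > 0L)
      picked[["CDS-recoding"]] <- take(cds_pool[!syn, , drop = FALSE],
                                       n_per[["CDS-recoding"]], "CDS-recoding")
    if (n_per[["CDS-synonymous"]] > 0L)
      picked[["CDS-synonymous"]] <- take(cds_pool[syn, , drop = FALSE],
                                         n_per[["CDS-synonymous"]],
                                         "CDS-synonymous")
  } else if (n_per[["CDS-recoding"]] > 0L || n_per[["CDS-synonymous"]] > 0L) {
    stopf("plant_truth: no CDS A positions available")
  }
  if (n_per[["UTR3"]] > 0L)
    picked[["UTR3"]] <- take(pool("UTR3"), n_per[["UTR3"]], "UTR3")
  if (n_per[["UTR5"]] > 0L)
    picked[["UTR5"]] <- take(pool("UTR5"), n_per[["UTR5"]], "UTR5")

  sites <- do.call(rbind, picked)
  rownames(sites) <- NULL
  sites$site_id <- sprintf("S%04d", seq_len(nrow(sites)))
  sites$ref_fwd <- ifelse(sites$strand == "+", "A", "T")
  sites <- sites[, c("site_id", "chrom", "pos0", "strand", "class",
                     "gene_id", "ref_fwd")]

  ## per-region true levels
  levels <- matrix(NA_real_, nrow(sites), config$n_regions,
                   dimnames = list(sites$site_id,
                                   sprintf("R%d", seq_len(config$n_regions))))
  for (cl in unique(sites$class)) {
    idx <- which(sites$class == cl)
    spec <- config$level_model[[cl]]
    if (is.null(spec)) spec <- list(dist = "beta", shape1 = 1, shape2 = 9)
    levels[idx, ] <- sample_levels(spec, length(idx), config$n_regions)
  }
  rec <- which(sites$class == "CDS-recoding")
  if (length(rec) && !any(apply(levels[rec, , drop = FALSE] >= 0.99, 1L, all)))
    levels[rec[1L], ] <- 0.995

  ## heterozygous SNP confounders at gene A positions, disjoint from sites
  het <- data.frame(chrom = character(), pos0 = integer(), ref = character(),
                    alt = character(), stringsAsFactors = FALSE)
  if (config$n_het_snps > 0L) {
    cand <- rbind(pool("intron"), cds_pool)
    cand <- cand[!paste(cand$chrom, cand$pos0) %in% used, , drop = FALSE]
    if (nrow(cand) < config$n_het_snps)
      stopf("plant_truth: not enough positions for het SNPs")
    cand <- cand[sample.int(nrow(cand), config$n_het_snps), ]
    ref <- ifelse(cand$strand == "+", "A", "T")
    het <- data.frame(chrom = cand$chrom, pos0 = cand$pos0, ref = ref,
                      alt = ifelse(ref == "A", "G", "C"),
                      stringsAsFactors = FALSE)
    rownames(het) <- NULL
  }

  structure(list(sites = sites, levels = levels, het_snps = het,
                 regions = colnames(levels),
                 hyper_reads = data.frame(read_id = character(),
                                          sample_id = character(),
                                          chrom = character(),
                                          start0 = integer(),
                                          strand = character(),
                                          stringsAsFactors = FALSE)),
            class = "TruthSet")
}

#' @export
print.TruthSet <- function(x, ...) {
  cat(sprintf("TruthSet: %d sites (%s), %d het SNPs, %d regions\n",
              nrow(x$sites),
              paste(names(table(x$sites$class)), table(x$sites$class),
                    sep = "=", collapse = ", "),
              nrow(x$het_snps), length(x$regions)))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Read simulation

apply_subst <- function(seqs, idx, offsets, bases) {
  ## elementwise substr<- with possibly repeated read indices: process in
  ## rounds so later hits to the same read are not lost
  if (!length(idx)) return(seqs)
  rank <- ave(seq_along(idx), idx, FUN = seq_along)
  for (r in seq_len(max(rank))) {
    k <- rank == r
    s <- seqs[idx[k]]
    substr(s, offsets[k], offsets[k]) <- bases[k]
    seqs[idx[k]] <- s
  }
  seqs
}

sim_one_sample <- function(bundle, truth, config, sample_id, region_idx,
                           layer = c("RNA", "DNA")) {
  layer <- match.arg(layer)
  L <- config$read_length
  chrom_names <- names(bundle$genome)
  chrom_len <- nchar(bundle$genome)

  if (layer == "RNA") {
    g <- bundle$genes
    n_per_gene <- rpois(nrow(g), config$rna_depth * (g$end - g$start0) / L)
    gene_idx <- rep(seq_len(nrow(g)), n_per_gene)
    n <- length(gene_idx)
    start0 <- g$start0[gene_idx] +
      floor(runif(n) * (g$end[gene_idx] - g$start0[gene_idx] - L + 1L))
    chrom <- g$chrom[gene_idx]
    strand <- g$strand[gene_idx]
  } else {
    n_per_chrom <- rpois(length(chrom_len), config$dna_depth * chrom_len / L)
    chrom <- rep(chrom_names, n_per_chrom)
    n <- length(chrom)
    start0 <- floor(runif(n) * (chrom_len[chrom] - L + 1L))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    gene_idx <- rep(NA_integer_, n)
  }
  ord <- order(match(chrom, chrom_names), start0)
  chrom <- chrom[ord]; start0 <- as.integer(start0[ord])
  strand <- strand[ord]; gene_idx <- gene_idx[ord]

  seqs <- character(n)
  for (ci in chrom_names) {
    k <- chrom == ci
    seqs[k] <- substring(bundle$genome[[ci]], start0[k] + 1L, start0[k] + L)
  }

  ## het SNP alleles, ~50/50 per read (both layers: the SNP is genomic)
  het <- truth$het_snps
  for (i in seq_len(nrow(het))) {
    k <- which(chrom == het$chrom[i] & start0 > het$pos0[i] - L &
               start0 <= het$pos0[i])
    if (!length(k)) next
    carry <- k[runif(length(k)) < 0.5]
    if (length(carry))
      seqs <- apply_subst(seqs, carry, het$pos0[i] - start0[carry] + 1L,
                          rep(het$alt[i], length(carry)))
  }

  hyper <- integer()
  if (layer == "RNA") {
    n_hyper <- round(config$hyper_read_fraction * n)
    if (n_hyper > 0L) hyper <- sample.int(n, n_hyper)
    is_hyper <- rep(FALSE, n); is_hyper[hyper] <- TRUE

    ## planted editing: per covering read, Bernoulli(true level of region)
    sites <- truth$sites
    lv <- truth$levels[, region_idx]
    for (ci in chrom_names) {
      k <- which(chrom == ci & !is_hyper)
      if (!length(k)) next
      st <- start0[k]
      si <- which(sites$chrom == ci)
      for (s in si) {
        p0 <- sites$pos0[s]
        lo <- findInterval(p0 - L, st) + 1L
        hi <- findInterval(p0, st)
        if (hi < lo) next
        cover <- k[lo:hi]
        edited <- cover[runif(length(cover)) < lv[s]]
        if (!length(edited)) next
        newb <- if (sites$strand[s] == "+") "G" else "C"
        seqs <- apply_subst(seqs, edited, p0 - start0[edited] + 1L,
                            rep(newb, length(edited)))
      }
    }
    ## hyper-edited molecules: every transcribed-strand A edited with
    ## probability hyper_edit_prob
    for (h in hyper) {
      want <- if (strand[h] == "+") "A" else "T"
      newb <- if (strand[h] == "+") "G" else "C"
      s <- seqs[h]
      av <- base_positions(s, 0L, nchar(s), want) + 1L
      at <- av[runif(length(av)) < config$hyper_edit_prob]
      ## a hyper-edited molecule has >= 20% of its As edited (and enough
      ## edits to be recoverable); top up when the Bernoulli draw fell short
      min_ed <- min(length(av), max(5L, ceiling(0.2 * length(av))))
      if (length(at) < min_ed) {
        extra <- setdiff(av, at)
        at <- c(at, extra[sample.int(length(extra), min_ed - length(at))])
      }
      for (o in at) substr(s, o, o) <- newb
      seqs[h] <- s
    }
  }

  ## sequencing errors
  if (config$base_error_rate > 0) {
    n_err <- rbinom(1L, n * L, config$base_error_rate)
    if (n_err > 0L) {
      ri <- sample.int(n, n_err, replace = TRUE)
      off <- sample.int(L, n_err, replace = TRUE)
      old <- substr(seqs[ri], off, off)
      shift <- sample.int(3L, n_err, replace = TRUE)
      newb <- BASES[(match(old, BASES) - 1L + shift) %% 4L + 1L]
      seqs <- apply_subst(seqs, ri, off, newb)
    }
  }

  ## qualities: Phred 40 ('I'), a configurable fraction at Phred 20 ('5')
  qcodes <- rep(73L, n * L)
  qcodes[runif(n * L) < config$low_qual_fraction] <- 53L
  quals <- chunk_string(intToUtf8(qcodes), L, n)

  read_id <- sprintf("%s_%07d", sample_id, seq_len(n))
  aln <- data.frame(read_id = read_id, chrom = chrom, start0 = start0,
                    strand = strand, seq = seqs, qual = quals, mapq = 60L,
                    stringsAsFactors = FALSE)

  unmapped <- NULL
  if (length(hyper)) {
    h <- aln[hyper, ]
    ## emit in read orientation (reverse strand reads are reverse-complemented)
    minus <- h$strand == "-"
    h$seq[minus] <- revcomp(h$seq[minus])
    h$qual[minus] <- vapply(strsplit(h$qual[minus], ""), function(q)
      paste(rev(q), collapse = ""), character(1))
    unmapped <- data.frame(read_id = h$read_id, seq = h$seq, qual = h$qual,
                           stringsAsFactors = FALSE)
    hyper_tab <- data.frame(read_id = h$read_id, sample_id = sample_id,
                            chrom = aln$chrom[hyper],
                            start0 = aln$start0[hyper],
                            strand = aln$strand[hyper],
                            stringsAsFactors = FALSE)
    aln <- aln[-hyper, ]
  } else {
    hyper_tab <- data.frame(read_id = character(), sample_id = character(),
                            chrom = character(), start0 = integer(),
                            strand = character(), stringsAsFactors = FALSE)
  }

  ## PCR duplicates: exact copies at identical coordinates
  if (config$duplicate_rate > 0 && nrow(aln) > 0L) {
    n_dup <- round(config$duplicate_rate * nrow(aln))
    if (n_dup > 0L) {
      di <- sample.int(nrow(aln), n_dup)
      dup <- aln[di, ]
      dup$read_id <- paste0(dup$read_id, "_dup")
      aln <- rbind(aln, dup)
      aln <- aln[order(match(aln$chrom, chrom_names), aln$start0,
                       aln$read_id), ]
    }
  }
  rownames(aln) <- NULL
  list(aligned = aln, unmapped = unmapped, hyper = hyper_tab)
}

#' Simulate DNA and RNA reads with confounders
#'
#' Emits pre-aligned single-end reads (ungapped, MAPQ 60): strand-specific
#' RNA reads over gene spans per sample, and genome-wide DNA reads per
#' animal. RNA reads covering a planted site carry G on the edited strand
#' with probability equal to the region's true level, independently per
#' read; DNA and RNA reads carry heterozygous SNP alleles at ~50/50;
#' sequencing errors, sub-Q30 base qualities and exact PCR duplicates are
#' added; hyper-edited molecules are diverted to an unmapped FASTQ table
#' instead of the alignment set.
#'
#' @param bundle,truth,config simulation inputs.
#' @return list with `rna` (named list of per-sample alignment data frames),
#'   `dna` (per-animal), `unmapped` (per-sample FASTQ tables), `samples`
#'   (sample metadata), and `truth` updated with the hyper-edited read
#'   ledger.
#' @export
simulate_reads <- function(bundle, truth, config) {
  stopifnot(inherits(bundle, "GenomeBundle"), inherits(truth, "TruthSet"))
  set.seed(config$rng_seed + 2L)
  samples <- expand.grid(animal = seq_len(config$samples_per_region),
                         region = seq_len(config$n_regions))
  samples <- data.frame(
    sample_id = sprintf("R%d_A%d", samples$region, samples$animal),
    region = sprintf("R%d", samples$region),
    animal = sprintf("A%d", samples$animal),
    stringsAsFactors = FALSE)

  rna <- list(); unmapped <- list(); hyper_l <- list()
  for (i in seq_len(nrow(samples))) {
    r <- sim_one_sample(bundle, truth, config, samples$sample_id[i],
                        match(samples$region[i], truth$regions), "RNA")
    rna[[samples$sample_id[i]]] <- r$aligned
    unmapped[[samples$sample_id[i]]] <- r$unmapped %||%
      data.frame(read_id = character(), seq = character(),
                 qual = character(), stringsAsFactors = FALSE)
    hyper_l[[i]] <- r$hyper
  }
  dna <- list()
  for (a in unique(samples$animal)) {
    d <- sim_one_sample(bundle, truth, config, paste0(a, "_dna"), 1L, "DNA")
    dna[[a]] <- d$aligned
  }
  truth$hyper_reads <- do.call(rbind, hyper_l)
  rownames(truth$hyper_reads) <- NULL
  list(rna = rna, dna = dna, unmapped = unmapped, samples = samples,
       truth = truth)
}
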