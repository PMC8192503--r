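## Two-round A-to-I editing-site identification. Round 1 (de novo) applies,
## per sample: (I) DNA homozygous for the reference with depth >= 10; (II)
## Q30 / end-clip filtered RNA evidence with >= 3 edited reads and level >=
## 5%; (III) a paralog filter realigning the variant-supporting reads and
## requiring >= 50% to map uniquely back to the site; (IV) support in >= 2
## samples. Round 2 re-quantifies every master site in every sample with >=
## 10 covering reads, flagging edited status at >= 1 edited read.

#' Calling thresholds
#'
#' @param dna_min_depth minimum DNA depth for the homozygosity call.
#' @param dna_major_allele_min_frac major-allele fraction required to call
#'   the gDNA homozygous (default 1.0: strict, no non-reference base after
#'   the quality filter).
#' @param rna_quality_min minimum Phred for RNA (and DNA) bases.
#' @param end_clip bases clipped from each aligned RNA read end.
#' @param min_edited_reads_r1 round-1 minimum edited-read count.
#' @param min_level_r1 round-1 minimum editing level.
#' @param blat_qualifying_min_frac minimum fraction of variant reads that
#'   realign uniquely to the site locus.
#' @param min_samples samples that must independently qualify a site.
#' @param r2_min_total round-2 minimum total (A+G) coverage.
#' @param r2_min_edited round-2 minimum edited reads for the edited flag.
#' @param known_min_total coverage floor for "known-site" calling against
#'   external samples (default 4).
#' @param max_mismatch_frac,k realignment parameters for the paralog filter.
#' @return object of class `CallConfig`.
#' @export
call_config <- function(dna_min_depth = 10L, dna_major_allele_min_frac = 1.0,
                        rna_quality_min = 30L, end_clip = 6L,
                        min_edited_reads_r1 = 3L, min_level_r1 = 0.05,
                        blat_qualifying_min_frac = 0.5, min_samples = 2L,
                        r2_min_total = 10L, r2_min_edited = 1L,
                        known_min_total = 4L, max_mismatch_frac = 0.1,
                        k = 16L) {
  cfg <- list(dna_min_depth = as.integer(dna_min_depth),
              dna_major_allele_min_frac = dna_major_allele_min_frac,
              rna_quality_min = as.integer(rna_quality_min),
              end_clip = as.integer(end_clip),
              min_edited_reads_r1 = as.integer(min_edited_reads_r1),
              min_level_r1 = min_level_r1,
              blat_qualifying_min_frac = blat_qualifying_min_frac,
              min_samples = as.integer(min_samples),
              r2_min_total = as.integer(r2_min_total),
              r2_min_edited = as.integer(r2_min_edited),
              known_min_total = as.integer(known_min_total),
              max_mismatch_frac = max_mismatch_frac, k = as.integer(k))
  fr <- c(cfg$dna_major_allele_min_frac, cfg$min_level_r1,
          cfg$blat_qualifying_min_frac)
  if (any(fr < 0 | fr > 1)) stopf("call_config: fractions must be in [0,1]")
  structure(cfg, class = "CallConfig")
}

#' Test gDNA homozygosity at one position
#'
#' @param dna_counts named counts for A, C, G, T (quality-filtered).
#' @param cfg a [call_config()].
#' @return list with `homozygous` and `major_allele`.
#' @export
is_dna_homozygous <- function(dna_counts, cfg = call_config()) {
  dna_counts <- dna_counts[BASES]
  depth <- sum(dna_counts)
  if (depth == 0L) return(list(homozygous = FALSE, major_allele = NA_character_))
  major <- which.max(dna_counts)
  list(homozygous = depth >= cfg$dna_min_depth &&
         dna_counts[major] / depth >= cfg$dna_major_allele_min_frac,
       major_allele = BASES[major])
}

#' Assign edited strand and mismatch type
#'
#' Strand is the annotated gene strand when the site lies in exactly one
#' gene span; for intergenic or ambiguous sites, the strand under which the
#' mismatch reads A-to-G is preferred, else "+". The mismatch type is
#' expressed on the edited strand (a genomic T>C inside a minus-strand gene
#' is A-to-G).
#'
#' @param chrom,pos0 site position (0-based).
#' @param ref_base,variant_base forward-genome bases.
#' @param genes gene table (`chrom`, `start0`, `end`, `strand`).
#' @return list with `edited_strand` and `mismatch_type`.
#' @export
classify_mismatch <- function(chrom, pos0, ref_base, variant_base, genes) {
  hit <- which(genes$chrom == chrom & genes$start0 <= pos0 & pos0 < genes$end)
  strand <- if (length(hit) == 1L) {
    genes$strand[hit]
  } else if (ref_base == "A" && variant_base == "G") {
    "+"
  } else if (ref_base == "T" && variant_base == "C") {
    "-"
  } else "+"
  if (strand == "+") {
    type <- paste0(ref_base, "-to-", variant_base)
  } else {
    type <- paste0(comp_base(ref_base), "-to-", comp_base(variant_base))
  }
  list(edited_strand = strand, mismatch_type = type)
}

## variant-supporting reads at one site: reads whose (quality- and
## clip-filtered) base at the site equals the variant. `aln` must be a
## single-chromosome table sorted by start0.
variant_reads_at <- function(aln, pos0, variant, cfg, maxlen) {
  lo <- findInterval(pos0 - maxlen, aln$start0) + 1L
  hi <- findInterval(pos0, aln$start0)
  if (hi < lo) return(integer())
  k <- lo:hi
  off <- pos0 - aln$start0[k] + 1L
  len <- nchar(aln$seq[k])
  ok <- off >= 1L & off > cfg$end_clip & off <= len - cfg$end_clip
  base <- substr(aln$seq[k], off, off)
  qchar <- substr(aln$qual[k], off, off)
  qual <- rep(-1L, length(k))
  one <- nchar(qchar) == 1L
  if (any(one))
    qual[one] <- utf8ToInt(paste(qchar[one], collapse = "")) - 33L
  k[ok & base == variant & qual >= cfg$rna_quality_min]
}

#' Paralog (misalignment) filter for one site
#'
#' Realigns the variant-supporting reads by seed-and-extend; a read
#' qualifies when its best hit is unique and overlaps the site's original
#' locus. The site passes when qualifying / total >= the configured
#' fraction.
#'
#' @param read_seqs variant-supporting read sequences (forward genome
#'   strand).
#' @param chrom,pos0 site locus.
#' @param index a [seed_index()] over the original genome.
#' @param cfg a [call_config()].
#' @return list with `pass`, `qualifying_fraction`, `n_reads`, and `reason`
#'   when no read could be realigned.
#' @export
paralog_filter <- function(read_seqs, chrom, pos0, index,
                           cfg = call_config()) {
  n <- length(read_seqs)
  if (n == 0L)
    return(list(pass = FALSE, qualifying_fraction = NA_real_, n_reads = 0L,
                reason = "no_realignable_reads"))
  hits <- align_reads(index, read_seqs, cfg$max_mismatch_frac)
  lens <- nchar(read_seqs)
  qual <- logical(n)
  if (nrow(hits)) {
    u <- hits[hits$is_unique, , drop = FALSE]
    at_site <- u$chrom == chrom & u$start0 <= pos0 &
      pos0 < u$start0 + lens[u$read]
    qual[unique(u$read[at_site])] <- TRUE
  }
  frac <- sum(qual) / n
  list(pass = frac >= cfg$blat_qualifying_min_frac,
       qualifying_fraction = frac, n_reads = n, reason = NULL)
}

## vectorised per-sample candidate scan over one chromosome
scan_candidates <- function(rna_m, dna_m, ref_code, cfg) {
  ## rna_m, dna_m: 4 x L count matrices; ref_code: 1..4 per position
  L <- ncol(rna_m)
  idx <- cbind(ref_code, seq_len(L))
  dna_depth <- colSums(dna_m)
  dna_ref <- dna_m[idx]
  dna_ok <- dna_depth >= cfg$dna_min_depth &
    dna_ref / pmax(dna_depth, 1L) >= cfg$dna_major_allele_min_frac
  rna_ref <- rna_m[idx]
  var_m <- rna_m
  var_m[idx] <- -1L
  variant_code <- max.col(t(var_m), ties.method = "first")
  var_count <- var_m[cbind(variant_code, seq_len(L))]
  level <- var_count / pmax(rna_ref + var_count, 1L)
  multi <- colSums(var_m >= cfg$min_edited_reads_r1) >= 2L
  cand <- which(dna_ok & var_count >= cfg$min_edited_reads_r1 &
                level >= cfg$min_level_r1 & !multi & !is.na(ref_code))
  data.frame(pos0 = cand - 1L, ref = BASES[ref_code[cand]],
             variant = BASES[variant_code[cand]],
             edited = var_count[cand],
             total = rna_ref[cand] + var_count[cand],
             level = level[cand], stringsAsFactors = FALSE)
}

#' Round-1 (de novo) editing-site identification
#'
#' Evaluates criteria I-III independently in every sample and admits to the
#' master list the sites qualifying in at least `min_samples` samples.
#'
#' @param samples list of per-sample lists, each with `sample_id`,
#'   `rna_pileup`, `dna_pileup` (both `Pileup`s) and `rna_alignments` (the
#'   de-duplicated reads behind the RNA pileup, used for the paralog
#'   filter).
#' @param bundle the `GenomeBundle` (genome + gene models).
#' @param cfg a [call_config()].
#' @param index optional precomputed [seed_index()] of the genome.
#' @return data frame (master list): `chrom`, `pos0`, `strand`,
#'   `mismatch_type`, `ref_fwd`, `variant_fwd`, `n_supporting_samples`.
#' @export
call_round1 <- function(samples, bundle, cfg = call_config(), index = NULL) {
  if (is.null(index)) index <- seed_index(bundle$genome, cfg$k)
  chrom_names <- names(bundle$genome)
  ref_codes <- lapply(bundle$genome, base_codes)

  per_sample <- list()
  for (s in samples) {
    rows <- list()
    for (ci in chrom_names) {
      cand <- scan_candidates(s$rna_pileup$counts[[ci]],
                              s$dna_pileup$counts[[ci]],
                              ref_codes[[ci]], cfg)
      if (!nrow(cand)) next
      aln <- s$rna_alignments[s$rna_alignments$chrom == ci, , drop = FALSE]
      aln <- aln[order(aln$start0), , drop = FALSE]
      maxlen <- if (nrow(aln)) max(nchar(aln$seq)) else 0L
      keep <- logical(nrow(cand))
      for (i in seq_len(nrow(cand))) {
        vr <- variant_reads_at(aln, cand$pos0[i], cand$variant[i], cfg,
                               maxlen)
        pf <- paralog_filter(aln$seq[vr], ci, cand$pos0[i], index, cfg)
        keep[i] <- isTRUE(pf$pass)
      }
      cand <- cand[keep, , drop = FALSE]
      if (nrow(cand)) { cand$chrom <- ci; rows[[ci]] <- cand }
    }
    per_sample[[s$sample_id]] <- if (length(rows)) do.call(rbind, rows) else
      data.frame(chrom = character(), pos0 = integer(), ref = character(),
                 variant = character(), stringsAsFactors = FALSE)
  }

  all <- do.call(rbind, lapply(names(per_sample), function(sid) {
    d <- per_sample[[sid]]
    if (nrow(d)) cbind(d[, c("chrom", "pos0", "ref", "variant")],
                       sample_id = sid) else NULL
  }))
  if (is.null(all) || nrow(all) == 0L)
    return(data.frame(chrom = character(), pos0 = integer(),
                      strand = character(), mismatch_type = character(),
                      ref_fwd = character(), variant_fwd = character(),
                      n_supporting_samples = integer(),
                      stringsAsFactors = FALSE))
  key <- paste(all$chrom, all$pos0, all$variant)
  tab <- table(key)
  master_keys <- names(tab)[tab >= cfg$min_samples]
  m <- all[!duplicated(key) & key %in% master_keys, , drop = FALSE]
  strand <- character(nrow(m)); mtype <- character(nrow(m))
  for (i in seq_len(nrow(m))) {
    cl <- classify_mismatch(m$chrom[i], m$pos0[i], m$ref[i], m$variant[i],
                            bundle$genes)
    strand[i] <- cl$edited_strand; mtype[i] <- cl$mismatch_type
  }
  out <- data.frame(chrom = m$chrom, pos0 = m$pos0, strand = strand,
                    mismatch_type = mtype, ref_fwd = m$ref,
                    variant_fwd = m$variant,
                    n_supporting_samples = as.integer(tab[paste(m$chrom, m$pos0, m$variant)]),
                    stringsAsFactors = FALSE)
  out <- out[!duplicated(paste(out$chrom, out$pos0, out$strand)), ]
  out <- out[order(match(out$chrom, chrom_names), out$pos0), ]
  rownames(out) <- NULL
  out
}

#' Round-2 per-sample quantification of master sites
#'
#' For every master site with total (ref + variant) coverage of at least
#' `min_total` in a sample, records counts and level and flags edited
#' status at >= `r2_min_edited` edited reads; covered-but-unedited sites
#' are emitted with level 0 so pooled denominators stay correct. Sites
#' below the coverage floor are absent for that sample. Pass
#' `min_total = cfg$known_min_total` for known-site calling against
#' external samples.
#'
#' @param master round-1 master list.
#' @param samples as in [call_round1()] (only `rna_pileup` is used).
#' @param cfg a [call_config()].
#' @param min_total coverage floor (default `cfg$r2_min_total`).
#' @return long data frame: site coordinates plus `sample_id`, `A_count`
#'   (reference base on the edited strand), `G_count` (edited base),
#'   `level`, `edited`.
#' @export
call_round2 <- function(master, samples, cfg = call_config(),
                        min_total = NULL) {
  min_total <- min_total %||% cfg$r2_min_total
  rows <- list()
  ref_i <- match(master$ref_fwd, BASES)
  var_i <- match(master$variant_fwd, BASES)
  for (s in samples) {
    A <- integer(nrow(master)); G <- integer(nrow(master))
    for (ci in unique(master$chrom)) {
      k <- which(master$chrom == ci)
      m <- s$rna_pileup$counts[[ci]]
      A[k] <- m[cbind(ref_i[k], master$pos0[k] + 1L)]
      G[k] <- m[cbind(var_i[k], master$pos0[k] + 1L)]
    }
    tot <- A + G
    keep <- which(tot >= min_total)
    if (!length(keep)) next
    rows[[s$sample_id]] <- data.frame(
      chrom = master$chrom[keep], pos0 = master$pos0[keep],
      strand = master$strand[keep], sample_id = s$sample_id,
      A_count = A[keep], G_count = G[keep], level = G[keep] / tot[keep],
      edited = G[keep] >= cfg$r2_min_edited, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), pos0 = integer(), strand = character(),
               sample_id = character(), A_count = integer(),
               G_count = integer(), level = numeric(), edited = logical(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Assemble per-sample caller inputs from a simulation
#'
#' Convenience constructor: de-duplicates reads, builds RNA (Q30, clip 6)
#' and DNA (Q30, no clip) pileups, optionally recovers hyper-edited reads
#' from the unmapped pool and merges them into the RNA pileup.
#'
#' @param sim result of [simulate_reads()] / [simulate_to_dir()].
#' @param bundle the `GenomeBundle`.
#' @param cfg a [call_config()].
#' @param recover_hyper whether to run hyper-editing recovery first.
#' @param hyper_cfg a [hyper_config()].
#' @return list of per-sample lists suitable for [call_round1()].
#' @export
prepare_samples <- function(sim, bundle, cfg = call_config(),
                            recover_hyper = TRUE,
                            hyper_cfg = hyper_config()) {
  chrom_lengths <- nchar(bundle$genome)
  dna_pile <- lapply(sim$dna, function(a)
    build_pileup(remove_duplicates(a), chrom_lengths, cfg$rna_quality_min,
                 0L, layer = "DNA"))
  idx <- if (recover_hyper) hyper_indexes(bundle$genome, hyper_cfg$k) else NULL
  out <- list()
  for (i in seq_len(nrow(sim$samples))) {
    sid <- sim$samples$sample_id[i]
    aln <- remove_duplicates(sim$rna[[sid]])
    if (recover_hyper && nrow(sim$unmapped[[sid]])) {
      rec <- recover_hyper_edited(sim$unmapped[[sid]], bundle$genome,
                                  hyper_cfg, idx)
      if (nrow(rec$alignments)) {
        aln <- rbind(aln, rec$alignments[, names(aln)])
        aln <- aln[order(match(aln$chrom, names(chrom_lengths)),
                         aln$start0), , drop = FALSE]
      }
    }
    pile <- build_pileup(aln, chrom_lengths, cfg$rna_quality_min,
                         cfg$end_clip, sid, "RNA")
    out[[sid]] <- list(sample_id = sid, region = sim$samples$region[i],
                       animal = sim$samples$animal[i], rna_pileup = pile,
                       dna_pileup = dna_pile[[sim$samples$animal[i]]],
                       rna_alignments = aln)
  }
  out
}

#' Export the master list as a 1-based TSV
#'
#' @param master round-1 master list.
#' @param path output file.
#' @export
write_master_tsv <- function(master, path) {
  out <- data.frame(chrom = master$chrom, pos1 = master$pos0 + 1L,
                    strand = master$strand, mismatch = master$mismatch_type,
                    n_supporting_samples = master$n_supporting_samples)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
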