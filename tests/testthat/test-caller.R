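test_that("gDNA homozygosity requires depth 10 and a clean major allele", {
  cfg <- call_config()
  h <- is_dna_homozygous(c(A = 12L, C = 0L, G = 0L, T = 0L), cfg)
  expect_true(h$homozygous); expect_identical(h$major_allele, "A")
  expect_false(is_dna_homozygous(c(A = 9L, C = 0L, G = 0L, T = 0L),
                                 cfg)$homozygous)   # depth
  expect_false(is_dna_homozygous(c(A = 8L, C = 0L, G = 4L, T = 0L),
                                 cfg)$homozygous)   # heterozygous
  ## relaxed major-allele fraction is configurable
  relaxed <- call_config(dna_major_allele_min_frac = 0.9)
  expect_true(is_dna_homozygous(c(A = 19L, C = 0L, G = 1L, T = 0L),
                                relaxed)$homozygous)
})

test_that("mismatch typing respects gene strand and the A-to-G tie rule", {
  genes <- data.frame(chrom = "chr1", start0 = c(100L, 500L),
                      end = c(300L, 700L), strand = c("-", "+"),
                      gene_id = c("g1", "g2"), stringsAsFactors = FALSE)
  ## genomic T>C inside a minus-strand gene reads A-to-G on "-"
  m <- classify_mismatch("chr1", 150L, "T", "C", genes)
  expect_identical(m$edited_strand, "-")
  expect_identical(m$mismatch_type, "A-to-G")
  ## genomic A>G in a plus-strand gene
  m2 <- classify_mismatch("chr1", 600L, "A", "G", genes)
  expect_identical(m2$edited_strand, "+")
  expect_identical(m2$mismatch_type, "A-to-G")
  ## intergenic T>C resolves to A-to-G on "-" by the tie rule
  m3 <- classify_mismatch("chr1", 900L, "T", "C", genes)
  expect_identical(m3$edited_strand, "-")
  expect_identical(m3$mismatch_type, "A-to-G")
  ## non A-to-G-able intergenic mismatch defaults to "+"
  m4 <- classify_mismatch("chr1", 900L, "C", "T", genes)
  expect_identical(m4$edited_strand, "+")
  expect_identical(m4$mismatch_type, "C-to-T")
})

test_that("paralog filter passes unique reads and fails duplicated loci", {
  set.seed(61)
  genome <- c(chr1 = rand_dna(4000))
  ## plant an exact 300-bp duplication
  dup <- substr(genome[["chr1"]], 501L, 800L)
  substr(genome[["chr1"]], 3001L, 3300L) <- dup
  idx <- seed_index(genome)
  cfg <- call_config()
  ## reads from a unique region all qualify
  uniq_reads <- vapply(0:4, function(i)
    substr(genome[["chr1"]], 1501L + i * 10L, 1600L + i * 10L), character(1))
  pf <- paralog_filter(uniq_reads, "chr1", 1550L, idx, cfg)
  expect_true(pf$pass); expect_equal(pf$qualifying_fraction, 1)
  ## reads fully inside the duplication have two equal best hits
  dup_reads <- vapply(0:4, function(i)
    substr(genome[["chr1"]], 551L + i * 20L, 650L + i * 20L), character(1))
  pf2 <- paralog_filter(dup_reads, "chr1", 620L, idx, cfg)
  expect_false(pf2$pass); expect_equal(pf2$qualifying_fraction, 0)
  ## 2 qualifying of 5 -> 0.4, fail
  pf3 <- paralog_filter(c(uniq_reads[1:2], dup_reads[1:3]), "chr1", 1550L,
                        idx, cfg)
  expect_false(pf3$pass); expect_equal(pf3$qualifying_fraction, 0.4)
  ## no realignable reads -> explicit failure reason
  pf4 <- paralog_filter(character(), "chr1", 100L, idx, cfg)
  expect_false(pf4$pass); expect_identical(pf4$reason, "no_realignable_reads")
})

## construct a minimal hand-made sample: one gene, one site, exact counts
mini_sample <- function(genome, sample_id, pos0, n_edited, n_ref,
                        dna_depth = 15L, dna_alt = 0L, L = 60L) {
  reads <- list(); rid <- 0L
  mk <- function(start0, seq) {
    rid <<- rid + 1L
    aln_row(sprintf("%s_%03d", sample_id, rid), "chr1", start0, seq)
  }
  ## RNA reads centred so the site sits mid-read (offset 31, unclipped)
  for (i in seq_len(n_edited + n_ref)) {
    st <- pos0 - 30L
    s <- substr(genome[["chr1"]], st + 1L, st + L)
    if (i <= n_edited) substr(s, 31L, 31L) <- "G"
    reads[[length(reads) + 1L]] <- mk(st, s)
  }
  rna <- do.call(rbind, reads)
  rna$read_id <- sprintf("%s_r%03d", sample_id, seq_len(nrow(rna)))
  dna_reads <- list()
  for (i in seq_len(dna_depth)) {
    st <- pos0 - 30L
    s <- substr(genome[["chr1"]], st + 1L, st + L)
    if (i <= dna_alt) substr(s, 31L, 31L) <- "G"
    dna_reads[[i]] <- aln_row(sprintf("%s_d%03d", sample_id, i), "chr1",
                              st + i %% 3L, substr(genome[["chr1"]],
                                                   st + i %% 3L + 1L,
                                                   st + i %% 3L + L))
  }
  ## write the alt allele into the first dna_alt reads at the site
  dna <- do.call(rbind, dna_reads)
  if (dna_alt > 0L) {
    off <- pos0 - dna$start0[seq_len(dna_alt)] + 1L
    s <- dna$seq[seq_len(dna_alt)]
    substr(s, off, off) <- "G"
    dna$seq[seq_len(dna_alt)] <- s
  }
  clen <- nchar(genome)
  list(sample_id = sample_id,
       rna_pileup = build_pileup(rna, clen, sample_id = sample_id),
       dna_pileup = build_pileup(dna, clen, end_clip = 0L, layer = "DNA"),
       rna_alignments = rna)
}

test_that("round-1 thresholds follow the edited-read and level criteria", {
  set.seed(71)
  genome <- c(chr1 = rand_dna(3000))
  pos <- 1500L
  substr(genome[["chr1"]], pos + 1L, pos + 1L) <- "A"  # reference A site
  bundle <- structure(list(
    genome = genome,
    genes = data.frame(chrom = "chr1", start0 = 0L, end = 3000L,
                       strand = "+", gene_id = "g1", transcript_id = "g1.t1",
                       stringsAsFactors = FALSE),
    features = data.frame(), repeats = data.frame()), class = "GenomeBundle")
  cfg <- call_config()
  ## 3 edited / 60 total (level 0.05) in 2 samples, clean DNA -> called
  s1 <- mini_sample(genome, "s1", pos, 3L, 57L)
  s2 <- mini_sample(genome, "s2", pos, 3L, 57L)
  m <- call_round1(list(s1, s2), bundle, cfg)
  expect_equal(nrow(m), 1L)
  expect_equal(m$pos0, pos)
  expect_identical(m$mismatch_type, "A-to-G")
  expect_equal(m$n_supporting_samples, 2L)
  ## only one sample qualifying -> not called
  s2lo <- mini_sample(genome, "s2", pos, 0L, 60L)
  expect_equal(nrow(call_round1(list(s1, s2lo), bundle, cfg)), 0L)
  ## 2 edited reads everywhere -> below the 3-read threshold
  s1b <- mini_sample(genome, "s1", pos, 2L, 8L)
  s2b <- mini_sample(genome, "s2", pos, 2L, 8L)
  expect_equal(nrow(call_round1(list(s1b, s2b), bundle, cfg)), 0L)
  ## 3 edited / 80 total: level 0.0375 < 5% -> not called
  s1c <- mini_sample(genome, "s1", pos, 3L, 77L)
  s2c <- mini_sample(genome, "s2", pos, 3L, 77L)
  expect_equal(nrow(call_round1(list(s1c, s2c), bundle, cfg)), 0L)
  ## heterozygous DNA (8 ref / 4 alt) blocks the call
  s1d <- mini_sample(genome, "s1", pos, 6L, 54L, dna_depth = 12L,
                     dna_alt = 4L)
  s2d <- mini_sample(genome, "s2", pos, 6L, 54L, dna_depth = 12L,
                     dna_alt = 4L)
  expect_equal(nrow(call_round1(list(s1d, s2d), bundle, cfg)), 0L)
})

test_that("round 2 quantifies master sites under the coverage floor", {
  set.seed(72)
  genome <- c(chr1 = rand_dna(3000))
  pos <- 1500L
  substr(genome[["chr1"]], pos + 1L, pos + 1L) <- "A"
  master <- data.frame(chrom = "chr1", pos0 = pos, strand = "+",
                       mismatch_type = "A-to-G", ref_fwd = "A",
                       variant_fwd = "G", n_supporting_samples = 2L,
                       stringsAsFactors = FALSE)
  cfg <- call_config()
  ## 1 edited / 10 total -> included at level 0.1, flagged edited
  sA <- mini_sample(genome, "sA", pos, 1L, 9L)
  ## 1 edited / 9 total -> absent (below 10-read floor)
  sB <- mini_sample(genome, "sB", pos, 1L, 8L)
  ## 0 edited / 15 total -> covered-but-unedited record
  sC <- mini_sample(genome, "sC", pos, 0L, 15L)
  r2 <- call_round2(master, list(sA, sB, sC), cfg)
  expect_setequal(r2$sample_id, c("sA", "sC"))
  expect_equal(r2$level[r2$sample_id == "sA"], 0.1)
  expect_true(r2$edited[r2$sample_id == "sA"])
  expect_equal(r2$level[r2$sample_id == "sC"], 0)
  expect_false(r2$edited[r2$sample_id == "sC"])
  ## "known-site" mode lowers the floor to 4 reads
  r2k <- call_round2(master, list(sB), cfg, min_total = cfg$known_min_total)
  expect_equal(nrow(r2k), 1L)
  ## round-2 coordinates never leave the master list
  expect_true(all(paste(r2$chrom, r2$pos0) %in%
                  paste(master$chrom, master$pos0)))
})

test_that("calling is monotone in its thresholds on the simulated fixture", {
  fx <- fix_small()
  samples <- prepare_samples(fx$sim, fx$bundle)
  idx <- seed_index(fx$bundle$genome)
  n_base <- nrow(call_round1(samples, fx$bundle, call_config(), idx))
  expect_gt(n_base, 0L)
  stricter <- list(call_config(min_edited_reads_r1 = 5L),
                   call_config(min_level_r1 = 0.2),
                   call_config(min_samples = 4L),
                   call_config(dna_min_depth = 25L))
  for (cfg in stricter)
    expect_lte(nrow(call_round1(samples, fx$bundle, cfg, idx)), n_base)
  ## A-to-G is the modal mismatch type
  m <- call_round1(samples, fx$bundle, call_config(), idx)
  expect_identical(names(which.max(table(m$mismatch_type))), "A-to-G")
})
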