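test_that("reference generation is byte-deterministic for a fixed seed", {
  cfg <- sim_config(rng_seed = 42L, n_chroms = 1L, chrom_length = 30000L,
                    n_genes = 4L, n_sites = 20L, n_het_snps = 5L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_genome_bundle(generate_reference(cfg), d1)
  write_genome_bundle(generate_reference(cfg), d2)
  for (f in c("genome.fa", "genes.gtf", "repeats.bed"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("gene-model geometry matches the configuration", {
  cfg <- sim_config(rng_seed = 3L, n_chroms = 1L, chrom_length = 40000L,
                    n_genes = 5L, exons_per_gene = 3L, n_sites = 10L,
                    n_het_snps = 0L)
  b <- generate_reference(cfg)
  expect_equal(nrow(b$genes), 5L)
  expect_equal(sum(b$features$type == "exon"), 15L)
  ## CDS length divisible by 3, exons non-overlapping within a transcript
  for (tid in unique(b$features$transcript_id)) {
    cds <- b$features[b$features$type == "CDS" &
                      b$features$transcript_id == tid, ]
    expect_equal(sum(cds$end - cds$start0) %% 3L, 0L)
    ex <- b$features[b$features$type == "exon" &
                     b$features$transcript_id == tid, ]
    ex <- ex[order(ex$start0), ]
    if (nrow(ex) > 1L) expect_true(all(ex$start0[-1L] >= ex$end[-nrow(ex)]))
  }
  ## repeat_fraction = 0 -> no repeats
  cfg0 <- sim_config(rng_seed = 3L, n_chroms = 1L, chrom_length = 40000L,
                     n_genes = 5L, repeat_fraction = 0, n_sites = 10L,
                     n_het_snps = 0L, class_mix = c(
                       "repeat" = 0, intron = 0.6, "CDS-recoding" = 0.2,
                       "CDS-synonymous" = 0.1, UTR3 = 0.1, UTR5 = 0))
  expect_equal(nrow(generate_reference(cfg0)$repeats), 0L)
  ## infeasible sizing is refused explicitly
  expect_error(generate_reference(
    sim_config(n_chroms = 1L, chrom_length = 5000L, n_genes = 10L)),
    "do not fit")
})

test_that("planted truth sits on reference A of the edited strand", {
  fx <- fix_small()
  s <- fx$truth$sites
  for (i in seq_len(nrow(s))) {
    base <- substr(fx$bundle$genome[[s$chrom[i]]], s$pos0[i] + 1L,
                   s$pos0[i] + 1L)
    expect_identical(base, if (s$strand[i] == "+") "A" else "T")
  }
  ## het SNPs disjoint from sites; empty when requested
  expect_length(intersect(paste(s$chrom, s$pos0),
                          paste(fx$truth$het_snps$chrom,
                                fx$truth$het_snps$pos0)), 0L)
  cfg0 <- sim_config(rng_seed = 5L, n_chroms = 1L, chrom_length = 40000L,
                     n_genes = 5L, n_sites = 10L, n_het_snps = 0L)
  b0 <- generate_reference(cfg0)
  expect_equal(nrow(plant_truth(b0, cfg0)$het_snps), 0L)
  ## at least one CDS site is nearly fully edited in all regions
  rec <- which(s$class == "CDS-recoding")
  expect_true(any(apply(fx$truth$levels[rec, , drop = FALSE] >= 0.99, 1L,
                        all)))
})

test_that("Beta(1,9) level model has the analytic mean", {
  cfg <- sim_config(rng_seed = 9L, n_chroms = 2L, chrom_length = 120000L,
                    n_genes = 30L, n_sites = 500L, n_het_snps = 0L,
                    level_model = list(
                      "repeat" = list(dist = "beta", shape1 = 1, shape2 = 9),
                      intron = list(dist = "beta", shape1 = 1, shape2 = 9),
                      "CDS-recoding" = list(dist = "beta", shape1 = 1, shape2 = 9),
                      "CDS-synonymous" = list(dist = "beta", shape1 = 1, shape2 = 9),
                      UTR3 = list(dist = "beta", shape1 = 1, shape2 = 9),
                      UTR5 = list(dist = "beta", shape1 = 1, shape2 = 9)))
  tr <- plant_truth(generate_reference(cfg), cfg)
  lv <- tr$levels[, 1L]
  lv <- lv[tr$sites$class != "CDS-recoding" | lv < 0.99]  # drop forced Q/R site
  ## Beta(1,9): mean 0.1, sd sqrt(9/(100*11))
  se <- sqrt(9 / (100 * 11)) / sqrt(length(lv))
  expect_lt(abs(mean(lv) - 0.1), 3 * se)
})

test_that("repeat-class sites are spatially clustered as configured", {
  fx <- fix_small()
  rep_sites <- fx$truth$sites[fx$truth$sites$class == "repeat", ]
  frac <- cluster_fraction(rep_sites[, c("chrom", "pos0")],
                           window = 100L, min_sites = 3L)
  expect_gte(frac, 0.5 * fx$cfg$cluster_fraction)
})

test_that("simulated reads carry edits at the planted per-read probability", {
  cfg <- sim_config(rng_seed = 21L, n_chroms = 1L, chrom_length = 30000L,
                    n_genes = 4L, n_sites = 12L, n_het_snps = 0L,
                    rna_depth = 200, base_error_rate = 0,
                    duplicate_rate = 0, hyper_read_fraction = 0,
                    n_regions = 1L, samples_per_region = 1L,
                    level_model = list(
                      "repeat" = list(dist = "fixed", value = 0.5),
                      intron = list(dist = "fixed", value = 1.0),
                      "CDS-recoding" = list(dist = "fixed", value = 1.0),
                      "CDS-synonymous" = list(dist = "fixed", value = 0.5),
                      UTR3 = list(dist = "fixed", value = 0.5),
                      UTR5 = list(dist = "fixed", value = 0.5)))
  b <- generate_reference(cfg)
  tr <- plant_truth(b, cfg)
  ## the guaranteed-high CDS site keeps its fixed level
  sim <- simulate_reads(b, tr, cfg)
  aln <- sim$rna[[1L]]
  L <- cfg$read_length
  observed <- function(i) {
    s <- tr$sites[i, ]
    k <- which(aln$chrom == s$chrom & aln$start0 <= s$pos0 &
               s$pos0 < aln$start0 + L)
    base <- substr(aln$seq[k], s$pos0 - aln$start0[k] + 1L,
                   s$pos0 - aln$start0[k] + 1L)
    edited_base <- if (s$strand == "+") "G" else "C"
    c(edited = sum(base == edited_base), total = length(k))
  }
  for (i in which(tr$levels[, 1L] == 1)) {
    o <- observed(i)
    expect_equal(o[["edited"]], o[["total"]])  # level 1 -> all reads edited
  }
  half <- which(abs(tr$levels[, 1L] - 0.5) < 1e-9)
  o <- observed(half[1L])
  ci <- qbinom(c(0.005, 0.995), o[["total"]], 0.5)
  expect_gte(o[["edited"]], ci[1L])
  expect_lte(o[["edited"]], ci[2L])
  ## duplicate_rate = 0 -> no planted PCR copies (coincidental identical
  ## fragments can still arise from Poisson start sampling, as in real
  ## shotgun libraries)
  expect_false(any(grepl("_dup$", aln$read_id)))
  ## with a positive rate, each planted copy matches its original exactly
  cfg_d <- cfg; cfg_d$duplicate_rate <- 0.1
  sim_d <- simulate_reads(b, tr, cfg_d)
  aln_d <- sim_d$rna[[1L]]
  dups <- grep("_dup$", aln_d$read_id, value = TRUE)
  expect_gt(length(dups), 0L)
  orig <- match(sub("_dup$", "", dups), aln_d$read_id)
  copy <- match(dups, aln_d$read_id)
  expect_equal(aln_d[orig, c("chrom", "start0", "strand", "seq")],
               aln_d[copy, c("chrom", "start0", "strand", "seq")],
               ignore_attr = TRUE)
})

test_that("DNA reads show both alleles at het SNP positions", {
  fx <- fix_small()
  dna <- fx$sim$dna[[1L]]
  L <- fx$cfg$read_length
  het <- fx$truth$het_snps
  both <- 0L; covered <- 0L
  for (i in seq_len(nrow(het))) {
    k <- which(dna$chrom == het$chrom[i] & dna$start0 <= het$pos0[i] &
               het$pos0[i] < dna$start0 + L)
    if (length(k) < 20L) next
    covered <- covered + 1L
    base <- substr(dna$seq[k], het$pos0[i] - dna$start0[k] + 1L,
                   het$pos0[i] - dna$start0[k] + 1L)
    if (any(base == het$ref[i]) && any(base == het$alt[i]))
      both <- both + 1L
  }
  expect_gt(covered, 0L)
  expect_identical(both, covered)
})

test_that("hyper-edited molecules go to the unmapped pool, not the SAM", {
  fx <- fix_small()
  hy <- fx$truth$hyper_reads
  expect_gt(nrow(hy), 0L)
  for (sid in names(fx$sim$rna)) {
    ids <- hy$read_id[hy$sample_id == sid]
    expect_length(intersect(ids, fx$sim$rna[[sid]]$read_id), 0L)
    expect_setequal(intersect(ids, fx$sim$unmapped[[sid]]$read_id), ids)
  }
  ## >= 20% of the As of each hyper read are edited (vs its emitting locus)
  un <- fx$sim$unmapped[[hy$sample_id[1L]]]
  r <- hy[1L, ]
  seq_read <- un$seq[un$read_id == r$read_id]
  fwd <- if (r$strand == "-") revcomp(seq_read) else seq_read
  ref <- substr(fx$bundle$genome[[r$chrom]], r$start0 + 1L,
                r$start0 + nchar(fwd))
  mm <- .count_mismatch_pairs_for_test(ref, fwd)
  want <- if (r$strand == "+") mm["A>G"] else mm["T>C"]
  nA <- lengths(regmatches(ref, gregexpr(if (r$strand == "+") "A" else "T",
                                         ref)))
  expect_gte(want / nA, 0.2)
})
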