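## Shared fixtures, built once per test run and memoised.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, make) {
  if (!exists(name, .fixture_env)) assign(name, make(), .fixture_env)
  get(name, .fixture_env)
}

## small but complete simulated dataset (1 chrom, 2 regions x 2 samples)
fix_small <- function() memo("small", function() {
  cfg <- sim_config(rng_seed = 11L, n_chroms = 1L, chrom_length = 60000L,
                    n_genes = 8L, n_sites = 60L, n_het_snps = 10L,
                    rna_depth = 50, dna_depth = 30, n_regions = 2L,
                    samples_per_region = 2L)
  bundle <- generate_reference(cfg)
  truth <- plant_truth(bundle, cfg)
  sim <- simulate_reads(bundle, truth, cfg)
  list(cfg = cfg, bundle = bundle, truth = sim$truth, sim = sim)
})

## full-scale planted-truth fixture: the generator defaults (2 x 200 kb,
## 500 sites, 50 het SNPs, 3 regions x 4 samples, depth 60, 0.1% error)
fix_acceptance <- function() memo("acceptance", function() {
  cfg <- sim_config(rng_seed = 20240L)
  bundle <- generate_reference(cfg)
  truth <- plant_truth(bundle, cfg)
  sim <- simulate_reads(bundle, truth, cfg)
  samples <- prepare_samples(sim, bundle)
  master <- call_round1(samples, bundle)
  list(cfg = cfg, bundle = bundle, truth = sim$truth, sim = sim,
       samples = samples, master = master)
})

## hand-built alignment row
aln_row <- function(read_id, chrom, start0, seq, strand = "+",
                    qual = NULL, mapq = 60L) {
  data.frame(read_id = read_id, chrom = chrom, start0 = start0,
             strand = strand, seq = seq,
             qual = qual %||% strrep("I", nchar(seq)), mapq = mapq,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## independent per-pair mismatch tally used to audit simulated reads
.count_mismatch_pairs_for_test <- function(ref, read) {
  a <- strsplit(ref, "")[[1]]
  b <- strsplit(read, "")[[1]]
  c("A>G" = sum(a == "A" & b == "G"), "T>C" = sum(a == "T" & b == "C"))
}

## 0-based positions of a base in a sequence string
base_positions_for_test <- function(s, base) {
  m <- gregexpr(base, s, fixed = TRUE)[[1]]
  if (m[1] == -1L) integer() else as.integer(m) - 1L
}

## random DNA string
rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
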