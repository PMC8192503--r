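## End-to-end orchestration over the stage functions: simulate -> dedup /
## pileup (+ hyper-editing recovery) -> round-1 calling -> round-2
## quantification -> annotation -> landscape statistics -> specificity ->
## miRNA alteration scan. Emits per-stage artifacts and a JSON manifest
## with config echo, seed, record counts and output checksums.

#' Run the full editing-landscape pipeline on a simulated dataset
#'
#' Stages run in dependency order on in-memory objects; every stage writes
#' its artifact into `out_dir` and registers it (path, records, md5) in the
#' manifest. When `resume = TRUE` and `out_dir` already holds a manifest
#' produced from an identical configuration whose artifact checksums all
#' still verify, the previous manifest is returned without recomputation;
#' any corrupted or missing artifact triggers a fresh run.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory.
#' @param call_cfg a [call_config()].
#' @param hyper_cfg a [hyper_config()].
#' @param seeds optional seed table (miRNA stage); skipped when `NULL`.
#' @param resume reuse a verified previous run (default TRUE).
#' @return the manifest (list), invisibly; artifacts under `out_dir`.
#' @export
run_pipeline <- function(config, out_dir, call_cfg = call_config(),
                         hyper_cfg = hyper_config(), seeds = NULL,
                         resume = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(out_dir, "manifest.json")
  cfg_plain <- unclass(config)
  cfg_hash <- digest_obj(cfg_plain)
  if (resume && file.exists(manifest_path)) {
    prev <- tryCatch(jsonlite::read_json(manifest_path, simplifyVector = TRUE),
                     error = function(e) NULL)
    if (!is.null(prev) && identical(prev$config_hash, cfg_hash) &&
        all(vapply(prev$artifacts$path, file.exists, logical(1))) &&
        identical(unname(tools::md5sum(prev$artifacts$path)),
                  prev$artifacts$md5)) {
      message("run_pipeline: verified previous run, resuming from manifest")
      return(invisible(prev))
    }
  }

  artifacts <- list()
  reg <- function(stage, path, records) {
    artifacts[[length(artifacts) + 1L]] <<- data.frame(
      stage = stage, path = path, records = records,
      md5 = unname(tools::md5sum(path)), stringsAsFactors = FALSE)
  }
  log_stage <- function(...) message("[edscape] ", sprintf(...))

  log_stage("simulate: seed %d", config$rng_seed)
  sim <- simulate_to_dir(config, out_dir)
  bundle <- sim$bundle
  reg("simulate", file.path(out_dir, "genome.fa"), length(bundle$genome))
  reg("simulate", file.path(out_dir, "truth_sites.tsv"),
      nrow(sim$truth$sites))

  log_stage("pileup + hyper-editing recovery")
  samples <- prepare_samples(sim, bundle, call_cfg, recover_hyper = TRUE,
                             hyper_cfg)

  log_stage("round-1 calling over %d samples", length(samples))
  index <- seed_index(bundle$genome, call_cfg$k)
  master <- call_round1(samples, bundle, call_cfg, index)
  master <- annotate_sites(master, bundle)
  master_path <- file.path(out_dir, "master_sites.tsv")
  write_master_tsv(master, master_path)
  reg("call_round1", master_path, nrow(master))

  log_stage("round-2 quantification of %d master sites", nrow(master))
  calls <- call_round2(master, samples, call_cfg)
  calls_path <- file.path(out_dir, "site_quantification.tsv")
  out <- calls; out$pos1 <- out$pos0 + 1L; out$pos0 <- NULL
  write.table(out, calls_path, sep = "\t", quote = FALSE, row.names = FALSE)
  reg("call_round2", calls_path, nrow(calls))

  log_stage("landscape statistics")
  em <- calls_to_matrix(calls, sim$samples$sample_id)
  region_map <- sim$samples$region[match(colnames(em$G),
                                         sim$samples$sample_id)]
  region_m <- pool_counts(em, region_map)
  overall <- vapply(colnames(em$G), function(s) overall_editing(em, s),
                    numeric(1))
  stats_path <- file.path(out_dir, "overall_editing.tsv")
  write.table(data.frame(sample_id = names(overall),
                         overall_editing = unname(overall),
                         n_uniquely_mapped = vapply(samples, function(s)
                           s$rna_pileup$n_reads, numeric(1))[names(overall)],
                         row.names = NULL),
              stats_path, sep = "\t", quote = FALSE, row.names = FALSE)
  reg("stats", stats_path, length(overall))
  for (rg in colnames(region_m$G)) {
    lv <- editing_levels(region_m)[, rg]
    keys <- strsplit(rownames(region_m$G), ":", fixed = TRUE)
    bg <- data.frame(chrom = vapply(keys, `[`, "", 1L),
                     pos0 = as.integer(vapply(keys, `[`, "", 2L)) - 1L,
                     level = lv, stringsAsFactors = FALSE)
    bg <- bg[!is.na(bg$level), ]
    bg_path <- file.path(out_dir, sprintf("levels_%s.bedGraph", rg))
    write_bedgraph(bg, bg_path, paste0("editing_", rg))
    reg("stats", bg_path, nrow(bg))
  }

  log_stage("specificity classification")
  spec <- classify_specificity_all(region_m, min_total = call_cfg$r2_min_total)
  spec_path <- file.path(out_dir, "specificity.tsv")
  write.table(spec, spec_path, sep = "\t", quote = FALSE, row.names = FALSE)
  reg("specificity", spec_path, nrow(spec))

  n_mirna_hits <- NA_integer_
  if (!is.null(seeds)) {
    log_stage("miRNA alteration scan")
    hits <- mirna_alterations(master, bundle, seeds)
    hits_path <- file.path(out_dir, "mirna_alterations.tsv")
    write.table(hits, hits_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    reg("mirna", hits_path, nrow(hits))
    n_mirna_hits <- nrow(hits)
  }

  manifest <- list(
    tool = "edscape",
    version = as.character(utils::packageVersion("edscape")),
    seed = config$rng_seed,
    config = cfg_plain,
    config_hash = cfg_hash,
    counts = list(samples = length(samples),
                  master_sites = nrow(master),
                  round2_records = nrow(calls),
                  mirna_hits = n_mirna_hits),
    artifacts = do.call(rbind, artifacts))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "columns")
  invisible(manifest)
}

## content hash of an R object via its serialized text representation
digest_obj <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  dput(x, file = f, control = c("all", "hexNumeric"))
  unname(tools::md5sum(f))
}
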