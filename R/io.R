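## Deterministic writers/readers for the standard interchange formats the
## pipeline emits: FASTA genome, GTF gene models, BED6 repeats, truth TSV
## (1-based), bedGraph level tracks. All tables on disk are 1-based unless
## the format itself is 0-based half-open (BED, bedGraph).

#' Write a genome bundle to disk
#'
#' Emits `genome.fa`, `genes.gtf` (gene/transcript/exon/CDS/UTR records with
#' `gene_id`/`transcript_id` attributes) and `repeats.bed` (BED6, name =
#' repeat subfamily) into `dir`.
#'
#' @param bundle a `GenomeBundle`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_genome_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  gset <- Biostrings::DNAStringSet(bundle$genome)
  Biostrings::writeXStringSet(gset, fa, width = 70L)

  gtf <- file.path(dir, "genes.gtf")
  lines <- character()
  type_map <- c(exon = "exon", CDS = "CDS", UTR5 = "five_prime_utr",
                UTR3 = "three_prime_utr")
  for (g in seq_len(nrow(bundle$genes))) {
    gn <- bundle$genes[g, ]
    attr_g <- sprintf('gene_id "%s";', gn$gene_id)
    attr_t <- sprintf('gene_id "%s"; transcript_id "%s";', gn$gene_id,
                      gn$transcript_id)
    lines <- c(lines,
      sprintf("%s\tedscape\tgene\t%d\t%d\t.\t%s\t.\t%s", gn$chrom,
              gn$start0 + 1L, gn$end, gn$strand, attr_g),
      sprintf("%s\tedscape\ttranscript\t%d\t%d\t.\t%s\t.\t%s", gn$chrom,
              gn$start0 + 1L, gn$end, gn$strand, attr_t))
    f <- bundle$features[bundle$features$gene_id == gn$gene_id, ]
    f <- f[order(f$start0, f$type), ]
    lines <- c(lines, sprintf("%s\tedscape\t%s\t%d\t%d\t.\t%s\t.\t%s",
                              f$chrom, type_map[f$type], f$start0 + 1L,
                              f$end, f$strand, attr_t))
  }
  writeLines(lines, gtf)

  bed <- file.path(dir, "repeats.bed")
  r <- bundle$repeats
  if (nrow(r)) {
    writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", r$chrom, r$start0, r$end,
                       r$name, r$strand), bed)
  } else writeLines(character(), bed)
  invisible(c(fa, gtf, bed))
}

#' Read a genome bundle back from disk
#'
#' @param dir directory written by [write_genome_bundle()].
#' @return a `GenomeBundle`.
#' @export
read_genome_bundle <- function(dir) {
  gset <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  genome <- stats::setNames(as.character(gset), names(gset))

  lines <- readLines(file.path(dir, "genes.gtf"))
  f <- strsplit(lines, "\t", fixed = TRUE)
  m <- matrix(unlist(lapply(f, `[`, 1:9)), ncol = 9L, byrow = TRUE)
  type_map <- c(exon = "exon", CDS = "CDS", five_prime_utr = "UTR5",
                three_prime_utr = "UTR3")
  gid <- sub('.*gene_id "([^"]+)".*', "\\1", m[, 9L])
  tid <- ifelse(grepl("transcript_id", m[, 9L]),
                sub('.*transcript_id "([^"]+)".*', "\\1", m[, 9L]), NA)
  df <- data.frame(chrom = m[, 1L], type = m[, 3L],
                   start0 = as.integer(m[, 4L]) - 1L,
                   end = as.integer(m[, 5L]), strand = m[, 7L],
                   gene_id = gid, transcript_id = tid,
                   stringsAsFactors = FALSE)
  genes <- df[df$type == "gene", c("chrom", "start0", "end", "strand",
                                   "gene_id")]
  tr <- df[df$type == "transcript", c("gene_id", "transcript_id")]
  genes$transcript_id <- tr$transcript_id[match(genes$gene_id, tr$gene_id)]
  feats <- df[df$type %in% names(type_map), ]
  feats$type <- unname(type_map[feats$type])
  feats <- feats[, c("chrom", "start0", "end", "strand", "type", "gene_id",
                     "transcript_id")]
  rownames(genes) <- rownames(feats) <- NULL

  bedp <- file.path(dir, "repeats.bed")
  bl <- readLines(bedp)
  repeats <- if (length(bl)) {
    bm <- matrix(unlist(strsplit(bl, "\t", fixed = TRUE)), ncol = 6L,
                 byrow = TRUE)
    data.frame(chrom = bm[, 1L], start0 = as.integer(bm[, 2L]),
               end = as.integer(bm[, 3L]), strand = bm[, 6L],
               name = bm[, 4L], stringsAsFactors = FALSE)
  } else data.frame(chrom = character(), start0 = integer(),
                    end = integer(), strand = character(),
                    name = character(), stringsAsFactors = FALSE)
  structure(list(genome = genome, genes = genes, features = feats,
                 repeats = repeats), class = "GenomeBundle")
}

#' Write / read the ground-truth ledger
#'
#' Sites and SNPs are written 1-based; per-region true levels appear as
#' `level_<region>` columns.
#'
#' @param truth a `TruthSet`.
#' @param dir output directory.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- truth$sites
  s$pos1 <- s$pos0 + 1L
  lv <- as.data.frame(truth$levels)
  names(lv) <- paste0("level_", truth$regions)
  out <- cbind(s[, c("site_id", "chrom", "pos1", "strand", "class",
                     "gene_id", "ref_fwd")], lv)
  write.table(out, file.path(dir, "truth_sites.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  h <- truth$het_snps
  h$pos1 <- h$pos0 + 1L
  write.table(h[, c("chrom", "pos1", "ref", "alt")],
              file.path(dir, "truth_het_snps.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(truth$hyper_reads, file.path(dir, "truth_hyper_reads.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_truth
#' @export
read_truth <- function(dir) {
  s <- read.table(file.path(dir, "truth_sites.tsv"), header = TRUE,
                  sep = "\t", stringsAsFactors = FALSE)
  lv_cols <- grep("^level_", names(s), value = TRUE)
  levels <- as.matrix(s[, lv_cols, drop = FALSE])
  colnames(levels) <- sub("^level_", "", lv_cols)
  rownames(levels) <- s$site_id
  s$pos0 <- s$pos1 - 1L
  sites <- s[, c("site_id", "chrom", "pos0", "strand", "class", "gene_id",
                 "ref_fwd")]
  h <- read.table(file.path(dir, "truth_het_snps.tsv"), header = TRUE,
                  sep = "\t", stringsAsFactors = FALSE,
                  colClasses = c("character", "integer", "character",
                                 "character"))
  h$pos0 <- h$pos1 - 1L
  hy <- read.table(file.path(dir, "truth_hyper_reads.tsv"), header = TRUE,
                   sep = "\t", stringsAsFactors = FALSE)
  structure(list(sites = sites, levels = levels,
                 het_snps = h[, c("chrom", "pos0", "ref", "alt")],
                 regions = colnames(levels), hyper_reads = hy),
            class = "TruthSet")
}

#' Write per-region editing levels as bedGraph
#'
#' 0-based half-open intervals of width 1; the score is the editing level in
#' percent.
#'
#' @param sites data frame with `chrom`, `pos0` and `level`.
#' @param path output file.
#' @param track_name track label.
#' @export
write_bedgraph <- function(sites, path, track_name = "editing_level") {
  lines <- c(sprintf("track type=bedGraph name=\"%s\"", track_name),
             sprintf("%s\t%d\t%d\t%s", sites$chrom, sites$pos0,
                     sites$pos0 + 1L, format(sites$level * 100,
                                             trim = TRUE, digits = 6)))
  writeLines(lines, path)
  invisible(path)
}

#' Run a simulation end to end and write all artifacts
#'
#' Writes genome FASTA/GTF/BED, per-animal DNA SAM, per-sample RNA SAM and
#' unmapped FASTQ, the truth ledger, and a JSON echo of the configuration.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory.
#' @return invisibly, the in-memory simulation (bundle, truth, reads).
#' @export
simulate_to_dir <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  bundle <- generate_reference(config)
  truth <- plant_truth(bundle, config)
  sim <- simulate_reads(bundle, truth, config)
  chrom_lengths <- nchar(bundle$genome)
  write_genome_bundle(bundle, out_dir)
  write_truth(sim$truth, out_dir)
  for (sid in names(sim$rna)) {
    write_sam(sim$rna[[sid]], file.path(out_dir, paste0(sid, ".rna.sam")),
              chrom_lengths)
    write_fastq(sim$unmapped[[sid]],
                file.path(out_dir, paste0(sid, ".unmapped.fastq")))
  }
  for (an in names(sim$dna))
    write_sam(sim$dna[[an]], file.path(out_dir, paste0(an, ".dna.sam")),
              chrom_lengths)
  write.table(sim$samples, file.path(out_dir, "samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cfg <- config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(sim, list(bundle = bundle, config = config)))
}
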