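## Alignment ingestion (SAM text), PCR-duplicate removal, filtered pileups
## and the seed-and-extend aligner used for paralog checks and hyper-editing
## realignment. Internal coordinates are 0-based half-open; SAM is 1-based.

#' Write single-end ungapped alignments as SAM
#'
#' @param alignments data frame with columns `read_id`, `chrom`, `start0`,
#'   `strand`, `seq`, `qual`, `mapq`. Sequences are stored on the forward
#'   genome strand (standard SAM convention); `strand == "-"` sets FLAG 16.
#' @param path output file.
#' @param chrom_lengths named integer vector for the `@SQ` header lines.
#' @export
write_sam <- function(alignments, path, chrom_lengths) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                   as.integer(chrom_lengths)))
  a <- alignments
  rec <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t%s",
                 a$read_id, ifelse(a$strand == "-", 16L, 0L), a$chrom,
                 a$start0 + 1L, a$mapq, nchar(a$seq), a$seq, a$qual)
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Read a SAM file into an alignment table
#'
#' Accepts single-end records with simple `<n>M` CIGARs; malformed records
#' raise an error naming the offending line. Reads with MAPQ below
#' `min_mapq` are dropped on ingest ("uniquely mapped" operationalised as
#' MAPQ >= 30).
#'
#' @param path SAM file (must carry `@SQ` headers).
#' @param min_mapq minimum mapping quality retained.
#' @return data frame as accepted by [write_sam()]; chromosome names seen in
#'   the header are attached as attribute `chrom_lengths`.
#' @export
read_sam <- function(path, min_mapq = 30L) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "@")
  sq <- lines[startsWith(lines, "@SQ")]
  if (!length(sq)) stopf("read_sam: %s has no @SQ header lines", path)
  sn <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
  ln <- as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq))
  body_idx <- which(!is_hdr)
  if (!length(body_idx)) {
    out <- data.frame(read_id = character(), chrom = character(),
                      start0 = integer(), strand = character(),
                      seq = character(), qual = character(),
                      mapq = integer(), stringsAsFactors = FALSE)
    attr(out, "chrom_lengths") <- stats::setNames(ln, sn)
    return(out)
  }
  fields <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L))
    stopf("read_sam: line %d has %d fields (need >= 11)",
          body_idx[which(nf < 11L)[1]], nf[nf < 11L][1])
  m <- matrix(unlist(lapply(fields, `[`, 1:11)), ncol = 11L, byrow = TRUE)
  bad <- nchar(m[, 10L]) != nchar(m[, 11L])
  if (any(bad))
    stopf("read_sam: line %d: sequence/quality length mismatch",
          body_idx[which(bad)[1]])
  bad <- !m[, 3L] %in% sn
  if (any(bad))
    stopf("read_sam: line %d: unknown reference '%s'",
          body_idx[which(bad)[1]], m[which(bad)[1], 3L])
  flag <- as.integer(m[, 2L])
  out <- data.frame(read_id = m[, 1L], chrom = m[, 3L],
                    start0 = as.integer(m[, 4L]) - 1L,
                    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
                    seq = m[, 10L], qual = m[, 11L],
                    mapq = as.integer(m[, 5L]), stringsAsFactors = FALSE)
  out <- out[out$mapq >= min_mapq, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "chrom_lengths") <- stats::setNames(ln, sn)
  out
}

#' Write / read FASTQ tables
#'
#' @param fq data frame with `read_id`, `seq`, `qual`.
#' @param path file path.
#' @export
write_fastq <- function(fq, path) {
  if (nrow(fq) == 0L) { writeLines(character(), path); return(invisible(path)) }
  writeLines(as.vector(rbind(paste0("@", fq$read_id), fq$seq, "+", fq$qual)),
             path)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (!length(lines))
    return(data.frame(read_id = character(), seq = character(),
                      qual = character(), stringsAsFactors = FALSE))
  if (length(lines) %% 4L != 0L) stopf("read_fastq: truncated file %s", path)
  i <- seq(1L, length(lines), by = 4L)
  data.frame(read_id = sub("^@", "", lines[i]), seq = lines[i + 1L],
             qual = lines[i + 3L], stringsAsFactors = FALSE)
}

#' Remove PCR duplicates
#'
#' At most one read is retained per (chrom, start, strand); the retained
#' read is the one with the highest base-quality sum, ties broken by
#' lexicographically smallest read id. Idempotent.
#'
#' @param alignments single-sample alignment table.
#' @return de-duplicated alignment table.
#' @export
remove_duplicates <- function(alignments) {
  if (nrow(alignments) <= 1L) return(alignments)
  qsum <- vapply(alignments$qual, function(q) sum(utf8ToInt(q)), numeric(1),
                 USE.NAMES = FALSE)
  key <- paste(alignments$chrom, alignments$start0, alignments$strand)
  ord <- order(key, -qsum, alignments$read_id)
  keep <- ord[!duplicated(key[ord])]
  out <- alignments[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a quality- and clip-filtered pileup
#'
#' A base contributes to the pileup iff its Phred quality is at least
#' `quality_min` and its read offset lies in `[end_clip, len - end_clip)`.
#' RNA pileups use the default 6-base end clip; DNA pileups should pass
#' `end_clip = 0` (no clipping).
#'
#' @param alignments de-duplicated alignment table.
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param quality_min minimum Phred score (default 30).
#' @param end_clip bases ignored at each read end (default 6).
#' @param sample_id,layer metadata carried on the object.
#' @return object of class `Pileup`: per-chromosome 4 x length integer
#'   count matrices (rows A, C, G, T) plus metadata, including `n_reads`.
#' @export
build_pileup <- function(alignments, chrom_lengths, quality_min = 30L,
                         end_clip = 6L, sample_id = NA_character_,
                         layer = "RNA") {
  cn <- names(chrom_lengths)
  cidx <- match(alignments$chrom, cn)
  if (anyNA(cidx)) stopf("build_pileup: unknown chromosome in alignments")
  counts <- .pileup_counts(as.integer(chrom_lengths), cidx,
                           as.integer(alignments$start0), alignments$seq,
                           alignments$qual, as.integer(quality_min),
                           as.integer(end_clip))
  names(counts) <- cn
  for (i in seq_along(counts)) rownames(counts[[i]]) <- BASES
  structure(list(counts = counts, sample_id = sample_id, layer = layer,
                 n_reads = nrow(alignments), quality_min = quality_min,
                 end_clip = end_clip),
            class = "Pileup")
}

#' @export
print.Pileup <- function(x, ...) {
  cat(sprintf("Pileup (%s, sample %s): %d chrom(s), %d reads, Q>=%d, clip %d\n",
              x$layer, x$sample_id, length(x$counts), x$n_reads,
              x$quality_min, x$end_clip))
  invisible(x)
}

#' Merge additional reads into an existing pileup
#'
#' Used to fold recovered hyper-edited alignments into the RNA pileup; the
#' same quality and clip filters are applied.
#'
#' @param pileup a `Pileup`.
#' @param alignments extra alignment rows.
#' @param chrom_lengths named chromosome lengths (must match the pileup).
#' @return updated `Pileup`.
#' @export
merge_pileup <- function(pileup, alignments, chrom_lengths) {
  extra <- build_pileup(alignments, chrom_lengths, pileup$quality_min,
                        pileup$end_clip, pileup$sample_id, pileup$layer)
  for (ci in names(pileup$counts))
    pileup$counts[[ci]] <- pileup$counts[[ci]] + extra$counts[[ci]]
  pileup$n_reads <- pileup$n_reads + nrow(alignments)
  pileup
}

## ---------------------------------------------------------------------------
## Seed-and-extend aligner

#' Build a k-mer seed index over a genome
#'
#' @param genome named character vector of chromosome sequences.
#' @param k seed length (default 16).
#' @return opaque index object for [align_reads()].
#' @export
seed_index <- function(genome, k = 16L) {
  idx <- .se_index_build(names(genome), unname(genome), as.integer(k))
  structure(list(ptr = idx, chroms = names(genome), k = as.integer(k)),
            class = "SeedIndex")
}

#' Align reads by seed-and-extend
#'
#' Reports every locus (both strands) at which some k-mer of the read seeds
#' an ungapped full-length extension with mismatch fraction at most
#' `max_mismatch_frac`. Hits are sorted by mismatch count, then coordinate;
#' `is_unique` is TRUE when the best score is achieved at exactly one locus.
#'
#' @param index a [seed_index()].
#' @param reads character vector of read sequences.
#' @param max_mismatch_frac maximum mismatch fraction (default 0.1).
#' @return data frame with `read` (index into `reads`), `chrom`, `start0`,
#'   `strand`, `mismatch_count`, `is_unique`.
#' @export
align_reads <- function(index, reads, max_mismatch_frac = 0.1) {
  stopifnot(inherits(index, "SeedIndex"))
  short <- nchar(reads) < index$k
  if (any(short))
    stopf("align_reads: read %d is shorter than the seed length %d",
          which(short)[1], index$k)
  hits <- .se_align_batch(index$ptr, reads, max_mismatch_frac)
  hits$chrom <- index$chroms[hits$chrom]
  names(hits)[names(hits) == "mismatches"] <- "mismatch_count"
  hits <- hits[order(hits$read, hits$mismatch_count,
                     match(hits$chrom, index$chroms), hits$start0,
                     hits$strand), , drop = FALSE]
  best <- ave(hits$mismatch_count, hits$read, FUN = min)
  n_best <- ave(hits$mismatch_count == best, hits$read, FUN = sum)
  hits$is_unique <- hits$mismatch_count == best & n_best == 1L
  rownames(hits) <- NULL
  hits
}

#' Align a single read sequence against a genome
#'
#' Convenience wrapper around [seed_index()] + [align_reads()] matching the
#' one-read contract; for batches, build the index once.
#'
#' @param read_sequence a single read (length >= `k`).
#' @param genome named character vector of chromosome sequences.
#' @param k seed length.
#' @param max_mismatch_frac maximum mismatch fraction.
#' @return data frame of hits (see [align_reads()]).
#' @export
seed_extend_align <- function(read_sequence, genome, k = 16L,
                              max_mismatch_frac = 0.1) {
  if (nchar(read_sequence) < k)
    stopf("seed_extend_align: read length %d < seed length %d",
          nchar(read_sequence), k)
  align_reads(seed_index(genome, k), read_sequence, max_mismatch_frac)
}

#' Dump a pileup as a TSV table
#'
#' One row per covered position and base layer: chrom, 1-based position,
#' sample, A/C/G/T counts, layer.
#'
#' @param pileup a `Pileup`.
#' @param path output TSV.
#' @export
write_pileup_tsv <- function(pileup, path) {
  rows <- list()
  for (ci in names(pileup$counts)) {
    m <- pileup$counts[[ci]]
    cov <- which(colSums(m) > 0L)
    if (!length(cov)) next
    rows[[ci]] <- data.frame(chrom = ci, pos1 = cov,
                             sample = pileup$sample_id,
                             A = m[1L, cov], C = m[2L, cov], G = m[3L, cov],
                             T = m[4L, cov], layer = pileup$layer,
                             stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), pos1 = integer(), sample = character(),
               A = integer(), C = integer(), G = integer(), T = integer(),
               layer = character())
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
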