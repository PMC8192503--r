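## Hyper-edited read recovery: reads carrying so many A-to-G changes that
## direct alignment fails are rescued by collapsing the editable base -- the
## read's As become Gs and the genome is indexed once as A->G (sense editing)
## and once as T->C (antisense editing on the forward genome) -- realigning,
## restoring the original sequence at the hit locus, and requiring the
## restored mismatches to be dominated by A->G.

#' Hyper-editing recovery configuration
#'
#' @param min_ag_fraction_of_mismatches minimum fraction of restored
#'   mismatches that must read A-to-G on the edited strand (default 0.6).
#' @param min_edits_per_read minimum A-to-G mismatch count (default 5).
#' @param max_other_mismatch_frac maximum fraction of read length taken up
#'   by non-A-to-G mismatches (default 0.05).
#' @param max_mismatch_frac mismatch ceiling for the transformed-space
#'   alignment itself (default 0.1).
#' @param k seed length for the transformed-genome index.
#' @return object of class `HyperConfig`.
#' @export
hyper_config <- function(min_ag_fraction_of_mismatches = 0.6,
                         min_edits_per_read = 5L,
                         max_other_mismatch_frac = 0.05,
                         max_mismatch_frac = 0.1, k = 16L) {
  props <- c(min_ag_fraction_of_mismatches, max_other_mismatch_frac,
             max_mismatch_frac)
  if (any(props < 0 | props > 1))
    stopf("hyper_config: proportions must be in [0,1]")
  structure(list(min_ag_fraction_of_mismatches = min_ag_fraction_of_mismatches,
                 min_edits_per_read = as.integer(min_edits_per_read),
                 max_other_mismatch_frac = max_other_mismatch_frac,
                 max_mismatch_frac = max_mismatch_frac, k = as.integer(k)),
            class = "HyperConfig")
}

#' Collapse one base into another
#'
#' @param seq character vector of nucleotide strings.
#' @param from_base,to_base single bases.
#' @return transformed strings (length preserved; idempotent).
#' @export
transform_bases <- function(seq, from_base = "A", to_base = "G") {
  chartr(paste0(toupper(from_base), tolower(from_base)),
         paste0(toupper(to_base), tolower(to_base)), seq)
}

#' Recover hyper-edited reads by base-transformed realignment
#'
#' Each unmapped read is A->G collapsed and aligned (both strands) against
#' two collapsed forward-genome indexes: A->G (captures sense-strand
#' editing) and T->C (captures editing on the reverse strand as seen on
#' forward coordinates). A read is recovered iff the best transformed-space
#' hit is unique across both schemes and, after restoring the original
#' sequence at that locus, (a) edited-strand A->G mismatches >=
#' `min_edits_per_read`, (b) their fraction among all mismatches >=
#' `min_ag_fraction_of_mismatches`, and (c) other mismatches <=
#' `max_other_mismatch_frac` of the read length. Unrecovered reads are
#' reported with a reason code.
#'
#' @param unmapped data frame with `read_id`, `seq`, `qual` (read
#'   orientation, as in FASTQ).
#' @param genome named character vector of chromosome sequences.
#' @param cfg a [hyper_config()].
#' @param indexes optional precomputed list from [hyper_indexes()] (reused
#'   across samples).
#' @return list with `alignments` (forward-strand SAM-convention rows plus
#'   an `edits` column) and `report` (read_id, status, reason).
#' @export
recover_hyper_edited <- function(unmapped, genome, cfg = hyper_config(),
                                 indexes = NULL) {
  n <- nrow(unmapped)
  empty_aln <- data.frame(read_id = character(), chrom = character(),
                          start0 = integer(), strand = character(),
                          seq = character(), qual = character(),
                          mapq = integer(), edits = integer(),
                          stringsAsFactors = FALSE)
  if (n == 0L)
    return(list(alignments = empty_aln,
                report = data.frame(read_id = character(),
                                    status = character(),
                                    reason = character(),
                                    stringsAsFactors = FALSE)))
  if (is.null(indexes)) indexes <- hyper_indexes(genome, cfg$k)
  tr <- transform_bases(unmapped$seq, "A", "G")
  hits_ag <- align_reads(indexes$ag, tr, cfg$max_mismatch_frac)
  hits_tc <- align_reads(indexes$tc, tr, cfg$max_mismatch_frac)
  hits <- rbind(hits_ag, hits_tc)
  ## dedupe identical loci discovered under both schemes (keep the better)
  hits <- hits[order(hits$read, hits$mismatch_count), ]
  dup <- duplicated(hits[, c("read", "chrom", "start0", "strand")])
  hits <- hits[!dup, ]

  status <- rep("unaligned", n)
  reason <- rep("no_transformed_hit", n)
  out <- vector("list", n)
  L <- nchar(unmapped$seq)

  split_hits <- split(hits, hits$read)
  for (key in names(split_hits)) {
    i <- as.integer(key)
    h <- split_hits[[key]]
    best <- h[h$mismatch_count == min(h$mismatch_count), , drop = FALSE]
    if (nrow(best) > 1L) {
      status[i] <- "rejected"; reason[i] <- "ambiguous_locus"
      next
    }
    b <- best[1L, ]
    ## restore: place the original sequence on the forward genome strand
    fwd_seq <- if (b$strand == "+") unmapped$seq[i] else revcomp(unmapped$seq[i])
    gsub_ <- substr(genome[[b$chrom]], b$start0 + 1L, b$start0 + L[i])
    mm <- .count_mismatch_pairs(gsub_, fwd_seq)[1L, ]
    ## mismatch matrix is ref-major 4x4 (A,C,G,T): A->G at [1,3] => col 3;
    ## T->C at [4,2] => col 14. Which one is "edited-strand A->G" depends on
    ## the strand the editing occurred on, i.e. the scheme x strand combo.
    ag_fwd <- mm[3L]    # genome A, read G (sense editing on +)
    tc_fwd <- mm[14L]   # genome T, read C (sense editing on -)
    edits <- max(ag_fwd, tc_fwd)
    other <- sum(mm) - edits
    if (sum(mm) > 0L &&
        edits / sum(mm) < cfg$min_ag_fraction_of_mismatches) {
      status[i] <- "rejected"; reason[i] <- "low_ag_fraction"
      next
    }
    if (edits < cfg$min_edits_per_read && sum(mm) > 0L) {
      status[i] <- "rejected"; reason[i] <- "too_few_edits"
      next
    }
    if (other / L[i] > cfg$max_other_mismatch_frac) {
      status[i] <- "rejected"; reason[i] <- "excess_other_mismatches"
      next
    }
    fwd_qual <- if (b$strand == "+") unmapped$qual[i] else
      paste(rev(strsplit(unmapped$qual[i], "")[[1]]), collapse = "")
    status[i] <- "recovered"; reason[i] <- ""
    out[[i]] <- data.frame(read_id = unmapped$read_id[i], chrom = b$chrom,
                           start0 = b$start0, strand = b$strand,
                           seq = fwd_seq, qual = fwd_qual, mapq = 60L,
                           edits = as.integer(edits),
                           stringsAsFactors = FALSE)
  }
  aln <- if (any(status == "recovered")) do.call(rbind, out[status == "recovered"]) else empty_aln
  rownames(aln) <- NULL
  list(alignments = aln,
       report = data.frame(read_id = unmapped$read_id, status = status,
                           reason = reason, stringsAsFactors = FALSE))
}

#' Build the two collapsed-genome indexes used for hyper-editing recovery
#'
#' @param genome named character vector of chromosome sequences.
#' @param k seed length.
#' @return list with `ag` (A->G collapsed) and `tc` (T->C collapsed)
#'   [seed_index()] objects.
#' @export
hyper_indexes <- function(genome, k = 16L) {
  list(ag = seed_index(vapply(genome, transform_bases, character(1),
                              "A", "G"), k),
       tc = seed_index(vapply(genome, transform_bases, character(1),
                              "T", "C"), k))
}
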