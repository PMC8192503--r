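## Site annotation: genic region with a fixed precedence, repeat subfamily
## membership, recoding consequence via spliced-CDS translation, and
## flanking-base context on the edited strand.

GENIC_PRECEDENCE <- c("CDS", "UTR3", "UTR5", "intron", "noncoding-gene",
                      "intergenic")

#' Assign one genic-region label per site
#'
#' Overlapping transcripts are resolved by the fixed precedence
#' CDS > UTR3 > UTR5 > intron > noncoding-gene > intergenic, so the
#' assignment is a deterministic total function.
#'
#' @param sites data frame with `chrom`, `pos0`.
#' @param bundle a `GenomeBundle` (or a list with `genes` and `features`).
#' @return character vector of labels, one per site.
#' @export
assign_genic_region <- function(sites, bundle) {
  n <- nrow(sites)
  rank <- rep(6L, n)  # intergenic
  f <- bundle$features
  g <- bundle$genes
  sgr <- GenomicRanges::GRanges(sites$chrom,
                                IRanges::IRanges(sites$pos0 + 1L, width = 1L))
  label_hit <- function(df, lab_rank) {
    if (is.null(df) || nrow(df) == 0L) return()
    gr <- GenomicRanges::GRanges(df$chrom,
                                 IRanges::IRanges(df$start0 + 1L, df$end))
    hit <- unique(S4Vectors::queryHits(GenomicRanges::findOverlaps(sgr, gr)))
    rank[hit] <<- pmin(rank[hit], lab_rank)
  }
  label_hit(f[f$type == "CDS", ], 1L)
  label_hit(f[f$type == "UTR3", ], 2L)
  label_hit(f[f$type == "UTR5", ], 3L)
  ## intron = gene span (coding gene, rank 4) or noncoding gene span (5)
  coding_genes <- unique(f$gene_id[f$type == "CDS"])
  label_hit(g[g$gene_id %in% coding_genes, ], 4L)
  label_hit(g[!g$gene_id %in% coding_genes, ], 5L)
  GENIC_PRECEDENCE[rank]
}

#' Assign repeat subfamily membership
#'
#' Membership by half-open interval overlap; overlapping repeats are
#' resolved by smallest interval, then alphabetical subfamily name.
#'
#' @param sites data frame with `chrom`, `pos0`.
#' @param repeats repeat table (`chrom`, `start0`, `end`, `name`).
#' @return character vector of subfamily names, `NA` where outside all
#'   repeats.
#' @export
assign_repeat <- function(sites, repeats) {
  out <- rep(NA_character_, nrow(sites))
  if (is.null(repeats) || nrow(repeats) == 0L) return(out)
  sgr <- GenomicRanges::GRanges(sites$chrom,
                                IRanges::IRanges(sites$pos0 + 1L, width = 1L))
  rgr <- GenomicRanges::GRanges(repeats$chrom,
                                IRanges::IRanges(repeats$start0 + 1L,
                                                 repeats$end))
  ov <- GenomicRanges::findOverlaps(sgr, rgr)
  if (!length(ov)) return(out)
  q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
  width <- repeats$end[s] - repeats$start0[s]
  ord <- order(q, width, tolower(repeats$name[s]), method = "radix")
  first <- ord[!duplicated(q[ord])]
  out[q[first]] <- repeats$name[s[first]]
  out
}

## spliced CDS of a transcript: sequence, and genomic positions in coding
## order
spliced_cds <- function(bundle, transcript_id) {
  f <- bundle$features
  cds <- f[f$type == "CDS" & f$transcript_id == transcript_id, , drop = FALSE]
  if (nrow(cds) == 0L) return(NULL)
  strand <- cds$strand[1L]
  cds <- cds[order(if (strand == "+") cds$start0 else -cds$start0), ]
  pieces <- character(nrow(cds)); pos <- list()
  for (p in seq_len(nrow(cds))) {
    s <- substr(bundle$genome[[cds$chrom[p]]], cds$start0[p] + 1L, cds$end[p])
    if (strand == "-") {
      pieces[p] <- revcomp(s)
      pos[[p]] <- seq.int(cds$end[p] - 1L, cds$start0[p])
    } else {
      pieces[p] <- s
      pos[[p]] <- seq.int(cds$start0[p], cds$end[p] - 1L)
    }
  }
  list(seq = paste(pieces, collapse = ""), pos0 = unlist(pos),
       chrom = cds$chrom[1L], strand = strand)
}

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) NA_character_ else aa
}

#' Recoding consequence of a CDS editing site
#'
#' Builds the codon from the spliced CDS on the coding strand, substitutes
#' G at the edited position (inosine decoded as guanosine), and translates
#' with the standard genetic code. The notation follows the
#' ref-AA + codon-index + alt-AA convention (e.g. `Q607R`); synonymous
#' changes keep `is_synonymous = TRUE` and a `X<pos>X`-style notation is
#' not emitted for them.
#'
#' @param site list or one-row data frame with `chrom`, `pos0`, `strand`.
#' @param bundle a `GenomeBundle`.
#' @param gene_or_transcript gene or transcript identifier; defaults to the
#'   transcript whose CDS contains the site.
#' @return object of class `RecodingEffect`: `gene`, `transcript`,
#'   `codon_index`, `ref_aa`, `alt_aa`, `is_synonymous`, `notation`.
#' @export
recoding_effect <- function(site, bundle, gene_or_transcript = NULL) {
  f <- bundle$features
  if (is.null(gene_or_transcript)) {
    cds <- f[f$type == "CDS" & f$chrom == site$chrom &
             f$start0 <= site$pos0 & site$pos0 < f$end, , drop = FALSE]
    if (nrow(cds) == 0L) stopf("recoding_effect: site not in any CDS")
    tid <- cds$transcript_id[1L]
  } else {
    tid <- gene_or_transcript
    if (tid %in% f$gene_id)
      tid <- f$transcript_id[f$gene_id == tid][1L]
  }
  sc <- spliced_cds(bundle, tid)
  if (is.null(sc)) stopf("recoding_effect: transcript %s has no CDS", tid)
  if (nchar(sc$seq) %% 3L != 0L)
    return(structure(list(gene = NA, transcript = tid, codon_index = NA,
                          ref_aa = NA, alt_aa = NA, is_synonymous = NA,
                          notation = NA,
                          error = "CDS length not divisible by 3"),
                     class = "RecodingEffect"))
  off <- match(site$pos0, sc$pos0)  # 1-based offset in coding sequence
  if (is.na(off)) stopf("recoding_effect: site not in CDS of %s", tid)
  if (substr(sc$seq, off, off) != "A")
    stopf("recoding_effect: coding-strand base at site is not A")
  codon_index <- (off - 1L) %/% 3L + 1L
  cpos <- (off - 1L) %% 3L + 1L
  cstart <- (codon_index - 1L) * 3L + 1L
  ref_codon <- substr(sc$seq, cstart, cstart + 2L)
  alt_codon <- ref_codon
  substr(alt_codon, cpos, cpos) <- "G"
  ref_aa <- translate_codon(ref_codon)
  alt_aa <- translate_codon(alt_codon)
  gene <- f$gene_id[f$transcript_id == tid][1L]
  syn <- identical(ref_aa, alt_aa)
  structure(list(gene = gene, transcript = tid, codon_index = codon_index,
                 ref_aa = ref_aa, alt_aa = alt_aa, is_synonymous = syn,
                 notation = if (syn) NA_character_ else
                   sprintf("%s%d%s", ref_aa, codon_index, alt_aa)),
            class = "RecodingEffect")
}

#' @export
print.RecodingEffect <- function(x, ...) {
  if (!is.null(x$error)) cat("RecodingEffect: <", x$error, ">\n") else
    cat(sprintf("RecodingEffect: %s %s (%s%d%s)%s\n", x$gene, x$transcript,
                x$ref_aa, x$codon_index, x$alt_aa,
                if (x$is_synonymous) " synonymous" else ""))
  invisible(x)
}

#' Flanking-base frequencies around editing sites
#'
#' Reads `flank` bases on each side of every site on its edited strand
#' (reverse complement for minus-strand sites) and tabulates per-offset
#' base frequencies. Offsets are -flank..-1, +1..+flank; frequencies at
#' each offset sum to 1 over A/C/G/T (N excluded from the denominator).
#' Sites too close to a contig edge are excluded and counted.
#'
#' @param sites data frame with `chrom`, `pos0`, `strand`.
#' @param genome named character vector of chromosome sequences.
#' @param flank flank width in bp (default 5).
#' @return list with `freq` (4 x 2*flank matrix), `n_used`, `n_excluded`.
#' @export
context_frequencies <- function(sites, genome, flank = 5L) {
  offsets <- c(-(flank:1), seq_len(flank))
  counts <- matrix(0L, 4L, 2L * flank,
                   dimnames = list(BASES, as.character(offsets)))
  n_used <- 0L; n_excl <- 0L
  clen <- nchar(genome)
  for (i in seq_len(nrow(sites))) {
    p <- sites$pos0[i]
    if (p - flank < 0L || p + flank >= clen[[sites$chrom[i]]]) {
      n_excl <- n_excl + 1L
      next
    }
    ctx <- substr(genome[[sites$chrom[i]]], p - flank + 1L, p + flank + 1L)
    if (sites$strand[i] == "-") ctx <- revcomp(ctx)
    b <- strsplit(ctx, "")[[1]][-(flank + 1L)]  # drop the site itself
    code <- match(b, BASES)
    ok <- !is.na(code)
    counts[cbind(code[ok], which(ok))] <- counts[cbind(code[ok], which(ok))] + 1L
    n_used <- n_used + 1L
  }
  denom <- colSums(counts)
  freq <- sweep(counts, 2L, pmax(denom, 1L), "/")
  list(freq = freq, n_used = n_used, n_excluded = n_excl)
}

#' Randomly selected genomic A sites
#'
#' Background set for context comparisons: `n` positions with reference A
#' on the forward strand, drawn uniformly.
#'
#' @param genome named character vector of chromosome sequences.
#' @param n number of sites.
#' @param seed RNG seed.
#' @return data frame with `chrom`, `pos0`, `strand` ("+").
#' @export
random_A_background <- function(genome, n, seed = 1L) {
  set.seed(seed)
  pools <- lapply(names(genome), function(ci)
    base_positions(genome[[ci]], 0L, nchar(genome[[ci]]), "A"))
  names(pools) <- names(genome)
  sizes <- lengths(pools)
  if (sum(sizes) < n) stopf("random_A_background: fewer than %d A sites", n)
  ci <- sample(rep(names(genome), sizes), n)
  tab <- table(factor(ci, levels = names(genome)))
  out <- list()
  for (cn in names(genome)) {
    k <- tab[[cn]]
    if (k > 0L)
      out[[cn]] <- data.frame(chrom = cn,
                              pos0 = sample(pools[[cn]], k),
                              strand = "+", stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Annotate a master site list
#'
#' Adds genic-region label, repeat subfamily and (for CDS sites) the
#' recoding notation.
#'
#' @param master round-1 master list.
#' @param bundle a `GenomeBundle`.
#' @return `master` with `genic_region`, `repeat_name`, `recoding` columns.
#' @export
annotate_sites <- function(master, bundle) {
  master$genic_region <- assign_genic_region(master, bundle)
  master$repeat_name <- assign_repeat(master, bundle$repeats)
  master$recoding <- NA_character_
  for (i in which(master$genic_region == "CDS")) {
    eff <- tryCatch(recoding_effect(master[i, ], bundle),
                    error = function(e) NULL)
    if (!is.null(eff) && is.null(eff$error))
      master$recoding[i] <- if (isTRUE(eff$is_synonymous)) "synonymous" else
        eff$notation
  }
  master
}
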