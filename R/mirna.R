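## miRNA seed-site alteration prediction: does a 3'-UTR editing event
## destroy or create an exact Watson-Crick seed match (no G.U wobble)
## within the 13-nt flank centred on the site?

#' Load mature miRNA sequences
#'
#' Reads a miRBase-style FASTA; sequences are uppercased and T normalized
#' to U. Records containing characters outside A/U/C/G are rejected with a
#' message.
#'
#' @param path FASTA of mature miRNAs.
#' @return data frame with `id` and `seq` (RNA alphabet).
#' @export
load_mirnas <- function(path) {
  x <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  seqs <- chartr("Tt", "Uu", toupper(as.character(x)))
  ok <- !grepl("[^AUCG]", seqs)
  for (bad in which(!ok))
    message("load_mirnas: rejecting ", ids[bad],
            " (non-AUCG characters)")
  data.frame(id = ids[ok], seq = unname(seqs[ok]), stringsAsFactors = FALSE)
}

#' Extract the seed of a mature miRNA
#'
#' The default scheme takes positions 2-8 (a 7-nt seed); the literal 2-7
#' 6-nt scheme is selectable.
#'
#' @param mirna_sequence mature miRNA sequence (length >= 8).
#' @param scheme `"2-8"` (default, 7 nt) or `"2-7"` (6 nt).
#' @return seed string.
#' @export
seed_of <- function(mirna_sequence, scheme = c("2-8", "2-7")) {
  scheme <- match.arg(scheme)
  if (nchar(mirna_sequence) < 8L)
    stopf("seed_of: miRNA shorter than 8 nt")
  substr(mirna_sequence, 2L, if (scheme == "2-8") 8L else 7L)
}

## reverse complement in RNA alphabet
revcomp_rna <- function(x) {
  vapply(x, function(s)
    chartr("AUCGaucg", "UAGCuagc",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")),
    character(1), USE.NAMES = FALSE)
}

#' Scan a site flank for seed matches
#'
#' The 13-nt mRNA-sense flank (6 nt each side of the site) carries the
#' chosen allele at its centre. A (miRNA, offset) pair is reported iff the
#' seed-length window starting at that offset is the exact reverse
#' complement of the seed (A-U/G-C only) and the window covers the centre
#' position -- otherwise editing could not alter the match.
#'
#' @param flank13 13-nt flank on the transcript strand (DNA or RNA
#'   alphabet).
#' @param allele `"A"` or `"G"`, substituted at the centre.
#' @param seeds data frame with `id` and `seed` columns (see
#'   [seed_table()]).
#' @return data frame with `mirna` and `offset` (1-based window start in
#'   the flank); zero rows when nothing matches. `NULL` with a warning if
#'   the flank contains N.
#' @export
scan_site <- function(flank13, allele = c("A", "G"), seeds) {
  allele <- match.arg(allele)
  flank <- chartr("Tt", "Uu", toupper(flank13))
  if (nchar(flank) != 13L) stopf("scan_site: flank must be 13 nt")
  if (grepl("N", flank, fixed = TRUE)) {
    warning("scan_site: flank contains N; site skipped")
    return(NULL)
  }
  centre <- 7L
  substr(flank, centre, centre) <- if (allele == "A") "A" else "G"
  out <- list()
  if (nrow(seeds)) {
    wlen <- nchar(seeds$seed)
    target <- revcomp_rna(seeds$seed)
    for (i in seq_len(nrow(seeds))) {
      w <- wlen[i]
      for (off in seq_len(13L - w + 1L)) {
        if (!(off <= centre && centre <= off + w - 1L)) next
        if (substr(flank, off, off + w - 1L) == target[i])
          out[[length(out) + 1L]] <- data.frame(mirna = seeds$id[i],
                                                offset = off,
                                                stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(mirna = character(), offset = integer(),
               stringsAsFactors = FALSE)
}

#' Precompute a seed table from mature miRNAs
#'
#' @param mirnas [load_mirnas()] output.
#' @param scheme seed scheme, see [seed_of()].
#' @return data frame with `id` and `seed`.
#' @export
seed_table <- function(mirnas, scheme = "2-8") {
  keep <- nchar(mirnas$seq) >= 8L
  data.frame(id = mirnas$id[keep],
             seed = vapply(mirnas$seq[keep], seed_of, character(1),
                           scheme = scheme, USE.NAMES = FALSE),
             stringsAsFactors = FALSE)
}

#' Classify miRNA-site alteration by an editing event
#'
#' Runs [scan_site()] for both alleles: matches present with A but lost
#' with G are `destroyed`; matches created by G are `created`.
#'
#' @param flank13 13-nt transcript-strand flank centred on the site.
#' @param seeds seed table.
#' @return data frame of `MirnaHit` rows: `mirna`, `offset`, `status`,
#'   `allele` (the allele generating the match). Zero rows when no match
#'   under either allele.
#' @export
classify_alteration <- function(flank13, seeds) {
  a <- scan_site(flank13, "A", seeds)
  g <- scan_site(flank13, "G", seeds)
  if (is.null(a) || is.null(g))
    return(data.frame(mirna = character(), offset = integer(),
                      status = character(), allele = character(),
                      stringsAsFactors = FALSE))
  key_a <- paste(a$mirna, a$offset); key_g <- paste(g$mirna, g$offset)
  destroyed <- a[!key_a %in% key_g, , drop = FALSE]
  created <- g[!key_g %in% key_a, , drop = FALSE]
  unchanged <- a[key_a %in% key_g, , drop = FALSE]
  out <- rbind(
    if (nrow(destroyed)) cbind(destroyed, status = "destroyed", allele = "A"),
    if (nrow(created)) cbind(created, status = "created", allele = "G"),
    if (nrow(unchanged)) cbind(unchanged, status = "unchanged", allele = "A"))
  out %||% data.frame(mirna = character(), offset = integer(),
                      status = character(), allele = character(),
                      stringsAsFactors = FALSE)
}

#' Transcript-strand flank of a genomic site
#'
#' @param bundle a `GenomeBundle`.
#' @param chrom,pos0,strand site coordinates and edited strand.
#' @param width flank width each side (default 6).
#' @return flank string read 5'->3' on the edited strand, or `NA` if the
#'   site is too close to the contig edge.
#' @export
site_flank <- function(bundle, chrom, pos0, strand, width = 6L) {
  clen <- nchar(bundle$genome[[chrom]])
  if (pos0 - width < 0L || pos0 + width >= clen) return(NA_character_)
  s <- substr(bundle$genome[[chrom]], pos0 - width + 1L, pos0 + width + 1L)
  if (strand == "-") revcomp(s) else s
}

#' Predict miRNA-site alterations for annotated 3'-UTR sites
#'
#' @param master annotated master list (needs `genic_region`).
#' @param bundle a `GenomeBundle`.
#' @param seeds seed table.
#' @return data frame with one row per (site, miRNA, window) hit.
#' @export
mirna_alterations <- function(master, bundle, seeds) {
  rows <- list()
  for (i in which(master$genic_region == "UTR3")) {
    fl <- site_flank(bundle, master$chrom[i], master$pos0[i],
                     master$strand[i])
    if (is.na(fl)) next
    hits <- classify_alteration(fl, seeds)
    if (nrow(hits)) {
      hits$chrom <- master$chrom[i]; hits$pos0 <- master$pos0[i]
      rows[[length(rows) + 1L]] <- hits
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mirna = character(), offset = integer(), status = character(),
               allele = character(), chrom = character(), pos0 = integer(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
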