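## Cross-species (or cross-condition) differential editing at conserved
## sites: per-region count pooling, a two-sided Fisher exact test built on
## direct hypergeometric enumeration, and bias classification at an
## absolute level difference >= 20 percentage points and P < 0.01.

#' Read a conserved-site mapping table
#'
#' TSV with 1-based positions:
#' `chrom_a, pos_a, strand_a, chrom_b, pos_b, strand_b`. The mapping must
#' be one-to-one.
#'
#' @param path TSV path.
#' @return data frame with the six columns plus 0-based `pos0_a`, `pos0_b`.
#' @export
read_conserved_map <- function(path) {
  m <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("chrom_a", "pos_a", "strand_a", "chrom_b", "pos_b", "strand_b")
  if (!all(need %in% names(m)))
    stopf("read_conserved_map: columns must be %s", paste(need, collapse = ", "))
  ka <- paste(m$chrom_a, m$pos_a); kb <- paste(m$chrom_b, m$pos_b)
  if (anyDuplicated(ka) || anyDuplicated(kb))
    stopf("read_conserved_map: mapping is not one-to-one")
  m$pos0_a <- m$pos_a - 1L
  m$pos0_b <- m$pos_b - 1L
  m
}

#' Pool per-sample counts into per-region counts for one species
#'
#' Shares the [pool_counts()] contract; provided as the species-facing
#' entry point of the cross-species comparison.
#'
#' @param m per-sample `EditingMatrix` of one species.
#' @param region_map character vector mapping each sample column to a
#'   region.
#' @return region-level `EditingMatrix`.
#' @export
pool_by_region <- function(m, region_map) pool_counts(m, region_map)

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Enumerates the hypergeometric support with fixed margins and sums the
#' probabilities of all tables whose point probability does not exceed
#' that of the observed table (relative tolerance 1e-7). A zero margin
#' gives p = 1.
#'
#' @param a,b,c,d cell counts of the table `rbind(c(a, b), c(c, d))`
#'   (e.g. edited/unedited x species).
#' @return two-sided p value.
#' @export
fisher_exact_two_sided <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  m1 <- a + b; m2 <- c + d; k <- a + c
  if (m1 == 0 || m2 == 0 || k == 0 || (b + d) == 0) return(1)
  lo <- max(0, k - m2); hi <- min(k, m1)
  x <- lo:hi
  logp <- lchoose(m1, x) + lchoose(m2, k - x) - lchoose(m1 + m2, k)
  p_obs <- logp[x == a]
  sum(exp(logp[logp <= p_obs + log(1 + 1e-7)]))
}

#' Differential editing calls at conserved sites
#'
#' For each (site, region) with both species covered at
#' `min_coverage` or more pooled reads, tests the edited/unedited split by
#' [fisher_exact_two_sided()] and labels the site `A-biased` / `B-biased`
#' when the absolute level difference is at least `delta_min` and p is
#' below `alpha`; `unbiased` otherwise; `untestable` where a species lacks
#' coverage.
#'
#' @param counts data frame with one row per (site, region):
#'   `site`, `region`, `G_a`, `total_a`, `G_b`, `total_b`.
#' @param delta_min minimum absolute level difference (default 0.20,
#'   percentage points).
#' @param alpha significance threshold on the raw p value (default 0.01;
#'   no multiple-testing correction unless `adjust = "BH"`).
#' @param min_coverage per-species pooled coverage floor (default 10).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return `counts` with `p`, `delta_level` (A - B) and `bias` columns.
#' @export
call_differential <- function(counts, delta_min = 0.20, alpha = 0.01,
                              min_coverage = 10L, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  n <- nrow(counts)
  p <- rep(NA_real_, n); delta <- rep(NA_real_, n)
  bias <- rep("untestable", n)
  testable <- !is.na(counts$total_a) & !is.na(counts$total_b) &
    counts$total_a >= min_coverage & counts$total_b >= min_coverage
  for (i in which(testable)) {
    ga <- counts$G_a[i]; ta <- counts$total_a[i]
    gb <- counts$G_b[i]; tb <- counts$total_b[i]
    p[i] <- fisher_exact_two_sided(ga, ta - ga, gb, tb - gb)
    delta[i] <- ga / ta - gb / tb
  }
  p_eff <- p
  if (adjust == "BH") p_eff[testable] <- stats::p.adjust(p[testable], "BH")
  sig <- testable & !is.na(p_eff) & abs(delta) >= delta_min & p_eff < alpha
  bias[testable] <- "unbiased"
  bias[sig & delta > 0] <- "A-biased"
  bias[sig & delta < 0] <- "B-biased"
  counts$p <- p
  counts$delta_level <- delta
  counts$bias <- bias
  counts
}

#' Compare editing levels of conserved vs non-conserved sites
#'
#' Two-sided Wilcoxon rank-sum test on per-site pooled levels, with group
#' medians; used for the conserved-recoding comparison.
#'
#' @param conserved_levels,nonconserved_levels numeric level vectors.
#' @return list with `median_conserved`, `median_nonconserved`,
#'   `statistic`, `p`.
#' @export
conserved_vs_nonconserved_levels <- function(conserved_levels,
                                             nonconserved_levels) {
  if (!length(conserved_levels) || !length(nonconserved_levels))
    stopf("conserved_vs_nonconserved_levels: both groups must be non-empty")
  wt <- wilcoxon_rank_sum(conserved_levels, nonconserved_levels)
  list(median_conserved = median(conserved_levels),
       median_nonconserved = median(nonconserved_levels),
       statistic = wt$statistic, p = wt$p)
}
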