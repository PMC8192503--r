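## Region-specificity classification of editing sites, adapted from the
## tissue-expression stratification scheme: region-enriched, group-enriched
## and region-enhanced categories under a minimum level (25%) and an
## absolute margin (20 percentage points), after expression and coverage
## gates.

#' Gate genes by expression stability
#'
#' A gene is eligible when its coefficient of variation across regions is
#' below `cv_max` and its normalized expression is at least `min_expr` in
#' every region.
#'
#' @param expression genes x regions matrix of normalized expression.
#' @param cv_max CV threshold (default 1).
#' @param min_expr expression floor (default 10).
#' @param cv_type CV convention, see [coef_variation()].
#' @return character vector of eligible gene names.
#' @export
gate_genes <- function(expression, cv_max = 1, min_expr = 10,
                       cv_type = "population") {
  cv <- apply(expression, 1L, coef_variation, type = cv_type)
  ok <- cv < cv_max & apply(expression, 1L, function(x) all(x >= min_expr))
  rownames(expression)[which(ok)]
}

#' Gate sites for specificity evaluation
#'
#' A site is evaluable when its pooled region total is at least `min_total`
#' in at least two-thirds of the regions (rounded per `round`) and its
#' host gene passed [gate_genes()].
#'
#' @param m region-level `EditingMatrix`.
#' @param site_genes character vector of host-gene ids per site (`NA` for
#'   intergenic sites, which are never evaluable).
#' @param eligible_genes output of [gate_genes()].
#' @param min_total per-region coverage floor (default 10 reads).
#' @param coverage_fraction fraction of regions that must pass (default
#'   2/3).
#' @param round rounding rule for the region quorum, `"ceiling"` (default)
#'   or `"floor"`.
#' @return logical vector of evaluable sites.
#' @export
gate_sites <- function(m, site_genes, eligible_genes, min_total = 10L,
                       coverage_fraction = 2 / 3,
                       round = c("ceiling", "floor")) {
  round <- match.arg(round)
  n_regions <- ncol(m$total)
  quorum <- if (round == "ceiling") ceiling(coverage_fraction * n_regions)
            else floor(coverage_fraction * n_regions)
  covered <- rowSums(m$total >= min_total & !is.na(m$total)) >= quorum
  covered & !is.na(site_genes) & site_genes %in% eligible_genes
}

#' Classify the region specificity of one site
#'
#' Categories are evaluated in the order region-enriched, group-enriched,
#' region-enhanced, low-specificity, so they are mutually exclusive:
#' \itemize{
#' \item region-enriched: one region with level >= `min_level` exceeding
#'   every other region by >= `margin`;
#' \item group-enriched: a set S of 2..`group_max` regions, each >=
#'   `min_level`, whose minimum exceeds every region outside S by >=
#'   `margin` (the smallest such S is taken, ties by region name);
#' \item region-enhanced: one region >= `min_level` exceeding the mean of
#'   all regions by >= `margin`.
#' }
#' Differences are absolute (percentage points). Sites with undefined
#' levels in more than a third of the regions are `not-evaluated`.
#'
#' @param levels named numeric vector of per-region pooled levels (`NA`
#'   where not covered).
#' @param min_level minimum level of the driving region(s) (default 0.25).
#' @param margin required absolute difference (default 0.20).
#' @param group_max largest group size (default `floor(n/3)`).
#' @return object of class `SpecificityCall`: `category`, `regions`,
#'   `margin`.
#' @export
classify_specificity <- function(levels, min_level = 0.25, margin = 0.20,
                                 group_max = NULL) {
  n <- length(levels)
  if (is.null(names(levels))) names(levels) <- paste0("R", seq_len(n))
  group_max <- group_max %||% floor(n / 3)
  call <- function(category, regions = character(), mar = NA_real_)
    structure(list(category = category, regions = regions, margin = mar),
              class = "SpecificityCall")
  if (sum(is.na(levels)) > n / 3) return(call("not-evaluated"))
  def <- levels[!is.na(levels)]
  if (length(def) < 2L) return(call("not-evaluated"))
  ord <- order(-def, names(def))
  sorted <- def[ord]
  ## region-enriched: top region vs the best of the rest
  if (sorted[1L] >= min_level && sorted[1L] - sorted[2L] >= margin)
    return(call("region-enriched", names(sorted)[1L],
                unname(sorted[1L] - sorted[2L])))
  ## group-enriched: any qualifying S must contain exactly the top |S|
  ## levels, so scan sorted prefixes from the smallest size up
  if (group_max >= 2L && length(def) > 2L) {
    for (m in 2:min(group_max, length(def) - 1L)) {
      if (sorted[m] >= min_level && sorted[m] - sorted[m + 1L] >= margin)
        return(call("group-enriched", sort(names(sorted)[seq_len(m)]),
                    unname(sorted[m] - sorted[m + 1L])))
    }
  }
  ## region-enhanced: top region vs the mean of all defined regions
  if (sorted[1L] >= min_level && sorted[1L] - mean(def) >= margin)
    return(call("region-enhanced", names(sorted)[1L],
                unname(sorted[1L] - mean(def))))
  call("low-specificity")
}

#' @export
print.SpecificityCall <- function(x, ...) {
  cat(sprintf("SpecificityCall: %s%s%s\n", x$category,
              if (length(x$regions)) paste0(" [", paste(x$regions,
                                                        collapse = ","), "]")
              else "",
              if (!is.na(x$margin)) sprintf(" margin %.3f", x$margin) else ""))
  invisible(x)
}

#' Classify specificity for every evaluable site of a matrix
#'
#' @param m region-level `EditingMatrix`.
#' @param evaluable logical gate from [gate_sites()] (default: all).
#' @param min_total coverage floor below which a region's level is treated
#'   as undefined.
#' @param ... passed to [classify_specificity()].
#' @return data frame with `site`, `category`, `regions`, `margin`.
#' @export
classify_specificity_all <- function(m, evaluable = NULL, min_total = 10L,
                                     ...) {
  lv <- editing_levels(m)
  lv[is.na(m$total) | m$total < min_total] <- NA_real_
  evaluable <- evaluable %||% rep(TRUE, nrow(lv))
  rows <- lapply(seq_len(nrow(lv)), function(i) {
    if (!evaluable[i])
      return(data.frame(site = rownames(lv)[i], category = "not-evaluated",
                        regions = "", margin = NA_real_,
                        stringsAsFactors = FALSE))
    cl <- classify_specificity(lv[i, ], ...)
    data.frame(site = rownames(lv)[i], category = cl$category,
               regions = paste(cl$regions, collapse = ","),
               margin = cl$margin, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
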