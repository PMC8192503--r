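test_that("count pooling follows the coverage-weighted identities", {
  m <- editing_matrix(G = cbind(s1 = c(1L, 2L), s2 = c(3L, 8L)),
                      total = cbind(s1 = c(10L, 10L), s2 = c(10L, 10L)))
  pooled <- pool_counts(m, c("r", "r"))
  expect_equal(unname(pooled$G[, 1L]), c(4L, 10L))
  expect_equal(unname(editing_levels(pooled)[1L, 1L]), 0.2)  # 4/20
  ## single-sample group is the identity
  id <- pool_counts(m, c("a", "b"))
  expect_equal(unname(id$G), unname(m$G))
  ## pooled level equals the coverage-weighted mean of member levels
  set.seed(101)
  G <- matrix(rbinom(60, 40, 0.3), 10)
  total <- G + matrix(rbinom(60, 60, 0.5), 10)
  mm <- editing_matrix(G, total)
  pl <- editing_levels(pool_counts(mm, rep("all", 6)))[, 1L]
  w <- editing_levels(mm) * mm$total
  expect_equal(unname(pl), unname(rowSums(w) / rowSums(mm$total)))
  ## associativity over nested groupings
  g1 <- c("a", "a", "b", "b", "c", "c")
  nested <- pool_counts(pool_counts(mm, g1), c("x", "x", "y"))
  direct <- pool_counts(mm, c("x", "x", "x", "x", "y", "y"))
  expect_equal(nested$G, direct$G)
  expect_equal(nested$total, direct$total)
  ## empty/invalid group labels are refused
  expect_error(pool_counts(m, c("r", NA)), "group")
})

test_that("overall editing equals single-group pooling", {
  m <- editing_matrix(G = cbind(s = c(2L, 8L)), total = cbind(s = c(10L, 10L)))
  expect_equal(overall_editing(m, "s"), 0.5)  # 10/20
  all0 <- editing_matrix(G = cbind(s = c(0L, 0L)),
                         total = cbind(s = c(10L, 5L)))
  expect_equal(overall_editing(all0, "s"), 0)
  set.seed(7)
  G <- matrix(rbinom(40, 30, 0.2), 10); total <- G + 20L
  mm <- editing_matrix(G, total)
  pooled <- pool_counts(mm, rep("all", 4))
  for (j in 1:4)
    expect_equal(overall_editing(mm, j),
                 sum(mm$G[, j]) / sum(mm$total[, j]))
  expect_equal(overall_editing(pooled, "all"),
               sum(G) / sum(total))
  ## zero total -> undefined
  expect_true(is.na(overall_editing(
    editing_matrix(cbind(0L), cbind(0L)), 1L)))
})

test_that("normalized site counts scale as sites per million reads", {
  expect_equal(normalized_site_count(1000, 1e7), 100)
  expect_equal(normalized_site_count(0, 1e7), 0)
  expect_equal(normalized_site_count(500, 2e6),
               normalized_site_count(500, 1e6) / 2)
  expect_error(normalized_site_count(10, 0), "> 0")
})

test_that("size factors reproduce the median-of-ratios closed forms", {
  x <- matrix(rpois(200, 50) + 1L, 50)
  same <- cbind(a = x[, 1L], b = x[, 1L])
  expect_equal(unname(size_factors(same)$size_factors), c(1, 1))
  doubled <- cbind(a = x[, 1L], b = 2L * x[, 1L])
  expect_equal(unname(size_factors(doubled)$size_factors),
               c(1 / sqrt(2), sqrt(2)))
  nf <- size_factors(doubled)$normalized
  expect_equal(unname(colSums(nf)[1L]), unname(colSums(nf)[2L]))
  ## invariance to gene order; scaling one sample scales its factor
  set.seed(13)
  m <- matrix(rpois(300, 30) + 1L, 100)
  sf <- size_factors(m)$size_factors
  perm <- sample(nrow(m))
  expect_equal(size_factors(m[perm, ])$size_factors, sf)
  ## scaling one sample by c scales its factor by c relative to the others
  m2 <- m; m2[, 2L] <- m2[, 2L] * 3L
  sf2 <- size_factors(m2)$size_factors
  expect_equal((sf2[2L] / sf2[1L]) / (sf[2L] / sf[1L]), 3, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_error(size_factors(matrix(c(0L, 1L, 1L, 0L), 2)), "positive")
})

test_that("size factors agree with the DESeq2 reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(19)
  counts <- matrix(rnbinom(600, mu = 100, size = 5), 100)
  counts[counts == 0] <- 1L
  ours <- size_factors(counts)$size_factors
  ref <- DESeq2::estimateSizeFactorsForMatrix(counts)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-8)
})

test_that("cluster fraction matches the all-windows brute force", {
  expect_equal(cluster_fraction(c(1, 50, 99)), 1)
  expect_equal(cluster_fraction(c(1, 200, 400)), 0)
  brute <- function(pos, window = 100, m = 3) {
    pos <- sort(pos)
    n <- length(pos)
    out <- logical(n)
    for (i in seq_len(n)) for (j in seq_len(n)) for (k in j:n) {
      if (j <= i && i <= k && k - j + 1L >= m &&
          pos[k] - pos[j] <= window) { out[i] <- TRUE; break }
    }
    mean(out)
  }
  set.seed(23)
  for (rep in 1:10) {
    pos <- sample.int(2000L, 80L)
    expect_equal(cluster_fraction(pos), brute(pos))
    expect_equal(cluster_fraction(pos, min_sites = 4L),
                 brute(pos, m = 4))
  }
  ## monotone non-decreasing in window size
  pos <- sample.int(5000L, 200L)
  fr <- vapply(c(50, 100, 200, 400), function(w)
    cluster_fraction(pos, window = w), numeric(1))
  expect_true(all(diff(fr) >= 0))
})

test_that("level PCA is centred, orthonormal and complete", {
  set.seed(29)
  G <- matrix(rbinom(200, 50, 0.3), 50)
  total <- matrix(50L, 50, 4)
  m <- editing_matrix(G, total)
  p <- pca_on_levels(m)
  expect_equal(sum(p$explained), 1)
  expect_equal(crossprod(p$rotation), diag(ncol(p$rotation)),
               ignore_attr = TRUE)
  ## reconstruction equals the centred input
  lv <- t(editing_levels(m))
  centred <- scale(lv, center = TRUE, scale = FALSE)
  expect_equal(unname(p$scores %*% t(p$rotation)), unname(centred),
               tolerance = 1e-9, ignore_attr = TRUE)
  ## identical columns -> zero variance everywhere
  m2 <- editing_matrix(cbind(G[, 1L], G[, 1L]), total[, 1:2])
  expect_equal(sum(pca_on_levels(m2)$scores^2), 0)
  ## one varying site -> PC1 explains everything
  G3 <- matrix(10L, 20, 3); G3[5L, ] <- c(0L, 25L, 50L)
  p3 <- pca_on_levels(editing_matrix(G3, matrix(50L, 20, 3)))
  expect_equal(p3$explained[1L], 1)
  ## coverage gate removes low-coverage sites
  G4 <- G; G4[1L, 2L] <- 0L
  total4 <- total; total4[1L, 2L] <- 5L
  expect_equal(pca_on_levels(editing_matrix(G4, total4))$n_sites, 49L)
  expect_error(pca_on_levels(editing_matrix(cbind(G[, 1L]),
                                            cbind(total[, 1L]))), "two")
})

test_that("correlation and variance explained follow the closed forms", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(variance_explained(x, 2 * x + 1)$r_squared, 1)
  y <- c(1, -1, 1, -1, 1) - mean(c(1, -1, 1, -1, 1))
  expect_equal(pearson_r(x - mean(x), y), 0)
  set.seed(37)
  for (i in 1:5) {
    a <- rnorm(20); b <- rnorm(20)
    manual <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(pearson_r(a, b), manual, tolerance = 1e-12)
    ve <- variance_explained(a, b)
    expect_equal(ve$r_squared, manual^2, tolerance = 1e-12)
    ## p from the t transform of r
    tt <- manual * sqrt(18 / (1 - manual^2))
    expect_equal(ve$p, 2 * pt(-abs(tt), 18), tolerance = 1e-10)
  }
  expect_true(is.na(pearson_r(c(1, 1, 1), c(1, 2, 3))))
})

test_that("rank-sum test is exact for small samples, approximate beyond", {
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4))$p, 1 / 3)
  expect_equal(wilcoxon_rank_sum(c(5, 6, 7), c(5, 6, 7))$p, 1)
  ## exact enumeration oracle over all C(6,3) assignments
  a <- c(1.2, 3.4, 0.5); b <- c(2.2, 5.1, 4.4)
  pooled <- c(a, b)
  combos <- combn(6L, 3L)
  w_obs <- sum(rank(pooled)[1:3]) - 3 * 4 / 2
  ws <- apply(combos, 2L, function(idx)
    sum(rank(pooled)[idx]) - 3 * 4 / 2)
  p_oracle <- mean(abs(ws - 4.5) >= abs(w_obs - 4.5))
  expect_equal(wilcoxon_rank_sum(a, b)$p, p_oracle)
  ## exact and normal approximation agree closely at n = 12
  set.seed(43)
  for (i in 1:5) {
    g1 <- rnorm(6); g2 <- rnorm(6)
    p_exact <- wilcoxon_rank_sum(g1, g2)$p
    p_approx <- suppressWarnings(
      stats::wilcox.test(g1, g2, exact = FALSE, correct = TRUE)$p.value)
    expect_lt(abs(p_exact - p_approx), 0.02)
  }
})

test_that("level strata and CV conventions behave as documented", {
  s <- stratify_levels(c(0.1, 0.5, 0.8, 0.25, 0.75))
  expect_equal(as.character(s), c("low", "mid", "high", "mid", "high"))
  expect_equal(coef_variation(c(2, 2, 2)), 0)
  x <- c(1, 2, 3, 4)
  expect_equal(coef_variation(x, "population"),
               sqrt(mean((x - 2.5)^2)) / 2.5)
  expect_equal(coef_variation(x, "sample"), sd(x) / 2.5)
})
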