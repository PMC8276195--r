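test_that("CPM follows the direct formula and is scale invariant", {
  m <- matrix(c(1, 1, 2), 3, 1, dimnames = list(paste0("f", 1:3), "s1"))
  expect_equal(unname(cpm_matrix(m)[, 1]), c(250000, 250000, 500000))
  set.seed(31)
  m2 <- matrix(rpois(60, 40), 10, 6,
               dimnames = list(paste0("f", 1:10), paste0("s", 1:6)))
  expect_equal(cpm_matrix(m2), cpm_matrix(2 * m2))
  direct <- sweep(m2, 2, colSums(m2), "/") * 1e6
  expect_equal(unname(cpm_matrix(m2)), unname(direct))
  expect_equal(unname(colSums(cpm_matrix(m2))), rep(1e6, 6))
  expect_error(cpm_matrix(cbind(m2, s7 = 0)), "zero library")
})

test_that("low-expression filter keeps exactly the planted passers", {
  set.seed(32)
  pass <- matrix(rpois(100 * 4, 200), 100, 4)
  fail <- matrix(rpois(50 * 4, 0.05), 50, 4)
  m <- rbind(pass, fail)
  rownames(m) <- paste0("f", 1:150); colnames(m) <- paste0("s", 1:4)
  fl <- filter_low(m, 1, 2)
  expect_equal(nrow(fl$counts), 100)
  expect_setequal(fl$kept, paste0("f", 1:100))
  # idempotent
  fl2 <- filter_low(fl$counts, 1, 2)
  expect_identical(fl2$counts, fl$counts)
  expect_error(filter_low(m, 1, 10), "exceeds")
  expect_equal(nrow(fl$avg_log_cpm), 150)
})

test_that("TMM factors are 1 for identical or purely rescaled libraries", {
  set.seed(33)
  base <- rpois(500, 60)
  m <- matrix(base, 500, 4,
              dimnames = list(paste0("f", 1:500), paste0("s", 1:4)))
  for (variant in c("TMM", "TMMwsp")) {
    f <- tmm_factors(m, variant)
    expect_equal(unname(f), rep(1, 4), tolerance = 1e-9)
  }
  # doubled depth, same composition: factor ratio stays within 1% of 1
  m2 <- m; m2[, 2] <- rpois(500, 2 * base)
  f2 <- tmm_factors(m2)
  expect_lt(abs(f2[["s2"]] / f2[["s1"]] - 1), 0.01)
  expect_equal(exp(mean(log(f2))), 1, tolerance = 1e-9)
  expect_error(tmm_factors(cbind(m, z = 0)), "all-zero")
})

test_that("TMM resists planted asymmetric composition shifts", {
  set.seed(34)
  mu <- rgamma(2000, 5, scale = 10)
  shifted <- 1:100  # 5% of features strongly up in s2 only
  s1 <- rpois(2000, mu)
  mu2 <- mu; mu2[shifted] <- mu2[shifted] * 20
  s2 <- rpois(2000, mu2)
  m <- cbind(s1 = s1, s2 = s2)
  rownames(m) <- paste0("f", 1:2000)
  f <- tmm_factors(m)
  ratio_tmm <- f[["s2"]] / f[["s1"]]
  # both samples sequence the unshifted majority at equal depth, so equal
  # effective library sizes (colsum x factor) are the truth:
  # factor ratio = colsum1/colsum2 < 1; column-sum scaling alone sits at 1
  truth <- sum(m[, 1]) / sum(m[, 2])
  expect_equal(log(ratio_tmm), log(truth), tolerance = 0.1)
  expect_lt(abs(log(ratio_tmm) - log(truth)), abs(log(1) - log(truth)))
})

test_that("RLE size factors match the median-of-ratios oracle", {
  set.seed(35)
  m <- matrix(rpois(2000, 100), 500, 4,
              dimnames = list(paste0("f", 1:500), paste0("s", 1:4)))
  ident <- matrix(m[, 1], 500, 4,
                  dimnames = dimnames(m))
  expect_equal(unname(rle_factors(ident)), rep(1, 4))
  m3 <- m; m3[, 3] <- round(m[, 3] * 3)
  raw <- rle_factors(m3, rescale = FALSE)
  expect_equal(unname(raw[3] / raw[1]), 3, tolerance = 0.05)
  skip_if_not_installed("DESeq2")
  oracle <- DESeq2::estimateSizeFactorsForMatrix(m3)
  expect_equal(unname(rle_factors(m3, rescale = FALSE)), unname(oracle),
               tolerance = 1e-6)
  expect_error(rle_factors(matrix(c(0, 1, 1, 0), 2, 2)), "positive")
})

test_that("RLE plot statistics centre and track sample shifts", {
  set.seed(36)
  x <- matrix(rnorm(300 * 5, 5), 300, 5,
              dimnames = list(NULL, paste0("s", 1:5)))
  st <- rle_plot_stats(x)
  expect_true(all(abs(st$median) < 0.2))
  x2 <- x; x2[, 3] <- x2[, 3] + 2
  st2 <- rle_plot_stats(x2)
  expect_equal(st2$median[3], 2, tolerance = 0.25)
  # invariant to feature order
  st3 <- rle_plot_stats(x2[sample(nrow(x2)), ])
  expect_equal(st2, st3)
})

test_that("biodetection reproduces planted biotype shares", {
  set.seed(37)
  n_pi <- 300; n_mi <- 100
  universe <- c(rep("piRNA", n_pi), rep("miRNA", n_mi))
  names(universe) <- paste0("f", seq_along(universe))
  bt <- universe
  # sample 1: ~75% of detected features are piRNA; sample 2: ~20%
  s1 <- c(rbinom(n_pi, 1, 0.9), rbinom(n_mi, 1, 0.9)) * rpois(400, 20)
  det2 <- c(rep(1, 50), rep(0, 250), rep(1, 100))
  s2 <- det2 * rpois(400, 20)
  m <- cbind(s1 = s1, s2 = s2)
  rownames(m) <- names(universe)
  bd <- biodetection(m, bt, universe)
  expect_equal(sum(bd$within_sample_pct[bd$sample == "s1"]), 100,
               tolerance = 0.01)
  expect_equal(sum(bd$within_sample_pct[bd$sample == "s2"]), 100,
               tolerance = 0.01)
  pi1 <- bd$within_sample_pct[bd$sample == "s1" & bd$biotype == "piRNA"]
  pi2 <- bd$within_sample_pct[bd$sample == "s2" & bd$biotype == "piRNA"]
  expect_equal(pi1, 75, tolerance = 8)
  expect_lt(pi2, 45)
  expect_equal(unique(bd$genome_pct[bd$biotype == "piRNA"]), 75)
  # empty sample detects nothing
  m0 <- cbind(m, s3 = 0)
  bd0 <- biodetection(m0, bt, universe)
  expect_equal(sum(bd0$detected_n[bd0$sample == "s3"]), 0)
  expect_error(biodetection(m, bt[-1], universe), "without biotype")
})

test_that("ordination separates planted groups and matches SVD", {
  set.seed(38)
  base <- matrix(rnorm(400 * 6, 8), 400, 6,
                 dimnames = list(paste0("f", 1:400), paste0("s", 1:6)))
  base[1:80, 4:6] <- base[1:80, 4:6] + 3
  for (kind in c("MDS", "PCA")) {
    co <- ordination(base, kind)
    d <- as.matrix(dist(co[, c("dim1", "dim2")]))
    within <- c(d[1, 2], d[1, 3], d[4, 5], d[4, 6])
    between <- c(d[1, 4], d[2, 5], d[3, 6])
    expect_gt(min(between), max(within))
  }
  # PCA equals the SVD of centred data
  co <- ordination(base, "PCA")
  ce <- scale(t(base), center = TRUE, scale = FALSE)
  sv <- svd(ce)
  pc <- sv$u[, 1:2] %*% diag(sv$d[1:2])
  expect_equal(abs(co$dim1), abs(pc[, 1]), tolerance = 1e-8)
  expect_equal(abs(co$dim2), abs(pc[, 2]), tolerance = 1e-8)
  expect_equal(sum(attr(co, "explained") <= 1), 2)
  # identical samples collapse to a point
  same <- matrix(5, 50, 3, dimnames = list(NULL, paste0("s", 1:3)))
  co0 <- ordination(same, "MDS")
  expect_true(all(co0$dim1 == 0 & co0$dim2 == 0))
  expect_error(ordination(base[, 1:2], "PCA"), "at least 3")
})

test_that("clustering splits planted groups under all linkages", {
  set.seed(39)
  x <- matrix(rnorm(200 * 6, 10), 200, 6,
              dimnames = list(NULL, c(paste0("a", 1:3), paste0("b", 1:3))))
  x[1:50, 4:6] <- x[1:50, 4:6] + 4
  for (linkage in c("ward", "complete", "average")) {
    cl <- cluster_samples(x, linkage)
    groups <- cutree(cl$hclust, k = 2)
    expect_equal(length(unique(groups[1:3])), 1)
    expect_equal(length(unique(groups[4:6])), 1)
    expect_false(groups[1] == groups[4])
  }
  expect_equal(dim(cl$correlation), c(6, 6))
})

test_that("average-linkage merge heights match naive agglomeration", {
  set.seed(40)
  x <- matrix(rnorm(30 * 6), 30, 6,
              dimnames = list(NULL, paste0("s", 1:6)))
  hc <- cluster_samples(x, "average")$hclust
  # naive average-linkage agglomeration on the same distance matrix
  d <- as.matrix(dist(t(x)))
  clusters <- as.list(1:6)
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, 0, 0)
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1)) {
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best[1]) best <- c(h, j, i)
      }
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  expect_equal(sort(hc$height), sort(heights), tolerance = 1e-9)
})

test_that("summaries are invariant to feature and sample order", {
  set.seed(41)
  m <- matrix(rpois(300 * 4, 50), 300, 4,
              dimnames = list(paste0("f", 1:300), paste0("s", 1:4)))
  fo <- sample(nrow(m))
  f1 <- tmm_factors(m)
  f2 <- tmm_factors(m[fo, ])
  expect_equal(f1, f2)
  r1 <- rle_factors(m); r2 <- rle_factors(m[fo, ])
  expect_equal(r1, r2)
  so <- c(3, 1, 4, 2)
  expect_equal(tmm_factors(m[, so]), f1[so])
})
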