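mat <- function(x, genes = NULL, samples = NULL) {
  m <- as.matrix(x)
  rownames(m) <- genes %||% sprintf("g%d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("s%d", seq_len(ncol(m)))
  storage.mode(m) <- "integer"
  m
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("filter_low_expression keeps exactly genes with total >= cutoff", {
  m <- mat(rbind(c(5, 4), c(5, 5), c(0, 0)))
  kept <- filter_low_expression(m, 10)
  expect_identical(rownames(kept), c("g2"))

  expect_warning(out <- filter_low_expression(mat(matrix(0L, 3, 2))), "no genes")
  expect_equal(nrow(out), 0L)

  # brute-force oracle on a random 100-gene matrix
  set.seed(1)
  m <- mat(matrix(rpois(100 * 4, 3), 100, 4))
  kept <- filter_low_expression(m, 10)
  oracle <- rownames(m)[sapply(seq_len(nrow(m)), function(i) sum(m[i, ]) >= 10)]
  expect_identical(rownames(kept), oracle)
})

test_that("size_factors implements median-of-ratios", {
  m <- mat(matrix(rep(c(10L, 20L, 40L, 80L, 5L), 4), 5, 4))
  expect_equal(unname(size_factors(m)), rep(1, 4))

  # doubling one column doubles its size factor relative to the others
  # (each geometric mean also moves by 2^(1/n), so compare ratios)
  set.seed(2)
  m <- mat(matrix(rpois(50 * 4, 50), 50, 4))
  m2 <- m
  m2[, 2] <- 2L * m[, 2]
  s1 <- size_factors(m)
  s2 <- size_factors(m2)
  expect_equal((s2[2] / s2[1]) / (s1[2] / s1[1]), 2,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unname(s2[-2] / s1[-2]), rep(2^(-1 / 4), 3), tolerance = 1e-12)

  # hand computation oracle on a 5x4 matrix via explicit loops
  m <- mat(rbind(c(10, 20, 30, 40), c(4, 8, 12, 16), c(100, 90, 110, 120),
                 c(7, 7, 7, 7), c(50, 25, 75, 100)))
  geo <- apply(m, 1, function(x) prod(x)^(1 / length(x)))
  oracle <- sapply(seq_len(ncol(m)), function(j) median(m[, j] / geo))
  expect_equal(unname(size_factors(m)), oracle, tolerance = 1e-12)

  # no gene positive in every sample -> guided error
  bad <- mat(rbind(c(0, 5), c(5, 0)))
  expect_error(size_factors(bad), "size factors undefined")
})

test_that("size factors match the DESeq2 reference on a random matrix", {
  set.seed(3)
  m <- mat(matrix(rnbinom(200 * 6, mu = 100, size = 5), 200, 6))
  sf <- size_factors(m)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(sf), unname(ref), tolerance = 1e-10)
})

test_that("dispersion trend recovers simulation truth", {
  set.seed(4)
  n <- 8L
  # Poisson counts: true alpha = 0 everywhere
  mu <- 2^runif(2000, 3, 10)
  m <- mat(matrix(rpois(2000 * n, rep(mu, n)), 2000, n))
  tr <- fit_dispersion_trend(m, setNames(rep(1, n), colnames(m)))
  expect_lte(tr$a0, 0.01)

  # NB counts with a0 = 0.05, a1 = 2: both recovered within 50%
  a0 <- 0.05; a1 <- 2
  mu <- 2^runif(5000, 3, 10)
  alpha <- a0 + a1 / mu
  m <- mat(matrix(rnbinom(5000 * n, mu = rep(mu, n), size = rep(1 / alpha, n)),
                  5000, n))
  tr <- fit_dispersion_trend(m, setNames(rep(1, n), colnames(m)))
  expect_lt(abs(tr$a0 - a0) / a0, 0.5)
  expect_lt(abs(tr$a1 - a1) / a1, 0.5)
})

test_that("constant genes get zero dispersion and trigger the fallback", {
  m <- mat(rbind(rep(5L, 4), c(1L, 9L, 2L, 8L)))
  sf <- setNames(rep(1, 4), colnames(m))
  expect_warning(tr <- fit_dispersion_trend(m, sf), "fewer than 10")
  expect_equal(tr$alpha[[1]], 0)
  expect_equal(tr$a0, 0.01)
  expect_equal(tr$a1, 1)
})

test_that("vst_transform matches its closed form and is monotone", {
  trend <- structure(list(a0 = 0.01, a1 = 1), class = "dispersion_trend")
  sf <- c(s1 = 1)
  vst1 <- function(q) {
    m <- matrix(q, 1, 1, dimnames = list("g", "s1"))
    vst_transform(m, sf, trend)[1, 1]
  }
  expect_equal(vst1(0), log2((1 + 1) / (4 * 0.01)), tolerance = 1e-12)

  grid <- seq(0, 5000, length.out = 1000)
  vals <- vapply(grid, vst1, numeric(1))
  expect_true(all(diff(vals) > 0))

  # vst(q) asymptotes to log2(q): within 0.05 at q = 1e6
  expect_lt(abs(vst1(1e6) - log2(1e6)), 0.05)

  # degenerate trend falls back to log2(q + 1)
  bad <- structure(list(a0 = 0, a1 = 1), class = "dispersion_trend")
  m <- matrix(c(0, 7), 2, 1, dimnames = list(c("a", "b"), "s1"))
  expect_warning(out <- vst_transform(m, sf, bad), "log2")
  expect_equal(out[, 1], log2(c(a = 1, b = 8)))
})

test_that("vst stabilizes variance better than log2(q+1) on NB data", {
  set.seed(6)
  n <- 12L
  mu <- 2^runif(3000, 3, 12)
  alpha <- 0.02 + 1 / mu
  m <- mat(matrix(rnbinom(3000 * n, mu = rep(mu, n), size = rep(1 / alpha, n)),
                  3000, n))
  sf <- size_factors(m)
  tr <- fit_dispersion_trend(m, sf)
  q <- sweep(m, 2, sf, `/`)
  v <- vst_transform(m, sf, tr)
  decile_cv <- function(x) {
    sds <- apply(x, 1, sd)
    dec <- cut(rank(rowMeans(q)), 10)
    per <- tapply(sds, dec, mean)
    sd(per) / mean(per)
  }
  expect_lt(decile_cv(v), decile_cv(log2(q + 1)))
})

test_that("size-factor recovery is within 5% on simulated data", {
  design <- make_design(seed = 21L)
  sim <- simulate_dataset(design, list(), n_background_genes = 2000L,
                          n_de_per_tissue = 0L, seed = 21L)
  sf <- size_factors(sim$counts)
  norm <- function(x) x / exp(mean(log(x))) # compare up to geometric mean
  ratio <- norm(sf) / norm(sim$size_factors_true)
  expect_true(all(abs(ratio - 1) < 0.05))
})

test_that("filter -> size factors -> vst is sample-permutation equivariant", {
  sim <- small_module_sim()
  counts <- sim$counts
  perm <- sample(ncol(counts))
  run <- function(m) {
    f <- filter_low_expression(m)
    sf <- size_factors(f)
    vst_transform(f, sf, fit_dispersion_trend(f, sf))
  }
  e1 <- run(counts)
  e2 <- run(counts[, perm])
  expect_equal(e2[, colnames(e1)], e1, tolerance = 1e-12)
})

test_that("detect_outlier_samples flags constructed outliers only", {
  expr <- small_module_expr()
  out <- detect_outlier_samples(expr)
  expect_length(out$flagged, 0L)

  shifted <- expr
  shifted[, 5] <- shifted[, 5] + 20
  out2 <- detect_outlier_samples(shifted)
  expect_identical(out2$flagged, colnames(expr)[5])

  # invariance to column order
  perm <- sample(ncol(shifted))
  out3 <- detect_outlier_samples(shifted[, perm])
  expect_setequal(out3$flagged, out2$flagged)

  expect_warning(res <- detect_outlier_samples(expr[, 1:2]), "fewer than 3")
  expect_length(res$flagged, 0L)
})
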