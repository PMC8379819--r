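# Count-matrix intake: filtering, median-of-ratios size factors, a
# closed-form variance-stabilizing transformation driven by a fitted
# dispersion-mean trend, and dendrogram-based sample-outlier flagging.

#' Read a gene-by-sample count matrix from TSV
#'
#' First column `gene_id`, remaining columns one per sample, integer cells.
#'
#' @param path TSV file path.
#' @return integer matrix with gene IDs as rownames.
#' @export
read_counts <- function(path) {
  df <- read_tsv(path)
  if (names(df)[1] != "gene_id") stop("counts file must start with a gene_id column")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  storage.mode(m) <- "integer"
  validate_counts(m)
  m
}

#' Read sample metadata from TSV
#'
#' @param path TSV with columns `sample_id, breed, group, tissue`.
#' @return data frame.
#' @export
read_metadata <- function(path) {
  df <- read_tsv(path)
  need <- c("sample_id", "breed", "group", "tissue")
  if (!all(need %in% names(df))) {
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$sample_id)) stop("duplicated sample_id in metadata")
  df
}

validate_counts <- function(counts) {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("count matrix must have gene and sample identifiers")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicated gene identifiers")
  if (anyDuplicated(colnames(counts))) stop("duplicated sample identifiers")
  if (any(counts < 0)) stop("count matrix has negative entries")
  invisible(counts)
}

#' Drop low-expression genes
#'
#' Retains exactly the genes whose total count across samples reaches
#' `min_total`; gene order is preserved.
#'
#' @param counts gene x sample count matrix.
#' @param min_total minimum row sum to retain (default 10).
#' @return the filtered matrix (possibly 0 rows, with a warning).
#' @export
filter_low_expression <- function(counts, min_total = 10) {
  validate_counts(counts)
  keep <- rowSums(counts) >= min_total
  if (!any(keep)) warning("no genes pass the low-expression filter")
  counts[keep, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' For each gene expressed in all samples, the geometric mean across
#' samples is computed; each sample's counts are divided by those means and
#' the per-sample median ratio is its size factor. Corrects library size
#' and composition bias.
#'
#' @param counts gene x sample count matrix.
#' @return named positive numeric vector, one per sample.
#' @export
size_factors <- function(counts) {
  validate_counts(counts)
  ref <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref)) {
    stop("size factors undefined: no gene has positive counts in every ",
         "sample; filter samples or genes (e.g. remove empty libraries) first")
  }
  logc <- log(counts[ref, , drop = FALSE])
  loggeo <- rowMeans(logc)
  s <- exp(apply(logc - loggeo, 2, stats::median))
  stats::setNames(s, colnames(counts))
}

#' Fit the dispersion-mean trend alpha(mu) = a0 + a1/mu
#'
#' Per-gene method-of-moments dispersions on size-factor-normalized counts,
#' `alpha_g = max(0, (var - mu)/mu^2)`, are regressed on `1/mu` by least
#' squares over genes with positive `alpha_g`, with one trimming pass
#' removing the 5% largest absolute residuals. Coefficients are clamped at
#' 1e-8 so the trend stays positive.
#'
#' @param counts gene x sample count matrix (>= 2 samples).
#' @param sf size factors from [size_factors()].
#' @return A `dispersion_trend` list: `a0`, `a1`, per-gene `mu` and raw
#'   `alpha`.
#' @export
fit_dispersion_trend <- function(counts, sf) {
  if (ncol(counts) < 2L) stop("dispersion trend needs >= 2 samples")
  q <- sweep(counts, 2, sf, `/`)
  mu <- rowMeans(q)
  v <- apply(q, 1, stats::var)
  alpha <- ifelse(mu > 0, pmax(0, (v - mu) / mu^2), 0)
  use <- alpha > 0 & mu > 0
  if (sum(use) < 10L) {
    warning("fewer than 10 genes with positive dispersion; ",
            "falling back to default trend a0=0.01, a1=1")
    a0 <- 0.01; a1 <- 1
  } else {
    x <- 1 / mu[use]; y <- alpha[use]
    fit <- stats::lm.fit(cbind(1, x), y)
    r <- abs(fit$residuals)
    keep <- r <= stats::quantile(r, 0.95)
    fit <- stats::lm.fit(cbind(1, x[keep]), y[keep])
    a0 <- max(fit$coefficients[1], 1e-8)
    a1 <- max(fit$coefficients[2], 1e-8)
  }
  structure(list(a0 = unname(a0), a1 = unname(a1), mu = mu, alpha = alpha),
            class = "dispersion_trend")
}

#' Closed-form variance-stabilizing transformation
#'
#' With normalized counts `q = count/s_j` and the parametric trend
#' `alpha(mu) = a0 + a1/mu`, applies
#' `vst(q) = log2((1 + a1 + 2*a0*q + 2*sqrt(a0*q*(1 + a1 + a0*q)))/(4*a0))`,
#' the integral solution that makes per-gene variance approximately
#' mean-independent; it is strictly increasing and asymptotes to `log2(q)`.
#'
#' @param counts gene x sample count matrix.
#' @param sf size factors.
#' @param trend a `dispersion_trend` (or a list with `a0`, `a1`).
#' @return real matrix on a log2-like scale, same dimnames as `counts`.
#' @export
vst_transform <- function(counts, sf, trend) {
  q <- sweep(counts, 2, sf, `/`)
  a0 <- trend$a0; a1 <- trend$a1
  if (a0 <= 0) {
    warning("a0 = 0: variance stabilization undefined, using log2(q + 1)")
    return(log2(q + 1))
  }
  log2((1 + a1 + 2 * a0 * q + 2 * sqrt(a0 * q * (1 + a1 + a0 * q))) / (4 * a0))
}

#' Flag outlier samples by hierarchical clustering
#'
#' Samples are clustered by average linkage on the Euclidean distance of
#' their expression columns; the tree is cut at `cut_fraction` of the
#' maximum merge height, and samples falling in clusters smaller than 10%
#' of n are flagged. Nothing is removed automatically.
#'
#' @param expr expression matrix (genes x samples), e.g. VST output.
#' @param cut_fraction fraction of the maximum merge height (default 0.85).
#' @param max_cluster_frac clusters below this fraction of n are outliers.
#' @return list with `flagged` (sample IDs), `clusters`, and the `hclust`
#'   tree.
#' @export
detect_outlier_samples <- function(expr, cut_fraction = 0.85,
                                   max_cluster_frac = 0.10) {
  n <- ncol(expr)
  if (n < 3L) {
    warning("fewer than 3 samples: outlier detection skipped")
    return(list(flagged = character(), clusters = NULL, hclust = NULL))
  }
  hc <- stats::hclust(stats::dist(t(expr)), method = "average")
  cl <- stats::cutree(hc, h = cut_fraction * max(hc$height))
  sizes <- table(cl)
  small <- as.integer(names(sizes)[sizes < max_cluster_frac * n])
  list(flagged = colnames(expr)[cl %in% small], clusters = cl, hclust = hc)
}
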