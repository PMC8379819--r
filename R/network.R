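# Weighted co-expression network construction: Pearson correlation,
# soft-threshold power scan with the signed scale-free fit index, the
# powered-absolute-correlation adjacency, and unsigned topological overlap.

#' Gene-gene Pearson correlation matrix
#'
#' @param expr expression matrix, genes x samples (>= 3 samples); genes
#'   must be non-constant.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(expr) {
  if (ncol(expr) < 3L) stop("need >= 3 samples for correlations")
  sds <- apply(expr, 1, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance gene(s): ",
         paste(utils::head(rownames(expr)[sds == 0], 5), collapse = ", "))
  }
  C <- stats::cor(t(expr))
  C <- (C + t(C)) / 2
  diag(C) <- 1
  C
}

#' Soft-threshold adjacency A_ij = |cor|^beta
#'
#' @param cors correlation matrix.
#' @param beta soft-thresholding power (> 0).
#' @return symmetric adjacency in \[0,1\] with unit diagonal and attribute
#'   `beta`.
#' @export
adjacency_matrix <- function(cors, beta) {
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0) {
    stop("invalid parameter: beta must be a positive number")
  }
  A <- abs(cors)^beta
  diag(A) <- 1
  attr(A, "beta") <- beta
  A
}

#' Whole-network connectivity k_i = sum_{j != i} A_ij
#'
#' @param A adjacency matrix.
#' @return numeric vector of connectivities.
#' @export
connectivity <- function(A) {
  stats::setNames(rowSums(A) - diag(A), rownames(A))
}

#' Signed scale-free topology fit index
#'
#' Connectivities are binned into `n_bins` equal-width bins; per non-empty
#' bin the mean connectivity and empirical frequency are computed and
#' `log10 p(k)` is regressed on `log10 k`. The index is
#' `-sign(slope) * R^2`, so a power-law (negative-slope) fit scores
#' positively.
#'
#' @param k connectivity vector.
#' @param n_bins number of equal-width bins (default 10).
#' @return named vector `c(r2_signed, slope)`; both NA when fewer than 3
#'   non-empty bins remain.
#' @export
scale_free_fit <- function(k, n_bins = 10L) {
  undefined <- c(r2_signed = NA_real_, slope = NA_real_)
  if (length(unique(k)) < 2L) return(undefined)
  breaks <- seq(min(k), max(k), length.out = n_bins + 1L)
  bin <- cut(k, breaks, include.lowest = TRUE)
  cnt <- tabulate(bin, nbins = n_bins)
  keep <- cnt > 0L
  if (sum(keep) < 3L) return(undefined)
  mean_k <- tapply(k, bin, mean)[keep]
  p_k <- cnt[keep] / length(k)
  if (any(mean_k <= 0)) return(undefined)
  x <- log10(mean_k); y <- log10(p_k)
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  r2 <- summary(fit)$r.squared
  c(r2_signed = -sign(slope) * r2, slope = slope)
}

#' Scan soft-thresholding powers for scale-free topology
#'
#' For each candidate power the adjacency, connectivity distribution and
#' scale-free fit are computed. The chosen power is the smallest one whose
#' signed fit index reaches `r2_cut`; if none does, the power maximizing
#' the index is chosen with a warning.
#'
#' @param expr expression matrix (genes x samples).
#' @param powers ascending candidate powers (default 1..20).
#' @param r2_cut signed-R^2 threshold (default 0.8).
#' @param n_bins bins for [scale_free_fit()].
#' @return A `soft_threshold_scan`: `table` (power, r2_signed, slope,
#'   mean_k, median_k, max_k) and `chosen_power`.
#' @export
pick_soft_threshold <- function(expr, powers = 1:20, r2_cut = 0.8,
                                n_bins = 10L) {
  if (length(powers) < 1L || is.unsorted(powers, strictly = TRUE)) {
    stop("powers must be non-empty and strictly ascending")
  }
  C <- correlation_matrix(expr)
  absC <- abs(C)
  rows <- lapply(powers, function(b) {
    A <- absC^b
    diag(A) <- 1
    k <- rowSums(A) - 1
    f <- scale_free_fit(k, n_bins)
    data.frame(power = b, r2_signed = f[["r2_signed"]], slope = f[["slope"]],
               mean_k = mean(k), median_k = stats::median(k), max_k = max(k))
  })
  tab <- do.call(rbind, rows)
  ok <- which(!is.na(tab$r2_signed) & tab$r2_signed >= r2_cut)
  if (length(ok)) {
    chosen <- tab$power[ok[1]]
  } else {
    warning("no power reaches the scale-free fit cut ", r2_cut,
            "; using the power with the best fit")
    chosen <- tab$power[which.max(tab$r2_signed)]
  }
  structure(list(table = tab, chosen_power = chosen, r2_cut = r2_cut),
            class = "soft_threshold_scan")
}

#' Unsigned topological overlap matrix
#'
#' `TOM_ij = (L_ij + A_ij) / (min(k_i, k_j) + 1 - A_ij)` for `i != j`,
#' where `L_ij = sum_{u != i,j} A_iu A_uj` counts shared neighbors and
#' `k_i` is the connectivity; `TOM_ii = 1`. The clustering dissimilarity is
#' `1 - TOM`.
#'
#' @param A symmetric adjacency with entries in \[0,1\].
#' @return symmetric TOM matrix in \[0,1\] with unit diagonal.
#' @export
tom_similarity <- function(A) {
  if (!isTRUE(all.equal(A, t(A), check.attributes = FALSE))) {
    stop("adjacency must be symmetric")
  }
  diag(A) <- 1
  k <- rowSums(A) - 1
  L <- A %*% A - 2 * A # off-diagonal: sum over u != i,j of A_iu A_uj
  denom <- outer(k, k, pmin) + 1 - A
  tom <- (L + A) / denom
  diag(tom) <- 1
  tom[tom < 0] <- 0 # numeric guard
  tom[tom > 1] <- 1
  attributes(tom) <- list(dim = dim(A), dimnames = dimnames(A))
  tom
}

#' TOM-based dissimilarity
#'
#' @param tom a TOM from [tom_similarity()].
#' @return `1 - TOM` with zero diagonal.
#' @export
tom_dissimilarity <- function(tom) {
  d <- 1 - tom
  diag(d) <- 0
  d
}
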