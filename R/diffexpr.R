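# Two-group negative-binomial Wald differential expression per tissue and
# breed, Cook's-distance count-outlier flagging, the union/intersection
# candidate-gene set algebra across breeds, and the 2^-ddCt qPCR utility.

#' Fit a two-group negative-binomial GLM to one gene
#'
#' Log-link NB regression of one gene's counts on a two-level group
#' indicator with offset `log(s_j)`, dispersion fixed at the trend value
#' `alpha = a0 + a1/mean(normalized counts)`. Iteratively reweighted least
#' squares with expected-information weights `mu/(1 + alpha*mu)`; standard
#' errors from the expected Fisher information. Coefficients are estimated
#' on the natural-log scale and reported as log2 fold changes.
#'
#' If one group is all zeros (separation) the gene is refit on counts + 0.5
#' and flagged `pseudo`; an all-zero gene is returned unconverged with
#' missing effect size.
#'
#' @param y integer counts, one per sample.
#' @param group logical or 0/1 indicator (1 = High).
#' @param sf positive size factors, same length as `y`.
#' @param trend a `dispersion_trend` (only `a0`, `a1` are used).
#' @param maxit,tol IRLS iteration cap and convergence tolerance on the
#'   coefficient change.
#' @return An `nb_fit` list: `lfc`, `se_lfc` (log2), `beta0`, `mu_hat`,
#'   `alpha`, `weights`, `converged`, `pseudo`.
#' @export
nb_wald_fit <- function(y, group, sf, trend, maxit = 50L, tol = 1e-8) {
  group <- as.numeric(group)
  stopifnot(length(y) == length(group), length(y) == length(sf))
  mu_bar <- mean(y / sf)
  alpha <- trend$a0 + trend$a1 / max(mu_bar, 1e-8)
  out <- list(lfc = NA_real_, se_lfc = NA_real_, beta0 = NA_real_,
              mu_hat = NULL, alpha = alpha, weights = NULL,
              X = cbind(1, group), offset = log(sf),
              converged = FALSE, pseudo = FALSE)
  class(out) <- "nb_fit"
  if (all(y == 0)) return(out)
  zero0 <- all(y[group == 0] == 0); zero1 <- all(y[group == 1] == 0)
  yfit <- y
  if (xor(zero0, zero1)) { # separation: pseudo-count fallback caps the lfc
    yfit <- y + 0.5
    out$pseudo <- TRUE
  }
  X <- out$X; o <- out$offset
  m0 <- mean(yfit[group == 0] / sf[group == 0])
  m1 <- mean(yfit[group == 1] / sf[group == 1])
  beta <- c(log(max(m0, 1e-8)), log(max(m1, 1e-8) / max(m0, 1e-8)))
  conv <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta) + o
    mu <- pmin(exp(eta), 1e12)
    w <- mu / (1 + alpha * mu)
    z <- eta - o + (yfit - mu) / mu
    xtwx <- crossprod(X, w * X)
    beta_new <- drop(solve(xtwx, crossprod(X, w * z)))
    if (max(abs(beta_new - beta)) < tol) { beta <- beta_new; conv <- TRUE; break }
    beta <- beta_new
  }
  eta <- drop(X %*% beta) + o
  mu <- exp(eta)
  w <- mu / (1 + alpha * mu)
  cov <- solve(crossprod(X, w * X))
  out$beta0 <- unname(beta[1])
  out$lfc <- unname(beta[2]) / log(2)
  out$se_lfc <- sqrt(cov[2, 2]) / log(2)
  out$mu_hat <- mu
  out$weights <- w
  out$converged <- conv
  out
}

#' Flag count outliers with Cook's distance
#'
#' Per-sample Cook's distances from the NB fit's expected-information
#' weights: `D_j = (r_j^2 / p) * h_jj / (1 - h_jj)^2` with Pearson
#' residuals `r_j = (y - mu)/sqrt(mu*(1 + alpha*mu))`, p = 2 parameters,
#' dispersion parameter phi fixed at 1. The gene is flagged when the
#' maximum distance exceeds the `F(p, m - p)` quantile.
#'
#' @param fit an `nb_fit` from [nb_wald_fit()].
#' @param y the gene's counts.
#' @param threshold_quantile F-distribution quantile (default 0.99; 1 never
#'   flags).
#' @return logical flag.
#' @export
cooks_outlier_flag <- function(fit, y, threshold_quantile = 0.99) {
  m <- length(y); p <- 2L
  if (m <= p) {
    warning("too few samples for Cook's distance; flag skipped")
    return(FALSE)
  }
  if (!isTRUE(fit$converged) || is.null(fit$mu_hat)) return(FALSE)
  mu <- fit$mu_hat; w <- fit$weights; X <- fit$X
  r <- (y - mu) / sqrt(mu * (1 + fit$alpha * mu))
  xtwx_inv <- solve(crossprod(X, w * X))
  h <- w * rowSums((X %*% xtwx_inv) * X)
  h <- pmin(h, 1 - 1e-12)
  d <- (r^2 / p) * h / (1 - h)^2
  cutoff <- stats::qf(threshold_quantile, p, m - p)
  any(d > cutoff)
}

#' Differential expression for one breed x tissue contrast
#'
#' Subsets the samples of one breed and tissue, recomputes size factors
#' within the subset, fits every gene with [nb_wald_fit()], applies Cook's
#' flagging (flagged genes get a missing p-value), and tests High vs Low
#' with a two-sided Wald z test. Raw p-values; no multiplicity adjustment.
#'
#' @param counts gene x sample count matrix.
#' @param metadata sample metadata with `sample_id, breed, group, tissue`.
#' @param breed,tissue the contrast cell.
#' @param alpha significance threshold on the raw p-value (default 0.05).
#' @param trend optional pre-fitted `dispersion_trend`; refit on the subset
#'   when NULL.
#' @param cooks_quantile passed to [cooks_outlier_flag()].
#' @return data frame `gene_id, lfc, se, z, p, cooks_flagged, significant`
#'   with attributes `breed`, `tissue`.
#' @export
run_de_contrast <- function(counts, metadata, breed, tissue, alpha = 0.05,
                            trend = NULL, cooks_quantile = 0.99) {
  sel <- metadata$breed == breed & metadata$tissue == tissue
  md <- metadata[sel, , drop = FALSE]
  if (any(table(factor(md$group, levels = c("High", "Low"))) < 2L)) {
    stop("contrast refused: need >= 2 samples per group for ",
         breed, " / ", tissue)
  }
  sub <- counts[, md$sample_id, drop = FALSE]
  sf <- size_factors(sub)
  if (is.null(trend)) trend <- fit_dispersion_trend(sub, sf)
  grp <- as.numeric(md$group == "High")
  res <- data.frame(gene_id = rownames(sub), lfc = NA_real_, se = NA_real_,
                    z = NA_real_, p = NA_real_, cooks_flagged = FALSE,
                    stringsAsFactors = FALSE)
  for (g in seq_len(nrow(sub))) {
    y <- sub[g, ]
    fit <- nb_wald_fit(y, grp, sf, trend)
    if (!is.na(fit$lfc)) {
      res$lfc[g] <- fit$lfc
      res$se[g] <- fit$se_lfc
      res$z[g] <- fit$lfc / fit$se_lfc
      flag <- cooks_outlier_flag(fit, y, cooks_quantile)
      res$cooks_flagged[g] <- flag
      if (!flag) res$p[g] <- 2 * stats::pnorm(-abs(res$z[g]))
    }
  }
  res$significant <- !is.na(res$p) & res$p < alpha
  attr(res, "breed") <- breed
  attr(res, "tissue") <- tissue
  attr(res, "alpha") <- alpha
  res
}

#' Candidate-gene set algebra across tissues and breeds
#'
#' Within each breed the significant genes of its tissue contrasts are
#' unioned into that breed's candidate set; the cross-breed candidate set
#' is the intersection of the per-breed unions.
#'
#' @param de_sets nested named list: breed -> tissue -> either a character
#'   vector of gene IDs or a [run_de_contrast()] result (its `significant`
#'   genes are used).
#' @return A `candidate_sets` list: `per_breed` (tissue-level sets),
#'   `union` (per-breed unions), `intersection`, `sizes`.
#' @export
combine_candidate_sets <- function(de_sets) {
  if (length(de_sets) < 1L) stop("need at least one breed")
  as_genes <- function(x) {
    if (is.data.frame(x)) x$gene_id[x$significant] else as.character(x)
  }
  per_breed <- lapply(de_sets, function(tl) lapply(tl, as_genes))
  unions <- lapply(per_breed, function(tl) {
    sort(unique(unlist(tl, use.names = FALSE)))
  })
  if (length(unions) < 2L) {
    warning("single breed: intersection equals that breed's union")
    inter <- unions[[1]]
  } else {
    inter <- sort(Reduce(intersect, unions))
  }
  structure(
    list(per_breed = per_breed, union = unions, intersection = inter,
         sizes = c(vapply(unions, length, integer(1)),
                   intersection = length(inter))),
    class = "candidate_sets"
  )
}

#' Relative mRNA abundance by the 2^-ddCt method
#'
#' Per sample, `dCt = target_ct - reference_ct`; per non-control condition,
#' `ddCt = mean dCt(condition) - mean dCt(control)` and the relative
#' quantity is `2^-ddCt`.
#'
#' @param ct data frame with columns `sample, condition, target_ct,
#'   reference_ct` (triplicate Cts averaged upstream).
#' @param control the reference condition label.
#' @return data frame `condition, n, ddct, rq` (control row has ddct 0,
#'   rq 1).
#' @export
ddct_relative_abundance <- function(ct, control) {
  need <- c("sample", "condition", "target_ct", "reference_ct")
  if (!all(need %in% names(ct))) {
    stop("ct table must have columns: ", paste(need, collapse = ", "))
  }
  if (anyNA(ct$reference_ct)) stop("missing reference gene Ct values")
  if (!control %in% ct$condition) stop("control condition not present")
  dct <- ct$target_ct - ct$reference_ct
  means <- tapply(dct, ct$condition, mean)
  ddct <- means - means[[control]]
  data.frame(condition = names(means),
             n = as.integer(table(ct$condition)[names(means)]),
             ddct = as.numeric(ddct), rq = 2^-as.numeric(ddct),
             row.names = NULL, stringsAsFactors = FALSE)
}
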