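# Gene-set over-representation: GMT parsing, the hypergeometric upper-tail
# test, Benjamini-Hochberg FDR, and ranked per-category reporting.

#' Read a gene-set collection in GMT format
#'
#' Each line: term ID, a description used here as the category tag (e.g.
#' BP/MF/CC; empty fields become "default"), then tab-separated member
#' genes. Duplicate members are dropped; if a universe is supplied, members
#' are restricted to it and emptied terms removed.
#'
#' @param path GMT file.
#' @param universe optional character vector of background genes.
#' @return A `gene_set_collection`: `sets` (named list), `categories`
#'   (named character), `universe`.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warning("empty GMT file")
    return(structure(list(sets = list(), categories = character(),
                          universe = universe %||% character()),
                     class = "gene_set_collection"))
  }
  sets <- list(); categories <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop("malformed GMT line ", i, ": fewer than 3 fields")
    members <- unique(f[-(1:2)])
    if (!is.null(universe)) members <- intersect(members, universe)
    if (!length(members)) next
    sets[[f[1]]] <- members
    categories[f[1]] <- if (nzchar(f[2])) f[2] else "default"
  }
  if (is.null(universe)) universe <- sort(unique(unlist(sets, use.names = FALSE)))
  structure(list(sets = sets, categories = categories, universe = universe),
            class = "gene_set_collection")
}

#' Write a gene-set collection as GMT
#'
#' @param collection a `gene_set_collection`.
#' @param path output file.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(id) {
    paste(c(id, collection$categories[[id]] %||% "default",
            collection$sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation p-value
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the chance of drawing at
#' least `k` term members in a query of size `n` from a universe of `N`
#' genes of which `K` are in the term.
#'
#' @param k overlap size.
#' @param K term size.
#' @param n query size.
#' @param N universe size.
#' @return upper-tail probability in (0, 1\].
#' @export
hypergeometric_test <- function(k, K, n, N) {
  if (k < 0 || K > N || n > N || k > min(K, n)) {
    stop("inconsistent counts: need 0 <= k <= min(K, n) <= N")
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Sorts p ascending, takes the running minimum of `p_(j) * m / j` from the
#' largest rank down, clips at 1, and returns values in the input order.
#' Missing p-values propagate as NA and are excluded from `m`.
#'
#' @param p numeric vector of p-values in \[0,1\].
#' @return FDR-adjusted values, same length and order.
#' @export
bh_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (!m) return(out)
  ord <- ok[order(p[ok])]
  q <- p[ord] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out[ord] <- pmin(q, 1)
  out
}

#' Over-representation analysis of a gene list
#'
#' Tests the query against every term, adjusts p-values by BH within each
#' category, keeps terms with `fdr < fdr_cut`, and reports the `top_n`
#' per category ranked by fdr, then p, then term ID. Query genes outside
#' the universe are dropped (count reported via message).
#'
#' @param genes query gene IDs.
#' @param collection a `gene_set_collection`.
#' @param fdr_cut FDR threshold (default 0.05).
#' @param top_n terms kept per category (default 10).
#' @return data frame `term_id, category, k, K, n, N, p, fdr, rank`.
#' @export
enrich_gene_list <- function(genes, collection, fdr_cut = 0.05, top_n = 10L) {
  universe <- collection$universe
  q <- unique(genes)
  dropped <- sum(!q %in% universe)
  if (dropped) message(dropped, " query gene(s) outside the universe dropped")
  q <- intersect(q, universe)
  empty <- data.frame(term_id = character(), category = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p = numeric(), fdr = numeric(),
                      rank = integer(), stringsAsFactors = FALSE)
  if (!length(q)) {
    warning("empty query after restriction to the universe")
    return(empty)
  }
  if (!length(collection$sets)) return(empty)
  N <- length(universe); n <- length(q)
  res <- data.frame(
    term_id = names(collection$sets),
    category = unname(collection$categories[names(collection$sets)]),
    k = vapply(collection$sets, function(s) length(intersect(s, q)), integer(1)),
    K = lengths(collection$sets),
    n = n, N = N, stringsAsFactors = FALSE, row.names = NULL
  )
  res$p <- mapply(hypergeometric_test, res$k, res$K, res$n, res$N)
  res$fdr <- NA_real_
  for (cat in unique(res$category)) {
    sel <- res$category == cat
    res$fdr[sel] <- bh_adjust(res$p[sel])
  }
  res <- res[res$fdr < fdr_cut, , drop = FALSE]
  res$rank <- rep(NA_integer_, nrow(res))
  out <- empty
  for (cat in unique(res$category)) {
    sub <- res[res$category == cat, , drop = FALSE]
    sub <- sub[order(sub$fdr, sub$p, sub$term_id), , drop = FALSE]
    sub <- utils::head(sub, top_n)
    if (nrow(sub)) sub$rank <- seq_len(nrow(sub))
    out <- rbind(out, sub)
  }
  rownames(out) <- NULL
  out
}
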