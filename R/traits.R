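# Module-trait association and gene-level network statistics: trait
# indicator design, module-trait correlations with t-based p-values, gene
# significance, module membership, module significance, intramodular
# connectivity, hub-gene ranking, and hub-network edge export.

#' One-hot trait design matrix from sample metadata
#'
#' One binary indicator column per level of breed, group and tissue, in
#' that factor order with levels alphabetical within each factor. The
#' backfat trait is the `group_High` column. Columns with a single level
#' are recorded as constant (unusable for correlation).
#'
#' @param metadata data frame with `sample_id, breed, group, tissue`.
#' @return numeric samples x indicators matrix with attributes
#'   `trait_column` ("group_High") and `constant` (constant column names).
#' @export
trait_design_matrix <- function(metadata) {
  need <- c("sample_id", "breed", "group", "tissue")
  if (!all(need %in% names(metadata))) {
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  }
  cols <- list()
  for (f in c("breed", "group", "tissue")) {
    for (lev in sort(unique(metadata[[f]]))) {
      cols[[paste(f, lev, sep = "_")]] <- as.numeric(metadata[[f]] == lev)
    }
  }
  D <- do.call(cbind, cols)
  rownames(D) <- metadata$sample_id
  attr(D, "trait_column") <- "group_High"
  attr(D, "constant") <- colnames(D)[apply(D, 2, function(x) length(unique(x)) == 1L)]
  D
}

cor_pvalue <- function(r, n) {
  t <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(-abs(t), n - 2)
}

#' Module-trait correlation table
#'
#' Pearson correlation of each module eigengene with each trait indicator,
#' with two-sided p-values from `t = r*sqrt((n-2)/(1-r^2))` on n-2 df.
#'
#' @param eigengenes samples x modules matrix from [module_eigengenes()].
#' @param trait_design matrix from [trait_design_matrix()] (>= 4 samples).
#' @return A `module_trait` list with matrices `r` and `p` (NA for
#'   constant traits, with a warning).
#' @export
module_trait_correlation <- function(eigengenes, trait_design) {
  n <- nrow(eigengenes)
  if (n < 4L) stop("need >= 4 samples for module-trait correlation")
  if (!identical(rownames(eigengenes), rownames(trait_design))) {
    trait_design <- trait_design[rownames(eigengenes), , drop = FALSE]
  }
  const <- apply(trait_design, 2, function(x) stats::sd(x) == 0)
  if (any(const)) warning("constant trait column(s): ",
                          paste(colnames(trait_design)[const], collapse = ", "))
  r <- matrix(NA_real_, ncol(eigengenes), ncol(trait_design),
              dimnames = list(colnames(eigengenes), colnames(trait_design)))
  ok <- !const
  if (any(ok)) {
    r[, ok] <- stats::cor(eigengenes, trait_design[, ok, drop = FALSE])
  }
  p <- cor_pvalue(r, n)
  structure(list(r = r, p = p, n = n), class = "module_trait")
}

#' Gene significance for a trait
#'
#' `GS_i = |cor(x_i, T)|` by default; the signed correlation is available
#' via `signed = TRUE`. Constant genes get NA.
#'
#' @param expr expression matrix (genes x samples).
#' @param trait numeric trait vector (non-constant), one value per sample.
#' @param signed keep the correlation's sign?
#' @return named numeric vector of GS values.
#' @export
gene_significance <- function(expr, trait, signed = FALSE) {
  if (stats::sd(trait) == 0) stop("trait is constant")
  sds <- apply(expr, 1, stats::sd)
  r <- rep(NA_real_, nrow(expr))
  ok <- sds > 0
  r[ok] <- drop(stats::cor(t(expr[ok, , drop = FALSE]), trait))
  names(r) <- rownames(expr)
  if (signed) r else abs(r)
}

#' Module significance: mean gene significance per module
#'
#' @param gs gene-significance vector (names = genes).
#' @param assignment named integer module labels.
#' @return named numeric vector of MS per module label (including "0").
#' @export
module_significance <- function(gs, assignment) {
  gs <- gs[names(assignment)]
  out <- tapply(gs, assignment, mean, na.rm = TRUE)
  stats::setNames(as.numeric(out), names(out))
}

#' Module membership: gene-eigengene correlations
#'
#' `MM_{i,m} = cor(x_i, ME_m)` for every gene and module.
#'
#' @param expr expression matrix (genes x samples).
#' @param eigengenes samples x modules eigengene matrix.
#' @return genes x modules correlation matrix (NA rows for constant genes).
#' @export
module_membership <- function(expr, eigengenes) {
  sds <- apply(expr, 1, stats::sd)
  mm <- matrix(NA_real_, nrow(expr), ncol(eigengenes),
               dimnames = list(rownames(expr), colnames(eigengenes)))
  ok <- sds > 0
  mm[ok, ] <- stats::cor(t(expr[ok, , drop = FALSE]), eigengenes)
  mm
}

#' Whole-network and intramodular connectivity
#'
#' `kTotal_i` sums the gene's adjacency to all other genes; `kWithin_i`
#' only to genes of its own module. Grey genes get kWithin over the grey
#' set but are excluded from hub ranking downstream.
#'
#' @param A adjacency matrix.
#' @param assignment named integer module labels over the same genes.
#' @return data frame `gene_id, module, kTotal, kWithin`.
#' @export
intramodular_connectivity <- function(A, assignment) {
  if (!identical(rownames(A), names(assignment))) {
    if (is.null(rownames(A)) || !setequal(rownames(A), names(assignment))) {
      stop("adjacency and assignment must cover the same genes")
    }
    assignment <- assignment[rownames(A)]
  }
  k_total <- rowSums(A) - diag(A)
  k_within <- numeric(length(k_total))
  for (m in unique(assignment)) {
    idx <- which(assignment == m)
    sub <- A[idx, idx, drop = FALSE]
    k_within[idx] <- rowSums(sub) - diag(sub)
  }
  data.frame(gene_id = rownames(A), module = as.integer(assignment),
             kTotal = unname(k_total), kWithin = unname(k_within),
             stringsAsFactors = FALSE)
}

#' Top hub genes per module by intramodular connectivity
#'
#' @param conn data frame from [intramodular_connectivity()].
#' @param n hubs per module (default 30; truncated to module size).
#' @param mm,gs optional module-membership matrix and gene-significance
#'   vector to annotate the hub rows.
#' @return named list (one data frame per non-grey module label) ordered by
#'   decreasing kWithin, ties by gene ID.
#' @export
select_hub_genes <- function(conn, n = 30L, mm = NULL, gs = NULL) {
  mods <- sort(unique(conn$module[conn$module > 0L]))
  out <- list()
  for (m in mods) {
    sub <- conn[conn$module == m, , drop = FALSE]
    sub <- sub[order(-sub$kWithin, sub$gene_id), , drop = FALSE]
    sub <- utils::head(sub, n)
    if (!is.null(mm)) sub$MM <- mm[sub$gene_id, paste0("ME", m)]
    if (!is.null(gs)) sub$GS <- unname(gs[sub$gene_id])
    rownames(sub) <- NULL
    out[[as.character(m)]] <- sub
  }
  out
}

#' Export the hub-gene subnetwork as an edge table
#'
#' All pairwise edges among the given hub genes with the adjacency as edge
#' weight; each pair appears once, oriented lexicographically
#' (source < target). Importable into graph tools as a weighted edge list.
#'
#' @param A adjacency matrix.
#' @param hub_genes character vector of hub gene IDs.
#' @return data frame `source, target, weight`.
#' @export
export_hub_network <- function(A, hub_genes) {
  if (!length(hub_genes)) stop("hub list is empty")
  g <- sort(hub_genes)
  if (length(g) < 2L) {
    return(data.frame(source = character(), target = character(),
                      weight = numeric(), stringsAsFactors = FALSE))
  }
  pairs <- utils::combn(g, 2L)
  data.frame(source = pairs[1, ], target = pairs[2, ],
             weight = A[cbind(pairs[1, ], pairs[2, ])],
             stringsAsFactors = FALSE)
}
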