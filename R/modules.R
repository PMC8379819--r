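# Module detection: average-linkage dendrogram on TOM dissimilarity,
# static tree cut with a minimum module size, module eigengenes via SVD,
# and iterative eigengene-based module merging.

#' Average-linkage dendrogram on a dissimilarity matrix
#'
#' @param diss symmetric dissimilarity matrix with zero diagonal and no
#'   missing values.
#' @return an [stats::hclust] object (UPGMA).
#' @export
build_dendrogram <- function(diss) {
  if (anyNA(diss)) stop("dissimilarity contains missing values")
  if (!isTRUE(all.equal(diss, t(diss), check.attributes = FALSE))) {
    stop("dissimilarity must be symmetric")
  }
  if (any(abs(diag(diss)) > 1e-12)) stop("dissimilarity diagonal must be zero")
  stats::hclust(stats::as.dist(diss), method = "average")
}

#' Detect modules by a static cut of the dendrogram
#'
#' Cuts the tree at `cut_height` (default 0.99 of the maximum merge
#' height); clusters smaller than `min_size` become unassigned (label 0,
#' "grey"), the rest are labeled 1..M by decreasing size (ties broken by
#' the smaller original cluster index).
#'
#' @param dendro an `hclust` from [build_dendrogram()].
#' @param min_size minimum module size (default 30).
#' @param cut_height cut height in (0, max merge height\].
#' @return named integer vector of module labels, with attribute `colors`.
#' @export
detect_modules <- function(dendro, min_size = 30L, cut_height = NULL) {
  hmax <- max(dendro$height)
  if (is.null(cut_height)) cut_height <- 0.99 * hmax
  if (cut_height <= 0 || cut_height > hmax) {
    stop("cut_height must lie in (0, max merge height]")
  }
  # average linkage is reducible, so heights are non-decreasing up to float
  # noise from tied averages; repair sub-1e-8 inversions for cutree
  if (is.unsorted(dendro$height)) {
    if (any(diff(dendro$height) < -1e-8)) stop("dendrogram heights decrease")
    dendro$height <- cummax(dendro$height)
  }
  cl <- stats::cutree(dendro, h = cut_height)
  sizes <- table(cl)
  big <- names(sizes)[sizes >= min_size]
  # order retained clusters by decreasing size, then original index
  ord <- big[order(-as.integer(sizes[big]), as.integer(big))]
  relabel <- stats::setNames(rep(0L, length(sizes)), names(sizes))
  relabel[ord] <- seq_along(ord)
  labels <- unname(relabel[as.character(cl)])
  names(labels) <- names(cl)
  attr(labels, "colors") <- module_colors(labels)
  labels
}

#' Module eigengenes (first principal component per module)
#'
#' Each module's gene x sample block is standardized per gene (mean 0,
#' SD 1); the eigengene is the first right singular vector (unit Euclidean
#' norm), sign-fixed so it correlates positively with the module's mean
#' standardized expression. The variance explained is the leading singular
#' value's share of the total.
#'
#' @param expr expression matrix (genes x samples).
#' @param assignment named integer module labels (0 ignored).
#' @return list with `eigengenes` (samples x modules matrix, columns
#'   `ME<label>`) and `var_explained`.
#' @export
module_eigengenes <- function(expr, assignment) {
  mods <- sort(unique(assignment[assignment > 0L]))
  if (!length(mods)) stop("no non-grey modules to summarize")
  me <- matrix(NA_real_, ncol(expr), length(mods),
               dimnames = list(colnames(expr), paste0("ME", mods)))
  ve <- stats::setNames(numeric(length(mods)), paste0("ME", mods))
  for (j in seq_along(mods)) {
    genes <- names(assignment)[assignment == mods[j]]
    X <- expr[genes, , drop = FALSE]
    sds <- apply(X, 1, stats::sd)
    if (any(sds == 0)) stop("constant gene in module ", mods[j])
    Xs <- (X - rowMeans(X)) / sds
    if (nrow(Xs) == 1L) {
      warning("module ", mods[j], " has a single gene; eigengene is its profile")
      v <- drop(Xs) / sqrt(sum(Xs^2))
      ve[j] <- 1
    } else {
      sv <- svd(Xs)
      v <- sv$v[, 1]
      ve[j] <- sv$d[1]^2 / sum(sv$d^2)
    }
    if (stats::cor(v, colMeans(Xs)) < 0) v <- -v
    me[, j] <- v
  }
  list(eigengenes = me, var_explained = ve)
}

#' Merge modules with similar eigengenes
#'
#' Iteratively: compute eigengenes, cluster them by average linkage on
#' `1 - cor(ME_a, ME_b)`, merge every group of modules joined below
#' `merge_cut`, and recompute — until a fixed point or `max_iter`
#' iterations. Grey (label 0) never merges. Final labels are renumbered
#' 1..M by decreasing size.
#'
#' @param expr expression matrix.
#' @param assignment named integer module labels.
#' @param merge_cut eigengene dissimilarity threshold (default 0.25;
#'   <= 0 returns the input unchanged).
#' @param max_iter iteration cap.
#' @return list with `assignment` (relabeled, with `colors` attribute),
#'   `history` (data frame iter/from/into on pre-renumbering labels) and
#'   `n_iter`.
#' @export
merge_modules <- function(expr, assignment, merge_cut = 0.25, max_iter = 10L) {
  history <- data.frame(iter = integer(), from = integer(), into = integer())
  labels <- assignment
  if (merge_cut > 0) {
    for (it in seq_len(max_iter)) {
      mods <- sort(unique(labels[labels > 0L]))
      if (length(mods) < 2L) break
      me <- module_eigengenes(expr, labels)$eigengenes
      D <- 1 - stats::cor(me)
      hc <- stats::hclust(stats::as.dist(D), method = "average")
      grp <- stats::cutree(hc, h = merge_cut)
      if (all(table(grp) == 1L)) break
      merged <- FALSE
      for (g in unique(grp)) {
        members <- mods[grp == g]
        if (length(members) < 2L) next
        into <- min(members)
        for (from in setdiff(members, into)) {
          labels[labels == from] <- into
          history <- rbind(history,
                           data.frame(iter = it, from = from, into = into))
          merged <- TRUE
        }
      }
      if (!merged) break
    }
  }
  # renumber by decreasing size (ties by old label)
  mods <- sort(unique(labels[labels > 0L]))
  if (length(mods)) {
    sizes <- vapply(mods, function(m) sum(labels == m), integer(1))
    ord <- mods[order(-sizes, mods)]
    map <- stats::setNames(seq_along(ord), ord)
    new <- labels
    nz <- labels > 0L
    new[nz] <- map[as.character(labels[nz])]
    labels <- new
  }
  attr(labels, "colors") <- module_colors(labels)
  list(assignment = labels, history = history,
       n_iter = if (nrow(history)) max(history$iter) else 0L)
}
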