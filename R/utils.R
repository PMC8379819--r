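`%||%` <- function(a, b) if (is.null(a)) b else a

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same objects,
#' used to score recovered module assignments against planted ground truth.
#' Label values are arbitrary; only the induced partitions matter.
#'
#' @param a,b vectors of equal length giving cluster labels.
#' @return A number in \[-1, 1\]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must have equal length")
  tab <- table(a, b)
  n <- length(a)
  sum_comb <- sum(choose(tab, 2))
  a_comb <- sum(choose(rowSums(tab), 2))
  b_comb <- sum(choose(colSums(tab), 2))
  expected <- a_comb * b_comb / choose(n, 2)
  max_comb <- (a_comb + b_comb) / 2
  if (max_comb == expected) return(1) # both partitions trivial
  (sum_comb - expected) / (max_comb - expected)
}

# Conventional module color sequence, by decreasing module size; label 0
# ("unassigned") is always "grey". Recycled with a numeric suffix if a run
# somehow produces more modules than named colors.
.module_palette <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue"
)

#' Map module labels to conventional color names
#'
#' @param labels integer module labels (0 = unassigned).
#' @return character vector of color aliases ("grey" for label 0).
#' @export
module_colors <- function(labels) {
  pal <- .module_palette
  k <- max(labels, 0L)
  if (k > length(pal)) {
    pal <- c(pal, paste0("module", seq(length(pal) + 1L, k)))
  }
  out <- ifelse(labels == 0L, "grey", pal[pmax(labels, 1L)])
  names(out) <- names(labels)
  out
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}
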