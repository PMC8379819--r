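# Synthetic multi-tissue count data with planted co-expression modules,
# trait effects and differentially expressed genes. Every downstream stage
# of the pipeline is validated against the ground truth emitted here.

#' Build a factorial study design and its sample metadata
#'
#' Emulates a two-breed, high/low-backfat, three-tissue RNA-seq design:
#' one sample per breed x group x tissue x replicate cell. Sample IDs encode
#' `breed_group_rep_tissue`.
#'
#' @param breeds,groups,tissues character vectors of factor levels
#'   (non-empty, unique within each factor).
#' @param reps_per_cell replicates per design cell (>= 1).
#' @param seed integer stored with the design (consumed by
#'   [simulate_dataset()]).
#' @return An object of class `study_design`: the factor levels plus a
#'   `metadata` data frame with columns `sample_id, breed, group, tissue`.
#' @examples
#' d <- make_design()
#' nrow(d$metadata) # 36
#' @export
make_design <- function(breeds = c("Landrace", "Songliao"),
                        groups = c("High", "Low"),
                        tissues = c("Fat", "Liver", "Muscle"),
                        reps_per_cell = 3L, seed = 1L) {
  for (f in list(breeds = breeds, groups = groups, tissues = tissues)) {
    if (length(f) < 1L) stop("invalid design: empty factor level list")
    if (anyDuplicated(f)) stop("invalid design: duplicated factor levels")
  }
  if (reps_per_cell < 1L) stop("invalid design: reps_per_cell must be >= 1")
  grid <- expand.grid(
    rep = seq_len(reps_per_cell), tissue = tissues, group = groups,
    breed = breeds, stringsAsFactors = FALSE
  )
  metadata <- data.frame(
    sample_id = paste(grid$breed, grid$group, paste0("r", grid$rep),
                      grid$tissue, sep = "_"),
    breed = grid$breed, group = grid$group, tissue = grid$tissue,
    stringsAsFactors = FALSE
  )
  stopifnot(!anyDuplicated(metadata$sample_id))
  structure(
    list(breeds = breeds, groups = groups, tissues = tissues,
         reps_per_cell = as.integer(reps_per_cell), seed = as.integer(seed),
         n_samples = nrow(metadata), metadata = metadata),
    class = "study_design"
  )
}

#' Specify one planted co-expression module
#'
#' @param module_id positive integer module label.
#' @param size number of genes in the module (>= 1).
#' @param tissue_effect named numeric vector of per-tissue shifts of the
#'   module's latent profile, log2 scale.
#' @param group_effect log2 shift added to the latent profile in High-group
#'   samples (0 for trait-neutral modules).
#' @param loading_range `(low, high)` range of per-gene loadings on the
#'   latent profile.
#' @param noise_sd per-gene residual standard deviation, log2 scale (> 0).
#' @return A `module_spec` list.
#' @export
module_spec <- function(module_id, size, tissue_effect, group_effect = 0,
                        loading_range = c(0.8, 1.0), noise_sd = 0.3) {
  if (size < 1L) stop("module size must be >= 1")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (loading_range[1] > loading_range[2]) stop("loading_range low > high")
  structure(
    list(module_id = as.integer(module_id), size = as.integer(size),
         tissue_effect = tissue_effect, group_effect = group_effect,
         loading_range = loading_range, noise_sd = noise_sd),
    class = "module_spec"
  )
}

# The six icosahedral axes in R^3, rotated (by a Householder reflection)
# so the first axis is exactly (0, 0, 1). Pairwise |cos| = 1/sqrt(5): the
# minimax-angle arrangement of 6 lines in three dimensions.
icosahedral_directions <- function() {
  phi <- (1 + sqrt(5)) / 2
  ax <- rbind(c(0, 1, phi), c(0, 1, -phi), c(1, phi, 0),
              c(1, -phi, 0), c(phi, 0, 1), c(-phi, 0, 1))
  ax <- ax / sqrt(rowSums(ax^2))
  v <- ax[1, ] - c(0, 0, 1)
  H <- diag(3) - 2 * tcrossprod(v) / sum(v^2)
  out <- ax %*% H
  out[abs(out) < 1e-12] <- 0
  out
}

#' Default planted-module specifications for a balanced 3-tissue design
#'
#' Six modules with sizes 300..50 whose latent (tissue, group) effect
#' patterns are the six icosahedral axes of the design's 3-dimensional
#' contrast space (2 tissue contrasts + 1 group contrast), rotated so that
#' exactly one module (id 4) is the pure backfat-group direction; the
#' remaining modules have moderate group components (|cos| = 1/sqrt(5)),
#' mirroring a primary trait module plus secondary trait-correlated ones.
#'
#' @param design a `study_design` with exactly 3 tissues and 2 groups.
#' @param sizes module sizes, decreasing, length 6.
#' @param amplitude total sample-space norm of each latent pattern; the
#'   default gives a per-sample pattern SD of `amplitude/sqrt(n)` = 1.5
#'   log2 units at n = 36.
#' @return list of six [module_spec()] objects.
#' @export
default_module_specs <- function(design,
                                 sizes = c(300L, 250L, 200L, 150L, 100L, 50L),
                                 amplitude = 9) {
  if (length(design$tissues) != 3L || length(design$groups) != 2L) {
    stop("default_module_specs requires 3 tissues and 2 groups")
  }
  n <- design$n_samples
  r <- n / 3 # samples per tissue (balanced)
  dirs <- icosahedral_directions()
  # axis 1 is the pure group direction; give it module id 4 (size 150)
  axis_for_module <- c(2L, 3L, 4L, 1L, 5L, 6L)
  u1 <- c(1, -1, 0) / sqrt(2 * r)  # unit-norm tissue contrasts in sample space
  u2 <- c(1, 1, -2) / sqrt(6 * r)
  g_norm <- sqrt(n) / 2            # norm of the centered group indicator
  specs <- vector("list", 6L)
  for (m in seq_len(6L)) {
    d <- dirs[axis_for_module[m], ]
    te <- amplitude * (d[1] * u1 + d[2] * u2)
    names(te) <- design$tissues
    specs[[m]] <- module_spec(
      module_id = m, size = sizes[m], tissue_effect = te,
      group_effect = amplitude * d[3] / g_norm
    )
  }
  specs
}

#' Simulate a count matrix with planted modules, trait effects and DE genes
#'
#' Gene-level log2 signal is `x_gs = mu_g + lambda_g * e_(m(g),s) + eps`,
#' with `eps ~ N(0, noise_sd)` and per-module latent profile
#' `e_(m,s) = tissue_effect(tissue_s) + group_effect * 1[group_s = High]
#' + N(0, 0.2)`. Counts are negative binomial with mean `s_s * 2^x_gs` and
#' dispersion `alpha(mu) = a0 + a1/mu`; size factors `s_s` are log-uniform
#' on `size_factor_range`. Planted per-tissue DE genes (drawn from the
#' background) get `+/- de_lfc` added in High-group samples of their
#' designated tissue. Deterministic given `seed`.
#'
#' @param design a `study_design` from [make_design()].
#' @param module_specs list of [module_spec()]s (possibly empty).
#' @param n_background_genes unstructured genes beyond the modules.
#' @param n_de_per_tissue planted DE background genes per tissue.
#' @param de_lfc absolute log2 fold change of planted DE genes.
#' @param a0,a1 dispersion-trend parameters (both > 0).
#' @param background_sd log2 residual SD of background genes.
#' @param size_factor_range range of true per-sample size factors.
#' @param seed overrides `design$seed` if given.
#' @return A `fatdep_sim` list: `counts` (integer gene x sample matrix),
#'   `metadata`, `truth` (gene_id, module_id, per-tissue DE flags),
#'   `eigenprofiles` (module x sample latent profiles), `loadings`,
#'   `size_factors_true`, `mu`, and the generator parameters.
#' @export
simulate_dataset <- function(design, module_specs = default_module_specs(design),
                             n_background_genes = 450L, n_de_per_tissue = 30L,
                             de_lfc = 2, a0 = 0.01, a1 = 1,
                             background_sd = 0.4,
                             size_factor_range = c(0.5, 2),
                             seed = design$seed) {
  if (a0 <= 0 || a1 <= 0) stop("invalid parameter: dispersion a0, a1 must be > 0")
  if (n_de_per_tissue * length(design$tissues) > n_background_genes) {
    stop("not enough background genes to host the planted DE genes")
  }
  set.seed(as.integer(seed))
  meta <- design$metadata
  n <- nrow(meta)
  sizes <- vapply(module_specs, `[[`, integer(1), "size")
  n_mod_genes <- sum(sizes)
  n_genes <- n_mod_genes + n_background_genes
  gene_ids <- sprintf("G%05d", seq_len(n_genes))

  module_of <- c(rep(vapply(module_specs, `[[`, integer(1), "module_id"), sizes),
                 rep(0L, n_background_genes))
  mu <- stats::runif(n_genes, 3, 12)
  s_true <- exp(stats::runif(n, log(size_factor_range[1]),
                             log(size_factor_range[2])))
  names(s_true) <- meta$sample_id

  x <- matrix(mu, n_genes, n) # log2 signal
  lambda <- numeric(n_genes)
  eig <- NULL
  if (length(module_specs)) {
    eig <- matrix(0, length(module_specs), n,
                  dimnames = list(vapply(module_specs, `[[`, integer(1),
                                         "module_id"), meta$sample_id))
    for (i in seq_along(module_specs)) {
      sp <- module_specs[[i]]
      e <- sp$tissue_effect[meta$tissue] +
        sp$group_effect * (meta$group == "High") + stats::rnorm(n, 0, 0.2)
      eig[i, ] <- e
      idx <- which(module_of == sp$module_id)
      lambda[idx] <- stats::runif(length(idx), sp$loading_range[1],
                                  sp$loading_range[2])
      x[idx, ] <- x[idx, ] + lambda[idx] %o% e +
        matrix(stats::rnorm(length(idx) * n, 0, sp$noise_sd), length(idx), n)
    }
  }
  bg <- which(module_of == 0L)
  if (length(bg)) {
    x[bg, ] <- x[bg, ] +
      matrix(stats::rnorm(length(bg) * n, 0, background_sd), length(bg), n)
  }

  # planted per-tissue DE genes among the background, alternating sign
  de <- matrix(0L, n_genes, length(design$tissues),
               dimnames = list(NULL, design$tissues))
  if (n_de_per_tissue > 0L && length(bg)) {
    picked <- sample(bg, n_de_per_tissue * length(design$tissues))
    for (t in seq_along(design$tissues)) {
      idx <- picked[seq((t - 1L) * n_de_per_tissue + 1L, t * n_de_per_tissue)]
      sgn <- rep_len(c(1, -1), length(idx))
      cols <- meta$group == "High" & meta$tissue == design$tissues[t]
      x[idx, cols] <- x[idx, cols] + sgn * de_lfc
      de[idx, t] <- 1L
    }
  }
  # module genes driven by a group effect differ between groups in every tissue
  if (length(module_specs)) {
    for (sp in module_specs) {
      if (abs(sp$group_effect) > 0) de[module_of == sp$module_id, ] <- 1L
    }
  }

  m <- sweep(2^x, 2, s_true, `*`)
  alpha <- a0 + a1 / m
  counts <- matrix(
    stats::rnbinom(length(m), mu = m, size = 1 / alpha),
    n_genes, n, dimnames = list(gene_ids, meta$sample_id)
  )
  storage.mode(counts) <- "integer"

  truth <- data.frame(gene_id = gene_ids, module_id = module_of,
                      stringsAsFactors = FALSE)
  for (t in design$tissues) truth[[paste0("de_", tolower(t))]] <- de[, t]

  structure(
    list(counts = counts, metadata = meta, truth = truth,
         eigenprofiles = eig, loadings = stats::setNames(lambda, gene_ids),
         size_factors_true = s_true, mu = stats::setNames(mu, gene_ids),
         params = list(a0 = a0, a1 = a1, de_lfc = de_lfc, seed = seed,
                       background_sd = background_sd)),
    class = "fatdep_sim"
  )
}

#' Write a simulated dataset to plain-text fixture files
#'
#' Emits `counts.tsv` (first column `gene_id`, one integer column per
#' sample), `metadata.tsv` (`sample_id, breed, group, tissue`) and
#' `truth.tsv` (`gene_id, module_id, de_<tissue>...`). Round-trips
#' losslessly through [read_counts()]/[read_metadata()].
#'
#' @param sim a `fatdep_sim`.
#' @param dir output directory (created if absent).
#' @return Invisibly, a named character vector of the written paths.
#' @export
write_fixture <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  counts_df <- data.frame(gene_id = rownames(sim$counts), sim$counts,
                          check.names = FALSE, stringsAsFactors = FALSE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_tsv(counts_df, paths["counts"])
  write_tsv(sim$metadata, paths["metadata"])
  write_tsv(sim$truth, paths["truth"])
  invisible(paths)
}

#' Build a synthetic GMT-style gene-set collection from simulation truth
#'
#' One term per planted module (its exact member genes) plus random decoy
#' terms, with category tags cycling through BP/MF/CC, so enrichment can be
#' exercised offline with known expected hits.
#'
#' @param sim a `fatdep_sim`.
#' @param n_random_terms decoy terms drawn uniformly from all genes.
#' @param size_range size range of decoy terms.
#' @param seed RNG seed for the decoys.
#' @return A `gene_set_collection` (see [read_gmt()]).
#' @export
make_module_gene_sets <- function(sim, n_random_terms = 20L,
                                  size_range = c(10L, 50L), seed = 1L) {
  set.seed(as.integer(seed))
  genes <- sim$truth$gene_id
  sets <- list(); categories <- character()
  cats <- c("BP", "MF", "CC")
  for (m in sort(unique(sim$truth$module_id[sim$truth$module_id > 0L]))) {
    id <- sprintf("MODULE_M%d", m)
    sets[[id]] <- genes[sim$truth$module_id == m]
    categories[id] <- cats[(m - 1L) %% 3L + 1L]
  }
  for (i in seq_len(n_random_terms)) {
    id <- sprintf("RANDOM_T%03d", i)
    sz <- sample(seq(size_range[1], size_range[2]), 1L)
    sets[[id]] <- sample(genes, sz)
    categories[id] <- cats[(i - 1L) %% 3L + 1L]
  }
  structure(list(sets = sets, categories = categories, universe = genes),
            class = "gene_set_collection")
}
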