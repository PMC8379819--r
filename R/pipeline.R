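# End-to-end orchestration: preprocess -> differential expression ->
# network -> modules -> trait statistics -> enrichment, with a resolved
# config, a machine-readable output manifest and a plain-text summary.

#' Pipeline configuration
#'
#' Defaults equal the published analysis thresholds: low-expression filter
#' at total count 10, soft-threshold grid 1..20 with scale-free R^2 cut
#' 0.8, minimum module size 30, eigengene merge cut 0.25, raw DE p < 0.05,
#' 30 hub genes per module, enrichment FDR < 0.05 with the top 10 terms,
#' and module-trait significance p < 0.01 for candidate modules.
#'
#' @param counts path to counts.tsv or a count matrix.
#' @param metadata path to metadata.tsv or a data frame.
#' @param outdir output directory.
#' @param gmt optional GMT path or `gene_set_collection`.
#' @param min_total,power_grid,r2_cut,n_bins,min_module_size,
#'   cut_height_frac,merge_cut,de_alpha,cooks_quantile,hub_n,trait_p_cut,
#'   enrich_fdr,top_terms analysis knobs (see the stage functions).
#' @param seed integer recorded in the config (the pipeline itself is
#'   deterministic; the seed matters when the inputs are simulated).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(counts, metadata, outdir, gmt = NULL,
                            min_total = 10, power_grid = 1:20, r2_cut = 0.8,
                            n_bins = 10L, min_module_size = 30L,
                            cut_height_frac = 0.99, merge_cut = 0.25,
                            de_alpha = 0.05, cooks_quantile = 0.99,
                            hub_n = 30L, trait_p_cut = 0.01,
                            enrich_fdr = 0.05, top_terms = 10L, seed = 1L) {
  structure(
    list(counts = counts, metadata = metadata, outdir = outdir, gmt = gmt,
         min_total = min_total, power_grid = power_grid, r2_cut = r2_cut,
         n_bins = as.integer(n_bins),
         min_module_size = as.integer(min_module_size),
         cut_height_frac = cut_height_frac, merge_cut = merge_cut,
         de_alpha = de_alpha, cooks_quantile = cooks_quantile,
         hub_n = as.integer(hub_n), trait_p_cut = trait_p_cut,
         enrich_fdr = enrich_fdr, top_terms = as.integer(top_terms),
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the full co-expression candidate-gene pipeline
#'
#' Stage order: read/validate, low-expression filter, size factors,
#' dispersion trend, VST, sample-outlier flagging (flags only), per
#' breed x tissue NB Wald DE, candidate-set algebra, soft-threshold scan,
#' adjacency, TOM, dendrogram, static module cut, eigengene merge, trait
#' design, module-trait correlation, GS/MM/MS, intramodular connectivity,
#' hub selection, hub-network export, and (if a GMT is given) enrichment
#' of each candidate module. Strong candidates are hub genes of
#' trait-associated modules that are also cross-breed DE candidates.
#' Deterministic given identical inputs and config.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with every intermediate result plus
#'   `manifest` (named vector of written files) and `summary` lines.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  outdir <- config$outdir
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  manifest <- c()
  emit <- function(x, name) {
    path <- file.path(outdir, name)
    write_tsv(x, path)
    manifest[[name]] <<- path
    path
  }
  log_msg <- function(...) message("[fatdep] ", ...)

  counts <- if (is.character(config$counts)) read_counts(config$counts) else config$counts
  metadata <- if (is.character(config$metadata)) read_metadata(config$metadata) else config$metadata
  validate_counts(counts)
  if (!setequal(colnames(counts), metadata$sample_id)) {
    stop("counts and metadata disagree on sample identifiers")
  }
  counts <- counts[, metadata$sample_id, drop = FALSE]
  summary_lines <- sprintf("input: %d genes x %d samples",
                           nrow(counts), ncol(counts))

  # --- preprocess ---
  log_msg("filtering low-expression genes")
  counts <- filter_low_expression(counts, config$min_total)
  summary_lines <- c(summary_lines,
                     sprintf("after filter (total count >= %g): %d genes",
                             config$min_total, nrow(counts)))
  sf <- size_factors(counts)
  trend <- fit_dispersion_trend(counts, sf)
  expr <- vst_transform(counts, sf, trend)
  out <- detect_outlier_samples(expr)
  summary_lines <- c(summary_lines,
                     sprintf("flagged outlier samples: %s",
                             if (length(out$flagged)) paste(out$flagged, collapse = ", ") else "none"))
  emit(data.frame(sample_id = names(sf), size_factor = unname(sf)),
       "sizefactors.tsv")
  emit(data.frame(gene_id = rownames(expr), expr, check.names = FALSE),
       "expr.tsv")
  writeLines(out$flagged, file.path(outdir, "outliers.txt"))
  manifest[["outliers.txt"]] <- file.path(outdir, "outliers.txt")

  # --- differential expression per breed x tissue ---
  de_tables <- list()
  for (b in sort(unique(metadata$breed))) {
    de_tables[[b]] <- list()
    for (t in sort(unique(metadata$tissue))) {
      log_msg("DE contrast ", b, " / ", t)
      de <- run_de_contrast(counts, metadata, b, t, alpha = config$de_alpha,
                            cooks_quantile = config$cooks_quantile)
      de_tables[[b]][[t]] <- de
      emit(de, sprintf("de_%s_%s.tsv", b, t))
    }
  }
  cand <- combine_candidate_sets(de_tables)
  all_sig <- sort(unique(unlist(cand$union, use.names = FALSE)))
  cand_df <- data.frame(gene_id = all_sig, stringsAsFactors = FALSE)
  for (b in names(cand$union)) {
    cand_df[[paste0("in_", b)]] <- as.integer(all_sig %in% cand$union[[b]])
  }
  cand_df$in_intersection <- as.integer(all_sig %in% cand$intersection)
  emit(cand_df, "candidates.tsv")
  summary_lines <- c(summary_lines,
                     sprintf("DE candidates: %s; cross-breed intersection: %d",
                             paste(sprintf("%s=%d", names(cand$union),
                                           lengths(cand$union)), collapse = ", "),
                             length(cand$intersection)))

  # --- network ---
  log_msg("soft-threshold scan")
  scan <- pick_soft_threshold(expr, powers = config$power_grid,
                              r2_cut = config$r2_cut, n_bins = config$n_bins)
  emit(scan$table, "softthreshold_scan.tsv")
  beta <- scan$chosen_power
  summary_lines <- c(summary_lines, sprintf("chosen soft threshold: beta = %d", beta))
  A <- adjacency_matrix(correlation_matrix(expr), beta)
  tom <- tom_similarity(A)
  dendro <- build_dendrogram(tom_dissimilarity(tom))
  assignment <- detect_modules(dendro, min_size = config$min_module_size,
                               cut_height = config$cut_height_frac * max(dendro$height))
  merged <- merge_modules(expr, assignment, merge_cut = config$merge_cut)
  assignment <- merged$assignment
  emit(merged$history, "merge_history.tsv")
  mods <- sort(unique(assignment[assignment > 0L]))
  sizes <- vapply(mods, function(m) sum(assignment == m), integer(1))
  summary_lines <- c(summary_lines,
                     sprintf("modules: %d (sizes %s); grey: %d genes",
                             length(mods), paste(sizes, collapse = ", "),
                             sum(assignment == 0L)))
  emit(data.frame(gene_id = names(assignment),
                  module_label = unname(assignment),
                  module_color = unname(attr(assignment, "colors"))),
       "modules.tsv")

  # --- trait statistics ---
  if (!length(mods)) {
    warning("no modules detected; trait statistics and enrichment skipped")
    emit(data.frame(gene_id = character()), "strong_candidates.tsv")
    writeLines(summary_lines, file.path(outdir, "summary.txt"))
    manifest[["summary.txt"]] <- file.path(outdir, "summary.txt")
    jsonlite::write_json(as.list(names(manifest)),
                         file.path(outdir, "manifest.json"), auto_unbox = TRUE)
    return(invisible(list(
      counts = counts, metadata = metadata, size_factors = sf, trend = trend,
      expr = expr, outliers = out, de_tables = de_tables, candidates = cand,
      scan = scan, adjacency = A, tom = tom, dendrogram = dendro,
      assignment = assignment, merge_history = merged$history,
      strong_candidates = character(), manifest = unlist(manifest),
      summary = summary_lines
    )))
  }
  me <- module_eigengenes(expr, assignment)
  emit(data.frame(sample_id = rownames(me$eigengenes), me$eigengenes,
                  check.names = FALSE), "eigengenes.tsv")
  design <- trait_design_matrix(metadata)
  mt <- module_trait_correlation(me$eigengenes, design)
  mt_long <- data.frame(
    module = rep(rownames(mt$r), ncol(mt$r)),
    trait = rep(colnames(mt$r), each = nrow(mt$r)),
    r = as.vector(mt$r), p = as.vector(mt$p), stringsAsFactors = FALSE
  )
  emit(mt_long, "module_trait.tsv")
  trait <- design[, attr(design, "trait_column")]
  gs <- gene_significance(expr, trait)
  mm <- module_membership(expr, me$eigengenes)
  ms <- module_significance(gs, assignment)
  conn <- intramodular_connectivity(A, assignment)
  genestats <- data.frame(conn, GS = unname(gs[conn$gene_id]),
                          stringsAsFactors = FALSE)
  emit(genestats, "genestats.tsv")
  emit(data.frame(module = names(ms), MS = as.numeric(ms)),
       "module_significance.tsv")
  hubs <- select_hub_genes(conn, n = config$hub_n, mm = mm, gs = gs)
  for (m in names(hubs)) {
    emit(hubs[[m]], sprintf("hubs_M%s.tsv", m))
    emit(export_hub_network(A, hubs[[m]]$gene_id),
         sprintf("hub_network_M%s.tsv", m))
  }

  # trait-associated ("candidate") modules and strong candidates
  tcol <- attr(design, "trait_column")
  trait_mods <- rownames(mt$p)[!is.na(mt$p[, tcol]) &
                                 mt$p[, tcol] < config$trait_p_cut]
  trait_mod_ids <- as.integer(sub("^ME", "", trait_mods))
  hub_pool <- unlist(lapply(as.character(trait_mod_ids),
                            function(m) hubs[[m]]$gene_id), use.names = FALSE)
  strong <- sort(intersect(hub_pool, cand$intersection))
  summary_lines <- c(summary_lines,
                     sprintf("trait-associated modules (p < %g): %s",
                             config$trait_p_cut,
                             if (length(trait_mods)) paste(trait_mods, collapse = ", ") else "none"),
                     sprintf("strong candidates (trait-module hub & cross-breed DE): %s",
                             if (length(strong)) paste(strong, collapse = ", ") else "none"))
  emit(data.frame(gene_id = strong), "strong_candidates.tsv")

  # --- enrichment ---
  enrich <- NULL
  if (!is.null(config$gmt)) {
    collection <- if (is.character(config$gmt)) {
      read_gmt(config$gmt, universe = rownames(expr))
    } else config$gmt
    enrich <- list()
    for (m in trait_mod_ids) {
      genes_m <- names(assignment)[assignment == m]
      er <- enrich_gene_list(genes_m, collection, fdr_cut = config$enrich_fdr,
                             top_n = config$top_terms)
      enrich[[as.character(m)]] <- er
      emit(er, sprintf("enrichment_M%d.tsv", m))
    }
    if (length(cand$intersection)) {
      er <- enrich_gene_list(cand$intersection, collection,
                             fdr_cut = config$enrich_fdr,
                             top_n = config$top_terms)
      enrich[["candidates"]] <- er
      emit(er, "enrichment_candidates.tsv")
    }
  }

  # --- reporting ---
  cfg <- config
  cfg$counts <- if (is.character(config$counts)) config$counts else "<matrix>"
  cfg$metadata <- if (is.character(config$metadata)) config$metadata else "<data.frame>"
  cfg$gmt <- if (is.character(config$gmt)) config$gmt else if (is.null(config$gmt)) NULL else "<collection>"
  jsonlite::write_json(unclass(cfg), file.path(outdir, "config.json"),
                       auto_unbox = TRUE, null = "null")
  manifest[["config.json"]] <- file.path(outdir, "config.json")
  writeLines(summary_lines, file.path(outdir, "summary.txt"))
  manifest[["summary.txt"]] <- file.path(outdir, "summary.txt")
  # manifest records paths relative to outdir so reruns compare bytewise
  jsonlite::write_json(as.list(names(manifest)),
                       file.path(outdir, "manifest.json"), auto_unbox = TRUE)

  invisible(list(
    counts = counts, metadata = metadata, size_factors = sf, trend = trend,
    expr = expr, outliers = out, de_tables = de_tables, candidates = cand,
    scan = scan, adjacency = A, tom = tom, dendrogram = dendro,
    assignment = assignment, merge_history = merged$history,
    eigengenes = me, module_trait = mt, gs = gs, mm = mm, ms = ms,
    connectivity = conn, hubs = hubs, trait_modules = trait_mod_ids,
    strong_candidates = strong, enrichment = enrich,
    manifest = unlist(manifest), summary = summary_lines
  ))
}

#' Minimal command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic fixture) and `run-all`
#' (full pipeline). Example:
#' `Rscript -e 'fatdep::fatdep_cli()' run-all --counts counts.tsv
#' --metadata metadata.tsv --outdir out --seed 1`.
#'
#' @param args character vector (defaults to the command line).
#' @return exit status 0 invisibly; stops on errors.
#' @export
fatdep_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: fatdep <simulate|run-all> [--counts F] [--metadata F]",
    "[--gmt F] [--outdir D] [--seed N] [--n-background N]"
  )
  if (!length(args)) stop(usage, call. = FALSE)
  cmd <- args[1]
  opt <- list(outdir = "fatdep_out", seed = 1L, `n-background` = 450L)
  i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (i + 1L > length(args)) stop("missing value for --", key, call. = FALSE)
    opt[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  seed <- as.integer(opt$seed)
  if (cmd == "simulate") {
    design <- make_design(seed = seed)
    sim <- simulate_dataset(design,
                            n_background_genes = as.integer(opt$`n-background`),
                            seed = seed)
    paths <- write_fixture(sim, opt$outdir)
    write_gmt(make_module_gene_sets(sim, seed = seed),
              file.path(opt$outdir, "genesets.gmt"))
    message("wrote fixture to ", opt$outdir)
  } else if (cmd == "run-all") {
    if (is.null(opt$counts) || is.null(opt$metadata)) {
      stop("run-all requires --counts and --metadata", call. = FALSE)
    }
    cfg <- pipeline_config(opt$counts, opt$metadata, opt$outdir,
                           gmt = opt$gmt, seed = seed)
    run_pipeline(cfg)
    message("pipeline finished; outputs in ", opt$outdir)
  } else {
    stop(usage, call. = FALSE)
  }
  invisible(0L)
}
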