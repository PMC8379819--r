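test_that("trait_design_matrix one-hot encodes the three factors", {
  md <- make_design()$metadata
  D <- trait_design_matrix(md)
  expect_equal(ncol(D), 7L) # 2 breeds + 2 groups + 3 tissues
  expect_true(all(D %in% c(0, 1)))
  expect_identical(attr(D, "trait_column"), "group_High")
  # columns of one factor partition the samples
  for (f in c("breed", "group", "tissue")) {
    cols <- grep(paste0("^", f, "_"), colnames(D))
    expect_equal(unname(rowSums(D[, cols, drop = FALSE])), rep(1, nrow(D)))
  }

  # single-level factor flagged as constant
  md1 <- md[md$breed == "Landrace", ]
  D1 <- trait_design_matrix(md1)
  expect_true("breed_Landrace" %in% attr(D1, "constant"))

  expect_error(trait_design_matrix(md[, -2]), "columns")
})

test_that("module_trait_correlation matches the t-transform and cor.test", {
  set.seed(40)
  n <- 36L
  md <- make_design()$metadata
  D <- trait_design_matrix(md)
  me <- matrix(rnorm(n * 3), n, 3,
               dimnames = list(md$sample_id, c("ME1", "ME2", "ME3")))
  # make ME1 equal to the standardized trait: r = 1, p ~ 0
  me[, 1] <- scale(D[, "group_High"])
  mt <- module_trait_correlation(me, D)
  expect_equal(mt$r["ME1", "group_High"], 1)
  expect_lt(mt$p["ME1", "group_High"], 1e-12)

  # p-values agree with the cor.test oracle everywhere
  for (m in c("ME2", "ME3")) {
    for (tr in colnames(D)) {
      o <- cor.test(me[, m], D[, tr])
      expect_equal(mt$r[m, tr], unname(o$estimate), tolerance = 1e-12)
      expect_equal(mt$p[m, tr], o$p.value, tolerance = 1e-10)
    }
  }

  # consistent sample permutation leaves the table unchanged
  perm <- sample(n)
  mt2 <- module_trait_correlation(me[perm, ], D[perm, ])
  expect_equal(mt2$r, mt$r, tolerance = 1e-12)

  # constant trait produces NA with a warning
  md1 <- md[md$breed == "Landrace", ]
  D1 <- trait_design_matrix(md1)
  expect_warning(mt1 <- module_trait_correlation(me[md1$sample_id, ], D1),
                 "constant")
  expect_true(is.na(mt1$r["ME2", "breed_Landrace"]))
})

test_that("gene significance is the absolute trait correlation", {
  set.seed(41)
  n <- 20L
  trait <- rep(c(1, 0), each = n / 2)
  expr <- rbind(
    same = trait, flip = -trait,
    matrix(rnorm(3 * n), 3, dimnames = list(paste0("g", 1:3), NULL))
  )
  colnames(expr) <- paste0("s", 1:n)
  gs <- gene_significance(expr, trait)
  expect_equal(unname(gs[c("same", "flip")]), c(1, 1))
  for (g in paste0("g", 1:3)) {
    expect_equal(unname(gs[g]), abs(cor(expr[g, ], trait)), tolerance = 1e-12)
  }
  signed <- gene_significance(expr, trait, signed = TRUE)
  expect_equal(unname(signed["flip"]), -1)
  expect_error(gene_significance(expr, rep(1, n)), "constant")
})

test_that("module significance is the module mean of GS", {
  gs <- setNames(c(0.5, 0.5, 0.9, 0.1, 0.3), paste0("g", 1:5))
  asg <- setNames(c(1L, 1L, 2L, 2L, 0L), paste0("g", 1:5))
  ms <- module_significance(gs, asg)
  expect_equal(ms[["1"]], 0.5)
  expect_equal(ms[["2"]], 0.5)
  expect_equal(ms[["0"]], 0.3)
  # bounded by the module's GS range
  expect_gte(ms[["2"]], 0.1); expect_lte(ms[["2"]], 0.9)
})

test_that("planted trait module has higher MS than a neutral one", {
  sim <- small_module_sim()
  expr <- small_module_expr()
  asg <- setNames(sim$truth$module_id, sim$truth$gene_id)[rownames(expr)]
  trait <- as.numeric(sim$metadata$group == "High")
  ms <- module_significance(gene_significance(expr, trait), asg)
  expect_gt(ms[["3"]], ms[["1"]]) # module 3 carries the group effect
  expect_gt(ms[["3"]], ms[["2"]])
})

test_that("module membership equals the gene-by-eigengene correlation oracle", {
  expr <- small_module_expr()[1:60, ]
  sim <- small_module_sim()
  asg <- setNames(sim$truth$module_id, sim$truth$gene_id)[rownames(expr)]
  me <- module_eigengenes(small_module_expr(),
                          setNames(sim$truth$module_id, sim$truth$gene_id))
  mm <- module_membership(expr, me$eigengenes)
  for (g in sample(rownames(expr), 10)) {
    for (m in colnames(me$eigengenes)) {
      expect_equal(mm[g, m], cor(expr[g, ], me$eigengenes[, m]),
                   tolerance = 1e-12)
    }
  }
  # a rank-1 module is fully described by its driver gene
  driver <- rnorm(ncol(expr))
  e2 <- rbind(expr, drv1 = driver, drv2 = driver * 2 + 1)
  me2 <- module_eigengenes(e2, setNames(c(rep(0L, nrow(expr)), 9L, 9L),
                                        rownames(e2)))
  mm2 <- module_membership(e2, me2$eigengenes)
  expect_equal(abs(mm2["drv1", "ME9"]), 1, tolerance = 1e-10)
})

test_that("GS and MM correlate within a trait module", {
  sim <- small_module_sim()
  expr <- small_module_expr()
  asg <- setNames(sim$truth$module_id, sim$truth$gene_id)[rownames(expr)]
  me <- module_eigengenes(expr, asg)
  trait <- as.numeric(sim$metadata$group == "High")
  gs <- gene_significance(expr, trait)
  mm <- module_membership(expr, me$eigengenes)
  genes3 <- names(asg)[asg == 3L]
  expect_gt(cor(gs[genes3], abs(mm[genes3, "ME3"])), 0.5)
})

test_that("intramodular connectivity matches a double-loop oracle", {
  set.seed(42)
  e <- matrix(rnorm(15 * 10), 15, 10,
              dimnames = list(sprintf("g%02d", 1:15), sprintf("s%02d", 1:10)))
  A <- adjacency_matrix(correlation_matrix(e), 4)
  asg <- setNames(rep(c(1L, 2L, 0L), each = 5), rownames(A))
  conn <- intramodular_connectivity(A, asg)
  for (i in seq_len(15)) {
    kt <- 0; kw <- 0
    for (j in seq_len(15)) {
      if (i == j) next
      kt <- kt + A[i, j]
      if (asg[i] == asg[j]) kw <- kw + A[i, j]
    }
    expect_equal(conn$kTotal[i], kt, tolerance = 1e-10)
    expect_equal(conn$kWithin[i], kw, tolerance = 1e-10)
  }
  expect_true(all(conn$kWithin <= conn$kTotal + 1e-12))

  # singleton module has no within-module neighbors
  asg1 <- asg; asg1[1] <- 7L
  expect_equal(intramodular_connectivity(A, asg1)$kWithin[1], 0)
  # one whole-network module saturates kWithin at kTotal
  asg_all <- setNames(rep(1L, 15), rownames(A))
  c_all <- intramodular_connectivity(A, asg_all)
  expect_equal(c_all$kWithin, c_all$kTotal)

  expect_error(intramodular_connectivity(A, asg[1:5]), "same genes")
})

test_that("select_hub_genes ranks by kWithin with deterministic ties", {
  conn <- data.frame(
    gene_id = sprintf("g%02d", 1:10), module = rep(1L, 10),
    kTotal = 10:1, kWithin = c(5, 5, 9, 1, 8, 2, 7, 3, 6, 4)
  )
  hubs <- select_hub_genes(conn, n = 30)
  expect_equal(nrow(hubs[["1"]]), 10L) # truncated to module size
  expect_true(all(diff(hubs[["1"]]$kWithin) <= 0))
  # tie at kWithin = 5 resolved by gene ID
  pos <- match(c("g01", "g02"), hubs[["1"]]$gene_id)
  expect_equal(pos[1] + 1L, pos[2])

  top3 <- select_hub_genes(conn, n = 3)
  expect_equal(top3[["1"]]$gene_id, c("g03", "g05", "g07"))

  # hub membership invariant to input row order
  perm <- sample(10)
  hub_p <- select_hub_genes(conn[perm, ], n = 3)
  expect_equal(hub_p[["1"]], top3[["1"]])
})

test_that("a gene with inflated loading becomes a hub across seeds", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- 24
    e <- rnorm(n)
    lam <- c(1.8, runif(29, 0.4, 0.7)) # gene 1 loads far above the rest
    expr <- lam %o% e + matrix(rnorm(30 * n, sd = 0.4), 30, n)
    dimnames(expr) <- list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:n))
    A <- adjacency_matrix(correlation_matrix(expr), 6)
    conn <- intramodular_connectivity(A, setNames(rep(1L, 30), rownames(expr)))
    hubs <- select_hub_genes(conn, n = 5)
    expect_true("g01" %in% hubs[["1"]]$gene_id)
  }
})

test_that("export_hub_network emits each pair once with adjacency weights", {
  set.seed(43)
  e <- matrix(rnorm(30 * 10), 30, 10,
              dimnames = list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:10)))
  A <- adjacency_matrix(correlation_matrix(e), 3)
  edges <- export_hub_network(A, rownames(A))
  expect_equal(nrow(edges), 30 * 29 / 2) # 435
  expect_true(all(edges$source < edges$target))
  for (i in sample(nrow(edges), 20)) {
    expect_equal(edges$weight[i], A[edges$source[i], edges$target[i]])
  }
  few <- export_hub_network(A, c("g05", "g03", "g09"))
  expect_equal(nrow(few), 3L)
  expect_error(export_hub_network(A, character()), "empty")
})
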