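# Shared fixtures, memoised so expensive simulations run once per session.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A small single-tissue two-group design for DE-level tests.
small_de_design <- function(reps = 3L, seed = 7L) {
  make_design(breeds = "B", groups = c("High", "Low"), tissues = "T",
              reps_per_cell = reps, seed = seed)
}

# Small planted-module simulation (3 modules x 40 genes + background) for
# fast network/module tests. Distinct tissue patterns, one group module.
small_module_sim <- function(seed = 11L) {
  memo(paste0("small_sim_", seed), {
    design <- make_design(reps_per_cell = 3L, seed = seed)
    specs <- list(
      module_spec(1L, 40L, c(Fat = 3, Liver = -1.5, Muscle = -1.5)),
      module_spec(2L, 40L, c(Fat = -1.5, Liver = 3, Muscle = -1.5)),
      module_spec(3L, 40L, c(Fat = 0, Liver = 0, Muscle = 0), group_effect = 3)
    )
    simulate_dataset(design, specs, n_background_genes = 80L,
                     n_de_per_tissue = 0L, seed = seed)
  })
}

# VST expression for the small simulation.
small_module_expr <- function(seed = 11L) {
  memo(paste0("small_expr_", seed), {
    sim <- small_module_sim(seed)
    counts <- filter_low_expression(sim$counts)
    sf <- size_factors(counts)
    vst_transform(counts, sf, fit_dispersion_trend(counts, sf))
  })
}

# Independent brute-force oracles (kept deliberately naive).

upgma_oracle <- function(d) {
  # O(n^3) average-linkage agglomeration; returns merge heights sorted.
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  dm <- d
  diag(dm) <- Inf
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    m <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in seq_len(m - 1L)) {
      for (j in seq(i + 1L, m)) {
        dij <- mean(d[clusters[[i]], clusters[[j]]])
        if (dij < best[1]) best <- c(dij, i, j)
      }
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  heights
}

tom_oracle <- function(A) {
  n <- nrow(A)
  diag(A) <- 1
  k <- rowSums(A) - 1
  tom <- diag(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      l <- 0
      for (u in seq_len(n)) if (u != i && u != j) l <- l + A[i, u] * A[u, j]
      tom[i, j] <- (l + A[i, j]) / (min(k[i], k[j]) + 1 - A[i, j])
    }
  }
  tom
}

hyper_tail_oracle <- function(k, K, n, N) {
  # exhaustive summation of the hypergeometric pmf upper tail
  i <- seq(k, min(K, n))
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    j <- seq(i, m)
    q[ord[i]] <- min(1, min(p[ord[j]] * m / j))
  }
  q
}
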