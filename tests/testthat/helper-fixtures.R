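# Desk-scale simulation config used across tests: ~330 probes over 30 genes,
# 10 agents (2 constant), the same archetype mix as the defaults.
small_config <- function(seed = 1L, ...) {
  args <- list(
    n_genes = 30L,
    probes_per_class = c(
      TSS1500 = 2L, TSS200 = 2L, `5UTR` = 1L,
      `1stExon` = 1L, Body = 3L, `3UTR` = 1L
    ),
    n_intergenic = 30L,
    n_agents = 10L,
    n_constant_agents = 2L,
    archetypes = c(
      canonical_repressive = 3L, positive_coupled = 2L,
      cn_driven = 1L, lineage_linked = 2L
    ),
    seed = seed
  )
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

# Minimal hand-built manifest for parser tests.
tiny_manifest <- function() {
  tibble::tibble(
    probe_id = c("cg01", "cg02", "cg03"),
    chromosome = "chr1",
    position = c(100L, 300L, 900L),
    cytoband = "1p1",
    gene_names = c("GENEA;GENEA", "GENEA;GENEB", ""),
    region_classes = c("TSS200;Body", "TSS200;Body", ""),
    snp_masked = FALSE
  )
}

# Independent brute-force step-up BH oracle (kept deliberately naive).
bh_brute_force <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  sorted <- p[o] * m / seq_len(m)
  # step-up monotonization from the largest rank down
  running <- Inf
  for (i in rev(seq_len(m))) {
    running <- min(running, sorted[i])
    adj[o[i]] <- min(running, 1)
  }
  adj
}

# All permutations of 1..n as a matrix (rows = permutations); recursive,
# used as the exact Spearman null oracle at small n.
all_perms <- function(n) {
  if (n == 1L) {
    return(matrix(1L, 1L, 1L))
  }
  sub <- all_perms(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (k in seq_len(n)) {
    for (i in seq_len(nrow(sub))) {
      rest <- sub[i, ] + (sub[i, ] >= k)
      out[row, ] <- c(k, rest)
      row <- row + 1L
    }
  }
  out
}

# Exact two-sided permutation p-value for Spearman at small n.
spearman_perm_p <- function(x, y, perms) {
  rx <- rank(x)
  ry <- rank(y)
  obs <- stats::cor(rx, ry)
  rho <- as.numeric(perms %*% (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  # perms permute rank positions of x against fixed y residuals
  mean(abs(rho) >= abs(obs) - 1e-12)
}
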