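# Shared fixtures: all data is built in code at test time.

# small, fast simulation config
small_config <- function(seed = 1L, ...) {
  sim_config(n_genes = 200L, n_deg_per_class = 3L, n_primed_high = 4L,
             n_primed_low = 4L, n_init_diff = 10L, n_unmapped_probes = 5L,
             seed = seed, ...)
}

# noiseless, offset-free config: estimates equal planted values exactly
noiseless_config <- function(seed = 1L, array_offset_sd = 0, ...) {
  small_config(seed = seed, noise_sd = 0, array_offset_sd = array_offset_sd,
               probe_offset_sd = 0, spread_init = 0, spread_drought = 0,
               organ_effect = 0, condition_effect = 0, genotype_effect = 0,
               baseline_sd = 0, ...)
}

# a balanced sample sheet for hand-built matrices (one organ)
one_organ_samples <- function(organ = "root", n = 3L) {
  grid <- expand.grid(replicate = seq_len(n),
                      condition = c("control", "drought"),
                      genotype = c("tolerant", "sensitive"),
                      stringsAsFactors = FALSE)
  data.frame(sample_id = paste(organ, grid$genotype, grid$condition,
                               paste0("r", grid$replicate), sep = "_"),
             organ = organ, genotype = grid$genotype,
             condition = grid$condition, replicate = grid$replicate,
             stringsAsFactors = FALSE)
}

# probe matrix from per-cell values: cells named genotype.condition
matrix_from_cells <- function(cells, samples, probe_ids = NULL) {
  if (is.null(dim(cells))) cells <- matrix(cells, nrow = 1,
                                           dimnames = list(NULL, names(cells)))
  if (is.null(probe_ids)) probe_ids <- paste0("p", seq_len(nrow(cells)))
  key <- paste(samples$genotype, samples$condition, sep = ".")
  m <- cells[, key, drop = FALSE]
  dimnames(m) <- list(probe_ids, samples$sample_id)
  m
}

# independent step-up BH oracle: q_i = min over p_(j) >= p_i of min(1, m p_(j)/j)
bh_oracle <- function(p) {
  m <- length(p)
  vapply(p, function(pi) {
    cand <- vapply(seq_len(m), function(j) {
      pj <- sort(p)[j]
      if (pj >= pi - 1e-15) min(1, m * pj / j) else Inf
    }, 1)
    min(cand)
  }, 1)
}

# exhaustive hypergeometric upper tail by direct summation of the pmf
hyper_oracle <- function(N, K, n, x) {
  ks <- max(0, x):min(n, K)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# brute-force Ward.D2 agglomeration via Lance-Williams on squared distances;
# returns merge heights and, after each merge, the active-cluster partition
# of the leaf labels as canonical strings
ward_oracle <- function(d, labels) {
  d2 <- as.matrix(d)^2
  n <- nrow(d2)
  active <- as.list(seq_len(n))
  sizes <- rep(1L, n)
  heights <- numeric(0)
  partitions <- list()
  repeat {
    k <- length(active)
    if (k == 1L) break
    best <- c(Inf, NA, NA)
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      if (d2[i, j] < best[1] - 1e-12) best <- c(d2[i, j], i, j)
    }
    i <- best[2]; j <- best[3]
    heights <- c(heights, sqrt(best[1]))
    ni <- sizes[i]; nj <- sizes[j]
    newrow <- vapply(seq_len(k), function(l) {
      if (l == i || l == j) return(NA_real_)
      nl <- sizes[l]
      ((ni + nl) * d2[i, l] + (nj + nl) * d2[j, l] - nl * d2[i, j]) /
        (ni + nj + nl)
    }, 1)
    keep <- setdiff(seq_len(k), c(i, j))
    d2 <- rbind(cbind(d2[keep, keep, drop = FALSE], newrow[keep]),
                c(newrow[keep], 0))
    active <- c(active[keep], list(sort(c(active[[i]], active[[j]]))))
    sizes <- c(sizes[keep], ni + nj)
    partitions[[length(partitions) + 1L]] <-
      sort(vapply(active, function(cl)
        paste(sort(labels[cl]), collapse = ","), ""))
  }
  list(heights = heights, partitions = partitions)
}

# leaf partitions of an hclust tree at every k, as canonical string sets
tree_partitions <- function(tree) {
  n <- length(tree$order)
  lapply(seq_len(n), function(k) {
    cl <- cutree(tree, k)
    unname(sort(vapply(split(names(cl), cl),
                       function(g) paste(sort(g), collapse = ","), "")))
  })
}
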