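# gene-level stat table builder for rule tests
gene_tab <- function(ids, fc, q, dir, pass = NULL, conflict = FALSE) {
  if (is.null(pass)) pass <- rep(TRUE, length(ids))
  conflict <- rep(conflict, length.out = length(ids))
  data.frame(gene_id = ids, FC = fc, q = q, direction = dir, pass = pass,
             conflict = conflict, delta = ifelse(dir == "up", 1, -1) * log2(fc),
             p = q / 2, stringsAsFactors = FALSE)
}

test_that("initial_difference_genes applies the lowered-stringency filter", {
  tab <- gene_tab(c("g1", "g2", "g3"),
                  fc = c(2.0, 1.9, 5),
                  q = c(0.05, 0.001, 0.2),
                  dir = c("up", "up", "down"),
                  pass = c(TRUE, FALSE, FALSE))
  out <- initial_difference_genes(tab)
  expect_equal(out$gene_id, "g1")             # boundary FC = 2, q = 0.05 passes
  expect_equal(out$sign, "tolerant_higher")
  expect_equal(nrow(initial_difference_genes(tab[0, ])), 0L)
  # wrong contrast kind is refused
  wrong <- contrast_spec("root", "drought_vs_control", genotype = "sensitive")
  expect_error(initial_difference_genes(tab, wrong), "wrong contrast kind")
})

test_that("select_primed applies the direction-consistency rule", {
  init <- initial_difference_genes(gene_tab(
    c("gH", "gX", "gL"), fc = c(2.5, 2.5, 3), q = c(0.01, 0.01, 0.01),
    dir = c("up", "up", "down")))
  sen <- gene_tab(c("gH", "gX", "gL", "gZ"),
                  fc = c(4, 4, 5, 8), q = rep(0.01, 4),
                  dir = c("up", "down", "down", "up"))
  tol <- gene_tab("gH", fc = 3.5, q = 0.02, dir = "up")
  calls <- select_primed(init, sen, tol, organ = "root")
  calls <- calls[order(calls$gene_id), ]
  # gH: tolerant-higher and sensitive drought-up -> primed_high
  # gL: tolerant-lower and sensitive drought-down -> primed_low
  # gX: tolerant-higher but sensitive drought-DOWN -> rejected
  # gZ: no initial difference -> never considered
  expect_equal(calls$gene_id, c("gH", "gL"))
  expect_equal(calls$priming_direction, c("primed_high", "primed_low"))
  expect_equal(calls$tolerant_drought_overlap, c(TRUE, FALSE))
})

test_that("select_primed equals a brute-force rule oracle on noiseless data", {
  ds <- simulate_dataset(noiseless_config(seed = 3))
  rep <- run_pipeline(ds$raw, ds$samples, ds$probe_map)
  for (o in c("root", "leaf")) {
    init_tab <- rep$contrasts[[paste0("initial_", o)]]
    sen_tab <- rep$contrasts[[paste0("sensitive_", o)]]
    # oracle: exhaustive filter-by-filter evaluation over all genes
    oracle <- character(0)
    for (g in init_tab$gene_id) {
      i <- init_tab[init_tab$gene_id == g, ]
      s <- sen_tab[sen_tab$gene_id == g, ]
      if (nrow(s) == 0) next
      ok_init <- i$pass && i$FC >= 2 && i$q <= 0.05 && !i$conflict
      ok_sen <- s$pass && s$FC >= 3 && s$q <= 0.05 && !s$conflict
      ok_dir <- (i$direction == "up" && s$direction == "up") ||
                (i$direction == "down" && s$direction == "down")
      if (ok_init && ok_sen && ok_dir) oracle <- c(oracle, g)
    }
    got <- rep$priming$gene_id[rep$priming$organ == o]
    expect_setequal(got, oracle)
  }
})

test_that("every emitted call satisfies its direction invariant", {
  ds <- simulate_dataset(small_config(seed = 5))
  rep <- run_pipeline(ds$raw, ds$samples, ds$probe_map)
  calls <- rep$priming
  for (i in seq_len(nrow(calls))) {
    o <- calls$organ[i]
    init <- rep$contrasts[[paste0("initial_", o)]]
    sen <- rep$contrasts[[paste0("sensitive_", o)]]
    idir <- init$direction[init$gene_id == calls$gene_id[i]]
    sdir <- sen$direction[sen$gene_id == calls$gene_id[i]]
    if (calls$priming_direction[i] == "primed_high") {
      expect_equal(idir, "up"); expect_equal(sdir, "up")
    } else {
      expect_equal(idir, "down"); expect_equal(sdir, "down")
    }
    expect_gte(calls$initial_FC[i], 2)
    expect_gte(calls$sensitive_drought_FC[i], 3)
    expect_lte(calls$initial_q[i], 0.05)
    expect_lte(calls$sensitive_drought_q[i], 0.05)
  }
})

test_that("selection is monotone in the thresholds", {
  set.seed(23)
  n <- 60
  base_init <- gene_tab(sprintf("g%02d", 1:n),
                        fc = runif(n, 1.5, 6), q = runif(n, 0, 0.1),
                        dir = sample(c("up", "down"), n, TRUE),
                        pass = rep(TRUE, n))
  sen <- gene_tab(sprintf("g%02d", 1:n),
                  fc = runif(n, 2, 8), q = runif(n, 0, 0.1),
                  dir = sample(c("up", "down"), n, TRUE))
  tol <- gene_tab(character(0), numeric(0), numeric(0), character(0))
  calls_at <- function(tau_init, tau_drought, alpha) {
    init <- base_init
    init$pass <- init$FC >= tau_init & init$q <= alpha
    s <- sen; s$pass <- s$FC >= tau_drought & s$q <= alpha
    init_g <- initial_difference_genes(init, tau_init = tau_init, alpha = alpha)
    select_primed(init_g, s, tol, organ = "root")$gene_id
  }
  base <- calls_at(2, 3, 0.05)
  expect_true(all(calls_at(2.5, 3, 0.05) %in% base))  # raising tau_init
  expect_true(all(calls_at(2, 4, 0.05) %in% base))    # raising tau_drought
  expect_true(all(calls_at(2, 3, 0.01) %in% base))    # lowering alpha
})

test_that("organ classification partitions calls with discordance flags", {
  mk <- function(g, o, d) data.frame(
    gene_id = g, organ = o, priming_direction = d,
    initial_FC = 3, initial_q = 0.01, sensitive_drought_FC = 4,
    sensitive_drought_q = 0.01, tolerant_drought_overlap = FALSE,
    stringsAsFactors = FALSE)
  root <- rbind(mk("gA", "root", "primed_high"), mk("gB", "root", "primed_high"))
  leaf <- rbind(mk("gB", "leaf", "primed_low"), mk("gC", "leaf", "primed_high"))
  out <- classify_priming_by_organ(root, leaf)
  oc <- setNames(out$organ_class, paste(out$gene_id, out$organ))
  expect_equal(unname(oc["gA root"]), "root_only")
  expect_equal(unname(oc["gB root"]), "both")
  expect_equal(unname(oc["gC leaf"]), "leaf_only")
  # gB called primed_high in root, primed_low in leaf: both + discordant
  expect_true(all(out$discordant[out$gene_id == "gB"]))
  expect_false(any(out$discordant[out$gene_id != "gB"]))
  # disjoint call sets give no "both"
  out2 <- classify_priming_by_organ(mk("g1", "root", "primed_high"),
                                    mk("g2", "leaf", "primed_high"))
  expect_false(any(out2$organ_class == "both"))
  # planted organ-specific primed sets are recovered on noiseless data
  ds <- simulate_dataset(noiseless_config(seed = 4))
  repb <- run_pipeline(ds$raw, ds$samples, ds$probe_map)
  lab <- ds$truth$labels
  primed_root <- lab$gene_id[lab$organ == "root" & lab$primed_label != "none"]
  primed_leaf <- lab$gene_id[lab$organ == "leaf" & lab$primed_label != "none"]
  got <- repb$priming[!duplicated(repb$priming$gene_id), ]
  expect_setequal(got$gene_id[got$organ_class == "root_only"],
                  setdiff(primed_root, primed_leaf))
  expect_setequal(got$gene_id[got$organ_class == "leaf_only"],
                  setdiff(primed_leaf, primed_root))
  expect_setequal(got$gene_id[got$organ_class == "both"],
                  intersect(primed_root, primed_leaf))
})

test_that("overlap counts equal hand intersections", {
  mk <- function(g, o, oc) data.frame(
    gene_id = g, organ = o, priming_direction = "primed_high",
    initial_FC = 3, initial_q = 0.01, sensitive_drought_FC = 4,
    sensitive_drought_q = 0.01, tolerant_drought_overlap = NA,
    organ_class = oc, discordant = FALSE, stringsAsFactors = FALSE)
  calls <- rbind(mk(c("g1", "g2", "g3"), "root", "root_only"),
                 mk(c("g4", "g5"), "leaf", "leaf_only"),
                 mk("g6", "root", "both"), mk("g6", "leaf", "both"))
  out <- overlap_with_tolerant_degs(calls,
                                    tolerant_deg_root = c("g1", "g6", "g9"),
                                    tolerant_deg_leaf = c("g4", "g5"))
  expect_equal(out$n_overlap[out$organ_class == "root_only"], 1L)
  expect_equal(out$n_overlap[out$organ_class == "leaf_only"], 2L)
  expect_equal(out$n_overlap[out$organ_class == "both"], 1L)
  # no tolerant DEGs at all -> zero overlap; calls subset -> full overlap
  none <- overlap_with_tolerant_degs(calls, character(0), character(0))
  expect_equal(none$n_overlap, c(0L, 0L, 0L))
  all_in <- overlap_with_tolerant_degs(calls, paste0("g", 1:9), paste0("g", 1:9))
  expect_equal(all_in$n_overlap, all_in$n_calls)
})
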