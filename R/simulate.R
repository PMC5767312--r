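#' Simulation configuration for the planted-truth expression generator
#'
#' Defines the study design the generator emulates: 2 genotypes x 2 organs x
#' 2 conditions with `n_replicates` arrays per cell, many-to-one
#' probe-to-gene mapping, per-array scaling offsets, and planted effects with
#' known labels. Planted effect magnitudes are drawn as
#' `delta + Exponential(mean = spread)`, so `delta_init` and
#' `delta_drought` are floors on the true log2 differences, mirroring the
#' heavy-tailed fold-change distributions seen on real arrays.
#'
#' @param n_genes number of genes.
#' @param probes_per_gene integer range (min, max) of probes per gene; each
#'   gene's probe count is drawn uniformly from this range.
#' @param n_replicates biological replicates per design cell.
#' @param baseline_mean,baseline_sd log2-scale gene baseline distribution.
#' @param organ_effect,condition_effect,genotype_effect standard deviations
#'   (log2) of per-gene background coefficients for the three design factors.
#'   The defaults are ordered organ > condition > genotype, and the organ
#'   term is large enough to dominate the planted condition- and
#'   genotype-level effects, so that sample clustering splits first by
#'   organ, then condition, then genotype. The condition and genotype terms
#'   are kept well below the fold-change labelling floors so background
#'   genes do not crowd the decision boundary.
#' @param n_deg_per_class planted drought-DEG genes per (genotype-exclusivity
#'   x organ-class x direction) cell; genotype-exclusivity runs over
#'   tolerant-only / sensitive-only / shared and organ-class over
#'   root-only / leaf-only / both.
#' @param n_primed_high,n_primed_low planted priming candidates per organ
#'   class (root-only, leaf-only, both).
#' @param n_init_diff genes per organ class with an initial between-genotype
#'   difference but no drought response in either genotype; these model
#'   ordinary genotype divergence and challenge the priming selector's
#'   false-discovery control.
#' @param delta_init floor (log2) on planted initial between-genotype
#'   differences.
#' @param delta_drought floor (log2) on planted drought responses.
#' @param spread_init,spread_drought means of the exponential excess above
#'   the respective floors; 0 gives magnitudes exactly at the floor. The
#'   drought spread is the larger, keeping within-organ condition
#'   separation above genotype separation in the clustering.
#' @param p_tolerant_overlap probability that a primed gene also carries a
#'   drought response in the tolerant genotype (same direction), exercising
#'   the overlap bookkeeping of the priming module.
#' @param noise_sd per-observation log2 noise.
#' @param probe_offset_sd per-probe constant offset (log2).
#' @param array_offset_sd per-array additive log2 offset (multiplicative on
#'   the linear scale); removed exactly by percentile-shift normalization.
#' @param n_unmapped_probes background probes carried on the array but absent
#'   from the probe-to-gene map.
#' @param seed integer seed from which all randomness flows.
#'
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 2000L,
                       probes_per_gene = c(1L, 3L),
                       n_replicates = 3L,
                       baseline_mean = 8, baseline_sd = 2,
                       organ_effect = 3, condition_effect = 0.25,
                       genotype_effect = 0.15,
                       n_deg_per_class = 25L,
                       n_primed_high = 20L, n_primed_low = 20L,
                       n_init_diff = 100L,
                       delta_init = 1.5, delta_drought = 2,
                       spread_init = 1.25, spread_drought = 1.5,
                       p_tolerant_overlap = 0.3,
                       noise_sd = 0.5,
                       probe_offset_sd = 0.5,
                       array_offset_sd = 0.3,
                       n_unmapped_probes = 50L,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    probes_per_gene = as.integer(probes_per_gene),
    n_replicates = as.integer(n_replicates),
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    organ_effect = organ_effect, condition_effect = condition_effect,
    genotype_effect = genotype_effect,
    n_deg_per_class = as.integer(n_deg_per_class),
    n_primed_high = as.integer(n_primed_high),
    n_primed_low = as.integer(n_primed_low),
    n_init_diff = as.integer(n_init_diff),
    delta_init = delta_init, delta_drought = delta_drought,
    spread_init = spread_init, spread_drought = spread_drought,
    p_tolerant_overlap = p_tolerant_overlap,
    noise_sd = noise_sd,
    probe_offset_sd = probe_offset_sd,
    array_offset_sd = array_offset_sd,
    n_unmapped_probes = as.integer(n_unmapped_probes),
    seed = as.integer(seed)
  )
  counts <- c("n_genes", "n_replicates", "n_deg_per_class", "n_primed_high",
              "n_primed_low", "n_init_diff", "n_unmapped_probes")
  for (nm in counts) {
    if (length(cfg[[nm]]) != 1L || is.na(cfg[[nm]]) || cfg[[nm]] < 0L)
      stop("configuration error: '", nm, "' must be a single count >= 0")
  }
  if (cfg$n_replicates < 2L)
    stop("configuration error: n_replicates must be >= 2 for a testable design")
  if (length(cfg$probes_per_gene) != 2L || any(cfg$probes_per_gene < 1L) ||
      cfg$probes_per_gene[1] > cfg$probes_per_gene[2])
    stop("configuration error: probes_per_gene must be an increasing pair of counts >= 1")
  if (cfg$delta_init <= 0 || cfg$delta_drought <= 0)
    stop("configuration error: delta_init and delta_drought must be > 0")
  if (cfg$noise_sd < 0 || cfg$array_offset_sd < 0 || cfg$probe_offset_sd < 0 ||
      cfg$spread_init < 0 || cfg$spread_drought < 0)
    stop("configuration error: noise/offset/spread parameters must be >= 0")
  if (cfg$p_tolerant_overlap < 0 || cfg$p_tolerant_overlap > 1)
    stop("configuration error: p_tolerant_overlap must be in [0, 1]")
  n_planted <- 3L * 3L * 2L * cfg$n_deg_per_class +
    3L * (cfg$n_primed_high + cfg$n_primed_low) + 3L * cfg$n_init_diff
  if (n_planted > cfg$n_genes)
    stop("configuration error: planted sets (", n_planted,
         " genes) exceed n_genes (", cfg$n_genes, ")")
  structure(cfg, class = "sim_config")
}

# organ classes used for planted sets
.ORGAN_CLASSES <- c("root_only", "leaf_only", "both")

.organs_of_class <- function(oc) {
  switch(oc,
         root_only = "root",
         leaf_only = "leaf",
         both = c("leaf", "root"),
         stop("unknown organ class: ", oc))
}

# magnitude above the floor: delta + Exp(mean = spread); spread 0 => floor
.planted_magnitude <- function(n, delta, spread) {
  if (spread == 0) rep(delta, n) else delta + rexp(n, rate = 1 / spread)
}

#' Simulate an expression dataset with planted ground truth
#'
#' Generates linear-scale intensities for the full 2 x 2 x 2 x n design.
#' Each gene has a true log2 cell mean per (organ, genotype, condition);
#' all of its probes share that mean plus a per-probe constant offset and
#' independent Gaussian noise; each array carries an additive log2 offset
#' (multiplicative on the linear scale). Ground-truth labels are derived
#' from the true cell means with the same fold-change floors the pipeline
#' applies, so they can be recomputed from the stored means at any time.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_dataset` with components `raw` (linear-scale
#'   matrix, probes x samples), `samples` (sample sheet data frame),
#'   `probe_map` (probe_id, gene_id), and `truth` (see [truth_from_means()]).
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ng <- config$n_genes
  genes <- sprintf("G%05d", seq_len(ng))

  # true cell means: gene x organ x genotype x condition
  mu <- array(0, dim = c(ng, 2L, 2L, 2L),
              dimnames = list(genes, .ORGANS, .GENOTYPES, .CONDITIONS))
  baseline <- rnorm(ng, config$baseline_mean, config$baseline_sd)
  organ_coef <- rnorm(ng, 0, config$organ_effect)
  cond_coef <- rnorm(ng, 0, config$condition_effect)
  geno_coef <- rnorm(ng, 0, config$genotype_effect)
  for (o in .ORGANS) for (g in .GENOTYPES) for (cc in .CONDITIONS) {
    mu[, o, g, cc] <- baseline +
      organ_coef * (o == "root") +
      cond_coef * (cc == "drought") +
      geno_coef * (g == "sensitive")
  }

  # ---- planted effects ----------------------------------------------------
  next_gene <- 1L
  take <- function(n) {
    idx <- seq.int(next_gene, length.out = n)
    next_gene <<- next_gene + n
    idx
  }
  planted <- data.frame(gene_id = character(0), role = character(0),
                        organ_class = character(0), direction = character(0),
                        stringsAsFactors = FALSE)

  # drought DEGs by (genotype-exclusivity x organ class x direction)
  for (gc in c("tolerant_only", "sensitive_only", "shared")) {
    for (oc in .ORGAN_CLASSES) {
      for (dir in c("up", "down")) {
        n <- config$n_deg_per_class
        if (n == 0L) next
        idx <- take(n)
        s <- if (dir == "up") 1 else -1
        for (o in .organs_of_class(oc)) {
          if (gc %in% c("tolerant_only", "shared")) {
            d <- .planted_magnitude(n, config$delta_drought, config$spread_drought)
            mu[idx, o, "tolerant", "drought"] <-
              mu[idx, o, "tolerant", "drought"] + s * d
          }
          if (gc %in% c("sensitive_only", "shared")) {
            d <- .planted_magnitude(n, config$delta_drought, config$spread_drought)
            mu[idx, o, "sensitive", "drought"] <-
              mu[idx, o, "sensitive", "drought"] + s * d
          }
        }
        planted <- rbind(planted, data.frame(
          gene_id = genes[idx], role = paste0("deg_", gc),
          organ_class = oc, direction = dir, stringsAsFactors = FALSE))
      }
    }
  }

  # priming candidates: tolerant holds the "stressed-like" level already in
  # control; the sensitive genotype reaches it only under drought
  for (oc in .ORGAN_CLASSES) {
    for (lbl in c("primed_high", "primed_low")) {
      n <- if (lbl == "primed_high") config$n_primed_high else config$n_primed_low
      if (n == 0L) next
      idx <- take(n)
      s <- if (lbl == "primed_high") 1 else -1
      for (o in .organs_of_class(oc)) {
        d_init <- .planted_magnitude(n, config$delta_init, config$spread_init)
        d_dr <- .planted_magnitude(n, config$delta_drought, config$spread_drought)
        # genotype-level offset in this organ (both conditions)
        mu[idx, o, "tolerant", ] <- mu[idx, o, "tolerant", ] + s * d_init
        mu[idx, o, "sensitive", "drought"] <-
          mu[idx, o, "sensitive", "drought"] + s * d_dr
        overlap <- runif(n) < config$p_tolerant_overlap
        if (any(overlap)) {
          d_tol <- .planted_magnitude(sum(overlap), config$delta_drought,
                                      config$spread_drought)
          mu[idx[overlap], o, "tolerant", "drought"] <-
            mu[idx[overlap], o, "tolerant", "drought"] + s * d_tol
        }
      }
      planted <- rbind(planted, data.frame(
        gene_id = genes[idx], role = lbl, organ_class = oc,
        direction = if (lbl == "primed_high") "up" else "down",
        stringsAsFactors = FALSE))
    }
  }

  # plain initial genotype differences, no drought response
  for (oc in .ORGAN_CLASSES) {
    n <- config$n_init_diff
    if (n == 0L) next
    idx <- take(n)
    s <- ifelse(runif(n) < 0.5, 1, -1)
    for (o in .organs_of_class(oc)) {
      d_init <- .planted_magnitude(n, config$delta_init, config$spread_init)
      mu[idx, o, "tolerant", ] <- mu[idx, o, "tolerant", ] + s * d_init
    }
    planted <- rbind(planted, data.frame(
      gene_id = genes[idx], role = "init_diff", organ_class = oc,
      direction = ifelse(s > 0, "up", "down"), stringsAsFactors = FALSE))
  }

  # ---- probes and samples -------------------------------------------------
  k <- sample(seq.int(config$probes_per_gene[1], config$probes_per_gene[2]),
              ng, replace = TRUE)
  probe_gene <- rep(seq_len(ng), k)
  probe_ids <- unlist(lapply(seq_len(ng), function(i)
    paste0(genes[i], "_p", seq_len(k[i]))), use.names = FALSE)
  n_mapped <- length(probe_ids)
  if (config$n_unmapped_probes > 0L) {
    probe_ids <- c(probe_ids,
                   sprintf("CTRL_p%03d", seq_len(config$n_unmapped_probes)))
  }
  np <- length(probe_ids)
  probe_map <- data.frame(probe_id = probe_ids[seq_len(n_mapped)],
                          gene_id = genes[probe_gene],
                          stringsAsFactors = FALSE)

  grid <- expand.grid(replicate = seq_len(config$n_replicates),
                      condition = .CONDITIONS, genotype = .GENOTYPES,
                      organ = .ORGANS,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = paste(grid$organ, grid$genotype, grid$condition,
                      paste0("r", grid$replicate), sep = "_"),
    organ = grid$organ, genotype = grid$genotype,
    condition = grid$condition, replicate = grid$replicate,
    stringsAsFactors = FALSE)
  ns <- nrow(samples)

  probe_offset <- rnorm(np, 0, config$probe_offset_sd)
  array_offset <- rnorm(ns, 0, config$array_offset_sd)

  log2_vals <- matrix(0, np, ns, dimnames = list(probe_ids, samples$sample_id))
  unmapped_base <- if (np > n_mapped)
    rnorm(np - n_mapped, config$baseline_mean, config$baseline_sd) else numeric(0)
  for (j in seq_len(ns)) {
    sig <- mu[cbind(probe_gene,
                    match(samples$organ[j], .ORGANS),
                    match(samples$genotype[j], .GENOTYPES),
                    match(samples$condition[j], .CONDITIONS))]
    col <- c(sig, unmapped_base) + probe_offset + array_offset[j]
    if (config$noise_sd > 0)
      col <- col + rnorm(np, 0, config$noise_sd)
    log2_vals[, j] <- col
  }

  truth <- truth_from_means(mu)
  truth$means <- mu
  truth$planted <- planted
  truth$config <- config

  structure(list(raw = 2^log2_vals, samples = samples,
                 probe_map = probe_map, truth = truth),
            class = "sim_dataset")
}

#' Derive ground-truth labels from true cell means
#'
#' Labels are a pure function of the true log2 cell means and the fold-change
#' floors, so the stored labels of a simulated dataset can always be
#' reproduced by recomputation: a gene is a true drought DEG in a genotype if
#' its true |drought - control| log2 difference is at least `log2(tau_drought)`;
#' it is a true priming candidate if additionally the true initial
#' between-genotype difference reaches `log2(tau_init)` with the matching
#' sign (tolerant-higher with sensitive drought-up, or the mirror).
#'
#' @param means gene x organ x genotype x condition array of true log2 means.
#' @param tau_drought,tau_init linear fold-change floors used for labelling.
#' @return list with `labels`, a data frame with one row per (gene, organ).
#' @export
truth_from_means <- function(means, tau_drought = 3, tau_init = 2) {
  genes <- dimnames(means)[[1]]
  out <- list()
  for (o in .ORGANS) {
    d_tol <- means[, o, "tolerant", "drought"] - means[, o, "tolerant", "control"]
    d_sen <- means[, o, "sensitive", "drought"] - means[, o, "sensitive", "control"]
    d_init <- means[, o, "tolerant", "control"] - means[, o, "sensitive", "control"]
    tol_deg <- abs(d_tol) >= log2(tau_drought)
    sen_deg <- abs(d_sen) >= log2(tau_drought)
    deg_class <- ifelse(tol_deg & sen_deg, "shared",
                 ifelse(tol_deg, "tolerant_only",
                 ifelse(sen_deg, "sensitive_only", "none")))
    primed <- ifelse(d_init >= log2(tau_init) & d_sen >= log2(tau_drought),
                     "primed_high",
              ifelse(-d_init >= log2(tau_init) & -d_sen >= log2(tau_drought),
                     "primed_low", "none"))
    out[[o]] <- data.frame(
      gene_id = genes, organ = o,
      tolerant_deg = tol_deg,
      tolerant_direction = ifelse(d_tol >= 0, "up", "down"),
      sensitive_deg = sen_deg,
      sensitive_direction = ifelse(d_sen >= 0, "up", "down"),
      deg_class = deg_class,
      initial_delta = d_init,
      primed_label = primed,
      stringsAsFactors = FALSE)
  }
  list(labels = do.call(rbind, c(out, list(make.row.names = FALSE))))
}

#' Simulate GO annotations and a small ontology for a planted truth
#'
#' Background genes receive random direct annotations; for each designated
#' "enriched" term, genes of the planted target set are annotated at
#' `enrichment_factor` times the background rate (capped at 1). A small
#' is_a ontology is emitted: terms are arranged under a single root, with a
#' fraction given a second parent so the graph is a DAG rather than a tree.
#' `enrichment_factor = 1` yields a null annotation set.
#'
#' @param truth truth component of a [simulate_dataset()] result (or any list
#'   with a `labels` data frame).
#' @param target_genes character vector of genes the enriched terms favour;
#'   defaults to the primed genes of `truth`.
#' @param n_terms number of leaf terms.
#' @param n_enriched how many terms are planted-enriched.
#' @param enrichment_factor rate multiplier (>= 1) for target-set annotation.
#' @param base_rate background probability that a gene carries a given term.
#' @param seed integer seed.
#' @return list with `annotations` (named list gene -> character vector of
#'   direct term ids), `dag` (a `go_dag`, see [go_dag()]), and
#'   `enriched_terms` (ids of the planted-enriched terms).
#' @export
simulate_go_annotations <- function(truth, target_genes = NULL,
                                    n_terms = 40L, n_enriched = 5L,
                                    enrichment_factor = 5,
                                    base_rate = 0.05, seed = 1L) {
  if (n_terms < 1L) stop("configuration error: n_terms must be >= 1")
  if (enrichment_factor < 1) stop("configuration error: enrichment_factor must be >= 1")
  if (n_enriched > n_terms) stop("configuration error: n_enriched > n_terms")
  set.seed(seed)
  genes <- unique(truth$labels$gene_id)
  if (is.null(target_genes))
    target_genes <- unique(truth$labels$gene_id[truth$labels$primed_label != "none"])

  terms <- sprintf("TERM:%04d", seq_len(n_terms))
  root <- "TERM:0000"
  # single-root is_a hierarchy; ~25% of non-first terms get a second parent
  parents <- lapply(seq_len(n_terms), function(i) {
    p <- if (i == 1L) root else terms[sample.int(i - 1L, 1L)]
    if (i > 2L && runif(1) < 0.25) {
      q <- terms[sample.int(i - 1L, 1L)]
      unique(c(p, q))
    } else p
  })
  names(parents) <- terms
  dag <- go_dag(
    terms = data.frame(id = c(root, terms),
                       name = c("root", paste("simulated term", seq_len(n_terms))),
                       namespace = "biological_process",
                       stringsAsFactors = FALSE),
    parents = c(setNames(list(character(0)), root), parents))

  is_target <- genes %in% target_genes
  enriched <- sample(terms, n_enriched)
  ann <- vector("list", length(genes))
  names(ann) <- genes
  for (tm in terms) {
    rate_bg <- base_rate
    rate_tg <- if (tm %in% enriched) min(1, base_rate * enrichment_factor) else base_rate
    hit <- runif(length(genes)) < ifelse(is_target, rate_tg, rate_bg)
    for (g in which(hit)) ann[[g]] <- c(ann[[g]], tm)
  }
  ann <- ann[vapply(ann, length, 1L) > 0L]
  list(annotations = ann, dag = dag,
       enriched_terms = if (enrichment_factor > 1) enriched else character(0))
}

#' Simulate a qPCR plate concordant with the planted expression truth
#'
#' Ct values follow `Ct = intercept - log_E(expression) + noise` with a
#' per-amplicon efficiency drawn uniformly from `e_range`; the designated
#' reference amplicon is generated condition-invariant. Optionally emits raw
#' amplification curves `F(c) = F0 * E^c` with a saturating plateau for
#' efficiency-estimation tests.
#'
#' @param truth truth component of a [simulate_dataset()] result (must carry
#'   `means`).
#' @param genes target genes to assay (must exist in the truth).
#' @param organ,genotype design cell pair assayed: drought vs control within
#'   this genotype and organ.
#' @param reference_id amplicon id used as the reference; generated with
#'   constant expression and must not name a target gene.
#' @param n_replicates wells per (amplicon, condition).
#' @param e_range range of true amplification efficiencies.
#' @param ct_noise_sd Gaussian noise on Ct values.
#' @param intercept Ct of an amplicon with log2 expression 0.
#' @param curves if TRUE, also return per-well amplification curves.
#' @param seed integer seed.
#' @return list with `plate` (well-level data frame: well, amplicon, organ,
#'   genotype, condition, replicate, ct), `efficiencies` (amplicon, E), and
#'   optionally `curves` (long data frame: well, amplicon, cycle,
#'   fluorescence).
#' @export
simulate_qpcr <- function(truth, genes, organ = "root", genotype = "sensitive",
                          reference_id = "REF", n_replicates = 3L,
                          e_range = c(1.8, 2.0), ct_noise_sd = 0.15,
                          intercept = 38, curves = FALSE, seed = 1L) {
  stopifnot(!is.null(truth$means))
  missing <- setdiff(genes, dimnames(truth$means)[[1]])
  if (length(missing))
    stop("genes not present in truth: ", paste(head(missing, 5), collapse = ", "))
  if (reference_id %in% genes)
    stop("configuration error: reference amplicon must not be in the varying set")
  set.seed(seed)
  amplicons <- c(genes, reference_id)
  E <- runif(length(amplicons), e_range[1], e_range[2])
  names(E) <- amplicons
  ref_level <- truth$config$baseline_mean %||% 8

  rows <- list(); crv <- list(); well <- 0L
  for (a in amplicons) {
    for (cond in .CONDITIONS) {
      expr_log2 <- if (a == reference_id) ref_level else
        truth$means[a, organ, genotype, cond]
      for (r in seq_len(n_replicates)) {
        well <- well + 1L
        ct <- intercept - expr_log2 * log(2) / log(E[a])
        if (ct_noise_sd > 0) ct <- ct + rnorm(1, 0, ct_noise_sd)
        wid <- sprintf("W%04d", well)
        rows[[well]] <- data.frame(
          well = wid, amplicon = a, organ = organ, genotype = genotype,
          condition = cond, replicate = r, ct = ct, stringsAsFactors = FALSE)
        if (curves) {
          cyc <- seq_len(40L)
          f0 <- 10^(-ct * log10(E[a]))  # so F crosses 1 at cycle ct
          f <- f0 * E[a]^cyc
          f <- f / (1 + f / 50)  # saturating plateau
          crv[[well]] <- data.frame(well = wid, amplicon = a, cycle = cyc,
                                    fluorescence = f, stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- list(plate = do.call(rbind, rows),
              efficiencies = data.frame(amplicon = amplicons, E = unname(E),
                                        stringsAsFactors = FALSE),
              reference_id = reference_id)
  if (curves) out$curves <- do.call(rbind, crv)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
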