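#' Specify a contrast for the two-factor model
#'
#' Two kinds of contrast are supported, matching the comparisons the design
#' reports: the drought-vs-control difference within one genotype
#' (`"drought_vs_control"`, fold-change floor 3 by default) and the
#' tolerant-vs-sensitive difference within control conditions
#' (`"tolerant_vs_sensitive_control"`, floor 2 by default, used to find
#' initial expression differences).
#'
#' @param organ `"leaf"` or `"root"`.
#' @param kind contrast kind (see Description).
#' @param genotype genotype for `drought_vs_control` contrasts.
#' @param fc_threshold linear fold-change floor (>= 1); defaults to 3 for
#'   drought contrasts and 2 for the initial contrast.
#' @param q_threshold BH-adjusted significance level, default 0.05.
#' @return object of class `contrast_spec`.
#' @export
contrast_spec <- function(organ,
                          kind = c("drought_vs_control",
                                   "tolerant_vs_sensitive_control"),
                          genotype = NULL,
                          fc_threshold = NULL,
                          q_threshold = 0.05) {
  kind <- match.arg(kind)
  organ <- match.arg(organ, .ORGANS)
  if (kind == "drought_vs_control") {
    genotype <- match.arg(genotype, .GENOTYPES)
    if (is.null(fc_threshold)) fc_threshold <- 3
  } else {
    if (is.null(fc_threshold)) fc_threshold <- 2
  }
  if (fc_threshold < 1) stop("fc_threshold must be >= 1")
  if (q_threshold <= 0 || q_threshold >= 1) stop("q_threshold must be in (0, 1)")
  structure(list(organ = organ, kind = kind, genotype = genotype,
                 fc_threshold = fc_threshold, q_threshold = q_threshold),
            class = "contrast_spec")
}

#' Fit per-probe cell means for the 2 x 2 design within one organ
#'
#' For each probe, the four (genotype x condition) cell means are the
#' arithmetic means of the log2 values, and the error variance is the
#' within-cell variance pooled across the four cells with
#' `df = N_organ - 4`. Every cell must hold at least two replicates.
#'
#' @param mat normalized log2 matrix (probes x samples).
#' @param samples sample sheet data frame with columns `sample_id`, `organ`,
#'   `genotype`, `condition` covering the columns of `mat`.
#' @param organ organ whose samples are fitted.
#' @return object of class `cellmeans_fit`: list with `means` (probes x 4
#'   matrix, columns `<genotype>.<condition>`), `mse`, `df`, `n_per_cell`,
#'   and `organ`.
#' @export
fit_cell_means <- function(mat, samples, organ) {
  organ <- match.arg(organ, .ORGANS)
  miss <- setdiff(colnames(mat), samples$sample_id)
  if (length(miss))
    stop("sample sheet does not describe matrix column(s): ",
         paste(head(miss, 5), collapse = ", "))
  samples <- samples[match(colnames(mat), samples$sample_id), ]
  sel <- samples$organ == organ
  if (!any(sel)) stop("no samples for organ '", organ, "'")
  sub <- mat[, sel, drop = FALSE]
  cell <- paste(samples$genotype[sel], samples$condition[sel], sep = ".")
  cells <- as.vector(outer(.GENOTYPES, .CONDITIONS, paste, sep = "."))
  n_per_cell <- as.integer(table(factor(cell, levels = cells)))
  names(n_per_cell) <- cells
  if (any(n_per_cell < 2L))
    stop("design error: cell(s) with < 2 replicates in organ '", organ, "': ",
         paste(cells[n_per_cell < 2L], collapse = ", "))

  f <- factor(cell, levels = cells)
  idx <- split(seq_len(ncol(sub)), f)
  means <- vapply(idx, function(j) rowMeans(sub[, j, drop = FALSE]),
                  numeric(nrow(sub)))
  if (nrow(sub) == 1L) means <- matrix(means, nrow = 1L,
                                       dimnames = list(rownames(sub), cells))
  ss <- 0
  for (cn in cells) {
    j <- idx[[cn]]
    ss <- ss + rowSums((sub[, j, drop = FALSE] - means[, cn])^2)
  }
  df <- ncol(sub) - 4L
  structure(list(means = means, mse = ss / df, df = df,
                 n_per_cell = n_per_cell, organ = organ,
                 probe_ids = rownames(sub)),
            class = "cellmeans_fit")
}

#' Test a contrast on a cell-means fit
#'
#' The contrast estimate `delta` is the difference of the two relevant cell
#' means; its t statistic uses the pooled error variance,
#' `t = delta / sqrt(MSE (1/n1 + 1/n2))`, with a two-sided p value on the
#' pooled degrees of freedom. Probes with `MSE = 0` take the degenerate
#' rule `p = 1` if `delta = 0` and `p = 0` otherwise, so noiseless fixtures
#' remain testable. BH-adjusted q values are computed across all probes of
#' the contrast with [bh_adjust()].
#'
#' @param fit a [fit_cell_means()] result.
#' @param spec a [contrast_spec()] for the same organ.
#' @return data frame (one row per probe): `probe_id`, `delta` (mean log2
#'   difference), `FC` (`2^|delta|`), `direction` (`"up"`/`"down"` by the
#'   sign of `delta`), `p`, `q`.
#' @export
contrast_test <- function(fit, spec) {
  stopifnot(inherits(fit, "cellmeans_fit"), inherits(spec, "contrast_spec"))
  if (fit$organ != spec$organ)
    stop("fit is for organ '", fit$organ, "' but spec is for '", spec$organ, "'")
  if (spec$kind == "drought_vs_control") {
    a <- paste(spec$genotype, "drought", sep = ".")
    b <- paste(spec$genotype, "control", sep = ".")
  } else if (spec$kind == "tolerant_vs_sensitive_control") {
    a <- "tolerant.control"
    b <- "sensitive.control"
  } else stop("unknown contrast kind: ", spec$kind)

  delta <- fit$means[, a] - fit$means[, b]
  n1 <- fit$n_per_cell[[a]]; n2 <- fit$n_per_cell[[b]]
  se <- sqrt(fit$mse * (1 / n1 + 1 / n2))
  p <- numeric(length(delta))
  pos <- se > 0
  p[pos] <- 2 * pt(abs(delta[pos]) / se[pos], fit$df, lower.tail = FALSE)
  p[!pos] <- ifelse(delta[!pos] == 0, 1, 0)
  data.frame(probe_id = fit$probe_ids, delta = unname(delta),
             FC = 2^abs(unname(delta)),
             direction = ifelse(delta >= 0, "up", "down"),
             p = unname(p), q = bh_adjust(unname(p)),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validated wrapper over `p.adjust(method = "BH")`:
#' `q_i = min over j with p_(j) >= p_(i) of min(1, m p_(j) / j)`.
#' Order-preserving, values in `[0, 1]`.
#'
#' @param p vector of raw p values in `[0, 1]`.
#' @return vector of adjusted q values in the input order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p values must lie in [0, 1] with no missing values")
  p.adjust(p, method = "BH")
}

#' Call probe-level differential expression
#'
#' A probe passes iff `q <= q_threshold` and `FC >= fc_threshold`; both
#' boundaries are inclusive.
#'
#' @param stats a [contrast_test()] result.
#' @param spec the matching [contrast_spec()].
#' @return `stats` with a logical `pass` column.
#' @export
call_probe_degs <- function(stats, spec) {
  stopifnot(inherits(spec, "contrast_spec"),
            all(c("q", "FC") %in% names(stats)))
  stats$pass <- stats$q <= spec$q_threshold & stats$FC >= spec$fc_threshold
  stats
}

#' Collapse probe-level calls to gene level
#'
#' A gene passes in a direction iff at least one mapped probe passes in that
#' direction. Genes with probes passing in both directions receive a
#' `conflict` flag and count in both direction tallies. The representative
#' probe is the passing probe with the smallest q (smallest q overall for
#' non-passing genes); its `delta`, `FC`, `p` and `q` are reported at gene
#' level. Probes absent from the map are ignored for gene calls; those that
#' pass are returned in `attr(, "unmapped_passing")`.
#'
#' @param stats a [call_probe_degs()] result (probe level, with `pass`).
#' @param probe_map data frame `probe_id`, `gene_id`; a probe may map to at
#'   most one gene (one-to-many gene-to-probe is the allowed direction).
#' @return data frame, one row per gene with at least one mapped probe:
#'   `gene_id`, `probe_id` (representative), `delta`, `FC`, `p`, `q`,
#'   `pass_up`, `pass_down`, `pass`, `direction`, `conflict`, `n_probes`.
#' @export
collapse_probes_to_genes <- function(stats, probe_map) {
  stopifnot(all(c("probe_id", "gene_id") %in% names(probe_map)),
            all(c("probe_id", "pass", "direction", "q") %in% names(stats)))
  dup <- unique(probe_map$probe_id[duplicated(probe_map$probe_id)])
  if (length(dup))
    stop("mapping error: probe(s) mapped to more than one gene: ",
         paste(head(dup, 5), collapse = ", "))
  m <- match(stats$probe_id, probe_map$probe_id)
  unmapped_passing <- stats$probe_id[is.na(m) & stats$pass]
  mapped <- stats[!is.na(m), , drop = FALSE]
  mapped$gene_id <- probe_map$gene_id[m[!is.na(m)]]

  split_idx <- split(seq_len(nrow(mapped)), mapped$gene_id)
  rows <- lapply(split_idx, function(i) {
    g <- mapped[i, , drop = FALSE]
    pass_up <- any(g$pass & g$direction == "up")
    pass_down <- any(g$pass & g$direction == "down")
    cand <- if (any(g$pass)) g[g$pass, , drop = FALSE] else g
    rep <- cand[which.min(cand$q), , drop = FALSE]
    data.frame(gene_id = g$gene_id[1], probe_id = rep$probe_id,
               delta = rep$delta, FC = rep$FC, p = rep$p, q = rep$q,
               pass_up = pass_up, pass_down = pass_down,
               pass = pass_up || pass_down,
               direction = if (pass_up && !pass_down) "up"
                           else if (pass_down && !pass_up) "down"
                           else if (pass_up && pass_down) "conflict"
                           else rep$direction,
               conflict = pass_up && pass_down,
               n_probes = nrow(g), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unmapped_passing") <- unmapped_passing
  out
}

#' Run one contrast end to end at gene level
#'
#' Chains [fit_cell_means()], [contrast_test()], [call_probe_degs()] and
#' [collapse_probes_to_genes()].
#'
#' @inheritParams fit_cell_means
#' @inheritParams collapse_probes_to_genes
#' @param spec a [contrast_spec()].
#' @return gene-level data frame as from [collapse_probes_to_genes()].
#' @export
gene_contrast <- function(mat, samples, spec, probe_map) {
  fit <- fit_cell_means(mat, samples, spec$organ)
  st <- call_probe_degs(contrast_test(fit, spec), spec)
  collapse_probes_to_genes(st, probe_map)
}
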