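#' Genes with an initial between-genotype expression difference
#'
#' Filters the gene-level tolerant-vs-sensitive control contrast at a
#' lowered stringency (fold change >= `tau_init`, BH q <= `alpha`), on the
#' premise that even modest constitutive differences may prime the tolerant
#' genotype for a faster stress response. The sign records which genotype
#' sits higher: `"tolerant_higher"` for positive contrast deltas
#' (tolerant minus sensitive), `"tolerant_lower"` otherwise.
#'
#' @param control_contrast gene-level table from [gene_contrast()] run with
#'   a `tolerant_vs_sensitive_control` spec; the spec used must be attached
#'   via the `spec` argument for a kind check.
#' @param spec the [contrast_spec()] the table was produced with; must be of
#'   kind `tolerant_vs_sensitive_control`.
#' @param tau_init fold-change floor, default 2.
#' @param alpha BH significance level, default 0.05.
#' @return data frame `gene_id`, `sign`, `initial_FC`, `initial_q`,
#'   `conflict`; conflict-flagged genes are retained here and filtered at
#'   selection time.
#' @export
initial_difference_genes <- function(control_contrast, spec = NULL,
                                     tau_init = 2, alpha = 0.05) {
  if (!is.null(spec)) {
    stopifnot(inherits(spec, "contrast_spec"))
    if (spec$kind != "tolerant_vs_sensitive_control")
      stop("wrong contrast kind: expected tolerant_vs_sensitive_control, got ",
           spec$kind)
  }
  x <- control_contrast
  keep <- x$pass & x$FC >= tau_init & x$q <= alpha
  x <- x[keep, , drop = FALSE]
  data.frame(gene_id = x$gene_id,
             sign = ifelse(x$direction == "conflict", "conflict",
                           ifelse(x$direction == "up",
                                  "tolerant_higher", "tolerant_lower")),
             initial_FC = x$FC, initial_q = x$q,
             conflict = x$conflict, stringsAsFactors = FALSE)
}

#' Select priming candidates for one organ
#'
#' The "stressed-like readiness" rule: a gene is emitted iff (a) it shows an
#' initial between-genotype difference under control conditions, (b) it
#' passes the sensitive genotype's drought contrast, and (c) the directions
#' agree — the sensitive genotype moves under drought toward the level the
#' tolerant genotype already holds. Tolerant-higher with sensitive
#' drought-up gives `primed_high`; tolerant-lower with sensitive
#' drought-down gives `primed_low`. Membership in the tolerant genotype's
#' drought DEG list is recorded as `tolerant_drought_overlap` but never used
#' to exclude a gene. Genes with probe-level direction conflicts in either
#' contrast are excluded by default.
#'
#' @param initial output of [initial_difference_genes()] for this organ.
#' @param sensitive_drought,tolerant_drought gene-level tables from
#'   [gene_contrast()] for the organ's drought contrasts.
#' @param organ organ label carried into the calls.
#' @param include_conflicts if TRUE, direction-conflicted genes are eligible
#'   (their sensitive direction is then taken from the representative
#'   probe).
#' @return data frame of class `priming_calls`: `gene_id`, `organ`,
#'   `priming_direction`, `initial_FC`, `initial_q`, `sensitive_drought_FC`,
#'   `sensitive_drought_q`, `tolerant_drought_overlap`.
#' @export
select_primed <- function(initial, sensitive_drought, tolerant_drought,
                          organ, include_conflicts = FALSE) {
  organ <- match.arg(organ, .ORGANS)
  sen <- sensitive_drought[sensitive_drought$pass, , drop = FALSE]
  tol_set <- tolerant_drought$gene_id[tolerant_drought$pass]
  if (!include_conflicts) {
    initial <- initial[initial$sign != "conflict", , drop = FALSE]
    sen <- sen[!sen$conflict, , drop = FALSE]
  }
  m <- match(initial$gene_id, sen$gene_id)
  hit <- !is.na(m)
  init <- initial[hit, , drop = FALSE]
  sen <- sen[m[hit], , drop = FALSE]
  consistent <-
    (init$sign == "tolerant_higher" & sen$direction == "up") |
    (init$sign == "tolerant_lower" & sen$direction == "down")
  init <- init[consistent, , drop = FALSE]
  sen <- sen[consistent, , drop = FALSE]
  out <- data.frame(
    gene_id = init$gene_id, organ = rep(organ, nrow(init)),
    priming_direction = ifelse(init$sign == "tolerant_higher",
                               "primed_high", "primed_low"),
    initial_FC = init$initial_FC, initial_q = init$initial_q,
    sensitive_drought_FC = sen$FC, sensitive_drought_q = sen$q,
    tolerant_drought_overlap = init$gene_id %in% tol_set,
    stringsAsFactors = FALSE)
  # per-call direction invariant, asserted on every run
  stopifnot(all((out$priming_direction == "primed_high") ==
                  (init$sign == "tolerant_higher" & sen$direction == "up")))
  class(out) <- c("priming_calls", class(out))
  out
}

#' Classify priming calls by organ exclusivity
#'
#' Two-set partition on gene id across the two organs' call lists. A gene
#' called in both organs is `"both"` regardless of direction; calls whose
#' directions differ between organs are flagged discordant.
#'
#' @param root_calls,leaf_calls [select_primed()] results for each organ.
#' @return the two call tables row-bound, with `organ_class` in
#'   `root_only` / `leaf_only` / `both` and a logical `discordant` column.
#' @export
classify_priming_by_organ <- function(root_calls, leaf_calls) {
  all_calls <- rbind(as.data.frame(root_calls), as.data.frame(leaf_calls))
  if (nrow(all_calls) == 0L) {
    all_calls$organ_class <- character(0)
    all_calls$discordant <- logical(0)
    return(all_calls)
  }
  in_root <- all_calls$gene_id %in% root_calls$gene_id
  in_leaf <- all_calls$gene_id %in% leaf_calls$gene_id
  all_calls$organ_class <- ifelse(in_root & in_leaf, "both",
                                  ifelse(in_root, "root_only", "leaf_only"))
  dirs <- tapply(all_calls$priming_direction, all_calls$gene_id,
                 function(d) length(unique(d)))
  all_calls$discordant <- dirs[all_calls$gene_id] > 1L
  rownames(all_calls) <- NULL
  all_calls
}

#' Overlap of priming candidates with the tolerant genotype's drought DEGs
#'
#' Per organ class, counts how many candidates were also differentially
#' expressed under drought in the tolerant genotype, in the matching organ.
#' A recorded overlap never disqualifies a candidate.
#'
#' @param calls classified calls from [classify_priming_by_organ()].
#' @param tolerant_deg_root,tolerant_deg_leaf character vectors of the
#'   tolerant genotype's drought DEGs per organ.
#' @return data frame `organ_class`, `n_calls` (distinct genes),
#'   `n_overlap`.
#' @export
overlap_with_tolerant_degs <- function(calls, tolerant_deg_root,
                                       tolerant_deg_leaf) {
  classes <- c("root_only", "leaf_only", "both")
  rows <- lapply(classes, function(cl) {
    sub <- calls[calls$organ_class == cl, , drop = FALSE]
    genes <- unique(sub$gene_id)
    tol <- if (cl == "root_only") tolerant_deg_root
           else if (cl == "leaf_only") tolerant_deg_leaf
           else union(tolerant_deg_root, tolerant_deg_leaf)
    data.frame(organ_class = cl, n_calls = length(genes),
               n_overlap = sum(genes %in% tol), stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
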