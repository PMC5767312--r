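#' Estimate amplification efficiency from a raw qPCR curve
#'
#' Window-of-linearity approach: the mean fluorescence of cycles 1-5 is
#' subtracted as a fixed baseline; log10 of the positive baseline-corrected
#' signal is regressed on cycle number over every contiguous window of
#' `window` cycles, and the window with the highest R-squared gives the
#' slope `s`, with `E = 10^s`. Values are clamped to (1, 2.5] with a warning
#' outside (1, 2.1].
#'
#' @param cycle integer cycle indices (>= 10 cycles).
#' @param fluorescence fluorescence readings, same length, finite.
#' @param window window size in cycles (4-6 typical).
#' @return list with `E`, `r_squared`, `window` (cycle indices used).
#' @export
estimate_efficiency <- function(cycle, fluorescence, window = 5L) {
  if (length(cycle) != length(fluorescence) || length(cycle) < 10L)
    stop("curve needs >= 10 (cycle, fluorescence) pairs")
  if (any(!is.finite(fluorescence))) stop("non-finite fluorescence")
  if (window < 3L) stop("window must be >= 3 cycles")
  ord <- order(cycle)
  cycle <- cycle[ord]; fluorescence <- fluorescence[ord]
  baseline <- mean(fluorescence[cycle <= 5])
  y <- fluorescence - baseline
  ok <- y > 0
  best <- NULL
  for (s in seq_len(length(cycle) - window + 1L)) {
    idx <- s:(s + window - 1L)
    if (!all(ok[idx]) || any(diff(y[idx]) <= 0)) next
    fit <- lm(log10(y[idx]) ~ cycle[idx])
    r2 <- summary(fit)$r.squared
    if (is.null(best) || r2 > best$r_squared)
      best <- list(E = 10^coef(fit)[[2]], r_squared = r2,
                   window = cycle[idx])
  }
  if (is.null(best))
    stop("estimation error: no qualifying exponential window in the curve")
  if (best$E <= 1 || best$E > 2.5)
    stop("estimation error: slope implies efficiency ", round(best$E, 3),
         " outside (1, 2.5]")
  if (best$E > 2.1)
    warning("estimated efficiency ", round(best$E, 3), " outside (1, 2.1]")
  best
}

#' Per-amplicon efficiencies from a set of curves
#'
#' Runs [estimate_efficiency()] per well and averages the estimates that
#' reach `min_r2` per amplicon.
#'
#' @param curves long data frame: `well`, `amplicon`, `cycle`,
#'   `fluorescence`.
#' @param window window size passed through.
#' @param min_r2 minimum per-well R-squared for inclusion, default 0.99.
#' @return data frame `amplicon`, `E`, `n_wells`.
#' @export
amplicon_efficiencies <- function(curves, window = 5L, min_r2 = 0.99) {
  per_well <- lapply(split(curves, curves$well), function(w) {
    est <- tryCatch(estimate_efficiency(w$cycle, w$fluorescence, window),
                    error = function(e) NULL)
    if (is.null(est)) return(NULL)
    data.frame(amplicon = w$amplicon[1], E = est$E,
               r_squared = est$r_squared, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, per_well)
  tab <- tab[tab$r_squared >= min_r2, , drop = FALSE]
  if (is.null(tab) || nrow(tab) == 0L)
    stop("estimation error: no well passed the R-squared filter")
  agg <- lapply(split(tab, tab$amplicon), function(a)
    data.frame(amplicon = a$amplicon[1], E = mean(a$E), n_wells = nrow(a),
               stringsAsFactors = FALSE))
  out <- do.call(rbind, c(agg, list(make.row.names = FALSE)))
  rownames(out) <- NULL
  out
}

#' Efficiency-corrected relative expression ratio
#'
#' `R = E_target^dCt_target / E_ref^dCt_ref`, where each `dCt` is
#' `mean Ct(control) - mean Ct(treated)` for that amplicon. With both
#' efficiencies equal to 2 this reduces to the classical `2^ddCt`.
#'
#' @param e_target,e_ref amplification efficiencies in (1, 2.5].
#' @param dct_target,dct_ref Ct differences (control minus treated).
#' @return the linear ratio `R > 0`.
#' @export
pfaffl_ratio <- function(e_target, dct_target, e_ref, dct_ref) {
  for (e in c(e_target, e_ref))
    if (!is.finite(e) || e <= 1 || e > 2.5)
      stop("efficiency must lie in (1, 2.5], got ", e)
  e_target^dct_target / e_ref^dct_ref
}

#' Randomization test for a relative expression ratio
#'
#' Fixed-reallocation test: the observed ratio comes from [pfaffl_ratio()]
#' on group mean Cts; condition labels of the paired (target, reference)
#' observations are then reallocated without replacement and the ratio
#' recomputed. Two-sided significance is judged on |log R|. When the number
#' of distinct reallocations is at most `max_exhaustive`, all are
#' enumerated and `p` is the exact fraction at least as extreme (the
#' identity reallocation included); otherwise `n_perm` random reallocations
#' are drawn and `p = (1 + #extreme) / (1 + n_perm)`.
#'
#' @param ct_target_control,ct_target_treated target-amplicon Cts per group
#'   (>= 2 each).
#' @param ct_ref_control,ct_ref_treated reference-amplicon Cts, paired with
#'   the target observations.
#' @param e_target,e_ref amplification efficiencies.
#' @param n_perm random reallocations when not exhaustive, default 2000.
#' @param max_exhaustive enumeration threshold, default 10000.
#' @param seed integer seed for the sampled mode.
#' @return list with `ratio`, `p`, `n_permutations`, `exhaustive`, `seed`.
#' @export
randomization_test <- function(ct_target_control, ct_target_treated,
                               ct_ref_control, ct_ref_treated,
                               e_target = 2, e_ref = 2,
                               n_perm = 2000L, max_exhaustive = 10000L,
                               seed = 1L) {
  n1 <- length(ct_target_control); n2 <- length(ct_target_treated)
  if (n1 < 2L || n2 < 2L) stop("each group needs >= 2 observations")
  if (length(ct_ref_control) != n1 || length(ct_ref_treated) != n2)
    stop("reference Cts must pair with target Cts")
  if (n_perm < 1L) stop("n_perm must be >= 1")
  tgt <- c(ct_target_control, ct_target_treated)
  ref <- c(ct_ref_control, ct_ref_treated)
  ratio_for <- function(ctrl_idx) {
    trt_idx <- setdiff(seq_len(n1 + n2), ctrl_idx)
    pfaffl_ratio(e_target, mean(tgt[ctrl_idx]) - mean(tgt[trt_idx]),
                 e_ref, mean(ref[ctrl_idx]) - mean(ref[trt_idx]))
  }
  obs <- ratio_for(seq_len(n1))
  stat_obs <- abs(log(obs))

  n_all <- choose(n1 + n2, n1)
  if (n_all <= max_exhaustive) {
    allocs <- combn(n1 + n2, n1, simplify = FALSE)
    stats <- vapply(allocs, function(a) abs(log(ratio_for(a))), 1)
    p <- mean(stats >= stat_obs - 1e-12)
    n_used <- n_all; exhaustive <- TRUE
  } else {
    set.seed(seed)
    stats <- vapply(seq_len(n_perm), function(i)
      abs(log(ratio_for(sample.int(n1 + n2, n1)))), 1)
    p <- (1 + sum(stats >= stat_obs - 1e-12)) / (1 + n_perm)
    n_used <- n_perm; exhaustive <- FALSE
  }
  list(ratio = obs, p = p, n_permutations = n_used,
       exhaustive = exhaustive, seed = seed)
}

#' Relative expression as 40 minus delta-Ct
#'
#' `40 - (Ct_target - Ct_reference)`: a display value placing
#' equally-expressed target and reference at 40, with one unit per Ct cycle.
#'
#' @param ct_target,ct_reference Ct values (> 0).
#' @return numeric value(s).
#' @export
relative_expression_40_minus_dct <- function(ct_target, ct_reference) {
  if (any(ct_target <= 0) || any(ct_reference <= 0)) stop("Ct values must be > 0")
  40 - (ct_target - ct_reference)
}

#' Cross-platform concordance of fold changes
#'
#' Spearman rank correlation (average ranks for ties) between per-gene
#' array and qPCR log2 fold changes, with a seeded permutation p value.
#'
#' @param log2fc_array,log2fc_qpcr per-gene log2 fold changes, matched by
#'   position (>= 3 pairs).
#' @param n_perm permutations for the p value.
#' @param seed integer seed.
#' @return list with `rho`, `n`, `p`.
#' @export
platform_concordance <- function(log2fc_array, log2fc_qpcr,
                                 n_perm = 1999L, seed = 1L) {
  keep <- is.finite(log2fc_array) & is.finite(log2fc_qpcr)
  x <- log2fc_array[keep]; y <- log2fc_qpcr[keep]
  if (length(x) < 3L) stop("need >= 3 shared genes")
  rho <- cor(x, y, method = "spearman")
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i)
    cor(x, sample(y), method = "spearman"), 1)
  p <- (1 + sum(abs(perm) >= abs(rho) - 1e-12)) / (1 + n_perm)
  list(rho = rho, n = length(x), p = p)
}

#' Fold changes and significance for a qPCR plate
#'
#' Per target amplicon: `dCt = mean Ct(control) - mean Ct(drought)` for the
#' target and the reference, the Pfaffl ratio against the reference, and a
#' fixed-reallocation randomization p value.
#'
#' @param plate well-level data frame (`amplicon`, `condition`, `ct`);
#'   conditions `control` and `drought`.
#' @param efficiencies data frame `amplicon`, `E`.
#' @param reference_id reference amplicon id present on the plate.
#' @param n_perm,seed randomization-test settings.
#' @return data frame `amplicon`, `E`, `dct`, `ratio`, `log2_ratio`, `p`.
#' @export
qpcr_fold_changes <- function(plate, efficiencies, reference_id,
                              n_perm = 2000L, seed = 1L) {
  if (!reference_id %in% plate$amplicon)
    stop("reference amplicon '", reference_id, "' absent from the plate")
  e_of <- setNames(efficiencies$E, efficiencies$amplicon)
  ref <- plate[plate$amplicon == reference_id, ]
  ref_c <- ref$ct[ref$condition == "control"]
  ref_d <- ref$ct[ref$condition == "drought"]
  targets <- setdiff(unique(plate$amplicon), reference_id)
  rows <- lapply(targets, function(a) {
    w <- plate[plate$amplicon == a, ]
    ct_c <- w$ct[w$condition == "control"]
    ct_d <- w$ct[w$condition == "drought"]
    dct <- mean(ct_c) - mean(ct_d)
    dct_ref <- mean(ref_c) - mean(ref_d)
    r <- pfaffl_ratio(e_of[[a]], dct, e_of[[reference_id]], dct_ref)
    rt <- randomization_test(ct_c, ct_d, ref_c, ref_d,
                             e_target = e_of[[a]], e_ref = e_of[[reference_id]],
                             n_perm = n_perm, seed = seed)
    data.frame(amplicon = a, E = e_of[[a]], dct = dct, ratio = r,
               log2_ratio = log2(r), p = rt$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
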