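#' Run the full analysis pipeline on in-memory objects
#'
#' Chains the stages in their analysis order: normalization (percentile
#' shift to the 75th percentile, then baseline to the median of all
#' samples), per-organ cell-means fits and the three contrasts per organ
#' (drought vs control within each genotype; tolerant vs sensitive within
#' control), BH adjustment and fold-change calls, probe-to-gene collapse,
#' DEG partitioning, priming-candidate selection, optional GO enrichment of
#' the priming candidates, and Ward sample clustering.
#'
#' @param raw linear-scale intensity matrix (probes x samples).
#' @param samples sample sheet covering the matrix columns.
#' @param probe_map probe-to-gene map.
#' @param annotations optional named list gene -> direct GO terms.
#' @param dag optional [go_dag()] for propagation.
#' @param tau_drought fold-change floor for drought contrasts, default 3.
#' @param tau_init fold-change floor for the initial contrast, default 2.
#' @param alpha BH significance level, default 0.05.
#' @param p_go,min_mapping GO enrichment settings (raw p 0.01, minimum 5
#'   mapped input genes).
#' @return list of class `drought_report` with components `normalized`,
#'   `contrasts` (gene-level tables, named `<genotype>_<organ>` and
#'   `initial_<organ>`), `deg_partition`, `priming` (classified calls),
#'   `priming_overlap`, `enrichment` (per organ class, when annotations are
#'   given), `tree` (hclust), and `thresholds`.
#' @export
run_pipeline <- function(raw, samples, probe_map,
                         annotations = NULL, dag = NULL,
                         tau_drought = 3, tau_init = 2, alpha = 0.05,
                         p_go = 0.01, min_mapping = 5) {
  if (tau_drought < 3)
    warning("tau_drought = ", tau_drought,
            " is below the conventional stringency of 3")
  mat <- normalize_expression(raw)

  specs <- list()
  for (o in .ORGANS) {
    for (g in .GENOTYPES)
      specs[[paste(g, o, sep = "_")]] <-
        contrast_spec(o, "drought_vs_control", genotype = g,
                      fc_threshold = tau_drought, q_threshold = alpha)
    specs[[paste0("initial_", o)]] <-
      contrast_spec(o, "tolerant_vs_sensitive_control",
                    fc_threshold = tau_init, q_threshold = alpha)
  }
  contrasts <- lapply(specs, function(sp)
    gene_contrast(mat, samples, sp, probe_map))

  parts <- classify_degs(contrasts$tolerant_root, contrasts$sensitive_root,
                         contrasts$tolerant_leaf, contrasts$sensitive_leaf)

  calls <- lapply(c(root = "root", leaf = "leaf"), function(o) {
    select_primed(
      initial_difference_genes(contrasts[[paste0("initial_", o)]],
                               specs[[paste0("initial_", o)]],
                               tau_init = tau_init, alpha = alpha),
      contrasts[[paste0("sensitive_", o)]],
      contrasts[[paste0("tolerant_", o)]],
      organ = o)
  })
  priming <- classify_priming_by_organ(calls$root, calls$leaf)
  overlap <- overlap_with_tolerant_degs(
    priming,
    contrasts$tolerant_root$gene_id[contrasts$tolerant_root$pass],
    contrasts$tolerant_leaf$gene_id[contrasts$tolerant_leaf$pass])

  enrichment <- NULL
  if (!is.null(annotations)) {
    background <- unique(probe_map$gene_id)
    enrichment <- tryCatch(
      enrich(unique(priming$gene_id), background, annotations, dag,
             p_threshold = p_go, min_mapping = min_mapping),
      error = function(e) {
        warning("enrichment stage skipped: ", conditionMessage(e))
        NULL
      })
  }

  tree <- ward_linkage(distance_matrix(mat))

  structure(list(
    normalized = mat, contrasts = contrasts, deg_partition = parts,
    priming = priming, priming_overlap = overlap, enrichment = enrichment,
    tree = tree,
    thresholds = list(tau_drought = tau_drought, tau_init = tau_init,
                      alpha = alpha, p_go = p_go, min_mapping = min_mapping)),
    class = "drought_report")
}

#' Run the pipeline from files and write a report directory
#'
#' File-based front end over [run_pipeline()]: reads the expression TSV,
#' sample sheet and probe map (plus optional annotation table and OBO
#' ontology), runs the analysis, and writes one TSV per stage, a Newick
#' dendrogram, JSON count summaries, and a JSON manifest with thresholds
#' and input checksums sufficient to re-run the deterministic stages
#' bit-identically.
#'
#' @param expression_path,samples_path,probe_map_path input TSV paths.
#' @param out_dir output directory (created).
#' @param annotations_path optional gene-term TSV or GAF path.
#' @param obo_path optional OBO ontology path.
#' @param ... thresholds forwarded to [run_pipeline()].
#' @return the `drought_report`, invisibly; side effect: files under
#'   `out_dir`.
#' @export
run_pipeline_files <- function(expression_path, samples_path, probe_map_path,
                               out_dir, annotations_path = NULL,
                               obo_path = NULL, ...) {
  raw <- read_expression(expression_path)
  samples <- read_sample_sheet(samples_path, matrix_columns = colnames(raw))
  probe_map <- read_probe_map(probe_map_path)
  annotations <- if (!is.null(annotations_path))
    read_annotations(annotations_path) else NULL
  dag <- if (!is.null(obo_path)) read_obo(obo_path) else NULL

  report <- run_pipeline(raw, samples, probe_map,
                         annotations = annotations, dag = dag, ...)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name)
    write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  for (nm in names(report$contrasts))
    tsv(report$contrasts[[nm]], paste0("contrast_", nm, ".tsv"))
  tsv(report$deg_partition$summary, "deg_partition.tsv")
  tsv(report$priming, "priming_calls.tsv")
  tsv(report$priming_overlap, "priming_overlap.tsv")
  if (!is.null(report$enrichment)) tsv(report$enrichment, "enrichment.tsv")
  write_newick(report$tree, file.path(out_dir, "sample_dendrogram.nwk"))

  inputs <- c(expression = expression_path, samples = samples_path,
              probe_map = probe_map_path)
  if (!is.null(annotations_path)) inputs["annotations"] <- annotations_path
  if (!is.null(obo_path)) inputs["ontology"] <- obo_path
  manifest <- list(
    package = "droughtprime",
    version = as.character(utils::packageVersion("droughtprime")),
    thresholds = report$thresholds,
    inputs = as.list(inputs),
    input_md5 = as.list(tools::md5sum(unname(inputs))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  counts <- list(
    deg = split(setNames(report$deg_partition$summary$n,
                         report$deg_partition$summary$class),
                report$deg_partition$summary$scope),
    priming = as.list(table(report$priming$organ_class[
      !duplicated(report$priming$gene_id)])))
  jsonlite::write_json(counts, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(report)
}

#' Score pipeline calls against a simulation's ground truth
#'
#' Compares the gene-level priming calls (and optionally DEG calls) of a
#' report with the labels planted by [simulate_dataset()]. Sensitivity is
#' the fraction of true (gene, organ) priming labels recovered with the
#' correct direction; the false discovery proportion (FDP) is the fraction
#' of emitted calls whose (gene, organ) pair carries no matching true
#' label.
#'
#' @param report a `drought_report` from [run_pipeline()].
#' @param truth truth component of the matching [simulate_dataset()].
#' @return list with `priming` (sensitivity, fdp, n_true, n_called) and
#'   `deg` (per-organ per-genotype sensitivity/fdp data frame).
#' @export
score_against_truth <- function(report, truth) {
  lab <- truth$labels
  true_primed <- lab[lab$primed_label != "none", c("gene_id", "organ",
                                                   "primed_label")]
  calls <- report$priming
  key <- function(g, o, d) paste(g, o, d, sep = "|")
  true_keys <- key(true_primed$gene_id, true_primed$organ,
                   true_primed$primed_label)
  call_keys <- key(calls$gene_id, calls$organ, calls$priming_direction)
  tp <- sum(call_keys %in% true_keys)
  priming <- list(
    sensitivity = if (length(true_keys)) tp / length(true_keys) else NA_real_,
    fdp = if (length(call_keys)) 1 - tp / length(call_keys) else 0,
    n_true = length(true_keys), n_called = length(call_keys))

  deg_rows <- list()
  for (o in .ORGANS) for (g in .GENOTYPES) {
    tab <- report$contrasts[[paste(g, o, sep = "_")]]
    lo <- lab[lab$organ == o, ]
    truth_deg <- lo$gene_id[lo[[paste0(g, "_deg")]]]
    called <- tab$gene_id[tab$pass]
    tp <- sum(called %in% truth_deg)
    deg_rows[[paste(g, o)]] <- data.frame(
      genotype = g, organ = o,
      sensitivity = if (length(truth_deg)) tp / length(truth_deg) else NA_real_,
      fdp = if (length(called)) 1 - tp / length(called) else 0,
      n_true = length(truth_deg), n_called = length(called),
      stringsAsFactors = FALSE)
  }
  list(priming = priming,
       deg = do.call(rbind, c(deg_rows, list(make.row.names = FALSE))))
}
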