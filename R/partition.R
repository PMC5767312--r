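#' Partition an organ's DEGs by genotype exclusivity
#'
#' Standard two-set partition of the organ's DEG universe: genes
#' differentially expressed in the tolerant genotype only, in the sensitive
#' genotype only, and in both ("shared"). Inputs are treated as sets
#' (duplicates removed); the three classes are pairwise disjoint and their
#' union is the organ's DEG universe, so class counts always sum to the
#' total.
#'
#' @param deg_tolerant,deg_sensitive character vectors of gene ids passing
#'   the drought contrast in each genotype, for the same organ.
#' @return list with `tolerant_only`, `sensitive_only`, `shared` (sorted
#'   character vectors) and `counts` (named integer vector including
#'   `total`).
#' @export
partition_by_genotype <- function(deg_tolerant, deg_sensitive) {
  a <- unique(as.character(deg_tolerant))
  b <- unique(as.character(deg_sensitive))
  out <- list(tolerant_only = sort(setdiff(a, b)),
              sensitive_only = sort(setdiff(b, a)),
              shared = sort(intersect(a, b)))
  out$counts <- c(tolerant_only = length(out$tolerant_only),
                  sensitive_only = length(out$sensitive_only),
                  shared = length(out$shared),
                  total = length(union(a, b)))
  stopifnot(out$counts[["total"]] ==
              sum(out$counts[c("tolerant_only", "sensitive_only", "shared")]))
  out
}

#' Partition DEGs by organ exclusivity
#'
#' Two-set partition of the gene-level DEG universes of the two organs:
#' genes differential exclusively in roots, exclusively in leaves, and in
#' both organs. "Differentially expressed in an organ" means passing the
#' drought contrast in at least one genotype for that organ.
#'
#' @param deg_root,deg_leaf character vectors of gene ids in each organ's
#'   DEG universe.
#' @return list with `root_exclusive`, `leaf_exclusive`, `both` and
#'   `counts`.
#' @export
partition_by_organ <- function(deg_root, deg_leaf) {
  r <- unique(as.character(deg_root))
  l <- unique(as.character(deg_leaf))
  out <- list(root_exclusive = sort(setdiff(r, l)),
              leaf_exclusive = sort(setdiff(l, r)),
              both = sort(intersect(r, l)))
  out$counts <- c(root_exclusive = length(out$root_exclusive),
                  leaf_exclusive = length(out$leaf_exclusive),
                  both = length(out$both),
                  total = length(union(r, l)))
  stopifnot(out$counts[["total"]] ==
              sum(out$counts[c("root_exclusive", "leaf_exclusive", "both")]))
  out
}

#' Full DEG classification for the four drought contrasts
#'
#' Builds the per-organ genotype-exclusivity partitions and the cross-organ
#' partition from four gene-level contrast tables. A gene DE with opposite
#' directions in the two genotypes still counts as shared, but is flagged
#' direction-discordant.
#'
#' @param tol_root,sen_root,tol_leaf,sen_leaf gene-level contrast tables
#'   (from [gene_contrast()]) for the drought contrast of each
#'   (genotype, organ) pair.
#' @return list with `root`, `leaf` (per-organ genotype partitions, each
#'   with a `discordant` gene vector), `organ` (cross-organ partition), and
#'   `summary` (data frame of all counts).
#' @export
classify_degs <- function(tol_root, sen_root, tol_leaf, sen_leaf) {
  passing <- function(x) x$gene_id[x$pass]
  dir_of <- function(x) setNames(x$direction, x$gene_id)
  per_organ <- function(tol, sen) {
    part <- partition_by_genotype(passing(tol), passing(sen))
    dt <- dir_of(tol); ds <- dir_of(sen)
    shared <- part$shared
    part$discordant <- shared[!is.na(dt[shared]) & !is.na(ds[shared]) &
                                dt[shared] != ds[shared] &
                                dt[shared] != "conflict" &
                                ds[shared] != "conflict"]
    part
  }
  root <- per_organ(tol_root, sen_root)
  leaf <- per_organ(tol_leaf, sen_leaf)
  organ <- partition_by_organ(
    union(passing(tol_root), passing(sen_root)),
    union(passing(tol_leaf), passing(sen_leaf)))
  summary <- data.frame(
    scope = c(rep("root", 4), rep("leaf", 4), rep("organ", 4)),
    class = c(names(root$counts), names(leaf$counts), names(organ$counts)),
    n = c(unname(root$counts), unname(leaf$counts), unname(organ$counts)),
    stringsAsFactors = FALSE)
  list(root = root, leaf = leaf, organ = organ, summary = summary)
}
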