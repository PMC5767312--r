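#' Construct a GO DAG object
#'
#' A `go_dag` holds the term table and the is_a / part_of parent lists.
#' Acyclicity is verified on construction (via igraph); a cyclic ontology is
#' rejected.
#'
#' @param terms data frame with columns `id`, `name`, `namespace`.
#' @param parents named list: term id -> character vector of parent ids.
#' @return object of class `go_dag`.
#' @export
go_dag <- function(terms, parents) {
  stopifnot(all(c("id", "name", "namespace") %in% names(terms)))
  if (!all(names(parents) %in% terms$id))
    stop("ontology error: parent list names unknown in term table")
  unknown <- setdiff(unlist(parents, use.names = FALSE), terms$id)
  if (length(unknown))
    stop("ontology error: unknown parent term(s): ",
         paste(head(unknown, 5), collapse = ", "))
  edges <- .dag_edges(parents)
  if (nrow(edges)) {
    g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                       vertices = terms$id)
    if (!igraph::is_dag(g))
      stop("ontology error: cycle detected in the term graph")
  }
  structure(list(terms = terms, parents = parents), class = "go_dag")
}

.dag_edges <- function(parents) {
  n <- vapply(parents, length, 1L)
  data.frame(from = rep(names(parents), n),
             to = unlist(parents, use.names = FALSE),
             stringsAsFactors = FALSE)
}

#' All ancestors of each term in a DAG
#'
#' @param dag a [go_dag()].
#' @return named list: term id -> character vector of ancestor ids
#'   (excluding the term itself).
#' @export
term_ancestors <- function(dag) {
  stopifnot(inherits(dag, "go_dag"))
  edges <- .dag_edges(dag$parents)
  ids <- dag$terms$id
  if (!nrow(edges)) return(setNames(rep(list(character(0)), length(ids)), ids))
  g <- igraph::graph_from_data_frame(edges, directed = TRUE, vertices = ids)
  anc <- lapply(igraph::V(g), function(v)
    setdiff(names(igraph::subcomponent(g, v, mode = "out")),
            igraph::V(g)$name[v]))
  setNames(anc, ids)
}

#' True-path propagation of annotations
#'
#' Extends each gene's direct annotations to every ancestor of each term in
#' the DAG. Idempotent: propagating an already-propagated set changes
#' nothing.
#'
#' @param annotations named list: gene id -> character vector of term ids.
#' @param dag a [go_dag()]; annotated terms must exist in it.
#' @return annotations list of the same shape, term sets sorted.
#' @export
propagate_annotations <- function(annotations, dag) {
  stopifnot(inherits(dag, "go_dag"))
  used <- unique(unlist(annotations, use.names = FALSE))
  unknown <- setdiff(used, dag$terms$id)
  if (length(unknown))
    stop("ontology error: annotated term(s) absent from the DAG: ",
         paste(head(unknown, 5), collapse = ", "))
  anc <- term_ancestors(dag)
  lapply(annotations, function(tt)
    sort(unique(c(tt, unlist(anc[tt], use.names = FALSE)))))
}

#' Upper-tail hypergeometric p value
#'
#' `p = P(X >= x)` for X hypergeometric with `N` background genes of which
#' `K` carry the term, drawing `n` input genes. Computed via `phyper` in
#' log-stable form; `x = 0` gives `p = 1`.
#'
#' @param N annotated background size.
#' @param K background genes with the term.
#' @param n annotated input genes.
#' @param x input genes with the term.
#' @return upper-tail probability in `(0, 1]`.
#' @export
hypergeometric_upper_tail <- function(N, K, n, x) {
  if (any(c(N, K, n, x) < 0) || K > N || n > N || x > min(n, K))
    stop("inconsistent counts: need 0 <= x <= min(n, K), K <= N, n <= N")
  if (x == 0) return(1)
  phyper(x - 1, K, N - K, n, lower.tail = FALSE)
}

#' Singular enrichment analysis over GO terms
#'
#' For every term of the (optionally propagated) annotation set, counts
#' `x` input and `K` background genes carrying the term against the
#' annotated input size `n` and annotated background size `N`, and tests
#' the upper hypergeometric tail. A term is reported significant iff
#' `x >= min_mapping` and `p <= p_threshold` (optionally after BH
#' adjustment). Genes without any annotation are excluded from both `N` and
#' `n`; input genes outside the background are dropped with a warning.
#'
#' @param input_genes character vector of study-set gene ids.
#' @param background_genes character vector of background gene ids.
#' @param annotations named list: gene id -> direct term ids.
#' @param dag optional [go_dag()]; when supplied, annotations are
#'   true-path-propagated before counting.
#' @param p_threshold raw significance level, default 0.01.
#' @param min_mapping minimum input genes mapped to a term, default 5.
#' @param adjust if TRUE, apply BH across terms and gate significance on the
#'   adjusted values; off by default (raw p at 0.01, matching common SEA
#'   practice).
#' @return data frame sorted by p: `term`, `description`, `x`, `n`, `K`,
#'   `N`, `p` (and `q` when `adjust`), `significant`.
#' @export
enrich <- function(input_genes, background_genes, annotations, dag = NULL,
                   p_threshold = 0.01, min_mapping = 5, adjust = FALSE) {
  input_genes <- unique(as.character(input_genes))
  background_genes <- unique(as.character(background_genes))
  outside <- setdiff(input_genes, background_genes)
  if (length(outside)) {
    warning(length(outside), " input gene(s) outside the background dropped")
    input_genes <- setdiff(input_genes, outside)
  }
  if (!is.null(dag)) annotations <- propagate_annotations(annotations, dag)
  annotations <- annotations[names(annotations) %in% background_genes]
  bg <- names(annotations)
  inp <- intersect(input_genes, bg)
  if (length(inp) == 0L) stop("no annotated input genes")
  N <- length(bg); n <- length(inp)

  gene_of <- rep(names(annotations), vapply(annotations, length, 1L))
  term_of <- unlist(annotations, use.names = FALSE)
  K_tab <- table(term_of)
  x_tab <- table(term_of[gene_of %in% inp])
  terms <- names(K_tab)
  x <- as.integer(x_tab[terms]); x[is.na(x)] <- 0L
  K <- as.integer(K_tab[terms])
  p <- ifelse(x == 0, 1, phyper(x - 1L, K, N - K, n, lower.tail = FALSE))
  desc <- if (!is.null(dag))
    dag$terms$name[match(terms, dag$terms$id)] else NA_character_
  out <- data.frame(term = terms, description = desc, x = x, n = n,
                    K = K, N = N, p = p, stringsAsFactors = FALSE)
  if (adjust) {
    out$q <- bh_adjust(out$p)
    out$significant <- out$x >= min_mapping & out$q <= p_threshold
  } else {
    out$significant <- out$x >= min_mapping & out$p <= p_threshold
  }
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  stopifnot(all(out$x <= pmin(out$n, out$K)), all(out$K <= out$N),
            all(out$p > 0 & out$p <= 1))
  out
}

#' Read a minimal OBO ontology file
#'
#' Parses only what enrichment needs from `[Term]` stanzas: `id`, `name`,
#' `namespace`, `is_a` and `relationship: part_of` lines. Obsolete terms are
#' skipped. This is a deliberately small reader for plain-text OBO, not a
#' general ontology parser.
#'
#' @param path OBO file path.
#' @return a [go_dag()].
#' @export
read_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  stanza_starts <- grep("^\\[", lines)
  term_starts <- grep("^\\[Term\\]$", lines)
  if (!length(term_starts)) stop("ontology error: no [Term] stanzas in ", path)
  ends <- c(stanza_starts[-1] - 1L, length(lines))
  names(ends) <- stanza_starts
  ids <- character(0); nms <- character(0); ns <- character(0)
  parents <- list()
  for (s in term_starts) {
    block <- lines[(s + 1L):ends[[as.character(s)]]]
    if (any(grepl("^is_obsolete: *true", block))) next
    id <- sub("^id: *", "", grep("^id:", block, value = TRUE)[1])
    nm <- sub("^name: *", "", grep("^name:", block, value = TRUE)[1])
    nsp <- sub("^namespace: *", "", grep("^namespace:", block, value = TRUE)[1])
    isa <- sub(" *!.*$", "", sub("^is_a: *", "", grep("^is_a:", block, value = TRUE)))
    po <- grep("^relationship: *part_of ", block, value = TRUE)
    po <- sub(" *!.*$", "", sub("^relationship: *part_of *", "", po))
    ids <- c(ids, id); nms <- c(nms, nm)
    ns <- c(ns, if (is.na(nsp)) "unknown" else nsp)
    parents[[id]] <- unique(c(isa, po))
  }
  # drop dangling parent references (terms outside the parsed file)
  parents <- lapply(parents, function(p) intersect(p, ids))
  go_dag(data.frame(id = ids, name = nms, namespace = ns,
                    stringsAsFactors = FALSE), parents)
}

#' Read a gene-to-term annotation table
#'
#' Accepts a two-column tab-separated file (`gene`, `term`; header optional)
#' or GAF 2.x (comment lines starting `!`; columns 2 and 5 used).
#'
#' @param path annotation file path.
#' @return named list: gene id -> character vector of direct term ids.
#' @export
read_annotations <- function(path) {
  first <- readLines(path, n = 50L, warn = FALSE)
  gaf <- any(grepl("^!gaf-version", first))
  if (gaf) {
    tab <- read.delim(path, header = FALSE, comment.char = "!",
                      stringsAsFactors = FALSE)
    df <- data.frame(gene = tab[[2]], term = tab[[5]], stringsAsFactors = FALSE)
  } else {
    tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 2L) stop("annotation file needs two columns: gene, term")
    if (identical(tolower(as.character(tab[1, 1:2])), c("gene", "term")))
      tab <- tab[-1, , drop = FALSE]
    df <- data.frame(gene = tab[[1]], term = tab[[2]], stringsAsFactors = FALSE)
  }
  lapply(split(df$term, df$gene), function(x) sort(unique(x)))
}
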