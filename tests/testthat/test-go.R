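toy_dag <- function() {
  go_dag(terms = data.frame(id = c("T:R", "T:A", "T:B", "T:C"),
                            name = c("root", "a", "b", "c"),
                            namespace = "biological_process",
                            stringsAsFactors = FALSE),
         parents = list(`T:R` = character(0), `T:A` = "T:R",
                        `T:B` = "T:A", `T:C` = c("T:A", "T:B")))
}

test_that("go_dag rejects cycles and unknown parents", {
  expect_error(go_dag(data.frame(id = c("x", "y"), name = c("x", "y"),
                                 namespace = "bp"),
                      parents = list(x = "y", y = "x")),
               "cycle")
  expect_error(go_dag(data.frame(id = "x", name = "x", namespace = "bp"),
                      parents = list(x = "zzz")),
               "unknown parent")
})

test_that("propagation annotates ancestors and is idempotent", {
  dag <- toy_dag()
  ann <- list(g1 = "T:B", g2 = "T:C", g3 = "T:R")
  out <- propagate_annotations(ann, dag)
  expect_equal(out$g1, c("T:A", "T:B", "T:R"))
  expect_equal(out$g2, c("T:A", "T:B", "T:C", "T:R"))
  expect_equal(out$g3, "T:R")
  expect_equal(propagate_annotations(out, dag), out)  # idempotence
  expect_error(propagate_annotations(list(g = "T:missing"), dag), "absent")
})

test_that("propagation equals a brute-force reachability oracle on random DAGs", {
  set.seed(31)
  for (trial in 1:5) {
    n <- 10
    ids <- sprintf("T:%02d", 1:n)
    parents <- lapply(seq_len(n), function(i) {
      if (i == 1) character(0)
      else ids[sample.int(i - 1, sample(1:min(2, i - 1), 1))]
    })
    names(parents) <- ids
    dag <- go_dag(data.frame(id = ids, name = ids, namespace = "bp",
                             stringsAsFactors = FALSE), parents)
    # oracle: iterate parent expansion to a fixed point
    reach <- function(t) {
      seen <- character(0); frontier <- t
      while (length(frontier)) {
        nxt <- unique(unlist(parents[frontier], use.names = FALSE))
        frontier <- setdiff(nxt, seen)
        seen <- union(seen, nxt)
      }
      seen
    }
    ann <- list(gene = sample(ids, 3))
    out <- propagate_annotations(ann, dag)
    expect_setequal(out$gene,
                    union(ann$gene, unlist(lapply(ann$gene, reach))))
  }
})

test_that("hypergeometric upper tail matches exhaustive enumeration", {
  # the worked example: N=10, K=5, n=4, x=4 -> 5/210
  expect_equal(hypergeometric_upper_tail(10, 5, 4, 4), 5 / 210,
               tolerance = 1e-12)
  expect_equal(hypergeometric_upper_tail(10, 5, 4, 0), 1)
  expect_equal(hypergeometric_upper_tail(8, 8, 8, 8), 1)  # forced draw
  expect_error(hypergeometric_upper_tail(10, 11, 4, 2), "inconsistent")
  expect_error(hypergeometric_upper_tail(10, 5, 4, 5), "inconsistent")
  for (N in 1:12) for (K in 0:N) for (n in 0:N) {
    for (x in max(0, n + K - N):min(n, K)) {
      expect_equal(hypergeometric_upper_tail(N, K, n, x),
                   hyper_oracle(N, K, n, x), tolerance = 1e-12)
    }
  }
})

test_that("p is monotone non-increasing in x at fixed (N, K, n)", {
  ps <- vapply(0:6, function(x) hypergeometric_upper_tail(40, 12, 6, x), 1)
  expect_true(all(diff(ps) <= 1e-15))
})

test_that("enrich applies the minimum-mapping filter and count invariants", {
  genes <- sprintf("g%03d", 1:200)
  # term TA on exactly 4 input genes (tiny p, blocked by the mapping
  # filter); TB on 8 of 12 input genes (significant)
  input <- genes[1:12]
  ann <- c(setNames(rep(list("TA"), 4), genes[1:4]),
           setNames(rep(list("TB"), 8), genes[5:12]),
           setNames(rep(list(c("TB", "TC")), 20), genes[41:60]),
           setNames(rep(list("TC"), 140), genes[61:200]))
  out <- enrich(input, genes, ann, dag = NULL, p_threshold = 0.01,
                min_mapping = 5)
  ta <- out[out$term == "TA", ]
  expect_lt(ta$p, 1e-4)
  expect_false(ta$significant)   # x = 4 < 5: mapping filter blocks it
  tb <- out[out$term == "TB", ]
  expect_true(tb$significant)
  expect_equal(tb$x, 8)
  expect_true(all(out$x <= pmin(out$n, out$K)))
  expect_true(all(out$p > 0 & out$p <= 1))
  expect_true(!is.unsorted(out$p))
  # input outside the background is dropped with a warning
  expect_warning(enrich(c(input, "NOT_THERE"), genes, ann), "dropped")
  expect_error(enrich("g013", genes, ann), "no annotated input")
})

test_that("null annotations yield about 1% of terms at p <= 0.01", {
  truth <- list(labels = data.frame(gene_id = sprintf("g%03d", 1:300),
                                    organ = "root", primed_label = "none",
                                    stringsAsFactors = FALSE))
  frac <- vapply(1:50, function(s) {
    sim <- simulate_go_annotations(truth, target_genes = character(0),
                                   n_terms = 40, enrichment_factor = 1,
                                   base_rate = 0.1, seed = s)
    set.seed(s + 1000)
    input <- sample(truth$labels$gene_id, 60)
    out <- enrich(input, truth$labels$gene_id, sim$annotations, dag = NULL,
                  min_mapping = 0)
    mean(out$p <= 0.01)
  }, 1)
  expect_lte(mean(frac), 0.01 + 3 * sd(frac) / sqrt(length(frac)) + 0.005)
  expect_equal(length(simulate_go_annotations(truth, n_terms = 40,
    enrichment_factor = 1, seed = 1)$enriched_terms), 0L)
})

test_that("planted-enriched terms are recovered", {
  truth <- list(labels = data.frame(gene_id = sprintf("g%03d", 1:400),
                                    organ = "root",
                                    primed_label = c(rep("primed_high", 50),
                                                     rep("none", 350)),
                                    stringsAsFactors = FALSE))
  sim <- simulate_go_annotations(truth, n_terms = 30, n_enriched = 4,
                                 enrichment_factor = 5, base_rate = 0.08,
                                 seed = 7)
  input <- truth$labels$gene_id[truth$labels$primed_label != "none"]
  out <- enrich(input, truth$labels$gene_id, sim$annotations, sim$dag,
                p_threshold = 0.01, min_mapping = 5)
  hits <- out$term[out$significant]
  expect_gte(length(intersect(sim$enriched_terms, hits)),
             length(sim$enriched_terms) - 1L)
  # determinism: same seed, identical tables
  sim2 <- simulate_go_annotations(truth, n_terms = 30, n_enriched = 4,
                                  enrichment_factor = 5, base_rate = 0.08,
                                  seed = 7)
  expect_identical(sim$annotations, sim2$annotations)
  expect_identical(sim$enriched_terms, sim2$enriched_terms)
})

test_that("OBO round trip: parse, propagate, reject cycles", {
  obo <- c("format-version: 1.2", "",
           "[Term]", "id: T:0001", "name: root process",
           "namespace: biological_process", "",
           "[Term]", "id: T:0002", "name: child",
           "namespace: biological_process",
           "is_a: T:0001 ! root process", "",
           "[Term]", "id: T:0003", "name: grandchild",
           "namespace: biological_process",
           "is_a: T:0002 ! child",
           "relationship: part_of T:0001 ! root process", "",
           "[Term]", "id: T:0004", "name: gone",
           "is_obsolete: true", "",
           "[Typedef]", "id: part_of", "name: part of")
  path <- withr::local_tempfile(fileext = ".obo")
  writeLines(obo, path)
  dag <- read_obo(path)
  expect_setequal(dag$terms$id, c("T:0001", "T:0002", "T:0003"))
  expect_equal(sort(dag$parents[["T:0003"]]), c("T:0001", "T:0002"))
  out <- propagate_annotations(list(g = "T:0003"), dag)
  expect_equal(out$g, c("T:0001", "T:0002", "T:0003"))

  cyc <- c("[Term]", "id: A", "name: a", "is_a: B", "",
           "[Term]", "id: B", "name: b", "is_a: A")
  path2 <- withr::local_tempfile(fileext = ".obo")
  writeLines(cyc, path2)
  expect_error(read_obo(path2), "cycle")
})

test_that("annotation reader accepts two-column TSV and GAF", {
  p1 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tterm", "g1\tT:1", "g1\tT:2", "g2\tT:1"), p1)
  a1 <- read_annotations(p1)
  expect_equal(a1$g1, c("T:1", "T:2"))
  expect_equal(a1$g2, "T:1")
  p2 <- withr::local_tempfile(fileext = ".gaf")
  writeLines(c("!gaf-version: 2.1",
               paste("DB", "g9", "SYM", "", "T:9", "REF", "IEA", "", "P",
                     "", "", "protein", "taxon:4513", "20180101", "DB",
                     sep = "\t")), p2)
  a2 <- read_annotations(p2)
  expect_equal(a2$g9, "T:9")
})
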