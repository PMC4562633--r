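test_that("predictor pool is the universe minus both pathways", {
  pp <- build_predictor_pool(c("a", "b", "c", "d", "e"), "a", "b")
  expect_equal(pp$pool, c("c", "d", "e"))
  expect_equal(pp$chi1, "a")
  expect_equal(pp$chi2, "b")

  expect_error(build_predictor_pool(letters[1:5], "a", c("a", "b")), "overlap")
  expect_error(build_predictor_pool(c("a", "b"), "a", "b"), "pool is empty")
  expect_warning(build_predictor_pool(letters[1:5], c("a", "zz"), "b"),
                 "absent")
  expect_error(suppressWarnings(
    build_predictor_pool(letters[1:5], "zz", "b")), "empty after matching")
})

# deterministic construction: pathway genes built from known pool profiles so
# the neighbor sets are predictable
make_planted_matrix <- function(seed = 21) {
  set.seed(seed)
  T <- 16
  base <- matrix(rnorm(6 * T), 6, T)
  g1 <- base[1, ]; g2 <- base[2, ]; g3 <- base[3, ]
  vals <- rbind(
    a  = g1 + rnorm(T, sd = 0.05),            # pathway1 gene, driven by g1
    b  = g2 + rnorm(T, sd = 0.05),            # pathway1 gene, driven by g2
    c  = g3 + rnorm(T, sd = 0.05),            # pathway2 gene, driven by g3
    d  = g2 + rnorm(T, sd = 0.05),            # pathway2 gene, driven by g2
    g1 = g1, g2 = g2, g3 = g3,
    n1 = base[4, ], n2 = base[5, ], n3 = base[6, ])
  colnames(vals) <- paste0("s", seq_len(T))
  vals <- (vals - rowMeans(vals)) / apply(vals, 1, sd)
  expression_matrix(vals, condition = "WT", stage = "zscore")
}

test_that("pathway neighbor sets are unions of per-gene neighbor calls", {
  m <- make_planted_matrix()
  pair <- build_predictor_pool(rownames(m), c("a", "b"), c("c", "d"))
  n1 <- neighbors_of_pathway(m, pair, 1)
  expect_true(all(c("g1", "g2") %in% n1$gamma))        # union over a and b
  expect_true(all(n1$gamma %in% pair$pool))
  expect_true("g1" %in% n1$edges$neighbor_gene[n1$edges$pathway_gene == "a"])
  expect_true("g2" %in% n1$edges$neighbor_gene[n1$edges$pathway_gene == "b"])
  expect_true(all(n1$edges$met_target))
})

test_that("shared neighbors are the intersection with full provenance", {
  m <- make_planted_matrix()
  pair <- build_predictor_pool(rownames(m), c("a", "b"), c("c", "d"))
  res <- shared_neighbors(m, pair)
  expect_s3_class(res, "neighbor_result")
  # g2 drives one gene in each pathway; g1 and g3 drive only one pathway
  expect_true("g2" %in% res$shared)
  expect_false("g1" %in% res$shared)
  expect_false("g3" %in% res$shared)
  # containment invariants
  expect_true(all(res$shared %in% res$gamma1))
  expect_true(all(res$shared %in% res$gamma2))
  expect_true(all(c(res$gamma1, res$gamma2) %in% pair$pool))
  expect_equal(res$shared, intersect(res$gamma1, res$gamma2))
  # edge rows carry selection metadata
  expect_true(all(c("weight", "penalty", "variance_explained", "met_target")
                  %in% names(res$edges)))
})

test_that("neighbor discovery is deterministic", {
  m <- make_planted_matrix()
  pair <- build_predictor_pool(rownames(m), c("a", "b"), c("c", "d"))
  r1 <- shared_neighbors(m, pair)
  r2 <- shared_neighbors(m, pair)
  expect_identical(r1$edges, r2$edges)
  expect_identical(r1$shared, r2$shared)
})

test_that("neighbor results round-trip to disk in the documented layout", {
  m <- make_planted_matrix()
  pair <- build_predictor_pool(rownames(m), c("a", "b"), c("c", "d"))
  res <- shared_neighbors(m, pair)
  dir <- tempfile()
  paths <- write_neighbor_result(res, dir, header_lines = "v0 test")
  expect_true(all(file.exists(file.path(dir, paste0(
    "WT_pathway1-pathway2_", c("edges.tsv", "gamma1.txt", "gamma2.txt",
                               "shared.txt"))))))
  shared_back <- read_gene_sets(file.path(dir, "WT_pathway1-pathway2_shared.txt"))
  expect_equal(shared_back$sets[[1]]$genes, res$shared)
  edges <- read.delim(file.path(dir, "WT_pathway1-pathway2_edges.tsv"),
                      comment.char = "#")
  expect_equal(nrow(edges), nrow(res$edges))
  expect_equal(sort(unique(edges$pathway_id)), c("pathway1", "pathway2"))
})
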