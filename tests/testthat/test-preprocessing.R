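test_that("read_expression parses well-formed TSV and reports offenders", {
  p <- write_tsv_fixture(c("gene\ts1\ts2\ts3\ts4",
                           "Tlr4\t1\t2\t3\t4",
                           "Myd88\t5\t6\t7\t8",
                           "Gapdh\t0\t0\t1\t2"))
  m <- read_expression(p, condition = "WT")
  expect_equal(dim(m), c(3L, 4L))
  expect_equal(rownames(m), c("Tlr4", "Myd88", "Gapdh"))
  expect_equal(unclass(m)["Myd88", "s3"], 7)
  expect_equal(attr(m, "condition"), "WT")

  dup <- write_tsv_fixture(c("gene\ts1\ts2", "Gapdh\t1\t2", "Gapdh\t3\t4"))
  expect_error(read_expression(dup, "WT"), "Gapdh")

  na <- write_tsv_fixture(c("gene\ts1\ts2", "Tlr4\t1\tNA"))
  expect_error(read_expression(na, "WT"), "Tlr4.*s2")

  ragged <- write_tsv_fixture(c("gene\ts1\ts2", "Tlr4\t1"))
  expect_error(read_expression(ragged, "WT"), "malformed")
})

test_that("expression round-trips through write/read at printed precision", {
  m <- fixture_matrix(c("g1", "g2", "g3"), T = 5)
  p <- tempfile(fileext = ".tsv")
  write_expression(m, p, header_lines = "test header")
  m2 <- read_expression(p, condition = "WT", stage = "zscore")
  expect_equal(unclass(m2), unclass(m), tolerance = 1e-15)
})

test_that("dynamic-range filter applies max > floor and max > fold*min", {
  mk <- function(rows, cond) expression_matrix(
    matrix(unlist(rows), nrow = length(rows), byrow = TRUE,
           dimnames = list(names(rows), paste0("s", 1:3))), cond)
  m <- mk(list(kept = c(1, 2, 6),        # 6 > 5, 6 > 2*1
               flat = c(4, 4, 4),        # max 4 <= 5
               zero_min = c(0, 0, 7),    # 7 > 5, 7 > 0
               high_flat = c(10, 10, 10) # max fine, no fold change
               ), "WT")
  expect_equal(filter_dynamic_genes(list(m)), c("kept", "zero_min"))

  # kept if the rule passes in at least one condition
  m2 <- mk(list(kept = c(4, 4, 4), flat = c(4, 4, 4),
                zero_min = c(1, 1, 1), high_flat = c(2, 30, 2)), "KO")
  expect_equal(filter_dynamic_genes(list(m, m2)),
               c("kept", "zero_min", "high_flat"))

  # monotone in thresholds: raising floor or fold never adds a gene
  set.seed(7)
  r <- expression_matrix(matrix(rexp(200, 0.2), 40, 5,
                                dimnames = list(paste0("g", 1:40),
                                                paste0("s", 1:5))), "WT")
  base <- filter_dynamic_genes(list(r), fold = 2, floor = 5)
  for (fl in c(6, 10, 20)) expect_true(
    all(filter_dynamic_genes(list(r), fold = 2, floor = fl) %in% base))
  for (fd in c(3, 5, 10)) expect_true(
    all(filter_dynamic_genes(list(r), fold = fd, floor = 5) %in% base))

  expect_error(filter_dynamic_genes(list(m, mk(list(x = c(1, 2, 3)), "KO"))),
               "universe")
})

test_that("znormalize yields mean 0 / sample sd 1 rows and is idempotent", {
  m <- expression_matrix(matrix(c(1, 2, 3), 1, 3,
                                dimnames = list("g1", paste0("s", 1:3))), "WT")
  z <- znormalize(m)
  expect_equal(as.numeric(z), c(-1, 0, 1))

  set.seed(3)
  r <- expression_matrix(matrix(rnorm(60, mean = 4, sd = 3), 12, 5,
                                dimnames = list(paste0("g", 1:12),
                                                paste0("s", 1:5))), "WT")
  z <- znormalize(r)
  expect_lt(max(abs(rowMeans(z))), 1e-8)
  expect_lt(max(abs(apply(z, 1, sd) - 1)), 1e-8)
  expect_equal(unclass(znormalize(z)), unclass(z), tolerance = 1e-8)

  const <- expression_matrix(matrix(c(5, 5, 5, 1, 2, 3), 2, 3, byrow = TRUE,
                                    dimnames = list(c("flat", "ok"),
                                                    paste0("s", 1:3))), "WT")
  expect_error(znormalize(const), "flat")
  expect_warning(dropped <- drop_zero_variance(const), "zero-variance")
  expect_equal(rownames(dropped), "ok")
})

test_that("q75 count normalization divides by the non-zero upper quartile", {
  vals <- matrix(c(2, 4, 6, 8, 0,
                   3, 3, 3, 3, 3), ncol = 2,
                 dimnames = list(paste0("g", 1:5), c("s1", "s2")))
  m <- expression_matrix(vals, "WT")
  nm <- normalize_counts_q75(m)
  # sorted non-zero s1 counts [2,4,6,8]: type-7 quantile at 0.75*(4-1) -> 6.5
  expect_equal(unclass(nm)[4, "s1"], 8 / 6.5)
  expect_equal(unclass(nm)[5, "s1"], 0)           # zeros stay zero
  expect_equal(unname(unclass(nm)[, "s2"]), rep(1, 5))  # identical counts -> 1

  # scale equivariance per sample: multiplying a column by k changes nothing
  vals2 <- vals
  vals2[, 1] <- vals2[, 1] * 7
  nm2 <- normalize_counts_q75(expression_matrix(vals2, "WT"))
  expect_equal(unclass(nm2), unclass(nm), tolerance = 1e-12)

  zero <- expression_matrix(matrix(0, 5, 1, dimnames = list(paste0("g", 1:5), "s1")), "WT")
  expect_error(normalize_counts_q75(zero), "all-zero")
})

test_that("minimum-read filter requires min_count in every sample", {
  vals <- matrix(c(1, 1, 1, 1,
                   0, 9, 9, 9,
                   5, 5, 5, 5), nrow = 3, byrow = TRUE,
                 dimnames = list(c("a", "b", "c"), paste0("s", 1:4)))
  m <- expression_matrix(vals, "WT")
  expect_equal(filter_min_reads(m), c("a", "c"))
  expect_equal(filter_min_reads(m, min_count = 0), c("a", "b", "c"))
  expect_equal(filter_min_reads(m, min_count = 2), "c")
})

test_that("gene sets read from GMT and plain lists with validation", {
  gmt <- write_tsv_fixture(c("TLR\tdesc\tTlr4\tMyd88",
                             "APP\tantigen\tTap1\tTap2\tB2m"))
  gs <- read_gene_sets(gmt)
  expect_equal(sort(names(gs$sets)), c("APP", "TLR"))
  expect_equal(gs$sets$TLR$genes, c("Tlr4", "Myd88"))
  expect_equal(gs$sets$APP$description, "antigen")

  plain <- write_tsv_fixture(c("Ifit1", "Ifit2", "Isg15"))
  ps <- read_gene_sets(plain)
  expect_length(ps$sets, 1)
  expect_equal(ps$sets[[1]]$genes, c("Ifit1", "Ifit2", "Isg15"))

  dup <- write_tsv_fixture(c("TLR\td\tTlr4", "TLR\td\tMyd88"))
  expect_error(read_gene_sets(dup), "duplicate term")
  empty <- write_tsv_fixture(c("TLR\td\t"))
  expect_error(read_gene_sets(empty), "empty gene set")
})
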