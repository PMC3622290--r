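test_that("experiment construction validates counts and design", {
  counts <- matrix(0:7, 2, 4,
                   dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
  exp <- make_exp(counts, time = c(1, 1, 2, 2))
  expect_s3_class(exp, "tse")
  expect_equal(dim(exp), c(2L, 4L))

  neg <- counts; neg[1, 1] <- -1
  expect_error(make_exp(neg, time = c(1, 1, 2, 2)), "negative")
  frac <- counts; frac[1, 1] <- 0.5
  expect_error(make_exp(frac, time = c(1, 1, 2, 2)), "integer")
  expect_error(tse(counts, time = c(1, 1, 2, 2),
                   condition = rep("A", 4), replicate = c(1, 1, 1, 2)),
               "duplicate")
  expect_error(make_exp(counts, time = rep(1, 4)), "distinct time")
})

test_that("read/write round-trips integer experiments bit-exactly", {
  counts <- matrix(rpois(12, 30), 3, 4,
                   dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  exp <- make_exp(counts, time = c(7, 11, 14, 21))
  cp <- tempfile(fileext = ".tsv"); mp <- tempfile(fileext = ".tsv")
  write_experiment(exp, cp, mp)
  back <- read_experiment(cp, mp)
  expect_identical(back$counts, exp$counts)
  expect_equal(back$samples, exp$samples)
  expect_equal(back$lib_sizes, exp$lib_sizes)

  # metadata row missing for one column names the offender
  md <- read.table(mp, header = TRUE, sep = "\t")
  write.table(md[-2, ], mp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_experiment(cp, mp), "s2")
})

test_that("normalization scales by depth and keeps raw counts", {
  counts <- matrix(c(5L, 10L), 1, 2,
                   dimnames = list("g1", c("a", "b")))
  exp <- tse(counts, time = 1:2, condition = c("A", "A"),
             replicate = c(1, 1), lib_sizes = c(1e6, 1e6))
  nn <- normalize_experiment(exp, "cpm")
  expect_equal(unname(nn$counts[1, ]), c(5, 10))  # count/libsize * 1e6
  expect_true(nn$normalized)
  expect_identical(nn$raw_counts, exp$counts)
  expect_identical(normalize_experiment(exp, "none"), exp)
  expect_error(normalize_experiment(exp, "rpkm"), "gene_lengths")
  rp <- normalize_experiment(exp, "rpkm", gene_lengths = c(g1 = 2000))
  expect_equal(unname(rp$counts[1, ]), c(2.5, 5))

  # equal library sizes: cpm is one common scale factor
  counts2 <- matrix(rpois(8, 20), 2, 4,
                    dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
  e2 <- make_exp(counts2, time = 1:4, lib_sizes = rep(2e6, 4))
  n2 <- normalize_experiment(e2, "cpm")
  expect_equal(n2$counts, counts2 / 2, ignore_attr = FALSE)
})

test_that("gene filtering removes low-count and low-CV genes, idempotently", {
  # 10 genes with strictly increasing CV: scale a fixed pattern
  base <- c(10, 12, 8, 11, 9, 10, 10, 10)
  counts <- t(sapply(1:10, function(i) {
    round(100 + (base - 10) * i)
  }))
  counts[1, ] <- 100L  # CV exactly 0
  rownames(counts) <- paste0("g", 1:10)
  exp <- make_exp(counts, time = 1:8)
  cvs <- apply(counts, 1, sd) / rowMeans(counts)
  thr <- mean(sort(cvs)[4:5])  # between 4th and 5th order statistic
  kept <- filter_genes(exp, min_total_count = 1, cv_threshold = thr)
  expect_equal(nrow(kept$counts), 6L)
  expect_false("g1" %in% gene_ids(kept))  # constant gene removed

  again <- filter_genes(kept, min_total_count = 1, cv_threshold = thr)
  expect_identical(again$counts, kept$counts)

  zero <- counts; zero[2, ] <- 0L
  e0 <- make_exp(zero, time = 1:8)
  expect_false("g2" %in% gene_ids(filter_genes(e0, min_total_count = 1)))
  expect_warning(filter_genes(exp, cv_threshold = 10), "all genes")
})

test_that("BH adjustment matches the step-up recursion", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.1, NaN)), "NA")
  expect_error(bh_fdr(c(0.1, 1.2)), "0, 1")

  set.seed(42)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-12)
  }
  # order-preserving and >= raw p
  p <- runif(50)
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("gene_series orders by time with replicates grouped", {
  counts <- matrix(1:8, 2, 4,
                   dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
  exp <- tse(counts, time = c(2, 1, 2, 1), condition = rep("A", 4),
             replicate = c(1, 1, 2, 2))
  s <- gene_series(exp, "g1")
  expect_equal(s$times, c(1, 1, 2, 2))
  expect_equal(length(s$values), 4L)
  expect_error(gene_series(exp, "g1", condition = "missing"), "condition")
})
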