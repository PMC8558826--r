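test_that("compute_tpm applies the length-normalized rescaling", {
  # single gene takes the whole million
  one <- compute_tpm(tibble::tibble(gene = "A", length_kb = 1.5, s1 = 7))
  expect_equal(one$s1, 1e6)

  # equal lengths reduce to count proportions
  two <- compute_tpm(tibble::tibble(gene = c("A", "B"), length_kb = c(1, 1),
                                    s1 = c(10, 90)))
  expect_equal(two$s1, c(1e5, 9e5))

  # unequal lengths: rates 10 and 5
  rates <- compute_tpm(tibble::tibble(gene = c("A", "B"), length_kb = c(1, 2),
                                      s1 = c(10, 10)))
  expect_equal(rates$s1, c(2e6 / 3, 1e6 / 3))
})

test_that("TPM columns sum to one million and are scale invariant", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(5:50, 1)
    counts <- tibble::tibble(
      gene = paste0("G", seq_len(n)),
      length_kb = runif(n, 0.2, 20),
      a = rpois(n, 30) + 1, b = rpois(n, 5), c = rpois(n, 100)
    )
    tpm <- compute_tpm(counts)
    expect_equal(sum(tpm$a), 1e6, tolerance = 1e-9)
    expect_equal(sum(tpm$b), 1e6, tolerance = 1e-9)
    expect_equal(sum(tpm$c), 1e6, tolerance = 1e-9)
    # multiplying one sample's counts leaves its TPM unchanged
    scaled <- counts
    scaled$a <- scaled$a * 7
    expect_equal(compute_tpm(scaled)$a, tpm$a)
    # equal lengths: proportions equal count proportions exactly
    eq <- counts
    eq$length_kb <- 2.5
    expect_equal(compute_tpm(eq)$c, 1e6 * counts$c / sum(counts$c))
  }
})

test_that("compute_tpm rejects invalid tables with informative errors", {
  expect_error(
    compute_tpm(tibble::tibble(gene = c("A", "B"), length_kb = c(1, 1),
                               s1 = c(0, 0), s2 = c(1, 2))),
    "all-zero.*s1")
  expect_error(
    compute_tpm(tibble::tibble(gene = "A", length_kb = 0, s1 = 5)),
    "length_kb")
  expect_error(
    compute_tpm(tibble::tibble(gene = c("A", "a"), length_kb = 1, s1 = c(1, 2))),
    "duplicate")
  expect_error(
    compute_tpm(tibble::tibble(gene = "A", length_kb = 1, s1 = -3)),
    "negative")
})

test_that("summarize_genes averages replicates and applies strict cutoffs", {
  tpm <- tibble::tibble(
    gene = c("edge2", "mid", "edge100"),
    s1 = c(1, 8, 400), s2 = c(3, 12, 0), s3 = c(2, 10, 0), s4 = c(2, 14, 0)
  )
  s <- summarize_genes(tpm)
  expect_equal(s$mean_tpm, c(2, 11, 100))
  expect_equal(s$n_samples, rep(4L, 3))
  # mean exactly 2 is not expressed; exactly 100 is not very high
  expect_equal(s$expressed, c(FALSE, TRUE, TRUE))
  expect_equal(s$high, c(FALSE, TRUE, TRUE))
  expect_equal(s$very_high, c(FALSE, FALSE, FALSE))
  expect_error(summarize_genes(tpm[0, ]), "empty")
})

test_that("summary flags agree with brute-force recomputation", {
  set.seed(22)
  cfg <- screen_config()
  for (rep in 1:50) {
    n <- sample(2:30, 1)
    k <- sample(1:6, 1)
    m <- matrix(10^runif(n * k, -2, 2.5), n, k)
    tpm <- tibble::as_tibble(as.data.frame(m))
    tpm <- dplyr::bind_cols(tibble::tibble(gene = paste0("G", 1:n)), tpm)
    s <- summarize_genes(tpm, cfg)
    means <- apply(m, 1, mean)
    expect_equal(s$mean_tpm, unname(means))
    expect_equal(s$expressed, unname(means > 2))
    expect_equal(s$high, unname(means > 10))
    expect_equal(s$very_high, unname(means > 100))
  }
})

test_that("read_expression parses TPM and counts dialects", {
  tpm_file <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2\ts3\ts4",
               "npr2\t1\t3\t2\t3.6",
               "Itgb1\t20\t22\t18\t20",
               "BG1\t0\t0\t0.5\t0"), tpm_file)
  mat <- read_expression(tpm_file)
  expect_equal(dim(mat), c(3L, 5L))
  expect_equal(mat$gene, c("NPR2", "ITGB1", "BG1"))
  expect_equal(attr(mat, "provenance"), "supplied_tpm")
  # supplied TPM is never renormalized
  expect_false(isTRUE(all.equal(sum(mat$s1), 1e6)))

  counts_file <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tlength_kb\ts1", "A\t1\t10", "B\t2\t10"), counts_file)
  cm <- read_expression(counts_file, mode = "counts")
  expect_equal(attr(cm, "provenance"), "from_counts")
  expect_equal(cm$s1, c(2e6 / 3, 1e6 / 3))
})

test_that("read_expression errors name the defect", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene", "A"), f)
  expect_error(read_expression(f), "no sample columns")

  writeLines(c("gene\ts1", "A\t1", "B\ttwo"), f)
  expect_error(read_expression(f), "line 3")

  writeLines(c("gene\ts1", "A\t1", "a\t2"), f)
  expect_error(read_expression(f), "duplicate.*line 3")

  writeLines(c("gene\ts1", "A\t1", "B\t2"), f)
  expect_error(read_expression(f, mode = "counts"), "length_kb")
  expect_error(read_expression("/nonexistent/x.tsv"), "not found")
})

test_that("duplicate symbols resolve by sum (counts) or max (tpm) when asked", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tlength_kb\ts1", "A\t1\t10", "a\t1\t20", "B\t1\t70"), f)
  expect_message(
    cm <- read_expression(f, mode = "counts", duplicates = "sum"),
    "resolving 1 duplicate")
  expect_equal(sort(cm$gene), c("A", "B"))
  expect_equal(cm$s1[cm$gene == "A"] / cm$s1[cm$gene == "B"], 30 / 70)

  writeLines(c("gene\ts1", "A\t10", "a\t25", "B\t7"), f)
  suppressMessages(tm <- read_expression(f, duplicates = "max"))
  expect_equal(tm$s1[tm$gene == "A"], 25)
})
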