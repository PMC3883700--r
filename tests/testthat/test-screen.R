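make_ds <- function(vals, calls = NULL, log2_scale = TRUE) {
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1)
  if (is.null(rownames(vals))) rownames(vals) <- sprintf("G%d", seq_len(nrow(vals)))
  if (is.null(colnames(vals))) colnames(vals) <- sprintf("S%d", seq_len(ncol(vals)))
  expression_dataset(vals, calls = calls, log2_scale = log2_scale)
}

make_samples <- function(groups, mmse, nft) {
  data.frame(sample_id = sprintf("S%d", seq_along(groups)), group = groups,
             mmse = mmse, nft = nft, stringsAsFactors = FALSE)
}

test_that("detection filter keeps genes present/marginal on enough chips", {
  calls <- rbind(
    c(rep("P", 16), rep("A", 6)),   # exactly at threshold: retained
    rep("A", 22),                   # never detected: removed
    c(rep("P", 15), rep("A", 7)),   # one below threshold: removed
    c(rep("M", 10), rep("P", 8), rep("A", 4))  # P+M = 18: retained
  )
  vals <- matrix(rnorm(4 * 22), nrow = 4)
  ds <- make_ds(vals, calls = calls)
  out <- filter_by_detection(ds, min_detected = 16)
  expect_equal(gene_ids(out), c("G1", "G4"))
  expect_equal(ncol(out$values), 22L)

  no_calls <- make_ds(vals)
  expect_error(filter_by_detection(no_calls, 16), "skip the .* filter")
  expect_error(filter_by_detection(ds, 23), "exceeds the number of samples")
})

test_that("log2 median normalization matches hand computation", {
  ds <- make_ds(matrix(c(2, 8, 32), nrow = 1), log2_scale = FALSE)
  out <- normalize_log2_median(ds)
  expect_equal(unname(out$values[1, ]), c(-2, 0, 2))
  expect_true(out$log2_scale)

  const <- normalize_log2_median(make_ds(matrix(rep(5, 4), 1)))
  expect_equal(unname(const$values[1, ]), rep(0, 4))
  expect_equal(median(out$values[1, ]), 0)

  neg <- make_ds(matrix(c(1, -2, 3), 1), log2_scale = FALSE)
  expect_error(normalize_log2_median(neg), "gene 'G1'.*sample 'S2'")
})

test_that("median centering leaves Pearson correlations unchanged", {
  set.seed(5)
  vals <- matrix(2^rnorm(40, 6, 1), nrow = 4,
                 dimnames = list(paste0("G", 1:4), paste0("S", 1:10)))
  samples <- make_samples(rep("early", 10),
                          round(runif(10, 10, 28)), runif(10, 1, 9))
  raw_log <- make_ds(log2(vals))
  norm <- normalize_log2_median(make_ds(vals, log2_scale = FALSE))
  for (score in c("MMSE", "sqrtNFT")) {
    r1 <- stagewise_pearson(raw_log, samples, score, stages = "early")
    r2 <- stagewise_pearson(norm, samples, score, stages = "early")
    expect_equal(r1$r, r2$r, tolerance = 1e-12)
    expect_equal(r1$p, r2$p, tolerance = 1e-12)
  }
})

test_that("sqrt transform is exact, rejects negatives, preserves order", {
  expect_equal(sqrt_transform(c(0, 1, 4, 9)), c(0, 1, 2, 3))
  expect_error(sqrt_transform(c(1, -0.1)), "non-negative")
  set.seed(3)
  x <- sort(runif(50, 0, 100))
  expect_false(is.unsorted(sqrt_transform(x)))
})

test_that("omnibus normality statistic matches an independent transcription", {
  set.seed(21)
  for (n in c(8, 12, 30, 200)) {
    x <- rnorm(n) + rexp(n) * sample(c(0, 1), 1)
    got <- dagostino_pearson_test(x)
    expect_equal(got$k2, transcribe_k2(x), tolerance = 1e-12)
    expect_gte(got$k2, 0)
    expect_equal(got$p, pchisq(got$k2, 2, lower.tail = FALSE))
  }
  expect_error(dagostino_pearson_test(rnorm(7)), "n < 8")
})

test_that("omnibus normality statistic matches reference values", {
  # frozen from an independent implementation of the same published
  # formulas (scipy.stats.normaltest) on these exact vectors
  set.seed(42)
  x <- round(rnorm(30, 10, 2), 6)
  got <- dagostino_pearson_test(x)
  expect_equal(got$k2, 0.615180322543, tolerance = 1e-9)
  expect_equal(got$p, 0.735216576498, tolerance = 1e-9)

  set.seed(7)
  y <- round(rexp(40), 6)
  got <- dagostino_pearson_test(y)
  expect_equal(got$k2, 24.21207268, tolerance = 1e-8)
  expect_equal(got$p, 5.52605521314e-06, tolerance = 1e-6)
})

test_that("normality test accepts normal and rejects exponential samples", {
  set.seed(100)
  accept <- vapply(1:200, function(i)
    dagostino_pearson_test(rnorm(1000))$p > 0.05, logical(1))
  # acceptance rate is nominally 0.95; allow 3 binomial standard errors
  expect_gte(mean(accept), 0.95 - 3 * sqrt(0.95 * 0.05 / 200))
  set.seed(101)
  expect_lt(dagostino_pearson_test(rexp(1000))$p, 0.001)
})

test_that("stage-wise Pearson matches the product-moment formula", {
  set.seed(9)
  samples <- make_samples(rep(c("early", "medium", "late"), each = 6),
                          round(runif(18, 5, 28)), runif(18, 0.5, 9))
  vals <- matrix(rnorm(10 * 18), nrow = 10,
                 dimnames = list(paste0("G", 1:10), samples$sample_id))
  ds <- make_ds(vals)
  rec <- stagewise_pearson(ds, samples, "MMSE")
  expect_equal(nrow(rec), 30L)
  for (st in c("early", "medium", "late")) {
    idx <- samples$group == st
    y <- samples$mmse[idx]
    for (g in paste0("G", 1:10)) {
      x <- vals[g, idx]
      r_brute <- sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
      row <- rec[rec$gene_id == g & rec$stage == st, ]
      expect_equal(row$r, r_brute, tolerance = 1e-12)
      expect_equal(row$r2, row$r^2, tolerance = 1e-12)
      # p-value against the standard test
      ct <- suppressWarnings(cor.test(x, y))
      expect_equal(row$p, ct$p.value, tolerance = 1e-10)
    }
  }
})

test_that("exact linear dependence gives r = 1; constant rows are undefined", {
  samples <- make_samples(rep("early", 6), c(10, 14, 18, 22, 26, 28),
                          rep(1, 6))
  vals <- rbind(2 * samples$mmse + 1, rep(3, 6))
  dimnames(vals) <- list(c("lin", "flat"), samples$sample_id)
  rec <- stagewise_pearson(make_ds(vals), samples, "MMSE", stages = "early")
  expect_equal(rec$r[rec$gene_id == "lin"], 1)
  expect_equal(rec$r2[rec$gene_id == "lin"], 1)
  expect_equal(rec$p[rec$gene_id == "lin"], 0)
  expect_true(rec$undefined[rec$gene_id == "flat"])
  expect_true(is.na(rec$r[rec$gene_id == "flat"]))
})

test_that("stages with too few usable samples are named in the error", {
  samples <- make_samples(c("early", "early", "medium", "medium", "medium"),
                          c(20, 22, 18, 16, 14), rep(1, 5))
  vals <- matrix(rnorm(10), 2,
                 dimnames = list(c("G1", "G2"), samples$sample_id))
  expect_error(
    stagewise_pearson(make_ds(vals), samples, "MMSE",
                      stages = c("early", "medium")),
    "stage 'early'")
})

test_that("BH adjustment matches hand values and the step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.04), 0.04)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(77)
  for (i in 1:50) {
    p <- runif(sample(1:12, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, brute_bh(p), tolerance = 1e-15)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    expect_false(is.unsorted(adj[order(p)]))
  }
})

test_that("AD-gene calling applies the two-step rule with strict thresholds", {
  rec <- data.frame(
    gene_id = c("A", "B", "C"),
    stage = "early", score_type = "MMSE", n = 7,
    r = c(0.6, sqrt(0.30), -0.99),
    r2 = c(0.36, 0.30, 0.9801),
    p = c(0.001, 0.0001, 0.00001),
    undefined = FALSE, stringsAsFactors = FALSE
  )
  out <- call_ad_genes(rec)
  recs <- out$records
  # r2 exactly at 0.30 is NOT above the strict threshold
  expect_false(recs$flagged[recs$gene_id == "B"])
  expect_true(is.na(recs$p_adj[recs$gene_id == "B"]))
  expect_true(recs$flagged[recs$gene_id == "A"])
  # clinical direction: positive r with MMSE means expression falls with
  # disease, i.e. down-regulated
  expect_equal(recs$direction[recs$gene_id == "A"], "down")
  expect_equal(recs$direction[recs$gene_id == "C"], "up")
  expect_error(call_ad_genes(rec[0, ]), "empty")
})

test_that("p_adj >= p and flag counts are monotone in the thresholds", {
  set.seed(13)
  samples <- make_samples(rep(c("early", "medium", "late"), each = 10),
                          round(runif(30, 5, 29)), runif(30, 0.2, 9))
  vals <- matrix(rnorm(200 * 30), 200,
                 dimnames = list(sprintf("G%03d", 1:200), samples$sample_id))
  # make some genes truly correlated
  vals[1:10, samples$group == "early"] <-
    rep(samples$mmse[samples$group == "early"], each = 10) * 0.3 +
    rnorm(100, 0, 0.8)
  rec <- stagewise_pearson(make_ds(vals), samples, "MMSE")
  base <- call_ad_genes(rec, r2_min = 0.3, alpha = 0.05)
  expect_true(all(base$records$p_adj >= base$records$p, na.rm = TRUE))
  # raising r2_min shrinks the set of records entering BH adjustment
  # (flag counts themselves need not be monotone in r2_min, because a
  # smaller BH family is corrected less); lowering alpha shrinks flags
  stricter_r2 <- call_ad_genes(rec, r2_min = 0.5, alpha = 0.05)
  stricter_a <- call_ad_genes(rec, r2_min = 0.3, alpha = 0.01)
  expect_lte(sum(!is.na(stricter_r2$records$p_adj)),
             sum(!is.na(base$records$p_adj)))
  expect_lte(sum(stricter_a$records$flagged), sum(base$records$flagged))
  expect_true(all(stricter_a$records$flagged <= base$records$flagged))
  # every flagged record has a direction; gene table covers exactly the
  # flagged genes
  fl <- base$records[base$records$flagged, ]
  expect_false(any(is.na(fl$direction)))
  expect_setequal(base$genes$gene_id, unique(fl$gene_id))
})

test_that("null data yields raw p-values uniform at each stage", {
  set.seed(19)
  samples <- make_samples(rep(c("early", "medium", "late"), each = 12),
                          round(runif(36, 5, 29)), runif(36, 0.2, 9))
  vals <- matrix(rnorm(1000 * 36), 1000,
                 dimnames = list(sprintf("G%04d", 1:1000),
                                 samples$sample_id))
  rec <- stagewise_pearson(make_ds(vals), samples, "MMSE")
  for (st in c("early", "medium", "late")) {
    frac <- mean(rec$p[rec$stage == st] < 0.05)
    se <- sqrt(0.05 * 0.95 / 1000)
    expect_lt(abs(frac - 0.05), 3.5 * se + 1e-12)
  }
})
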