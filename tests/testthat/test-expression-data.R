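test_that("expression matrices round-trip through plain TSV exactly", {
  x <- matrix(c(1.25, -3.5e-7, 2/3, 1e12, 0, -1), nrow = 3,
              dimnames = list(c("p1", "p2", "p3"), c("s1", "s2")))
  attr(x, "scale_tag") <- "log2"
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(x, path)
  y <- read_expression_matrix(path)
  expect_equal(unclass(y)[, ], unclass(x)[, ], tolerance = 0)
  expect_identical(dimnames(y), dimnames(x))
  # empty matrix -> header-only file
  e <- matrix(numeric(0), 0, 2, dimnames = list(NULL, c("s1", "s2")))
  write_expression_matrix(e, path)
  expect_length(readLines(path), 1)
  expect_equal(dim(read_expression_matrix(path)), c(0, 2))
})

test_that("a large synthetic matrix survives the text round trip", {
  b <- generate_study(hmx_design(), duration = 4, seed = 3,
                      signal = signal_config(n_genes = 300))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(b$expression, path)
  y <- read_expression_matrix(path)
  expect_equal(max(abs(y - b$expression)), 0)
})

test_that("format violations are reported by name", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("probe_id\ts1\ts2", "gA\t1\t2", "gA\t3\t4"), path)
  expect_error(read_expression_matrix(path), "gA")
  writeLines(c("probe_id\ts1\ts2", "gA\t1\t2", "gB\t3"), path)
  expect_error(read_expression_matrix(path), "ragged")
  # non-numeric cells become flagged missing, not errors
  writeLines(c("probe_id\ts1\ts2", "gA\tnull\t2"), path)
  expect_identical(as.vector(read_expression_matrix(path)), c(NA, 2))
})

test_that("series-matrix-like dialect skips metadata and quotes", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("!Series_title\t\"toy\"", "!Sample_count\t2",
               "\"ID_REF\"\t\"GSM1\"\t\"GSM2\"",
               "\"TA1-1\"\t7.5\t8.25", "\"TA1-2\"\t6\t5.5"), path)
  y <- read_expression_matrix(path, dialect = "series_matrix_like")
  expect_equal(dim(y), c(2, 2))
  expect_equal(unname(y["TA1-2", "GSM2"]), 5.5)
})

test_that("align_bundle restricts to the shared samples in annotation order", {
  b <- generate_study(hmx_design(), duration = 4, seed = 2,
                      signal = signal_config(n_genes = 50))
  ann <- b$annotation
  # shuffle expression columns and add an extra annotation row
  shuf <- sample(ncol(b$expression))
  expr <- b$expression[, shuf]
  extra <- ann[1, ]; extra$sample_id <- "ghost_sample"
  ann2 <- rbind(ann, extra)
  expect_message(ab <- align_bundle(expr, ann2, b$residue), "dropped 1")
  expect_identical(colnames(ab$expression), ann$sample_id)
  expect_identical(names(ab$residue), ann$sample_id)
  expect_equal(ab$expression[, ann$sample_id[3]],
               b$expression[, ann$sample_id[3]])
  # disjoint ids -> integrity error
  expr2 <- expr; colnames(expr2) <- paste0("x_", colnames(expr2))
  expect_error(align_bundle(expr2, ann, b$residue), "integrity")
})

test_that("quantile normalization matches the hand-computed 2x2 table", {
  x <- matrix(c(1, 3, 4, 2), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  attr(x, "scale_tag") <- "log2"
  q <- preprocess(x, steps = "quantile_normalize")
  # sorted-column means are (1.5, 3.5); ranks map them back per column
  expect_equal(unclass(q)[, ],
               matrix(c(1.5, 3.5, 3.5, 1.5), 2,
                      dimnames = dimnames(x))[, ])
  expect_identical(attr(q, "scale_tag"), "normalized")
})

test_that("quantile normalization is an idempotent fixed point", {
  b <- generate_study(hmx_design(), duration = 4, seed = 8,
                      signal = signal_config(n_genes = 100))
  q1 <- preprocess(b$expression, steps = "quantile_normalize")
  q2 <- preprocess(q1, steps = "quantile_normalize")
  expect_equal(q2[, ], q1[, ], tolerance = 1e-12)
  # columns that are permutations of each other become identical
  v <- c(5, 1, 3, 2, 4)
  xp <- cbind(s1 = v, s2 = rev(v), s3 = sample(v))
  rownames(xp) <- paste0("g", 1:5)
  qp <- preprocess(xp, steps = "quantile_normalize")
  # sample-wise sorted value vectors become identical (the defining property)
  expect_equal(unname(sort(qp[, 1])), unname(sort(qp[, 2])))
  expect_equal(unname(sort(qp[, 1])), unname(sort(qp[, 3])))
  expect_equal(unname(sort(qp[, 1])), sort(v))
})

test_that("median centering and missing-value handling behave as specified", {
  x <- matrix(rnorm(40), 8, 5, dimnames = list(paste0("g", 1:8), paste0("s", 1:5)))
  x[1, 1:4] <- NA   # 80% missing
  x[2, 1] <- NA     # 20% missing
  attr(x, "scale_tag") <- "log2"
  f <- preprocess(x, steps = "filter_missing", missing_threshold = 0.5)
  expect_identical(rownames(f), paste0("g", 2:8))
  m <- preprocess(f, steps = "median_center")
  expect_equal(unname(apply(m, 2, stats::median, na.rm = TRUE)), rep(0, 5))
  imp <- impute_missing(f)
  expect_false(anyNA(imp))
  expect_equal(imp[1, 1], mean(f[1, ], na.rm = TRUE))
})

test_that("log2 transform enforces scale and positivity", {
  raw <- matrix(c(2, 4, 8, 16), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  attr(raw, "scale_tag") <- "raw"
  lg <- preprocess(raw, steps = "log2")
  expect_equal(unclass(lg)[, ], log2(unclass(raw))[, ])
  expect_error(preprocess(lg, steps = "log2"), "already")
  neg <- raw; neg[1, 1] <- -1; attr(neg, "scale_tag") <- "raw"
  expect_error(preprocess(neg, steps = "log2"), "non-positive")
  ok <- preprocess(neg, steps = "log2", log_offset = 2)
  expect_equal(unname(ok[1, 1]), 0)
})

test_that("study bundles round-trip through the plain-text directory format", {
  b <- generate_study(hmx_design(), duration = 14, seed = 21,
                      signal = signal_config(n_genes = 40,
                                             n_residue_linked = 4,
                                             n_dose_responsive = 2))
  dir <- withr::local_tempdir()
  write_study_bundle(b, dir)
  b2 <- read_study_bundle(dir)
  expect_equal(b2$expression[, ], b$expression[, ])
  expect_equal(b2$residue, b$residue)
  expect_identical(b2$annotation$class_label, b$annotation$class_label)
  expect_setequal(b2$truth$residue_linked_ids, b$truth$residue_linked_ids)
})

test_that("study configs read back from YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("design:", "  compound: RDX", "  durations: [4]",
               "  concentrations: [0, 8, 16]", "  replicates: 4",
               "  include_t0: false",
               "uptake:", "  k: 0.25", "  tau: 10",
               "signal:", "  n_genes: 123"), path)
  cfg <- read_study_config(path)
  expect_identical(cfg$design$compound, "RDX")
  expect_equal(cfg$uptake$k, 0.25)
  expect_equal(cfg$signal$n_genes, 123L)
  expect_equal(cfg$signal$variance_prior_a, 3)  # default preserved
})
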