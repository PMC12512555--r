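test_that("expression TSV round-trips and rejects malformed input", {
  x <- matrix(c(0.5, 2, 7, 0, 1.25, 3), nrow = 3,
              dimnames = list(c("gA", "gB", "gC"), c("s1", "s2")))
  m <- expression_matrix(x, space = "tpm")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_expression(m, f)
  m2 <- read_expression(f, space = "tpm")
  expect_identical(dim(m2), c(3L, 2L))
  expect_equal(m2$values, m$values)
  # second write of the re-read object is byte-identical
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_expression(m2, f2)
  expect_identical(readLines(f), readLines(f2))

  lines <- readLines(f)
  dupf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(lines, lines[2]), dupf)
  expect_error(read_expression(dupf, "tpm"), "duplicate gene id")

  badf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(sub("1.25", "oops", lines, fixed = TRUE), badf)
  expect_error(read_expression(badf, "tpm"), "malformed numeric")

  negf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(sub("1.25", "-4", lines, fixed = TRUE), negf)
  expect_error(read_expression(negf, "tpm"), ">= 0")
})

test_that("log2(TPM + 1.01) transform matches exact values and inverts", {
  m <- expression_matrix(
    matrix(c(0.99, 0, 7), 3, 1, dimnames = list(c("a", "b", "c"), "s")),
    space = "tpm")
  lg <- normalize_expression(m)
  expect_identical(lg$space, "log2")
  expect_identical(lg$values["a", "s"], 1)            # log2(2) exactly
  expect_equal(lg$values["b", "s"], log2(1.01), tolerance = 1e-12)
  expect_equal(lg$values["c", "s"], log2(8.01), tolerance = 1e-12)
  expect_error(normalize_expression(lg), "double-transform")

  # round-trip recovery within 1e-9 relative tolerance, strict monotonicity
  set.seed(1)
  tpm <- matrix(stats::rexp(200, 0.2), 20,
                dimnames = list(sprintf("g%d", 1:20), sprintf("s%d", 1:10)))
  m2 <- expression_matrix(tpm, "tpm")
  back <- denormalize_expression(normalize_expression(m2), clip = FALSE)
  expect_equal(back$values, tpm, tolerance = 1e-9)
  ord <- order(tpm)
  expect_true(all(diff(normalize_expression(m2)$values[ord]) >= 0))
})

test_that("sample table validation enforces the survival contract", {
  df <- data.frame(sample_id = c("s1", "s2"), tissue = c("tumor", "normal"),
                   surv_time = c(100, NA), surv_event = c(1, NA))
  expect_s3_class(validate_sample_table(df), "SampleTable")
  df_bad <- df; df_bad$surv_event <- NULL
  expect_error(validate_sample_table(df_bad), "surv_event")
  df_neg <- df; df_neg$surv_time[1] <- -5
  expect_error(validate_sample_table(df_neg), ">= 0")
  df_dup <- df; df_dup$sample_id <- c("s1", "s1")
  expect_error(validate_sample_table(df_dup), "duplicate")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_sample_table(validate_sample_table(df), f)
  expect_equal(read_sample_table(f)$surv_time, df$surv_time)
})

test_that("gene sets and signature weights validate membership rules", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(sprintf("SF%03d", 1:167), f)
  gs <- read_gene_set(f)
  expect_length(gs$members, 167)
  expect_error(gene_set(character(0)), "empty")
  expect_error(gene_set(c("a", "a")), "duplicate")

  wf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tweight", "g1\t0.5", "g2\t-0.2", "g1\t0.1"), wf)
  expect_error(read_weights(wf), "uniquely named")
  writeLines(c("gene_id\tweight", "g1\t0.5", "g2\t0.5"), wf)
  expect_error(read_weights(wf), "distinct")
  writeLines(c("gene_id\tweight", "g1\t0.5", "g2\t-0.2"), wf)
  expect_equal(as.numeric(read_weights(wf)), c(0.5, -0.2))
})

test_that("event tables parse paired count columns and enforce integrality", {
  tab <- make_event_table(inc1 = c(10, 12), skip1 = c(3, 4),
                          inc2 = c(5, 6), skip2 = c(8, 9),
                          tpm = matrix(c(2, 3), 1, dimnames = list("ev1", c("g1", "g2"))))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_event_table(tab, f)
  tab2 <- read_event_table(f)
  expect_identical(tab2$inc["ev1", "A1"], 10L)
  expect_identical(tab2$skip["ev1", "A1"], 3L)
  expect_equal(tab2$tpm["ev1", "g2"], 3)

  lines <- readLines(f)
  badf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(sub("\t12\t", "\t12.5\t", lines), badf)
  expect_error(read_event_table(badf), "non-negative integers")
  mis <- withr::local_tempfile(fileext = ".tsv")
  writeLines(sub("event_id", "evt", lines), mis)
  expect_error(read_event_table(mis), "missing column")
})
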