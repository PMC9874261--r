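test_that("loadUmiCsv round-trips a matrix and validates input", {
  mats <- toy_allele_matrices()
  path <- withr::local_tempfile(fileext = ".csv")
  write_toy_umi_csv(mats$cast, path)
  se <- loadUmiCsv(path, allele = "cast")
  expect_equal(SummarizedExperiment::assay(se, "counts"), mats$cast)
  expect_equal(unique(se$allele), "cast")
  # write + reload is the identity
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeUmiCsv(se, path2)
  expect_equal(SummarizedExperiment::assay(loadUmiCsv(path2), "counts"),
               mats$cast)
  expect_error(loadUmiCsv(file.path(tempdir(), "nope.csv")), "not found")
})

test_that("loadUmiCsv rejects duplicates and invalid counts", {
  bad <- toy_allele_matrices()$cast
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(gene = c("g1", "g1", "g3", "g4"), bad,
                   check.names = FALSE)
  data.table::fwrite(df, path)
  expect_error(loadUmiCsv(path), "duplicate gene ids: g1")
  df2 <- data.frame(gene = rownames(bad), bad, check.names = FALSE)
  df2[2, "cell3"] <- -1
  data.table::fwrite(df2, path)
  expect_error(loadUmiCsv(path), "gene 'g2', cell 'cell3'")
})

test_that("qcFilter matches the hand-computed survivor sets", {
  mats <- toy_allele_matrices()
  cast <- qcFilter(mats$cast, minCells = 2, minGenes = 2, minMean = 1)
  expect_equal(rownames(cast), c("g1", "g2", "g4"))
  expect_equal(colnames(cast), c("cell1", "cell2", "cell3"))
  rep_cast <- attr(cast, "qc_report")
  expect_equal(rep_cast$dropped, c(1L, 1L, 0L))  # g3, cell4, none
  c57 <- qcFilter(mats$c57, minCells = 2, minGenes = 2, minMean = 1)
  expect_equal(rownames(c57), c("g1", "g2", "g3"))
  expect_equal(colnames(c57), paste0("cell", 1:4))
  expect_equal(attr(c57, "qc_report")$dropped, c(0L, 0L, 1L))  # g4
  expect_error(qcFilter(mats$cast, minCells = 5, minGenes = 1,
                        minMean = 1), "survive")
})

test_that("qcFilter is idempotent on its own output", {
  mats <- toy_allele_matrices()
  for (m in mats) {
    once <- qcFilter(m, minCells = 2, minGenes = 2, minMean = 1)
    twice <- qcFilter(once, minCells = 2, minGenes = 2, minMean = 1)
    attr(once, "qc_report") <- attr(twice, "qc_report") <- NULL
    expect_identical(once, twice)
  }
})

test_that("qcPipeline intersects alleles and merges cells", {
  mats <- toy_allele_matrices()
  se <- qcPipeline(mats$cast, mats$c57, minCells = 2, minGenes = 2,
                   minMean = 1, tailQ = 0)
  expect_equal(rownames(se), c("g1", "g2"))   # survive both alleles
  expect_equal(colnames(se),
               c(paste0("cell", 1:3, "_cast"), paste0("cell", 1:4, "_c57")))
  expect_equal(se$allele, c(rep("cast", 3), rep("c57", 4)))
  expect_equal(unname(SummarizedExperiment::assay(se, "counts")["g1", ]),
               c(5, 6, 7, 4, 5, 8, 6))
  expect_true(all(SummarizedExperiment::assay(se, "keep")))  # tailQ = 0
  report <- S4Vectors::metadata(se)$qc_report
  expect_setequal(unique(report$allele), c("cast", "c57"))
})

test_that("the upper-tail mask drops only counts above the quantile", {
  mats <- toy_allele_matrices()
  se <- qcPipeline(mats$cast, mats$c57, minCells = 2, minGenes = 2,
                   minMean = 1, tailQ = 0.25)
  keep <- SummarizedExperiment::assay(se, "keep")
  # g1 merged row (5,6,7,4,5,8,6): type-1 quantile at 0.75 is 7 -> mask the 8
  expect_equal(unname(keep["g1", ]), c(rep(TRUE, 5), FALSE, TRUE))
  # g2 merged row (3,4,2,2,3,3,4): quantile 4 -> nothing masked
  expect_true(all(keep["g2", ]))
})

test_that("qcPipeline is idempotent on its surviving submatrices", {
  mats <- toy_allele_matrices()
  se <- qcPipeline(mats$cast, mats$c57, minCells = 2, minGenes = 2,
                   minMean = 1, tailQ = 0)
  m <- SummarizedExperiment::assay(se, "counts")
  cast2 <- m[, se$allele == "cast"]
  c572 <- m[, se$allele == "c57"]
  colnames(cast2) <- sub("_cast$", "", colnames(cast2))
  colnames(c572) <- sub("_c57$", "", colnames(c572))
  se2 <- qcPipeline(cast2, c572, minCells = 2, minGenes = 2,
                    minMean = 1, tailQ = 0)
  expect_equal(SummarizedExperiment::assay(se2, "counts"), m)
})
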