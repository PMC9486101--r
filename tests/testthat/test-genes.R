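# synthetic single-chromosome annotation fixtures, built in code
make_marker_table <- function() {
  data.frame(marker = c("mL", "mR", "mX", "m2"),
             chromosome = c("chr1", "chr1", "chr2", "chr1"),
             pos_bp = c(1000000, 2000000, 500000, 3000000),
             stringsAsFactors = FALSE)
}

make_genes <- function() {
  data.frame(gene_id = sprintf("gene%02d", 1:6),
             chromosome = c(rep("chr1", 5), "chr2"),
             start_bp = c(900000, 1100000, 1500000, 1990000, 2500000,
                          100000),
             end_bp   = c(1050000, 1200000, 1600000, 2100000, 2600000,
                          200000),
             description = "synthetic gene model",
             stringsAsFactors = FALSE)
}

make_expression <- function() {
  data.frame(gene_id = rep(sprintf("gene%02d", 1:6), each = 2),
             condition = rep(c("drought", "control"), 6),
             tpm = c(5, 1, 3, 9, 0.5, 0.2, 4.2, 1, 2, 2, 8, 8),
             stringsAsFactors = FALSE)
}

test_that("flanking markers define a normalized physical interval", {
  tab <- make_marker_table()
  ivl <- mqtl_physical_interval("mL", "mR", tab)
  expect_equal(ivl, list(chromosome = "chr1", start_bp = 1000000,
                         end_bp = 2000000))
  # reverse order normalizes ascending
  expect_equal(mqtl_physical_interval("mR", "mL", tab), ivl)
  expect_warning(expect_null(mqtl_physical_interval("mL", "absent", tab)),
                 "absent")
  expect_warning(expect_null(mqtl_physical_interval("mL", "mX", tab)),
                 "different chromosomes")
})

test_that("gene-interval queries use the any-overlap rule", {
  genes <- make_genes()
  ivl <- list(chromosome = "chr1", start_bp = 1000000, end_bp = 2000000)
  hit <- genes_in_interval(ivl, genes)
  # gene01 [0.9-1.05 Mb] straddles the start; gene04 [1.99-2.1 Mb] the end
  expect_equal(hit$gene_id, c("gene01", "gene02", "gene03", "gene04"))
  expect_true(all(diff(hit$start_bp) >= 0))
  # brute-force oracle over all genes
  brute <- genes$gene_id[genes$chromosome == "chr1" &
                           genes$start_bp <= 2000000 &
                           genes$end_bp >= 1000000]
  expect_setequal(hit$gene_id, brute)
})

test_that("GFF3 annotations round-trip through the reader", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsynthetic\tgene\t900000\t1050000\t.\t+\t.\tID=gene01;description=synthetic gene model",
    "chr1\tsynthetic\tmRNA\t900000\t1050000\t.\t+\t.\tID=t1;Parent=gene01",
    "chr1\tsynthetic\tgene\t1100000\t1200000\t.\t-\t.\tID=gene02"
  ), gff)
  g <- read_genes_gff3(gff)
  expect_equal(nrow(g), 2)       # mRNA feature excluded
  expect_equal(g$gene_id, c("gene01", "gene02"))
  expect_equal(g$start_bp, c(900000, 1100000))
  expect_equal(g$end_bp[1], 1050000)
})

test_that("the expression filter is strict and maximizes over conditions", {
  genes <- make_genes()
  expr <- make_expression()
  kept <- filter_expressed(genes, expr, threshold = 3)
  # gene02 has tpm exactly 3 under drought and 9 under control: kept via 9
  expect_true("gene02" %in% kept$gene_id)
  expect_equal(kept$max_tpm[kept$gene_id == "gene02"], 9)
  # strictly-greater boundary: a gene whose max tpm is exactly 3 is dropped
  expr3 <- data.frame(gene_id = "gene05", condition = "drought", tpm = 3)
  expect_equal(nrow(filter_expressed(genes, expr3, threshold = 3)), 0)
  # sorted by descending tpm
  expect_true(all(diff(kept$max_tpm) <= 0))
  # condition restriction
  only_drought <- filter_expressed(genes, expr, threshold = 3,
                                   conditions = "drought")
  expect_false("gene02" %in% only_drought$gene_id)  # 9 was under control
  # empty expression -> empty result
  expect_equal(nrow(filter_expressed(genes, expr[0, ], 3)), 0)
  # monotone nonincreasing in the threshold
  n_prev <- Inf
  for (th in c(0.1, 1, 3, 5, 10)) {
    n_th <- nrow(filter_expressed(genes, expr, th))
    expect_lte(n_th, n_prev)
    n_prev <- n_th
  }
})

test_that("the candidate-gene driver joins MQTL, annotation and expression", {
  mqtl <- data.frame(mqtl_id = c("MQ1", "MQ2"),
                     left_marker = c("mL", "mL"),
                     right_marker = c("mR", "missing"),
                     stringsAsFactors = FALSE)
  res <- candidate_genes(mqtl, make_marker_table(), make_genes(),
                         make_expression(), threshold = 3,
                         conditions = "drought")
  expect_true(all(res$mqtl_id == "MQ1"))   # MQ2 has no physical interval
  expect_true(all(res$max_tpm > 3))
  expect_setequal(res$gene_id, c("gene01", "gene04"))
})
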