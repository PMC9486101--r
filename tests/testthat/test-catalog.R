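test_that("well-formed files ingest row-for-row with no rejections", {
  path <- write_tsv_tmp(make_catalog_df())
  cat <- read_catalog(path)
  expect_s3_class(cat, "qtl_catalog")
  expect_equal(nrow(cat), 3)
  expect_equal(nrow(attr(cat, "rejections")), 0)
  expect_equal(cat$qtl_id, c("q1", "q2", "q3"))
})

test_that("invalid rows become machine-readable rejections", {
  df <- make_catalog_df()
  df$pve[2] <- 1.5
  cat <- as_qtl_catalog(df)
  expect_equal(nrow(cat), 2)
  rej <- attr(cat, "rejections")
  expect_equal(rej$qtl_id, "q2")
  expect_equal(rej$reason_code, "pve_out_of_range")

  df2 <- make_catalog_df()
  df2$peak_cm <- as.character(df2$peak_cm)
  df2$peak_cm[1] <- "abc"
  cat2 <- as_qtl_catalog(df2)
  expect_equal(nrow(cat2), 2)
  expect_equal(attr(cat2, "rejections")$reason_code, "unparseable_numeric")

  df3 <- make_catalog_df()
  df3$ci_lo_cm[1] <- 60   # above ci_hi
  cat3 <- as_qtl_catalog(df3)
  expect_equal(attr(cat3, "rejections")$reason_code, "ci_reversed")
})

test_that("missing mandatory columns are a hard error naming the column", {
  df <- make_catalog_df()
  path <- write_tsv_tmp(df[, setdiff(names(df), "pve")])
  expect_error(read_catalog(path), "pve")
})

test_that("percent-scale PVE files are normalized to proportion with a log entry", {
  df <- make_catalog_df()
  df$pve <- c(12, 8, 20)   # whole file on the percent scale
  cat <- as_qtl_catalog(df)
  expect_equal(cat$pve, c(0.12, 0.08, 0.2))
  expect_equal(nrow(attr(cat, "conversions")), 3)
  # a stray > 1 value in a proportion-scale file is rejected, not rescaled
  df2 <- make_catalog_df()
  df2$pve[2] <- 1.5
  cat2 <- as_qtl_catalog(df2)
  expect_equal(attr(cat2, "rejections")$reason_code, "pve_out_of_range")
})

test_that("a catalog with the 25-study structure reproduces per-study counts", {
  studies <- utils::read.delim(table_fixture("table2_studies.tsv"),
                               stringsAsFactors = FALSE)
  expect_equal(nrow(studies), 25)
  rows <- do.call(rbind, lapply(seq_len(nrow(studies)), function(i) {
    s <- studies[i, ]
    data.frame(qtl_id = sprintf("%s_q%02d", s$study_id, seq_len(s$n_qtl)),
               study_id = s$study_id, pop_type = s$pop_type,
               pop_size = s$pop_size, trait = "TGW", regime = "rainfed",
               chromosome = "1A", map_id = s$study_id, peak_cm = 10,
               ci_lo_cm = NA, ci_hi_cm = NA, lod = 3, pve = 0.1,
               stringsAsFactors = FALSE)
  }))
  cat <- read_catalog(write_tsv_tmp(rows))
  expect_equal(nrow(attr(cat, "rejections")), 0)
  counts <- table(cat$study_id)
  expect_equal(unname(counts[studies$study_id]), studies$n_qtl,
               ignore_attr = TRUE)
  expect_equal(unname(counts[["S10"]]), 64)  # Kofa x Svevo
})

test_that("inclusion screening applies the four criteria and imputes midpoints", {
  df <- make_catalog_df()
  df$lod[1] <- NA
  df$peak_cm[3] <- NA   # CI present -> midpoint imputation
  v <- validate_inclusion(as_qtl_catalog(df))
  expect_false(v$included[1])
  expect_equal(v$exclusion_reason[1], "no_lod")
  expect_true(v$included[2])
  expect_true(v$included[3])
  expect_equal(v$peak_cm[3], 30)  # midpoint of [25, 35]

  df2 <- make_catalog_df()
  df2$peak_cm[2] <- NA  # no CI either
  v2 <- validate_inclusion(as_qtl_catalog(df2))
  expect_equal(v2$exclusion_reason[2], "no_position")
})

test_that("CI width formulas are exact and monotone in N and R2", {
  expect_equal(estimate_ci_width("RIL", 163, 1.0), 1.0)
  expect_equal(estimate_ci_width("F2", 106, 0.05), 100.0)
  expect_equal(estimate_ci_width("DH", 287, 0.5), 2.0)
  # nearest-design mapping
  expect_equal(estimate_ci_width("F2:3", 100, 0.1),
               estimate_ci_width("F2", 100, 0.1))
  expect_equal(estimate_ci_width("MAGIC", 100, 0.1),
               estimate_ci_width("RIL", 100, 0.1))
  # strict monotonicity on a grid
  for (pt in c("RIL", "DH", "F2", "BC")) {
    ns <- seq(50, 500, by = 50)
    w_n <- estimate_ci_width(pt, ns, 0.1)
    expect_true(all(diff(w_n) < 0))
    r2s <- seq(0.05, 1, by = 0.05)
    w_r <- estimate_ci_width(pt, 150, r2s)
    expect_true(all(diff(w_r) < 0))
  }
  expect_error(estimate_ci_width("RIL", 1, 0.1), "size")
  expect_error(estimate_ci_width("RIL", 100, 0), "r2")
  expect_error(estimate_ci_width("NIL", 100, 0.1), "pop_type")
})

test_that("missing CIs are materialized symmetrically, clipped, idempotently", {
  df <- make_catalog_df()  # q2 has no CI: RIL, N = 150, pve = 0.08
  cat <- fill_missing_ci(as_qtl_catalog(df))
  expect_equal(cat$ci_lo_cm[1], 45)  # reported CI untouched
  expect_equal(cat$ci_hi_cm[1], 55)
  w <- 163 / (150 * 0.08)
  expect_equal(cat$ci_lo_cm[2], 80 - w / 2)
  expect_equal(cat$ci_hi_cm[2], 80 + w / 2)
  expect_true(cat$ci_from_formula[2])
  expect_false(cat$ci_from_formula[1])
  # the worked instance: RIL, N = 100, R2 = 0.1, peak 50 -> [41.85, 58.15]
  df2 <- make_catalog_df()[1, ]
  df2$ci_lo_cm <- df2$ci_hi_cm <- NA
  df2$pop_size <- 100; df2$pve <- 0.1; df2$peak_cm <- 50
  c2 <- fill_missing_ci(as_qtl_catalog(df2))
  expect_equal(c(c2$ci_lo_cm, c2$ci_hi_cm), c(41.85, 58.15))
  # clipping at zero: BC, N = 530, R2 = 1 -> width 1, peak 0.2
  df3 <- make_catalog_df()[1, ]
  df3$pop_type <- "BC"; df3$pop_size <- 530; df3$pve <- 1
  df3$peak_cm <- 0.2; df3$ci_lo_cm <- df3$ci_hi_cm <- NA
  c3 <- fill_missing_ci(as_qtl_catalog(df3))
  expect_equal(c(c3$ci_lo_cm, c3$ci_hi_cm), c(0, 0.7))
  # idempotence
  again <- fill_missing_ci(cat)
  expect_equal(again$ci_lo_cm, cat$ci_lo_cm)
  expect_equal(again$ci_hi_cm, cat$ci_hi_cm)
})

test_that("catalog summaries conserve counts and average correctly", {
  df <- make_catalog_df()
  df$ci_lo_cm <- c(50, 75, 20)
  df$ci_hi_cm <- c(50, 85, 40)   # widths 0, 10, 20
  df$peak_cm <- c(50, 80, 30)
  s <- summarize_catalog(as_qtl_catalog(df))
  expect_equal(unname(s$ci_width["mean"]), 10)
  expect_equal(sum(s$by_chromosome), s$n)
  expect_equal(sum(s$by_trait), s$n)
  expect_equal(sum(s$by_regime), s$n)
  df2 <- make_catalog_df()[1:2, ]
  df2$pve <- c(0.1, 0.3)
  expect_equal(unname(summarize_catalog(as_qtl_catalog(df2))$pve["mean"]),
               0.2)
  expect_error(summarize_catalog(as_qtl_catalog(make_catalog_df()[0, ])),
               "empty")
})

test_that("catalogs round-trip through write/read bit-identically", {
  cat <- as_qtl_catalog(make_catalog_df())
  path <- tempfile(fileext = ".tsv")
  write_catalog(cat, path)
  back <- read_catalog(path)
  for (col in names(cat))
    expect_equal(back[[col]], cat[[col]], info = col)
})
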