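test_that("map files are read sorted and duplicate conflicts rejected", {
  df <- data.frame(marker = c("b", "a", "c"), chromosome = "1A",
                   pos_cm = c(20, 10, 5))
  path <- write_tsv_tmp(df)
  m <- read_map(path)
  expect_equal(nrow(m), 3)
  expect_equal(m$marker, c("c", "a", "b"))   # sorted by position
  df2 <- rbind(df, data.frame(marker = "a", chromosome = "1A", pos_cm = 99))
  expect_error(read_map(write_tsv_tmp(df2)), "conflicting")
})

test_that("anchor search returns the tightest bracketing shared pair", {
  src <- make_map("1A", 100, 5, map_id = "src")
  cons <- make_map("1A", 100, 5, map_id = "cons")
  a <- shared_anchor_pair(src, cons, "1A", 12)
  expect_equal(a$s, c(10, 15))
  # only a subset shared: markers at 5, 15, 30
  keep <- src$pos_cm %in% c(5, 15, 30)
  src2 <- as_genetic_map(as.data.frame(src)[keep, ], "src2")
  a2 <- shared_anchor_pair(src2, cons, "1A", 16)
  expect_equal(a2$s, c(15, 30))   # tightest bracketing pair
  # peak outside the span of shared markers -> none
  expect_null(shared_anchor_pair(src2, cons, "1A", 40))
  expect_null(shared_anchor_pair(src2, cons, "1A", 2))
  # exact hit anchors to the marker itself
  a3 <- shared_anchor_pair(src2, cons, "1A", 15)
  expect_equal(a3$left, a3$right)
  expect_equal(project_position(15, a3), 15)
})

test_that("homothetic rescaling is exact, identity-preserving, order-preserving", {
  anchors <- list(left = "L", right = "R", s = c(10, 20), c = c(100, 120))
  expect_equal(project_position(12, anchors), 104)
  expect_equal(project_position(10, anchors), 100)  # at the left anchor
  id <- list(left = "L", right = "R", s = c(10, 20), c = c(10, 20))
  for (p in c(10, 13.7, 20)) expect_equal(project_position(p, id), p)
  # order preservation on one anchor pair
  ps <- sort(runif(20, 10, 20))
  proj <- vapply(ps, project_position, 0, anchors = anchors)
  expect_true(all(diff(proj) >= 0))
})

test_that("projection of a catalog handles identity, stretch, ceiling, rejection", {
  cons <- make_map("1A", 200, 5, map_id = "consensus")
  src <- cons
  attr(src, "map_id") <- "s1"
  df <- make_catalog_df()[1, ]
  df$chromosome <- "1A"; df$map_id <- "s1"
  df$peak_cm <- 50; df$ci_lo_cm <- 41.85; df$ci_hi_cm <- 58.15
  cat <- validate_inclusion(as_qtl_catalog(df))
  p <- project_qtl(cat, list(s1 = src), cons)
  expect_equal(p$status, "projected")
  expect_equal(p$cons_peak_cm, 50)
  expect_equal(p$cons_ci_lo_cm, 41.85)
  expect_equal(p$cons_ci_hi_cm, 58.15)
  # 2x stretch: consensus positions doubled
  cons2 <- as_genetic_map(within(as.data.frame(cons),
                                 pos_cm <- pos_cm * 2), "consensus")
  p2 <- project_qtl(cat, list(s1 = src), cons2)
  expect_equal(p2$cons_peak_cm, 100)
  expect_equal(p2$cons_ci_hi_cm - p2$cons_ci_lo_cm, 2 * (58.15 - 41.85))
  # large-CI ceiling
  p3 <- project_qtl(cat, list(s1 = src), cons2, max_ci_cm = 30)
  expect_equal(p3$status, "rejected_large_ci")
  # no shared markers
  src_alien <- make_map("1A", 200, 5, map_id = "s1", prefix = "other")
  p4 <- project_qtl(cat, list(s1 = src_alien), cons)
  expect_equal(p4$status, "rejected_no_shared_markers")
})

test_that("projecting a map onto itself is the identity within 1e-9", {
  set.seed(42)
  m <- make_map("3B", 150, 7, map_id = "m")
  for (pos in runif(10, 0, 150)) {
    a <- shared_anchor_pair(m, m, "3B", pos)
    expect_lt(abs(project_position(pos, a) - pos), 1e-9)
  }
})

test_that("A->B->A composition through shared anchors recovers positions", {
  set.seed(7)
  mapA <- make_map("2A", 120, 4, map_id = "A")
  # B: monotone distortion of A with the same markers
  dfB <- as.data.frame(mapA)
  dfB$pos_cm <- dfB$pos_cm * 1.3 + cumsum(runif(nrow(dfB), 0, 0.3))
  dfB$pos_cm <- sort(dfB$pos_cm)
  mapB <- as_genetic_map(dfB, "B")
  for (pos in runif(10, 5, 115)) {
    ab <- shared_anchor_pair(mapA, mapB, "2A", pos)
    posB <- project_position(pos, ab)
    ba <- shared_anchor_pair(mapB, mapA, "2A", posB)
    expect_lt(abs(project_position(posB, ba) - pos), 1e-6)
  }
})
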