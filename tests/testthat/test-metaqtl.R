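make_obs <- function(x, s, study = NULL, trait = "TGW") {
  n <- length(x)
  data.frame(qtl_id = sprintf("q%d", seq_len(n)),
             study_id = if (is.null(study)) sprintf("s%d", seq_len(n))
                        else study,
             trait = trait, x = x, s = s, stringsAsFactors = FALSE)
}

test_that("MQTL admission needs two QTL from two studies", {
  cons <- make_map("1A", 100, 1)
  obs <- make_obs(c(10, 11), c(1, 1), study = c("s1", "s1"))
  model <- fit_mixture(obs$x, obs$s, K = 1)
  cr <- build_mqtl(obs, model, cons, "1A", "irrigated")
  expect_equal(nrow(cr$mqtl), 0)
  expect_equal(nrow(cr$singletons), 2)
  # same positions, two studies -> one MQTL
  obs2 <- make_obs(c(10, 11), c(1, 1), study = c("s1", "s2"))
  cr2 <- build_mqtl(obs2, model, cons, "1A", "irrigated")
  expect_equal(nrow(cr2$mqtl), 1)
  expect_equal(cr2$mqtl$mqtl_id, "YIELD_MQTL1A.1_I")
})

test_that("MQTL peak and CI follow precision-weighted pooling", {
  cons <- make_map("2B", 100, 1)
  obs <- make_obs(c(10, 11, 12), c(1, 1, 1),
                  study = c("s1", "s2", "s3"))
  model <- fit_mixture(obs$x, obs$s, K = 1)
  cr <- build_mqtl(obs, model, cons, "2B", "rainfed")
  expect_equal(cr$mqtl$peak_cm, 11)
  expect_equal(cr$mqtl$ci95_width_cm, 3.92 / sqrt(3))
  expect_equal(cr$mqtl$mqtl_id, "YIELD_MQTL2B.1_D")
  # precision-sum inequality: MQTL CI never wider than its narrowest member
  set.seed(13)
  for (rep in 1:5) {
    n <- sample(3:8, 1)
    o <- make_obs(rnorm(n, 40, 1), runif(n, 0.5, 4))
    m <- fit_mixture(o$x, o$s, K = 1)
    cr <- build_mqtl(o, m, cons, "2B", "rainfed")
    expect_lte(cr$mqtl$ci95_width_cm, min(3.92 * o$s))
  }
})

test_that("flanking markers bracket the MQTL confidence interval", {
  cons <- make_map("2B", 100, 10, prefix = "mk")
  obs <- make_obs(c(44, 46, 48), c(1, 1, 1))
  model <- fit_mixture(obs$x, obs$s, K = 1)
  cr <- build_mqtl(obs, model, cons, "2B", "rainfed")
  cm <- as.data.frame(cons)
  lo <- cr$mqtl$ci_lo_cm; hi <- cr$mqtl$ci_hi_cm
  expect_lte(cm$pos_cm[cm$marker == cr$mqtl$left_marker], lo)
  expect_gte(cm$pos_cm[cm$marker == cr$mqtl$right_marker], hi)
})

test_that("regime runs switch analysis paths at ten QTL per chromosome", {
  cons <- make_map("1A", 200, 1)
  mk <- function(n) {
    set.seed(n)
    data.frame(qtl_id = sprintf("q%d", 1:n),
               study_id = sprintf("s%d", rep(1:5, length.out = n)),
               trait = "TGW", regime = "rainfed", chromosome = "1A",
               status = "projected",
               cons_peak_cm = runif(n, 20, 180),
               cons_ci_lo_cm = NA, cons_ci_hi_cm = NA,
               stringsAsFactors = FALSE) |>
      transform(cons_ci_lo_cm = cons_peak_cm - 5,
                cons_ci_hi_cm = cons_peak_cm + 5)
  }
  r9 <- run_regime(mk(9), cons, "rainfed", seed = 1)
  expect_equal(r9[["1A"]]$model$method, "partition")
  r11 <- run_regime(mk(11), cons, "rainfed", seed = 1)
  expect_equal(r11[["1A"]]$model$method, "mixture")
})

test_that("members and singletons always partition the observations", {
  for (seed in c(2, 9)) {
    sim <- simulate_dataset(seed = seed, n_chrom = 2, length_cm = 150,
                            n_qtl_total = 80)
    fit <- metaqtl(sim$projected, sim$consensus, seed = seed)
    for (rg in names(fit$results)) for (cr in fit$results[[rg]]) {
      n_members <- sum(!is.na(cr$members))
      expect_equal(n_members + nrow(cr$singletons), cr$n)
      expect_equal(sum(cr$mqtl$n_qtl), n_members)
      expect_true(all(cr$singletons$reason %in%
                        c("no_overlap", "multi_overlap", "peak_outside")))
    }
  }
})

test_that("a two-cluster chromosome is recovered within 2 cM", {
  set.seed(77)
  truth_pos <- c(50, 90)   # separation 40 cM
  x <- c(rnorm(10, truth_pos[1], 1), rnorm(10, truth_pos[2], 1))
  ciw <- rep(3 * 3.92, 20)  # s ~ 3
  cons <- make_map("5B", 150, 1)
  proj <- data.frame(qtl_id = sprintf("q%d", 1:20),
                     study_id = sprintf("s%d", rep(1:5, 4)),
                     trait = "TGW", regime = "rainfed", chromosome = "5B",
                     status = "projected", cons_peak_cm = x,
                     cons_ci_lo_cm = x - ciw / 2,
                     cons_ci_hi_cm = x + ciw / 2,
                     stringsAsFactors = FALSE)
  res <- run_regime(proj, cons, "rainfed", seed = 4)
  mq <- res[["5B"]]$mqtl
  expect_equal(nrow(mq), 2)
  expect_lt(max(abs(sort(mq$peak_cm) - truth_pos)), 2)
})

test_that("fits are deterministic given the seed", {
  sim <- simulate_dataset(seed = 5, n_chrom = 1, length_cm = 120,
                          n_qtl_total = 40)
  f1 <- metaqtl(sim$projected, sim$consensus, seed = 11)
  f2 <- metaqtl(sim$projected, sim$consensus, seed = 11)
  expect_identical(f1$mqtl, f2$mqtl)
})

test_that("metaqtl objects support the standard S3 generics", {
  sim <- simulate_dataset(seed = 21, n_chrom = 1, length_cm = 120,
                          n_qtl_total = 40)
  fit <- metaqtl(sim$projected, sim$consensus, seed = 21)
  expect_output(print(fit), "Meta-QTL fit")
  s <- summary(fit)
  expect_s3_class(s, "summary.metaqtl")
  expect_output(print(s), "MQTL")
  cf <- coef(fit)
  expect_true(all(c("mqtl_id", "peak_cm") %in% names(cf)))
  pdf(NULL)
  expect_silent(plot(fit))
  dev.off()
})
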