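# hand-built phenotype tables with known composition
.pheno_table <- function(n_gfp, n_red, n_white, sex = "male", replicate = 1) {
  n <- n_gfp + n_red + n_white
  data.frame(replicate = replicate,
             sex = rep(sex, n),
             eye = c(rep("white", n_gfp), rep("red", n_red),
                     rep("white", n_white)),
             body = "brown",
             gfp = c(rep(TRUE, n_gfp), rep(FALSE, n_red + n_white)),
             rfp = FALSE)
}

test_that("the 50% normalization arithmetic decodes phenotype counts", {
  # 75% GFP+, 25% red GFP-: homing 50, cleavage 50, r2 0
  tbl <- .pheno_table(n_gfp = 75, n_red = 25, n_white = 0)
  e <- estimate_frequencies(tbl, "w-")
  expect_equal(e$mean[e$quantity == "homing"], 50)
  expect_equal(e$mean[e$quantity == "cleavage_w"], 50)
  expect_equal(e$mean[e$quantity == "r2_w"], 0)
  # all progeny GFP+: homing 100
  e2 <- estimate_frequencies(.pheno_table(100, 0, 0), "w-")
  expect_equal(e2$mean[e2$quantity == "homing"], 100)
  # per-replicate values land in [0, 100] after clamping
  expect_true(all(unlist(e$values) >= 0 & unlist(e$values) <= 100))
})

test_that("w+ father designs decode from sons and demand male rows", {
  tbl <- .pheno_table(60, 30, 10, sex = "female")
  expect_error(estimate_frequencies(tbl, "w+"), "male progeny")
  tbl$sex <- "male"
  e <- estimate_frequencies(tbl, "w+")
  expect_equal(e$mean[e$quantity == "homing"], 20)
  expect_equal(e$mean[e$quantity == "r2_w"], 20)
})

test_that("estimates recover a known gamete composition at scale", {
  # generating partition of the cleavable half: homing .6 / r2 .3 / intact .1
  p <- fit_preset_from_observed(60, 30, intact = 10)
  n <- 1e5
  gd <- make_gamete_distribution(f1_female(1, "vas"), p)
  set.seed(52)
  draw <- sample(seq_len(nrow(gd)), n, replace = TRUE, prob = gd$prob)
  tbl <- data.frame(replicate = 1, sex = "male",
                    eye = ifelse(gd$w[draw] %in% c("w+", "wR1"), "red", "white"),
                    body = "brown",
                    gfp = gd$w[draw] == "wGDE", rfp = FALSE)
  e <- estimate_frequencies(tbl, "w-")
  expect_lt(abs(e$mean[e$quantity == "homing"] - 60), 1)
  expect_lt(abs(e$mean[e$quantity == "r2_w"] - 30), 1)
  expect_lt(abs(e$mean[e$quantity == "intact_w"] - 10), 1)
})

test_that("replicate summaries use the sample definition", {
  s <- summarize_replicates(c(10, 10, 10))
  expect_equal(s$mean, 10); expect_equal(s$sd, 0)
  expect_equal(summarize_replicates(c(11.2, 13.2, 18.6, 36.7))$mean, 19.925)
  a <- 3.7; b <- 9.1
  expect_equal(summarize_replicates(c(a, b))$sd, abs(a - b) / sqrt(2))
  expect_true(is.na(summarize_replicates(5)$sd))
})

test_that("the pooled-variance t-test matches closed form and references", {
  r <- ttest_equal_var(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r$t, -1.224745, tolerance = 1e-6)
  expect_equal(r$df, 4)
  same <- ttest_equal_var(c(2, 4), c(2, 4))
  expect_equal(same$t, 0); expect_equal(same$p, 1)
  deg <- ttest_equal_var(c(1, 1), c(2, 2))
  expect_true(deg$degenerate); expect_equal(deg$p, 0)
  # independent route: stats::t.test with equal variance
  set.seed(53)
  for (i in 1:10) {
    a <- rnorm(sample(3:8, 1), mean = runif(1, 0, 5))
    b <- rnorm(sample(3:8, 1), mean = runif(1, 0, 5))
    ref <- stats::t.test(a, b, var.equal = TRUE)
    r <- ttest_equal_var(a, b)
    expect_equal(r$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(r$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("the t-test p value agrees with a permutation oracle", {
  set.seed(54)
  a <- rnorm(12, 0.0); b <- rnorm(12, 0.8)
  obs <- ttest_equal_var(a, b)
  pool <- c(a, b)
  n_perm <- 1e4
  tstat <- replicate(n_perm, {
    idx <- sample(length(pool), length(a))
    ttest_equal_var(pool[idx], pool[-idx])$t
  })
  p_perm <- mean(abs(tstat) >= abs(obs$t))
  mc_err <- 3 * sqrt(p_perm * (1 - p_perm) / n_perm)
  expect_lt(abs(obs$p - p_perm), mc_err + 0.02)
})

test_that("frequency inversion reproduces its worked examples", {
  p <- fit_preset_from_observed(60, 30, intact = 10)
  expect_equal(p$c_germ_w, 0.9)
  expect_equal(p$h, 2 / 3)
  expect_equal(fit_preset_from_observed(0, 0, intact = 100)$c_germ_w, 0)
  p2 <- fit_preset_from_observed(59.3, 38.7, intact = 2.0)
  expect_equal(p2$c_germ_w, 0.980)
  expect_equal(p2$h, 0.605, tolerance = 1e-3)
  expect_error(fit_preset_from_observed(40, 30, intact = 40), "at most 100")
  expect_error(fit_preset_from_observed(10, 50, intact = 40,
                                        context = "embryonic"),
               "infeasible")
  pe <- fit_preset_from_observed(0, 80, intact = 20, context = "embryonic")
  expect_equal(pe$c_emb_w, 0.8)
  expect_equal(pe$c_germ_w, 0)
})

test_that("fit -> simulate -> estimate round trips for all four presets", {
  for (prom in promoters()) {
    sl <- REG[[prom]]$maternal
    m <- f1_female(1, prom)
    tbl <- run_cross(cross_spec(m, tester_male("w-"), n_replicates = 1,
                                n_progeny = 2e4,
                                seed = 55 + match(prom, promoters())), REG)
    e <- estimate_frequencies(tbl, "w-")
    exp_homing <- 100 * sl$c_germ_w * sl$h
    exp_r2 <- 100 * sl$c_germ_w * (1 - sl$h) * (1 - sl$r1_w)
    expect_within_3sigma(e$mean[e$quantity == "homing"] / 100,
                         exp_homing / 100, 2e4 / 4)
    expect_within_3sigma(e$mean[e$quantity == "r2_w"] / 100,
                         exp_r2 / 100, 2e4 / 4)
  }
})
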