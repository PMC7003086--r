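test_that("a fixed seed reproduces the progeny table bit-exactly", {
  spec <- cross_spec(f1_female(2, "BicC"), tester_male("w+"),
                     n_progeny = 150, seed = 33)
  t1 <- run_cross(spec, REG)
  t2 <- run_cross(spec, REG)
  expect_identical(t1, t2)
  t3 <- run_cross(cross_spec(f1_female(2, "BicC"), tester_male("w+"),
                             n_progeny = 150, seed = 34), REG)
  expect_false(identical(t1, t3))
  expect_error(run_cross(cross_spec(f1_female(1, "nos"), tester_male("w+"),
                                    n_progeny = 0), REG),
               "empty table")
})

test_that("an idle cross is Mendelian in markers and sex", {
  tbl <- run_cross(cross_spec(f1_female(3, "Ubi"), tester_male("w-"),
                              n_replicates = 1, n_progeny = 1e4, seed = 35),
                   REG)
  expect_within_3sigma(mean(tbl$gfp), 0.5, nrow(tbl))
  expect_within_3sigma(mean(tbl$sex == "male"), 0.5, nrow(tbl))
  expect_true(all(tbl$mat_w %in% c("w+", "wGDE")))  # no events without Cas9
})

test_that("the stochastic engine matches the expectation oracle at n = 1e5", {
  m <- f1_female(2, "nos")
  sl <- registry_get_preset("nos", m$context, REG)
  off_ctx <- deposition_context(maternal_cas9_protein = TRUE,
                                maternal_grna = TRUE, zygotic_cas9 = TRUE,
                                zygotic_grna = TRUE, maternal_promoter = "nos")
  sl_off <- registry_get_preset("nos", off_ctx, REG)
  exp_off <- expected_generation(
    list(list(genotype = m, freq = 1)),
    list(list(genotype = tester_male("w+"), freq = 1)),
    sl$params, offspring_params = sl_off$params)

  n <- 1e5
  tbl <- run_cross(cross_spec(m, tester_male("w+"), n_replicates = 1,
                              n_progeny = n, seed = 36), REG)
  for (cls in white_classes()) {
    expected <- sum(exp_off$prob[exp_off$x1_w == cls])
    if (expected %in% c(0, 1)) next
    expect_within_3sigma(mean(tbl$x1_w == cls), expected, n)
  }
  for (cls in c("y+", "y-", "yR2")) {
    expected <- sum(exp_off$prob[exp_off$x1_y == cls])
    if (expected %in% c(0, 1)) next
    expect_within_3sigma(mean(tbl$x1_y == cls), expected, n)
  }
  expect_within_3sigma(mean(tbl$cas9 > 0),
                       sum(exp_off$prob[exp_off$cas9 > 0]), n)
})

test_that("paternal-Cas9 heterozygous mothers transmit only intact alleles", {
  sch <- run_scheme("score_F1_females_1_to_4", "BicC", REG, seed = 37,
                    n_progeny = 150)
  f3 <- sch$f2$female3
  expect_true(all(f3$mat_w %in% c("w+", "wGDE")))
  expect_true(all(f3$mat_y %in% c("y+", "y-")))
})

test_that("resistance accumulates and homing collapses from F2 to F3", {
  for (prom in promoters()) {
    sch <- run_scheme("F3_scoring", prom, REG, seed = 38, n_progeny = 400)
    e2 <- estimate_frequencies(sch$f2$female2, "w+")
    e3 <- estimate_frequencies(sch$f3$female6, "w+")
    r2_f2 <- e2$mean[e2$quantity == "r2_w"]
    r2_f3 <- e3$mean[e3$quantity == "r2_w"]
    expect_gt(r2_f3, r2_f2)
    expect_lt(e3$mean[e3$quantity == "homing"],
              e2$mean[e2$quantity == "homing"])
  }
})

test_that("F2 virgin selection follows the marker phenotypes", {
  sch <- run_scheme("F2_collection", "Ubi", REG, seed = 39, n_progeny = 300)
  for (g in sch$f2_mothers$female6) {
    expect_true("wGDE" %in% c(g$x1[["w"]], g$x2[["w"]]))
    expect_gt(g$cas9, 0)
  }
  for (g in sch$f2_mothers$female5) {
    expect_true("wGDE" %in% c(g$x1[["w"]], g$x2[["w"]]))
    expect_equal(g$cas9, 0L)
  }
})

test_that("a null registry keeps allele frequencies flat across generations", {
  reg0 <- zero_registry()
  sch <- run_scheme("F3_scoring", "nos", reg0, seed = 40, n_progeny = 400)
  for (tbl in list(sch$f2$female1, sch$f3$female5)) {
    e <- estimate_frequencies(tbl, "w-")
    expect_equal(e$mean[e$quantity == "r2_w"], 0)
    expect_true(all(tbl$mat_y %in% c("y+", "y-")))  # no induced yellow alleles
    # homing and yellow readouts are zero up to (clamped) sampling noise
    expect_lt(e$mean[e$quantity == "cleavage_y"], 10)
    expect_lt(abs(e$mean[e$quantity == "homing"]), 15)
  }
})
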