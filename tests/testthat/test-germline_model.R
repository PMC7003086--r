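test_that("gametogenesis is Mendelian without drive activity", {
  m <- f1_female(1, "BicC")
  gd <- make_gamete_distribution(m, germline_event_params())
  expect_equal(nrow(gd), 2)
  expect_equal(gd$prob[gd$w == "wGDE"], 0.5)
  expect_equal(gd$prob[gd$w == "w+"], 0.5)
  # inactive context: parameters are ignored, not an error
  m2 <- genotype("female", x_state("w+", "y+"), x_state("wGDE", "y-"))
  m2$context$zygotic_grna <- TRUE  # gRNA but no Cas9 source
  m2$context$zygotic_cas9 <- FALSE
  gd2 <- make_gamete_distribution(m2, germline_event_params(c_germ_w = 1, h = 1))
  expect_equal(sort(gd2$prob), c(0.5, 0.5))
  expect_error(make_gamete_distribution(tester_male("w+"),
                                        germline_event_params()),
               "female")
})

test_that("fitted shadow-drive parameters reproduce the outcome composition", {
  # observation set homing 59.3 / R2 38.7 / intact 2.0 on the cleavable half
  p <- fit_preset_from_observed(59.3, 38.7, intact = 2.0)
  gd <- make_gamete_distribution(f1_female(1, "BicC"), p)
  w_marg <- tapply(gd$prob, gd$w, sum)
  expect_equal(unname(w_marg[["wGDE"]]), 0.5 + 0.5 * 0.593, tolerance = 1e-9)
  expect_equal(unname(w_marg[["wR2"]]), 0.5 * 0.387, tolerance = 1e-9)
  expect_equal(unname(w_marg[["w+"]]), 0.5 * 0.020, tolerance = 1e-9)
})

test_that("resistant homologs segregate 50:50 whatever the parameters", {
  m <- genotype("female", x_state("wR2", "y+"), x_state("wGDE", "y-"),
                context = deposition_context(maternal_cas9_protein = TRUE,
                                             maternal_promoter = "nos"))
  set.seed(5)
  for (i in 1:10) {
    p <- random_params()
    gd <- make_gamete_distribution(m, p)
    expect_equal(sum(gd$prob[gd$w == "wGDE"]), 0.5, tolerance = 1e-12)
    expect_equal(sum(gd$prob[gd$w == "wR2"]), 0.5, tolerance = 1e-12)
  }
})

test_that("gamete distributions always normalize and conserve the w+ half", {
  set.seed(6)
  m <- f1_female(2, "Ubi")
  for (i in 1:20) {
    p <- random_params()
    gd <- make_gamete_distribution(m, p)
    expect_equal(sum(gd$prob), 1, tolerance = 1e-12)
    w_marg <- tapply(gd$prob, gd$w, sum)
    homed <- sum(w_marg[names(w_marg) == "wGDE"]) - 0.5
    rest <- sum(w_marg[names(w_marg) %in% c("w+", "wR1", "wR2")])
    expect_equal(homed + rest, 0.5, tolerance = 1e-12)
  }
})

test_that("embryonic cutting cannibalizes the homing substrate monotonically", {
  base <- load_presets()$Ubi$maternal
  m <- f1_female(2, "Ubi")
  m$context$maternal_grna <- TRUE  # RNP carryover context
  prev <- 1
  for (c_emb in c(0, 0.3, 0.6, 0.9, 1)) {
    p <- germline_event_params(c_emb_w = c_emb, c_germ_w = base$c_germ_w,
                               h = base$h, r1_w = base$r1_w)
    off <- expected_generation(list(list(genotype = m, freq = 1)),
                               list(list(genotype = tester_male("w+"), freq = 1)),
                               p)
    gde <- sum(off$prob[off$x1_w == "wGDE"])
    expect_lte(gde, prev + 1e-12)
    prev <- gde
  }
})

test_that("maternal protein alone drives homing above 50% (shadow drive)", {
  m <- f1_female(1, "vas")  # no Cas9 gene, maternally deposited protein
  expect_false(m$context$zygotic_cas9)
  p <- germline_event_params(c_germ_w = 0.9, h = 0.8)
  gd <- make_gamete_distribution(m, p)
  expect_gt(sum(gd$prob[gd$w == "wGDE"]), 0.5)
})

test_that("male gametes are an unchanged 1:1 X:Y draw", {
  f <- cas9_male("Ubi")
  g <- male_gametes(f)
  expect_equal(g$prob, c(0.5, 0.5))
  expect_equal(g$w[g$type == "X"], "w+")  # Cas9 carriage mutates nothing
  expect_identical(g$w[g$type == "X"], male_gametes(tester_male("w+"))$w[1])
  expect_error(male_gametes(gde_female()), "male")
})

test_that("embryonic cleavage respects context and converts whole animals", {
  p <- germline_event_params(c_emb_w = 1, r1_w = 0, c_emb_y = 0)
  # no maternal protein: unchanged
  z1 <- f1_female(4, "nos")
  expect_identical(apply_embryonic_cleavage(z1, p), z1)
  # RNP context with complete cutting: every w+ becomes wR2
  z2 <- f1_female(2, "nos")
  z2$context$maternal_grna <- TRUE
  set.seed(11)
  for (i in 1:20) {
    out <- apply_embryonic_cleavage(z2, p)
    expect_equal(out$x1[["w"]], "wR2")
    expect_equal(out$x2[["w"]], "wGDE")
  }
})

test_that("embryonic survival matches the binomial expectation at scale", {
  n <- 1e5
  set.seed(12)
  alleles <- splitdrive:::.emb_convert(rep("w+", n), "w+", 0.9, 0, "wR1", "wR2")
  expect_within_3sigma(mean(alleles == "w+"), 0.1, n)
  expect_true(all(alleles %in% c("w+", "wR2")))
})

test_that("the expectation oracle is a normalized Mendelian cross when idle", {
  mothers <- list(list(genotype = f1_female(3, "BicC"), freq = 1))
  fathers <- list(list(genotype = tester_male("w-"), freq = 1))
  off <- expected_generation(mothers, fathers, germline_event_params())
  expect_equal(sum(off$prob), 1, tolerance = 1e-12)
  fem <- off[off$sex == "female", ]
  gfp <- sum(fem$prob[fem$x1_w == "wGDE" | fem$x2_w == "wGDE"]) / sum(fem$prob)
  expect_equal(gfp, 0.5, tolerance = 1e-12)
  bad <- list(list(genotype = f1_female(3, "BicC"), freq = 0.7))
  expect_error(expected_generation(bad, fathers, germline_event_params()),
               "sum to 1")
})
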