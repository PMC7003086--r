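site_w <- drive_target_sites()$white
ref <- synthetic_reference(site_w)

test_that("target validation enforces length and the NGG PAM", {
  t1 <- validate_target("GGCGATACTTGGATGCCCTGCGG")
  expect_equal(t1$pam, "CGG")
  expect_equal(t1$cut_offset, 17L)
  t2 <- validate_target("GGTTTTGGACACTGGAACCGTGG")
  expect_equal(t2$pam, "TGG")
  expect_error(validate_target("GGCGATACTTGGATGCCCTGAAT"), "PAM")
  expect_error(validate_target("GGCGATACTTGGATGCCC"), "length")
  expect_error(validate_target("GGCGATACTTGGATGCCCTGNGG"), "non-ACGT")
})

test_that("indel calls follow the frame rule at the cut site", {
  expect_equal(classify_indel(ref, ref, site_w)$class, "WT")
  cut <- 60 + 17  # reference coordinate of the blunt cut
  del3 <- paste0(substr(ref, 1, cut - 3), substr(ref, cut + 1, nchar(ref)))
  call3 <- classify_indel(ref, del3, site_w)
  expect_equal(call3$class, "R1")
  expect_equal(call3$net, -3L)
  ins1 <- paste0(substr(ref, 1, cut), "A", substr(ref, cut + 1, nchar(ref)))
  call1 <- classify_indel(ref, ins1, site_w)
  expect_equal(call1$class, "R2")
  expect_equal(call1$net, 1L)
})

test_that("seed or PAM substitutions without length change call R1", {
  pos <- regexpr(site_w$seq, ref, fixed = TRUE)
  mutate_at <- function(at) {
    old <- substr(ref, at, at)
    new <- setdiff(c("A", "C", "G", "T"), old)[1]
    s <- ref; substr(s, at, at) <- new; s
  }
  in_seed <- classify_indel(ref, mutate_at(pos + 15), site_w)
  expect_equal(in_seed$class, "R1")
  expect_equal(in_seed$net, 0L)
  in_pam <- classify_indel(ref, mutate_at(pos + 21), site_w)
  expect_equal(in_pam$class, "R1")
  # a distal substitution does not disrupt the site
  far <- classify_indel(ref, mutate_at(5), site_w)
  expect_equal(far$class, "WT")
})

test_that("calls are invariant to flank length beyond the window", {
  long_ref <- synthetic_reference(site_w, flank = 120, seed = 404)
  cut_s <- 60 + 17
  cut_l <- 120 + 17
  del6_s <- paste0(substr(ref, 1, cut_s - 6), substr(ref, cut_s + 1, nchar(ref)))
  del6_l <- paste0(substr(long_ref, 1, cut_l - 6),
                   substr(long_ref, cut_l + 1, nchar(long_ref)))
  cs <- classify_indel(ref, del6_s, site_w)
  cl <- classify_indel(long_ref, del6_l, site_w)
  expect_equal(cs$class, cl$class)
  expect_equal(cs$net, cl$net)
})

test_that("classification depends only on net length change modulo 3", {
  set.seed(61)
  cut <- 60 + 17
  for (i in 1:25) {
    k <- sample(c(-9:-1, 1:6), 1)
    if (k < 0) {
      obs <- paste0(substr(ref, 1, cut + k), substr(ref, cut + 1, nchar(ref)))
    } else {
      ins <- paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
                   collapse = "")
      obs <- paste0(substr(ref, 1, cut), ins, substr(ref, cut + 1, nchar(ref)))
    }
    call <- classify_indel(ref, obs, site_w)
    expect_equal(call$net, as.integer(k))
    expect_equal(call$class, if (k %% 3 == 0) "R1" else "R2")
  }
})

test_that("generated mutants round-trip through the classifier", {
  expect_equal(nrow(generate_mutant_amplicons(ref, site_w, 0)), 0)
  all_r1 <- generate_mutant_amplicons(ref, site_w, 30, r1_fraction = 1,
                                      seed = 62)
  calls <- classify_amplicons(ref, stats::setNames(all_r1$seq, all_r1$id),
                              site_w)
  expect_true(all(calls$class == "R1"))
  mixed <- generate_mutant_amplicons(ref, site_w, 500, r1_fraction = 0.3,
                                     sub_fraction = 0.1, seed = 63)
  calls <- classify_amplicons(ref, stats::setNames(mixed$seq, mixed$id),
                              site_w)
  expect_equal(calls$class, mixed$truth_class)
  expect_false(any(calls$flagged))
})
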