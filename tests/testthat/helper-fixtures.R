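# Shared fixtures: all generated in code, no stored data.

REG <- load_presets()

# registry in which no promoter ever cuts (null model)
zero_registry <- function() {
  zero <- list(c_emb_w = 0, c_germ_w = 0, h = 0, r1_w = 0,
               c_y = 0, r1_y = 0, c_emb_y = 0,
               p_som_white = 0, p_som_yellow = 0)
  slices <- list(maternal = zero, zygotic = zero,
                 rnp = list(c_emb_w = 0, c_emb_y = 0))
  stats::setNames(rep(list(slices), length(promoters())), promoters())
}

# random valid event parameters
random_params <- function() {
  germline_event_params(c_emb_w = runif(1), c_germ_w = runif(1),
                        h = runif(1), r1_w = runif(1), c_y = runif(1),
                        r1_y = runif(1), c_emb_y = runif(1))
}

# synthetic amplicon: the white-locus target embedded in fixed random flanks
synthetic_reference <- function(site = drive_target_sites()$white,
                                flank = 60, seed = 404) {
  set.seed(seed)
  left <- paste(sample(c("A", "C", "G", "T"), flank, replace = TRUE),
                collapse = "")
  right <- paste(sample(c("A", "C", "G", "T"), flank, replace = TRUE),
                 collapse = "")
  paste0(left, site$seq, right)
}

# binomial 3-sigma check helper
expect_within_3sigma <- function(observed_frac, expected_frac, n) {
  sigma <- sqrt(expected_frac * (1 - expected_frac) / n)
  expect_lt(abs(observed_frac - expected_frac), 3 * sigma + 1e-12)
}
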