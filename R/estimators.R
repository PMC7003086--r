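# Phenotype -> allele-class decoding, normalization to the 50% heterozygous
# allele pool, replicate statistics, the equal-variance t-test, and the
# inversion of observed outcome frequencies into germline event parameters.

.clamp_pct <- function(x) pmin(100, pmax(0, x))

#' Replicate mean and standard deviation
#'
#' The replicate cross, not the fly, is the statistical unit: arithmetic
#' mean and sample standard deviation (n-1 denominator) over per-replicate
#' percentages. A single replicate has no defined SD (`NA`).
#'
#' @param values Numeric vector of per-replicate values.
#' @return List with `mean`, `sd`, `n`.
#' @examples
#' summarize_replicates(c(11.2, 13.2, 18.6, 36.7))$mean  # 19.925
#' @export
summarize_replicates <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 1)
  list(mean = mean(values),
       sd = if (length(values) >= 2) stats::sd(values) else NA_real_,
       n = length(values))
}

#' Recover allele-class frequencies from a scored progeny table
#'
#' Decodes the maternally transmitted white allele from phenotype and
#' markers: GFP+ progeny carry the drive (`wGDE`); GFP- white-eyed progeny
#' carry `wR2`; GFP- red or white-mosaic progeny carry an intact-reading
#' allele (`w+` or, indistinguishably, `wR1` - true cleavage is therefore
#' underestimated by the in-frame fraction). With a `w-` tester father the
#' maternal allele is read from all progeny; with a `w+` father it is read
#' from male progeny only, because paternal `w+` alleles complement
#' (mask) maternal `wR2` in daughters. Yellow loss-of-function is scored
#' only in male progeny, whose single X is maternal. Frequencies are
#' normalized to the 50% heterozygous allele pool:
#' homing% = (f(wGDE) - 0.5)/0.5 * 100, r2% = f(wR2)/0.5 * 100,
#' intact% = f(red)/0.5 * 100, cleavage% = 100 - intact%, and yellow
#' cleavage% = (f(yellow body in males) - 0.5)/0.5 * 100; each clamped to
#' [0, 100]. Mean and SD are computed over replicates.
#'
#' @param table Progeny table from [run_cross()].
#' @param father_w White genotype of the tester father: `"w-"` or `"w+"`.
#' @return Data frame with one row per quantity (`cleavage_w`, `homing`,
#'   `r2_w`, `intact_w`, `cleavage_y`): `mean`, `sd`, `n_replicates`, and a
#'   list column `values` of per-replicate percentages.
#' @export
estimate_frequencies <- function(table, father_w = c("w-", "w+")) {
  father_w <- match.arg(father_w)
  needed <- c("replicate", "sex", "eye", "body", "gfp", "rfp")
  if (!all(needed %in% names(table))) {
    stop("table lacks phenotype columns: ",
         paste(setdiff(needed, names(table)), collapse = ", "))
  }
  reps <- sort(unique(table$replicate))
  per <- lapply(reps, function(r) {
    tr <- table[table$replicate == r, , drop = FALSE]
    sub <- if (father_w == "w-") tr else tr[tr$sex == "male", , drop = FALSE]
    if (nrow(sub) == 0) {
      stop("decoding error: w+ father design requires male progeny rows")
    }
    f_gde <- mean(sub$gfp)
    f_r2 <- mean(!sub$gfp & sub$eye == "white")
    f_intact <- mean(!sub$gfp & sub$eye %in% c("red", "mosaic"))
    males <- tr[tr$sex == "male", , drop = FALSE]
    if (nrow(males) == 0) {
      stop("decoding error: yellow scoring requires male progeny rows")
    }
    f_yellow <- mean(males$body == "yellow")
    c(homing = .clamp_pct((f_gde - 0.5) / 0.5 * 100),
      r2_w = .clamp_pct(f_r2 / 0.5 * 100),
      intact_w = .clamp_pct(f_intact / 0.5 * 100),
      cleavage_y = .clamp_pct((f_yellow - 0.5) / 0.5 * 100))
  })
  mat <- do.call(rbind, per)
  vals <- list(cleavage_w = 100 - mat[, "intact_w"],
               homing = mat[, "homing"],
               r2_w = mat[, "r2_w"],
               intact_w = mat[, "intact_w"],
               cleavage_y = mat[, "cleavage_y"])
  out <- data.frame(quantity = names(vals),
                    mean = vapply(vals, function(v) summarize_replicates(v)$mean, 1),
                    sd = vapply(vals, function(v) summarize_replicates(v)$sd, 1),
                    n_replicates = length(reps), row.names = NULL)
  out$values <- I(unname(vals))
  out
}

#' Two-sample Student's t-test with equal variance
#'
#' Pooled-variance t statistic with `df = n_a + n_b - 2` and a two-sided p
#' value. Degenerate inputs: zero pooled variance with equal means gives
#' `t = 0, p = 1`; with unequal means `p = 0`, flagged degenerate.
#'
#' @param a,b Numeric vectors of replicate values (each length >= 2).
#' @return List with `t`, `df`, `p`, `degenerate`.
#' @export
ttest_equal_var <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  na <- length(a); nb <- length(b)
  df <- na + nb - 2
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / df
  d <- mean(a) - mean(b)
  if (sp2 <= 0) {
    if (d == 0) return(list(t = 0, df = df, p = 1, degenerate = FALSE))
    return(list(t = sign(d) * Inf, df = df, p = 0, degenerate = TRUE))
  }
  t <- d / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df), degenerate = FALSE)
}

#' Invert observed outcome frequencies into germline event parameters
#'
#' The printed quantities are outcome frequencies on the cleavable half of
#' the heterozygous female's gamete pool; this inverts them into the
#' generative decomposition. For a germline context (cutting at the
#' HDR-competent stage): `c_germ_w = (100 - intact)/100` and
#' `h = homing / (homing + r2 + r1)`, with the in-frame NHEJ fraction
#' `r1_w = r1 / (r2 + r1)`. For an embryonic context (cutting before HDR
#' competence) the same cut total is absorbed by `c_emb_w`, and a non-zero
#' homing request is infeasible. The residual `r1 = 100 - homing - r2 -
#' intact` serves as the in-frame proxy when not given. Round trip:
#' simulating with the fitted parameters and re-estimating recovers the
#' inputs within sampling error.
#'
#' @param homing,r2 Observed homing and `wR2` percentages.
#' @param intact Observed intact (red-reading) percentage; default the
#'   complement of `homing + r2 + r1`.
#' @param r1 In-frame resistance percentage (proxy); default the residual.
#' @param context `"germline"` or `"embryonic"`.
#' @param yellow_lof Observed germline yellow loss-of-function percentage
#'   (normalized to the 50% pool). Phenotype scoring misses in-frame
#'   repairs, so the cut rate is `c_y = yellow_lof / (1 - r1_y)`,
#'   capped at 1.
#' @param r1_y In-frame fraction at yellow (unconstrained by phenotype
#'   scoring; documented default 0.1).
#' @return [germline_event_params()].
#' @examples
#' p <- fit_preset_from_observed(homing = 60, r2 = 30, intact = 10)
#' c(p$c_germ_w, p$h)  # 0.9, 0.667
#' @export
fit_preset_from_observed <- function(homing, r2, intact = NULL, r1 = NULL,
                                     context = c("germline", "embryonic"),
                                     yellow_lof = 0, r1_y = 0.1) {
  context <- match.arg(context)
  if (is.null(r1) && is.null(intact)) {
    stop("one of `intact` or `r1` must be given")
  }
  if (is.null(r1)) r1 <- 100 - homing - r2 - intact
  if (is.null(intact)) intact <- 100 - homing - r2 - r1
  tol <- 1e-6
  if (min(homing, r2, intact, r1) < -tol ||
      homing + r2 + r1 + intact > 100 + tol) {
    stop("observed percentages must be non-negative and sum to at most 100")
  }
  r1 <- max(r1, 0)
  cut <- (100 - intact) / 100
  nhej <- r2 + r1
  r1_w <- if (nhej > 0) r1 / nhej else 0
  stopifnot(yellow_lof >= 0, yellow_lof <= 100)
  c_y <- min(1, (yellow_lof / 100) / (1 - r1_y))
  if (context == "embryonic") {
    if (homing > tol) {
      stop("infeasible: homing cannot occur in an embryonic-only context")
    }
    return(germline_event_params(c_emb_w = cut, r1_w = r1_w,
                                 c_y = c_y, r1_y = r1_y, c_emb_y = c_y))
  }
  denom <- homing + nhej
  h <- if (denom > 0) homing / denom else 0
  germline_event_params(c_germ_w = cut, h = h, r1_w = r1_w,
                        c_y = c_y, r1_y = r1_y)
}
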