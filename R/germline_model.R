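# Gamete-level model of drive activity in the female germline: cleavage,
# HDR homing, NHEJ resistance-allele formation, and the timing effect of
# maternally deposited Cas9 protein (embryonic cuts pre-date HDR competence).

.aggregate_dist <- function(df, by, prob = "prob") {
  agg <- stats::aggregate(df[[prob]], by = df[by], FUN = sum)
  names(agg)[ncol(agg)] <- prob
  agg
}

# outcome partition of one white allele in the germline
.w_partition <- function(w, params, donor) {
  if (w != "w+") return(data.frame(w = w, p = 1))
  cg <- params$c_germ_w
  h <- if (donor) params$h else 0
  r1 <- params$r1_w
  data.frame(
    w = c("w+", "wGDE", "wR1", "wR2"),
    p = c(1 - cg, cg * h, cg * (1 - h) * r1, cg * (1 - h) * (1 - r1)))
}

.y_partition <- function(y, params) {
  if (y != "y+") return(data.frame(y = y, p = 1))
  cy <- params$c_y
  r1 <- params$r1_y
  data.frame(y = c("y+", "yR1", "yR2"),
             p = c(1 - cy, cy * r1, cy * (1 - r1)))
}

#' Exact gamete distribution of a female
#'
#' Each X chromosome is transmitted with probability 1/2. On a transmitted
#' chromosome, a cleavable `w+` allele is partitioned into
#' uncut / homed (`wGDE`) / `wR1` / `wR2` via the germline-stage cut
#' probability `c_germ_w`, the HDR fraction `h` and the in-frame NHEJ
#' fraction `r1_w`; a `y+` allele is independently partitioned via `c_y`
#' and `r1_y`. Homing requires a `wGDE` homolog as HDR donor; without one,
#' every cut is repaired by NHEJ. Resistance alleles and `y-` pass through
#' unchanged. No events occur unless the mother's deposition context
#' supplies both a Cas9 source and a gRNA source. Embryonic cleavage of
#' the mother herself is not part of gametogenesis; apply
#' [apply_embryonic_cleavage()] to her zygote first.
#'
#' @param mother A female [genotype()].
#' @param params [germline_event_params()] for her deposition context.
#' @return Data frame with columns `w`, `y`, `prob` summing to 1.
#' @examples
#' m <- genotype("female", x_state("w+", "y+"), x_state("wGDE", "y-"),
#'               context = deposition_context(maternal_cas9_protein = TRUE,
#'                                            maternal_promoter = "BicC"))
#' make_gamete_distribution(m, germline_event_params())  # Mendelian 50:50
#' @export
make_gamete_distribution <- function(mother, params) {
  stopifnot(inherits(mother, "genotype"), inherits(params, "germline_event_params"))
  if (mother$sex != "female") stop("gamete distribution model applies to females")
  active <- context_is_active(mother$context)
  if (!active) params <- germline_event_params()  # zero-event, not an error
  donor <- "wGDE" %in% .carried(mother, "w")
  per_x <- lapply(list(mother$x1, mother$x2), function(x) {
    wp <- .w_partition(x[["w"]], params, donor)
    yp <- .y_partition(x[["y"]], params)
    out <- merge(wp, yp, by = NULL)
    data.frame(w = out$w, y = out$y, prob = 0.5 * out$p.x * out$p.y)
  })
  dist <- .aggregate_dist(do.call(rbind, per_x), c("w", "y"))
  stopifnot(abs(sum(dist$prob) - 1) < 1e-12)
  dist[dist$prob > 0, , drop = FALSE]
}

#' Gamete distribution of a male
#'
#' Males are hemizygous: the single X and the Y are each transmitted with
#' probability 1/2, unchanged. There is no cutting and no homing in males,
#' and paternal Cas9 carriage does not mutate target loci in gametes.
#'
#' @param father A male [genotype()].
#' @return Data frame with columns `type` (`"X"`/`"Y"`), `w`, `y`, `prob`.
#' @export
male_gametes <- function(father) {
  stopifnot(inherits(father, "genotype"))
  if (father$sex != "male") stop("male_gametes requires a male genotype")
  data.frame(type = c("X", "Y"),
             w = c(father$x1[["w"]], NA), y = c(father$x1[["y"]], NA),
             prob = c(0.5, 0.5))
}

# vectorised embryonic conversion of one locus's allele vector
.emb_convert <- function(alleles, cleavable, c_emb, r1, r1_class, r2_class) {
  idx <- which(alleles == cleavable)
  if (!length(idx) || c_emb <= 0) return(alleles)
  cut <- idx[stats::runif(length(idx)) < c_emb]
  if (length(cut)) {
    inframe <- stats::runif(length(cut)) < r1
    alleles[cut] <- ifelse(inframe, r1_class, r2_class)
  }
  alleles
}

#' Embryonic (pre-HDR) cleavage of a zygote
#'
#' Maternally deposited Cas9 protein, together with a gRNA source, can cut
#' target alleles in the early mitotic embryo, before the developmental
#' stages where efficient HDR repair occurs. Each cleavable `w+` allele is
#' therefore converted to `wR1`/`wR2` (never `wGDE`) with probability
#' `c_emb_w` (in-frame split `r1_w`), and analogously `y+` via `c_emb_y`
#' and `r1_y`. The conversion is whole-animal: it applies to both the soma
#' and the germline precursor of the individual. Inactive contexts (no
#' maternal protein, or no gRNA source) leave the zygote unchanged.
#'
#' Stochastic: call once per zygote; draws come from R's RNG.
#'
#' @param zygote A [genotype()].
#' @param params [germline_event_params()] for the zygote's context.
#' @return The (possibly modified) genotype.
#' @export
apply_embryonic_cleavage <- function(zygote, params) {
  stopifnot(inherits(zygote, "genotype"), inherits(params, "germline_event_params"))
  ctx <- zygote$context
  if (!(ctx$maternal_cas9_protein && (ctx$maternal_grna || ctx$zygotic_grna))) {
    return(zygote)
  }
  fix_x <- function(x) {
    if (is.null(x)) return(NULL)
    x[["w"]] <- .emb_convert(x[["w"]], "w+", params$c_emb_w, params$r1_w, "wR1", "wR2")
    x[["y"]] <- .emb_convert(x[["y"]], "y+", params$c_emb_y, params$r1_y, "yR1", "yR2")
    x
  }
  zygote$x1 <- fix_x(zygote$x1)
  zygote$x2 <- fix_x(zygote$x2)
  zygote
}

# exact post-embryonic expansion of allele classes (expectation analogue of
# .emb_convert): returns data.frame(allele, p)
.emb_expand <- function(allele, cleavable, c_emb, r1, r1_class, r2_class) {
  if (allele != cleavable || c_emb <= 0) return(data.frame(a = allele, p = 1))
  data.frame(a = c(cleavable, r1_class, r2_class),
             p = c(1 - c_emb, c_emb * r1, c_emb * (1 - r1)))
}

# exact distribution over post-embryonic genotype states of one zygote,
# as a data.frame of allele columns + prob
.emb_expand_genotype <- function(g, params) {
  ctx <- g$context
  active <- ctx$maternal_cas9_protein && (ctx$maternal_grna || ctx$zygotic_grna)
  pw <- if (active) params$c_emb_w else 0
  py <- if (active) params$c_emb_y else 0
  w1 <- .emb_expand(g$x1[["w"]], "w+", pw, params$r1_w, "wR1", "wR2")
  y1 <- .emb_expand(g$x1[["y"]], "y+", py, params$r1_y, "yR1", "yR2")
  if (is.null(g$x2)) {
    out <- merge(w1, y1, by = NULL, suffixes = c("_w1", "_y1"))
    return(data.frame(x1_w = out$a_w1, x1_y = out$a_y1,
                      x2_w = NA, x2_y = NA,
                      prob = out$p_w1 * out$p_y1))
  }
  w2 <- .emb_expand(g$x2[["w"]], "w+", pw, params$r1_w, "wR1", "wR2")
  y2 <- .emb_expand(g$x2[["y"]], "y+", py, params$r1_y, "yR1", "yR2")
  grid <- expand.grid(i = seq_len(nrow(w1)), j = seq_len(nrow(y1)),
                      k = seq_len(nrow(w2)), l = seq_len(nrow(y2)))
  data.frame(x1_w = w1$a[grid$i], x1_y = y1$a[grid$j],
             x2_w = w2$a[grid$k], x2_y = y2$a[grid$l],
             prob = w1$p[grid$i] * y1$p[grid$j] * w2$p[grid$k] * y2$p[grid$l])
}

#' Exact offspring genotype distribution of a cross (deterministic oracle)
#'
#' Convolves [make_gamete_distribution()] with [male_gametes()] and 1:1 sex
#' assignment, in expectation: the mothers' own embryonic cleavage, their
#' germline events, Mendelian Cas9 transmission, and (optionally) the
#' offspring's embryonic cleavage are all applied analytically. This is the
#' oracle the stochastic cross engine is checked against.
#'
#' @param mothers List of `list(genotype = , freq = )` entries (zygote-stage
#'   females); frequencies must sum to 1.
#' @param fathers Same structure, males.
#' @param params [germline_event_params()] governing the mothers (their
#'   embryonic stage via `c_emb_*` and their germline via `c_germ_w` etc.).
#' @param offspring_params Optional [germline_event_params()] whose
#'   `c_emb_*` entries are applied to the offspring zygotes (deposition
#'   from the mothers); `NULL` for none.
#' @return Data frame with columns `sex`, `x1_w`, `x1_y`, `x2_w`, `x2_y`
#'   (`NA` for males), `cas9`, `prob`; `prob` sums to 1.
#' @export
expected_generation <- function(mothers, fathers, params,
                                offspring_params = NULL) {
  check_pool <- function(pool, sex) {
    fr <- vapply(pool, `[[`, numeric(1), "freq")
    if (abs(sum(fr) - 1) > 1e-9) stop("pool frequencies must sum to 1")
    for (e in pool) {
      if (e$genotype$sex != sex) stop("pool must contain only ", sex, "s")
    }
  }
  check_pool(mothers, "female")
  check_pool(fathers, "male")

  rows <- list()
  for (me in mothers) {
    m0 <- me$genotype
    # exact expansion over the mother's own embryonic conversion
    mpost <- .emb_expand_genotype(m0, params)
    for (i in seq_len(nrow(mpost))) {
      m <- m0
      m$x1 <- x_state(mpost$x1_w[i], mpost$x1_y[i])
      m$x2 <- x_state(mpost$x2_w[i], mpost$x2_y[i])
      gd <- make_gamete_distribution(m, params)
      p_m_cas9 <- m0$cas9 / 2
      for (fe in fathers) {
        f <- fe$genotype
        fg <- male_gametes(f)
        p_f_cas9 <- f$cas9 / 2
        w_base <- me$freq * mpost$prob[i] * fe$freq
        for (k in seq_len(nrow(gd))) {
          for (s in c("female", "male")) {
            x2w <- if (s == "female") f$x1[["w"]] else NA
            x2y <- if (s == "female") f$x1[["y"]] else NA
            for (cm in 0:1) for (cf in 0:1) {
              pc <- (if (cm) p_m_cas9 else 1 - p_m_cas9) *
                (if (cf) p_f_cas9 else 1 - p_f_cas9)
              if (pc == 0) next
              rows[[length(rows) + 1]] <- data.frame(
                sex = s, x1_w = gd$w[k], x1_y = gd$y[k],
                x2_w = x2w, x2_y = x2y, cas9 = cm + cf,
                prob = w_base * gd$prob[k] * 0.5 * pc)
            }
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  # offspring embryonic conversion (maternal deposition), in expectation
  if (!is.null(offspring_params) &&
      (offspring_params$c_emb_w > 0 || offspring_params$c_emb_y > 0)) {
    expand_col <- function(df, col, cleavable, c_emb, r1, r1c, r2c) {
      idx <- !is.na(df[[col]]) & df[[col]] == cleavable
      if (!any(idx) || c_emb <= 0) return(df)
      keep <- df[!idx, , drop = FALSE]
      hit <- df[idx, , drop = FALSE]
      variants <- lapply(list(c(cleavable, 1 - c_emb), c(r1c, c_emb * r1),
                              c(r2c, c_emb * (1 - r1))), function(v) {
        d <- hit
        d[[col]] <- v[1]
        d$prob <- d$prob * as.numeric(v[2])
        d
      })
      rbind(keep, do.call(rbind, variants))
    }
    op <- offspring_params
    for (col in c("x1_w", "x2_w")) {
      out <- expand_col(out, col, "w+", op$c_emb_w, op$r1_w, "wR1", "wR2")
    }
    for (col in c("x1_y", "x2_y")) {
      out <- expand_col(out, col, "y+", op$c_emb_y, op$r1_y, "yR1", "yR2")
    }
  }
  out$x2_w[out$sex == "male"] <- NA
  out$x2_y[out$sex == "male"] <- NA
  key <- c("sex", "x1_w", "x1_y", "x2_w", "x2_y", "cas9")
  tmp <- out
  tmp$x2_w[is.na(tmp$x2_w)] <- "."
  tmp$x2_y[is.na(tmp$x2_y)] <- "."
  agg <- .aggregate_dist(tmp, key)
  agg$x2_w[agg$x2_w == "."] <- NA
  agg$x2_y[agg$x2_y == "."] <- NA
  stopifnot(abs(sum(agg$prob) - 1) < 1e-9)
  agg[agg$prob > 0, , drop = FALSE]
}
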