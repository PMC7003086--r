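# Seeded, replicated crosses and the multi-generation crossing schemes:
# F0 founder crosses -> F1 female classes 1-4 -> F2 scoring crosses ->
# F2 virgin collection (classes 5-6) -> F3 scoring crosses.

# ---------------------------------------------------------------------------
# founder and tester genotypes
# ---------------------------------------------------------------------------

#' Founder and tester genotypes
#'
#' Stock genotypes used by the crossing schemes: the GDe founder line is
#' `y-,wGDE` (homozygous females, hemizygous males); Cas9 lines are
#' heterozygous transgene carriers in a `w+,y+` background; tester males
#' are `w+,y+` or `w-,y+` (the founder white null is represented with the
#' `wR2` class).
#'
#' @param promoter Cas9 promoter of the transgene line.
#' @param w White allele of the tester male: `"w+"` or `"w-"`.
#' @return A [genotype()].
#' @name founders
NULL

#' @rdname founders
#' @export
gde_female <- function() {
  genotype("female", x_state("wGDE", "y-"), x_state("wGDE", "y-"))
}

#' @rdname founders
#' @export
gde_male <- function() genotype("male", x_state("wGDE", "y-"))

#' @rdname founders
#' @export
cas9_female <- function(promoter) {
  genotype("female", x_state("w+", "y+"), x_state("w+", "y+"),
           cas9 = 1L, promoter = promoter)
}

#' @rdname founders
#' @export
cas9_male <- function(promoter) {
  genotype("male", x_state("w+", "y+"), cas9 = 1L, promoter = promoter)
}

#' @rdname founders
#' @export
tester_male <- function(w = c("w+", "w-")) {
  w <- match.arg(w)
  genotype("male", x_state(if (w == "w+") "w+" else "wR2", "y+"))
}

#' F1 female classes of the bidirectional founder crosses
#'
#' Class 1: heterozygous `wGDE/w+` with maternally deposited Cas9 protein
#' but no Cas9 gene (shadow-drive class). Class 2: trans-heterozygous with
#' maternal Cas9 (protein and gene). Class 3: heterozygous from a paternal
#' Cas9 father, no Cas9 gene and no protein (negative-control class).
#' Class 4: trans-heterozygous with paternally inherited Cas9 (zygotic
#' expression only). Classes 1-2 descend from a Cas9-line mother crossed
#' to a GDe male; classes 3-4 from a GDe-line mother crossed to a
#' Cas9-line male. The founder mothers carry no complete nuclease+guide
#' pair, so these F1 genotypes are deterministic.
#'
#' @param class Integer 1-4.
#' @param promoter Cas9 promoter of the transgene line involved.
#' @return A female [genotype()] with its deposition context set.
#' @export
f1_female <- function(class, promoter) {
  stopifnot(class %in% 1:4)
  if (class %in% 1:2) {
    ctx <- deposition_context(maternal_cas9_protein = TRUE,
                              maternal_promoter = promoter)
    genotype("female", x_state("w+", "y+"), x_state("wGDE", "y-"),
             cas9 = if (class == 2) 1L else 0L,
             promoter = if (class == 2) promoter else NA_character_,
             context = ctx)
  } else {
    genotype("female", x_state("wGDE", "y-"), x_state("w+", "y+"),
             cas9 = if (class == 4) 1L else 0L,
             promoter = if (class == 4) promoter else NA_character_,
             context = deposition_context())
  }
}

# ---------------------------------------------------------------------------
# cross specification and engine
# ---------------------------------------------------------------------------

#' Specification of one replicated cross
#'
#' Defaults follow the triplicate 10 females x 10 males vial design.
#'
#' @param mother A female [genotype()], or a list of female genotypes to
#'   draw the vial's mothers from (virgin pools).
#' @param father A male [genotype()].
#' @param n_replicates Number of replicate crosses (>= 1).
#' @param n_mothers,n_fathers Parents per replicate vial.
#' @param n_progeny Scored progeny per replicate.
#' @param seed Integer seed; every draw of the cross derives from it.
#' @param mothers_at_zygote If `TRUE` the mothers are taken at their own
#'   zygote stage and [apply_embryonic_cleavage()] is applied to them
#'   first; set `FALSE` for mothers sampled from a simulated progeny table
#'   (already converted).
#' @return List of class `"cross_spec"`.
#' @export
cross_spec <- function(mother, father, n_replicates = 3L, n_mothers = 10L,
                       n_fathers = 10L, n_progeny = 200L, seed = 1L,
                       mothers_at_zygote = TRUE) {
  if (inherits(mother, "genotype")) mother <- list(mother)
  stopifnot(length(mother) >= 1, inherits(father, "genotype"),
            n_replicates >= 1)
  for (m in mother) {
    stopifnot(inherits(m, "genotype"))
    if (m$sex != "female") stop("mother pool must contain females")
  }
  if (father$sex != "male") stop("father must be male")
  structure(list(mother = mother, father = father,
                 n_replicates = as.integer(n_replicates),
                 n_mothers = as.integer(n_mothers),
                 n_fathers = as.integer(n_fathers),
                 n_progeny = as.integer(n_progeny),
                 seed = as.integer(seed),
                 mothers_at_zygote = isTRUE(mothers_at_zygote)),
            class = "cross_spec")
}

# promoter whose preset governs a slice; first available source wins
.resolve_promoter <- function(mother, father = NULL) {
  if (mother$context$maternal_cas9_protein) return(mother$context$maternal_promoter)
  if (mother$cas9 > 0) return(mother$promoter)
  if (!is.null(father) && father$cas9 > 0) return(father$promoter)
  "nos"  # irrelevant: no Cas9 source, slices resolve to zero
}

# vectorised embryonic conversion on a progeny data frame
.emb_convert_table <- function(df, active, params) {
  if (!any(active)) return(df)
  for (col in c("x1_w", "x2_w")) {
    sel <- active & !is.na(df[[col]]) & df[[col]] == "w+"
    df[[col]][sel] <- .emb_convert(df[[col]][sel], "w+", params$c_emb_w,
                                   params$r1_w, "wR1", "wR2")
  }
  for (col in c("x1_y", "x2_y")) {
    sel <- active & !is.na(df[[col]]) & df[[col]] == "y+"
    df[[col]][sel] <- .emb_convert(df[[col]][sel], "y+", params$c_emb_y,
                                   params$r1_y, "yR1", "yR2")
  }
  df
}

.sample_replicate <- function(spec, registry, rep_id) {
  pool <- spec$mother
  k <- spec$n_mothers
  idx <- if (length(pool) == 1) rep(1L, k) else
    sample.int(length(pool), k, replace = length(pool) < k)
  mothers <- pool[idx]
  father <- spec$father

  gds <- vector("list", k)
  for (i in seq_len(k)) {
    m <- mothers[[i]]
    slice <- registry_get_preset(.resolve_promoter(m, father), m$context,
                                 registry)
    if (spec$mothers_at_zygote) m <- apply_embryonic_cleavage(m, slice$params)
    mothers[[i]] <- m
    gds[[i]] <- make_gamete_distribution(m, slice$params)
  }

  n <- spec$n_progeny
  mi <- sample.int(k, n, replace = TRUE)
  mat_w <- character(n); mat_y <- character(n)
  for (i in seq_len(k)) {
    sel <- which(mi == i)
    if (!length(sel)) next
    g <- gds[[i]]
    gi <- sample.int(nrow(g), length(sel), replace = TRUE, prob = g$prob)
    mat_w[sel] <- g$w[gi]
    mat_y[sel] <- g$y[gi]
  }
  cas9_m <- vapply(mothers, `[[`, integer(1), "cas9")[mi]
  cas9_mat <- stats::rbinom(n, 1, cas9_m / 2)
  cas9_pat <- stats::rbinom(n, 1, father$cas9 / 2)
  sex <- ifelse(stats::runif(n) < 0.5, "female", "male")

  df <- data.frame(
    replicate = rep_id, sex = sex,
    mat_w = mat_w, mat_y = mat_y,
    x1_w = mat_w, x1_y = mat_y,
    x2_w = ifelse(sex == "female", father$x1[["w"]], NA),
    x2_y = ifelse(sex == "female", father$x1[["y"]], NA),
    cas9 = cas9_mat + cas9_pat)

  # offspring deposition context, set by the mothers' carried transgenes
  m0 <- spec$mother[[1]]
  mat_prot <- m0$cas9 > 0
  mat_grna <- "wGDE" %in% .carried(m0, "w")
  prom <- if (mat_prot) m0$promoter else
    if (father$cas9 > 0) father$promoter else
      if (!is.na(m0$promoter)) m0$promoter else "nos"
  off_ctx <- deposition_context(
    maternal_cas9_protein = mat_prot, maternal_grna = mat_grna,
    zygotic_cas9 = TRUE, zygotic_grna = TRUE,  # slice lookup; gated per row
    maternal_promoter = if (mat_prot) prom else NA_character_)
  slice_off <- registry_get_preset(prom, off_ctx, registry)

  has_gde <- df$x1_w == "wGDE" | (!is.na(df$x2_w) & df$x2_w == "wGDE")
  emb_active <- mat_prot & (mat_grna | has_gde)
  df <- .emb_convert_table(df, emb_active, slice_off$params)

  row_ctx <- list(maternal_cas9_protein = mat_prot, maternal_grna = mat_grna)
  cbind(df, .render_phenotypes(df, row_ctx, slice_off))
}

#' Run a seeded, replicated cross
#'
#' For each replicate, draws the vial's mothers, applies embryonic
#' cleavage at their own zygote stage, samples maternal gametes from the
#' exact per-mother gamete distributions and paternal gametes 1:1 X:Y,
#' transmits the autosomal Cas9 Mendelianly, assigns each offspring the
#' deposition context implied by its mother's carried transgenes, applies
#' embryonic cleavage to the offspring (whole-animal), and renders scored
#' phenotypes. Bit-reproducible for a fixed seed; replicate streams are
#' derived from the spec seed so earlier replicates are unchanged when
#' `n_replicates` grows.
#'
#' @param spec A [cross_spec()].
#' @param registry Preset registry from [load_presets()].
#' @return Progeny table (data frame): `replicate`, scored phenotype
#'   columns (`sex`, `eye`, `body`, `gfp`, `rfp`) and hidden-truth columns
#'   (`mat_w`, `mat_y` as transmitted by the mother; `x1_*`, `x2_*` after
#'   embryonic conversion; `cas9`). Estimators may only read the phenotype
#'   columns.
#' @examples
#' tbl <- run_cross(cross_spec(f1_female(1, "BicC"), tester_male("w-"),
#'                             n_progeny = 50, seed = 7))
#' table(tbl$gfp)
#' @export
run_cross <- function(spec, registry = load_presets()) {
  stopifnot(inherits(spec, "cross_spec"))
  if (spec$n_progeny < 1) stop("zero progeny requested: empty table")
  set.seed(spec$seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1, spec$n_replicates)
  out <- vector("list", spec$n_replicates)
  for (r in seq_len(spec$n_replicates)) {
    set.seed(rep_seeds[r])
    out[[r]] <- .sample_replicate(spec, registry, r)
  }
  do.call(rbind, out)
}

#' Write a progeny table as TSV
#'
#' Phenotype columns only by default; the hidden-truth genotype columns go
#' to a companion file when `truth` is given.
#'
#' @param table Progeny table from [run_cross()].
#' @param path Output TSV path.
#' @param truth Optional path for the hidden-truth TSV.
#' @return Invisibly, `path`.
#' @export
write_progeny_table <- function(table, path, truth = NULL) {
  pheno <- table[, c("replicate", "sex", "eye", "body", "gfp", "rfp")]
  utils::write.table(pheno, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(truth)) {
    utils::write.table(table, truth, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# multi-generation scheme
# ---------------------------------------------------------------------------

# rebuild genotypes from truth rows of a progeny table
.genotypes_from_rows <- function(rows, ctx) {
  lapply(seq_len(nrow(rows)), function(i) {
    genotype(rows$sex[i],
             x_state(rows$x1_w[i], rows$x1_y[i]),
             if (rows$sex[i] == "female")
               x_state(rows$x2_w[i], rows$x2_y[i]) else NULL,
             cas9 = rows$cas9[i],
             promoter = if (rows$cas9[i] > 0) ctx$maternal_promoter else NA_character_,
             context = ctx)
  })
}

#' Run a named multi-generation crossing scheme
#'
#' Chains the generations F0 to F3 for one promoter: the bidirectional
#' founder crosses produce the four F1 female classes; classes 1 and 3
#' (heterozygous) are crossed to `w-,y+` tester males and classes 2 and 4
#' (trans-heterozygous) to `w+,y+` males; F2 virgin females are collected
#' among the progeny of class-2 females by marker phenotype (class 5:
#' GFP+ RFP-, class 6: GFP+ RFP+) and crossed to `w-` and `w+` males,
#' respectively, giving the F3 tables. Class 5/6 mothers inherit the
#' protein-plus-gRNA (RNP) carryover context from their class-2 mothers.
#' The `scheme` name selects how far to run the chain.
#'
#' @param scheme One of `"F1_cross"`, `"score_F1_females_1_to_4"`,
#'   `"F2_collection"`, `"F3_scoring"`.
#' @param promoter Cas9 promoter line used throughout.
#' @param registry Preset registry.
#' @param seed Integer seed for the whole scheme.
#' @param n_replicates,n_progeny Per-cross replicate structure.
#' @param n_f2_mothers F2 virgin females collected per replicate vial.
#' @return Named list with (depending on `scheme`) elements `f1`
#'   (progeny tables of the two founder crosses), `f2` (tables for female
#'   classes 1-4), `f2_mothers` (selected class-5/6 genotypes), `f3`
#'   (tables for classes 5-6).
#' @export
run_scheme <- function(scheme = c("F3_scoring", "F1_cross",
                                  "score_F1_females_1_to_4", "F2_collection"),
                       promoter, registry = load_presets(), seed = 1L,
                       n_replicates = 3L, n_progeny = 200L,
                       n_f2_mothers = 10L) {
  scheme <- match.arg(scheme)
  stopifnot(promoter %in% promoters())
  stage <- match(scheme, c("F1_cross", "score_F1_females_1_to_4",
                           "F2_collection", "F3_scoring"))
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1, 8)

  out <- list()
  # F0 -> F1: Cas9 mother x GDe father (classes 1-2) and the reverse
  out$f1 <- list(
    maternal_cas9 = run_cross(cross_spec(cas9_female(promoter), gde_male(),
                                         n_replicates = n_replicates,
                                         n_progeny = n_progeny,
                                         seed = seeds[1]), registry),
    paternal_cas9 = run_cross(cross_spec(gde_female(), cas9_male(promoter),
                                         n_replicates = n_replicates,
                                         n_progeny = n_progeny,
                                         seed = seeds[2]), registry))
  if (stage < 2) return(out)

  # F1 females -> F2 scoring crosses
  testers <- c("w-", "w+", "w-", "w+")
  out$f2 <- stats::setNames(lapply(1:4, function(cl) {
    run_cross(cross_spec(f1_female(cl, promoter), tester_male(testers[cl]),
                         n_replicates = n_replicates, n_progeny = n_progeny,
                         seed = seeds[2 + cl]), registry)
  }), paste0("female", 1:4))
  if (stage < 3) return(out)

  # F2 virgin collection among class-2 progeny, by marker phenotype
  f2_tbl <- out$f2$female2
  rnp_ctx <- deposition_context(maternal_cas9_protein = TRUE,
                                maternal_grna = TRUE,
                                maternal_promoter = promoter)
  pick <- function(sel, label) {
    rows <- f2_tbl[sel, , drop = FALSE]
    if (nrow(rows) == 0) {
      stop("extinct selection class: no eligible ", label, " females")
    }
    n_take <- min(nrow(rows), n_f2_mothers * n_replicates)
    rows <- rows[sample.int(nrow(rows), n_take), , drop = FALSE]
    .genotypes_from_rows(rows, rnp_ctx)
  }
  set.seed(seeds[7])
  out$f2_mothers <- list(
    female5 = pick(f2_tbl$sex == "female" & f2_tbl$gfp & !f2_tbl$rfp, "GFP+ RFP-"),
    female6 = pick(f2_tbl$sex == "female" & f2_tbl$gfp & f2_tbl$rfp, "GFP+ RFP+"))
  if (stage < 4) return(out)

  # F2 females -> F3 scoring crosses
  out$f3 <- list(
    female5 = run_cross(cross_spec(out$f2_mothers$female5, tester_male("w-"),
                                   n_replicates = n_replicates,
                                   n_mothers = n_f2_mothers,
                                   n_progeny = n_progeny, seed = seeds[5],
                                   mothers_at_zygote = FALSE), registry),
    female6 = run_cross(cross_spec(out$f2_mothers$female6, tester_male("w+"),
                                   n_replicates = n_replicates,
                                   n_mothers = n_f2_mothers,
                                   n_progeny = n_progeny, seed = seeds[6],
                                   mothers_at_zygote = FALSE), registry))
  out
}
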