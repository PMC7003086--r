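# Phenotype rendering: constitutive genetics first, then somatic mosaicism.
# Mosaicism is scored as a per-fly, per-locus Bernoulli "visibly mosaic"
# event (presence/absence, not patch area), as in stereoscope scoring.

# vectorised core used by the cross engine; `df` holds genotype columns,
# `ctx` is the shared deposition context of all rows, `slice` the promoter
# preset slice for that context.
.render_phenotypes <- function(df, ctx, slice) {
  n <- nrow(df)
  male <- df$sex == "male"
  has <- function(col1, col2, classes) {
    a <- df[[col1]] %in% classes
    b <- !is.na(df[[col2]]) & df[[col2]] %in% classes
    a | b
  }
  gfp <- has("x1_w", "x2_w", "wGDE")
  rfp <- df$cas9 > 0
  w_funct <- has("x1_w", "x2_w", .w_functional)
  y_funct <- has("x1_y", "x2_y", .y_functional)
  eye <- ifelse(w_funct, "red", "white")
  body <- ifelse(y_funct, "brown", "yellow")

  # somatic mosaicism: needs an active Cas9+gRNA source for this individual
  # and a cleavable allele; only constitutively wild-type tissue can show it
  cas9_src <- ctx$maternal_cas9_protein | df$cas9 > 0
  grna_src <- ctx$maternal_grna | gfp
  active <- cas9_src & grna_src
  w_cleavable <- has("x1_w", "x2_w", "w+")
  y_cleavable <- has("x1_y", "x2_y", "y+")
  mos_w <- active & w_cleavable & eye == "red" &
    stats::runif(n) < slice$p_som_white
  mos_y <- active & y_cleavable & body == "brown" &
    stats::runif(n) < slice$p_som_yellow
  eye[mos_w] <- "mosaic"
  body[mos_y] <- "mosaic"
  data.frame(eye = eye, body = body, gfp = gfp, rfp = rfp)
}

#' Render the scored phenotype of one fly
#'
#' Constitutive genetics come first: white and yellow are recessive, so a
#' female is red-eyed iff at least one X carries a functional white allele
#' (`w+` or `wR1`) and brown-bodied iff one carries `y+`/`yR1`; hemizygous
#' males read their single X. The GFP eye marker reports carriage of the
#' drive element (`wGDE`), the RFP body marker carriage of the Cas9
#' transgene - both deterministic functions of genotype. If the individual
#' then has an active Cas9 source (zygotic gene or maternal protein), a
#' gRNA source, and a cleavable allele at a locus, the corresponding
#' mosaic loss-of-function phenotype is assigned with the preset's somatic
#' penetrance for that promoter and context.
#'
#' @param ind A [genotype()] with its deposition context set.
#' @param preset Slice from [registry_get_preset()] (uses `p_som_white`,
#'   `p_som_yellow`).
#' @return Data frame row: `sex`, `eye` (`red`/`white`/`mosaic`), `body`
#'   (`brown`/`yellow`/`mosaic`), `gfp`, `rfp`.
#' @examples
#' m <- genotype("male", x_state("wGDE", "y-"))
#' render_phenotype(m, registry_get_preset("nos", m$context))  # white, gfp+
#' @export
render_phenotype <- function(ind, preset) {
  stopifnot(inherits(ind, "genotype"))
  df <- data.frame(sex = ind$sex,
                   x1_w = ind$x1[["w"]], x1_y = ind$x1[["y"]],
                   x2_w = if (is.null(ind$x2)) NA else ind$x2[["w"]],
                   x2_y = if (is.null(ind$x2)) NA else ind$x2[["y"]],
                   cas9 = ind$cas9)
  cbind(sex = ind$sex, .render_phenotypes(df, ind$context, preset))
}
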