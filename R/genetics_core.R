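# Allele/genotype state space of the split homing gene drive (split-HGD):
# a gene-drive element (GDe) inserted at the X-linked white locus carrying
# gRNAs against white and yellow plus a GFP marker, and an autosomal Cas9
# transgene (RFP-marked) driven by one of four germline promoters.

#' Allele classes at the white locus
#'
#' `"w+"` intact wild type (cleavable), `"wGDE"` the gene-drive element
#' inserted at white (carries both gRNAs and the GFP marker; white-null),
#' `"wR1"` in-frame functional resistance allele (red-eyed, uncleavable),
#' `"wR2"` loss-of-function resistance allele (white-eyed, uncleavable).
#' `wR1`/`wR2` are terminal: no operation converts them to any other class.
#' The founder `w-` null of tester stocks is represented with `"wR2"`
#' (identical behaviour: loss of function, immune to cleavage).
#'
#' @return Character vector of the four white allele class codes.
#' @export
white_classes <- function() c("w+", "wGDE", "wR1", "wR2")

#' Allele classes at the yellow locus
#'
#' `"y+"` intact (cleavable), `"y-"` the pre-existing loss-of-function allele
#' of the GDe founder line, `"yR1"` Cas9-induced in-frame allele, `"yR2"`
#' Cas9-induced loss-of-function allele. Yellow has no homology donor in the
#' drive, so yellow alleles never undergo HDR conversion; `y-`/`yR1`/`yR2`
#' are terminal. `y-` and `yR2` are kept distinct although phenotypically
#' identical, so that induced germline mutations can be counted on the
#' receiver chromosome only.
#'
#' @return Character vector of the four yellow allele class codes.
#' @export
yellow_classes <- function() c("y+", "y-", "yR1", "yR2")

#' Registered Cas9 promoters
#' @return Character vector of promoter names.
#' @export
promoters <- function() c("nos", "vas", "BicC", "Ubi")

# alleles that still contain a functional gene product
.w_functional <- c("w+", "wR1")
.y_functional <- c("y+", "yR1")

#' One X chromosome of the split-drive system
#'
#' @param w White-locus allele class, see [white_classes()].
#' @param y Yellow-locus allele class, see [yellow_classes()].
#' @return Named character vector `c(w = , y = )`.
#' @examples
#' x_state("wGDE", "y-")  # the GDe founder chromosome
#' @export
x_state <- function(w, y) {
  if (!w %in% white_classes()) stop("unknown white allele class: ", w)
  if (!y %in% yellow_classes()) stop("unknown yellow allele class: ", y)
  c(w = w, y = y)
}

#' Cas9/gRNA deposition context of an individual
#'
#' Records which nuclease and guide sources an individual is exposed to.
#' Maternal flags describe cargo loaded into the egg by the mother
#' (protein if she carried a Cas9 transgene, gRNA if she carried a GDe
#' allele); zygotic flags describe the individual's own transgenes.
#' Paternal Cas9 carriage sets only `zygotic_cas9` in offspring that
#' inherit the gene: sperm carries no effective protein load.
#'
#' @param maternal_cas9_protein Mother carried a Cas9 transgene.
#' @param maternal_grna Mother carried a GDe (wGDE) allele.
#' @param zygotic_cas9 Individual carries a Cas9 transgene.
#' @param zygotic_grna Individual carries a wGDE allele.
#' @param maternal_promoter Promoter of the maternal Cas9 source, or `NA`.
#' @return List with the five fields, class `"deposition_context"`.
#' @export
deposition_context <- function(maternal_cas9_protein = FALSE,
                               maternal_grna = FALSE,
                               zygotic_cas9 = FALSE,
                               zygotic_grna = FALSE,
                               maternal_promoter = NA_character_) {
  if (maternal_cas9_protein && is.na(maternal_promoter)) {
    stop("maternal_cas9_protein = TRUE requires maternal_promoter")
  }
  structure(
    list(maternal_cas9_protein = isTRUE(maternal_cas9_protein),
         maternal_grna = isTRUE(maternal_grna),
         zygotic_cas9 = isTRUE(zygotic_cas9),
         zygotic_grna = isTRUE(zygotic_grna),
         maternal_promoter = maternal_promoter),
    class = "deposition_context")
}

#' Does a context supply both a nuclease and a guide?
#'
#' Cutting requires a Cas9 source (maternal protein or zygotic gene) and a
#' gRNA source (maternal carryover or an own wGDE allele). Paternal protein
#' deposition is never a source.
#'
#' @param context A [deposition_context()].
#' @return Logical.
#' @export
context_is_active <- function(context) {
  (context$maternal_cas9_protein || context$zygotic_cas9) &&
    (context$maternal_grna || context$zygotic_grna)
}

#' A fly genotype
#'
#' Females carry two X chromosomes, males one (`x2 = NULL`); homing is
#' therefore impossible in males. The Cas9 transgene is autosomal and
#' counted (0, 1 or 2 copies).
#'
#' @param sex `"female"` or `"male"`.
#' @param x1 Maternally inherited X, from [x_state()].
#' @param x2 Paternally inherited X ([x_state()]), or `NULL` for males.
#' @param cas9 Number of Cas9 transgene copies (0, 1, 2).
#' @param promoter Promoter of the carried Cas9 transgene (`NA` if `cas9 = 0`).
#' @param context [deposition_context()] of this individual. Zygotic flags
#'   are filled in from the genotype itself.
#' @return List of class `"genotype"`.
#' @examples
#' # F1 heterozygous female with maternally deposited BicC-Cas9 protein
#' genotype("female", x_state("w+", "y+"), x_state("wGDE", "y-"),
#'          context = deposition_context(maternal_cas9_protein = TRUE,
#'                                       maternal_promoter = "BicC"))
#' @export
genotype <- function(sex, x1, x2 = NULL, cas9 = 0L, promoter = NA_character_,
                     context = deposition_context()) {
  sex <- match.arg(sex, c("female", "male"))
  if (sex == "male" && !is.null(x2)) {
    stop("males are hemizygous: exactly one X chromosome")
  }
  if (sex == "female" && is.null(x2)) {
    stop("females carry two X chromosomes")
  }
  if (!cas9 %in% 0:2) stop("cas9 copy number must be 0, 1 or 2")
  if (cas9 > 0 && is.na(promoter)) stop("cas9 > 0 requires a promoter")
  if (!is.na(promoter) && !promoter %in% promoters()) {
    stop("unknown promoter: ", promoter)
  }
  context$zygotic_cas9 <- cas9 > 0
  context$zygotic_grna <- x1[["w"]] == "wGDE" ||
    (!is.null(x2) && x2[["w"]] == "wGDE")
  structure(list(sex = sex, x1 = x1, x2 = x2, cas9 = as.integer(cas9),
                 promoter = promoter, context = context),
            class = "genotype")
}

#' @export
print.genotype <- function(x, ...) {
  xs <- paste0(x$x1[["w"]], ",", x$x1[["y"]])
  if (!is.null(x$x2)) xs <- paste(xs, paste0(x$x2[["w"]], ",", x$x2[["y"]]), sep = " / ")
  cat(sprintf("<genotype> %s  X: %s  Cas9: %d%s\n", x$sex, xs, x$cas9,
              if (x$cas9 > 0) paste0(" (", x$promoter, ")") else ""))
  invisible(x)
}

#' Alleles carried anywhere in a genotype
#' @param g A [genotype()].
#' @return Character vector of white (and yellow) allele classes present.
#' @keywords internal
.carried <- function(g, locus = c("w", "y")) {
  locus <- match.arg(locus)
  out <- g$x1[[locus]]
  if (!is.null(g$x2)) out <- c(out, g$x2[[locus]])
  out
}

# ---------------------------------------------------------------------------
# Promoter preset registry
# ---------------------------------------------------------------------------

#' Germline event parameters of the generative model
#'
#' The per-gamete decomposition of cleavage outcomes at the two target loci.
#' Embryonic cuts (`c_emb_*`) happen in mitotic cells before the
#' developmental stages where efficient HDR repair occurs, so they never
#' produce homing; germline-stage cuts (`c_germ_w`) are repaired by HDR with
#' probability `h` (homing, requires the wGDE homolog as donor) and
#' otherwise by NHEJ, yielding an in-frame R1 allele with probability
#' `r1_w` (else R2). Yellow has no donor, so all yellow cuts are NHEJ.
#'
#' @param c_emb_w P(cleavable w+ allele is cut in the early embryo).
#' @param c_germ_w P(still-intact w+ is cut at the HDR-competent germline
#'   stage).
#' @param h P(a germline-stage cut is repaired by HDR rather than NHEJ).
#' @param r1_w P(an NHEJ repair at white is in-frame, giving wR1).
#' @param c_y P(a y+ allele is cut in the germline).
#' @param r1_y In-frame fraction of NHEJ repairs at yellow.
#' @param c_emb_y P(a y+ allele is cut in the early embryo).
#' @return List of class `"germline_event_params"`.
#' @export
germline_event_params <- function(c_emb_w = 0, c_germ_w = 0, h = 0, r1_w = 0,
                                  c_y = 0, r1_y = 0, c_emb_y = 0) {
  p <- list(c_emb_w = c_emb_w, c_germ_w = c_germ_w, h = h, r1_w = r1_w,
            c_y = c_y, r1_y = r1_y, c_emb_y = c_emb_y)
  bad <- names(p)[!vapply(p, function(v) is.numeric(v) && length(v) == 1 &&
                            is.finite(v) && v >= 0 && v <= 1, logical(1))]
  if (length(bad)) stop("probabilities outside [0,1]: ", paste(bad, collapse = ", "))
  structure(p, class = "germline_event_params")
}

#' Load the shipped promoter preset registry
#'
#' Fitted per-promoter, per-deposition-context event probabilities, stored
#' as data (YAML) so they can be regenerated with
#' [fit_preset_from_observed()] (see `analysis/00_fit_presets.R`).
#'
#' @param path Path to a preset YAML file; defaults to the bundled registry.
#' @return Nested list: `presets[[promoter]][[context]]`, contexts
#'   `"maternal"`, `"zygotic"`, `"rnp"`.
#' @export
load_presets <- function(path = system.file("extdata", "promoter_presets.yaml",
                                            package = "splitdrive")) {
  if (!nzchar(path) || !file.exists(path)) stop("preset file not found: ", path)
  yaml::read_yaml(path)
}

.zero_slice <- function(promoter = NA_character_) {
  list(promoter = promoter, params = germline_event_params(),
       p_som_white = 0, p_som_yellow = 0)
}

#' Parameter slice for a promoter in a deposition context
#'
#' Resolves the event probabilities that apply to one individual:
#' a context lacking either a Cas9 source or a gRNA source yields the
#' all-zero slice (no nuclease activity, not an error). The germline slice
#' comes from the `"maternal"` entry when maternal Cas9 protein is present
#' (carryover dominates the germline exposure) and from `"zygotic"`
#' otherwise; embryonic cut probabilities are non-zero only in the RNP
#' context (maternal protein *and* maternal gRNA loaded together).
#'
#' @param promoter One of [promoters()].
#' @param context A [deposition_context()].
#' @param registry Preset registry from [load_presets()].
#' @return List with elements `promoter`, `params`
#'   ([germline_event_params()]), `p_som_white`, `p_som_yellow`.
#' @examples
#' ctx <- deposition_context(zygotic_grna = TRUE)  # paternal protein only
#' registry_get_preset("nos", ctx)$params$c_germ_w  # 0: no nuclease source
#' @export
registry_get_preset <- function(promoter, context, registry = load_presets()) {
  if (!promoter %in% promoters()) stop("unknown promoter: ", promoter)
  entry <- registry[[promoter]]
  if (is.null(entry)) stop("promoter not in registry: ", promoter)
  if (!context_is_active(context)) return(.zero_slice(promoter))

  germ_ctx <- if (context$maternal_cas9_protein) "maternal" else "zygotic"
  g <- entry[[germ_ctx]]
  if (is.null(g)) stop("unregistered context '", germ_ctx, "' for ", promoter)
  emb <- list(c_emb_w = 0, c_emb_y = 0)
  if (context$maternal_cas9_protein && context$maternal_grna) {
    if (is.null(entry$rnp)) stop("unregistered context 'rnp' for ", promoter)
    emb$c_emb_w <- entry$rnp$c_emb_w
    emb$c_emb_y <- entry$rnp$c_emb_y
  }
  params <- germline_event_params(
    c_emb_w = emb$c_emb_w, c_germ_w = g$c_germ_w, h = g$h, r1_w = g$r1_w,
    c_y = g$c_y, r1_y = g$r1_y, c_emb_y = emb$c_emb_y)
  list(promoter = promoter, params = params,
       p_som_white = g$p_som_white, p_som_yellow = g$p_som_yellow)
}
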