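# Rescue-based drive architectures with lethal biallelic mosaicism:
# a homing drive inserted in an essential gene with a recoded rescue and a
# gRNA-mediated effector (HGD+R+GME), and a cleavage-only drive whose
# rescue sits at a separate locus (CGD+R+GME). Exact Punnett-square
# offspring calculators plus a deterministic infinite-population recursion.

#' Specification of a rescue-drive architecture
#'
#' `HGD_R_GME`: the drive allele `D` sits inside the essential gene (EG)
#' and carries Cas9, gRNAs against EG and a host gene (HG), a marker, and
#' a recoded cleavage-resistant rescue. `CGD_R_GME`: the construct `C`
#' sits at a separate locus and relies exclusively on cleavage - no HDR -
#' so `h` is fixed at 0. Cutting of a cleavable EG allele happens in the
#' carrier mother's germline with probability `cut`, and in her offspring's
#' zygotes via deposited Cas9/gRNA with probability `deposition * cut`
#' (deposition completeness interpolates linearly between the Mendelian
#' and full-cutting Punnett squares). Cut alleles are repaired in frame
#' (functional, immune `R1`) with probability `r1`, else become the
#' loss-of-function `CUT` class. An individual with no intact EG allele
#' (`WT` or `R1`) and no rescue-carrying construct is inviable (lethal
#' biallelic mosaicism); `lethal = FALSE` disables the viability filter,
#' which models split-drive targets like white where knockouts are viable.
#'
#' @param kind `"HGD_R_GME"` or `"CGD_R_GME"`.
#' @param cut Cut probability per cleavable EG allele.
#' @param h HDR (homing) probability for germline cuts; HGD only.
#' @param deposition Maternal deposition completeness in `[0, 1]`.
#' @param r1 In-frame fraction of NHEJ repairs.
#' @param rescue Construct carries a functional rescue (shipped designs
#'   always do).
#' @param lethal Apply the biallelic-mosaicism viability rule.
#' @return List of class `"arch_spec"`.
#' @export
arch_spec <- function(kind = c("HGD_R_GME", "CGD_R_GME"), cut = 1, h = 0,
                      deposition = 1, r1 = 0, rescue = TRUE, lethal = TRUE) {
  kind <- match.arg(kind)
  for (v in c(cut = cut, h = h, deposition = deposition, r1 = r1)) {
    stopifnot(is.numeric(v), v >= 0, v <= 1)
  }
  if (kind == "CGD_R_GME" && h > 0) {
    stop("CGD_R_GME relies exclusively on cleavage: h is fixed at 0")
  }
  structure(list(kind = kind, cut = cut, h = h, deposition = deposition,
                 r1 = r1, rescue = isTRUE(rescue), lethal = isTRUE(lethal)),
            class = "arch_spec")
}

# drive allele symbol of a spec
.drive_allele <- function(spec) if (spec$kind == "HGD_R_GME") "D" else "C"

#' Parent genotypes for the architecture calculators
#'
#' `arch_parent(spec, "het")` is the drive heterozygote (drive allele over
#' an intact essential gene), `arch_parent(spec, "wt")` the wild type.
#' Genotypes are lists with an `eg` allele pair and, for the cleavage-only
#' kind, a `drive` pair at the separate rescue locus; `hg` is the host
#' gene targeted by the effector gRNA.
#'
#' @param spec An [arch_spec()].
#' @param who `"het"` or `"wt"`.
#' @return List with `eg`, `drive` (CGD only) and `hg` allele pairs.
#' @export
arch_parent <- function(spec, who = c("het", "wt")) {
  who <- match.arg(who)
  if (spec$kind == "HGD_R_GME") {
    list(eg = if (who == "het") c("D", "WT") else c("WT", "WT"),
         drive = NULL, hg = c("WT", "WT"))
  } else {
    list(eg = c("WT", "WT"),
         drive = if (who == "het") c("C", "+") else c("+", "+"),
         hg = c("WT", "WT"))
  }
}

.is_carrier <- function(spec, g) .drive_allele(spec) %in% c(g$eg, g$drive)

.is_viable <- function(spec, eg_pair, carrier) {
  if (!spec$lethal) return(TRUE)
  any(eg_pair %in% c("WT", "R1")) || (spec$rescue && carrier)
}

# germline transformation of one EG allele drawn into a gamete of a carrier
# mother; returns data.frame(a, p)
.germline_eg <- function(spec, allele, carrier) {
  if (allele != "WT" || !carrier || spec$cut == 0) {
    return(data.frame(a = allele, p = 1))
  }
  cut <- spec$cut; h <- spec$h; r1 <- spec$r1
  data.frame(a = c("WT", "D", "R1", "CUT"),
             p = c(1 - cut, cut * h, cut * (1 - h) * r1,
                   cut * (1 - h) * (1 - r1)))
}

# gamete distribution over (eg, drive) for a mother (with germline events)
# or a father (Mendelian)
.arch_gametes <- function(spec, g, is_mother) {
  carrier <- .is_carrier(spec, g)
  eg <- do.call(rbind, lapply(g$eg, function(a) {
    d <- if (is_mother) .germline_eg(spec, a, carrier)
    else data.frame(a = a, p = 1)
    d$p <- d$p * 0.5
    d
  }))
  eg <- .aggregate_dist(stats::setNames(eg, c("a", "prob")), "a")
  if (is.null(g$drive)) {
    data.frame(eg = eg$a, drive = NA, prob = eg$prob)
  } else {
    dr <- data.frame(a = g$drive, prob = 0.5)
    dr <- .aggregate_dist(dr, "a")
    out <- merge(eg, dr, by = NULL)
    data.frame(eg = out$a.x, drive = out$a.y,
               prob = out$prob.x * out$prob.y)
  }
}

# expand one allele column by maternal-deposition cutting
.deposit_cut <- function(df, col, p_cut, r1) {
  if (p_cut <= 0) return(df)
  hit <- !is.na(df[[col]]) & df[[col]] == "WT"
  if (!any(hit)) return(df)
  keep <- df[!hit, , drop = FALSE]
  base <- df[hit, , drop = FALSE]
  parts <- Map(function(a, w) {
    d <- base; d[[col]] <- a; d$prob <- d$prob * w; d
  }, c("WT", "R1", "CUT"), c(1 - p_cut, p_cut * r1, p_cut * (1 - r1)))
  rbind(keep, do.call(rbind, parts))
}

#' Exact offspring outcomes of one architecture cross
#'
#' Enumerates all gamete combinations with exact fractions: germline
#' cutting (and, for the homing kind, HDR conversion at rate `h`) in the
#' carrier mother; Mendelian paternal gametes (paternal carriers
#' contribute zygotic expression but no deposition); maternal-deposition
#' cutting of offspring wild-type EG and HG alleles at
#' `deposition * cut`; then the lethal-biallelic-mosaicism viability rule.
#'
#' @param spec An [arch_spec()].
#' @param mother,father Parent genotypes from [arch_parent()] (both
#'   parents must be viable under the spec, else a contract violation).
#' @return Data frame of offspring classes: allele columns, `zygote_fraction`
#'   (summing to 1 before viability filtering), `viable`, `carrier`.
#'   Attributes `transmission` (% drive carriers among viable offspring),
#'   `viable_fraction` (of zygotes) and `refractoriness` (% viable
#'   offspring with both host-gene alleles knocked out).
#' @examples
#' po <- punnett_offspring(arch_spec("HGD_R_GME", cut = 1, h = 0.5),
#'                         arch_parent(arch_spec("HGD_R_GME"), "het"),
#'                         arch_parent(arch_spec("HGD_R_GME"), "wt"))
#' attr(po, "transmission")   # 100
#' attr(po, "viable_fraction")  # 0.75
#' @export
punnett_offspring <- function(spec, mother, father) {
  stopifnot(inherits(spec, "arch_spec"))
  for (g in list(mother, father)) {
    if (!.is_viable(spec, g$eg, .is_carrier(spec, g))) {
      stop("contract violation: inviable parental genotype")
    }
  }
  mg <- .arch_gametes(spec, mother, is_mother = TRUE)
  fg <- .arch_gametes(spec, father, is_mother = FALSE)
  z <- merge(mg, fg, by = NULL, suffixes = c("_m", "_f"))
  z <- data.frame(eg1 = z$eg_m, eg2 = z$eg_f,
                  drive1 = z$drive_m, drive2 = z$drive_f,
                  hg1 = mother$hg[1], hg2 = father$hg[1],
                  prob = z$prob_m * z$prob_f)

  p_dep <- if (.is_carrier(spec, mother)) spec$deposition * spec$cut else 0
  for (col in c("eg1", "eg2", "hg1", "hg2")) {
    z <- .deposit_cut(z, col, p_dep, spec$r1)
  }
  key <- c("eg1", "eg2", "drive1", "drive2", "hg1", "hg2")
  tmp <- z
  for (col in key) tmp[[col]][is.na(tmp[[col]])] <- "."
  z <- .aggregate_dist(tmp, key)
  for (col in key) z[[col]][z[[col]] == "."] <- NA
  z <- z[z$prob > 0, , drop = FALSE]

  da <- .drive_allele(spec)
  z$carrier <- z$eg1 == da | z$eg2 == da |
    (!is.na(z$drive1) & (z$drive1 == da | z$drive2 == da))
  z$viable <- mapply(function(a, b, carr) .is_viable(spec, c(a, b), carr),
                     z$eg1, z$eg2, z$carrier)
  names(z)[names(z) == "prob"] <- "zygote_fraction"
  stopifnot(abs(sum(z$zygote_fraction) - 1) < 1e-12)

  vf <- sum(z$zygote_fraction[z$viable])
  trans <- if (vf > 0) {
    100 * sum(z$zygote_fraction[z$viable & z$carrier]) / vf
  } else NA_real_
  hg_ko <- z$viable & z$hg1 == "CUT" & z$hg2 == "CUT"
  refr <- if (vf > 0) 100 * sum(z$zygote_fraction[hg_ko]) / vf else NA_real_
  structure(z, transmission = trans, viable_fraction = vf,
            refractoriness = refr)
}

# ---------------------------------------------------------------------------
# deterministic spread recursion
# ---------------------------------------------------------------------------

.geno_table <- function(spec) {
  eg_alleles <- if (spec$kind == "HGD_R_GME") c("D", "WT", "CUT", "R1")
  else c("WT", "CUT", "R1")
  eg <- expand.grid(a = eg_alleles, b = eg_alleles, stringsAsFactors = FALSE)
  eg <- eg[as.integer(factor(eg$a, eg_alleles)) <=
             as.integer(factor(eg$b, eg_alleles)), ]
  if (spec$kind == "HGD_R_GME") {
    data.frame(eg1 = eg$a, eg2 = eg$b, drive1 = NA, drive2 = NA)
  } else {
    dr <- data.frame(d1 = c("C", "C", "+"), d2 = c("C", "+", "+"))
    out <- merge(eg, dr, by = NULL)
    data.frame(eg1 = out$a, eg2 = out$b, drive1 = out$d1, drive2 = out$d2)
  }
}

.row_genotype <- function(spec, row) {
  list(eg = c(row$eg1, row$eg2),
       drive = if (spec$kind == "CGD_R_GME") c(row$drive1, row$drive2) else NULL,
       hg = c("WT", "WT"))
}

.geno_key <- function(df) {
  eg <- mapply(function(a, b) paste(sort(c(a, b)), collapse = "/"),
               df$eg1, df$eg2)
  dr <- ifelse(is.na(df$drive1), "",
               paste0(";", mapply(function(a, b) paste(sort(c(a, b)), collapse = "/"),
                                  df$drive1, df$drive2)))
  paste0(eg, dr)
}

#' Deterministic multi-generation spread of an architecture
#'
#' Infinite-population, random-mating recursion: each generation pairs
#' every mother genotype with every father genotype in proportion to their
#' frequencies, accumulates the exact zygote distributions from
#' [punnett_offspring()], applies the viability filter, and renormalizes.
#' Sexes are assumed to share genotype frequencies.
#'
#' @param spec An [arch_spec()].
#' @param p0 Initial drive allele frequency (Hardy-Weinberg start).
#' @param generations Number of generations to iterate.
#' @return Data frame, one row per generation (0 = initial): drive allele
#'   frequency `drive_freq`, carrier fraction `carrier_freq`, and the
#'   `WT`, `CUT` and `R1` essential-gene allele frequencies.
#' @examples
#' simulate_spread(arch_spec("HGD_R_GME", cut = 0), 0.1, 3)  # neutral
#' @export
simulate_spread <- function(spec, p0, generations) {
  stopifnot(inherits(spec, "arch_spec"), p0 >= 0, p0 <= 1, generations >= 1)
  gt <- .geno_table(spec)
  gt$key <- .geno_key(gt)

  # Hardy-Weinberg initial frequencies
  freq <- numeric(nrow(gt))
  da <- .drive_allele(spec)
  allele_p <- function(a, locus) {
    if (a == da) p0 else if (a %in% c("WT", "+")) 1 - p0 else 0
  }
  for (i in seq_len(nrow(gt))) {
    if (spec$kind == "HGD_R_GME") {
      pa <- allele_p(gt$eg1[i]); pb <- allele_p(gt$eg2[i])
      freq[i] <- pa * pb * (if (gt$eg1[i] == gt$eg2[i]) 1 else 2)
    } else {
      if (gt$eg1[i] != "WT" || gt$eg2[i] != "WT") next
      pa <- allele_p(gt$drive1[i]); pb <- allele_p(gt$drive2[i])
      freq[i] <- pa * pb * (if (gt$drive1[i] == gt$drive2[i]) 1 else 2)
    }
  }
  stopifnot(abs(sum(freq) - 1) < 1e-9)

  summarize <- function(freq) {
    eg_all <- c(gt$eg1, gt$eg2)
    w <- c(freq, freq) / 2
    carr <- gt$eg1 == da | gt$eg2 == da |
      (!is.na(gt$drive1) & (gt$drive1 == da | gt$drive2 == da))
    dr_freq <- if (spec$kind == "HGD_R_GME") {
      sum(w[eg_all == "D"])
    } else {
      sum(c(freq, freq)[c(gt$drive1, gt$drive2) == "C"] / 2)
    }
    data.frame(drive_freq = dr_freq, carrier_freq = sum(freq[carr]),
               WT = sum(w[eg_all == "WT"]), CUT = sum(w[eg_all == "CUT"]),
               R1 = sum(w[eg_all == "R1"]))
  }

  traj <- cbind(generation = 0, summarize(freq))
  active <- which(freq > 1e-15)
  for (gen in seq_len(generations)) {
    acc <- stats::setNames(numeric(nrow(gt)), gt$key)
    for (i in active) {
      gm <- .row_genotype(spec, gt[i, ])
      if (!.is_viable(spec, gm$eg, .is_carrier(spec, gm))) next
      for (j in active) {
        gf <- .row_genotype(spec, gt[j, ])
        if (!.is_viable(spec, gf$eg, .is_carrier(spec, gf))) next
        po <- punnett_offspring(spec, gm, gf)
        po <- po[po$viable & po$zygote_fraction > 0, , drop = FALSE]
        if (!nrow(po)) next
        keys <- .geno_key(po)
        w <- freq[i] * freq[j] * po$zygote_fraction
        for (k in seq_along(keys)) acc[keys[k]] <- acc[keys[k]] + w[k]
      }
    }
    if (sum(acc) <= 0) stop("population extinct under the viability rule")
    freq <- unname(acc / sum(acc))
    active <- which(freq > 1e-15)
    traj <- rbind(traj, cbind(generation = gen, summarize(freq)))
  }
  rownames(traj) <- NULL
  traj
}

#' Spread trajectory tracking functional-resistant (R1) leakage
#'
#' In-frame repair products are immune to re-cutting, fully functional and
#' viable, so with `r1 > 0` they accumulate while drive and wild type
#' coexist and ultimately cap the drive's spread.
#'
#' @param spec An [arch_spec()] with `r1` in `[0, 1)`.
#' @param p0 Initial drive allele frequency.
#' @param generations Number of generations.
#' @return As [simulate_spread()]; the `R1` column is the functional-
#'   resistant allele frequency.
#' @export
r1_leakage <- function(spec, p0, generations) {
  stopifnot(spec$r1 >= 0, spec$r1 < 1)
  simulate_spread(spec, p0, generations)
}
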