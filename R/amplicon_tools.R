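# Target-site validation and classification of amplicon sequences at a
# Cas9 cut site into wild type / in-frame functional (R1) / frameshift
# loss-of-function (R2), mirroring Sanger genotyping of resolved alleles.

#' Validate a 23-nt SpCas9 target (protospacer + PAM)
#'
#' Accepts exactly 23 uppercase bases whose last three match the NGG PAM.
#' The blunt cut falls between protospacer positions 17 and 18, i.e. 3 bp
#' 5' of the PAM.
#'
#' @param seq 23-character DNA string (protospacer then PAM).
#' @param reading_frame_offset Offset (0/1/2) of protospacer position 1
#'   relative to the coding frame; carried through for reporting.
#' @return List of class `"target_site"`: `protospacer`, `pam`,
#'   `cut_offset` (17), `reading_frame_offset`, `seq`.
#' @examples
#' validate_target("GGCGATACTTGGATGCCCTGCGG")$pam  # "CGG"
#' @export
validate_target <- function(seq, reading_frame_offset = 0L) {
  if (!is.character(seq) || length(seq) != 1) stop("seq must be one string")
  if (nchar(seq) != 23) {
    stop("target validation failed: length ", nchar(seq), ", expected 23")
  }
  if (grepl("[^ACGT]", seq)) {
    stop("target validation failed: non-ACGT characters present")
  }
  if (substr(seq, 22, 23) != "GG") {
    stop("target validation failed: PAM '", substr(seq, 21, 23),
         "' does not match NGG")
  }
  if (!reading_frame_offset %in% 0:2) stop("reading_frame_offset must be 0, 1 or 2")
  structure(list(protospacer = substr(seq, 1, 20), pam = substr(seq, 21, 23),
                 cut_offset = 17L,
                 reading_frame_offset = as.integer(reading_frame_offset),
                 seq = seq),
            class = "target_site")
}

# locate the target in a reference; returns 1-based start or errors
.locate_site <- function(reference, site, min_flank = 20L) {
  pos <- as.integer(regexpr(site$seq, reference, fixed = TRUE))
  if (pos < 1) stop("target site not found in reference")
  if (pos - 1 < min_flank || nchar(reference) - (pos + 22) < min_flank) {
    stop("reference must cover the target with >= ", min_flank, " bp flanks")
  }
  pos
}

#' Classify one amplicon sequence at a cut site
#'
#' Globally aligns the observed sequence against the reference
#' (match +1, mismatch -1, gap opening 4, gap extension 1) and computes
#' the net length change from insertions and deletions falling within a
#' +/- 20 bp window around the cut. Calls: `R2` if the net change is not
#' divisible by 3 (frameshift); `R1` if it is a non-zero multiple of 3
#' (in-frame), or zero with at least one substitution disrupting the seed
#' region (protospacer positions 13-20) or the PAM - the operational
#' proxy for functional resistance; `WT` otherwise. Indels outside the
#' window with none inside give `WT` with a warning flag. Equal-score
#' alignment placements are resolved by the aligner's deterministic
#' convention; the call depends only on the net length change, so ties
#' cannot change it.
#'
#' @param reference Reference amplicon sequence (uppercase DNA string)
#'   containing the target with at least 20 bp flanks.
#' @param observed Observed amplicon sequence.
#' @param site A [validate_target()] site present in the reference.
#' @return List: `net` (signed bp), `class` (`"WT"`/`"R1"`/`"R2"`),
#'   `span` (1-based reference coordinates of the affected region, `NA`
#'   if none), `flagged` (`TRUE` when indels occur only outside the
#'   window).
#' @export
classify_indel <- function(reference, observed, site) {
  stopifnot(inherits(site, "target_site"))
  pos <- .locate_site(reference, site)
  cut_after <- pos + site$cut_offset - 1L  # cut between this base and the next
  win <- c(cut_after - 19L, cut_after + 20L)

  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(observed), Biostrings::DNAString(reference),
    type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = TRUE),
    gapOpening = 4, gapExtension = 1)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ref_coord <- cumsum(s != "-")  # 0 before the first reference base

  ins_cols <- which(s == "-")
  del_cols <- which(p == "-")
  in_win <- function(cols) {
    rc <- pmax(ref_coord[cols], 1L)
    cols[rc >= win[1] & rc <= win[2]]
  }
  ins_w <- in_win(ins_cols)
  del_w <- in_win(del_cols)
  net <- length(ins_w) - length(del_w)

  # substitutions disrupting the seed (protospacer 13-20) or PAM
  sub_cols <- which(p != "-" & s != "-" & p != s)
  seed_pam <- c(pos + 12L, pos + 22L)
  sub_site <- sub_cols[ref_coord[sub_cols] >= seed_pam[1] &
                         ref_coord[sub_cols] <= seed_pam[2]]

  outside_only <- net == 0 &&
    (length(ins_cols) + length(del_cols) > length(ins_w) + length(del_w)) &&
    length(ins_w) + length(del_w) == 0
  cls <- if (net %% 3 != 0) "R2"
  else if (net != 0) "R1"
  else if (length(sub_site) > 0) "R1"
  else "WT"

  ev <- c(ref_coord[ins_w], ref_coord[del_w],
          if (cls == "R1" && net == 0) ref_coord[sub_site])
  span <- if (length(ev)) range(pmax(ev, 1L)) else c(NA_integer_, NA_integer_)
  if (outside_only) {
    warning("indels found only outside the cut-site window; calling WT")
  }
  list(net = as.integer(net), class = cls, span = span,
       flagged = outside_only)
}

#' Classify a set of amplicons
#'
#' @param reference Reference amplicon sequence.
#' @param amplicons Named character vector of observed sequences (e.g.
#'   from `Biostrings::readDNAStringSet()` coerced with `as.character()`).
#' @param site A [validate_target()] site.
#' @return Data frame: `id`, `net`, `class`, `flagged` - one row per
#'   amplicon, suitable for TSV export.
#' @export
classify_amplicons <- function(reference, amplicons, site) {
  if (is.null(names(amplicons))) names(amplicons) <- seq_along(amplicons)
  calls <- lapply(amplicons, function(o) {
    suppressWarnings(classify_indel(reference, o, site))
  })
  data.frame(id = names(amplicons),
             net = vapply(calls, `[[`, integer(1), "net"),
             class = vapply(calls, `[[`, character(1), "class"),
             flagged = vapply(calls, `[[`, logical(1), "flagged"),
             row.names = NULL)
}

#' Generate labeled mutant amplicons at a cut site
#'
#' Fixture generator for the classifier: emits edited copies of the
#' reference with truth labels. In-frame mutants are deletions of 3/6/9 bp
#' ending at the cut; frameshift mutants are 1-5 bp deletions or 1-2 bp
#' insertions at the cut; substitution mutants change one seed-region base
#' (net 0, labeled R1). Non-degenerate cases must round-trip through
#' [classify_indel()] exactly.
#'
#' @param reference Reference amplicon containing the site.
#' @param site A [validate_target()] site.
#' @param n Number of sequences.
#' @param r1_fraction Fraction of mutants drawn as in-frame deletions.
#' @param sub_fraction Fraction drawn as seed-region substitutions.
#' @param seed Integer seed.
#' @return Data frame: `id`, `seq`, `truth_class`, `net`.
#' @export
generate_mutant_amplicons <- function(reference, site, n, r1_fraction = 0.3,
                                      sub_fraction = 0, seed = 1L) {
  stopifnot(n >= 0, r1_fraction + sub_fraction <= 1)
  if (n == 0) {
    return(data.frame(id = character(), seq = character(),
                      truth_class = character(), net = integer()))
  }
  pos <- .locate_site(reference, site)
  cut_after <- pos + site$cut_offset - 1L
  set.seed(seed)
  type <- sample(c("inframe", "sub", "shift"), n, replace = TRUE,
                 prob = c(r1_fraction, sub_fraction,
                          1 - r1_fraction - sub_fraction))
  out <- lapply(seq_len(n), function(i) {
    if (type[i] == "inframe") {
      k <- sample(c(3L, 6L, 9L), 1)
      seqi <- paste0(substr(reference, 1, cut_after - k),
                     substr(reference, cut_after + 1, nchar(reference)))
      list(seq = seqi, cls = "R1", net = -k)
    } else if (type[i] == "sub") {
      at <- sample(seq(pos + 12L, pos + 19L), 1)
      old <- substr(reference, at, at)
      new <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
      seqi <- reference
      substr(seqi, at, at) <- new
      list(seq = seqi, cls = "R1", net = 0L)
    } else {
      k <- sample(c(-1L, -2L, -4L, -5L, 1L, 2L), 1)
      if (k < 0) {
        seqi <- paste0(substr(reference, 1, cut_after + k),
                       substr(reference, cut_after + 1, nchar(reference)))
      } else {
        ins <- paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
                     collapse = "")
        seqi <- paste0(substr(reference, 1, cut_after), ins,
                       substr(reference, cut_after + 1, nchar(reference)))
      }
      list(seq = seqi, cls = "R2", net = k)
    }
  })
  data.frame(id = sprintf("mut%04d", seq_len(n)),
             seq = vapply(out, `[[`, character(1), "seq"),
             truth_class = vapply(out, `[[`, character(1), "cls"),
             net = vapply(out, `[[`, integer(1), "net"),
             row.names = NULL)
}

#' The two gRNA target sites of the split-drive system
#'
#' Validated 23-mers (protospacer + PAM) at white and yellow.
#'
#' @return Named list of [validate_target()] sites `white` and `yellow`.
#' @export
drive_target_sites <- function() {
  list(white = validate_target("GGCGATACTTGGATGCCCTGCGG"),
       yellow = validate_target("GGTTTTGGACACTGGAACCGTGG"))
}
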