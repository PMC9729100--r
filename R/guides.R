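#' Enumerate SpCas9 guide candidates disrupted by the assay edits
#'
#' Scans both strands of the locus for NGG PAM sites and keeps protospacers in
#' which the variant (and, in joint mode, the WT-prime edit) falls inside the
#' PAM's GG dinucleotide or within the seed region -- the `seed_max`
#' PAM-proximal protospacer bases. Knock-in of an edit in seed or PAM destroys
#' the Cas9 target site and so prevents re-cutting of edited alleles. The cut
#' site is modelled as the canonical SpCas9 blunt cut between protospacer
#' positions 17 and 18 (3 nt 5' of the PAM).
#'
#' Candidates are ranked by increasing distance of the variant from the cut
#' (knock-in efficiency decays with distance), then by smaller seed offset,
#' then plus strand first.
#'
#' @param locus A [reference_locus()].
#' @param variant A [variant_spec()].
#' @param wtprime Optional second [variant_spec()] (the WT-prime edit) that
#'   must also disrupt the guide when `joint = TRUE`.
#' @param joint Require disruption by both edits (default) or by the variant
#'   alone.
#' @param seed_max Seed width in nt from the PAM-proximal protospacer end
#'   (default 10).
#' @return Tibble of guide candidates: `protospacer`, `pam`, `strand`,
#'   `cut_after` (cut falls between this plus-strand position and the next),
#'   `variant_distance_to_cut` (signed; negative = left of the cut),
#'   `disruption_offsets` (list column of seed/PAM offsets hit; PAM hits coded
#'   as 0), `min_seed_offset`.
#' @export
enumerate_guides <- function(locus, variant, wtprime = NULL, joint = TRUE,
                             seed_max = 10L) {
  s <- locus$sequence
  n <- nchar(s)
  flank <- c(variant$position - 1L, n - variant$position)
  if (n < 60L || min(flank) < 25L) {
    abort("locus too short around the variant to scan for guides (need >= 60 nt)")
  }
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]

  sites <- list()
  # plus strand: PAM 'NGG' at [p, p+2], protospacer [p-20, p-1]
  gg_plus <- which(ch[-n] == "G" & ch[-1L] == "G")  # positions p+1 of GG
  for (g1 in gg_plus) {
    p <- g1 - 1L                       # PAM start (the N)
    if (p - 20L < 1L || p + 2L > n) next
    sites[[length(sites) + 1L]] <- list(
      strand = "+", pam_start = p,
      protospacer = substr(s, p - 20L, p - 1L),
      pam = substr(s, p, p + 2L),
      cut_after = p - 4L
    )
  }
  # minus strand: plus-strand 'CCN' at [p, p+2], protospacer [p+3, p+22]
  cc_plus <- which(ch[-n] == "C" & ch[-1L] == "C")  # positions p of CC
  for (p in cc_plus) {
    if (p + 22L > n || p < 1L) next
    sites[[length(sites) + 1L]] <- list(
      strand = "-", pam_start = p,
      protospacer = reverse_complement(substr(s, p + 3L, p + 22L)),
      pam = reverse_complement(substr(s, p, p + 2L)),
      cut_after = p + 5L
    )
  }
  if (!length(sites)) return(empty_guide_tbl())

  edits <- list(variant)
  if (joint && !is.null(wtprime)) edits <- c(edits, list(wtprime))

  rows <- purrr::map(sites, function(site) {
    offs <- unlist(lapply(edits, function(e) {
      edit_site_offsets(e, site, seed_max = seed_max)
    }), use.names = FALSE)
    per_edit_ok <- vapply(edits, function(e) {
      o <- edit_site_offsets(e, site, seed_max = seed_max)
      length(o) > 0L && !anyNA(o)
    }, logical(1))
    if (!all(per_edit_ok)) return(NULL)
    d <- signed_cut_distance(variant, site$cut_after)
    tibble(
      protospacer = site$protospacer, pam = site$pam, strand = site$strand,
      pam_start = site$pam_start, cut_after = site$cut_after,
      variant_distance_to_cut = d,
      disruption_offsets = list(sort(offs)),
      min_seed_offset = min(offs[offs > 0L], Inf)
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty_guide_tbl())
  out <- bind_rows(rows)
  out[order(abs(out$variant_distance_to_cut), out$min_seed_offset,
            out$strand != "+"), , drop = FALSE]
}

empty_guide_tbl <- function() {
  tibble(protospacer = character(), pam = character(), strand = character(),
         pam_start = integer(), cut_after = integer(),
         variant_distance_to_cut = integer(),
         disruption_offsets = list(), min_seed_offset = double())
}

# Positions affected by an edit, on the plus strand of the locus.
edit_positions <- function(edit) {
  if (nzchar(edit$ref)) {
    seq.int(edit$position, edit$position + nchar(edit$ref) - 1L)
  } else {
    # pure insertion: lands between position-1 and position
    c(edit$position - 1L, edit$position)
  }
}

# Seed/PAM offsets hit by an edit at a guide site. Returns integer(0) if the
# edit misses the protospacer/PAM entirely, NA if it touches it only outside
# seed/PAM-GG (i.e. the guide is not reliably disrupted), else the offsets
# (seed offset 1..seed_max, PAM-GG hits coded 0).
edit_site_offsets <- function(edit, site, seed_max = 10L) {
  pos <- edit_positions(edit)
  if (site$strand == "+") {
    p <- site$pam_start
    proto <- pos >= p - 20L & pos <= p - 1L
    seed_off <- ifelse(proto, p - pos, NA_integer_)
    pam_gg <- pos %in% c(p + 1L, p + 2L)
    footprint <- pos >= p - 20L & pos <= p + 2L
  } else {
    p <- site$pam_start
    proto <- pos >= p + 3L & pos <= p + 22L
    seed_off <- ifelse(proto, pos - p - 2L, NA_integer_)
    pam_gg <- pos %in% c(p, p + 1L)
    footprint <- pos >= p & pos <= p + 22L
  }
  hit_seed <- !is.na(seed_off) & seed_off <= seed_max
  if (!any(footprint)) return(integer(0))
  offs <- c(seed_off[hit_seed], rep(0L, sum(pam_gg)))
  if (!length(offs)) return(NA_integer_)
  as.integer(offs)
}

# Signed distance from the cut junction to the nearest edited base:
# -1 = base immediately left of the cut, +1 = immediately right.
signed_cut_distance <- function(edit, cut_after) {
  pos <- edit_positions(edit)
  d <- ifelse(pos <= cut_after, pos - cut_after - 1L, pos - cut_after)
  d[which.min(abs(d))]
}

#' Screen a guide against off-target sites
#'
#' Exhaustively scans the supplied sequences (both strands) for 20-nt+NGG
#' sites within `max_mismatches` protospacer mismatches of the guide, excludes
#' the on-target site, and applies the design rule that the closest potential
#' off-target must carry at least one mismatch in the PAM or the seed region.
#' Because only sites that retain an NGG PAM are scanned (a lost GG abolishes
#' recognition outright; the N is degenerate), the rule reduces to requiring
#' a seed mismatch in every minimal-mismatch hit.
#'
#' @param guide One guide row from [enumerate_guides()] (or a list with
#'   `protospacer`, and optionally `pam_start`/`strand` to identify the
#'   on-target site).
#' @param references Named character vector of reference sequences to scan
#'   (e.g. the locus plus decoys). Desk-scale only; genome-wide screening is
#'   out of scope.
#' @param max_mismatches Maximum protospacer mismatches for a site to count
#'   as a potential off-target (default 3).
#' @param seed_max Seed width (default 10).
#' @return A list of class `offtarget_report`: `hits` tibble (`sequence`,
#'   `position`, `strand`, `mismatches`, `mismatch_offsets`, `seed_mismatch`),
#'   and `pass` flag.
#' @export
screen_offtargets <- function(guide, references, max_mismatches = 3L,
                              seed_max = 10L) {
  if (is.data.frame(guide)) guide <- as.list(guide[1L, ])
  proto <- strsplit(guide$protospacer, "", fixed = TRUE)[[1L]]
  stopifnot(length(proto) == 20L)
  if (is.null(names(references))) {
    names(references) <- paste0("ref", seq_along(references))
  }
  hits <- list()
  for (nm in names(references)) {
    s <- toupper(references[[nm]])
    n <- nchar(s)
    if (n < 23L) next
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    # plus-strand sites: NGG PAM at [p, p+2]
    gg <- which(ch[-n] == "G" & ch[-1L] == "G")
    for (g1 in gg) {
      p <- g1 - 1L
      if (p - 20L < 1L || p + 2L > n) next
      site <- ch[(p - 20L):(p - 1L)]
      mm <- which(site != proto)
      if (length(mm) > max_mismatches) next
      hits[[length(hits) + 1L]] <- tibble(
        sequence = nm, position = p - 20L, strand = "+",
        mismatches = length(mm),
        mismatch_offsets = list(21L - mm),   # 1 = PAM-proximal
        site_seq = paste(site, collapse = "")
      )
    }
    # minus-strand sites: CCN at [p, p+2] on the stored strand
    cc <- which(ch[-n] == "C" & ch[-1L] == "C")
    for (p in cc) {
      if (p + 22L > n) next
      site <- strsplit(reverse_complement(paste(ch[(p + 3L):(p + 22L)],
                                                collapse = "")),
                       "", fixed = TRUE)[[1L]]
      mm <- which(site != proto)
      if (length(mm) > max_mismatches) next
      hits[[length(hits) + 1L]] <- tibble(
        sequence = nm, position = p + 3L, strand = "-",
        mismatches = length(mm),
        mismatch_offsets = list(21L - mm),
        site_seq = paste(site, collapse = "")
      )
    }
  }
  hits <- if (length(hits)) bind_rows(hits) else
    tibble(sequence = character(), position = integer(), strand = character(),
           mismatches = integer(), mismatch_offsets = list(),
           site_seq = character())

  # drop the on-target site: by coordinate when known, else the first
  # zero-mismatch hit
  if (nrow(hits)) {
    if (!is.null(guide$pam_start) && !is.null(guide$strand)) {
      on_pos <- if (guide$strand == "+") guide$pam_start - 20L else
        guide$pam_start + 3L
      drop <- which(hits$mismatches == 0L & hits$position == on_pos &
                      hits$strand == guide$strand)[1L]
    } else {
      drop <- which(hits$mismatches == 0L)[1L]
    }
    if (!is.na(drop)) hits <- hits[-drop, , drop = FALSE]
  }

  hits$seed_mismatch <- vapply(hits$mismatch_offsets, function(o) {
    any(o <= seed_max)
  }, logical(1))

  pass <- if (!nrow(hits)) TRUE else {
    mmin <- min(hits$mismatches)
    all(hits$seed_mismatch[hits$mismatches == mmin])
  }
  structure(list(hits = hits[order(hits$mismatches), , drop = FALSE],
                 pass = pass, max_mismatches = max_mismatches),
            class = "offtarget_report")
}

#' @export
print.offtarget_report <- function(x, ...) {
  cat("<offtarget_report> ", nrow(x$hits), " hit(s) within ",
      x$max_mismatches, " mismatches; ",
      if (x$pass) "PASS" else "FAIL (closest hit lacks seed/PAM mismatch)",
      "\n", sep = "")
  invisible(x)
}
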