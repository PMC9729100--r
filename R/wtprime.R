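#' Splice-motif screen for candidate synonymous edits
#'
#' A deliberately simple position-weight-matrix screen for the two canonical
#' human splice motifs: the 9-nt donor site (3 exonic + 6 intronic bases,
#' consensus `MAG|GTRAGT`) and the acceptor region (a pyrimidine-rich tract
#' followed by the invariant `AG`). A candidate edit is rejected when it
#' creates a window scoring at or above the motif threshold where the
#' reference sequence scored below it. This is a conservative stand-in for a
#' full splicing-predictor model, and can be bypassed per candidate with an
#' allowlist in the designer config.
#'
#' Scores are summed log2 odds against a uniform background, so the maximum
#' donor score (perfect consensus at every position) is about 13 bits; the
#' default threshold of 8 bits corresponds to a near-consensus site with the
#' invariant GT present.
#'
#' @param reference,edited Same-length nucleotide strings.
#' @param center Position around which to screen (windows overlapping
#'   `center +/- flank` are evaluated).
#' @param flank Half-width of the screened region (default 12).
#' @param donor_threshold,acceptor_threshold Bits above which a window counts
#'   as a motif.
#' @return List: `ok` (logical), `donor_created`, `acceptor_created`,
#'   `max_donor`, `max_acceptor` (scores in the edited sequence).
#' @export
splice_screen <- function(reference, edited, center, flank = 12L,
                          donor_threshold = 8, acceptor_threshold = 8) {
  stopifnot(nchar(reference) == nchar(edited))
  don_ref <- max_motif_score(reference, donor_pwm(), center, flank)
  don_ed <- max_motif_score(edited, donor_pwm(), center, flank)
  acc_ref <- max_motif_score(reference, acceptor_pwm(), center, flank)
  acc_ed <- max_motif_score(edited, acceptor_pwm(), center, flank)
  donor_created <- don_ed >= donor_threshold && don_ref < donor_threshold
  acceptor_created <- acc_ed >= acceptor_threshold && acc_ref < acceptor_threshold
  list(ok = !donor_created && !acceptor_created,
       donor_created = donor_created, acceptor_created = acceptor_created,
       max_donor = don_ed, max_acceptor = acc_ed)
}

# Donor: positions -3..+6 around the exon|intron junction (consensus MAGGTRAGT).
# Base frequencies follow the classical human 5' splice-site compilation,
# lightly rounded; they only need to separate consensus-like from background.
donor_pwm <- function() {
  m <- rbind(
    A = c(0.33, 0.60, 0.08, 0.00, 0.00, 0.59, 0.70, 0.06, 0.15),
    C = c(0.37, 0.13, 0.04, 0.00, 0.00, 0.03, 0.08, 0.05, 0.19),
    G = c(0.18, 0.14, 0.81, 1.00, 0.00, 0.35, 0.12, 0.84, 0.20),
    T = c(0.12, 0.13, 0.07, 0.00, 1.00, 0.03, 0.10, 0.05, 0.46)
  )
  pmax(m, 0.01)
}

# Acceptor: 10-nt polypyrimidine tract, one spacer base, invariant AG, first
# exonic base (consensus (Y)10 N AG G).
acceptor_pwm <- function() {
  y <- c(A = 0.10, C = 0.35, G = 0.10, T = 0.45)
  m <- cbind(matrix(rep(y, 10L), nrow = 4L,
                    dimnames = list(names(y), NULL)),
             c(0.25, 0.30, 0.20, 0.25),              # spacer
             c(1.00, 0.00, 0.00, 0.00),              # invariant A
             c(0.00, 0.00, 1.00, 0.00),              # invariant G
             c(0.25, 0.15, 0.50, 0.10))              # +1 exonic G bias
  pmax(m, 0.01)
}

max_motif_score <- function(sequence, pwm, center, flank) {
  w <- ncol(pwm)
  n <- nchar(sequence)
  lo <- max(1L, center - flank - w + 1L)
  hi <- min(n - w + 1L, center + flank)
  if (hi < lo) return(-Inf)
  best <- -Inf
  ch <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  for (s in lo:hi) {
    idx <- cbind(match(ch[s:(s + w - 1L)], rownames(pwm)), seq_len(w))
    sc <- sum(log2(pwm[idx] / 0.25))
    if (sc > best) best <- sc
  }
  best
}

#' Design synonymous WT-prime normalization edits
#'
#' Enumerates single-nucleotide substitutions at, or within `max_distance`
#' nucleotides of, the variant position that (a) leave the translated protein
#' unchanged, (b) do not create a splice motif under [splice_screen()], (c) do
#' not produce a rarely used codon, and (d) fall in the guide's PAM-GG or
#' seed region so that WT-prime knock-in also destroys the Cas9 site.
#' Placing WT-prime at (nearly) the same position as the variant promotes
#' knock-in of the two templates at similar frequencies.
#'
#' For splice-site variants (`splice_mode = "exon_offset"`), where the variant
#' itself may be intronic, candidates are instead drawn from the exonic
#' positions nearest the affected exon boundary.
#'
#' Accepted candidates are ranked by distance from the variant (0, 1, 2, 3)
#' and then by the frequency of the resulting codon, descending.
#'
#' @param locus A [reference_locus()] with coding segments.
#' @param variant The [variant_spec()] under test.
#' @param guide A guide row from [enumerate_guides()], or `NULL` to skip the
#'   seed/PAM check.
#' @param usage Codon usage table, default [human_codon_usage()].
#' @param max_distance Maximum distance from the variant in nt (default 3).
#' @param min_codon_freq Rare-codon threshold in occurrences per thousand
#'   (default 5): a WT-prime may not create a codon rarer than this.
#' @param splice_mode `"standard"` or `"exon_offset"` (splice variants).
#' @param seed_max Seed width for the disruption check.
#' @param splice_allowlist Positions exempt from the splice screen.
#' @return A tibble of all evaluated candidates with per-rule pass flags, a
#'   `reason` for rejected ones, and `accepted` ranking order (accepted rows
#'   first, ranked; then rejected rows).
#' @export
design_wtprime <- function(locus, variant, guide = NULL,
                           usage = human_codon_usage(),
                           max_distance = 3L, min_codon_freq = 5,
                           splice_mode = c("standard", "exon_offset"),
                           seed_max = 10L, splice_allowlist = integer(0)) {
  splice_mode <- match.arg(splice_mode)
  if (is.null(locus$coding_segments)) {
    abort("WT-prime design needs coding segments (synonymy must be checkable)")
  }
  cs <- locus$coding_segments
  coding_pos <- unlist(purrr::map2(cs$start, cs$end, seq.int))
  wt_protein <- translate_coding(locus)

  if (splice_mode == "standard") {
    cand_pos <- seq.int(variant$position - max_distance,
                        variant$position + max_distance)
    cand_pos <- intersect(cand_pos, coding_pos)
  } else {
    # splice variant: take the exonic positions closest to the exon boundary
    # nearest the variant, offsetting WT-prime into the exon
    d_bound <- abs(outer(c(cs$start, cs$end), variant$position, "-"))
    nearest <- c(cs$start, cs$end)[which.min(d_bound)]
    ord <- coding_pos[order(abs(coding_pos - nearest), abs(coding_pos - variant$position))]
    cand_pos <- head(ord, 2L * max_distance + 1L)
  }
  if (!length(cand_pos)) {
    return(empty_wtprime_tbl())
  }

  ch <- strsplit(locus$sequence, "", fixed = TRUE)[[1L]]
  rows <- list()
  for (pos in sort(cand_pos)) {
    ref_base <- ch[pos]
    for (alt in setdiff(c("A", "C", "G", "T"), ref_base)) {
      # same position as the variant: the WT-prime base must differ from the
      # variant's alternative, or the two templates would be identical
      if (pos == variant$position && nchar(variant$ref) == 1L &&
          identical(alt, variant$alt)) next
      w <- variant_spec(pos, ref_base, alt, label = "WTprime",
                        variant_class = "synonymous")
      edited <- apply_edit(locus, w)
      synonymous <- identical(translate_coding(locus, edited), wt_protein)
      cod <- codon_of(locus, pos, edited)
      freq <- codon_frequency(cod, usage)
      codon_ok <- !is.na(freq) && freq >= min_codon_freq
      spl <- if (pos %in% splice_allowlist) {
        list(ok = TRUE)
      } else {
        splice_screen(locus$sequence, edited, pos)
      }
      in_seed <- if (is.null(guide)) TRUE else {
        o <- edit_site_offsets(w, as.list(if (is.data.frame(guide))
          guide[1L, ] else guide), seed_max = seed_max)
        length(o) > 0L && !anyNA(o)
      }
      reason <- if (!synonymous) "not synonymous"
        else if (!spl$ok) "creates splice motif"
        else if (!codon_ok) "rare codon"
        else if (!in_seed) "outside guide seed/PAM"
        else NA_character_
      rows[[length(rows) + 1L]] <- tibble(
        position = pos, ref = ref_base, alt = alt,
        distance = abs(pos - variant$position),
        new_codon = cod, codon_per_thousand = freq,
        synonymous = synonymous, splice_ok = spl$ok, codon_ok = codon_ok,
        in_seed = in_seed, accepted = is.na(reason), reason = reason
      )
    }
  }
  out <- bind_rows(rows)
  if (!nrow(out)) return(empty_wtprime_tbl())
  out <- out[order(!out$accepted, out$distance,
                   -replace(out$codon_per_thousand,
                            is.na(out$codon_per_thousand), 0)), , drop = FALSE]
  out
}

empty_wtprime_tbl <- function() {
  tibble(position = integer(), ref = character(), alt = character(),
         distance = integer(), new_codon = character(),
         codon_per_thousand = double(), synonymous = logical(),
         splice_ok = logical(), codon_ok = logical(), in_seed = logical(),
         accepted = logical(), reason = character())
}

# The codon (gene orientation) containing plus-strand position pos, read from
# `sequence` (same length as the locus).
codon_of <- function(locus, pos, sequence) {
  cs <- locus$coding_segments
  seg <- which(cs$start <= pos & cs$end >= pos)
  if (!length(seg)) return(NA_character_)
  pieces <- substring(sequence, cs$start, cs$end)
  if (locus$strand == "+") {
    cds <- paste(pieces, collapse = "")
    before <- if (seg > 1L) sum(cs$end[seq_len(seg - 1L)] -
                                  cs$start[seq_len(seg - 1L)] + 1L) else 0L
    idx <- before + (pos - cs$start[seg] + 1L)
    off <- cs$frame_offset[1L]
  } else {
    pieces_rc <- rev(vapply(pieces, reverse_complement, character(1)))
    cds <- paste(pieces_rc, collapse = "")
    nseg <- nrow(cs)
    after <- if (seg < nseg) sum(cs$end[(seg + 1L):nseg] -
                                   cs$start[(seg + 1L):nseg] + 1L) else 0L
    idx <- after + (cs$end[seg] - pos + 1L)
    off <- cs$frame_offset[nseg]
  }
  idx <- idx - off
  if (idx < 1L) return(NA_character_)   # inside the partial leading codon
  codon_i <- (idx - 1L) %/% 3L
  start <- off + codon_i * 3L + 1L
  if (start + 2L > nchar(cds)) return(NA_character_)  # trailing partial codon
  substr(cds, start, start + 2L)
}
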