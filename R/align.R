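#' Classifier configuration
#'
#' Alignment scoring and filtering parameters for amplicon read
#' classification. The default scoring (match +2, mismatch -4, gap open 10,
#' gap extend 1) makes two gap openings (cost 22) more expensive than three
#' mismatches (cost 18), so short error tracts are interpreted as
#' substitutions, not spurious indels.
#'
#' @param match,mismatch Substitution scores.
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @param min_identity Reads below this global alignment identity are flagged
#'   unalignable and classified `OTHER` (default 0.6).
#' @param min_read_length Reads shorter than this are discarded (default 50).
#' @param min_mean_quality Reads with mean Phred quality below this are
#'   discarded (default 20).
#' @param min_base_quality Substitutions at bases below this quality are
#'   ignored (default 20).
#' @param strict When `TRUE`, any substitution inside the quantification
#'   window other than the cassette edits makes a read `OTHER`; by default
#'   non-edit substitutions are tolerated as sequencing error.
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(match = 2L, mismatch = -4L, gap_open = 10,
                              gap_extend = 1, min_identity = 0.6,
                              min_read_length = 50L, min_mean_quality = 20,
                              min_base_quality = 20, strict = FALSE) {
  structure(as.list(environment()), class = "classifier_config")
}

#' Globally align a read to the amplicon reference
#'
#' Needleman-Wunsch global alignment with affine gaps (via
#' `Biostrings::pairwiseAlignment`), followed by left-normalization of every
#' indel so gap placement is deterministic: each gap run is shifted to its
#' leftmost equivalent position, the convention used for variant reporting.
#' Reads whose length equals the reference and whose Hamming distance is at
#' most 3 are scored as gapless alignments directly; under the default
#' scoring this is provably the optimal alignment, and it covers the vast
#' majority of substitution-error-only reads.
#'
#' @param read Read sequence (character).
#' @param amplicon_ref Amplicon reference sequence.
#' @param config A [classifier_config()].
#' @return A list: `identity`, `unalignable`, `subs` (tibble `ref_pos`,
#'   `read_base`), `indels` (tibble `op` ("ins"/"del"), `ref_pos`, `length`,
#'   `bases`; for insertions `ref_pos` is the reference base *after* which
#'   the insertion occurs).
#' @export
align_read <- function(read, amplicon_ref, config = classifier_config()) {
  n_ref <- nchar(amplicon_ref)
  if (nchar(read) == n_ref) {
    rch <- strsplit(read, "", fixed = TRUE)[[1L]]
    ach <- strsplit(amplicon_ref, "", fixed = TRUE)[[1L]]
    d <- which(rch != ach)
    if (length(d) <= 3L) {
      return(list(identity = 1 - length(d) / n_ref, unalignable = FALSE,
                  subs = tibble(ref_pos = d, read_base = rch[d]),
                  indels = empty_indel_tbl()))
    }
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(read), Biostrings::DNAString(amplicon_ref),
    type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = config$match, mismatch = config$mismatch),
    gapOpening = config$gap_open, gapExtension = config$gap_extend
  )
  parse_alignment(as.character(Biostrings::alignedPattern(aln)),
                  as.character(Biostrings::alignedSubject(aln)),
                  config)
}

# Batch version: classify many unique reads against one reference with a
# single affine-alignment call for everything the Hamming fast path misses.
# Mismatches and gaps are pulled from the vectorized accessors rather than
# from the aligned strings (whose element-wise extraction dominates runtime).
align_reads_batch <- function(reads, amplicon_ref, config = classifier_config()) {
  n_ref <- nchar(amplicon_ref)
  out <- vector("list", length(reads))
  ach <- strsplit(amplicon_ref, "", fixed = TRUE)[[1L]]
  no_indels <- empty_indel_tbl()
  no_subs <- tibble(ref_pos = integer(), read_base = character())
  need_full <- logical(length(reads))
  for (i in seq_along(reads)) {
    if (nchar(reads[i]) == n_ref) {
      rch <- strsplit(reads[i], "", fixed = TRUE)[[1L]]
      d <- which(rch != ach)
      if (length(d) <= 3L) {
        out[[i]] <- list(
          identity = 1 - length(d) / n_ref, unalignable = FALSE,
          subs = if (length(d)) tibble(ref_pos = d, read_base = rch[d])
                 else no_subs,
          indels = no_indels)
        next
      }
    }
    need_full[i] <- TRUE
  }
  if (!any(need_full)) return(out)

  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(reads[need_full]),
    Biostrings::DNAString(amplicon_ref), type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = config$match, mismatch = config$mismatch),
    gapOpening = config$gap_open, gapExtension = config$gap_extend
  )
  mm <- Biostrings::mismatchTable(aln)
  mm_by <- split(seq_len(nrow(mm)), factor(mm$PatternId,
                                           levels = seq_len(sum(need_full))))
  it <- Biostrings::indel(aln)
  ins_l <- Biostrings::insertion(it)   # gaps in subject, read coordinates
  del_l <- Biostrings::deletion(it)    # gaps in pattern, reference coordinates
  nmat <- Biostrings::nmatch(aln)
  full_idx <- which(need_full)
  for (k in seq_along(full_idx)) {
    i <- full_idx[k]
    ins_r <- ins_l[[k]]; del_r <- del_l[[k]]
    indels <- batch_indels(ins_r, del_r, reads[i], ach)
    rows <- mm_by[[k]]
    subs <- if (length(rows)) {
      tibble(ref_pos = mm$SubjectStart[rows],
             read_base = as.character(mm$PatternSubstring[rows]))
    } else no_subs
    alen <- n_ref + sum(IRanges::width(ins_r))
    identity <- nmat[k] / alen
    out[[i]] <- list(identity = identity,
                     unalignable = identity < config$min_identity,
                     subs = subs, indels = indels)
  }
  out
}

# Convert insertion and deletion gap ranges into reference-anchored,
# left-normalized indel records. The accessors report each gap in the
# coordinates of the sequence that keeps its letters there: insertions in
# reference coordinates (the ref position the gap would occupy), deletions in
# read coordinates. Running gap totals interleave the two event streams along
# the alignment and convert between the systems.
batch_indels <- function(ins_r, del_r, read, ref_chars) {
  n_ins <- length(ins_r); n_del <- length(del_r)
  if (n_ins + n_del == 0L) return(empty_indel_tbl())
  ins_s <- IRanges::start(ins_r); ins_w <- IRanges::width(ins_r)
  del_s <- IRanges::start(del_r); del_w <- IRanges::width(del_r)
  ii <- 1L; di <- 1L
  cum_ins <- 0L; cum_del <- 0L
  recs <- vector("list", n_ins + n_del)
  for (e in seq_len(n_ins + n_del)) {
    ins_col <- if (ii <= n_ins) ins_s[ii] + cum_ins else Inf
    del_col <- if (di <= n_del) del_s[di] + cum_del else Inf
    if (ins_col <= del_col) {
      w <- ins_w[ii]
      read_start <- ins_s[ii] + cum_ins - cum_del
      bases <- substr(read, read_start, read_start + w - 1L)
      norm <- normalize_ins(ins_s[ii] - 1L, bases, ref_chars)
      recs[[e]] <- list(op = "ins", ref_pos = norm$pos, length = w,
                        bases = norm$bases)
      cum_ins <- cum_ins + w; ii <- ii + 1L
    } else {
      w <- del_w[di]
      ref_start <- del_s[di] - cum_ins + cum_del
      start <- normalize_del(as.integer(ref_start), w, ref_chars)
      recs[[e]] <- list(op = "del", ref_pos = start, length = w,
                        bases = paste(ref_chars[start:(start + w - 1L)],
                                      collapse = ""))
      cum_del <- cum_del + w; di <- di + 1L
    }
  }
  tibble(op = vapply(recs, `[[`, character(1), "op"),
         ref_pos = vapply(recs, function(r) as.integer(r$ref_pos), integer(1)),
         length = vapply(recs, function(r) as.integer(r$length), integer(1)),
         bases = vapply(recs, `[[`, character(1), "bases"))
}

# Shift a deletion run leftward to its leftmost equivalent placement.
normalize_del <- function(start, len, ref_chars) {
  while (start > 1L && ref_chars[start - 1L] == ref_chars[start + len - 1L]) {
    start <- start - 1L
  }
  start
}

# Rotate an insertion leftward while the reference base before it equals the
# run's last inserted base; pos is the reference base after which the
# insertion occurs (0 = before the first base).
normalize_ins <- function(pos, bases, ref_chars) {
  while (pos >= 1L &&
         ref_chars[pos] == substr(bases, nchar(bases), nchar(bases))) {
    bases <- paste0(ref_chars[pos], substr(bases, 1L, nchar(bases) - 1L))
    pos <- pos - 1L
  }
  list(pos = pos, bases = bases)
}

empty_indel_tbl <- function() {
  tibble(op = character(), ref_pos = integer(), length = integer(),
         bases = character())
}

# Turn a pair of gapped strings (read over reference) into substitution and
# left-normalized indel tables.
parse_alignment <- function(read_aln, ref_aln, config = classifier_config()) {
  r <- strsplit(read_aln, "", fixed = TRUE)[[1L]]
  a <- strsplit(ref_aln, "", fixed = TRUE)[[1L]]
  stopifnot(length(r) == length(a))
  ref_chars <- a[a != "-"]
  ref_pos_at <- cumsum(a != "-")       # reference coordinate per column
  ident <- mean(r == a)

  subs <- tibble(ref_pos = ref_pos_at[r != a & r != "-" & a != "-"],
                 read_base = r[r != a & r != "-" & a != "-"])

  indels <- list()
  i <- 1L; ncol <- length(r)
  while (i <= ncol) {
    if (a[i] == "-") {                  # insertion run
      j <- i
      while (j < ncol && a[j + 1L] == "-") j <- j + 1L
      ins <- paste(r[i:j], collapse = "")
      pos <- if (i == 1L) 0L else ref_pos_at[i - 1L]
      norm <- normalize_ins(pos, ins, ref_chars)
      indels[[length(indels) + 1L]] <- tibble(
        op = "ins", ref_pos = norm$pos, length = j - i + 1L,
        bases = norm$bases)
      i <- j + 1L
    } else if (r[i] == "-") {           # deletion run
      j <- i
      while (j < ncol && r[j + 1L] == "-") j <- j + 1L
      len <- j - i + 1L
      start <- normalize_del(ref_pos_at[i], len, ref_chars)
      indels[[length(indels) + 1L]] <- tibble(
        op = "del", ref_pos = start, length = len,
        bases = paste(ref_chars[start:(start + len - 1L)], collapse = ""))
      i <- j + 1L
    } else i <- i + 1L
  }
  indels <- if (length(indels)) bind_rows(indels) else empty_indel_tbl()
  list(identity = ident, unalignable = ident < config$min_identity,
       subs = subs, indels = indels)
}
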