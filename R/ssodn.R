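#' Build an ssODN repair template for an edit
#'
#' Constructs a single-stranded oligodeoxynucleotide carrying the edit flanked
#' by homology arms of `arm_len` genomic nucleotides (default 45 nt). Polarity
#' follows the asymmetric-donor rule: when the nearest edited base lies more
#' than 4 bp from the Cas9 cut, a sense oligo is used for edits left of the
#' double-strand break and an antisense oligo for edits right of it;
#' otherwise polarity is not informative and the sense construction is
#' returned.
#'
#' @param locus A [reference_locus()].
#' @param guide A guide row from [enumerate_guides()] (needs `cut_after`).
#' @param edit A [variant_spec()].
#' @param arm_len Homology arm length in nt (default 45).
#' @return A list of class `ssodn`: `sequence` (5'->3' in the chosen
#'   polarity), `polarity` (`"sense"`/`"antisense"`), `arm_5_len`,
#'   `arm_3_len`, `encoded_edit`, `region_start`, `region_end` (the genomic
#'   footprint covered by the oligo, plus-strand coordinates), and
#'   `distance_to_cut`.
#' @export
build_ssodn <- function(locus, guide, edit, arm_len = 45L) {
  if (is.data.frame(guide)) guide <- as.list(guide[1L, ])
  check_ref_match(locus, edit)
  n <- nchar(locus$sequence)
  ref_len <- nchar(edit$ref)
  region_start <- edit$position - arm_len
  region_end <- edit$position + ref_len - 1L + arm_len
  if (ref_len == 0L) region_end <- edit$position + arm_len - 1L
  if (region_start < 1L || region_end > n) {
    abort("edit too close to the locus boundary for full homology arms")
  }
  left <- substr(locus$sequence, region_start, edit$position - 1L)
  right <- substr(locus$sequence, edit$position + ref_len, region_end)
  sense <- paste0(left, edit$alt, right)

  d <- signed_cut_distance(edit, guide$cut_after)
  polarity <- if (abs(d) > 4L) {
    if (d < 0L) "sense" else "antisense"
  } else "sense"
  seq_out <- if (polarity == "sense") sense else reverse_complement(sense)

  structure(
    list(sequence = seq_out, polarity = polarity,
         arm_5_len = arm_len, arm_3_len = arm_len,
         encoded_edit = edit,
         region_start = region_start, region_end = region_end,
         distance_to_cut = d),
    class = "ssodn"
  )
}

#' @export
print.ssodn <- function(x, ...) {
  cat("<ssodn> ", nchar(x$sequence), " nt (", x$polarity, "), arms ",
      x$arm_5_len, "/", x$arm_3_len, " nt, edit ", x$encoded_edit$label,
      " at ", x$encoded_edit$position, " (", x$distance_to_cut,
      " nt from cut)\n", sep = "")
  invisible(x)
}
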