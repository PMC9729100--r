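#' Design target-site primers outside the ssODN-covered region
#'
#' Amplicon primers must anneal entirely outside the region covered by the
#' ssODN repair templates -- otherwise templated alleles and unedited alleles
#' would amplify differently and the all-allele quantification would be
#' biased. Each primer's annealing region is placed `offset` nucleotides
#' outside the covered region, with `offset` in `offset_range` (default
#' 40-120 nt), and the PCR product length must fall within `product_range`
#' (default 230-350 bp). Primer composition is filtered by length (18-25 nt),
#' GC content (35-65%) and a simple Wallace-rule melting temperature
#' (2(A+T) + 4(G+C), window 50-72 degrees C); full thermodynamic design is
#' deliberately out of scope.
#'
#' The search is deterministic: the valid pair with the smallest total offset
#' wins, ties broken by the most balanced GC content, then by the fixed
#' iteration order.
#'
#' @param locus A [reference_locus()].
#' @param region Integer vector `c(start, end)`: the ssODN-covered region in
#'   plus-strand locus coordinates (1-based inclusive).
#' @param offset_range,product_range Inclusive bounds on the primer offsets
#'   (nt) and the PCR product length (bp).
#' @param primer_len Allowed primer lengths.
#' @param gc_range Allowed GC fraction.
#' @param tm_range Allowed Wallace melting temperature.
#' @return A list of class `primer_pair`: `forward`, `reverse` (5'->3'
#'   sequences; the reverse primer is the reverse complement of the plus
#'   strand), `fwd_start`, `fwd_end`, `rev_start`, `rev_end` (plus-strand
#'   annealing coordinates), `fwd_offset`, `rev_offset`, `product_length`,
#'   `product_start`, `product_end`.
#' @export
design_primers <- function(locus, region,
                           offset_range = c(40L, 120L),
                           product_range = c(230L, 350L),
                           primer_len = 18:25,
                           gc_range = c(0.35, 0.65),
                           tm_range = c(50, 72)) {
  rs <- region[1L]; re <- region[2L]
  n <- nchar(locus$sequence)
  width <- re - rs + 1L
  max_left <- rs - 1L          # nt available left of the region
  max_right <- n - re          # nt available right of the region
  need <- offset_range[1L] + min(primer_len)
  if (max_left < need || max_right < need) {
    abort("offset window unsatisfiable: locus too short outside the ssODN-covered region")
  }

  offs <- seq.int(offset_range[1L], offset_range[2L])
  grid <- expand.grid(fwd_offset = offs, rev_offset = offs)
  grid <- grid[order(grid$fwd_offset + grid$rev_offset, grid$fwd_offset), ]

  best <- NULL; best_bal <- Inf
  geometric_ok <- FALSE
  for (i in seq_len(nrow(grid))) {
    offF <- grid$fwd_offset[i]; offR <- grid$rev_offset[i]
    if (!is.null(best) &&
        (offF + offR) > (best$fwd_offset + best$rev_offset)) break
    for (lenF in primer_len) {
      fs <- rs - offF - lenF
      if (fs < 1L) next
      for (lenR in primer_len) {
        pe <- re + offR + lenR
        if (pe > n) next
        prod <- width + offF + offR + lenF + lenR
        if (prod < product_range[1L] || prod > product_range[2L]) next
        geometric_ok <- TRUE
        fwd <- substr(locus$sequence, fs, rs - offF - 1L)
        rev_plus <- substr(locus$sequence, re + offR + 1L, pe)
        gcF <- gc_fraction(fwd); gcR <- gc_fraction(rev_plus)
        if (gcF < gc_range[1L] || gcF > gc_range[2L]) next
        if (gcR < gc_range[1L] || gcR > gc_range[2L]) next
        tmF <- wallace_tm(fwd); tmR <- wallace_tm(rev_plus)
        if (tmF < tm_range[1L] || tmF > tm_range[2L]) next
        if (tmR < tm_range[1L] || tmR > tm_range[2L]) next
        bal <- abs(gcF - 0.5) + abs(gcR - 0.5)
        if (is.null(best) || bal < best_bal - 1e-12) {
          best_bal <- bal
          best <- list(
            forward = fwd, reverse = reverse_complement(rev_plus),
            fwd_start = fs, fwd_end = rs - offF - 1L,
            rev_start = re + offR + 1L, rev_end = pe,
            fwd_offset = offF, rev_offset = offR,
            product_length = prod,
            product_start = fs, product_end = pe
          )
        }
      }
    }
  }
  if (is.null(best)) {
    if (!geometric_ok) {
      abort("product length window unsatisfiable for any offsets in range")
    }
    abort("primer composition (GC/Tm) unsatisfiable in the offset window")
  }
  structure(best, class = "primer_pair")
}

gc_fraction <- function(x) {
  ch <- strsplit(x, "", fixed = TRUE)[[1L]]
  mean(ch %in% c("G", "C"))
}

wallace_tm <- function(x) {
  ch <- strsplit(x, "", fixed = TRUE)[[1L]]
  2 * sum(ch %in% c("A", "T")) + 4 * sum(ch %in% c("G", "C"))
}

#' @export
print.primer_pair <- function(x, ...) {
  cat("<primer_pair> product ", x$product_length, " bp; offsets ",
      x$fwd_offset, "/", x$rev_offset, " nt\n  F: ", x$forward, "\n  R: ",
      x$reverse, "\n", sep = "")
  invisible(x)
}
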