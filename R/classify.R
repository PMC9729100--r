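#' Allele categories
#'
#' The mutually exclusive editing-outcome categories a read can be assigned
#' to: precise knock-in of the variant (`VARIANT_KI`) or of the synonymous
#' normalization mutation (`WTPRIME_KI`), reads carrying both templated edits
#' (`MIXED_KI`), InDels whose net coding-length change is (`INFRAME_INDEL`)
#' or is not (`FRAMESHIFT_INDEL`) a multiple of three, unedited (`WT`),
#' everything else (`OTHER`), and reads removed by quality filters
#' (`DISCARDED`).
#'
#' @return Character vector of category names, in canonical order.
#' @export
allele_categories <- function() {
  c("VARIANT_KI", "WTPRIME_KI", "FRAMESHIFT_INDEL", "INFRAME_INDEL",
    "WT", "MIXED_KI", "OTHER", "DISCARDED")
}

#' Classify an aligned read into an allele category
#'
#' Applies the CRISPR-Select decision order: (1) unalignable reads are
#' `OTHER`; (2) any InDel overlapping the quantification window takes
#' precedence over point edits -- the net length change within coding
#' segments decides `FRAMESHIFT_INDEL` (not a multiple of 3) versus
#' `INFRAME_INDEL` (a multiple of 3, or a purely non-coding InDel); (3) with
#' no InDel, the bases at the two edit positions decide `VARIANT_KI`,
#' `WTPRIME_KI`, `MIXED_KI` or `WT`; any other substitution pattern at the
#' edit positions (or, in strict mode, anywhere in the window) is `OTHER`.
#'
#' @param alignment Result of [align_read()].
#' @param map Amplicon feature map (internal; built from the cassette).
#' @param config A [classifier_config()].
#' @param low_quality_pos Optional integer vector of read-relative reference
#'   positions whose base quality is below `config$min_base_quality`;
#'   substitutions there are ignored.
#' @return A single category string.
#' @keywords internal
classify_alignment <- function(alignment, map, config = classifier_config(),
                               low_quality_pos = integer(0)) {
  if (alignment$unalignable) return("OTHER")
  w1 <- map$window[1L]; w2 <- map$window[2L]

  ind <- alignment$indels
  if (nrow(ind)) {
    span_start <- ifelse(ind$op == "del", ind$ref_pos, ind$ref_pos)
    span_end <- ifelse(ind$op == "del", ind$ref_pos + ind$length - 1L,
                       ind$ref_pos + 1L)
    in_win <- span_end >= w1 & span_start <= w2
    if (any(in_win)) {
      ind <- ind[in_win, , drop = FALSE]
      net <- coding_net_change(ind, map$coding)
      if (is.na(net)) return("INFRAME_INDEL")       # purely non-coding InDel
      return(if (net %% 3L != 0L) "FRAMESHIFT_INDEL" else "INFRAME_INDEL")
    }
  }

  subs <- alignment$subs
  if (length(low_quality_pos)) {
    subs <- subs[!(subs$ref_pos %in% low_quality_pos), , drop = FALSE]
  }
  base_at <- function(pos, ref) {
    hit <- subs$read_base[subs$ref_pos == pos]
    if (length(hit)) hit[1L] else ref
  }
  if (config$strict) {
    # strict mode: any window substitution beyond the templated edits
    # disqualifies the read
    other_sub <- subs$ref_pos >= w1 & subs$ref_pos <= w2 &
      !(subs$ref_pos %in% c(map$variant_pos, map$wtprime_pos))
    if (any(other_sub)) return("OTHER")
  }
  vb <- base_at(map$variant_pos, map$variant_ref)
  wb <- base_at(map$wtprime_pos, map$wtprime_ref)
  var_present <- identical(vb, map$variant_alt)
  wt_present <- identical(wb, map$wtprime_alt)
  if (var_present && !wt_present) return("VARIANT_KI")
  if (wt_present && !var_present) return("WTPRIME_KI")
  if (var_present && wt_present) return("MIXED_KI")
  # neither templated edit present
  if (!identical(vb, map$variant_ref) || !identical(wb, map$wtprime_ref)) {
    return("OTHER")                                  # third base at an edit position
  }
  "WT"
}

# Net coding-length change from the indels that overlap coding segments;
# NA when no indel touches coding sequence (frame undefined off-exon).
coding_net_change <- function(indels, coding) {
  if (is.null(coding) || !nrow(coding)) return(NA_integer_)
  net <- 0L; any_coding <- FALSE
  for (i in seq_len(nrow(indels))) {
    if (indels$op[i] == "del") {
      dstart <- indels$ref_pos[i]; dend <- dstart + indels$length[i] - 1L
      ov <- pmin(dend, coding$end) - pmax(dstart, coding$start) + 1L
      ov <- sum(ov[ov > 0L])
      if (ov > 0L) { net <- net - ov; any_coding <- TRUE }
    } else {
      # insertion after ref_pos: counts fully if it lands inside a segment
      p <- indels$ref_pos[i]
      inside <- any(p >= coding$start & p < coding$end)
      if (inside) { net <- net + indels$length[i]; any_coding <- TRUE }
    }
  }
  if (!any_coding) return(NA_integer_)
  net
}

#' Classify a single read
#'
#' Convenience wrapper: aligns `read` to the cassette's amplicon and applies
#' [classify_alignment()].
#'
#' @param read Read sequence.
#' @param cassette A [assemble_cassette()] result.
#' @param config A [classifier_config()].
#' @return A single category string.
#' @export
classify_read <- function(read, cassette, config = classifier_config()) {
  map <- amplicon_map(cassette)
  classify_alignment(align_read(read, cassette$amplicon$sequence, config),
                     map, config)
}

#' Quantify an amplicon sequencing sample
#'
#' Streams a FASTQ file, classifies every read into an allele category and
#' aggregates per-category read counts, frequencies (over retained reads) and
#' absolute cell estimates from the genomic template mass. Unique read
#' sequences are classified once and counts propagated, which makes deep
#' amplicon samples cheap.
#'
#' @param fastq_path Path to a FASTQ file (optionally gzipped), single
#'   pre-merged reads spanning the amplicon.
#' @param cassette A [assemble_cassette()] (or [read_cassette()]) result.
#' @param config A [classifier_config()].
#' @param gdna_ng Genomic DNA template mass in ng (default 100).
#' @param sample_id Sample label stored in the profile.
#' @return An `editing_profile`: a tibble with one row per category
#'   (`category`, `reads`, `frequency`, `cells`) and attributes `sample_id`,
#'   `total_reads`, `retained_reads`, `gdna_ng`, `genome_equivalents`,
#'   `unalignable_reads`, `warn_unalignable`.
#' @export
quantify_sample <- function(fastq_path, cassette,
                            config = classifier_config(), gdna_ng = 100,
                            sample_id = basename(fastq_path)) {
  if (!file.exists(fastq_path) || file.size(fastq_path) == 0L) {
    abort(sprintf("empty FASTQ: %s", fastq_path))
  }
  reads <- Biostrings::readDNAStringSet(fastq_path, format = "fastq",
                                        with.qualities = TRUE)
  if (!length(reads)) abort(sprintf("empty FASTQ: %s", fastq_path))
  seqs <- as.character(reads)
  quals <- as.character(S4Vectors::mcols(reads)$qualities)
  mean_q <- vapply(quals, function(q) {
    mean(utf8ToInt(q)) - 33
  }, numeric(1), USE.NAMES = FALSE)

  keep <- nchar(seqs) >= config$min_read_length &
    mean_q >= config$min_mean_quality
  discarded <- sum(!keep)
  seqs <- seqs[keep]

  map <- amplicon_map(cassette)
  amp <- cassette$amplicon$sequence
  cats <- character(length(seqs))
  unalignable <- 0L
  if (length(seqs)) {
    uniq <- unique(seqs)
    idx <- match(seqs, uniq)
    alns <- align_reads_batch(uniq, amp, config)
    ucat <- vapply(alns, classify_alignment, character(1),
                   map = map, config = config)
    ualn <- vapply(alns, `[[`, logical(1), "unalignable")
    cats <- ucat[idx]
    unalignable <- sum(tabulate(idx, nbins = length(uniq)) * ualn)
  }

  counts <- table(factor(cats, levels = allele_categories()))
  counts["DISCARDED"] <- counts["DISCARDED"] + discarded
  retained <- length(seqs)
  freq <- as.numeric(counts) / max(retained, 1L)
  freq[allele_categories() == "DISCARDED"] <- NA_real_

  pg <- cassette$config$pg_per_diploid_genome %||% 6.0
  ge <- estimate_absolute_cells(gdna_ng, 0, pg)$genome_equivalents

  out <- tibble(
    category = allele_categories(),
    reads = as.integer(counts),
    frequency = freq,
    cells = ge * freq
  )
  structure(
    out,
    sample_id = sample_id,
    total_reads = length(keep), retained_reads = retained,
    gdna_ng = gdna_ng, genome_equivalents = ge,
    unalignable_reads = unalignable,
    warn_unalignable = retained > 0L && unalignable / retained > 0.5,
    class = c("editing_profile", class(tibble())))
}

#' Estimate absolute cell numbers from template mass and allele frequency
#'
#' Converts the genomic DNA mass used as PCR template into diploid genome
#' equivalents (`mass * 1000 / pg_per_diploid_genome`; 100 ng at 6.0 pg per
#' diploid genome is about 17,000 equivalents) and multiplies by the read
#' frequency of a category to estimate the number of cells carrying it. The
#' read frequency is treated as a per-cell frequency, matching the assay's
#' published arithmetic; the allele-count interpretation (two alleles per
#' genome equivalent) is reported alongside as `alleles`.
#'
#' @param gdna_ng Template mass in ng (> 0).
#' @param frequency Allele-category read frequency (0-1); vectorized.
#' @param pg_per_diploid_genome Mass of one diploid genome in pg (default 6.0
#'   for human).
#' @return Tibble: `genome_equivalents` (raw), `genome_equivalents_rounded`
#'   (nearest thousand), `cells` (raw equivalents x frequency),
#'   `cells_rounded_template` (rounded equivalents x frequency, the printed
#'   arithmetic), `alleles`.
#' @examples
#' estimate_absolute_cells(100, 0.08)
#' @export
estimate_absolute_cells <- function(gdna_ng, frequency,
                                    pg_per_diploid_genome = 6.0) {
  if (!is.numeric(gdna_ng) || any(gdna_ng <= 0)) {
    abort("gdna_ng must be positive")
  }
  if (any(frequency < 0 | frequency > 1, na.rm = TRUE)) {
    abort("frequency must be within [0, 1]")
  }
  ge <- gdna_ng * 1000 / pg_per_diploid_genome
  ge_round <- round(ge / 1000) * 1000
  tibble(
    genome_equivalents = ge,
    genome_equivalents_rounded = ge_round,
    cells = ge * frequency,
    cells_rounded_template = ge_round * frequency,
    alleles = 2 * ge * frequency
  )
}

#' Write an editing profile to TSV / JSON
#'
#' @param profile An `editing_profile` from [quantify_sample()].
#' @param tsv,json Output paths (either may be `NULL`).
#' @return The profile, invisibly.
#' @export
write_profile <- function(profile, tsv = NULL, json = NULL) {
  meta <- list(
    sample_id = attr(profile, "sample_id"),
    total_reads = attr(profile, "total_reads"),
    retained_reads = attr(profile, "retained_reads"),
    gdna_ng = attr(profile, "gdna_ng"),
    genome_equivalents = attr(profile, "genome_equivalents"),
    unalignable_reads = attr(profile, "unalignable_reads")
  )
  if (!is.null(tsv)) {
    readr::write_tsv(as_tibble(profile), tsv)
  }
  if (!is.null(json)) {
    jsonlite::write_json(c(meta, list(categories = as_tibble(profile))),
                         json, auto_unbox = TRUE, digits = NA)
  }
  invisible(profile)
}

#' @export
print.editing_profile <- function(x, ...) {
  cat("<editing_profile> ", attr(x, "sample_id"), ": ",
      attr(x, "retained_reads"), "/", attr(x, "total_reads"),
      " reads retained; ", format(round(attr(x, "genome_equivalents"))),
      " genome equivalents from ", attr(x, "gdna_ng"), " ng\n", sep = "")
  if (isTRUE(attr(x, "warn_unalignable"))) {
    cat("  WARNING: >50% of retained reads unalignable\n")
  }
  NextMethod()
}
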