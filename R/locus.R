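#' Reference locus
#'
#' A reference locus is the genomic context in which a variant is assayed: the
#' nucleotide sequence of the region, the coding segments (exonic intervals
#' with their reading-frame offsets) and the strand the gene lies on. All
#' coordinates are 1-based and inclusive, the R/Bioconductor convention, and
#' refer to the stored (plus) strand of `sequence`.
#'
#' @param locus_id Character label for the locus (e.g. a gene/exon name).
#' @param sequence Nucleotide string. Upper-cased on input; only A/C/G/T are
#'   accepted (IUPAC ambiguity codes are rejected because the design rules
#'   operate on concrete bases).
#' @param coding_segments Data frame with columns `start`, `end`,
#'   `frame_offset` giving exonic intervals in locus coordinates.
#'   `frame_offset` (0, 1 or 2) is the number of leading bases of the segment
#'   (in gene orientation) that complete a codon started upstream. Segments
#'   must be sorted and non-overlapping. May be `NULL` for a non-coding locus.
#' @param strand `"+"` or `"-"`: the strand of the gene relative to the stored
#'   sequence.
#'
#' @return An object of class `reference_locus`.
#' @examples
#' loc <- reference_locus("toy", "ATGGCTAAA",
#'                        coding_segments = data.frame(start = 1, end = 9,
#'                                                     frame_offset = 0))
#' translate_coding(loc)
#' @export
reference_locus <- function(locus_id, sequence, coding_segments = NULL,
                            strand = c("+", "-")) {
  strand <- match.arg(strand)
  sequence <- toupper(sequence)
  if (!grepl("^[ACGT]+$", sequence)) {
    abort("locus sequence must contain only A/C/G/T (no ambiguity codes)")
  }
  n <- nchar(sequence)
  if (!is.null(coding_segments)) {
    cs <- as_tibble(coding_segments)
    stopifnot(all(c("start", "end", "frame_offset") %in% names(cs)))
    cs <- cs[order(cs$start), , drop = FALSE]
    if (any(cs$start < 1 | cs$end > n | cs$start > cs$end)) {
      abort("coding segments out of locus bounds")
    }
    if (nrow(cs) > 1 && any(cs$start[-1] <= cs$end[-nrow(cs)])) {
      abort("coding segments overlap")
    }
    if (!all(cs$frame_offset %in% 0:2)) abort("frame_offset must be 0, 1 or 2")
    coding_segments <- cs
  }
  structure(
    list(locus_id = locus_id, sequence = sequence,
         coding_segments = coding_segments, strand = strand),
    class = "reference_locus"
  )
}

#' @export
print.reference_locus <- function(x, ...) {
  cat("<reference_locus> ", x$locus_id, ": ", nchar(x$sequence), " nt, gene on '",
      x$strand, "' strand, ",
      if (is.null(x$coding_segments)) 0L else nrow(x$coding_segments),
      " coding segment(s)\n", sep = "")
  invisible(x)
}

#' Variant specification
#'
#' Describes the edit under test: the first affected locus position, the
#' reference bases replaced and the alternative bases installed. An empty
#' `ref` denotes a pure insertion (inserted before `position`); an empty
#' `alt` a pure deletion.
#'
#' @param position 1-based locus coordinate of the first affected base (for a
#'   pure insertion, the base before which the insertion occurs).
#' @param ref,alt Reference / alternative nucleotide strings (one may be
#'   empty, not both, and they must differ).
#' @param label Free-text label, e.g. `"GENE-p.T100R"`.
#' @param variant_class One of `"missense"`, `"nonsense"`, `"synonymous"`,
#'   `"splice"`, `"inframe_indel"`, `"frameshift_indel"`.
#' @param locus Optional [reference_locus()]; when given, `ref` is checked
#'   against the locus sequence at `position`.
#'
#' @return An object of class `variant_spec`.
#' @export
variant_spec <- function(position, ref, alt, label = "variant",
                         variant_class = c("missense", "nonsense", "synonymous",
                                           "splice", "inframe_indel",
                                           "frameshift_indel"),
                         locus = NULL) {
  variant_class <- match.arg(variant_class)
  ref <- toupper(ref); alt <- toupper(alt)
  if (identical(ref, alt)) abort("ref and alt must differ")
  if (nzchar(ref) && !grepl("^[ACGT]+$", ref)) abort("ref must be A/C/G/T")
  if (nzchar(alt) && !grepl("^[ACGT]+$", alt)) abort("alt must be A/C/G/T")
  v <- structure(
    list(position = as.integer(position), ref = ref, alt = alt,
         label = label, variant_class = variant_class),
    class = "variant_spec"
  )
  if (!is.null(locus)) check_ref_match(locus, v)
  v
}

#' @export
print.variant_spec <- function(x, ...) {
  cat("<variant_spec> ", x$label, ": ",
      if (nzchar(x$ref)) x$ref else "-", ">",
      if (nzchar(x$alt)) x$alt else "-",
      " at ", x$position, " (", x$variant_class, ")\n", sep = "")
  invisible(x)
}

check_ref_match <- function(locus, edit) {
  if (!nzchar(edit$ref)) return(invisible(TRUE))
  span_end <- edit$position + nchar(edit$ref) - 1L
  if (edit$position < 1L || span_end > nchar(locus$sequence)) {
    abort("edit falls outside the locus")
  }
  found <- substr(locus$sequence, edit$position, span_end)
  if (!identical(found, edit$ref)) {
    abort(sprintf("reference mismatch at %d: locus has '%s', edit expects '%s'",
                  edit$position, found, edit$ref))
  }
  invisible(TRUE)
}

#' Apply an edit to a locus sequence
#'
#' @param locus A [reference_locus()].
#' @param edit A [variant_spec()]; `edit$ref` must match the locus at
#'   `edit$position`.
#' @return The edited nucleotide string; its length differs from the locus by
#'   `nchar(alt) - nchar(ref)`.
#' @export
apply_edit <- function(locus, edit) {
  check_ref_match(locus, edit)
  s <- locus$sequence
  left <- substr(s, 1L, edit$position - 1L)
  right <- substr(s, edit$position + nchar(edit$ref), nchar(s))
  paste0(left, edit$alt, right)
}

#' Reverse complement
#'
#' Standard Watson-Crick reverse complement of an A/C/G/T string.
#'
#' @param sequence Nucleotide string (A/C/G/T only).
#' @return The reverse-complemented string.
#' @export
reverse_complement <- function(sequence) {
  if (!grepl("^[ACGT]*$", sequence)) abort("sequence must be A/C/G/T only")
  if (!nzchar(sequence)) return(sequence)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
}

#' Translate the coding portion of a locus
#'
#' Concatenates the locus's coding segments in gene orientation (reverse
#' complementing for a minus-strand gene), drops the leading `frame_offset`
#' bases of the first segment, translates with the standard genetic code and
#' drops any trailing partial codon. Stop codons appear as `*`.
#'
#' @param locus A [reference_locus()] with coding segments.
#' @param sequence Optional sequence to translate in place of the locus's own;
#'   must have the same length (substitution-edited copies).
#' @return Amino-acid string.
#' @export
translate_coding <- function(locus, sequence = NULL) {
  if (is.null(locus$coding_segments)) abort("locus has no coding segments")
  s <- sequence %||% locus$sequence
  if (nchar(s) != nchar(locus$sequence)) {
    abort("sequence length must match the locus (substitutions only)")
  }
  if (!grepl("^[ACGT]+$", s)) abort("ambiguous bases cannot be translated")
  cs <- locus$coding_segments
  pieces <- substring(s, cs$start, cs$end)
  if (locus$strand == "+") {
    cds <- paste(pieces, collapse = "")
    off <- cs$frame_offset[1L]
  } else {
    cds <- paste(rev(vapply(pieces, reverse_complement, character(1))),
                 collapse = "")
    off <- cs$frame_offset[nrow(cs)]
  }
  cds <- substr(cds, off + 1L, nchar(cds))
  n_codon <- nchar(cds) %/% 3L
  if (n_codon == 0L) return("")
  cds <- substr(cds, 1L, 3L * n_codon)
  as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                     no.init.codon = TRUE))
}

#' Read a locus from FASTA plus a coding annotation
#'
#' The annotation is a 4-column TSV (`locus_id`, `start`, `end`,
#' `frame_offset`) whose first line is a comment of the form `# strand=+`.
#'
#' @param fasta_path Path to a single-record FASTA file.
#' @param annotation_path Optional path to the annotation TSV.
#' @return A [reference_locus()].
#' @export
read_locus <- function(fasta_path, annotation_path = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) != 1L) abort("locus FASTA must contain exactly one record")
  id <- sub("\\s.*$", "", names(seqs)[1L])
  cs <- NULL; strand <- "+"
  if (!is.null(annotation_path)) {
    first <- readLines(annotation_path, n = 1L)
    m <- regmatches(first, regexpr("strand=[+-]", first))
    if (length(m)) strand <- substr(m, nchar(m), nchar(m))
    tab <- readr::read_tsv(annotation_path, comment = "#",
                           col_names = c("locus_id", "start", "end",
                                         "frame_offset"),
                           col_types = "ciii", progress = FALSE)
    tab <- tab[tab$locus_id == id, , drop = FALSE]
    if (nrow(tab)) cs <- tab[, c("start", "end", "frame_offset")]
  }
  reference_locus(id, as.character(seqs[[1L]]), coding_segments = cs,
                  strand = strand)
}

#' Write a locus annotation TSV
#'
#' @param locus A [reference_locus()].
#' @param path Output path.
#' @export
write_locus_annotation <- function(locus, path) {
  lines <- c(sprintf("# strand=%s", locus$strand))
  if (!is.null(locus$coding_segments)) {
    cs <- locus$coding_segments
    lines <- c(lines, sprintf("%s\t%d\t%d\t%d", locus$locus_id,
                              cs$start, cs$end, cs$frame_offset))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Import coding segments from a GFF3 file
#'
#' Convenience mapping of GFF `CDS` features onto the locus annotation model:
#' `phase` becomes `frame_offset` and the strand of the first CDS becomes the
#' gene strand.
#'
#' @param gff_path Path to a GFF3 file.
#' @param seqid Optional sequence id to filter on.
#' @return List with elements `coding_segments` (tibble) and `strand`.
#' @export
read_annotation_gff <- function(gff_path, seqid = NULL) {
  lines <- readLines(gff_path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) abort("no features in GFF")
  f <- strsplit(lines, "\t", fixed = TRUE)
  keep <- vapply(f, function(x) length(x) >= 8 && x[3] == "CDS", logical(1))
  f <- f[keep]
  if (!is.null(seqid)) f <- f[vapply(f, function(x) x[1] == seqid, logical(1))]
  if (!length(f)) abort("no CDS features found")
  cs <- tibble(
    start = vapply(f, function(x) as.integer(x[4]), integer(1)),
    end = vapply(f, function(x) as.integer(x[5]), integer(1)),
    frame_offset = vapply(f, function(x) {
      p <- suppressWarnings(as.integer(x[8])); if (is.na(p)) 0L else p
    }, integer(1))
  )
  list(coding_segments = cs[order(cs$start), ],
       strand = f[[1L]][7])
}
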