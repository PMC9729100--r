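#' Cassette design configuration
#'
#' Central defaults for the cassette designer. These are the assay's design
#' rules: 45-nt homology arms, WT-prime within 3 nt of the variant, seed
#' width 10 nt, primer offsets 40-120 nt outside the ssODN-covered region,
#' 230-350-bp products, rare-codon floor of 5 per thousand.
#'
#' @param arm_len ssODN homology arm length (nt).
#' @param seed_max Seed width from the PAM-proximal protospacer end (nt).
#' @param wtprime_max_distance Maximum WT-prime distance from the variant (nt).
#' @param min_codon_freq Rare-codon threshold (occurrences per thousand).
#' @param joint_disruption Require the guide to be disrupted by variant and
#'   WT-prime independently (default TRUE).
#' @param splice_mode `"standard"` or `"exon_offset"` (splice variants).
#' @param offset_range,product_range Primer placement windows.
#' @param max_offtarget_mismatches Protospacer mismatch radius for the
#'   off-target screen.
#' @param offtarget_refs Optional named character vector of extra sequences
#'   to screen against (the locus itself is always screened).
#' @param pg_per_diploid_genome Genomic DNA mass per diploid genome (pg).
#' @return A list of class `cassette_config`.
#' @export
cassette_config <- function(arm_len = 45L, seed_max = 10L,
                            wtprime_max_distance = 3L, min_codon_freq = 5,
                            joint_disruption = TRUE,
                            splice_mode = c("standard", "exon_offset"),
                            offset_range = c(40L, 120L),
                            product_range = c(230L, 350L),
                            max_offtarget_mismatches = 3L,
                            offtarget_refs = NULL,
                            pg_per_diploid_genome = 6.0) {
  splice_mode <- match.arg(splice_mode)
  structure(as.list(environment()), class = "cassette_config")
}

#' Assemble a complete CRISPR-Select cassette
#'
#' Runs the full designer: guide enumeration, WT-prime design, off-target
#' screen, both ssODN repair templates and target-site primers, producing a
#' `cassette` object plus a rule-by-rule design report. The two ssODNs are
#' identical except at their edit positions; one carries the variant of
#' interest, the other the synonymous WT-prime normalization mutation.
#'
#' Guides are tried in ranked order and the first guide for which a valid
#' WT-prime exists (in joint mode: one that independently disrupts the guide)
#' is selected. Failures name the stage that failed.
#'
#' @param locus A [reference_locus()] with coding segments.
#' @param variant A [variant_spec()].
#' @param config A [cassette_config()].
#' @return A list of class `cassette`: `locus`, `variant`, `wtprime`
#'   (variant_spec), `guide` (1-row tibble), `variant_ssodn`,
#'   `wtprime_ssodn`, `primers`, `offtargets`, `covered_region`
#'   (`c(start, end)` union footprint of both ssODNs), `amplicon` (list:
#'   `sequence`, `start`, `end`), `report` (tibble), `config`.
#' @export
assemble_cassette <- function(locus, variant, config = cassette_config()) {
  splice_mode <- if (variant$variant_class == "splice" &&
                     config$splice_mode == "standard") "exon_offset"
                 else config$splice_mode

  guides <- enumerate_guides(locus, variant, seed_max = config$seed_max)
  if (!nrow(guides)) {
    abort("design failed at stage 'guide': no NGG guide places the variant in seed/PAM")
  }

  chosen <- NULL
  for (i in seq_len(nrow(guides))) {
    g <- guides[i, ]
    wt <- design_wtprime(
      locus, variant, guide = if (config$joint_disruption) g else NULL,
      max_distance = config$wtprime_max_distance,
      min_codon_freq = config$min_codon_freq,
      splice_mode = splice_mode, seed_max = config$seed_max
    )
    acc <- wt[wt$accepted, , drop = FALSE]
    if (nrow(acc)) {
      chosen <- list(guide = g, wtprime_tbl = wt, best = acc[1L, ])
      break
    }
  }
  if (is.null(chosen)) {
    abort("design failed at stage 'wtprime': no synonymous WT-prime satisfies the rules")
  }
  g <- chosen$guide
  wtprime <- variant_spec(chosen$best$position, chosen$best$ref,
                          chosen$best$alt, label = paste0(variant$label, "-WTprime"),
                          variant_class = "synonymous", locus = locus)

  refs <- c(setNames(locus$sequence, locus$locus_id), config$offtarget_refs)
  ot <- screen_offtargets(g, refs,
                          max_mismatches = config$max_offtarget_mismatches,
                          seed_max = config$seed_max)

  v_ssodn <- build_ssodn(locus, g, variant, arm_len = config$arm_len)
  w_ssodn <- build_ssodn(locus, g, wtprime, arm_len = config$arm_len)
  covered <- c(min(v_ssodn$region_start, w_ssodn$region_start),
               max(v_ssodn$region_end, w_ssodn$region_end))

  primers <- design_primers(locus, covered,
                            offset_range = config$offset_range,
                            product_range = config$product_range)
  amplicon <- list(
    sequence = substr(locus$sequence, primers$product_start,
                      primers$product_end),
    start = primers$product_start, end = primers$product_end
  )

  var_offsets <- g$disruption_offsets[[1L]]
  report <- tibble(
    rule = c("guide_seed_pam", "wtprime_seed_pam", "wtprime_synonymous",
             "wtprime_distance", "offtarget_seed_mismatch",
             "arm_length", "primer_offsets", "product_length"),
    value = c(
      paste0("offsets ", paste(var_offsets, collapse = ",")),
      sprintf("pos %d", wtprime$position),
      "protein unchanged",
      sprintf("%d nt", abs(wtprime$position - variant$position)),
      sprintf("%d hit(s)", nrow(ot$hits)),
      sprintf("%d/%d nt", config$arm_len, config$arm_len),
      sprintf("%d/%d nt", primers$fwd_offset, primers$rev_offset),
      sprintf("%d bp", primers$product_length)
    ),
    pass = c(TRUE, TRUE, TRUE,
             abs(wtprime$position - variant$position) <=
               config$wtprime_max_distance ||
               splice_mode == "exon_offset",
             ot$pass, TRUE,
             all(c(primers$fwd_offset, primers$rev_offset) >=
                   config$offset_range[1L] &
                   c(primers$fwd_offset, primers$rev_offset) <=
                   config$offset_range[2L]),
             primers$product_length >= config$product_range[1L] &&
               primers$product_length <= config$product_range[2L])
  )

  structure(
    list(locus = locus, variant = variant, wtprime = wtprime, guide = g,
         wtprime_candidates = chosen$wtprime_tbl,
         variant_ssodn = v_ssodn, wtprime_ssodn = w_ssodn,
         primers = primers, offtargets = ot, covered_region = covered,
         amplicon = amplicon, report = report, config = config),
    class = "cassette"
  )
}

#' @export
print.cassette <- function(x, ...) {
  cat("<cassette> ", x$variant$label, " @ ", x$locus$locus_id, "\n",
      "  guide:   ", x$guide$protospacer, " ", x$guide$pam, " (",
      x$guide$strand, "), cut after ", x$guide$cut_after, "\n",
      "  variant: ", x$variant$ref, ">", x$variant$alt, " at ",
      x$variant$position, " (", x$guide$variant_distance_to_cut,
      " nt from cut)\n",
      "  WT':     ", x$wtprime$ref, ">", x$wtprime$alt, " at ",
      x$wtprime$position, " (synonymous, ",
      abs(x$wtprime$position - x$variant$position), " nt from variant)\n",
      "  ssODNs:  ", nchar(x$variant_ssodn$sequence), " nt (",
      x$variant_ssodn$polarity, ")\n",
      "  product: ", x$primers$product_length, " bp, offsets ",
      x$primers$fwd_offset, "/", x$primers$rev_offset, " nt\n", sep = "")
  invisible(x)
}

#' @rdname tidy-crisprselect
#' @export
tidy.cassette <- function(x, ...) x$report

#' @rdname tidy-crisprselect
#' @export
glance.cassette <- function(x, ...) {
  tibble(
    variant = x$variant$label,
    guide = x$guide$protospacer, pam = x$guide$pam, strand = x$guide$strand,
    variant_distance_to_cut = x$guide$variant_distance_to_cut,
    wtprime_distance = abs(x$wtprime$position - x$variant$position),
    ssodn_length = nchar(x$variant_ssodn$sequence),
    polarity = x$variant_ssodn$polarity,
    product_length = x$primers$product_length,
    offtarget_pass = x$offtargets$pass,
    all_rules_pass = all(x$report$pass)
  )
}

#' Write / read a cassette bundle
#'
#' Serializes the cassette (locus, variant, WT-prime, guide, ssODNs and
#' primers) to a YAML bundle that round-trips through [read_cassette()], and
#' optionally writes oligo sequences as FASTA plus a plain-text design report.
#'
#' @param cassette A [assemble_cassette()] result.
#' @param path Output YAML path.
#' @param fasta Optional path for ssODN + primer FASTA.
#' @param report Optional path for the plain-text design report.
#' @return `path`, invisibly.
#' @export
write_cassette <- function(cassette, path, fasta = NULL, report = NULL) {
  x <- cassette
  bundle <- list(
    locus = list(locus_id = x$locus$locus_id, sequence = x$locus$sequence,
                 strand = x$locus$strand,
                 coding_segments = if (is.null(x$locus$coding_segments)) NULL
                   else as.list(as.data.frame(x$locus$coding_segments))),
    variant = unclass(x$variant),
    wtprime = unclass(x$wtprime),
    guide = as.list(x$guide[, c("protospacer", "pam", "strand", "pam_start",
                                "cut_after", "variant_distance_to_cut")]),
    variant_ssodn = ssodn_fields(x$variant_ssodn),
    wtprime_ssodn = ssodn_fields(x$wtprime_ssodn),
    primers = unclass(x$primers),
    covered_region = as.integer(x$covered_region),
    amplicon = x$amplicon,
    config = unclass(x$config)
  )
  yaml::write_yaml(bundle, path)
  if (!is.null(fasta)) {
    recs <- c(
      setNames(x$variant_ssodn$sequence, paste0(x$variant$label, "_ssODN")),
      setNames(x$wtprime_ssodn$sequence, paste0(x$wtprime$label, "_ssODN")),
      setNames(x$primers$forward, "primer_F"),
      setNames(x$primers$reverse, "primer_R")
    )
    writeLines(paste0(">", names(recs), "\n", recs), fasta)
  }
  if (!is.null(report)) {
    rl <- c(sprintf("CRISPR-Select design report: %s", x$variant$label),
            sprintf("%-24s %-20s %s", x$report$rule, x$report$value,
                    ifelse(x$report$pass, "PASS", "FAIL")))
    writeLines(rl, report)
  }
  invisible(path)
}

ssodn_fields <- function(s) {
  list(sequence = s$sequence, polarity = s$polarity,
       arm_5_len = s$arm_5_len, arm_3_len = s$arm_3_len,
       region_start = s$region_start, region_end = s$region_end,
       distance_to_cut = s$distance_to_cut,
       edit = unclass(s$encoded_edit))
}

#' @rdname write_cassette
#' @export
read_cassette <- function(path) {
  b <- yaml::read_yaml(path)
  cs <- if (!is.null(b$locus$coding_segments))
    as_tibble(b$locus$coding_segments) else NULL
  locus <- reference_locus(b$locus$locus_id, b$locus$sequence,
                           coding_segments = cs, strand = b$locus$strand)
  mk_vs <- function(v) variant_spec(v$position, v$ref, v$alt, v$label,
                                    v$variant_class)
  mk_ss <- function(s) {
    structure(list(sequence = s$sequence, polarity = s$polarity,
                   arm_5_len = s$arm_5_len, arm_3_len = s$arm_3_len,
                   encoded_edit = mk_vs(s$edit),
                   region_start = s$region_start, region_end = s$region_end,
                   distance_to_cut = s$distance_to_cut), class = "ssodn")
  }
  cfg <- do.call(cassette_config,
                 b$config[intersect(names(b$config),
                                    names(formals(cassette_config)))])
  structure(
    list(locus = locus, variant = mk_vs(b$variant), wtprime = mk_vs(b$wtprime),
         guide = as_tibble(b$guide), wtprime_candidates = NULL,
         variant_ssodn = mk_ss(b$variant_ssodn),
         wtprime_ssodn = mk_ss(b$wtprime_ssodn),
         primers = structure(b$primers, class = "primer_pair"),
         offtargets = NULL,
         covered_region = as.integer(unlist(b$covered_region)),
         amplicon = list(sequence = b$amplicon$sequence,
                         start = b$amplicon$start, end = b$amplicon$end),
         report = NULL, config = cfg),
    class = "cassette"
  )
}

# Amplicon-relative coordinates of the cassette's features, used by the read
# classifier and the simulator.
amplicon_map <- function(cassette) {
  a0 <- cassette$amplicon$start - 1L
  cs <- cassette$locus$coding_segments
  coding <- if (is.null(cs)) NULL else {
    k <- tibble(start = pmax(cs$start - a0, 1L),
                end = pmin(cs$end - a0, nchar(cassette$amplicon$sequence)))
    k[k$start <= k$end, , drop = FALSE]
  }
  list(
    variant_pos = cassette$variant$position - a0,
    variant_ref = cassette$variant$ref, variant_alt = cassette$variant$alt,
    wtprime_pos = cassette$wtprime$position - a0,
    wtprime_ref = cassette$wtprime$ref, wtprime_alt = cassette$wtprime$alt,
    window = c(cassette$covered_region[1L] - a0,
               cassette$covered_region[2L] - a0),
    cut_after = cassette$guide$cut_after - a0,
    coding = coding
  )
}
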