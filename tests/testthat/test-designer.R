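# Constructed locus with a single NGG PAM on an A/T backbone: PAM at 40-42
# (TGG), protospacer 20-39, cut after 36.
single_pam_locus <- function() {
  ch <- rep(c("A", "T"), 40L)
  ch[41L] <- "G"; ch[42L] <- "G"
  reference_locus("onepam", paste(ch, collapse = ""))
}

test_that("guide enumeration finds only seed/PAM-disrupting candidates", {
  # no NGG on either strand
  atl <- reference_locus("noPAM", strrep("AT", 30L))
  v <- variant_spec(30, "T", "A")
  expect_identical(nrow(enumerate_guides(atl, v)), 0L)

  # locus too short
  shortl <- reference_locus("short", strrep("AT", 25L))
  expect_error(enumerate_guides(shortl, variant_spec(25, "A", "C")),
               "too short")

  loc <- single_pam_locus()
  # variant 2 nt from the PAM-proximal protospacer end -> one candidate
  g <- enumerate_guides(loc, variant_spec(38, "T", "A"))
  expect_identical(nrow(g), 1L)
  expect_identical(g$strand, "+")
  expect_identical(g$pam, "TGG")
  expect_equal(g$min_seed_offset, 2)
  expect_identical(g$cut_after, 36L)
  expect_identical(g$protospacer, substr(loc$sequence, 20, 39))

  # variant 12 nt from the PAM-proximal end: outside the seed -> none
  expect_identical(nrow(enumerate_guides(loc, variant_spec(28, "T", "A"))), 0L)

  # a variant in the PAM counts only when it hits a G of the GG
  g_gg <- enumerate_guides(loc, variant_spec(41, "G", "A"))
  expect_identical(nrow(g_gg), 1L)
  expect_true(0L %in% g_gg$disruption_offsets[[1L]])
  expect_identical(nrow(enumerate_guides(loc, variant_spec(40, "T", "C"))),
                   0L)  # the degenerate N
})

test_that("guides are ranked by cut distance, then seed offset, then strand", {
  battery <- design_battery(5L, seed = 301L)
  for (cas in battery) {
    g <- enumerate_guides(cas$locus, cas$variant)
    d <- abs(g$variant_distance_to_cut)
    expect_true(all(diff(d) >= 0))
  }
})

test_that("off-target screen applies the seed/PAM mismatch rule", {
  loc <- single_pam_locus()
  g <- enumerate_guides(loc, variant_spec(38, "T", "A"))

  # only the on-target site present
  rep0 <- screen_offtargets(g, setNames(loc$sequence, "onepam"))
  expect_true(rep0$pass)
  expect_identical(nrow(rep0$hits), 0L)

  proto <- strsplit(g$protospacer, "", fixed = TRUE)[[1L]]
  flip <- function(b) if (b == "A") "T" else "A"
  pad <- strrep("AT", 10L)

  # decoy with one mismatch at seed offset 5 (protospacer index 16) -> pass
  d1 <- proto; d1[16L] <- flip(d1[16L])
  decoy1 <- paste0(pad, paste(d1, collapse = ""), "TGG", pad)
  rep1 <- screen_offtargets(g, c(onepam = loc$sequence, decoy = decoy1))
  expect_true(rep1$pass)
  expect_identical(nrow(rep1$hits), 1L)
  expect_identical(rep1$hits$mismatches, 1L)
  expect_true(rep1$hits$seed_mismatch)

  # decoy matching seed and PAM, 2 mismatches at offsets 15 and 18 -> fail
  d2 <- proto; d2[6L] <- flip(d2[6L]); d2[3L] <- flip(d2[3L])
  decoy2 <- paste0(pad, paste(d2, collapse = ""), "TGG", pad)
  rep2 <- screen_offtargets(g, c(onepam = loc$sequence, decoy = decoy2))
  expect_false(rep2$pass)
  expect_identical(min(rep2$hits$mismatches), 2L)
  expect_false(any(rep2$hits$seed_mismatch[rep2$hits$mismatches == 2L]))
})

test_that("off-target scan agrees with a naive sliding-window oracle", {
  cas <- fixture_cassette()
  g <- cas$guide
  ref <- random_sequence(500L, seed = 77L)
  rep <- screen_offtargets(g, c(rand = ref), max_mismatches = 3L)

  proto <- strsplit(g$protospacer, "", fixed = TRUE)[[1L]]
  naive <- list()
  rch <- strsplit(ref, "", fixed = TRUE)[[1L]]
  rcch <- strsplit(reverse_complement(ref), "", fixed = TRUE)[[1L]]
  for (i in seq_len(500L - 22L)) {
    for (str in c("+", "-")) {
      win <- if (str == "+") rch[i:(i + 22L)] else rcch[i:(i + 22L)]
      if (win[22L] == "G" && win[23L] == "G") {
        mm <- sum(win[1:20] != proto)
        if (mm <= 3L)

          naive[[length(naive) + 1L]] <- c(strand = str, mm = mm)
      }
    }
  }
  expect_identical(nrow(rep$hits), length(naive))
  if (length(naive)) {
    expect_setequal(rep$hits$mismatches,
                    as.integer(vapply(naive, `[[`, character(1), "mm")))
  }
})

test_that("WT-prime design returns ranked synonymous candidates", {
  # Met-Leu-Ala-stop; variant in the Leu codon (CTG)
  loc <- reference_locus("leu", "ATGCTGGCTTAAATATATAT",
                         coding_segments = data.frame(start = 1, end = 12,
                                                      frame_offset = 0))
  v <- variant_spec(5, "T", "G", label = "L2R")  # CTG -> CGG, missense
  wt <- design_wtprime(loc, v, guide = NULL)
  acc <- wt[wt$accepted, ]
  expect_gt(nrow(acc), 0L)
  expect_true(all(acc$synonymous))
  expect_true(all(acc$distance <= 3L))
  # best candidate: third-position Leu wobble with the commonest codon (CTC)
  expect_identical(acc$new_codon[1L], "CTC")
  expect_identical(acc$position[1L], 6L)
  # every accepted candidate keeps the protein intact when applied
  for (i in seq_len(nrow(acc))) {
    w <- variant_spec(acc$position[i], acc$ref[i], acc$alt[i])
    expect_identical(translate_coding(loc, apply_edit(loc, w)),
                     translate_coding(loc))
  }
})

test_that("WT-prime design fails cleanly when no synonymous option exists", {
  # Met-Trp-Met: single-codon amino acids only within the +/-3 window
  loc <- reference_locus("met", "ATGTGGATGTAAATATATAT",
                         coding_segments = data.frame(start = 1, end = 12,
                                                      frame_offset = 0))
  v <- variant_spec(4, "T", "A", label = "W2R")
  wt <- design_wtprime(loc, v, guide = NULL)
  expect_identical(sum(wt$accepted), 0L)
  expect_true(all(wt$reason[!wt$accepted] == "not synonymous"))
})

test_that("rare-codon rule rejects codons below the usage threshold", {
  # Arg codon AGA (12.2); AGA->CGA (6.2) passes at threshold 5 but not at 10
  loc <- reference_locus("arg", "ATGAGAGCTTAAATATATAT",
                         coding_segments = data.frame(start = 1, end = 12,
                                                      frame_offset = 0))
  v <- variant_spec(6, "A", "G", label = "R2?")
  wt5 <- design_wtprime(loc, v, guide = NULL, min_codon_freq = 5)
  wt99 <- design_wtprime(loc, v, guide = NULL, min_codon_freq = 99)
  expect_gt(sum(wt5$accepted), sum(wt99$accepted))
  expect_true(any(wt99$reason == "rare codon", na.rm = TRUE))
})

test_that("splice screen flags created donor motifs", {
  # edited sequence gains a consensus donor site CAG|GTAAGT
  before <- paste0(strrep("C", 10L), "CAGGTATGT", strrep("C", 10L))
  after <- paste0(strrep("C", 10L), "CAGGTAAGT", strrep("C", 10L))
  scr <- splice_screen(before, after, center = 15L)
  expect_true(scr$max_donor > splice_screen(before, before, 15L)$max_donor)
  # a neutral edit far from any motif passes
  neutral <- splice_screen(strrep("ACGT", 10L),
                           sub("ACGTACGT", "ACGAACGT", strrep("ACGT", 10L)),
                           center = 4L)
  expect_true(neutral$ok)
})

test_that("ssODN arms, polarity and strand conventions are correct", {
  loc <- reference_locus("odn", random_sequence(200L, seed = 9L))
  guide <- list(cut_after = 100L)

  # SNV with 45-nt arms -> 91-nt oligo
  e_left <- variant_spec(90, substr(loc$sequence, 90, 90),
                         setdiff(c("A", "C", "G", "T"),
                                 substr(loc$sequence, 90, 90))[1L])
  s_left <- build_ssodn(loc, guide, e_left)
  expect_identical(nchar(s_left$sequence), 91L)
  expect_identical(s_left$polarity, "sense")
  expect_identical(s_left$arm_5_len, 45L)

  # same edit placed right of the break -> antisense, revcomp of sense
  e_right <- variant_spec(110, substr(loc$sequence, 110, 110),
                          setdiff(c("A", "C", "G", "T"),
                                  substr(loc$sequence, 110, 110))[1L])
  s_right <- build_ssodn(loc, guide, e_right)
  expect_identical(s_right$polarity, "antisense")
  sense_seq <- paste0(substr(loc$sequence, 65, 109), e_right$alt,
                      substr(loc$sequence, 111, 155))
  expect_identical(s_right$sequence, reverse_complement(sense_seq))

  # edit within 4 bp of the cut: polarity rule not triggered -> sense
  e_near <- variant_spec(99, substr(loc$sequence, 99, 99),
                         setdiff(c("A", "C", "G", "T"),
                                 substr(loc$sequence, 99, 99))[1L])
  expect_identical(build_ssodn(loc, guide, e_near)$polarity, "sense")

  # arms beyond the locus boundary
  expect_error(build_ssodn(loc, guide, variant_spec(
    30, substr(loc$sequence, 30, 30),
    setdiff(c("A", "C", "G", "T"), substr(loc$sequence, 30, 30))[1L])),
    "homology arms")
})

test_that("primer designer respects offsets, product window and determinism", {
  loc <- reference_locus("pr", random_sequence(700L, seed = 13L))
  pp <- design_primers(loc, c(300L, 396L))
  expect_true(pp$fwd_offset >= 40L && pp$fwd_offset <= 120L)
  expect_true(pp$rev_offset >= 40L && pp$rev_offset <= 120L)
  expect_true(pp$product_length >= 230L && pp$product_length <= 350L)
  expect_identical(nchar(pp$forward) >= 18L && nchar(pp$forward) <= 25L, TRUE)
  # annealing entirely outside the covered region
  expect_lt(pp$fwd_end, 300L - 39L)
  expect_gt(pp$rev_start, 396L + 39L)
  # deterministic
  pp2 <- design_primers(loc, c(300L, 396L))
  expect_identical(pp, pp2)
  # reverse primer is the reverse complement of the plus strand
  expect_identical(pp$reverse,
                   reverse_complement(substr(loc$sequence, pp$rev_start,
                                             pp$rev_end)))
})

test_that("primer designer errors name the violated constraint", {
  loc_short <- reference_locus("prs", random_sequence(300L, seed = 14L))
  expect_error(design_primers(loc_short, c(50L, 250L)),
               "offset window unsatisfiable")
  loc_wide <- reference_locus("prw", random_sequence(700L, seed = 15L))
  expect_error(design_primers(loc_wide, c(200L, 499L)),
               "product length window unsatisfiable")
})

test_that("assembled cassettes satisfy every published design rule", {
  cas <- fixture_cassette()
  cfg <- cas$config

  # guide disruption: all offsets in PAM-GG (0) or seed <= 10
  offs <- cas$guide$disruption_offsets[[1L]]
  expect_true(all(offs == 0L | (offs >= 1L & offs <= cfg$seed_max)))

  # WT-prime synonymous and within 3 nt
  expect_lte(abs(cas$wtprime$position - cas$variant$position), 3L)
  expect_identical(
    translate_coding(cas$locus, apply_edit(cas$locus, cas$wtprime)),
    translate_coding(cas$locus))

  # the ssODNs equal the locus-with-edit over their genomic footprint
  for (nm in c("variant_ssodn", "wtprime_ssodn")) {
    s <- cas[[nm]]
    edit <- s$encoded_edit
    expected_sense <- paste0(
      substr(cas$locus$sequence, s$region_start, edit$position - 1L),
      edit$alt,
      substr(cas$locus$sequence, edit$position + nchar(edit$ref),
             s$region_end))
    got <- if (s$polarity == "sense") s$sequence
           else reverse_complement(s$sequence)
    expect_identical(got, expected_sense)
    expect_identical(nchar(s$sequence), 2L * cfg$arm_len + nchar(edit$alt))
  }

  # primers outside the covered region, product in window
  expect_true(all(cas$report$pass))
  expect_lt(cas$primers$fwd_end, cas$covered_region[1L])
  expect_gt(cas$primers$rev_start, cas$covered_region[2L])

  # tidiers
  expect_s3_class(tidy(cas), "tbl_df")
  expect_identical(nrow(glance(cas)), 1L)
})

test_that("design failures propagate the failing stage", {
  atl <- reference_locus("noPAM", strrep("AT", 40L),
                         coding_segments = data.frame(start = 1, end = 78,
                                                      frame_offset = 0))
  expect_error(assemble_cassette(atl, variant_spec(40, "T", "A")),
               "stage 'guide'")
})

test_that("cassette bundles round-trip through YAML", {
  cas <- fixture_cassette()
  path <- tempfile(fileext = ".yaml")
  fa <- tempfile(fileext = ".fasta")
  write_cassette(cas, path, fasta = fa)
  cas2 <- read_cassette(path)
  expect_identical(cas2$amplicon$sequence, cas$amplicon$sequence)
  expect_identical(cas2$variant_ssodn$sequence, cas$variant_ssodn$sequence)
  expect_identical(cas2$wtprime$alt, cas$wtprime$alt)
  expect_identical(cas2$covered_region, as.integer(cas$covered_region))
  expect_identical(cas2$primers$forward, cas$primers$forward)
  fasta <- readLines(fa)
  expect_identical(sum(startsWith(fasta, ">")), 4L)
})
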