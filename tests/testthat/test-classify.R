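toy_read <- function(setting, edits) apply_toy_edits(setting$amplicon, edits)

toy_classify <- function(setting, read, config = classifier_config()) {
  al <- align_read(read, setting$amplicon, config)
  crisprselect:::classify_alignment(al, setting$map, config)
}

test_that("clean knock-in, WT and mixed reads are classified correctly", {
  s <- toy_setting()
  m <- s$map
  expect_identical(toy_classify(s, s$amplicon), "WT")
  expect_identical(
    toy_classify(s, toy_read(s, list(list(type = "sub", pos = m$variant_pos,
                                          base = m$variant_alt)))),
    "VARIANT_KI")
  expect_identical(
    toy_classify(s, toy_read(s, list(list(type = "sub", pos = m$wtprime_pos,
                                          base = m$wtprime_alt)))),
    "WTPRIME_KI")
  expect_identical(
    toy_classify(s, toy_read(s, list(
      list(type = "sub", pos = m$variant_pos, base = m$variant_alt),
      list(type = "sub", pos = m$wtprime_pos, base = m$wtprime_alt)))),
    "MIXED_KI")
  # a third base at the variant position is OTHER
  third <- setdiff(c("A", "C", "G", "T"),
                   c(m$variant_ref, m$variant_alt))[1L]
  expect_identical(
    toy_classify(s, toy_read(s, list(list(type = "sub", pos = m$variant_pos,
                                          base = third)))),
    "OTHER")
})

test_that("InDels take precedence over point edits and frame decides the call", {
  s <- toy_setting(); m <- s$map
  # variant substitution plus a 2-nt deletion -> frameshift, not knock-in
  r <- toy_read(s, list(list(type = "sub", pos = m$variant_pos,
                             base = m$variant_alt),
                        list(type = "del", pos = 20L, len = 2L)))
  expect_identical(toy_classify(s, r), "FRAMESHIFT_INDEL")
  # net 3-nt insertion -> in-frame
  r3 <- toy_read(s, list(list(type = "ins", pos = 25L, base = "ACT")))
  expect_identical(toy_classify(s, r3), "INFRAME_INDEL")
  # 1-nt deletion -> frameshift
  r1 <- toy_read(s, list(list(type = "del", pos = 33L, len = 1L)))
  expect_identical(toy_classify(s, r1), "FRAMESHIFT_INDEL")
  # indel outside the quantification window does not drive the call
  rout <- toy_read(s, list(list(type = "del", pos = 2L, len = 1L)))
  expect_identical(toy_classify(s, rout), "WT")
})

test_that("sequencing-error substitutions are tolerated unless strict", {
  s <- toy_setting(); m <- s$map
  r <- toy_read(s, list(list(type = "sub", pos = m$variant_pos,
                             base = m$variant_alt),
                        list(type = "sub", pos = 40L,
                             base = setdiff(c("A", "C", "G", "T"),
                                            substr(s$amplicon, 40, 40))[1L])))
  expect_identical(toy_classify(s, r), "VARIANT_KI")
  strict <- classifier_config(strict = TRUE)
  expect_identical(toy_classify(s, r, strict), "OTHER")
})

test_that("purely non-coding InDels are not called frameshift", {
  s <- toy_setting()
  m <- s$map
  m$coding <- tibble::tibble(start = 1L, end = 15L)  # window is 11..50
  r <- apply_toy_edits(s$amplicon, list(list(type = "del", pos = 40L,
                                             len = 2L)))
  al <- align_read(r, s$amplicon)
  expect_identical(crisprselect:::classify_alignment(al, m), "INFRAME_INDEL")
})

test_that("genome-equivalent arithmetic matches the published calculation", {
  est <- estimate_absolute_cells(100, 0.08)
  expect_equal(est$genome_equivalents, 100 * 1000 / 6)
  expect_equal(est$genome_equivalents_rounded, 17000)
  expect_true(est$cells_rounded_template >= 1300 &&
                est$cells_rounded_template <= 1600)
  expect_equal(estimate_absolute_cells(100, 0)$cells, 0)
  expect_error(estimate_absolute_cells(0, 0.5), "positive")
  expect_error(estimate_absolute_cells(100, 1.2), "0, 1")

  # linear in frequency and in mass
  e1 <- estimate_absolute_cells(100, 0.02)$cells
  expect_equal(estimate_absolute_cells(100, 0.04)$cells, 2 * e1)
  expect_equal(estimate_absolute_cells(200, 0.02)$cells, 2 * e1)
  # allele interpretation reported alongside
  expect_equal(estimate_absolute_cells(100, 0.05)$alleles,
               2 * estimate_absolute_cells(100, 0.05)$cells)
})

test_that("quantify_sample aggregates a known read mixture exactly", {
  cas <- fixture_cassette()
  amp <- cas$amplicon$sequence
  map <- crisprselect:::amplicon_map(cas)
  sub_at <- function(s, pos, alt) {
    substr(s, pos, pos) <- alt; s
  }
  var_read <- sub_at(amp, map$variant_pos, map$variant_alt)
  wtp_read <- sub_at(amp, map$wtprime_pos, map$wtprime_alt)
  del_read <- paste0(substr(amp, 1, map$cut_after - 1),
                     substr(amp, map$cut_after + 1, nchar(amp)))
  seqs <- c(rep(amp, 50L), rep(var_read, 8L), rep(wtp_read, 9L),
            rep(del_read, 33L))
  fq <- write_test_fastq(seqs)
  prof <- quantify_sample(fq, cas, gdna_ng = 100, sample_id = "mix")
  counts <- setNames(prof$reads, prof$category)
  expect_identical(counts[["WT"]], 50L)
  expect_identical(counts[["VARIANT_KI"]], 8L)
  expect_identical(counts[["WTPRIME_KI"]], 9L)
  expect_identical(counts[["FRAMESHIFT_INDEL"]], 33L)
  expect_identical(attr(prof, "retained_reads"), 100L)
  nd <- prof$frequency[prof$category != "DISCARDED"]
  expect_equal(sum(nd), 1, tolerance = 1e-12)
  # absolute estimates: genome equivalents x frequency
  expect_equal(prof$cells[prof$category == "VARIANT_KI"],
               (100 * 1000 / 6) * 0.08)
})

test_that("quantify_sample discards low-quality reads and flags junk", {
  cas <- fixture_cassette()
  amp <- cas$amplicon$sequence
  fq <- tempfile(fileext = ".fastq")
  writeLines(c("@good", amp, "+", strrep("I", nchar(amp)),
               "@bad", amp, "+", strrep("#", nchar(amp))), fq)
  prof <- quantify_sample(fq, cas)
  expect_identical(prof$reads[prof$category == "DISCARDED"], 1L)
  expect_identical(prof$reads[prof$category == "WT"], 1L)

  empty_fq <- tempfile(fileext = ".fastq")
  file.create(empty_fq)
  expect_error(quantify_sample(empty_fq, cas), "empty")

  junk <- strrep("AC", floor(nchar(amp) / 2))
  fq2 <- write_test_fastq(rep(junk, 10L))
  prof2 <- quantify_sample(fq2, cas)
  expect_true(attr(prof2, "warn_unalignable"))
  expect_identical(prof2$reads[prof2$category == "OTHER"], 10L)
})

test_that("classify_read works through the public cassette interface", {
  cas <- fixture_cassette()
  amp <- cas$amplicon$sequence
  map <- crisprselect:::amplicon_map(cas)
  expect_identical(classify_read(amp, cas), "WT")
  var_read <- amp
  substr(var_read, map$variant_pos, map$variant_pos) <- map$variant_alt
  expect_identical(classify_read(var_read, cas), "VARIANT_KI")
})
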