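# Fixtures are generated in code, under fixed seeds, so the suite needs no
# external data.

random_sequence <- function(n, seed) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = ""))
}

# A fully coding 2-kb synthetic locus (frame 0, plus strand).
make_random_locus <- function(n = 2000L, seed = 11L, id = "synthL") {
  s <- random_sequence(n, seed)
  reference_locus(id, s,
                  coding_segments = data.frame(start = 1L,
                                               end = (n %/% 3L) * 3L,
                                               frame_offset = 0L))
}

random_snv <- function(locus, pos, seed = pos) {
  refb <- substr(locus$sequence, pos, pos)
  altb <- withr::with_seed(seed,
                           sample(setdiff(c("A", "C", "G", "T"), refb), 1L))
  variant_spec(pos, refb, altb, label = paste0("snv", pos), locus = locus)
}

# Attempt cassette designs at random positions until n succeed; returns the
# list of cassettes. Success rate on random sequence is high but not 1 (some
# positions lack a seed-placing PAM or a synonymous neighbour).
design_battery <- function(n = 20L, seed = 101L, locus = NULL) {
  locus <- locus %||% make_random_locus(seed = seed)
  positions <- withr::with_seed(seed, sample(300:1700, 200L))
  out <- list()
  for (pos in positions) {
    if (length(out) >= n) break
    v <- random_snv(locus, pos)
    cas <- tryCatch(assemble_cassette(locus, v), error = function(e) NULL)
    if (!is.null(cas)) out[[length(out) + 1L]] <- cas
  }
  out
}

# One deterministic cassette shared across test files (designed once per R
# session).
.fixture_env <- new.env(parent = emptyenv())
fixture_cassette <- function() {
  if (is.null(.fixture_env$cas)) {
    locus <- make_random_locus(seed = 11L)
    v <- random_snv(locus, 313L)
    .fixture_env$cas <- assemble_cassette(locus, v)
  }
  .fixture_env$cas
}

# Write reads (+ optional qualities) as a FASTQ file; returns the path.
write_test_fastq <- function(seqs, path = tempfile(fileext = ".fastq"),
                             qual_char = "I") {
  lines <- as.vector(rbind(sprintf("@read%04d", seq_along(seqs)), seqs, "+",
                           strrep(qual_char, nchar(seqs))))
  writeLines(lines, path)
  path
}

# Toy amplicon classification setting: a 60-nt amplicon with explicit edit
# positions, used for oracle comparisons without running the designer.
toy_map <- function() {
  list(amplicon = random_sequence(60L, seed = 7L),
       map = list(variant_pos = 28L, variant_ref = NA, variant_alt = NA,
                  wtprime_pos = 30L, wtprime_ref = NA, wtprime_alt = NA,
                  window = c(11L, 50L), cut_after = 29L,
                  coding = tibble::tibble(start = 1L, end = 60L)))
}

# Fill in the toy map's ref/alt bases from its amplicon.
toy_setting <- function() {
  t <- toy_map()
  amp <- t$amplicon
  m <- t$map
  m$variant_ref <- substr(amp, m$variant_pos, m$variant_pos)
  m$variant_alt <- setdiff(c("A", "C", "G", "T"), m$variant_ref)[1L]
  m$wtprime_ref <- substr(amp, m$wtprime_pos, m$wtprime_pos)
  m$wtprime_alt <- setdiff(c("A", "C", "G", "T"), m$wtprime_ref)[1L]
  list(amplicon = amp, map = m)
}

# Apply a list of edits (each list(type, pos, base/len)) to a sequence.
# Edits are applied right-to-left so positions stay valid.
apply_toy_edits <- function(seq, edits) {
  ord <- order(vapply(edits, `[[`, numeric(1), "pos"), decreasing = TRUE)
  for (e in edits[ord]) {
    if (e$type == "sub") {
      substr(seq, e$pos, e$pos) <- e$base
    } else if (e$type == "del") {
      seq <- paste0(substr(seq, 1L, e$pos - 1L),
                    substr(seq, e$pos + e$len, nchar(seq)))
    } else {
      seq <- paste0(substr(seq, 1L, e$pos), e$base,
                    substr(seq, e$pos + 1L, nchar(seq)))
    }
  }
  seq
}

# Independent rule-table oracle: category from the KNOWN edits, never from
# an alignment.
toy_oracle <- function(edits, m) {
  w1 <- m$window[1L]; w2 <- m$window[2L]
  indels <- Filter(function(e) e$type != "sub", edits)
  in_win <- vapply(indels, function(e) {
    if (e$type == "del") (e$pos + e$len - 1L) >= w1 && e$pos <= w2
    else e$pos >= (w1 - 1L) && e$pos <= w2     # ins after pos
  }, logical(1))
  if (any(in_win)) {
    net <- sum(vapply(indels[in_win], function(e) {
      if (e$type == "del") -e$len else nchar(e$base)
    }, numeric(1)))
    return(if (net %% 3L != 0L) "FRAMESHIFT_INDEL" else "INFRAME_INDEL")
  }
  base_at <- function(pos, ref) {
    for (e in edits) {
      if (e$type == "sub" && e$pos == pos) return(e$base)
    }
    ref
  }
  vb <- base_at(m$variant_pos, m$variant_ref)
  wb <- base_at(m$wtprime_pos, m$wtprime_ref)
  vp <- vb == m$variant_alt; wp <- wb == m$wtprime_alt
  if (vp && !wp) return("VARIANT_KI")
  if (wp && !vp) return("WTPRIME_KI")
  if (vp && wp) return("MIXED_KI")
  if (vb != m$variant_ref || wb != m$wtprime_ref) return("OTHER")
  "WT"
}
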