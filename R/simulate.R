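#' Simulation configuration
#'
#' Parameters of the forward simulator. The defaults emulate the editing
#' regime observed in real assays: most cut alleles acquire InDels, with
#' frameshift InDels about five times more frequent than either knock-in, and
#' per-template knock-in frequencies of a few percent of all alleles.
#'
#' @param seed Integer RNG seed; mandatory -- there is no implicit
#'   randomness anywhere in the simulator.
#' @param n_cells Cells in the edited population (default 10000).
#' @param cut_prob Per-allele probability that Cas9 cuts (default 0.8).
#' @param outcome_probs Named probabilities of the repair outcome of a *cut*
#'   allele over `unedited`, `VARIANT_KI`, `WTPRIME_KI`, `FRAMESHIFT_INDEL`,
#'   `INFRAME_INDEL`; must sum to 1. Defaults: 0.32 / 0.085 / 0.085 / 0.425 /
#'   0.085 (a 5:1 frameshift:knock-in ratio per template).
#' @param frameshift_lengths,inframe_lengths Support of the InDel net-length
#'   distributions (negative = deletion); drawn uniformly.
#' @param fitness Named per-day growth-rate multipliers for cell classes
#'   `variant`, `wtprime`, `frameshift`, `inframe`, `wt` (a cell's class is
#'   its most informative allele, in that priority order). Default all 1
#'   (neutral).
#' @param timepoints Assay days; the first is the baseline (default
#'   `c(2, 12)`).
#' @param gdna_ng Genomic template mass sampled per sample (default 100).
#' @param depth Reads per sample (default 30000).
#' @param error_rate Per-base substitution sequencing error (default 0.003).
#' @param joint_table Optional explicit joint distribution of biallelic
#'   outcomes: a data frame `allele_1`, `allele_2`, `prob` (summing to 1)
#'   that overrides the independent per-allele model.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed, n_cells = 10000L, cut_prob = 0.8,
                       outcome_probs = c(unedited = 0.32,
                                         VARIANT_KI = 0.085,
                                         WTPRIME_KI = 0.085,
                                         FRAMESHIFT_INDEL = 0.425,
                                         INFRAME_INDEL = 0.085),
                       frameshift_lengths = c(-7L, -5L, -4L, -2L, -1L, 1L, 2L),
                       inframe_lengths = c(-6L, -3L, 3L),
                       fitness = c(variant = 1, wtprime = 1, frameshift = 1,
                                   inframe = 1, wt = 1),
                       timepoints = c(2, 12), gdna_ng = 100,
                       depth = 30000L, error_rate = 0.003,
                       joint_table = NULL) {
  if (missing(seed)) abort("sim_config: seed is mandatory")
  if (any(outcome_probs < 0)) abort("negative outcome probabilities")
  if (abs(sum(outcome_probs) - 1) > 1e-8) {
    abort("outcome_probs must sum to 1")
  }
  if (any(frameshift_lengths %% 3L == 0L)) {
    abort("frameshift_lengths must not be multiples of 3")
  }
  if (any(inframe_lengths %% 3L != 0L) || any(inframe_lengths == 0L)) {
    abort("inframe_lengths must be non-zero multiples of 3")
  }
  if (any(fitness < 0)) abort("negative fitness")
  if (!is.null(joint_table)) {
    joint_table <- as_tibble(joint_table)
    stopifnot(all(c("allele_1", "allele_2", "prob") %in% names(joint_table)))
    if (abs(sum(joint_table$prob) - 1) > 1e-8) {
      abort("joint_table probabilities must sum to 1")
    }
  }
  structure(as.list(environment()), class = "sim_config")
}

sim_allele_levels <- function() {
  c("WT", "VARIANT_KI", "WTPRIME_KI", "FRAMESHIFT_INDEL", "INFRAME_INDEL")
}

#' Simulate editing outcomes in a cell population
#'
#' Each diploid cell draws cut/no-cut independently per allele; each cut
#' allele draws a repair outcome from the conditional outcome distribution
#' ("unedited" means perfect repair, i.e. a WT allele). InDel alleles draw a
#' net length from the configured distributions. With an explicit
#' `joint_table` in the config, biallelic outcomes are drawn jointly instead,
#' which lets users reproduce empirically observed biallelic dependence that
#' the independence model cannot.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_population`: `cells` (tibble `cell_id`,
#'   `allele_1`, `allele_2`, `indel_len_1`, `indel_len_2`), `truth` (baseline
#'   allele-category counts and the variant:WT-prime cell ratio), `config`.
#' @export
simulate_editing <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_cells
  withr::with_seed(config$seed, {
    if (is.null(config$joint_table)) {
      draw_allele <- function(k) {
        cut <- stats::runif(k) < config$cut_prob
        out <- rep("WT", k)
        nc <- sum(cut)
        if (nc) {
          cats <- sample(names(config$outcome_probs), nc, replace = TRUE,
                         prob = config$outcome_probs)
          cats[cats == "unedited"] <- "WT"
          out[cut] <- cats
        }
        out
      }
      a1 <- draw_allele(n)
      a2 <- draw_allele(n)
    } else {
      jt <- config$joint_table
      pick <- sample.int(nrow(jt), n, replace = TRUE, prob = jt$prob)
      a1 <- jt$allele_1[pick]
      a2 <- jt$allele_2[pick]
    }
    draw_len <- function(cat, k) {
      lens <- integer(k)
      fs <- cat == "FRAMESHIFT_INDEL"
      inf <- cat == "INFRAME_INDEL"
      if (any(fs)) lens[fs] <- sample(config$frameshift_lengths, sum(fs),
                                      replace = TRUE)
      if (any(inf)) lens[inf] <- sample(config$inframe_lengths, sum(inf),
                                        replace = TRUE)
      lens
    }
    cells <- tibble(
      cell_id = sprintf("cell%06d", seq_len(n)),
      allele_1 = a1, allele_2 = a2,
      indel_len_1 = draw_len(a1, n), indel_len_2 = draw_len(a2, n)
    )
  })
  truth <- sim_truth_from_cells(cells)
  structure(list(cells = cells, truth = truth, config = config),
            class = "sim_population")
}

sim_truth_from_cells <- function(cells, weight = NULL) {
  w <- weight %||% rep(1, nrow(cells))
  lv <- sim_allele_levels()
  alleles <- c(
    tapply(w, factor(cells$allele_1, levels = lv), sum, default = 0),
    tapply(w, factor(cells$allele_2, levels = lv), sum, default = 0)
  )
  counts <- tapply(alleles, names(alleles), sum)[lv]
  n_var <- sum(w[cells$allele_1 == "VARIANT_KI" |
                   cells$allele_2 == "VARIANT_KI"])
  n_wtp <- sum(w[cells$allele_1 == "WTPRIME_KI" |
                   cells$allele_2 == "WTPRIME_KI"])
  list(allele_counts = setNames(as.numeric(counts), lv),
       variant_cells = n_var, wtprime_cells = n_wtp,
       variant_wtprime_cell_ratio = if (n_wtp > 0) n_var / n_wtp else NA_real_,
       total_cells = sum(w))
}

# Cell class used for fitness: the most informative allele wins.
sim_cell_class <- function(a1, a2) {
  pri <- c(VARIANT_KI = "variant", WTPRIME_KI = "wtprime",
           FRAMESHIFT_INDEL = "frameshift", INFRAME_INDEL = "inframe",
           WT = "wt")
  out <- rep("wt", length(a1))
  for (cat in names(pri)) {
    hit <- out == "wt" & (a1 == cat | a2 == cat)
    out[hit] <- pri[[cat]]
  }
  out
}

#' Simulate selection across assay timepoints
#'
#' Genotype-dependent exponential growth: the expected number of cells of a
#' class at day `t` is its baseline count times `fitness^(t - t0)`, with the
#' first configured timepoint as baseline `t0`. Growth is expectation-based
#' (no birth-death noise); multinomial resampling is applied only at
#' passaging, when `passage_fraction` is set, which keeps closed-form
#' expectations available as test oracles.
#'
#' @param population A [simulate_editing()] result.
#' @param passage_fraction Optional fraction of cells kept at each timepoint
#'   after the baseline (multinomial subsampling); `NULL` for none.
#' @return A list of class `sim_timecourse`: `weights` (matrix cells x
#'   timepoints of expected cell multiplicities), `truth` (tibble per
#'   timepoint: allele counts, variant/WT-prime cell counts and ratio),
#'   `population`.
#' @export
simulate_selection <- function(population, passage_fraction = NULL) {
  cfg <- population$config
  cells <- population$cells
  cls <- sim_cell_class(cells$allele_1, cells$allele_2)
  fit <- cfg$fitness[cls]
  if (anyNA(fit)) abort("fitness missing for some cell class")
  t0 <- cfg$timepoints[1L]
  W <- matrix(NA_real_, nrow(cells), length(cfg$timepoints),
              dimnames = list(NULL, paste0("day", cfg$timepoints)))
  withr::with_seed(cfg$seed + 1L, {
    for (j in seq_along(cfg$timepoints)) {
      w <- as.numeric(fit)^(cfg$timepoints[j] - t0)
      if (!is.null(passage_fraction) && j > 1L) {
        keep <- round(sum(w) * passage_fraction)
        w <- as.numeric(rmultinom(1L, keep, prob = w))
      }
      W[, j] <- w
    }
  })
  truth <- bind_rows(lapply(seq_along(cfg$timepoints), function(j) {
    tr <- sim_truth_from_cells(cells, W[, j])
    tibble(point = cfg$timepoints[j],
           variant_cells = tr$variant_cells,
           wtprime_cells = tr$wtprime_cells,
           cell_ratio = tr$variant_wtprime_cell_ratio,
           total_cells = tr$total_cells,
           !!!setNames(as.list(tr$allele_counts),
                       paste0("alleles_", names(tr$allele_counts))))
  }))
  structure(list(weights = W, truth = truth, population = population),
            class = "sim_timecourse")
}

# Template sequences for each allele category present in the population.
# InDels are placed at the cut site: deletions remove bases ending at the
# cut, insertions add random bases immediately after it.
sim_templates <- function(cassette, indel_lens, rng_seed) {
  map <- amplicon_map(cassette)
  amp <- cassette$amplicon$sequence
  sub_at <- function(s, pos, ref, alt) {
    paste0(substr(s, 1L, pos - 1L), alt, substr(s, pos + nchar(ref), nchar(s)))
  }
  tmpl <- list(
    WT = amp,
    VARIANT_KI = sub_at(amp, map$variant_pos, map$variant_ref,
                        map$variant_alt),
    WTPRIME_KI = sub_at(amp, map$wtprime_pos, map$wtprime_ref,
                        map$wtprime_alt)
  )
  cut <- map$cut_after
  withr::with_seed(rng_seed, {
    for (len in sort(unique(indel_lens[indel_lens != 0L]))) {
      key <- paste0("INDEL", len)
      tmpl[[key]] <- if (len < 0L) {
        paste0(substr(amp, 1L, cut + len), substr(amp, cut + 1L, nchar(amp)))
      } else {
        ins <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                     collapse = "")
        paste0(substr(amp, 1L, cut), ins, substr(amp, cut + 1L, nchar(amp)))
      }
    }
  })
  tmpl
}

#' Emit amplicon reads for a simulated sample
#'
#' Samples the configured genomic template mass from the population's allele
#' pool (2 alleles per cell, multinomially, honoring the per-timepoint cell
#' weights), then samples `depth` reads from the drawn genome equivalents,
#' applies per-base substitution errors, and writes a standard FASTQ with a
#' constant Phred quality consistent with the error rate. The truth read
#' counts per category always equal the emitted FASTQ record counts.
#'
#' @param population A [simulate_editing()] result.
#' @param cassette The designed [assemble_cassette()] the reads derive from.
#' @param fastq_path Output FASTQ path (`.gz` supported by extension).
#' @param weights Optional per-cell multiplicities (a column of
#'   [simulate_selection()]'s `weights`); default 1 per cell.
#' @param seed RNG seed for this emission (defaults to the config seed).
#' @param sample_id Read-name prefix.
#' @return A list: `fastq_path`, `truth` (tibble `category`, `reads`,
#'   `alleles_drawn`), `depth`.
#' @export
emit_reads <- function(population, cassette, fastq_path,
                       weights = NULL, seed = NULL,
                       sample_id = "sim") {
  cfg <- population$config
  cells <- population$cells
  seed <- seed %||% (cfg$seed + 2L)
  w <- weights %||% rep(1, nrow(cells))

  lv <- sim_allele_levels()
  key <- function(cat, len) ifelse(cat %in% c("FRAMESHIFT_INDEL",
                                              "INFRAME_INDEL"),
                                   paste0(cat, ":", len), cat)
  k1 <- key(cells$allele_1, cells$indel_len_1)
  k2 <- key(cells$allele_2, cells$indel_len_2)
  pool <- tapply(c(w, w), c(k1, k2), sum)
  pool_keys <- names(pool)
  pool <- as.numeric(pool)

  ge <- round(cfg$gdna_ng * 1000 / 6.0)
  depth <- cfg$depth
  if (depth == 0L) {
    warn("depth 0: writing empty FASTQ")
    writeLines(character(0), fastq_path)
    truth <- tibble(category = character(), reads = integer(),
                    alleles_drawn = integer())
    return(list(fastq_path = fastq_path, truth = truth, depth = 0L))
  }
  withr::with_seed(seed, {
    drawn <- as.numeric(rmultinom(1L, 2L * ge, prob = pool))
    present <- drawn > 0
    reads_per <- as.numeric(rmultinom(1L, depth, prob = drawn[present]))
    keys_present <- pool_keys[present]

    lens <- suppressWarnings(as.integer(sub("^.*:", "", keys_present)))
    lens[is.na(lens)] <- 0L
    tmpl <- sim_templates(cassette, lens, rng_seed = seed + 1L)

    phred <- if (cfg$error_rate > 0) {
      min(40L, round(-10 * log10(cfg$error_rate)))
    } else 40L
    qchar <- intToUtf8(33L + phred)

    all_seqs <- character(depth)
    all_cats <- character(depth)
    pos <- 0L
    for (i in seq_along(keys_present)) {
      nr <- reads_per[i]
      if (nr == 0L) next
      cat_i <- sub(":.*$", "", keys_present[i])
      tkey <- if (cat_i %in% c("FRAMESHIFT_INDEL", "INFRAME_INDEL")) {
        paste0("INDEL", lens[i])
      } else cat_i
      base_seq <- tmpl[[tkey]]
      sq <- rep(base_seq, nr)
      if (cfg$error_rate > 0) {
        L <- nchar(base_seq)
        nerr <- rbinom(nr, L, cfg$error_rate)
        for (r in which(nerr > 0L)) {
          p <- sample.int(L, nerr[r])
          s <- strsplit(sq[r], "", fixed = TRUE)[[1L]]
          s[p] <- vapply(s[p], function(b) {
            sample(setdiff(c("A", "C", "G", "T"), b), 1L)
          }, character(1))
          sq[r] <- paste(s, collapse = "")
        }
      }
      all_seqs[pos + seq_len(nr)] <- sq
      all_cats[pos + seq_len(nr)] <- cat_i
      pos <- pos + nr
    }
    ord <- sample.int(depth)          # shuffle so categories are interleaved
    all_seqs <- all_seqs[ord]
    all_cats <- all_cats[ord]

    lines <- character(4L * depth)
    lines[seq(1L, by = 4L, length.out = depth)] <-
      sprintf("@%s:%06d", sample_id, seq_len(depth))
    lines[seq(2L, by = 4L, length.out = depth)] <- all_seqs
    lines[seq(3L, by = 4L, length.out = depth)] <- "+"
    lines[seq(4L, by = 4L, length.out = depth)] <-
      strrep(qchar, nchar(all_seqs))
    con <- if (grepl("\\.gz$", fastq_path)) gzfile(fastq_path, "w")
      else file(fastq_path, "w")
    writeLines(lines, con, sep = "\n")
    close(con)

    truth <- tibble(category = lv) |>
      left_join(tibble(category = all_cats) |>
                  dplyr::count(.data$category, name = "reads"),
                by = "category") |>
      mutate(reads = ifelse(is.na(.data$reads), 0L, .data$reads))
    drawn_by_cat <- tapply(drawn, sub(":.*$", "", pool_keys), sum)
    truth$alleles_drawn <- as.numeric(drawn_by_cat[truth$category])
    truth$alleles_drawn[is.na(truth$alleles_drawn)] <- 0
  })
  list(fastq_path = fastq_path, truth = truth, depth = depth)
}

#' Simulate a complete multi-replicate selection experiment
#'
#' Convenience wrapper for the headline round trip: for each replicate,
#' simulates an independently edited population, applies selection across the
#' configured timepoints, and emits one FASTQ per (replicate, timepoint),
#' together with a ready-made sample sheet and the truth tables.
#'
#' @param cassette A designed [assemble_cassette()].
#' @param config A [sim_config()].
#' @param dir Output directory for FASTQ files.
#' @param n_replicates Number of independent replicates (default 3).
#' @return A list of class `sim_experiment`: `sample_sheet` (tibble
#'   `sample_id`, `replicate`, `point`, `fastq_path`, `gdna_ng`),
#'   `truth` (per replicate x point expected cell ratios and read counts),
#'   `config`.
#' @export
simulate_experiment <- function(cassette, config, dir, n_replicates = 3L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rep_seeds <- withr::with_seed(config$seed,
                                sample.int(2^30, n_replicates * 2L))
  sheets <- list(); truths <- list()
  for (r in seq_len(n_replicates)) {
    cfg_r <- config
    cfg_r$seed <- rep_seeds[2L * r - 1L]
    pop <- simulate_editing(cfg_r)
    tc <- simulate_selection(pop)
    for (j in seq_along(config$timepoints)) {
      pt <- config$timepoints[j]
      sid <- sprintf("rep%d_day%g", r, pt)
      fq <- file.path(dir, paste0(sid, ".fastq"))
      em <- emit_reads(pop, cassette, fq, weights = tc$weights[, j],
                       seed = rep_seeds[2L * r] + j, sample_id = sid)
      sheets[[length(sheets) + 1L]] <- tibble(
        sample_id = sid, replicate = r, point = pt, fastq_path = fq,
        gdna_ng = config$gdna_ng
      )
      truths[[length(truths) + 1L]] <- mutate(
        em$truth, sample_id = sid, replicate = r, point = pt,
        cell_ratio = tc$truth$cell_ratio[j], .before = 1L)
    }
  }
  structure(list(sample_sheet = bind_rows(sheets),
                 truth = bind_rows(truths), config = config),
            class = "sim_experiment")
}
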