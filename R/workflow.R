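#' Run the cassette design workflow
#'
#' File-level front end to [assemble_cassette()]: reads the locus FASTA and
#' annotation, designs the cassette, and writes the YAML bundle, oligo FASTA
#' and plain-text design report into `out_dir`. Re-running on the same inputs
#' produces byte-identical outputs (the designer is deterministic).
#'
#' @param locus_fasta,annotation_tsv Input locus files (see [read_locus()]).
#' @param variant A [variant_spec()], or a named list / YAML path with fields
#'   `position`, `ref`, `alt`, `label`, `variant_class`.
#' @param out_dir Output directory.
#' @param config A [cassette_config()].
#' @return The `cassette`, invisibly.
#' @export
run_design <- function(locus_fasta, annotation_tsv, variant, out_dir,
                       config = cassette_config()) {
  locus <- read_locus(locus_fasta, annotation_tsv)
  if (is.character(variant) && length(variant) == 1L && file.exists(variant)) {
    variant <- yaml::read_yaml(variant)
  }
  if (!inherits(variant, "variant_spec")) {
    variant <- variant_spec(variant$position, variant$ref, variant$alt,
                            variant$label %||% "variant",
                            variant$variant_class %||% "missense",
                            locus = locus)
  }
  cas <- assemble_cassette(locus, variant, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_cassette(cas,
                 path = file.path(out_dir, "cassette.yaml"),
                 fasta = file.path(out_dir, "oligos.fasta"),
                 report = file.path(out_dir, "design_report.txt"))
  invisible(cas)
}

#' Read a sample sheet
#'
#' TSV with columns `sample_id`, `replicate`, `point`, and optionally
#' `condition`, `fastq_path`, `gdna_ng`.
#'
#' @param path Sample sheet TSV path.
#' @return A tibble.
#' @export
read_sample_sheet <- function(path) {
  sheet <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("sample_id", "replicate", "point") %in% names(sheet)))
  sheet
}

#' Quantify all samples of a sample sheet
#'
#' @param sample_sheet Tibble (or TSV path) with `sample_id`, `fastq_path`
#'   and optionally `gdna_ng` (default 100 ng) plus metadata columns.
#' @param cassette A `cassette` or path to a cassette YAML bundle.
#' @param config A [classifier_config()].
#' @return Long tibble of per-sample editing profiles (see
#'   [bind_profiles()]).
#' @export
run_quantify <- function(sample_sheet, cassette,
                         config = classifier_config()) {
  if (is.character(sample_sheet)) sample_sheet <- read_sample_sheet(sample_sheet)
  if (is.character(cassette)) cassette <- read_cassette(cassette)
  missing_fq <- !file.exists(sample_sheet$fastq_path)
  if (any(missing_fq)) {
    abort(paste0("missing FASTQ for sample(s): ",
                 paste(sample_sheet$sample_id[missing_fq], collapse = ", ")))
  }
  gd <- sample_sheet$gdna_ng %||% rep(100, nrow(sample_sheet))
  profiles <- purrr::map(seq_len(nrow(sample_sheet)), function(i) {
    quantify_sample(sample_sheet$fastq_path[i], cassette, config,
                    gdna_ng = gd[i],
                    sample_id = sample_sheet$sample_id[i])
  })
  bind_profiles(profiles,
                sample_sheet[, setdiff(names(sample_sheet), "fastq_path")])
}

#' Run the selection analysis workflow
#'
#' Quantifies every sample on the sheet, computes variant:WT-prime ratios,
#' normalizes to the baseline point per replicate, and summarises selection
#' with the frameshift control verdict. When the sheet contains a `variant`
#' column (arrayed, multi-well mode), each variant is analysed independently
#' with identical arithmetic and `cassette` may be a named list/vector of
#' cassettes (or bundle paths) keyed by variant.
#'
#' @inheritParams run_quantify
#' @param baseline_point Value of `point` used as baseline.
#' @param out_dir Optional directory for TSV/JSON outputs.
#' @param alpha Significance threshold.
#' @return A tibble of selection results (one row per variant x point), with
#'   the per-variant `selection_result` objects in attribute `results`.
#' @export
run_select <- function(sample_sheet, cassette, baseline_point,
                       config = classifier_config(), out_dir = NULL,
                       alpha = 0.05) {
  if (is.character(sample_sheet) && length(sample_sheet) == 1L) {
    sample_sheet <- read_sample_sheet(sample_sheet)
  }
  has_variants <- "variant" %in% names(sample_sheet)
  groups <- if (has_variants) unique(sample_sheet$variant) else "all"
  results <- list()
  for (g in groups) {
    sheet_g <- if (has_variants) {
      sample_sheet[sample_sheet$variant == g, , drop = FALSE]
    } else sample_sheet
    cas_g <- if (has_variants && (is.list(cassette) || length(cassette) > 1L)) {
      cassette[[g]]
    } else cassette
    if (is.character(cas_g)) cas_g <- read_cassette(cas_g)
    long <- run_quantify(sheet_g, cas_g, config)
    ratios <- compute_ratios(long)
    norm <- normalize_to_baseline(ratios, baseline_point)
    results[[as.character(g)]] <- summarise_selection(norm, alpha = alpha)
  }
  out <- bind_rows(lapply(names(results), function(g) {
    mutate(as_tibble(results[[g]]), variant = g, .before = 1L)
  }))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(out, file.path(out_dir, "selection_results.tsv"))
    jsonlite::write_json(out, file.path(out_dir, "selection_results.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  attr(out, "results") <- results
  out
}

#' Run the simulator workflow
#'
#' @param cassette A `cassette` or bundle path.
#' @param config A [sim_config()] or path to a YAML file of its fields
#'   (must include `seed`).
#' @param out_dir Output directory for FASTQ, truth table and sample sheet.
#' @param n_replicates Replicates to simulate.
#' @return The `sim_experiment`, invisibly.
#' @export
run_simulate <- function(cassette, config, out_dir, n_replicates = 3L) {
  if (is.character(cassette)) cassette <- read_cassette(cassette)
  if (is.character(config)) {
    cfg <- yaml::read_yaml(config)
    if (!is.null(cfg$outcome_probs)) cfg$outcome_probs <- unlist(cfg$outcome_probs)
    if (!is.null(cfg$fitness)) cfg$fitness <- unlist(cfg$fitness)
    if (!is.null(cfg$timepoints)) cfg$timepoints <- unlist(cfg$timepoints)
    config <- do.call(sim_config, cfg)
  }
  ex <- simulate_experiment(cassette, config, out_dir,
                            n_replicates = n_replicates)
  readr::write_tsv(ex$sample_sheet, file.path(out_dir, "sample_sheet.tsv"))
  readr::write_tsv(ex$truth, file.path(out_dir, "truth.tsv"))
  jsonlite::write_json(list(seed = config$seed),
                       file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE)
  invisible(ex)
}

#' Run the zygosity workflow
#'
#' @param genotypes_tsv TSV of per-cell allele calls (see [read_genotypes()]).
#' @param out_dir Optional output directory.
#' @param target Conditioning category for [loh_assessment()].
#' @return List with `table` ([tabulate_zygosity()]) and `loh`
#'   ([loh_assessment()]).
#' @export
run_zygosity <- function(genotypes_tsv, out_dir = NULL,
                         target = "VARIANT_KI") {
  g <- read_genotypes(genotypes_tsv)
  tab <- tabulate_zygosity(g)
  loh <- loh_assessment(tab, target = target)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_zygosity(tab, file.path(out_dir, "zygosity_pairs.tsv"),
                   file.path(out_dir, "zygosity_conditional.tsv"))
  }
  list(table = tab, loh = loh)
}
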