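#' Compute variant:WT-prime and frameshift:WT-prime ratios per sample
#'
#' The selection readout is the ratio of variant knock-in reads to WT-prime
#' knock-in reads within a sample; the frameshift:WT-prime ratio serves as
#' the internal knock-out control. A 95% confidence interval on each ratio is
#' derived from a log-ratio normal approximation on the two counts
#' (`se = sqrt(1/a + 1/b)`), with a half-count correction applied for the CI
#' when either count is zero. Ratios with zero WT-prime reads are flagged
#' undefined (`NA`), never silent infinities.
#'
#' @param data A tibble in long format with columns `sample_id`, `category`,
#'   `reads`, plus any metadata columns (e.g. `replicate`, `point`,
#'   `condition`), such as produced by [bind_profiles()]. A single
#'   `editing_profile` is also accepted.
#' @param conf_level Confidence level for the ratio CI (default 0.95).
#' @return A tibble with one row per sample: metadata columns,
#'   `variant_reads`, `wtprime_reads`, `frameshift_reads`,
#'   `ratio` (variant:WT-prime), `ratio_lo`, `ratio_hi`,
#'   `ratio_frameshift`, `ratio_undefined`.
#' @export
compute_ratios <- function(data, conf_level = 0.95) {
  if (inherits(data, "editing_profile")) {
    data <- bind_profiles(list(data))
  }
  stopifnot(all(c("sample_id", "category", "reads") %in% names(data)))
  meta_cols <- setdiff(names(data), c("category", "reads", "frequency",
                                      "cells"))
  z <- qnorm(1 - (1 - conf_level) / 2)
  wide <- data |>
    filter(.data$category %in% c("VARIANT_KI", "WTPRIME_KI",
                                 "FRAMESHIFT_INDEL")) |>
    select(dplyr::all_of(c(meta_cols, "category", "reads"))) |>
    tidyr::pivot_wider(names_from = "category", values_from = "reads",
                       values_fill = 0L)
  for (cn in c("VARIANT_KI", "WTPRIME_KI", "FRAMESHIFT_INDEL")) {
    if (!cn %in% names(wide)) wide[[cn]] <- 0L
  }
  wide |>
    rename(variant_reads = "VARIANT_KI", wtprime_reads = "WTPRIME_KI",
           frameshift_reads = "FRAMESHIFT_INDEL") |>
    mutate(
      ratio_undefined = .data$wtprime_reads == 0L,
      ratio = ifelse(.data$ratio_undefined, NA_real_,
                     .data$variant_reads / .data$wtprime_reads),
      log_se = sqrt(1 / (.data$variant_reads + 0.5 * (.data$variant_reads == 0)) +
                      1 / (.data$wtprime_reads + 0.5 * (.data$wtprime_reads == 0))),
      ratio_lo = ifelse(.data$ratio_undefined | .data$variant_reads == 0,
                        NA_real_, exp(log(.data$ratio) - z * .data$log_se)),
      ratio_hi = ifelse(.data$ratio_undefined | .data$variant_reads == 0,
                        NA_real_, exp(log(.data$ratio) + z * .data$log_se)),
      ratio_frameshift = ifelse(.data$ratio_undefined, NA_real_,
                                .data$frameshift_reads / .data$wtprime_reads)
    ) |>
    select(-"log_se")
}

#' Combine editing profiles into a long table
#'
#' @param profiles List of `editing_profile` objects.
#' @param sample_sheet Optional tibble with a `sample_id` column plus
#'   metadata (`replicate`, `point`, `condition`, ...) joined onto the
#'   profiles.
#' @return Long tibble: `sample_id`, metadata, `category`, `reads`,
#'   `frequency`, `cells`.
#' @export
bind_profiles <- function(profiles, sample_sheet = NULL) {
  long <- bind_rows(lapply(profiles, function(p) {
    mutate(as_tibble(p), sample_id = attr(p, "sample_id"), .before = 1L)
  }))
  if (!is.null(sample_sheet)) {
    long <- left_join(long, as_tibble(sample_sheet), by = "sample_id")
    front <- c("sample_id", setdiff(names(sample_sheet), "sample_id"))
    long <- select(long, dplyr::all_of(front), dplyr::everything())
  }
  long
}

#' Normalize ratios to a baseline assay point
#'
#' The assay measures the *relative change* in the variant:WT-prime ratio
#' between a baseline point (typically day 2, when knock-in is complete but
#' selection has not yet acted) and later points -- which makes the readout
#' invariant to the initial variant:WT-prime stoichiometry. Per replicate,
#' every point's ratio is divided by that replicate's baseline ratio, so the
#' baseline maps to exactly 1; the frameshift control ratio is normalized the
#' same way. Replicates lacking a baseline sample are excluded with a
#' warning.
#'
#' @param ratios Output of [compute_ratios()] with `replicate` and `point`
#'   columns.
#' @param baseline_point Value of `point` identifying the baseline.
#' @param point_col,replicate_col Column names (defaults `"point"`,
#'   `"replicate"`).
#' @return A `selection_norm` tibble: per replicate x point, `fold`
#'   (normalized variant:WT-prime fold change) and `fold_frameshift`.
#' @export
normalize_to_baseline <- function(ratios, baseline_point,
                                  point_col = "point",
                                  replicate_col = "replicate") {
  stopifnot(all(c(point_col, replicate_col) %in% names(ratios)))
  r <- ratios
  r$.point <- r[[point_col]]
  r$.rep <- r[[replicate_col]]
  base <- r[r$.point == baseline_point, c(".rep", "ratio", "ratio_frameshift")]
  names(base) <- c(".rep", ".base_ratio", ".base_fs")
  missing_reps <- setdiff(unique(r$.rep), base$.rep)
  if (length(missing_reps)) {
    warn(sprintf("replicate(s) without baseline excluded: %s",
                 paste(missing_reps, collapse = ", ")))
    r <- r[!(r$.rep %in% missing_reps), , drop = FALSE]
  }
  out <- left_join(r, base, by = ".rep") |>
    mutate(fold = .data$ratio / .data$.base_ratio,
           fold_frameshift = .data$ratio_frameshift / .data$.base_fs) |>
    select(-".point", -".rep", -".base_ratio", -".base_fs")
  structure(out, baseline_point = baseline_point,
            point_col = point_col, replicate_col = replicate_col,
            class = c("selection_norm", class(tibble())))
}

#' Summarise normalized fold changes into a selection result
#'
#' Aggregates per-replicate normalized fold changes at each non-baseline
#' point (mean, s.d., n), tests the variant fold against no change (paired
#' t-test of per-replicate later vs baseline values, equivalently a
#' one-sample t-test of the normalized folds against 1), applies the same to
#' the frameshift control, and assigns a verdict:
#' * `depleted` / `enriched` -- variant fold beyond the neutral band;
#' * `validated_neutral` -- variant fold inside the neutral band while the
#'   frameshift control shows the expected depletion (the guard against a
#'   false-negative assay without selection pressure);
#' * `inconclusive` -- variant fold neutral but the control is too.
#'
#' @param norm A `selection_norm` from [normalize_to_baseline()].
#' @param alpha Significance threshold (default 0.05).
#' @param neutral_band Variant folds within this interval count as "no
#'   effect" (default `c(2/3, 1.5)`).
#' @param control_threshold The frameshift control validates neutrality when
#'   its mean fold is at or below this (default 2/3).
#' @param scale Test scale: `"linear"` (the plotted quantity) or `"log"`
#'   (recommended for strongly skewed folds).
#' @return A `selection_result` tibble: one row per non-baseline point with
#'   `fold_mean`, `fold_sd`, `n`, `t`, `p_value`, `significant`,
#'   `control_fold_mean`, `control_fold_sd`, `control_p_value`, `verdict`.
#' @export
summarise_selection <- function(norm, alpha = 0.05,
                                neutral_band = c(2 / 3, 1.5),
                                control_threshold = 2 / 3,
                                scale = c("linear", "log")) {
  scale <- match.arg(scale)
  point_col <- attr(norm, "point_col")
  baseline <- attr(norm, "baseline_point")
  pts <- setdiff(unique(norm[[point_col]]), baseline)
  rows <- purrr::map(pts, function(p) {
    x <- norm$fold[norm[[point_col]] == p]
    fs <- norm$fold_frameshift[norm[[point_col]] == p]
    x <- x[!is.na(x)]
    tt <- one_sample_fold_test(x, scale)
    ct <- one_sample_fold_test(fs[!is.na(fs)], scale)
    fold_mean <- mean(x)
    verdict <- if (fold_mean < neutral_band[1L]) "depleted"
      else if (fold_mean > neutral_band[2L]) "enriched"
      else if (length(fs) && mean(fs, na.rm = TRUE) <= control_threshold)
        "validated_neutral"
      else "inconclusive"
    tibble(
      point = p, fold_mean = fold_mean, fold_sd = sd(x), n = length(x),
      t = tt$statistic, p_value = tt$p_value,
      significant = !is.na(tt$p_value) & tt$p_value <= alpha,
      control_fold_mean = mean(fs, na.rm = TRUE),
      control_fold_sd = sd(fs[!is.na(fs)]),
      control_p_value = ct$p_value,
      verdict = verdict
    )
  })
  out <- bind_rows(rows)
  names(out)[names(out) == "point"] <- point_col
  structure(out, baseline_point = baseline, alpha = alpha, scale = scale,
            norm = norm,
            class = c("selection_result", class(tibble())))
}

one_sample_fold_test <- function(x, scale = "linear") {
  if (length(x) < 2L || sd(x) == 0) {
    return(list(statistic = if (length(x) && sd(x) == 0 &&
                                isTRUE(all.equal(mean(x), 1))) 0 else NA_real_,
                p_value = NA_real_))
  }
  y <- if (scale == "log") log(x) else x
  mu <- if (scale == "log") 0 else 1
  tt <- t.test(y, mu = mu)
  list(statistic = unname(tt$statistic), p_value = tt$p.value)
}

#' Two-tailed paired t-test between conditions
#'
#' Paired, two-tailed t-test on per-replicate values from two matched
#' conditions (e.g. two assay points, two FACS states or two compartments).
#'
#' @param a,b Equal-length numeric vectors, paired by replicate; `n >= 2`.
#' @param alpha Significance threshold (default 0.05).
#' @return Tibble: `statistic`, `df`, `p_value`, `significant`,
#'   `mean_difference`, `zero_variance` (when all differences are equal the
#'   p-value is undefined and flagged).
#' @export
paired_test <- function(a, b, alpha = 0.05) {
  if (length(a) != length(b)) abort("paired vectors must have equal length")
  if (length(a) < 2L) abort("paired t-test needs at least 2 replicates")
  d <- a - b
  if (sd(d) == 0) {
    return(tibble(statistic = if (all(d == 0)) 0 else NA_real_,
                  df = length(a) - 1L, p_value = NA_real_,
                  significant = NA, mean_difference = mean(d),
                  zero_variance = TRUE))
  }
  tt <- t.test(a, b, paired = TRUE)
  tibble(statistic = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, significant = tt$p.value <= alpha,
         mean_difference = mean(d), zero_variance = FALSE)
}

#' Frameshift InDel control assessment
#'
#' Applies the baseline normalization to the frameshift:WT-prime control
#' ratio and combines it with the variant verdict. A variant that appears
#' neutral is only "validated neutral" when the frameshift knock-out control
#' shows the depletion expected under selection pressure; if the control is
#' also flat, the assay had no selection pressure and the result is
#' inconclusive. A clearly depleted or enriched variant verdict stands on its
#' own.
#'
#' @inheritParams summarise_selection
#' @return The `selection_result` from [summarise_selection()] (the verdict
#'   column implements the control logic).
#' @export
frameshift_control <- function(norm, alpha = 0.05,
                               neutral_band = c(2 / 3, 1.5),
                               control_threshold = 2 / 3) {
  summarise_selection(norm, alpha = alpha, neutral_band = neutral_band,
                      control_threshold = control_threshold)
}

#' Normalize condition means to a reference condition
#'
#' Post-normalization mode for drug/vehicle style comparisons: expresses each
#' condition's normalized fold as a percentage of the reference condition's
#' mean (reference set to 100%).
#'
#' @param norm A `selection_norm` with a `condition` column.
#' @param reference Value of `condition` to set to 100%.
#' @param condition_col Name of the condition column (default `"condition"`).
#' @return The input with an added `percent_of_reference` column.
#' @export
normalize_to_condition <- function(norm, reference,
                                   condition_col = "condition") {
  stopifnot(condition_col %in% names(norm))
  ref_mean <- mean(norm$fold[norm[[condition_col]] == reference], na.rm = TRUE)
  norm$percent_of_reference <- 100 * norm$fold / ref_mean
  norm
}

#' @rdname tidy-crisprselect
#' @export
tidy.selection_result <- function(x, ...) {
  as_tibble(x)
}

#' @rdname tidy-crisprselect
#' @export
glance.selection_result <- function(x, ...) {
  last <- x[nrow(x), , drop = FALSE]
  tibble(fold = last$fold_mean, p_value = last$p_value,
         verdict = last$verdict, n = last$n,
         baseline_point = attr(x, "baseline_point"),
         alpha = attr(x, "alpha"))
}
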