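#' Recommend sequencing depth for a target knock-in frequency and effect size
#'
#' Guideline-style power calculation for the two-point selection readout. The
#' estimated log fold change `log((v2/w2)/(v1/w1))` of four approximately
#' Poisson read counts has variance close to the sum of reciprocal expected
#' counts; with baseline variant and WT-prime frequencies both `ki_frequency`
#' and the later-point variant frequency scaled by `effect_size`, that is
#' `(3 + 1/effect_size) / (depth * ki_frequency)` per replicate. The
#' recommended depth makes a two-sided normal-approximation test of the fold
#' change against 1 attain the requested power:
#' `depth = (z_alpha/2 + z_power)^2 * (3 + 1/f) / (n * ki * log(f)^2)`.
#' The companion Monte-Carlo check (see the test suite) simulates the full
#' count experiment at the recommended depth.
#'
#' @param ki_frequency Baseline knock-in frequency of each template (0-1,
#'   exclusive). Typical assays run at 0.02-0.10.
#' @param effect_size True fold change of the variant:WT-prime ratio between
#'   the points (e.g. 0.2 for a 5-fold depletion); must be positive and not 1.
#' @param alpha Two-sided significance level (default 0.05).
#' @param power Target power (default 0.9).
#' @param n_replicates Biological replicates (default 3).
#' @param gdna_ng Template mass per PCR, used to report the tracked clone
#'   count (default 100 ng).
#' @param pg_per_diploid_genome Mass per diploid genome (default 6.0 pg).
#' @param max_depth Depths above this are reported infeasible (default 1e7).
#' @return A `depth_recommendation` tibble: assumptions, `recommended_reads`
#'   (per sample, rounded up to the nearest 1000), `clone_count` (genome
#'   equivalents x frequency for the given template mass), `feasible`.
#' @examples
#' recommend_depth(0.02, 0.2)
#' @export
recommend_depth <- function(ki_frequency, effect_size, alpha = 0.05,
                            power = 0.9, n_replicates = 3L, gdna_ng = 100,
                            pg_per_diploid_genome = 6.0, max_depth = 1e7) {
  if (ki_frequency <= 0 || ki_frequency >= 1) {
    abort("ki_frequency must be in (0, 1)")
  }
  if (effect_size <= 0) abort("effect_size must be positive")
  if (effect_size == 1) abort("effect_size 1 means no effect to detect")
  if (n_replicates < 1L) abort("n_replicates must be >= 1")
  z <- qnorm(1 - alpha / 2) + qnorm(power)
  var_unit <- (3 + 1 / effect_size) / ki_frequency
  depth_raw <- z^2 * var_unit / (n_replicates * log(effect_size)^2)
  feasible <- depth_raw <= max_depth
  recommended <- if (feasible) ceiling(depth_raw / 1000) * 1000 else NA_real_
  ge <- estimate_absolute_cells(gdna_ng, ki_frequency,
                                pg_per_diploid_genome)
  structure(
    tibble(
      ki_frequency = ki_frequency, effect_size = effect_size,
      alpha = alpha, power = power, n_replicates = as.integer(n_replicates),
      depth_exact = depth_raw,
      recommended_reads = recommended,
      clone_count = ge$cells,
      feasible = feasible
    ),
    class = c("depth_recommendation", class(tibble()))
  )
}

#' Monte-Carlo power of the selection test at a given depth
#'
#' Simulates the four-count experiment (`n_sim` times) at a fixed read depth
#' and returns the fraction of simulations in which the normal-approximation
#' z-test on the pooled log fold change rejects no-change. Used to
#' cross-check [recommend_depth()].
#'
#' @param depth Reads per sample per point.
#' @inheritParams recommend_depth
#' @param n_sim Number of simulated experiments (default 2000).
#' @param seed RNG seed (required; the simulation is fully reproducible).
#' @return Estimated power (fraction of rejections).
#' @export
simulate_depth_power <- function(depth, ki_frequency, effect_size,
                                 alpha = 0.05, n_replicates = 3L,
                                 n_sim = 2000L, seed) {
  if (missing(seed)) abort("seed is required")
  z_crit <- qnorm(1 - alpha / 2)
  withr::with_seed(seed, {
    rej <- vapply(seq_len(n_sim), function(i) {
      lf <- vapply(seq_len(n_replicates), function(r) {
        v1 <- rbinom(1L, depth, ki_frequency)
        w1 <- rbinom(1L, depth, ki_frequency)
        v2 <- rbinom(1L, depth, ki_frequency * effect_size)
        w2 <- rbinom(1L, depth, ki_frequency)
        log(((v2 + 0.5) / (w2 + 0.5)) / ((v1 + 0.5) / (w1 + 0.5)))
      }, numeric(1))
      se <- sqrt((3 + 1 / effect_size) /
                   (depth * ki_frequency * n_replicates))
      abs(mean(lf)) / se >= z_crit
    }, logical(1))
    mean(rej)
  })
}
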