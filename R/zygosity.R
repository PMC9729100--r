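#' Tabulate biallelic editing outcomes across single cells
#'
#' Builds the single-cell zygosity table: counts of unordered allele-category
#' pairs, and for each conditioning category the distribution of the *other*
#' allele among cells carrying it -- the quantity behind the assay's
#' "built-in loss of heterozygosity": most cells with a knock-in on one
#' allele carry a disruptive edit on the other.
#'
#' Homozygous cells are counted once in the conditioning set, with the other
#' allele equal to the same category.
#'
#' @param genotypes Tibble with columns `cell_id`, `allele_1`, `allele_2`
#'   (allele categories; arbitrary labels are kept, standard ones come from
#'   [allele_categories()]). Allele order within a cell carries no meaning.
#' @return A list of class `zygosity_table`: `pairs` (tibble `allele_a`,
#'   `allele_b`, `cells` over unordered pairs), `conditional` (tibble
#'   `given`, `other`, `cells`, `fraction`; fractions sum to 1 within each
#'   `given`), `n_cells`.
#' @export
tabulate_zygosity <- function(genotypes) {
  g <- as_tibble(genotypes)
  stopifnot(all(c("allele_1", "allele_2") %in% names(g)))
  if (!nrow(g)) abort("no genotypes supplied")
  a <- pmin(g$allele_1, g$allele_2)
  b <- pmax(g$allele_1, g$allele_2)
  pairs <- tibble(allele_a = a, allele_b = b) |>
    dplyr::count(.data$allele_a, .data$allele_b, name = "cells")

  cats <- sort(unique(c(g$allele_1, g$allele_2)))
  conditional <- bind_rows(lapply(cats, function(target) {
    has <- g$allele_1 == target | g$allele_2 == target
    if (!any(has)) return(NULL)
    other <- ifelse(g$allele_1[has] == target, g$allele_2[has],
                    g$allele_1[has])
    tibble(given = target, other = other) |>
      dplyr::count(.data$given, .data$other, name = "cells") |>
      mutate(fraction = .data$cells / sum(.data$cells))
  }))
  structure(list(pairs = pairs, conditional = conditional, n_cells = nrow(g)),
            class = "zygosity_table")
}

#' @export
print.zygosity_table <- function(x, ...) {
  cat("<zygosity_table> ", x$n_cells, " cells, ", nrow(x$pairs),
      " distinct unordered genotype pair(s)\n", sep = "")
  print(x$conditional)
  invisible(x)
}

#' @rdname tidy-crisprselect
#' @export
tidy.zygosity_table <- function(x, ...) x$conditional

#' Assess built-in loss of heterozygosity
#'
#' Among cells carrying the target knock-in on one allele, sums the
#' conditional probability that the other allele carries a gene-disrupting
#' outcome: a frameshift InDel, the same knock-in again (biallelic variant),
#' or -- when configured -- an in-frame InDel (in-frame InDels at the target
#' codon typically destroy the assayed residue). The per-component breakdown
#' is reported alongside the total.
#'
#' @param table A [tabulate_zygosity()] result.
#' @param target Conditioning category (default `"VARIANT_KI"`).
#' @param disruptive Categories of the other allele counted as gene loss.
#' @return A list: `fraction_loss` (total conditional mass on disruptive
#'   outcomes; `NA` with a flag if no cell carries the target), `breakdown`
#'   (tibble `other`, `cells`, `fraction`), `n_conditioning_cells`.
#' @export
loh_assessment <- function(table, target = "VARIANT_KI",
                           disruptive = c("FRAMESHIFT_INDEL", "VARIANT_KI",
                                          "INFRAME_INDEL")) {
  stopifnot(inherits(table, "zygosity_table"))
  cond <- table$conditional[table$conditional$given == target, , drop = FALSE]
  if (!nrow(cond)) {
    return(list(fraction_loss = NA_real_, undefined = TRUE,
                breakdown = cond[, c("other", "cells", "fraction")],
                n_conditioning_cells = 0L))
  }
  hit <- cond[cond$other %in% disruptive, c("other", "cells", "fraction")]
  list(fraction_loss = sum(hit$fraction), undefined = FALSE,
       breakdown = hit, n_conditioning_cells = sum(cond$cells))
}

#' Read / write single-cell genotype tables
#'
#' @param path TSV with columns `cell_id`, `allele_1`, `allele_2`.
#' @return A tibble.
#' @export
read_genotypes <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                  progress = FALSE)
}

#' @rdname read_genotypes
#' @param table A [tabulate_zygosity()] result to write.
#' @param pairs_path,conditional_path Output TSV paths.
#' @export
write_zygosity <- function(table, pairs_path, conditional_path) {
  readr::write_tsv(table$pairs, pairs_path)
  readr::write_tsv(table$conditional, conditional_path)
  invisible(table)
}
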