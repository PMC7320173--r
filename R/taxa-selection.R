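#' Select prevalent species from metagenome abundance tables
#'
#' Applies the species-selection stage of network construction: a species is
#' retained when it is detected at a relative abundance of at least
#' `abundance_min` (default 0.001%) in at least a fraction `prevalence_min`
#' (default 90%) of the samples. When the table carries a `study` column and
#' `per_study = TRUE`, the rule is applied within each study and a species
#' qualifies if it passes in any study (each study contributes its own
#' list). Both thresholds are inclusive.
#'
#' @param ab a relative-mode, species-rank [abundance_table()].
#' @param prevalence_min minimum fraction of samples, in `(0, 1]`.
#' @param abundance_min detection threshold on relative abundance, in
#'   `(0, 1)`.
#' @param per_study apply the rule within studies when a study column is
#'   present.
#' @return A tibble with columns `taxon`, `prevalence` (the best per-study
#'   prevalence) and `mean_abundance`, containing only selected species,
#'   sorted by descending prevalence then name.
#' @section Errors: `gutnet_rank_error` if the table is not species-rank.
#' @export
select_prevalent_species <- function(ab, prevalence_min = 0.90,
                                     abundance_min = 1e-5,
                                     per_study = TRUE) {
  stopifnot(prevalence_min > 0, prevalence_min <= 1,
            abundance_min > 0, abundance_min < 1)
  if (!inherits(ab, "abundance_tbl") || ab_rank(ab) != "species") {
    stop_gutnet("gutnet_rank_error",
                "species selection needs a species-rank abundance table")
  }
  x <- as_tibble(ab)
  if (!per_study || all(is.na(x$study))) x$study <- "all"
  per <- summarise(
    group_by(x, .data$study, .data$taxon),
    prevalence = mean(.data$abundance >= abundance_min),
    .groups = "drop")
  best <- summarise(group_by(per, .data$taxon),
                    prevalence = max(.data$prevalence), .groups = "drop")
  mean_ab <- summarise(group_by(x, .data$taxon),
                       mean_abundance = mean(.data$abundance),
                       .groups = "drop")
  out <- filter(left_join(best, mean_ab, by = "taxon"),
                .data$prevalence >= prevalence_min)
  arrange(out, dplyr::desc(.data$prevalence), .data$taxon)
}

#' Genus-level coverage of a selected species set
#'
#' Measures how much of each sample's total microbial abundance is accounted
#' for by the genera of the selected species: per sample, the summed
#' relative abundance of all species whose genus occurs among the selected
#' species' genera, divided by the sample's total microbial abundance.
#'
#' @param ab a species-rank [abundance_table()].
#' @param selected character vector of selected species names (or the tibble
#'   returned by [select_prevalent_species()]).
#' @param genus_map optional named character vector mapping species names to
#'   genus names; by default the genus is the first word of the binomial
#'   name.
#' @return A list with `mean` and `sd` (across samples, `n - 1`
#'   denominator) and `per_sample`, a tibble of per-sample coverage
#'   fractions in `[0, 1]`.
#' @section Errors: `gutnet_empty_selection_error` on an empty selection.
#' @export
genus_coverage <- function(ab, selected, genus_map = NULL) {
  if (is.data.frame(selected)) selected <- selected$taxon
  if (length(selected) == 0L) {
    stop_gutnet("gutnet_empty_selection_error",
                "cannot compute coverage of an empty selection")
  }
  x <- as_tibble(ab)
  genus_of <- function(taxa) {
    g <- name_genus(taxa)
    if (!is.null(genus_map)) {
      hit <- taxa %in% names(genus_map)
      g[hit] <- unname(genus_map[taxa[hit]])
    }
    g
  }
  sel_genera <- unique(genus_of(selected))
  x$covered <- genus_of(x$taxon) %in% sel_genera
  per_sample <- summarise(
    group_by(x, .data$sample_id),
    fraction = sum(.data$abundance[.data$covered]) / sum(.data$abundance),
    .groups = "drop")
  list(mean = mean(per_sample$fraction),
       sd = sd(per_sample$fraction),
       per_sample = per_sample)
}
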