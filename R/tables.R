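#' Build an abundance table from a long data frame
#'
#' An `abundance_tbl` is a long tibble of taxon abundances per sample —
#' columns `sample_id`, `group`, optionally `study`, `taxon`, `abundance` —
#' tagged with the taxonomic rank of its taxa and an abundance mode
#' (`"relative"` fractions in `[0, 1]`, or `"absolute"` levels such as 16S
#' rRNA gene copies). Relative tables must have per-sample totals of at most
#' 1 (up to rounding).
#'
#' @param x data frame with columns `sample_id`, `group`, `taxon`,
#'   `abundance` and optionally `study`.
#' @param rank taxonomic rank of the taxa, `"species"` or `"genus"`.
#' @param mode `"relative"` or `"absolute"`.
#' @return A tibble of class `abundance_tbl` with attributes `rank`, `mode`
#'   and `group_levels` (groups in order of first appearance).
#' @export
abundance_table <- function(x, rank = c("species", "genus"),
                            mode = c("relative", "absolute")) {
  rank <- match.arg(rank)
  mode <- match.arg(mode)
  x <- as_tibble(x)
  need <- c("sample_id", "group", "taxon", "abundance")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop_gutnet("gutnet_parse_error",
                sprintf("abundance table missing column(s): %s",
                        paste(miss, collapse = ", ")))
  }
  if (!"study" %in% names(x)) x$study <- NA_character_
  x <- select(x, all_of(c("sample_id", "group", "study", "taxon",
                          "abundance")))
  if (any(x$abundance < 0, na.rm = TRUE)) {
    stop_gutnet("gutnet_negative_value_error",
                "abundance table contains negative values")
  }
  if (mode == "relative") {
    sums <- tapply(x$abundance, x$sample_id, sum)
    if (any(sums > 1 + 1e-6)) {
      stop_gutnet("gutnet_parse_error",
                  sprintf("relative abundances must sum to <= 1 per sample (max observed %.4g)",
                          max(sums)))
    }
  }
  structure(x, class = c("abundance_tbl", class(tibble())),
            rank = rank, mode = mode,
            group_levels = unique(x$group))
}

#' Read a samples-by-taxa abundance TSV
#'
#' Expects a wide TSV as emitted by taxonomic profilers: one row per sample,
#' a `sample_id` column, a group-label column, optionally a study column,
#' and one column per taxon. Percent-scaled relative tables (row sums near
#' 100) are detected and rescaled to fractions with a message.
#'
#' @param path TSV path.
#' @inheritParams abundance_table
#' @param group_col,study_col names of the group and (optional) study
#'   columns.
#' @return An [abundance_table()].
#' @section Errors: `gutnet_parse_error` with the offending line;
#'   `gutnet_negative_value_error` on negative abundances.
#' @export
read_abundance_table <- function(path, rank = c("species", "genus"),
                                 mode = c("relative", "absolute"),
                                 group_col = "group", study_col = NULL) {
  rank <- match.arg(rank)
  mode <- match.arg(mode)
  wide <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  prob <- readr::problems(wide)
  if (nrow(prob)) {
    stop_gutnet("gutnet_parse_error",
                sprintf("malformed TSV at line %d: %s", prob$row[1] + 1L,
                        prob$expected[1]))
  }
  id_col <- names(wide)[1]
  meta_cols <- c(id_col, group_col, study_col)
  taxa_cols <- setdiff(names(wide), meta_cols)
  long <- tidyr::pivot_longer(wide, all_of(taxa_cols), names_to = "taxon",
                              values_to = "abundance")
  long <- rename(long, sample_id = all_of(id_col), group = all_of(group_col))
  if (!is.null(study_col)) long <- rename(long, study = all_of(study_col))
  if (any(long$abundance < 0, na.rm = TRUE)) {
    stop_gutnet("gutnet_negative_value_error",
                "abundance table contains negative values")
  }
  if (mode == "relative") {
    sums <- tapply(long$abundance, long$sample_id, sum)
    if (stats::median(sums) > 50 && stats::median(sums) < 150) {
      inform("row sums near 100: interpreting abundances as percentages and rescaling to fractions")
      long$abundance <- long$abundance / 100
    }
  }
  abundance_table(long, rank = rank, mode = mode)
}

#' Build a metabolite concentration table
#'
#' A `metabolite_tbl` is a long tibble of replicate-resolved metabolite
#' concentrations per experimental group — columns `group`, `replicate`,
#' `metabolite`, `concentration` — plus a per-metabolite
#' `host_or_diet_derived` flag marking metabolites whose levels are driven
#' by the host or the diet rather than by microbial metabolism (these are
#' excluded from concordance analyses).
#'
#' @param x data frame with columns `group`, `replicate`, `metabolite`,
#'   `concentration` and optionally `host_or_diet_derived`.
#' @param units free-text concentration units.
#' @return A tibble of class `metabolite_tbl` with attributes `units` and
#'   `group_levels`.
#' @export
metabolite_table <- function(x, units = "arbitrary") {
  x <- as_tibble(x)
  need <- c("group", "replicate", "metabolite", "concentration")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop_gutnet("gutnet_parse_error",
                sprintf("metabolite table missing column(s): %s",
                        paste(miss, collapse = ", ")))
  }
  if (!"host_or_diet_derived" %in% names(x)) {
    x$host_or_diet_derived <- FALSE
  }
  x$host_or_diet_derived <- as.logical(x$host_or_diet_derived)
  # the flag is a per-metabolite property; make it consistent
  flag <- tapply(x$host_or_diet_derived, x$metabolite, any)
  x$host_or_diet_derived <- unname(flag[x$metabolite])
  if (any(x$concentration < 0, na.rm = TRUE)) {
    stop_gutnet("gutnet_negative_value_error",
                "metabolite table contains negative concentrations")
  }
  grid <- table(x$group, x$metabolite)
  if (any(grid == 0L)) {
    stop_gutnet("gutnet_parse_error",
                "every (group, metabolite) pair needs at least one replicate")
  }
  x <- select(x, all_of(c("group", "replicate", "metabolite",
                          "concentration", "host_or_diet_derived")))
  structure(x, class = c("metabolite_tbl", class(tibble())),
            units = units, group_levels = unique(x$group))
}

#' Read a replicate-resolved metabolite TSV
#'
#' Expects a long TSV with columns `group`, `replicate`, `metabolite`,
#' `concentration` and optionally `host_or_diet_derived` (logical or 0/1).
#'
#' @param path TSV path.
#' @param units free-text concentration units.
#' @return A [metabolite_table()].
#' @export
read_metabolite_table <- function(path, units = "arbitrary") {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  prob <- readr::problems(x)
  if (nrow(prob)) {
    stop_gutnet("gutnet_parse_error",
                sprintf("malformed TSV at line %d: %s", prob$row[1] + 1L,
                        prob$expected[1]))
  }
  metabolite_table(x, units = units)
}

ab_rank <- function(ab) attr(ab, "rank")
ab_mode <- function(ab) attr(ab, "mode")
tbl_groups <- function(x) attr(x, "group_levels")
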