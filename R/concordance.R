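#' Map a metabolite to its microbial producers or consumers
#'
#' At species rank, the producers of a metabolite are the members of the
#' candidate pool with a positive export association for it (consumers use
#' import links). At genus rank — the finest rank many 16S studies resolve —
#' a genus from the pool is a producer when a strict majority (> 50%) of
#' that genus's species in the network export the metabolite. Degradation
#' products are propagated first by default, so degraders of a macromolecule
#' count as producers of its products.
#'
#' @param net a valid [gut_network()].
#' @param metabolite small-molecule compound name.
#' @param rank `"species"` or `"genus"`.
#' @param candidate_pool character vector of taxon names observed in the
#'   study at that rank.
#' @param propagate run [propagate_degradation()] first (default `TRUE`).
#' @return A list of class `producer_set` with elements `metabolite`,
#'   `rank`, `direction`, `taxa` (a subset of the pool) and
#'   `candidate_pool`.
#' @section Errors: `gutnet_unknown_compound_error` if the metabolite is not
#'   in the network.
#' @export
producers_of <- function(net, metabolite, rank = c("species", "genus"),
                         candidate_pool, propagate = TRUE) {
  taxa_linked_to(net, metabolite, match.arg(rank), candidate_pool,
                 direction = "export", propagate = propagate)
}

#' @rdname producers_of
#' @export
consumers_of <- function(net, metabolite, rank = c("species", "genus"),
                         candidate_pool, propagate = TRUE) {
  taxa_linked_to(net, metabolite, match.arg(rank), candidate_pool,
                 direction = "import", propagate = propagate)
}

taxa_linked_to <- function(net, metabolite, rank, candidate_pool,
                           direction, propagate = TRUE) {
  assert_network(net)
  if (length(candidate_pool) == 0L) {
    stop_gutnet("gutnet_data_error", "candidate pool must be nonempty")
  }
  cmp <- net$compounds
  hit <- which(cmp$name == metabolite & cmp$klass == "small_molecule")
  if (length(hit) == 0L) {
    stop_gutnet("gutnet_unknown_compound_error",
                sprintf("metabolite '%s' is not a small molecule in the network",
                        metabolite))
  }
  if (propagate) net <- propagate_degradation(net)
  asc <- net$associations
  linked_ids <- unique(asc$organism_id[
    asc$compound_id == cmp$compound_id[hit[1]] &
      asc$activity == direction & asc$sign == "positive"])
  org <- net$organisms[net$organisms$kind == "microbe", ]
  linked_names <- org$name[org$organism_id %in% linked_ids]

  taxa <- if (rank == "species") {
    intersect(candidate_pool, linked_names)
  } else {
    genus <- organism_genus(org)
    sapply_keep <- vapply(unique(candidate_pool), function(g) {
      members <- org$name[genus == g]
      length(members) > 0 &&
        mean(members %in% linked_names) > 0.5   # strict majority
    }, logical(1))
    unique(candidate_pool)[sapply_keep]
  }
  structure(list(metabolite = metabolite, rank = rank,
                 direction = direction, taxa = sort(taxa),
                 candidate_pool = unique(candidate_pool)),
            class = "producer_set")
}

organism_genus <- function(org) {
  g <- vapply(org$lineage, function(l) {
    if ("genus" %in% names(l)) l[["genus"]] else NA_character_
  }, character(1))
  g[is.na(g)] <- name_genus(org$name[is.na(g)])
  g
}

#' @export
print.producer_set <- function(x, ...) {
  cat(sprintf("<producer_set> %s %ss of '%s': %d of %d candidates\n",
              x$rank,
              if (x$direction == "export") "producer" else "consumer",
              x$metabolite, length(x$taxa), length(x$candidate_pool)))
  invisible(x)
}

# replicate-mean abundance of each taxon per group: taxa x groups matrix
group_mean_matrix <- function(ab, taxa) {
  groups <- tbl_groups(ab)
  x <- as_tibble(ab)
  m <- matrix(0, nrow = length(taxa), ncol = length(groups),
              dimnames = list(taxa, groups))
  x <- x[x$taxon %in% taxa, ]
  if (nrow(x)) {
    agg <- summarise(group_by(x, .data$taxon, .data$group),
                     m = mean(.data$abundance), .groups = "drop")
    m[cbind(agg$taxon, agg$group)] <- agg$m
  }
  m
}

metabolite_group_means <- function(mb, metabolite) {
  x <- as_tibble(mb)
  x <- x[x$metabolite == metabolite, ]
  agg <- tapply(x$concentration, x$group, mean)
  agg[tbl_groups(mb)]
}

#' Screen metabolites for concordance analysis
#'
#' Applies the candidate filters of the validation pipeline: a metabolite is
#' analysed only if it is in the network, is not flagged host- or
#' diet-derived, and both its group-mean concentration and its producer-set
#' group-mean abundance span at least a `min_fold` change (default 1.5)
#' across groups. The consumer side is additionally checked: when total
#' consumer abundance is below half the producer abundance, consumers are
#' marked as too scarce to analyse.
#'
#' @param net a valid [gut_network()].
#' @param ab an [abundance_table()]; its taxa form the candidate pool.
#' @param mb a [metabolite_table()] sharing `ab`'s group labels.
#' @param rank taxonomic rank of the analysis.
#' @param min_fold minimum max/min fold change across group means.
#' @param propagate propagate degradation products first.
#' @return A tibble with columns `metabolite`, `producers` (list column of
#'   `producer_set`), `f_span`, `g_span` and `consumers_usable`.
#' @section Errors: `gutnet_group_mismatch_error` when the two tables
#'   disagree on group labels.
#' @export
select_candidates <- function(net, ab, mb, rank = c("species", "genus"),
                              min_fold = 1.5, propagate = TRUE) {
  rank <- match.arg(rank)
  if (!setequal(tbl_groups(ab), tbl_groups(mb))) {
    stop_gutnet("gutnet_group_mismatch_error",
                "abundance and metabolite tables declare different groups")
  }
  if (propagate) net <- propagate_degradation(net)
  pool <- unique(as_tibble(ab)$taxon)
  x <- as_tibble(mb)
  flags <- tapply(x$host_or_diet_derived, x$metabolite, any)
  mets <- intersect(unique(x$metabolite), net$compounds$name)

  rows <- purrr::compact(lapply(mets, function(m) {
    if (isTRUE(flags[[m]])) return(NULL)
    gm <- metabolite_group_means(mb, m)
    g_span <- if (min(gm) > 0) max(gm) / min(gm) else Inf
    ps <- producers_of(net, m, rank, pool, propagate = FALSE)
    if (length(ps$taxa) == 0L) return(NULL)
    pm <- colSums(group_mean_matrix(ab, ps$taxa))
    f_span <- if (min(pm) > 0) max(pm) / min(pm) else Inf
    if (g_span < min_fold || f_span < min_fold) return(NULL)
    cs <- consumers_of(net, m, rank, pool, propagate = FALSE)
    cons_ab <- if (length(cs$taxa)) sum(group_mean_matrix(ab, cs$taxa)) else 0
    tibble(metabolite = m, producers = list(ps), f_span = f_span,
           g_span = g_span,
           consumers_usable = cons_ab >= 0.5 * sum(pm))
  }))
  if (length(rows)) bind_rows(rows) else {
    tibble(metabolite = character(), producers = list(),
           f_span = double(), g_span = double(),
           consumers_usable = logical())
  }
}

#' Producer and metabolite fold changes between group pairs
#'
#' For each ordered group pair (i, j), `f` is the fold change in the
#' producer-set abundance (members' abundances summed per sample, then
#' averaged over the replicates of each group) and `g` the fold change in
#' the replicate-mean metabolite concentration, both oriented i -> j. A pair
#' matches when producer and metabolite shift the same way:
#' `(f - 1) * (g - 1) > 0`. Pairs with a zero denominator are dropped with a
#' message.
#'
#' @param ab an [abundance_table()].
#' @param mb a [metabolite_table()].
#' @param producer_set a `producer_set` from [producers_of()].
#' @param group_pairs optional two-column matrix/data frame of (i, j) group
#'   labels; defaults to all pairs i < j in the declared group order.
#' @return A tibble of class `fold_change_tbl`: `metabolite`, `group_i`,
#'   `group_j`, `f`, `g`, `qualifies_up` (`f >= 1 & g >= 1`),
#'   `qualifies_down`, `match` (`NA` when `f = 1` or `g = 1`).
#' @export
fold_changes <- function(ab, mb, producer_set, group_pairs = NULL) {
  groups <- tbl_groups(mb)
  if (is.null(group_pairs)) group_pairs <- default_pairs(groups)
  pm <- colSums(group_mean_matrix(ab, producer_set$taxa))
  gm <- metabolite_group_means(mb, producer_set$metabolite)

  rows <- purrr::compact(lapply(seq_len(nrow(group_pairs)), function(r) {
    i <- as.character(group_pairs[r, 1]); j <- as.character(group_pairs[r, 2])
    if (pm[[i]] <= 0 || gm[[i]] <= 0 || pm[[j]] <= 0 || gm[[j]] <= 0) {
      inform(sprintf("dropping pair (%s, %s) for '%s': zero group mean",
                     i, j, producer_set$metabolite))
      return(NULL)
    }
    f <- pm[[j]] / pm[[i]]
    g <- gm[[j]] / gm[[i]]
    tibble(metabolite = producer_set$metabolite, group_i = i, group_j = j,
           f = f, g = g,
           qualifies_up = f >= 1 & g >= 1,
           qualifies_down = f <= 1 & g <= 1,
           match = if (f == 1 || g == 1) NA else (f - 1) * (g - 1) > 0)
  }))
  out <- if (length(rows)) bind_rows(rows) else {
    tibble(metabolite = character(), group_i = character(),
           group_j = character(), f = double(), g = double(),
           qualifies_up = logical(), qualifies_down = logical(),
           match = logical())
  }
  structure(out, class = c("fold_change_tbl", class(tibble())))
}

default_pairs <- function(groups) {
  idx <- utils::combn(length(groups), 2)
  tibble(group_i = groups[idx[1, ]], group_j = groups[idx[2, ]])
}

#' Overall match rate of fold-change records
#'
#' Fraction of (metabolite, group pair) records whose producer and
#' metabolite fold changes agree in direction, among records where both
#' differ from 1.
#'
#' @param records a tibble of fold-change records (from [fold_changes()],
#'   possibly row-bound across metabolites).
#' @return A fraction in `[0, 1]`.
#' @section Errors: `gutnet_no_records_error` when no record has both
#'   `f != 1` and `g != 1`.
#' @export
match_rate <- function(records) {
  rec <- records[records$f != 1 & records$g != 1, ]
  if (nrow(rec) == 0L) {
    stop_gutnet("gutnet_no_records_error",
                "no fold-change records with f != 1 and g != 1")
  }
  mean((rec$f - 1) * (rec$g - 1) > 0)
}

#' Permutation test of producer-metabolite concordance
#'
#' Tests whether the observed producer fold changes beat what randomly
#' chosen producer sets achieve. For every permutation, each producer set is
#' re-assigned uniformly at random without replacement from its candidate
#' pool (keeping set sizes, and hence the total producer count, fixed; set
#' `pool = "global"` to draw the fixed total from the pooled candidates
#' instead). A permutation succeeds when its fold change f' satisfies
#' `f' >= f` for every qualifying up pair (`f` and `g` both >= 1) and
#' `f' <= f` for every qualifying down pair (both <= 1), jointly across all
#' producer sets. The P value is `(successes + 1) / (n_perm + 1)`, so it is
#' never zero and has resolution `1 / (n_perm + 1)`.
#'
#' @param ab an [abundance_table()].
#' @param mb a [metabolite_table()].
#' @param producer_sets list of `producer_set` objects (one per metabolite),
#'   e.g. the `producers` column of [select_candidates()].
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed; required for reproducibility.
#' @param group_pairs optional explicit group pairs (see [fold_changes()]).
#' @param pool `"per_source"` (default): each set is redrawn from its own
#'   candidate pool with its observed size; `"global"`: the total producer
#'   count is drawn from the union of pools and split by membership.
#' @return A list of class `concordance_result`: `records` (all fold-change
#'   records), `match_rate`, `p_value`, `p_raw` (the uncorrected success
#'   proportion), `n_perm`, `seed`, `n_qualifying_pairs`, `pool`.
#' @section Errors: `gutnet_no_qualifying_pairs_error` when no record
#'   qualifies; `gutnet_seed_required_error` when `seed` is missing.
#' @export
permutation_pvalue <- function(ab, mb, producer_sets, n_perm = 1000L,
                               seed = NULL, group_pairs = NULL,
                               pool = c("per_source", "global")) {
  pool <- match.arg(pool)
  if (is.null(seed)) {
    stop_gutnet("gutnet_seed_required_error",
                "a seed is required for the permutation draw")
  }
  if (n_perm < 100L) {
    stop_gutnet("gutnet_data_error", "n_perm must be at least 100")
  }
  if (inherits(producer_sets, "producer_set")) {
    producer_sets <- list(producer_sets)
  }
  groups <- tbl_groups(mb)
  if (is.null(group_pairs)) group_pairs <- default_pairs(groups)

  records <- bind_rows(lapply(producer_sets, function(ps)
    fold_changes(ab, mb, ps, group_pairs)))
  qual <- records[records$qualifies_up | records$qualifies_down, ]
  if (nrow(qual) == 0L) {
    stop_gutnet("gutnet_no_qualifying_pairs_error",
                "no (metabolite, group pair) record has f and g concordantly >= 1 or <= 1")
  }

  # per set: candidate-pool group-mean matrix, set size, qualifying pairs
  prep <- lapply(producer_sets, function(ps) {
    q <- qual[qual$metabolite == ps$metabolite, ]
    list(M = group_mean_matrix(ab, ps$candidate_pool),
         n = length(ps$taxa),
         i = q$group_i, j = q$group_j, f = q$f, up = q$qualifies_up)
  })
  prep <- prep[vapply(prep, function(p) length(p$f) > 0 || p$n > 0,
                      logical(1))]
  union_pool <- unique(unlist(lapply(producer_sets,
                                     function(ps) ps$candidate_pool)))
  n_total <- sum(vapply(producer_sets, function(ps) length(ps$taxa),
                        integer(1)))

  successes <- withr::with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(b) {
      drawn_global <- if (pool == "global") {
        sample(union_pool, min(n_total, length(union_pool)))
      }
      for (p in prep) {
        if (length(p$f) == 0L) next
        members <- if (pool == "per_source") {
          rownames(p$M)[sample.int(nrow(p$M), min(p$n, nrow(p$M)))]
        } else {
          intersect(drawn_global, rownames(p$M))
        }
        if (length(members) == 0L) return(FALSE)
        pm <- colSums(p$M[members, , drop = FALSE])
        fp <- pm[p$j] / pm[p$i]
        ok <- ifelse(p$up, fp >= p$f, fp <= p$f)
        if (!all(ok, na.rm = FALSE) || anyNA(ok)) return(FALSE)
      }
      TRUE
    }, logical(1)))
  })

  structure(list(
    records = records,
    match_rate = match_rate(records),
    p_value = (successes + 1) / (n_perm + 1),
    p_raw = successes / n_perm,
    n_perm = as.integer(n_perm),
    seed = as.integer(seed),
    n_qualifying_pairs = nrow(qual),
    pool = pool
  ), class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf(
    paste0("<concordance_result> %d fold-change records, %d qualifying\n",
           "  match rate: %.1f%%   P = %.4g (%d permutations, seed %d, %s pools)\n"),
    nrow(x$records), x$n_qualifying_pairs, 100 * x$match_rate, x$p_value,
    x$n_perm, x$seed, x$pool))
  invisible(x)
}

#' @export
tidy.concordance_result <- function(x, ...) as_tibble(x$records)

#' @export
glance.concordance_result <- function(x, ...) {
  tibble(match_rate = x$match_rate, p_value = x$p_value, p_raw = x$p_raw,
         n_perm = x$n_perm, n_qualifying_pairs = x$n_qualifying_pairs,
         n_records = nrow(x$records), pool = x$pool, seed = x$seed)
}
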