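#' Parameters for the synthetic network generator
#'
#' Defaults mirror the scale of the curated resource: 838 microbial species,
#' 266 small molecules, 17 macromolecules, organism import/export degrees
#' following exponential laws with rates about 0.2 and 0.3, compound degrees
#' following a truncated power law with exponent about 1.4, and roughly one
#' negative association per ten positive ones.
#'
#' @param n_species,n_metabolites,n_macromolecules node counts.
#' @param r_import,r_export exponential rates of the organism degree laws.
#' @param gamma power-law exponent of the compound degree law.
#' @param neg_fraction negative associations as a fraction of positive ones.
#' @param zero_fraction fraction of species with no link of a direction.
#' @param seed integer seed; all randomness in [gen_network()] flows from
#'   it.
#' @return A list of class `network_gen_params`.
#' @export
network_gen_params <- function(n_species = 838L, n_metabolites = 266L,
                               n_macromolecules = 17L, r_import = 0.2,
                               r_export = 0.3, gamma = 1.4,
                               neg_fraction = 0.1, zero_fraction = 0.1,
                               seed = 1L) {
  stopifnot(n_species > 0, n_metabolites > 0, n_macromolecules > 0,
            r_import > 0, r_export > 0, gamma > 0,
            neg_fraction >= 0, neg_fraction < 1,
            zero_fraction >= 0, zero_fraction < 1)
  structure(list(n_species = as.integer(n_species),
                 n_metabolites = as.integer(n_metabolites),
                 n_macromolecules = as.integer(n_macromolecules),
                 r_import = r_import, r_export = r_export, gamma = gamma,
                 neg_fraction = neg_fraction, zero_fraction = zero_fraction,
                 seed = as.integer(seed)),
            class = "network_gen_params")
}

# Proportional allocation of `total` units over weights `x` with a per-entry
# cap: capped entries are frozen and the remainder re-scaled over the free
# ones (waterfilling), so the total is preserved whenever sum(cap) allows.
allocate_capped <- function(x, total, cap) {
  y <- x / sum(x) * total
  for (i in seq_along(y)) {
    over <- y >= cap
    if (!any(y > cap) || all(over)) break
    y[over] <- cap
    y[!over] <- y[!over] * (total - sum(y[over])) / sum(y[!over])
  }
  pmin(y, cap)
}

# Largest-remainder rounding of nonnegative reals to integers with an exact
# total; ties broken by position for determinism.
round_to_total <- function(x, total) {
  y <- floor(x)
  need <- total - sum(y)
  if (need > 0) {
    ord <- order(x - y, decreasing = TRUE)
    y[ord[seq_len(need)]] <- y[ord[seq_len(need)]] + 1
  } else if (need < 0) {
    ord <- order(x - y)
    ord <- ord[y[ord] > 0]
    y[ord[seq_len(-need)]] <- y[ord[seq_len(-need)]] - 1
  }
  as.integer(y)
}

# Place bipartite edges realising an organism stub vector and a compound
# target-degree vector as closely as feasible: compounds are processed
# largest degree first, each connecting to the organisms with the most
# remaining stubs (bipartite Havel-Hakimi).
place_edges <- function(org_stubs, cmp_deg) {
  edges_o <- integer(0); edges_c <- integer(0)
  rem <- org_stubs
  for (ci in order(cmp_deg, decreasing = TRUE)) {
    d <- cmp_deg[ci]
    if (d == 0L) next
    avail <- which(rem > 0L)
    if (length(avail) == 0L) break
    take <- avail[order(rem[avail], decreasing = TRUE)][seq_len(min(d, length(avail)))]
    rem[take] <- rem[take] - 1L
    edges_o <- c(edges_o, take)
    edges_c <- c(edges_c, rep.int(ci, length(take)))
  }
  list(organism = edges_o, compound = edges_c,
       org_shortfall = sum(rem), cmp_shortfall = sum(cmp_deg) - length(edges_o))
}

#' Generate a synthetic organism-compound network
#'
#' Draws species import and export degrees from shifted geometric
#' (exponential) laws, compound target degrees from a truncated discrete
#' power law, reconciles the two marginals by proportionally rescaling and
#' re-rounding the compound targets to the organism stub total, and places
#' edges largest-degree-first so both degree sequences are met as closely as
#' feasible. Species are grouped into synthetic genera (sizes Poisson(3) +
#' 1) so genus-rank analyses are exercisable; every macromolecule gets a
#' degradation rule with 1-5 small-molecule products and a few degrading
#' species; a fraction of association triples is added as negative
#' statements. The result passes [validate_network()] and is fully
#' reproducible per seed.
#'
#' @param p a [network_gen_params()].
#' @return A `gut_network`; `meta$degree_reconciliation` records the
#'   rescaling factors and any unplaced stubs.
#' @section Errors: `gutnet_infeasible_degree_error` when one side of a
#'   direction has stubs and the other none.
#' @export
gen_network <- function(p = network_gen_params()) {
  stopifnot(inherits(p, "network_gen_params"))
  withr::with_seed(p$seed, gen_network_impl(p))
}

gen_network_impl <- function(p) {
  ns <- p$n_species; nm <- p$n_metabolites

  # genera of Poisson(3)+1 species each
  sizes <- integer(0)
  while (sum(sizes) < ns) sizes <- c(sizes, rpois(ns, 3) + 1L)
  genus_idx <- rep(seq_along(sizes), sizes)[seq_len(ns)]
  genus_names <- sprintf("Genus%03d", seq_len(max(genus_idx)))
  phyla <- c("Bacteroidetes", "Firmicutes", "Proteobacteria",
             "Actinobacteria", "Verrucomicrobia")
  genus_phylum <- sample(phyla, max(genus_idx), replace = TRUE)
  within_idx <- stats::ave(genus_idx, genus_idx, FUN = seq_along)
  sp_names <- sprintf("%s species%02d", genus_names[genus_idx], within_idx)

  organisms <- tibble(
    organism_id = sprintf("ORG_%05d", seq_len(ns)),
    name = sp_names, ncbi_taxid = 100000L + seq_len(ns),
    rank = "species", kind = "microbe",
    lineage = lapply(seq_len(ns), function(i)
      c(domain = "Bacteria", phylum = genus_phylum[genus_idx[i]],
        genus = genus_names[genus_idx[i]], species = sp_names[i])),
    sample_sources = rep(list("synthetic"), ns))

  compounds <- tibble(
    compound_id = sprintf("CMP_%05d", seq_len(nm + p$n_macromolecules)),
    name = c(sprintf("metabolite%03d", seq_len(nm)),
             sprintf("macromolecule%02d", seq_len(p$n_macromolecules))),
    kegg_cid = c(sprintf("C9%05d", seq_len(nm)),
                 rep(NA_character_, p$n_macromolecules)),
    klass = rep(c("small_molecule", "macromolecule"),
                c(nm, p$n_macromolecules)))

  recon <- list()
  edge_tbl <- list()
  for (dir in c("import", "export")) {
    r <- if (dir == "import") p$r_import else p$r_export
    d_org <- rdegree_exponential(ns, r)
    d_org[runif(ns) < p$zero_fraction] <- 0L
    d_org <- pmin(d_org, nm)
    d_cmp <- rdegree_powerlaw(nm, p$gamma, 1L, ns)
    if (sum(d_org) == 0L || sum(d_cmp) == 0L) {
      stop_gutnet("gutnet_infeasible_degree_error",
                  sprintf("cannot reconcile %s degree sequences: one side has no stubs",
                          dir))
    }
    scale <- sum(d_org) / sum(d_cmp)
    d_cmp2 <- pmin(round_to_total(
      allocate_capped(d_cmp, sum(d_org), ns), sum(d_org)), ns)
    pl <- place_edges(d_org, d_cmp2)
    recon[[dir]] <- list(rescale = scale, unplaced_stubs = pl$org_shortfall)
    edge_tbl[[dir]] <- tibble(
      organism_id = organisms$organism_id[pl$organism],
      compound_id = compounds$compound_id[pl$compound],
      activity = dir, sign = "positive")
  }

  # degradation rules and degrading species
  macro_ids <- compounds$compound_id[compounds$klass == "macromolecule"]
  small_ids <- compounds$compound_id[compounds$klass == "small_molecule"]
  rules <- tibble(
    compound_id = macro_ids,
    products = lapply(macro_ids, function(m)
      sample(small_ids, sample.int(5L, 1L))))
  deg_edges <- bind_rows(lapply(macro_ids, function(m) {
    degraders <- sample(organisms$organism_id,
                        min(1L + rpois(1L, 2), ns))
    tibble(organism_id = degraders, compound_id = m,
           activity = "degradation", sign = "positive")
  }))

  pos <- bind_rows(edge_tbl$import, edge_tbl$export, deg_edges)

  # negative statements on triples not already present
  n_neg <- round(p$neg_fraction * nrow(pos))
  neg <- NULL
  if (n_neg > 0) {
    have <- paste(pos$organism_id, pos$compound_id, pos$activity, sep = "\r")
    picked <- character(0)
    rows <- list()
    guard <- 0L
    while (length(rows) < n_neg && guard < 50L) {
      guard <- guard + 1L
      need <- n_neg - length(rows)
      oi <- sample.int(ns, need, replace = TRUE)
      act <- sample(c("import", "export"), need, replace = TRUE)
      ci <- sample.int(nm, need, replace = TRUE)
      cand <- tibble(organism_id = organisms$organism_id[oi],
                     compound_id = compounds$compound_id[ci],
                     activity = act)
      key <- paste(cand$organism_id, cand$compound_id, cand$activity,
                   sep = "\r")
      ok <- !key %in% have & !key %in% picked & !duplicated(key)
      picked <- c(picked, key[ok])
      if (any(ok)) rows[[length(rows) + 1L]] <- cand[ok, ]
      rows <- list(bind_rows(rows))
      if (nrow(rows[[1]]) >= n_neg) break
    }
    neg <- mutate(head(rows[[1]], n_neg), sign = "negative")
  }

  asc <- bind_rows(pos, neg)
  references <- tibble(ref_key = sprintf("REF_%03d", 1:10),
                       citation = sprintf("Synthetic reference %d", 1:10))
  asc <- mutate(asc,
                assoc_id = next_ids(character(), nrow(asc)),
                refs = lapply(sample.int(10L, nrow(asc), replace = TRUE),
                              function(i) references$ref_key[i]),
                provenance = "direct")

  gut_network(organisms, compounds, asc, rules, references,
              meta = list(degree_reconciliation = recon,
                          params = unclass(p)))
}

#' Design of a synthetic paired microbiome-metabolome experiment
#'
#' Describes the grouped, replicate-resolved experiments used to exercise
#' the concordance pipeline: per-group species abundances from a lognormal
#' compositional model, and metabolite levels tied to their producer-set
#' abundance through `level = baseline * producer_abundance^beta` with
#' multiplicative lognormal measurement noise `sigma`.
#'
#' @param groups named integer vector: group labels and replicate counts.
#' @param rank rank of the simulated taxa (`"species"` or `"genus"`).
#' @param beta planted exponent linking metabolite level to producer-set
#'   abundance (`0` = no dependence).
#' @param sigma lognormal measurement noise s.d. on metabolite levels.
#' @param n_metabolites number of measured metabolites.
#' @param host_derived_fraction fraction of measured metabolites flagged
#'   host/diet-derived.
#' @param group_effect_sd lognormal s.d. of per-(taxon, group) abundance
#'   shifts.
#' @param replicate_sd lognormal s.d. of per-replicate abundance noise.
#' @param seed integer seed.
#' @return A list of class `experiment_design`.
#' @export
experiment_design <- function(groups = c(I = 5L, II = 5L, III = 5L),
                              rank = c("species", "genus"), beta = 1,
                              sigma = 0.2, n_metabolites = 10L,
                              host_derived_fraction = 0.1,
                              group_effect_sd = 0.5, replicate_sd = 0.3,
                              seed = 1L) {
  rank <- match.arg(rank)
  stopifnot(length(groups) >= 2, all(groups >= 1),
            !is.null(names(groups)), beta >= 0, sigma >= 0,
            host_derived_fraction >= 0, host_derived_fraction <= 1)
  structure(list(groups = groups, rank = rank, beta = beta, sigma = sigma,
                 n_metabolites = as.integer(n_metabolites),
                 host_derived_fraction = host_derived_fraction,
                 group_effect_sd = group_effect_sd,
                 replicate_sd = replicate_sd, seed = as.integer(seed)),
            class = "experiment_design")
}

#' Simulate a paired abundance/metabolome experiment from a network
#'
#' `gen_experiment()` plants the producer-metabolite dependence declared in
#' the design: each measured metabolite's group-replicate level is
#' `baseline * P_g^beta * exp(N(0, sigma))`, where `P_g` is the realised
#' replicate-mean abundance of its network producers in group `g`. With
#' `beta = 1` and `sigma = 0`, metabolite fold changes equal producer fold
#' changes exactly. `gen_null_experiment()` instead draws metabolite levels
#' independently of the abundances (group shifts of their own), giving the
#' null for permutation-test calibration; its truth record has `beta = 0`.
#'
#' @param net a valid [gut_network()].
#' @param d an [experiment_design()].
#' @return A list with elements `abundance` (an [abundance_table()]),
#'   `metabolites` (a [metabolite_table()]) and `truth` (planted producer
#'   sets, `beta`, `sigma` and host/diet flags).
#' @export
gen_experiment <- function(net, d = experiment_design()) {
  assert_network(net)
  stopifnot(inherits(d, "experiment_design"))
  withr::with_seed(d$seed, gen_experiment_impl(net, d, planted = TRUE))
}

#' @rdname gen_experiment
#' @export
gen_null_experiment <- function(net, d = experiment_design()) {
  assert_network(net)
  stopifnot(inherits(d, "experiment_design"))
  withr::with_seed(d$seed, gen_experiment_impl(net, d, planted = FALSE))
}

gen_experiment_impl <- function(net, d, planted) {
  netp <- propagate_degradation(net)
  org <- netp$organisms[netp$organisms$kind == "microbe", ]
  taxa <- if (d$rank == "species") org$name else
    sort(unique(organism_genus(org)))
  nt <- length(taxa)
  groups <- names(d$groups)

  base <- rlnorm(nt, 0, 1.5)
  eff <- matrix(rlnorm(nt * length(groups), 0, d$group_effect_sd),
                nrow = nt, dimnames = list(taxa, groups))
  ab_rows <- list()
  for (g in groups) {
    for (r in seq_len(d$groups[[g]])) {
      raw <- base * eff[, g] * rlnorm(nt, 0, d$replicate_sd)
      ab_rows[[paste(g, r)]] <- tibble(
        sample_id = sprintf("%s_rep%02d", g, r), group = g,
        taxon = taxa, abundance = raw / sum(raw))
    }
  }
  ab <- abundance_table(bind_rows(ab_rows), rank = d$rank)

  # measured metabolites: small molecules with at least one producer at rank
  small <- netp$compounds$name[netp$compounds$klass == "small_molecule"]
  sets <- list()
  for (m in sample(small)) {
    ps <- producers_of(netp, m, d$rank, taxa, propagate = FALSE)
    if (length(ps$taxa)) sets[[m]] <- ps
    if (length(sets) >= d$n_metabolites) break
  }
  if (length(sets) == 0L) {
    stop_gutnet("gutnet_data_error",
                "network has no producible small molecule at this rank")
  }
  mets <- names(sets)
  n_host <- round(d$host_derived_fraction * length(mets))
  flagged <- if (n_host > 0) sample(mets, n_host) else character(0)
  baseline <- setNames(rlnorm(length(mets), 0, 1), mets)

  mb_rows <- list()
  for (m in mets) {
    pm <- colSums(group_mean_matrix(ab, sets[[m]]$taxa))
    gshift <- setNames(rlnorm(length(groups), 0, d$group_effect_sd), groups)
    for (g in groups) {
      n_rep <- d$groups[[g]]
      level <- if (planted) baseline[[m]] * pm[[g]]^d$beta else
        baseline[[m]] * gshift[[g]]
      mb_rows[[paste(m, g)]] <- tibble(
        group = g, replicate = seq_len(n_rep), metabolite = m,
        concentration = level * rlnorm(n_rep, 0, d$sigma),
        host_or_diet_derived = m %in% flagged)
    }
  }
  mb <- metabolite_table(bind_rows(mb_rows))

  list(abundance = ab, metabolites = mb,
       truth = list(producer_sets = sets,
                    beta = if (planted) d$beta else 0,
                    sigma = d$sigma, host_or_diet_derived = flagged))
}
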