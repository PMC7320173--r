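test_that("genus producers require a strict species majority", {
  org <- tibble::tibble(
    organism_id = sprintf("O%d", 1:5),
    name = c("Alpha sp1", "Alpha sp2", "Alpha sp3", "Beta sp1", "Beta sp2"),
    ncbi_taxid = 1:5, rank = "species", kind = "microbe",
    lineage = c(rep(list(c(genus = "Alpha")), 3),
                rep(list(c(genus = "Beta")), 2)),
    sample_sources = rep(list(character()), 5))
  cmp <- tibble::tibble(compound_id = "C1", name = "butyrate",
                        kegg_cid = "C00246", klass = "small_molecule")
  # Alpha: 2 of 3 exporters (majority); Beta: 1 of 2 (not a majority)
  asc <- tibble::tibble(
    assoc_id = sprintf("GEN_%05d", 1:3),
    organism_id = c("O1", "O2", "O4"), compound_id = "C1",
    activity = "export", sign = "positive",
    refs = list("R1", "R1", "R1"), provenance = "direct")
  net <- gut_network(org, cmp, asc)
  pool <- c("Alpha", "Beta", "Gamma")
  ps <- producers_of(net, "butyrate", "genus", pool)
  expect_identical(ps$taxa, "Alpha")

  # flipping one species over the 50% line flips membership
  asc2 <- dplyr::bind_rows(asc, tibble::tibble(
    assoc_id = "GEN_00004", organism_id = "O5", compound_id = "C1",
    activity = "export", sign = "positive", refs = list("R1"),
    provenance = "direct"))
  ps2 <- producers_of(gut_network(org, cmp, asc2), "butyrate", "genus",
                      pool)
  expect_setequal(ps2$taxa, c("Alpha", "Beta"))

  # species rank intersects the pool with exporters
  sp <- producers_of(net, "butyrate", "species",
                     c("Alpha sp1", "Beta sp2", "Gamma sp1"))
  expect_identical(sp$taxa, "Alpha sp1")
  # unknown metabolite
  expect_error(producers_of(net, "no such compound", "species", pool),
               class = "gutnet_unknown_compound_error")
  # metabolite exported by no one
  asc0 <- asc[0, ]
  ps0 <- producers_of(gut_network(org, cmp, asc0), "butyrate", "genus",
                      pool)
  expect_length(ps0$taxa, 0L)
})

test_that("degradation propagation feeds the producer mapping", {
  net <- read_toynet()
  # F. prausnitzii degrades cellulose -> counts as glucose producer
  ps <- producers_of(net, "glucose", "species",
                     net$organisms$name[net$organisms$kind == "microbe"])
  expect_true("Faecalibacterium prausnitzii" %in% ps$taxa)
  ps_raw <- producers_of(net, "glucose", "species",
                         net$organisms$name[net$organisms$kind == "microbe"],
                         propagate = FALSE)
  expect_false("Faecalibacterium prausnitzii" %in% ps_raw$taxa)
})

test_that("fold changes reproduce hand-computed ratios and orientations", {
  st <- study_fixture()
  ps <- fake_producer_set("butyrate", c("GenA", "GenB"), st$taxa)
  rec <- fold_changes(st$ab, st$mb, ps)
  # producer means: I: 0.7, II: 0.3 -> f = 3/7; metabolite 2 -> 1, g = 0.5
  expect_equal(rec$f, 0.3 / 0.7, tolerance = 1e-12)
  expect_equal(rec$g, 0.5, tolerance = 1e-12)
  expect_true(rec$qualifies_down)
  expect_false(rec$qualifies_up)
  expect_true(rec$match)

  # a 10-fold producer drop is a 90% decrease, same orientation as printed
  ab2 <- abundance_table(tibble::tibble(
    sample_id = c("I_1", "II_1"), group = c("I", "II"),
    taxon = "GenA", abundance = c(0.9, 0.09)), rank = "genus",
    mode = "relative")
  ps_a <- fake_producer_set("butyrate", "GenA", "GenA")
  rec2 <- fold_changes(ab2, st$mb, ps_a)
  expect_equal(rec2$f, 0.1, tolerance = 1e-12)

  # identical groups give f = g = 1 and an undefined match
  ab3 <- abundance_table(tibble::tibble(
    sample_id = c("I_1", "II_1"), group = c("I", "II"),
    taxon = "GenA", abundance = c(0.5, 0.5)), rank = "genus")
  mb3 <- metabolite_table(tibble::tibble(
    group = c("I", "II"), replicate = 1, metabolite = "butyrate",
    concentration = 1))
  rec3 <- fold_changes(ab3, mb3, ps_a)
  expect_identical(rec3$f, 1)
  expect_true(is.na(rec3$match))
  expect_error(match_rate(rec3), class = "gutnet_no_records_error")
})

test_that("match rate counts direction agreement among informative records", {
  rec <- tibble::tibble(f = c(2, 0.5), g = c(1.5, 2))
  expect_equal(match_rate(rec), 0.5)
  rec2 <- tibble::tibble(f = c(2, 0.5, 1), g = c(1.5, 0.2, 3))
  expect_equal(match_rate(rec2), 1)  # the f = 1 record is excluded
})

test_that("fold-change records are antisymmetric under pair reversal", {
  st <- study_fixture()
  ps <- fake_producer_set("butyrate", c("GenA", "GenC"), st$taxa)
  fwd <- fold_changes(st$ab, st$mb, ps,
                      tibble::tibble(group_i = "I", group_j = "II"))
  rev <- fold_changes(st$ab, st$mb, ps,
                      tibble::tibble(group_i = "II", group_j = "I"))
  expect_equal(rev$f, 1 / fwd$f, tolerance = 1e-12)
  expect_equal(rev$g, 1 / fwd$g, tolerance = 1e-12)
  expect_identical(rev$match, fwd$match)
})

test_that("candidate screening applies the 1.5-fold and host/diet filters", {
  org <- tibble::tibble(
    organism_id = c("O1", "O2"), name = c("GenA sp1", "GenB sp1"),
    ncbi_taxid = 1:2, rank = "species", kind = "microbe",
    lineage = list(c(genus = "GenA"), c(genus = "GenB")),
    sample_sources = rep(list(character()), 2))
  cmp <- tibble::tibble(
    compound_id = c("C1", "C2", "C3"),
    name = c("butyrate", "lactate", "cholate"),
    kegg_cid = NA_character_, klass = "small_molecule")
  asc <- tibble::tibble(
    assoc_id = sprintf("GEN_%05d", 1:3),
    organism_id = "O1", compound_id = c("C1", "C2", "C3"),
    activity = "export", sign = "positive",
    refs = list("R1", "R1", "R1"), provenance = "direct")
  net <- gut_network(org, cmp, asc)
  ab <- abundance_table(tibble::tibble(
    sample_id = rep(c("I_1", "II_1"), each = 2),
    group = rep(c("I", "II"), each = 2),
    taxon = rep(c("GenA", "GenB"), 2),
    abundance = c(0.6, 0.4, 0.3, 0.7)), rank = "genus")
  mb <- metabolite_table(tibble::tibble(
    group = rep(c("I", "II"), each = 3),
    replicate = 1,
    metabolite = rep(c("butyrate", "lactate", "cholate"), 2),
    concentration = c(2.0, 1.0, 5.0, 1.0, 0.8, 1.0),
    host_or_diet_derived = rep(c(FALSE, FALSE, TRUE), 2)))
  got <- select_candidates(net, ab, mb, rank = "genus")
  # butyrate: g spans 2x, producers (GenA) span 2x -> kept
  # lactate: g spans 1.25x only -> dropped; cholate: flagged -> dropped
  expect_identical(got$metabolite, "butyrate")
  expect_identical(got$producers[[1]]$taxa, "GenA")

  mb_bad <- metabolite_table(tibble::tibble(
    group = rep(c("I", "III"), each = 3), replicate = 1,
    metabolite = rep(c("butyrate", "lactate", "cholate"), 2),
    concentration = 1))
  expect_error(select_candidates(net, ab, mb_bad, rank = "genus"),
               class = "gutnet_group_mismatch_error")
})

test_that("the permutation p-value is exact when the pool equals the producer set", {
  st <- study_fixture()
  ps <- fake_producer_set("butyrate", c("GenA", "GenB"), c("GenA", "GenB"))
  res <- permutation_pvalue(st$ab, st$mb, list(ps), n_perm = 200, seed = 1)
  expect_equal(res$p_value, 1)
  expect_equal(res$p_raw, 1)
})

test_that("Monte-Carlo p-values agree with exhaustive enumeration on a small pool", {
  st <- study_fixture()
  pool <- st$taxa                       # C(4, 2) = 6 assignments
  obs <- c("GenA", "GenB")
  ps <- fake_producer_set("butyrate", obs, pool)

  # independent oracle: enumerate every 2-subset, recompute f' by hand
  means <- tibble::as_tibble(st$ab) |>
    dplyr::group_by(taxon, group) |>
    dplyr::summarise(m = mean(abundance), .groups = "drop") |>
    tidyr::pivot_wider(names_from = group, values_from = m)
  f_of <- function(taxa) {
    rows <- means[means$taxon %in% taxa, ]
    sum(rows$II) / sum(rows$I)
  }
  f_obs <- f_of(obs)
  combos <- combn(pool, 2, simplify = FALSE)
  # observed record qualifies downward (f, g both <= 1): success is f' <= f
  exact <- mean(vapply(combos, function(s) f_of(s) <= f_obs, logical(1)))

  res <- permutation_pvalue(st$ab, st$mb, list(ps), n_perm = 10000,
                            seed = 42)
  se <- sqrt(exact * (1 - exact) / 10000)
  expect_lt(abs(res$p_raw - exact), 3 * se + 1e-12)
  expect_gt(res$p_value, 0)
  expect_lte(res$p_value, 1)
})

test_that("a planted noise-free experiment gives a perfect match and tiny p", {
  net <- gen_network(small_gen_params(3, n_species = 60, n_metabolites = 30))
  des <- experiment_design(beta = 1, sigma = 0, n_metabolites = 8,
                           host_derived_fraction = 0, seed = 9)
  exp1 <- gen_experiment(net, des)
  recs <- dplyr::bind_rows(lapply(exp1$truth$producer_sets, function(ps)
    fold_changes(exp1$abundance, exp1$metabolites, ps)))
  expect_equal(recs$g, recs$f, tolerance = 1e-12)
  expect_equal(match_rate(recs), 1.0)

  # beta = 0, sigma = 0: metabolite levels are flat, all g = 1
  des0 <- experiment_design(beta = 0, sigma = 0, n_metabolites = 5,
                            host_derived_fraction = 0, seed = 9)
  exp0 <- gen_experiment(net, des0)
  recs0 <- dplyr::bind_rows(lapply(exp0$truth$producer_sets, function(ps)
    fold_changes(exp0$abundance, exp0$metabolites, ps)))
  expect_equal(recs0$g, rep(1, nrow(recs0)), tolerance = 1e-12)
})

test_that("with a single qualifying comparison and no selection, null p-values are near-uniform", {
  # Under producer-metabolite independence the observed producer set is
  # exchangeable with a random same-size draw, so with one metabolite, one
  # group pair and no candidate filtering the permutation p-value is close
  # to calibrated. (The full pipeline's joint, post-selection statistic is
  # deliberately not tested for uniformity; see the vignette.) Frozen from
  # this exact run: 48 qualifying studies, 8.3% at p <= 0.05, median 0.22.
  net <- gen_network(small_gen_params(8, n_species = 80,
                                      n_metabolites = 40))
  pvals <- c()
  for (seed in 1:100) {
    des <- experiment_design(groups = c(I = 5L, II = 5L), beta = 0,
                             sigma = 0.2, n_metabolites = 1,
                             host_derived_fraction = 0, seed = seed)
    e <- gen_null_experiment(net, des)
    sets <- lapply(e$truth$producer_sets, function(ps) {
      ps$candidate_pool <- unique(tibble::as_tibble(e$abundance)$taxon)
      ps
    })
    res <- tryCatch(
      suppressMessages(permutation_pvalue(e$abundance, e$metabolites, sets,
                                          n_perm = 199, seed = seed + 5000)),
      gutnet_no_qualifying_pairs_error = function(e) NULL)
    if (!is.null(res)) pvals <- c(pvals, res$p_value)
  }
  expect_gte(length(pvals), 30L)
  expect_lte(mean(pvals <= 0.05), 0.15)
  expect_gt(median(pvals), 0.05)   # not collapsed to the resolution floor
  expect_true(all(pvals > 0 & pvals <= 1))
})

test_that("seeds are required and reproducible for the permutation draw", {
  st <- study_fixture()
  ps <- fake_producer_set("butyrate", c("GenA", "GenB"), st$taxa)
  expect_error(permutation_pvalue(st$ab, st$mb, list(ps), n_perm = 200),
               class = "gutnet_seed_required_error")
  r1 <- permutation_pvalue(st$ab, st$mb, list(ps), n_perm = 500, seed = 7)
  r2 <- permutation_pvalue(st$ab, st$mb, list(ps), n_perm = 500, seed = 7)
  expect_identical(r1$p_value, r2$p_value)
  expect_identical(glance(r1)$p_value, r1$p_value)
  expect_identical(nrow(tidy(r1)), nrow(r1$records))
})
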