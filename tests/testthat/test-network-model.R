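test_that("a well-formed network validates cleanly and violations are reported per invariant", {
  expect_identical(nrow(validate_network(toy_network())), 0L)

  # opposite-sign duplicate on one (organism, compound, activity) triple
  asc <- toy_associations()
  asc <- dplyr::bind_rows(asc, dplyr::mutate(asc[1, ], assoc_id = "NJC19_00099",
                                             sign = "negative"))
  net <- gut_network(toy_organisms(), toy_compounds(), asc,
                     tibble::tibble(compound_id = "C4",
                                    products = list(c("C1", "C3"))))
  rep <- validate_network(net)
  expect_identical(rep$invariant, "sign_conflict")
  expect_identical(rep$record_id, "NJC19_00099")

  # transport of a macromolecule is an activity/class mismatch
  asc2 <- toy_associations()
  asc2$compound_id[1] <- "C4"
  rep2 <- validate_network(gut_network(toy_organisms(), toy_compounds(),
                                       asc2))
  expect_true("activity_class" %in% rep2$invariant)
  expect_true("NJC19_00001" %in% rep2$record_id)

  # microbe without a taxid, duplicate compound names, dangling refs
  org <- toy_organisms(); org$ncbi_taxid[2] <- NA
  cmp <- toy_compounds(); cmp$name[3] <- "glucose"
  asc3 <- toy_associations()[1:2, ]; asc3$organism_id[2] <- "NOPE"
  rep3 <- validate_network(gut_network(org, cmp, asc3))
  expect_setequal(rep3$invariant,
                  c("microbe_taxid", "compound_name_unique",
                    "association_resolves"))
})

test_that("strain consolidation pools annotations into one species organism", {
  strains <- tibble::tibble(
    organism_id = c("S1", "S2"),
    name = c("Lactobacillus reuteri DSM1", "Lactobacillus reuteri DSM2"),
    ncbi_taxid = c(9001L, 9002L),
    rank = "strain", kind = "microbe",
    lineage = list(c(genus = "Lactobacillus",
                     species = "Lactobacillus reuteri", strain = "DSM1"),
                   c(genus = "Lactobacillus",
                     species = "Lactobacillus reuteri", strain = "DSM2")),
    sample_sources = list("a", "b"))
  cmp <- toy_compounds()
  asc <- tibble::tibble(
    assoc_id = c("GEN_00001", "GEN_00002", "GEN_00003"),
    organism_id = c("S1", "S2", "S2"),
    compound_id = c("C1", "C2", "C1"),
    activity = c("import", "export", "import"),
    sign = "positive",
    refs = list("R1", "R2", "R3"),
    provenance = "direct")
  net <- gut_network(strains, cmp, asc)
  out <- consolidate_strains(net)

  expect_identical(nrow(out$organisms), 1L)
  expect_identical(out$organisms$name, "Lactobacillus reuteri")
  expect_identical(out$organisms$rank, "species")
  expect_identical(out$organisms$ncbi_taxid, 9001L)  # smallest strain taxid
  # union of strain features with the duplicate glucose import de-duplicated
  expect_identical(nrow(out$associations), 2L)
  glu <- out$associations[out$associations$compound_id == "C1", ]
  expect_setequal(glu$refs[[1]], c("R1", "R3"))  # refs merged
  expect_identical(nrow(validate_network(out)), 0L)

  # idempotence and no-strain identity
  expect_identical(assoc_signature(consolidate_strains(out)),
                   assoc_signature(out))
  expect_identical(consolidate_strains(toy_network()), toy_network())
})

test_that("strain consolidation surfaces opposite-sign conflicts", {
  strains <- tibble::tibble(
    organism_id = c("S1", "S2"),
    name = c("X y A", "X y B"), ncbi_taxid = c(1L, 2L),
    rank = "strain", kind = "microbe",
    lineage = list(c(species = "X y"), c(species = "X y")),
    sample_sources = list(character(), character()))
  asc <- tibble::tibble(
    assoc_id = c("GEN_00001", "GEN_00002"),
    organism_id = c("S1", "S2"), compound_id = "C1",
    activity = "import", sign = c("positive", "negative"),
    refs = list("R1", "R2"), provenance = "direct")
  net <- gut_network(strains, toy_compounds(), asc)
  expect_error(consolidate_strains(net), class = "gutnet_conflict_error")
})

test_that("degradation propagation adds indirect exports for every degrader x product", {
  net <- toy_network()
  out <- propagate_degradation(net)
  # one positive degrader (F. prausnitzii) x two products (glucose,
  # cellobiose) => 2 new indirect exports; the negative degrader gets none
  expect_identical(nrow(out$associations), nrow(net$associations) + 2L)
  new <- out$associations[out$associations$provenance ==
                            "indirect_degradation", ]
  expect_setequal(new$compound_id, c("C1", "C3"))
  expect_identical(unique(new$organism_id), "O3")
  expect_identical(unique(new$sign), "positive")
  expect_identical(nrow(validate_network(out)), 0L)

  # conservation: nothing removed, no sign changed
  expect_true(all(assoc_signature(net) %in% assoc_signature(out)))
  # idempotence
  expect_identical(assoc_signature(propagate_degradation(out)),
                   assoc_signature(out))
  # a pre-existing direct export suppresses the duplicate and keeps its
  # provenance
  asc <- dplyr::bind_rows(
    net$associations,
    tibble::tibble(assoc_id = "NJC19_00090", organism_id = "O3",
                   compound_id = "C1", activity = "export",
                   sign = "positive", refs = list("R1"),
                   provenance = "direct"))
  net2 <- gut_network(net$organisms, net$compounds, asc,
                      net$degradation_rules, net$references)
  out2 <- propagate_degradation(net2)
  expect_identical(nrow(out2$associations), nrow(asc) + 1L)
  kept <- out2$associations[out2$associations$assoc_id == "NJC19_00090", ]
  expect_identical(kept$provenance, "direct")

  # missing rule for a degraded macromolecule is an error
  net3 <- gut_network(net$organisms, net$compounds, net$associations)
  expect_error(propagate_degradation(net3),
               class = "gutnet_missing_rule_error")
})

test_that("propagation leaves every product's exporter set covering the degraders", {
  for (seed in 1:5) {
    net <- propagate_degradation(gen_network(small_gen_params(seed)))
    asc <- net$associations
    degraders <- split(
      asc$organism_id[asc$activity == "degradation" & asc$sign == "positive"],
      asc$compound_id[asc$activity == "degradation" & asc$sign == "positive"])
    exporters <- split(
      asc$organism_id[asc$activity == "export" & asc$sign == "positive"],
      asc$compound_id[asc$activity == "export" & asc$sign == "positive"])
    rules <- net$degradation_rules
    for (m in names(degraders)) {
      prods <- rules$products[[match(m, rules$compound_id)]]
      for (pr in prods) {
        # exhaustive subset scan, minus pairs vetoed by a negative export
        vetoed <- asc$organism_id[asc$activity == "export" &
                                    asc$sign == "negative" &
                                    asc$compound_id == pr]
        expect_true(all(setdiff(degraders[[m]], vetoed) %in%
                          exporters[[pr]]))
      }
    }
  }
})

test_that("network merge unifies shared nodes and is commutative with identity", {
  a <- toy_network()
  expect_identical(merge_networks(a, empty_network()), a)
  expect_identical(assoc_signature(merge_networks(empty_network(), a)),
                   assoc_signature(a))

  # second network shares glucose (same KEGG id) and E. coli (same taxid)
  b <- gut_network(
    tibble::tibble(
      organism_id = c("X1", "X2"),
      name = c("Escherichia coli", "Akkermansia muciniphila"),
      ncbi_taxid = c(562L, 239935L), rank = "species", kind = "microbe",
      lineage = list(c(genus = "Escherichia"), c(genus = "Akkermansia")),
      sample_sources = list(character(), character())),
    tibble::tibble(compound_id = c("K1", "K2"),
                   name = c("D-glucose", "propionate"),
                   kegg_cid = c("C00031", "C00163"),
                   klass = "small_molecule"),
    tibble::tibble(assoc_id = c("NJC19_00201", "NJC19_00202"),
                   organism_id = c("X2", "X1"),
                   compound_id = c("K1", "K2"),
                   activity = c("import", "export"), sign = "positive",
                   refs = list("R9", "R9"), provenance = "direct"),
    references = tibble::tibble(ref_key = "R9",
                                citation = "Synthetic citation nine"))
  m <- merge_networks(a, b)
  expect_identical(nrow(validate_network(m)), 0L)
  # glucose unified on its KEGG id: one node, importer set is the union
  glu <- m$compounds[m$compounds$kegg_cid == "C00031", ]
  expect_identical(nrow(glu), 1L)
  importers <- m$associations$organism_id[
    m$associations$compound_id == glu$compound_id &
      m$associations$activity == "import" & m$associations$sign == "positive"]
  expect_length(importers, 5L)  # O1, O2, O3, H1, Akkermansia
  # E. coli unified on taxid
  expect_identical(sum(m$organisms$ncbi_taxid == 562L, na.rm = TRUE), 1L)
  expect_identical(nrow(m$organisms), nrow(a$organisms) + 1L)
  # commutative up to record ordering
  expect_identical(sort(sub("D-glucose", "glucose",
                            assoc_signature(merge_networks(b, a)))),
                   sort(sub("D-glucose", "glucose", assoc_signature(m))))

  # opposite-sign duplicates across inputs are conflicts
  b2 <- b
  b2$associations$sign[1] <- "negative"
  b2$associations$organism_id[1] <- "X1"
  a2 <- a  # O2 (E. coli, taxid 562) imports glucose positively in `a`
  expect_error(merge_networks(a2, b2), class = "gutnet_conflict_error")
})

test_that("merging two disjoint halves of a generated network restores its association set", {
  net <- gen_network(small_gen_params(11))
  asc <- net$associations
  half <- seq_len(nrow(asc)) <= nrow(asc) / 2
  mk <- function(rows) gut_network(net$organisms, net$compounds, rows,
                                   net$degradation_rules, net$references)
  merged <- merge_networks(mk(asc[half, ]), mk(asc[!half, ]))
  expect_identical(assoc_signature(merged), assoc_signature(net))
})
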