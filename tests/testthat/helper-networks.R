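# Shared in-code fixtures: a hand-built toy network mirroring the JSON
# fixture under inst/extdata/toynet, plus small builders used across files.

toy_organisms <- function() {
  tibble::tibble(
    organism_id = c("O1", "O2", "O3", "H1"),
    name = c("Bacteroides fragilis", "Escherichia coli",
             "Faecalibacterium prausnitzii", "intestinal absorptive cell"),
    ncbi_taxid = c(817L, 562L, 853L, NA),
    rank = c("species", "species", "species", "cell_type"),
    kind = c("microbe", "microbe", "microbe", "host_cell"),
    lineage = list(
      c(domain = "Bacteria", phylum = "Bacteroidetes",
        genus = "Bacteroides", species = "Bacteroides fragilis"),
      c(domain = "Bacteria", phylum = "Proteobacteria",
        genus = "Escherichia", species = "Escherichia coli"),
      c(domain = "Bacteria", phylum = "Firmicutes",
        genus = "Faecalibacterium",
        species = "Faecalibacterium prausnitzii"),
      character()),
    sample_sources = list("mouse cecum", c("mouse feces", "human feces"),
                          "human feces", character()))
}

toy_compounds <- function() {
  tibble::tibble(
    compound_id = c("C1", "C2", "C3", "C4"),
    name = c("glucose", "acetate", "cellobiose", "cellulose"),
    kegg_cid = c("C00031", "C00033", "C00185", "C00760"),
    klass = c("small_molecule", "small_molecule", "small_molecule",
              "macromolecule"))
}

toy_associations <- function() {
  tibble::tibble(
    assoc_id = sprintf("NJC19_%05d", 1:10),
    organism_id = c("O1", "O1", "O2", "O2", "O3", "O3", "O2", "H1", "O1",
                    "O3"),
    compound_id = c("C1", "C2", "C1", "C2", "C4", "C2", "C3", "C1", "C4",
                    "C1"),
    activity = c("import", "export", "import", "export", "degradation",
                 "export", "import", "import", "degradation", "import"),
    sign = c(rep("positive", 6), "negative", "positive", "negative",
             "positive"),
    refs = list("R1", c("R1", "R2"), "R2", "R2", "R3", "R3", "R1", "R4",
                "R3", c("R3", "R4")),
    provenance = "direct")
}

toy_network <- function() {
  gut_network(
    toy_organisms(), toy_compounds(), toy_associations(),
    degradation_rules = tibble::tibble(compound_id = "C4",
                                       products = list(c("C1", "C3"))),
    references = tibble::tibble(
      ref_key = c("R1", "R2", "R3", "R4"),
      citation = paste("Synthetic citation", c("one", "two", "three",
                                               "four"))))
}

fixture_dir <- function() {
  system.file("extdata", "toynet", package = "gutnet")
}

read_toynet <- function() {
  d <- fixture_dir()
  read_network_json(file.path(d, "network.json"),
                    file.path(d, "organism.json"),
                    file.path(d, "compound.json"),
                    file.path(d, "reference.json"))
}

# canonical multiset signature of a network's associations, independent of
# internal ids
assoc_signature <- function(net) {
  org <- setNames(net$organisms$name, net$organisms$organism_id)
  cmp <- setNames(net$compounds$name, net$compounds$compound_id)
  a <- net$associations
  sort(paste(org[a$organism_id], cmp[a$compound_id], a$activity, a$sign))
}

small_gen_params <- function(seed, n_species = 40L, n_metabolites = 25L,
                             n_macromolecules = 3L) {
  network_gen_params(n_species = n_species, n_metabolites = n_metabolites,
                     n_macromolecules = n_macromolecules, seed = seed)
}

# abundance/metabolite builders for hand-computed cases
make_abundance <- function(df, rank = "species") {
  abundance_table(df, rank = rank)
}
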