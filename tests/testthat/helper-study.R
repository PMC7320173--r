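# a small hand-built study: 4 genera pool, abundances chosen so fold
# changes are easy to enumerate by hand
study_fixture <- function() {
  taxa <- c("GenA", "GenB", "GenC", "GenD")
  ab <- abundance_table(tibble::tibble(
    sample_id = rep(c("I_1", "I_2", "II_1", "II_2"), each = 4),
    group = rep(c("I", "I", "II", "II"), each = 4),
    taxon = rep(taxa, 4),
    abundance = c(0.40, 0.30, 0.20, 0.10,
                  0.40, 0.30, 0.20, 0.10,
                  0.10, 0.20, 0.30, 0.40,
                  0.10, 0.20, 0.30, 0.40)), rank = "genus")
  mb <- metabolite_table(tibble::tibble(
    group = rep(c("I", "II"), each = 2),
    replicate = rep(1:2, 2),
    metabolite = "butyrate",
    concentration = c(2.0, 2.0, 1.0, 1.0)))
  list(ab = ab, mb = mb, taxa = taxa)
}

fake_producer_set <- function(metabolite, taxa, pool,
                              direction = "export") {
  structure(list(metabolite = metabolite, rank = "genus",
                 direction = direction, taxa = sort(taxa),
                 candidate_pool = pool),
            class = "producer_set")
}
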