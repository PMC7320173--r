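#' Construct a bipartite organism-compound network
#'
#' A `gut_network` holds the two node catalogues (organisms and chemical
#' compounds), the signed metabolic associations joining them, macromolecule
#' degradation rules and the literature reference list. Organisms are
#' microbial species/strains/genera or host cell types; compounds are small
#' molecules or macromolecules; associations record an import, export or
#' degradation activity with a positive sign (observed) or a negative sign
#' (reported as not transportable/degradable).
#'
#' @param organisms tibble with columns `organism_id`, `name`,
#'   `ncbi_taxid` (integer, `NA` for host cells), `rank` (one of
#'   `"species"`, `"genus"`, `"strain"`, `"cell_type"`), `kind` (`"microbe"`
#'   or `"host_cell"`), `lineage` (list column of named character vectors,
#'   e.g. `c(domain = "Bacteria", phylum = "Bacteroidetes", genus =
#'   "Bacteroides")`) and `sample_sources` (list column of character).
#' @param compounds tibble with columns `compound_id`, `name`, `kegg_cid`
#'   (character or `NA`) and `klass` (`"small_molecule"` or
#'   `"macromolecule"`).
#' @param associations tibble with columns `assoc_id`, `organism_id`,
#'   `compound_id`, `activity` (`"import"`, `"export"`, `"degradation"`),
#'   `sign` (`"positive"`, `"negative"`), `refs` (list column of reference
#'   keys) and `provenance` (`"direct"` or `"indirect_degradation"`).
#' @param degradation_rules tibble with columns `compound_id` (the
#'   macromolecule) and `products` (list column of small-molecule compound
#'   ids).
#' @param references tibble with columns `ref_key` and `citation`.
#' @param meta named list of free-form metadata.
#'
#' @return An object of class `gut_network`.
#' @seealso [validate_network()], [read_network_json()], [gen_network()]
#' @export
gut_network <- function(organisms = NULL, compounds = NULL,
                        associations = NULL, degradation_rules = NULL,
                        references = NULL, meta = list()) {
  structure(
    list(
      organisms = normalise_organisms(organisms),
      compounds = normalise_compounds(compounds),
      associations = normalise_associations(associations),
      degradation_rules = normalise_rules(degradation_rules),
      references = normalise_references(references),
      meta = meta
    ),
    class = "gut_network"
  )
}

#' An empty network
#' @return A valid `gut_network` with no records.
#' @export
empty_network <- function() gut_network()

normalise_organisms <- function(x) {
  if (is.null(x) || nrow(as_tibble(x)) == 0L) {
    return(tibble(organism_id = character(), name = character(),
                  ncbi_taxid = integer(), rank = character(),
                  kind = character(), lineage = list(),
                  sample_sources = list()))
  }
  x <- as_tibble(x)
  if (!"lineage" %in% names(x)) x$lineage <- rep(list(character()), nrow(x))
  if (!"sample_sources" %in% names(x)) {
    x$sample_sources <- rep(list(character()), nrow(x))
  }
  if (!"ncbi_taxid" %in% names(x)) x$ncbi_taxid <- NA_integer_
  x$ncbi_taxid <- as.integer(x$ncbi_taxid)
  select(x, all_of(c("organism_id", "name", "ncbi_taxid", "rank", "kind",
                     "lineage", "sample_sources")))
}

normalise_compounds <- function(x) {
  if (is.null(x) || nrow(as_tibble(x)) == 0L) {
    return(tibble(compound_id = character(), name = character(),
                  kegg_cid = character(), klass = character()))
  }
  x <- as_tibble(x)
  if (!"kegg_cid" %in% names(x)) x$kegg_cid <- NA_character_
  x$kegg_cid <- as.character(x$kegg_cid)
  select(x, all_of(c("compound_id", "name", "kegg_cid", "klass")))
}

normalise_associations <- function(x) {
  if (is.null(x) || nrow(as_tibble(x)) == 0L) {
    return(tibble(assoc_id = character(), organism_id = character(),
                  compound_id = character(), activity = character(),
                  sign = character(), refs = list(),
                  provenance = character()))
  }
  x <- as_tibble(x)
  if (!"refs" %in% names(x)) x$refs <- rep(list(character()), nrow(x))
  if (!"provenance" %in% names(x)) x$provenance <- "direct"
  select(x, all_of(c("assoc_id", "organism_id", "compound_id", "activity",
                     "sign", "refs", "provenance")))
}

normalise_rules <- function(x) {
  if (is.null(x) || nrow(as_tibble(x)) == 0L) {
    return(tibble(compound_id = character(), products = list()))
  }
  select(as_tibble(x), all_of(c("compound_id", "products")))
}

normalise_references <- function(x) {
  if (is.null(x) || nrow(as_tibble(x)) == 0L) {
    return(tibble(ref_key = character(), citation = character()))
  }
  select(as_tibble(x), all_of(c("ref_key", "citation")))
}

#' @export
print.gut_network <- function(x, ...) {
  n_neg <- sum(x$associations$sign == "negative")
  cat(sprintf(
    paste0("<gut_network> %d organisms (%d microbes), %d compounds ",
           "(%d macromolecules)\n  %d associations (%d positive, %d ",
           "negative), %d degradation rules, %d references\n"),
    nrow(x$organisms), sum(x$organisms$kind == "microbe"),
    nrow(x$compounds), sum(x$compounds$klass == "macromolecule"),
    nrow(x$associations), nrow(x$associations) - n_neg, n_neg,
    nrow(x$degradation_rules), nrow(x$references)))
  invisible(x)
}

is_gut_network <- function(x) inherits(x, "gut_network")

assert_network <- function(net) {
  if (!is_gut_network(net)) {
    stop_gutnet("gutnet_type_error", "`net` must be a <gut_network>.")
  }
  net
}

#' Validate a network against its schema invariants
#'
#' Checks every structural invariant of the data model: microbes must carry
#' an NCBI taxid, `(name, rank)` pairs are unique, host cells have rank
#' `cell_type`, compound names are unique, import/export associations point
#' at small molecules and degradation associations at macromolecules,
#' `(organism, compound, activity)` triples are unique with no opposite-sign
#' conflicts, association endpoints resolve, and degradation rules have
#' distinct products not containing their own substrate.
#'
#' Violations are reported, never raised: an invalid network can always be
#' inspected.
#'
#' @param net a [gut_network()].
#' @return A tibble with columns `invariant`, `record_id` and `message`,
#'   ordered by `record_id` then `invariant`; zero rows iff the network is
#'   valid.
#' @export
validate_network <- function(net) {
  assert_network(net)
  org <- net$organisms
  cmp <- net$compounds
  asc <- net$associations
  v <- list()
  add <- function(invariant, id, msg) {
    v[[length(v) + 1L]] <<- tibble(invariant = invariant, record_id = id,
                                   message = msg)
  }

  # organism invariants
  bad <- org$kind == "microbe" & is.na(org$ncbi_taxid)
  for (i in which(bad)) {
    add("microbe_taxid", org$organism_id[i],
        sprintf("microbe '%s' has no NCBI taxid", org$name[i]))
  }
  dup <- duplicated(paste(org$name, org$rank, sep = "\r"))
  for (i in which(dup)) {
    add("organism_name_rank_unique", org$organism_id[i],
        sprintf("duplicate organism (name='%s', rank='%s')",
                org$name[i], org$rank[i]))
  }
  bad <- org$kind == "host_cell" & org$rank != "cell_type"
  for (i in which(bad)) {
    add("host_cell_rank", org$organism_id[i],
        sprintf("host cell '%s' has rank '%s', expected 'cell_type'",
                org$name[i], org$rank[i]))
  }

  # compound invariants
  for (i in which(duplicated(cmp$name))) {
    add("compound_name_unique", cmp$compound_id[i],
        sprintf("duplicate compound name '%s'", cmp$name[i]))
  }

  # association invariants
  klass_of <- setNames(cmp$klass, cmp$compound_id)
  for (i in seq_len(nrow(asc))) {
    oid <- asc$organism_id[i]; cid <- asc$compound_id[i]
    if (!oid %in% org$organism_id) {
      add("association_resolves", asc$assoc_id[i],
          sprintf("organism '%s' not in catalogue", oid))
      next
    }
    if (!cid %in% cmp$compound_id) {
      add("association_resolves", asc$assoc_id[i],
          sprintf("compound '%s' not in catalogue", cid))
      next
    }
    kl <- klass_of[[cid]]
    act <- asc$activity[i]
    if (act == "degradation" && kl != "macromolecule") {
      add("activity_class", asc$assoc_id[i],
          sprintf("degradation of non-macromolecule '%s'", cid))
    }
    if (act %in% c("import", "export") && kl != "small_molecule") {
      add("activity_class", asc$assoc_id[i],
          sprintf("%s of non-small-molecule '%s'", act, cid))
    }
  }
  if (nrow(asc) > 1L) {
    key <- paste(asc$organism_id, asc$compound_id, asc$activity, sep = "\r")
    for (k in unique(key[duplicated(key)])) {
      rows <- asc[key == k, ]
      id <- max(rows$assoc_id)
      if (n_distinct(rows$sign) > 1L) {
        add("sign_conflict", id,
            sprintf("opposite signs for (%s, %s, %s)", rows$organism_id[1],
                    rows$compound_id[1], rows$activity[1]))
      } else {
        add("association_unique", id,
            sprintf("duplicate (%s, %s, %s)", rows$organism_id[1],
                    rows$compound_id[1], rows$activity[1]))
      }
    }
  }

  # degradation rules
  rules <- net$degradation_rules
  for (i in seq_len(nrow(rules))) {
    cid <- rules$compound_id[i]
    prods <- rules$products[[i]]
    if (!cid %in% cmp$compound_id) {
      add("rule_resolves", cid, "rule substrate not in catalogue")
      next
    }
    if (klass_of[[cid]] != "macromolecule") {
      add("rule_substrate_class", cid,
          "degradation rule substrate is not a macromolecule")
    }
    if (length(prods) == 0L) add("rule_products_nonempty", cid,
                                 "rule has no products")
    if (anyDuplicated(prods)) add("rule_products_distinct", cid,
                                  "duplicate products in rule")
    if (cid %in% prods) add("rule_not_self", cid,
                            "macromolecule listed among its own products")
    miss <- setdiff(prods, cmp$compound_id)
    if (length(miss)) {
      add("rule_resolves", cid,
          sprintf("product(s) not in catalogue: %s",
                  paste(miss, collapse = ", ")))
    }
  }

  out <- if (length(v)) bind_rows(v) else {
    tibble(invariant = character(), record_id = character(),
           message = character())
  }
  arrange(out, .data$record_id, .data$invariant)
}

# Union association rows that agree on (organism, compound, activity, sign),
# merging their reference lists; raise a classed error on opposite signs.
dedupe_associations <- function(asc, conflict_context = "network") {
  if (nrow(asc) == 0L) return(asc)
  key3 <- paste(asc$organism_id, asc$compound_id, asc$activity, sep = "\r")
  signs <- split(asc$sign, key3)
  confl <- names(signs)[vapply(signs, function(s) n_distinct(s) > 1L,
                               logical(1))]
  if (length(confl)) {
    parts <- strsplit(confl, "\r", fixed = TRUE)
    detail <- paste(vapply(parts, function(p)
      sprintf("(%s, %s, %s)", p[1], p[2], p[3]), character(1)),
      collapse = "; ")
    stop_gutnet("gutnet_conflict_error",
                sprintf("opposite-sign associations in %s: %s",
                        conflict_context, detail))
  }
  grp <- match(key3, unique(key3))
  keep <- !duplicated(grp)
  merged_refs <- lapply(split(asc$refs, grp), function(r)
    sort(unique(unlist(r))))
  out <- asc[keep, ]
  out$refs <- merged_refs[as.character(grp[keep])]
  out
}

#' Consolidate strain-level records into their parent species
#'
#' All metabolite transport and macromolecule degradation annotations made at
#' strain rank are pooled into a single species-rank organism per species, as
#' the species' collective metabolic feature. The consolidated association
#' set is the union over strains, with duplicate evidence lines merged (their
#' references pooled). Strains must name their parent species in `lineage`
#' (key `"species"`).
#'
#' @param net a [gut_network()].
#' @return A new `gut_network` with no strain-rank organisms. Applying the
#'   operation twice is the identity.
#' @section Errors: `gutnet_conflict_error` if two strains contribute
#'   opposite signs for the same (compound, activity).
#' @export
consolidate_strains <- function(net) {
  assert_network(net)
  org <- net$organisms
  strains <- which(org$rank == "strain")
  if (length(strains) == 0L) return(net)

  sp_name <- vapply(org$lineage[strains], function(l) {
    if (!"species" %in% names(l)) NA_character_ else l[["species"]]
  }, character(1))
  if (anyNA(sp_name)) {
    stop_gutnet("gutnet_lineage_error",
                "every strain must carry its parent species in `lineage`")
  }

  asc <- net$associations
  new_orgs <- list()
  id_map <- character(0)
  for (sp in unique(sp_name)) {
    members <- strains[sp_name == sp]
    existing <- which(org$rank == "species" & org$name == sp)
    if (length(existing)) {
      target_id <- org$organism_id[existing[1]]
      target_row <- org[existing[1], ]
    } else {
      target_id <- org$organism_id[members[1]]
      lin <- org$lineage[[members[1]]]
      lin <- lin[setdiff(names(lin), "strain")]
      lin[["species"]] <- sp
      target_row <- tibble(
        organism_id = target_id, name = sp,
        ncbi_taxid = min(org$ncbi_taxid[members]),
        rank = "species", kind = org$kind[members[1]],
        lineage = list(lin), sample_sources = list(character()))
    }
    target_row$sample_sources <- list(sort(unique(unlist(
      c(target_row$sample_sources, org$sample_sources[members])))))
    new_orgs[[sp]] <- target_row
    id_map[org$organism_id[members]] <- target_id
  }

  keep <- org[-strains, ]
  # drop species rows that were re-built with merged sample sources
  rebuilt <- vapply(new_orgs, function(r) r$organism_id, character(1))
  keep <- keep[!keep$organism_id %in% rebuilt, ]
  org_out <- bind_rows(keep, bind_rows(new_orgs))

  hit <- asc$organism_id %in% names(id_map)
  asc$organism_id[hit] <- unname(id_map[asc$organism_id[hit]])
  asc <- dedupe_associations(asc, "strain consolidation")

  gut_network(org_out, net$compounds, asc, net$degradation_rules,
              net$references, net$meta)
}

#' Propagate macromolecule degradation products as indirect exports
#'
#' Macromolecule degradation in the gut releases small-molecule products into
#' the shared environment, so every organism with a positive degradation
#' association for a macromolecule is treated as an indirect exporter of each
#' of that macromolecule's degradation products. New export associations are
#' added with `provenance = "indirect_degradation"`, inheriting the
#' degradation association's references. Pairs that already have any export
#' association (direct, indirect, or a negative "cannot export" statement)
#' are left untouched.
#'
#' @param net a [gut_network()].
#' @return A new `gut_network`; never removes or re-signs a record, and is
#'   idempotent.
#' @section Errors: `gutnet_missing_rule_error` if a positively degraded
#'   macromolecule has no degradation rule.
#' @export
propagate_degradation <- function(net) {
  assert_network(net)
  asc <- net$associations
  deg <- asc[asc$activity == "degradation" & asc$sign == "positive", ]
  if (nrow(deg) == 0L) return(net)

  rules <- net$degradation_rules
  miss <- setdiff(unique(deg$compound_id), rules$compound_id)
  if (length(miss)) {
    stop_gutnet("gutnet_missing_rule_error",
                sprintf("no degradation rule for macromolecule(s): %s",
                        paste(miss, collapse = ", ")))
  }
  products <- setNames(rules$products, rules$compound_id)

  cand <- tidyr::unnest(
    tibble(organism_id = deg$organism_id, refs = deg$refs,
           product = products[deg$compound_id]),
    "product")
  if (nrow(cand)) {
    # one candidate per (organism, product); pool refs across macromolecules
    key <- paste(cand$organism_id, cand$product, sep = "\r")
    grp <- match(key, unique(key))
    refs <- lapply(split(cand$refs, grp), function(r) sort(unique(unlist(r))))
    cand <- cand[!duplicated(grp), c("organism_id", "product")]
    cand$refs <- refs[as.character(unique(grp))]
    have <- asc[asc$activity == "export", c("organism_id", "compound_id")]
    cand <- anti_join(
      rename(cand, compound_id = "product"), have,
      by = c("organism_id", "compound_id"))
  }
  if (nrow(cand) == 0L) return(net)

  new_asc <- tibble(
    assoc_id = next_ids(asc$assoc_id, nrow(cand)),
    organism_id = cand$organism_id, compound_id = cand$compound_id,
    activity = "export", sign = "positive", refs = cand$refs,
    provenance = "indirect_degradation")
  gut_network(net$organisms, net$compounds, bind_rows(asc, new_asc),
              net$degradation_rules, net$references, net$meta)
}

#' Merge two curated networks through their shared organisms and compounds
#'
#' Organisms are unified on NCBI taxid (falling back to name + rank when a
#' taxid is absent), compounds on KEGG compound id (falling back to name).
#' Associations are unioned with duplicate evidence merged; reference keys
#' whose citations clash are renumbered deterministically (stable order by
#' citation text). Merging with [empty_network()] is the identity, and the
#' merged association set is independent of argument order.
#'
#' @param a,b two [gut_network()] objects, individually valid.
#' @return The merged `gut_network`.
#' @section Errors: `gutnet_conflict_error` when the inputs carry
#'   opposite-sign associations for the same (organism, compound, activity).
#' @export
merge_networks <- function(a, b) {
  assert_network(a); assert_network(b)
  if (nrow(b$organisms) == 0L && nrow(b$compounds) == 0L) return(a)
  if (nrow(a$organisms) == 0L && nrow(a$compounds) == 0L) return(b)

  org_key <- function(o) {
    ifelse(!is.na(o$ncbi_taxid), paste0("taxid:", o$ncbi_taxid),
           paste0("name:", o$name, "\r", o$rank))
  }
  cmp_key <- function(cm) {
    ifelse(!is.na(cm$kegg_cid), paste0("kegg:", cm$kegg_cid),
           paste0("name:", cm$name))
  }

  ka <- org_key(a$organisms); kb <- org_key(b$organisms)
  org_map <- setNames(a$organisms$organism_id, ka)[kb]        # b id -> a id
  org_out <- a$organisms
  new_b <- b$organisms[is.na(org_map), ]
  # avoid id collisions between unrelated records
  clash <- new_b$organism_id %in% org_out$organism_id
  if (any(clash)) {
    new_b$organism_id[clash] <- next_ids(
      c(org_out$organism_id, new_b$organism_id), sum(clash), "ORG_")
  }
  borg_map <- character(nrow(b$organisms))
  borg_map[!is.na(org_map)] <- org_map[!is.na(org_map)]
  borg_map[is.na(org_map)] <- new_b$organism_id
  names(borg_map) <- b$organisms$organism_id
  org_out <- bind_rows(org_out, new_b)

  kca <- cmp_key(a$compounds); kcb <- cmp_key(b$compounds)
  cmp_map <- setNames(a$compounds$compound_id, kca)[kcb]
  cmp_out <- a$compounds
  new_bc <- b$compounds[is.na(cmp_map), ]
  clash <- new_bc$compound_id %in% cmp_out$compound_id
  if (any(clash)) {
    new_bc$compound_id[clash] <- next_ids(
      c(cmp_out$compound_id, new_bc$compound_id), sum(clash), "CMP_")
  }
  bcmp_map <- character(nrow(b$compounds))
  bcmp_map[!is.na(cmp_map)] <- cmp_map[!is.na(cmp_map)]
  bcmp_map[is.na(cmp_map)] <- new_bc$compound_id
  names(bcmp_map) <- b$compounds$compound_id
  cmp_out <- bind_rows(cmp_out, new_bc)

  # references: identical (key, citation) pairs collapse; clashing keys from b
  # are renumbered in stable citation-text order
  refs_a <- a$references; refs_b <- b$references
  ref_map <- setNames(refs_b$ref_key, refs_b$ref_key)
  clash <- refs_b$ref_key %in% refs_a$ref_key &
    !paste(refs_b$ref_key, refs_b$citation, sep = "\r") %in%
      paste(refs_a$ref_key, refs_a$citation, sep = "\r")
  if (any(clash)) {
    ord <- order(refs_b$citation[clash])
    newk <- next_ids(c(refs_a$ref_key, refs_b$ref_key), sum(clash), "REF_")
    ref_map[which(clash)[ord]] <- newk
  }
  refs_b$ref_key <- unname(ref_map[refs_b$ref_key])
  refs_out <- distinct(bind_rows(refs_a, refs_b), .data$ref_key,
                       .keep_all = TRUE)

  asc_b <- b$associations
  asc_b$organism_id <- unname(borg_map[asc_b$organism_id])
  asc_b$compound_id <- unname(bcmp_map[asc_b$compound_id])
  asc_b$refs <- lapply(asc_b$refs, function(r) unname(ref_map[r]))
  clash <- asc_b$assoc_id %in% a$associations$assoc_id
  if (any(clash)) {
    asc_b$assoc_id[clash] <- next_ids(
      c(a$associations$assoc_id, asc_b$assoc_id), sum(clash))
  }
  asc_out <- dedupe_associations(bind_rows(a$associations, asc_b),
                                 "merge")

  rules <- bind_rows(
    a$degradation_rules,
    mutate(b$degradation_rules,
           compound_id = unname(bcmp_map[.data$compound_id]),
           products = lapply(.data$products,
                             function(p) unname(bcmp_map[p]))))
  if (nrow(rules)) {
    rules <- summarise(group_by(rules, .data$compound_id),
                       products = list(sort(unique(unlist(.data$products)))),
                       .groups = "drop")
  }

  gut_network(org_out, cmp_out, asc_out, rules, refs_out,
              c(a$meta, b$meta))
}
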