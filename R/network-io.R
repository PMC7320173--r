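#' @section JSON dialect:
#' The curated-network JSON dialect spreads a network over four files. The
#' network file is an array of association objects, each carrying an `"id"`
#' of the form `"NJC19_"` (or, for generated records, `"GEN_"`) followed by
#' five digits, plus the four keys `"Species"`,
#' `"Small-molecule metabolite or macromolecule"`, `"Metabolic activity"`
#' and `"Ref. #"`. The organism, compound and reference files catalogue the
#' values those keys may take, annotated with NCBI taxonomy ids, KEGG
#' compound ids and citation text respectively. Macromolecule entries in the
#' compound file list their degradation products.
#' @name njc19-dialect
#' @keywords internal
NULL

NETWORK_KEYS <- c("id", "Species",
                  "Small-molecule metabolite or macromolecule",
                  "Metabolic activity", "Ref. #")
ID_PATTERN <- "^[A-Za-z0-9]+_[0-9]{5}$"

# "not-import" -> sign negative, activity import; the dialect map rewrites
# non-canonical tokens (e.g. "uptake" = "import") before this split.
parse_activity <- function(token, dialect = NULL, id = "?") {
  token <- trimws(token)
  if (!is.null(dialect) && token %in% names(dialect)) {
    token <- unname(dialect[[token]])
  }
  neg <- grepl("^not-", token)
  act <- sub("^not-", "", token)
  if (!act %in% c("import", "export", "degradation")) {
    stop_gutnet("gutnet_schema_error",
                sprintf("object '%s': unknown metabolic activity token '%s'",
                        id, token))
  }
  list(activity = act, sign = if (neg) "negative" else "positive")
}

format_activity <- function(activity, sign) {
  paste0(ifelse(sign == "negative", "not-", ""), activity)
}

#' Read a curated network from its four JSON files
#'
#' Parses the four-file JSON dialect (see [njc19-dialect]) into a
#' [gut_network()]. Every association object must hold the canonical four
#' keys and an id matching the `PREFIX_#####` grammar; organisms and
#' compounds named in the network file must appear in the side files.
#'
#' @param network_path,organism_path,compound_path,reference_path paths to
#'   the four JSON files.
#' @param dialect optional named character vector aliasing non-canonical
#'   `"Metabolic activity"` tokens to the canonical set `import`, `export`,
#'   `degradation`, optionally `not-` prefixed (e.g.
#'   `c("uptake" = "import")`).
#' @return A `gut_network` that passes [validate_network()]; association
#'   count equals the number of JSON objects.
#' @section Errors: `gutnet_schema_error` naming the first offending object
#'   id; `gutnet_crossref_error` when a network object names an organism or
#'   compound absent from the side files.
#' @export
read_network_json <- function(network_path, organism_path, compound_path,
                              reference_path, dialect = NULL) {
  objs <- jsonlite::read_json(network_path)
  orgs <- jsonlite::read_json(organism_path)
  cmps <- jsonlite::read_json(compound_path)
  refs <- jsonlite::read_json(reference_path)

  organisms <- tibble(
    organism_id = sprintf("ORG_%05d", seq_along(orgs)),
    name = vapply(orgs, function(o) chr1(o[["Species"]]), character(1)),
    ncbi_taxid = vapply(orgs, function(o) {
      tx <- o[["NCBI taxonomy ID"]]
      if (is.null(tx)) NA_integer_ else as.integer(tx)
    }, integer(1)),
    rank = vapply(orgs, function(o) chr1(o[["Rank"]] %||% "species"),
                  character(1)),
    kind = vapply(orgs, function(o) chr1(o[["Kind"]] %||% "microbe"),
                  character(1)),
    lineage = lapply(orgs, function(o) {
      lin <- o[["Lineage"]]
      if (is.null(lin)) character() else unlist(lin)
    }),
    sample_sources = lapply(orgs, function(o) {
      as.character(unlist(o[["Sample sources"]]))
    })
  )

  compounds <- tibble(
    compound_id = sprintf("CMP_%05d", seq_along(cmps)),
    name = vapply(cmps, function(cc) chr1(cc[["Compound"]]), character(1)),
    kegg_cid = vapply(cmps, function(cc) {
      k <- cc[["KEGG compound ID"]]
      if (is.null(k)) NA_character_ else chr1(k)
    }, character(1)),
    klass = vapply(cmps, function(cc) {
      sub(" ", "_", chr1(cc[["Class"]] %||% "small molecule"))
    }, character(1))
  )
  cmp_id <- setNames(compounds$compound_id, compounds$name)
  org_id <- setNames(organisms$organism_id, organisms$name)

  rules <- purrr::compact(lapply(seq_along(cmps), function(i) {
    prods <- unlist(cmps[[i]][["Degradation products"]])
    if (is.null(prods)) return(NULL)
    miss <- setdiff(prods, compounds$name)
    if (length(miss)) {
      stop_gutnet("gutnet_crossref_error",
                  sprintf("degradation product(s) of '%s' not in compound file: %s",
                          compounds$name[i], paste(miss, collapse = ", ")))
    }
    tibble(compound_id = compounds$compound_id[i],
           products = list(unname(cmp_id[prods])))
  }))
  rules <- if (length(rules)) bind_rows(rules) else NULL

  references <- tibble(
    ref_key = vapply(refs, function(r) chr1(r[["Ref. #"]]), character(1)),
    citation = vapply(refs, function(r) chr1(r[["Citation"]] %||% ""),
                      character(1))
  )

  rows <- lapply(seq_along(objs), function(i) {
    o <- objs[[i]]
    id <- chr1(o[["id"]] %||% sprintf("<object %d>", i))
    missing_keys <- setdiff(NETWORK_KEYS, names(o))
    if (length(missing_keys)) {
      stop_gutnet("gutnet_schema_error",
                  sprintf("object '%s' missing key(s): %s", id,
                          paste(sprintf('"%s"', missing_keys),
                                collapse = ", ")))
    }
    if (!grepl(ID_PATTERN, id)) {
      stop_gutnet("gutnet_schema_error",
                  sprintf("object '%s': id does not match the PREFIX_##### grammar",
                          id))
    }
    sp <- chr1(o[["Species"]])
    cm <- chr1(o[["Small-molecule metabolite or macromolecule"]])
    if (!sp %in% organisms$name) {
      stop_gutnet("gutnet_crossref_error",
                  sprintf("object '%s': organism '%s' not in organism file",
                          id, sp))
    }
    if (!cm %in% compounds$name) {
      stop_gutnet("gutnet_crossref_error",
                  sprintf("object '%s': compound '%s' not in compound file",
                          id, cm))
    }
    act <- parse_activity(chr1(o[["Metabolic activity"]]), dialect, id)
    rk <- o[["Ref. #"]]
    rk <- if (is.null(rk)) character() else
      trimws(unlist(strsplit(as.character(unlist(rk)), ";", fixed = TRUE)))
    tibble(assoc_id = id, organism_id = unname(org_id[[sp]]),
           compound_id = unname(cmp_id[[cm]]), activity = act$activity,
           sign = act$sign, refs = list(rk[nzchar(rk)]),
           provenance = chr1(o[["Provenance"]] %||% "direct"))
  })
  associations <- if (length(rows)) bind_rows(rows) else NULL

  gut_network(organisms, compounds, associations, rules, references)
}

#' Write a network to the four-file JSON dialect
#'
#' The inverse of [read_network_json()]: emits `network.json`,
#' `organism.json`, `compound.json` and `reference.json` under `out_dir`.
#' Records are sorted (associations by id, organisms and compounds by name,
#' references by key) so repeated writes are byte-identical and round-trips
#' preserve the association set.
#'
#' @param net a valid [gut_network()].
#' @param out_dir output directory, created if needed.
#' @return Named character vector of the four paths (`network`, `organism`,
#'   `compound`, `reference`), invisibly.
#' @export
write_network_json <- function(net, out_dir) {
  assert_network(net)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  org <- arrange(net$organisms, .data$name)
  cmp <- arrange(net$compounds, .data$name)
  asc <- arrange(net$associations, .data$assoc_id)
  refs <- arrange(net$references, .data$ref_key)
  org_name <- setNames(org$name, org$organism_id)
  cmp_name <- setNames(cmp$name, cmp$compound_id)
  rule_products <- setNames(net$degradation_rules$products,
                            net$degradation_rules$compound_id)

  net_objs <- lapply(seq_len(nrow(asc)), function(i) {
    o <- list(
      id = asc$assoc_id[i],
      Species = unname(org_name[[asc$organism_id[i]]]),
      `Small-molecule metabolite or macromolecule` =
        unname(cmp_name[[asc$compound_id[i]]]),
      `Metabolic activity` = format_activity(asc$activity[i], asc$sign[i]),
      `Ref. #` = as.list(asc$refs[[i]]),
      Provenance = asc$provenance[i])
    o
  })
  org_objs <- lapply(seq_len(nrow(org)), function(i) {
    host <- org$kind[i] == "host_cell"
    list(
      Species = org$name[i],
      `NCBI taxonomy ID` = if (is.na(org$ncbi_taxid[i])) NULL else
        org$ncbi_taxid[i],
      `Cell type` = if (host) org$name[i] else NULL,
      Rank = org$rank[i],
      Kind = org$kind[i],
      Lineage = as.list(org$lineage[[i]]),
      `Sample sources` = as.list(org$sample_sources[[i]]))
  })
  cmp_objs <- lapply(seq_len(nrow(cmp)), function(i) {
    prods <- rule_products[[cmp$compound_id[i]]]
    list(
      Compound = cmp$name[i],
      `KEGG compound ID` = if (is.na(cmp$kegg_cid[i])) NULL else
        cmp$kegg_cid[i],
      Class = sub("_", " ", cmp$klass[i]),
      `Degradation products` = if (is.null(prods)) NULL else
        as.list(unname(cmp_name[prods])))
  })
  ref_objs <- lapply(seq_len(nrow(refs)), function(i) {
    list(`Ref. #` = refs$ref_key[i], Citation = refs$citation[i])
  })

  paths <- c(network = file.path(out_dir, "network.json"),
             organism = file.path(out_dir, "organism.json"),
             compound = file.path(out_dir, "compound.json"),
             reference = file.path(out_dir, "reference.json"))
  dump <- function(x, path) {
    json <- jsonlite::toJSON(x, auto_unbox = TRUE, pretty = 2, digits = NA,
                             null = "null")
    writeLines(json, path, useBytes = TRUE)
  }
  dump(net_objs, paths[["network"]])
  dump(org_objs, paths[["organism"]])
  dump(cmp_objs, paths[["compound"]])
  dump(ref_objs, paths[["reference"]])
  invisible(paths)
}

#' Flatten a network to the supplementary association table
#'
#' One row per association, with exactly the four canonical columns of the
#' published association table. Negative associations carry a `not-` prefix
#' on the activity token; multiple references are `"; "`-delimited.
#'
#' @param net a valid [gut_network()].
#' @return A tibble with columns `Species`,
#'   `Small-molecule metabolite or macromolecule`, `Metabolic activity` and
#'   `Ref. #`, one row per association.
#' @export
network_to_table <- function(net) {
  assert_network(net)
  asc <- arrange(net$associations, .data$assoc_id)
  org_name <- setNames(net$organisms$name, net$organisms$organism_id)
  cmp_name <- setNames(net$compounds$name, net$compounds$compound_id)
  tibble(
    Species = unname(org_name[asc$organism_id]),
    `Small-molecule metabolite or macromolecule` =
      unname(cmp_name[asc$compound_id]),
    `Metabolic activity` = format_activity(asc$activity, asc$sign),
    `Ref. #` = vapply(asc$refs, paste, character(1), collapse = "; "))
}

#' Rebuild a network from an association table and a catalogue template
#'
#' Inverse of [network_to_table()]: given the four-column association table
#' and a network supplying the organism/compound/reference catalogues and
#' degradation rules, reconstructs the association set. Association ids are
#' regenerated in the `GEN_#####` namespace.
#'
#' @param tbl a tibble as returned by [network_to_table()].
#' @param template a [gut_network()] whose catalogues resolve every name in
#'   `tbl`.
#' @param dialect optional activity-token alias map (see
#'   [read_network_json()]).
#' @return A `gut_network`.
#' @export
table_to_network <- function(tbl, template, dialect = NULL) {
  assert_network(template)
  org_id <- setNames(template$organisms$organism_id, template$organisms$name)
  cmp_id <- setNames(template$compounds$compound_id, template$compounds$name)
  n <- nrow(tbl)
  miss_o <- setdiff(tbl$Species, names(org_id))
  if (length(miss_o)) {
    stop_gutnet("gutnet_crossref_error",
                sprintf("organism(s) not in template: %s",
                        paste(miss_o, collapse = ", ")))
  }
  cms <- tbl[["Small-molecule metabolite or macromolecule"]]
  miss_c <- setdiff(cms, names(cmp_id))
  if (length(miss_c)) {
    stop_gutnet("gutnet_crossref_error",
                sprintf("compound(s) not in template: %s",
                        paste(miss_c, collapse = ", ")))
  }
  acts <- lapply(tbl[["Metabolic activity"]], parse_activity, dialect = dialect)
  asc <- tibble(
    assoc_id = next_ids(character(), n),
    organism_id = unname(org_id[tbl$Species]),
    compound_id = unname(cmp_id[cms]),
    activity = vapply(acts, `[[`, character(1), "activity"),
    sign = vapply(acts, `[[`, character(1), "sign"),
    refs = lapply(tbl[["Ref. #"]], function(r) {
      r <- trimws(unlist(strsplit(r, ";", fixed = TRUE)))
      r[nzchar(r)]
    }),
    provenance = "direct")
  gut_network(template$organisms, template$compounds, asc,
              template$degradation_rules, template$references)
}
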