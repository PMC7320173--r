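#' Bipartite degree sequences
#'
#' For the organism side, the degree of a microbial species is the number of
#' distinct small molecules it imports (or exports) through a positive
#' association; for the compound side, the degree of a small molecule is the
#' number of microbial species importing (or exporting) it. Degrees count
#' only positive small-molecule transport associations — degradation links,
#' negative statements and duplicate evidence lines do not contribute.
#' Entities with no link of the requested direction are listed with degree
#' zero, so total degree is conserved across the two sides.
#'
#' @param net a valid [gut_network()].
#' @param direction `"import"` or `"export"`.
#' @param include_host_cells count host cells as organisms (default:
#'   microbes only).
#' @return A tibble of class `degree_seq` with columns `entity_id`, `name`
#'   and `k`, and attributes `side` and `direction`.
#' @export
organism_degrees <- function(net, direction = c("import", "export"),
                             include_host_cells = FALSE) {
  direction <- match.arg(direction)
  assert_network(net)
  org <- net$organisms
  if (!include_host_cells) org <- org[org$kind == "microbe", ]
  k <- transport_degrees(net, direction, by = "organism_id")
  out <- tibble(entity_id = org$organism_id, name = org$name,
                k = unname(k[org$organism_id]))
  out$k[is.na(out$k)] <- 0L
  structure(out, class = c("degree_seq", class(tibble())),
            side = "organism", direction = direction)
}

#' @rdname organism_degrees
#' @export
compound_degrees <- function(net, direction = c("import", "export"),
                             include_host_cells = FALSE) {
  direction <- match.arg(direction)
  assert_network(net)
  cmp <- net$compounds[net$compounds$klass == "small_molecule", ]
  k <- transport_degrees(net, direction, by = "compound_id",
                         include_host_cells = include_host_cells)
  out <- tibble(entity_id = cmp$compound_id, name = cmp$name,
                k = unname(k[cmp$compound_id]))
  out$k[is.na(out$k)] <- 0L
  structure(out, class = c("degree_seq", class(tibble())),
            side = "compound", direction = direction)
}

transport_degrees <- function(net, direction, by,
                              include_host_cells = FALSE) {
  asc <- net$associations
  sm <- net$compounds$compound_id[net$compounds$klass == "small_molecule"]
  keep_org <- if (include_host_cells) net$organisms$organism_id else
    net$organisms$organism_id[net$organisms$kind == "microbe"]
  asc <- asc[asc$activity == direction & asc$sign == "positive" &
               asc$compound_id %in% sm & asc$organism_id %in% keep_org, ]
  pairs <- unique(paste(asc$organism_id, asc$compound_id, sep = "\r"))
  side <- vapply(strsplit(pairs, "\r", fixed = TRUE), `[[`, character(1),
                 if (by == "organism_id") 1L else 2L)
  tb <- table(side)
  setNames(as.integer(tb), names(tb))
}

#' @export
print.degree_seq <- function(x, ...) {
  cat(sprintf("<degree_seq> %s-side %s degrees, %d entities, mean k = %.2f\n",
              attr(x, "side"), attr(x, "direction"), nrow(x), mean(x$k)))
  NextMethod()
}

#' Summarise bipartite degree statistics of a network
#'
#' Computes the per-side mean degrees, the maximum-degree entities and, for
#' each small molecule, the fraction of microbial species transporting it.
#' Organism-side means are taken over all microbial species including those
#' with degree zero (so the number of species is the divisor for fractions);
#' compound-side means are taken over small molecules with at least one link
#' of that direction, since most metabolites are never transported in a
#' given direction.
#'
#' @inheritParams organism_degrees
#' @return A list of class `degree_summary` with elements
#'   `organism_mean_import`, `organism_mean_export`,
#'   `compound_mean_import`, `compound_mean_export`, `n_species`, `top` (a
#'   tibble of maximum-degree entities per side/direction) and
#'   `compound_fractions` (k and k / n_species per compound and direction).
#' @export
degree_summary <- function(net, include_host_cells = FALSE) {
  seqs <- list(
    organism_import = organism_degrees(net, "import", include_host_cells),
    organism_export = organism_degrees(net, "export", include_host_cells),
    compound_import = compound_degrees(net, "import", include_host_cells),
    compound_export = compound_degrees(net, "export", include_host_cells))
  n_species <- nrow(seqs$organism_import)
  top <- bind_rows(lapply(names(seqs), function(nm) {
    s <- seqs[[nm]]
    if (nrow(s) == 0L) return(NULL)
    mutate(s[s$k == max(s$k), c("name", "k")],
           side = attr(s, "side"), direction = attr(s, "direction"))
  }))
  frac <- bind_rows(lapply(c("compound_import", "compound_export"),
                           function(nm) {
    s <- seqs[[nm]]
    tibble(compound = s$name, direction = attr(s, "direction"), k = s$k,
           fraction = if (n_species > 0) s$k / n_species else NA_real_)
  }))
  cmean <- function(s) if (any(s$k >= 1)) mean(s$k[s$k >= 1]) else NA_real_
  structure(list(
    organism_mean_import = mean(seqs$organism_import$k),
    organism_mean_export = mean(seqs$organism_export$k),
    compound_mean_import = cmean(seqs$compound_import),
    compound_mean_export = cmean(seqs$compound_export),
    n_species = n_species,
    top = top,
    compound_fractions = frac
  ), class = "degree_summary")
}

#' @export
print.degree_summary <- function(x, ...) {
  cat(sprintf(
    paste0("<degree_summary> %d microbial species\n",
           "  mean metabolites imported/exported per species: %.1f / %.1f\n",
           "  mean species importing/exporting per metabolite: %.1f / %.1f\n"),
    x$n_species, x$organism_mean_import, x$organism_mean_export,
    x$compound_mean_import, x$compound_mean_export))
  invisible(x)
}

new_degree_fit <- function(model, param, k_min, k_max, n_used, loglik,
                           method) {
  structure(list(model = model, param = param, k_min = k_min, k_max = k_max,
                 n_used = n_used, loglik = loglik, method = method),
            class = "degree_fit")
}

#' @export
print.degree_fit <- function(x, ...) {
  lab <- if (x$model == "exponential") "rate r" else "exponent gamma"
  cat(sprintf("<degree_fit> %s: %s = %.4f (k in [%d, %s], n = %d, logLik = %.2f)\n  method: %s\n",
              x$model, lab, x$param, x$k_min,
              if (is.finite(x$k_max)) x$k_max else "Inf", x$n_used,
              x$loglik, x$method))
  invisible(x)
}

#' @export
tidy.degree_fit <- function(x, ...) {
  tibble(term = if (x$model == "exponential") "r" else "gamma",
         estimate = x$param)
}

#' @export
glance.degree_fit <- function(x, ...) {
  tibble(model = x$model, estimate = x$param, k_min = x$k_min,
         k_max = x$k_max, n_used = x$n_used, logLik = x$loglik,
         method = x$method)
}

degree_values <- function(seq) {
  if (is.data.frame(seq)) seq$k else as.integer(seq)
}

#' Fit a discrete exponential (geometric) law to a degree sequence
#'
#' Maximum-likelihood fit of `P(k) proportional to exp(-r k)` on the support
#' `k >= k_min` — a shifted geometric distribution. The MLE has the closed
#' form `r = log(1 + 1 / (kbar - k_min))`, with `kbar` the mean of the
#' retained degrees. Zeros (and anything below `k_min`) are excluded, since
#' the law is fitted to the degree distribution of linked entities.
#'
#' @param seq a `degree_seq` (or a bare integer vector of degrees).
#' @param k_min lower support bound (default 1).
#' @return A `degree_fit` with [generics::tidy()] and [generics::glance()]
#'   methods.
#' @section Errors: `gutnet_degenerate_error` when all retained degrees
#'   equal `k_min` (the rate diverges); an ordinary error when fewer than 10
#'   degrees remain.
#' @export
fit_exponential <- function(seq, k_min = 1L) {
  k <- degree_values(seq)
  x <- k[k >= k_min]
  if (length(x) < 10L) {
    stop_gutnet("gutnet_data_error",
                "need at least 10 degrees >= k_min to fit")
  }
  if (all(x == k_min)) {
    stop_gutnet("gutnet_degenerate_error",
                "all degrees equal k_min; the exponential rate diverges")
  }
  kbar <- mean(x)
  r <- log(1 + 1 / (kbar - k_min))
  q <- exp(-r)
  loglik <- length(x) * log(1 - q) - r * sum(x - k_min)
  new_degree_fit("exponential", r, as.integer(k_min), Inf, length(x),
                 loglik, "discrete MLE, closed form, zeros excluded")
}

powerlaw_negloglik <- function(gamma, x, k_min, k_max) {
  z <- sum(seq.int(k_min, k_max)^(-gamma))
  length(x) * log(z) + gamma * sum(log(x))
}

#' Fit a truncated discrete power law to a degree sequence
#'
#' Maximum-likelihood fit of `P(k) proportional to k^-gamma` on the finite
#' support `[k_min, k_max]`, normalised by the generalised harmonic number.
#' Truncation is mandatory: compound degrees are bounded by the number of
#' species, and exponents below 2 are non-normalisable on infinite support.
#' The likelihood is maximised numerically to a tolerance of 1e-6.
#'
#' @inheritParams fit_exponential
#' @param k_max upper support bound; defaults to the largest retained
#'   degree. Use the number of species when fitting compound degrees.
#' @return A `degree_fit`.
#' @section Errors: `gutnet_degenerate_error` on constant input;
#'   `gutnet_convergence_error` when the optimiser is pinned to the search
#'   boundary.
#' @export
fit_powerlaw <- function(seq, k_min = 1L, k_max = NULL) {
  k <- degree_values(seq)
  if (is.null(k_max)) k_max <- max(k)
  x <- k[k >= k_min & k <= k_max]
  if (length(x) < 10L) {
    stop_gutnet("gutnet_data_error",
                "need at least 10 degrees in [k_min, k_max] to fit")
  }
  if (n_distinct(x) == 1L) {
    stop_gutnet("gutnet_degenerate_error",
                "constant degree sequence; the exponent is unidentified")
  }
  lo <- 1e-3; hi <- 20
  opt <- optimise(powerlaw_negloglik, c(lo, hi), x = x, k_min = k_min,
                  k_max = k_max, tol = 1e-6)
  if (opt$minimum < lo + 1e-2 || opt$minimum > hi - 1e-2) {
    stop_gutnet("gutnet_convergence_error",
                sprintf("power-law exponent pinned to the search boundary (%.3f)",
                        opt$minimum))
  }
  new_degree_fit("powerlaw", opt$minimum, as.integer(k_min),
                 as.integer(k_max), length(x), -opt$objective,
                 "truncated discrete MLE, Brent search, tol 1e-6")
}

#' Samplers for the fitted degree laws
#'
#' `rdegree_exponential()` draws from the shifted geometric law
#' `P(k) proportional to exp(-r k)` on `k >= k_min`; `rdegree_powerlaw()`
#' draws from the discrete power law `P(k) proportional to k^-gamma`
#' truncated to `[k_min, k_max]` by inversion of the discrete CDF.
#'
#' @param n number of draws.
#' @param r exponential rate (> 0).
#' @param gamma power-law exponent (> 0).
#' @param k_min,k_max support bounds.
#' @return Integer vector of degrees.
#' @export
rdegree_exponential <- function(n, r, k_min = 1L) {
  k_min + rgeom(n, prob = 1 - exp(-r))
}

#' @rdname rdegree_exponential
#' @export
rdegree_powerlaw <- function(n, gamma, k_min = 1L, k_max) {
  support <- seq.int(k_min, k_max)
  w <- support^(-gamma)
  cdf <- cumsum(w) / sum(w)
  support[pmin(findInterval(runif(n), cdf) + 1L, length(support))]
}
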