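#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_hline
#'   geom_vline scale_x_log10 scale_y_log10 labs theme_minimal
NULL

#' Plot an empirical degree distribution
#'
#' Shows the empirical probability `P(k)` of the degree sequence on
#' log-scaled axes (log-linear for organism-side sequences, where an
#' exponential law is a straight line; log-log for compound-side sequences,
#' where a power law is). An optional fitted law is overlaid.
#'
#' @param object a `degree_seq` from [organism_degrees()] or
#'   [compound_degrees()].
#' @param fit optional `degree_fit` from [fit_exponential()] or
#'   [fit_powerlaw()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.degree_seq <- function(object, fit = NULL, ...) {
  k <- object$k[object$k >= 1]
  tb <- as_tibble(as.data.frame(table(k = k), stringsAsFactors = FALSE))
  tb$k <- as.integer(tb$k)
  tb$p <- tb$Freq / length(k)
  pl <- ggplot(tb, aes(x = .data$k, y = .data$p)) +
    geom_point() +
    scale_y_log10() +
    labs(x = "degree k", y = "P(k)",
         title = sprintf("%s-side %s degree distribution",
                         attr(object, "side"), attr(object, "direction"))) +
    theme_minimal()
  if (attr(object, "side") == "compound") pl <- pl + scale_x_log10()
  if (!is.null(fit)) {
    ks <- seq.int(fit$k_min,
                  if (is.finite(fit$k_max)) fit$k_max else max(k))
    dens <- if (fit$model == "exponential") {
      (1 - exp(-fit$param)) * exp(-fit$param * (ks - fit$k_min))
    } else {
      ks^(-fit$param) / sum(ks^(-fit$param))
    }
    pl <- pl + geom_line(data = tibble(k = ks, p = dens),
                         aes(x = .data$k, y = .data$p), colour = "red3")
  }
  pl
}

#' Plot producer vs metabolite fold changes
#'
#' One point per (metabolite, group pair), producer fold change `f` against
#' metabolite fold change `g` on log-log axes; concordant records (both
#' shifts in the same direction) fall in the upper-right or lower-left
#' quadrant around (1, 1).
#'
#' @param object a `concordance_result` from [permutation_pvalue()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.concordance_result <- function(object, ...) {
  rec <- object$records
  rec$outcome <- dplyr::case_when(
    is.na(rec$match) ~ "tie", rec$match ~ "match", .default = "mismatch")
  ggplot(rec, aes(x = .data$f, y = .data$g, colour = .data$outcome)) +
    geom_point() +
    geom_hline(yintercept = 1, linetype = 2) +
    geom_vline(xintercept = 1, linetype = 2) +
    scale_x_log10() + scale_y_log10() +
    labs(x = "producer fold change f", y = "metabolite fold change g",
         subtitle = sprintf("match rate %.1f%%, P = %.3g",
                            100 * object$match_rate, object$p_value)) +
    theme_minimal()
}
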