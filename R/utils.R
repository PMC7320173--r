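#' @importFrom rlang abort warn inform %||% .data
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows distinct left_join anti_join n n_distinct across all_of rename
#' @importFrom tibble tibble as_tibble
#' @importFrom stats optimise rgeom rlnorm rpois runif sd setNames
#' @importFrom utils head
NULL

# Classed conditions; every user-facing failure mode has a stable class so
# callers can test for it with tryCatch/expect_error(class = ...).
stop_gutnet <- function(class, message, ...) {
  abort(message, class = c(class, "gutnet_error"), ...)
}

# Zero-padded serial ids in a reserved namespace ("GEN_#####" by default) so
# generated records never collide with curated "NJC19_#####" ids.
next_ids <- function(existing, n, prefix = "GEN_") {
  if (n == 0L) return(character(0))
  pat <- paste0("^", prefix, "([0-9]{5})$")
  used <- as.integer(sub(pat, "\\1", existing[grepl(pat, existing)]))
  start <- if (length(used)) max(used) else 0L
  sprintf("%s%05d", prefix, start + seq_len(n))
}

# First word of a binomial species name, used as the genus fallback when an
# organism's lineage map lacks an explicit genus entry.
name_genus <- function(name) {
  vapply(strsplit(name, "[ _]"), `[[`, character(1), 1L)
}

chr1 <- function(x) as.character(x)[1L]
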