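#' @importFrom rlang %||% .data abort warn inform
#' @importFrom tibble tibble as_tibble
#' @importFrom stats var cor sd rnorm pf p.adjust kmeans dist setNames
#' @importFrom utils head tail
NULL

# Deterministic child seeds: every stochastic step draws its seed from the
# single user seed plus a short tag, so stages can be re-run independently
# and still reproduce the full-pipeline stream. Kept below 2^31.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647L)
}

# Canonical unordered edge representation: a <= b lexicographically.
canonical_edges <- function(from, to) {
  a <- pmin(from, to)
  b <- pmax(from, to)
  tibble(from = a, to = b)
}

normalize_symbols <- function(x) toupper(trimws(x))

# lexicographic comparison of two character vectors (paths); TRUE if a < b
lex_less <- function(a, b) {
  n <- min(length(a), length(b))
  for (i in seq_len(n)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

dnb_log <- function(..., verbose = getOption("dnbtrace.verbose", TRUE)) {
  if (isTRUE(verbose)) inform(paste0("[dnbtrace] ", sprintf(...)))
}
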