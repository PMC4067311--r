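#' Normalize a chromosome label
#'
#' Reference catalogues and gap tables mix the `"chr1"` and `"1"` dialects;
#' all coordinate comparisons in this package go through a single normalized
#' form (`"chr"` prefix, case-insensitive on the prefix).
#'
#' @param x character vector (or factor) of chromosome labels.
#' @return character vector of normalized labels.
#' @examples
#' normalizeChrom(c("1", "chr1", "CHRX"))
#' @export
normalizeChrom <- function(x) {
  x <- as.character(x)
  if (!length(x)) return(character(0))
  paste0("chr", sub("^[Cc][Hh][Rr]", "", x))
}

# Round half away from zero (report-time convention; base round() is
# half-to-even which would format e.g. 0.125 differently than the tables
# this package mirrors).
roundHalfUp <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Minimal union-find over 1..n; used for connected components under
# pairwise predicates that plain interval reduction cannot express
# (reciprocal-overlap support rule).
unionFind <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (length(edges) && nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      ri <- find(edges[k, 1L]); rj <- find(edges[k, 2L])
      if (ri != rj) parent[ri] <- rj
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# Polynomial rolling hash over a deparsed object; config fingerprint for
# run logs (stability across runs is all that matters here).
configFingerprint <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

# Derive a stream seed below 2^31 from a base seed and a small offset, so
# independent simulator stages do not share a random stream.
deriveSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7 + k * 1000003) %% 2147483647)
}

stopNamed <- function(class, msg) {
  stop(errorCondition(msg, class = c(class, "CNVpopError")))
}
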