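# Internal helpers: seeded evaluation, sequence encoding, small conveniences.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so library functions never disturb the
#' caller's random stream. All stochastic operations in the package funnel
#' their `seed` argument through here.
#'
#' @param seed integer scalar, or `NULL` to use the current stream.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stage seed from a master seed; keeps every value < 2^31.
# Double arithmetic: products of a 31-bit seed stay exact in a double,
# while R's integer multiply would overflow to NA.
derive_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 1103 + as.numeric(stage) * 12289) %%
               2147483587)
}

DNA_BASES <- c("A", "C", "G", "T")

s2c <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]
c2s <- function(x) paste(x, collapse = "")

# Encode A/C/G/T as 0/1/2/3 (anything else, including N, becomes NA).
# Transitions are A<->G and C<->T, i.e. codes with equal parity.
base_codes <- function(chars) {
  code <- match(chars, DNA_BASES) - 1L
  code
}

code_to_base <- function(code) DNA_BASES[code + 1L]

#' Reverse complement of nucleotide strings
#'
#' Handles the full IUPAC alphabet (needed for degenerate primers).
#'
#' @param x character vector of sequences.
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("TGCA")     # "TGCA"
#' revcomp("AAW")      # "WTT"
revcomp <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVNacgtryswkmbdhvn",
                 "TGCAYRSWMKVHDBNtgcayrswmkvhdbn", x)
  vapply(comp, function(s) c2s(rev(s2c(s))), character(1L), USE.NAMES = FALSE)
}

# Uniform random DNA string.
random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  c2s(sample(DNA_BASES, n, replace = TRUE, prob = p))
}

# IUPAC degenerate base -> allowed bases.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

# Numeric k-mer codes (base-4) for every window of length k; windows that
# contain non-ACGT bases get NA. Exact for k <= 26 (codes < 2^52).
kmer_codes <- function(code, k) {
  n <- length(code)
  if (n < k) return(numeric(0))
  m <- n - k + 1L
  out <- numeric(m)
  x <- as.numeric(code)
  for (j in 0:(k - 1L)) out <- out + x[(1L + j):(m + j)] * 4^j
  out
}

# Percent identity of two equal-length character vectors (no gaps).
ungapped_identity <- function(a, b) 100 * mean(a == b)

`%||%` <- function(a, b) if (is.null(a)) b else a
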