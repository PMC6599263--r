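# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores the caller's `.Random.seed`, so seeded package
#' internals never perturb user-level random streams.
#' @param seed integer seed, or NULL for "use the current stream".
#' @param code expression to evaluate.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# deterministic 31-bit string hash (polynomial rolling hash)
string_hash <- function(s, mod = 2147483647) {
  h <- 0
  for (c in utf8ToInt(s)) h <- (h * 131 + c) %% mod
  h
}

# one derived stream per generator stage, all below 2^31
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) %% 65521 * 65521 + string_hash(stage, 65521)) %%
               2147483647)
}

dna_complement <- function(s) chartr("ACGTacgt", "TGCAtgca", s)

revcomp <- function(s) {
  vapply(s, function(x) {
    paste(rev(strsplit(dna_complement(x), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# all k-length substrings of s, in order
kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, seq_len(n - k + 1), k:n)
}

is_count <- function(x) length(x) == 1 && is.numeric(x) && !is.na(x) &&
  x >= 0 && x == floor(x)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Round half away from zero
#'
#' Used only for table-facing output (printed growth rates are reported to
#' 2 decimals); all internal arithmetic keeps full precision.
#' @param x numeric vector.
#' @param digits decimal places (default 2).
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
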