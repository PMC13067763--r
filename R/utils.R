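DNA_BASES <- c("A", "C", "G", "T")

# strict DNA validation on a plain uppercase string
assert_dna <- function(x, arg = deparse(substitute(x)), len = NULL) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single DNA string.", arg))
  }
  x <- toupper(x)
  if (grepl("[^ACGT]", x)) {
    abort(sprintf("`%s` contains non-ACGT characters.", arg))
  }
  if (!is.null(len) && nchar(x) != len) {
    abort(sprintf("`%s` must be %d nt long (got %d).", arg, len, nchar(x)))
  }
  x
}

assert_percent <- function(x, arg = deparse(substitute(x))) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    abort(sprintf("`%s` must be finite numeric.", arg))
  }
  if (any(x < 0 | x > 100)) {
    abort(sprintf("`%s` must lie in [0, 100] percent.", arg))
  }
  as.numeric(x)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# run RNG-dependent code under a local, restorable seed
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}
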