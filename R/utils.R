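# Shared internal helpers.

# The 20 canonical residue letters, alphabetical by one-letter code.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so generators are pure functions of (spec, seed).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Uniform random protein sequence, optionally excluding letters.
random_protein <- function(n, exclude = character()) {
  pool <- setdiff(AA_ALPHABET, exclude)
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

read_extdata <- function(file, key = file) {
  if (!is.null(.xb3_cache[[key]])) return(.xb3_cache[[key]])
  path <- system.file("extdata", file, package = "xb3scan", mustWork = TRUE)
  x <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  .xb3_cache[[key]] <- x
  x
}
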