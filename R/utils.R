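## Internal helpers shared across modules.

#' Standard amino-acid alphabet
#'
#' The 20 standard residues in alphabetical one-letter order. Exported as a
#' convenience for users building their own backgrounds or profiles.
#'
#' @format Character vector of length 20.
#' @export
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## Ambiguity / nonstandard codes that pass through extraction untouched and
## score 0 in every alignment and profile stage.
.AA_NONSTD <- c("B", "J", "Z", "X", "U", "O")

## Run `expr` under a private RNG stream seeded with `seed`, restoring the
## caller's .Random.seed afterwards. All stochastic operations in the package
## go through this so there is no hidden global RNG state.
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

## Deterministic child-seed derivation: one user-facing seed fans out to
## per-stage streams. Kept below 2^31 so the result is a valid R integer.
.childSeed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + 7919 * stage) %% 2147483647L)
}

.assertCount <- function(x, name, min = 0L) {
  if (length(x) != 1L || !is.finite(x) || x != round(x) || x < min)
    stop(sprintf("'%s' must be a single integer >= %d", name, min),
         call. = FALSE)
  as.integer(x)
}

.assertProb <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop(sprintf("'%s' must lie in [0, 1]", name), call. = FALSE)
  x
}

## Random amino-acid strings from a background distribution.
.randomAA <- function(n, len, prob = NULL) {
  vapply(seq_len(n), function(i)
    paste(sample(AA20, len, replace = TRUE, prob = prob), collapse = ""),
    character(1))
}

.strsplit1 <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

## Degap a character vector of gapped strings.
.ungap <- function(x) gsub("-", "", x, fixed = TRUE)
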