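# Internal helpers shared across modules.

# Standard 20-letter amino-acid alphabet.
AA_ALPHABET20 <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

# Run `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so generators never perturb the global stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

# Derive a per-unit substream seed from a master seed and a unit index so
# cohorts are reproducible regardless of generation order. Kept in
# [0, 2^31 - 1) for R's 32-bit integer seeds.
derive_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), is.numeric(index))
  (as.double(seed) * 48271 + as.double(index) * 16807 + 11) %% 2147483647
}

assert_scalar_number <- function(x, name, min = -Inf, max = Inf,
                                 allow_min = TRUE, allow_max = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name),
      class = "defensome_argument_error"
    )
  }
  lo_ok <- if (allow_min) x >= min else x > min
  hi_ok <- if (allow_max) x <= max else x < max
  if (!lo_ok || !hi_ok) {
    abort(sprintf(
      "`%s` must be in %s%s, %s%s; got %g.", name,
      if (allow_min) "[" else "(", format(min),
      format(max), if (allow_max) "]" else ")", x
    ), class = "defensome_argument_error")
  }
  invisible(x)
}

random_aa <- function(n) {
  paste(sample(AA_ALPHABET20, n, replace = TRUE), collapse = "")
}

logit <- function(p) qlogis(p)
inv_logit <- function(x) plogis(x)
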