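# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `code`
#' and restores the previous state, so seeded operations never perturb
#' the surrounding random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# Derive a distinct child seed from a base seed and an offset; kept within
# the 32-bit integer range.
deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(offset) * 7919) %%
               2147483629)
}

# Frequencies of the 0.5 Hz feature grid for each feature-set variant.
# The 12.0 Hz bin belongs to both the harmonic and the alpha set; the
# concatenation keeps both copies so the feature dimension is the
# advertised |set| x channels.
variantFrequencies <- function(variant) {
  variant <- match.arg(variant, c("simple", "simple+harmonic",
                                  "simple+alpha", "simple+alpha+harmonic"))
  simple   <- c(6.0, 7.5)
  harmonic <- c(12.0, 15.0)
  alpha    <- seq(8.0, 12.0, by = 0.5)
  switch(variant,
         "simple"                 = simple,
         "simple+harmonic"        = c(simple, harmonic),
         "simple+alpha"           = c(simple, alpha),
         "simple+alpha+harmonic"  = c(simple, harmonic, alpha))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
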