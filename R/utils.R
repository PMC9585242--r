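# run `expr` under a local RNG stream seeded with `seed`; the caller's
# .Random.seed is untouched
withLocalSeed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  expr
}

# ratio with the co-IP conventions: finite when control > 0, Inf when the
# control mean is zero but the bait mean is not, NaN (undefined) when both
# means are zero
.ratioConvention <- function(num, den) {
  if (any(num < 0, na.rm = TRUE) || any(den < 0, na.rm = TRUE)) {
    stop("means must be non-negative")
  }
  r <- num / den                     # R: x/0 = Inf for x > 0, 0/0 = NaN
  r[den == 0 & num == 0] <- NaN
  r
}

.fmtNum <- function(x) {
  out <- format(x, trim = TRUE, scientific = FALSE, digits = 15)
  out[is.infinite(x) & x > 0] <- "Inf"
  out[is.nan(x)] <- "NaN"
  out
}
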