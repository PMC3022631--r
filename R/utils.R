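# Internal helpers shared across modules.

# Evaluate `code` under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# Fixed-effect (inverse-variance weighted) meta-estimate. Shared by probe ->
# gene aggregation and gene-set meta-scores: estimate = sum(x/v) / sum(1/v),
# variance = 1 / sum(1/v).
fixed_effect_meta <- function(x, v) {
  stopifnot(length(x) == length(v))
  if (any(v <= 0)) stop("variances must be positive for the fixed-effect meta-estimate")
  w <- 1 / v
  list(estimate = sum(w * x) / sum(w), variance = 1 / sum(w))
}

# Average-tie ranks, NA kept NA.
avg_rank <- function(x) rank(x, ties.method = "average", na.last = "keep")

msg <- function(...) message("sigsearch: ", ...)

check_character_scalar <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop(what, " must be a single character string")
  invisible(x)
}

# Format doubles so that write -> read round-trips bit-identically.
format_full <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}
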