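# Small in-code fixtures shared across test files.

# A gene-level two-group experiment with values drawn under a fixed seed.
toy_experiment <- function(n_genes = 50, n_per_group = 4, seed = 1,
                           groups = c("normal", "disease"),
                           effect = 0, n_de = 0) {
  with_seed_test(seed, {
    v <- matrix(rnorm(n_genes * 2 * n_per_group), nrow = n_genes)
    if (n_de > 0)
      v[seq_len(n_de), seq_len(n_per_group) + n_per_group] <-
        v[seq_len(n_de), seq_len(n_per_group) + n_per_group] + effect
    rownames(v) <- sprintf("g%03d", seq_len(n_genes))
    colnames(v) <- sprintf("s%02d", seq_len(2 * n_per_group))
    expression_experiment(
      v,
      groups = stats::setNames(rep(groups, each = n_per_group), colnames(v)),
      experiment_id = "toy", factor_name = "disease state",
      is_log_scale = TRUE)
  })
}

# Random DE profile with valid p-values, for property-style tests.
random_profile <- function(n = 200, id = "p", seed = 1, space = "gene") {
  with_seed_test(seed, {
    de_profile(profile_id = id,
               feature_ids = sprintf("g%04d", seq_len(n)),
               scores = rnorm(n), space = space,
               pvalues = pmin(pmax(runif(n), 1e-12), 1),
               variances = rexp(n) + 0.1)
  })
}

# Local seed sandbox (tests must not disturb the global RNG stream).
with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# O(n^2) brute-force Benjamini-Hochberg step-up, the independent oracle.
bh_brute_force <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  for (i in seq_len(n)) {
    ji <- which(o == i)  # rank of p[i]
    adj[i] <- min(1, min(p[o[ji:n]] * n / (ji:n)))
  }
  adj
}

# Exhaustive concordant-pair AUC oracle (ties = half credit).
auc_brute_force <- function(scores, relevance) {
  pos <- scores[relevance]
  neg <- scores[!relevance]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(pos) * length(neg))
}
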