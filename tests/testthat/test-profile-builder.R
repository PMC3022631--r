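test_that("probe aggregation reproduces the fixed-effect meta-estimate by hand", {
  # two probes of one gene with across-sample variances exactly 1 and 3;
  # in sample s2 their values are 2 and 4
  v <- rbind(p1 = c(1, 2, 3),                       # var 1
             p2 = c(4 - sqrt(3), 4, 4 + sqrt(3)))   # var 3
  colnames(v) <- c("s1", "s2", "s3")
  ex <- expression_experiment(v, groups = c(s1 = "a", s2 = "a", s3 = "b"),
                              is_log_scale = TRUE)
  agg <- aggregate_probes_fixed_effects(ex, c(p1 = "gene1", p2 = "gene1"))
  # sample s2 has probe values 2 and 4 with variances 1 and 3
  expect_equal(agg$values["gene1", "s2"], (2 / 1 + 4 / 3) / (1 + 1 / 3))
  expect_equal(unname(agg$feature_variances["gene1"]), 1 / (1 + 1 / 3))

  # single-probe gene passes through with its own variance
  agg2 <- aggregate_probes_fixed_effects(ex, c(p1 = "gA", p2 = "gB"))
  expect_equal(agg2$values["gA", ], v["p1", ])
  expect_equal(unname(agg2$feature_variances["gA"]), 1)

  # equal variances give the arithmetic mean
  v3 <- rbind(q1 = c(1, 2, 3), q2 = c(5, 6, 7))
  colnames(v3) <- colnames(v)
  ex3 <- expression_experiment(v3, groups = ex$groups, is_log_scale = TRUE)
  agg3 <- aggregate_probes_fixed_effects(ex3, c(q1 = "g", q2 = "g"))
  expect_equal(agg3$values["g", ], colMeans(v3))

  # no overlap with the map is an error
  expect_error(aggregate_probes_fixed_effects(ex, c(zz = "g")), "probe map")
})

test_that("log fold-change profiles difference group means and are antisymmetric", {
  v <- rbind(g1 = c(2, 4, 1, 1), g2 = c(5, 5, 2, 4))
  colnames(v) <- sprintf("s%d", 1:4)
  ex <- expression_experiment(v, groups = stats::setNames(
    c("a", "a", "b", "b"), colnames(v)), is_log_scale = TRUE)
  pr <- logfc_profile(ex, "a", "b")
  expect_equal(unname(pr$scores["g1"]), 2.0)
  expect_equal(unname(pr$scores["g2"]), 2.0)
  expect_equal(pr$comparison, c("a", "b"))
  rev <- logfc_profile(ex, "b", "a")
  expect_identical(rev$scores, -pr$scores)
  expect_error(logfc_profile(ex, "a", "zz"), "zz")

  # identical groups give all-zero scores
  vv <- cbind(v, v)
  colnames(vv) <- sprintf("s%d", 1:8)
  ex0 <- expression_experiment(vv, groups = stats::setNames(
    rep(c("a", "b"), each = 4), colnames(vv)), is_log_scale = TRUE)
  expect_true(all(logfc_profile(ex0, "a", "b")$scores == 0))
})

test_that("moderated t with zero prior df reproduces the pooled t-test", {
  ex <- toy_experiment(n_genes = 40, n_per_group = 5, seed = 7)
  res <- moderated_t_pvalues(ex, "disease", "normal", prior_df = 0)
  ref <- apply(ex$values, 1, function(row) {
    stats::t.test(row[ex$groups == "disease"], row[ex$groups == "normal"],
                  var.equal = TRUE)$p.value
  })
  expect_equal(unname(res$p_value), unname(ref), tolerance = 1e-10)
})

test_that("moderated t agrees with the limma implementation", {
  skip_if_not_installed("limma")
  ex <- toy_experiment(n_genes = 300, n_per_group = 4, seed = 11,
                       effect = 1.5, n_de = 30)
  res <- moderated_t_pvalues(ex, "disease", "normal")
  design <- cbind(1, as.numeric(ex$groups == "disease"))
  fit <- limma::eBayes(limma::lmFit(ex$values, design))
  expect_equal(res$prior_df, fit$df.prior, tolerance = 1e-4)
  expect_equal(res$prior_var, fit$s2.prior, tolerance = 1e-4)
  expect_equal(unname(res$t), unname(fit$t[, 2]), tolerance = 1e-6)
  expect_equal(unname(res$p_value), unname(fit$p.value[, 2]), tolerance = 1e-6)
})

test_that("prior hyperparameters are recovered from a scaled inverse-chi-square truth", {
  d0_true <- 4; s02_true <- 1
  for (seed in 1:20) {
    ex <- with_seed_test(seed, {
      sigma2 <- d0_true * s02_true / rchisq(200, df = d0_true)
      v <- t(vapply(sigma2, function(s2) rnorm(8, sd = sqrt(s2)), numeric(8)))
      dimnames(v) <- list(sprintf("g%03d", 1:200), sprintf("s%d", 1:8))
      expression_experiment(v, groups = stats::setNames(
        rep(c("a", "b"), each = 4), colnames(v)), is_log_scale = TRUE)
    })
    res <- moderated_t_pvalues(ex, "a", "b")
    expect_gte(res$prior_df, 2); expect_lte(res$prior_df, 8)
    expect_gte(res$prior_var, 0.7); expect_lte(res$prior_var, 1.4)
  }
})

test_that("moderated t degenerate cases: zero difference, infinite shrinkage", {
  ex <- toy_experiment(n_genes = 30, n_per_group = 4, seed = 2)
  ex$values[1, ] <- rep(c(1, 2, 3, 4), 2)  # identical groups for g001
  res <- moderated_t_pvalues(ex, "disease", "normal")
  expect_equal(unname(res$t[1]), 0)
  expect_equal(unname(res$p_value[1]), 1)

  resInf <- moderated_t_pvalues(ex, "disease", "normal", prior_df = Inf)
  expect_true(all(abs(resInf$s2_posterior - resInf$prior_var) < 1e-12))

  # single-sample groups leave no residual df anywhere: prior inestimable
  v <- matrix(rnorm(10), 5, 2, dimnames = list(sprintf("g%d", 1:5),
                                               c("s1", "s2")))
  ex1 <- expression_experiment(v, groups = c(s1 = "a", s2 = "b"),
                               is_log_scale = TRUE)
  expect_error(moderated_t_pvalues(ex1, "a", "b"), "inestimable")
})

test_that("BH adjustment matches the brute-force step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.42), 0.42)
  expect_error(bh_adjust(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_adjust(c(0.5, 1.2)), "\\(0, 1\\]")

  for (seed in 1:50) {
    p <- with_seed_test(seed, runif(sample(2:50, 1)))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_brute_force(p))
    expect_true(all(adj >= p))
  }
})

test_that("rank profiles follow the median-of-pair-differences rule", {
  # single gene, two probes engineered so group-mean ranks are
  # a = (10, 20) and b = (12, 16) out of 21 probes
  n_probes <- 21
  v <- matrix(0, n_probes, 2,
              dimnames = list(sprintf("p%02d", 1:n_probes), c("sa", "sb")))
  # with distinct values, rank = the value itself when values are 1..21
  v[c(1, 2), 1] <- c(10, 20)
  v[-c(1, 2), 1] <- setdiff(seq_len(n_probes), c(10, 20))
  v[c(1, 2), 2] <- c(12, 16)
  v[-c(1, 2), 2] <- setdiff(seq_len(n_probes), c(12, 16))
  ex <- expression_experiment(v, groups = c(sa = "a", sb = "b"))
  pm <- stats::setNames(c("gene1", "gene1", rep("other", 19)), rownames(v))
  pr <- rank_profile(ex, "a", "b", pm)
  expect_equal(unname(pr$scores["gene1"]),
               stats::median(c(10 - 12, 10 - 16, 20 - 12, 20 - 16)))
  expect_equal(unname(pr$scores["gene1"]), 1.0)
})

test_that("rank profiles are invariant to strictly increasing transforms", {
  ex <- toy_experiment(n_genes = 60, n_per_group = 3, seed = 9)
  pm <- stats::setNames(rep(sprintf("gene%02d", 1:20), each = 3),
                        rownames(ex$values))
  base <- rank_profile(ex, "disease", "normal", pm)
  for (f in list(function(x) exp(x), function(x) x^3 + 5 * x,
                 function(x) atan(x))) {
    ex2 <- ex
    ex2$values <- f(ex$values)
    expect_equal(rank_profile(ex2, "disease", "normal", pm)$scores,
                 base$scores)
  }
  # single-probe gene: score is the mean-rank difference of that probe
  single <- rank_profile(ex, "disease", "normal",
                         stats::setNames("solo", rownames(ex$values)[1]))
  r1 <- apply(ex$values, 2, rank)[1, ]  # probe's rank among all probes
  expect_equal(unname(single$scores["solo"]),
               mean(r1[ex$groups == "disease"]) -
                 mean(r1[ex$groups == "normal"]))
})

test_that("homolog mapping keeps one-to-one entries and errors on empty survival", {
  hm <- homolog_map(data.frame(
    species = "mouse",
    source_gene_id = c("m1", "m2", "m3", "m4", "m5", "m5"),
    human_gene_id = c("h1", "h2", "h3", "h4", "h5a", "h5b"),
    stringsAsFactors = FALSE))
  pr <- de_profile("p", sprintf("m%d", 1:5), 1:5, space = "gene",
                   pvalues = rep(0.5, 5))
  mapped <- suppressMessages(map_to_human(pr, hm, "mouse"))
  expect_equal(mapped$feature_ids, c("h1", "h2", "h3", "h4"))
  expect_equal(unname(mapped$scores), 1:4 + 0)
  expect_equal(unname(mapped$pvalues), rep(0.5, 4))

  # human profiles are identity-mapped
  expect_identical(map_to_human(pr, hm, "human"), pr)

  # disjoint map fails with the mapping error
  pr2 <- de_profile("p2", c("x1", "x2"), c(1, 2), space = "gene")
  expect_error(map_to_human(pr2, hm, "mouse"), "failed to map")
})

test_that("comparison enumeration lists lexicographic unordered pairs", {
  mk <- function(groups) {
    n <- length(groups)
    v <- matrix(seq_len(2 * n), 2, n,
                dimnames = list(c("g1", "g2"), sprintf("s%d", 1:n)))
    expression_experiment(v, groups = stats::setNames(groups, colnames(v)))
  }
  cmp <- enumerate_comparisons(mk(c("1 hr", "2 hr", "4 hr")))
  expect_equal(cmp$group_a, c("1 hr", "1 hr", "2 hr"))
  expect_equal(cmp$group_b, c("2 hr", "4 hr", "4 hr"))

  expect_equal(nrow(enumerate_comparisons(mk(c("A", "B")))), 1L)
  expect_equal(nrow(enumerate_comparisons(mk(c("a", "b", "c", "d", "e")))),
               choose(5, 2))
  expect_error(enumerate_comparisons(mk(c("A", "A"))), "2 groups")
})

test_that("adjusted p-values stay calibrated under a global null", {
  n_genes <- 2000
  ex <- toy_experiment(n_genes = n_genes, n_per_group = 4, seed = 13)
  res <- moderated_t_pvalues(ex, "disease", "normal")
  frac <- mean(res$adj_p_value < 0.05)
  expect_lte(frac, 0.05 + 2 * sqrt(0.05 * 0.95 / n_genes))
})
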