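make_library <- function(n = 8, n_feat = 150, seed = 1, space = "gene") {
  lapply(seq_len(n), function(i)
    random_profile(n_feat, sprintf("lib%02d", i), seed = seed + i,
                   space = space))
}

test_that("indexing keeps valid profiles and reports exclusions", {
  lib <- make_library(10)
  idx <- build_index(lib)
  expect_length(idx, 10L)
  expect_equal(nrow(idx$exclusions), 0L)

  # profiles that cannot project onto the basis are excluded with a reason
  genes <- lib[[1]]$feature_ids
  s <- with_seed_test(3, matrix(rnorm(20 * length(genes)), 20,
                                dimnames = list(sprintf("IC%02d", 1:20),
                                                genes)))
  cm <- component_matrix(s)
  bad1 <- de_profile("bad1", c("zz1", "zz2"), c(1, 2), space = "gene")
  bad2 <- de_profile("bad2", c("yy1", "yy2"), c(1, 2), space = "gene")
  idx2 <- suppressMessages(build_index(c(lib, list(bad1, bad2)), components = cm))
  expect_length(idx2, 10L)
  expect_setequal(idx2$exclusions$profile_id, c("bad1", "bad2"))
  expect_equal(idx2$space, "component")

  # re-indexing the same inputs is deterministic
  idx3 <- suppressMessages(build_index(c(lib, list(bad1, bad2)), components = cm))
  expect_identical(idx2, idx3)

  expect_error(build_index(list()), "empty")
})

test_that("null sampling is seeded, self-pair free, and exhaustive when short", {
  lib <- make_library(5)
  idx <- build_index(lib)
  sch <- weight_scheme("unweighted")

  n1 <- suppressMessages(sample_null(idx, n_pairs = 10, seed = 7, scheme = sch,
                                     min_overlap = 10))
  expect_equal(n1$n_pairs, 10L)  # C(5,2) = 10 distinct pairs, used exactly
  n2 <- suppressMessages(sample_null(idx, n_pairs = 10, seed = 99, scheme = sch,
                                     min_overlap = 10))
  expect_identical(n1$scores, n2$scores)  # exhaustive: seed-independent

  # requesting more than available logs a shortfall and uses all pairs
  n3 <- suppressMessages(sample_null(idx, n_pairs = 10000, seed = 1,
                                     scheme = sch, min_overlap = 10))
  expect_equal(n3$n_pairs, 10L)

  # none of the exhaustive scores is a self-similarity (which would be 1)
  expect_true(all(n3$scores < 1 - 1e-8))

  # subsampling is reproducible under the seed
  lib2 <- make_library(12, seed = 50)
  idx2 <- build_index(lib2)
  a <- sample_null(idx2, n_pairs = 20, seed = 5, scheme = sch, min_overlap = 10)
  b <- sample_null(idx2, n_pairs = 20, seed = 5, scheme = sch, min_overlap = 10)
  expect_identical(a$scores, b$scores)
  expect_equal(a$seed, 5)
})

test_that("empirical q-values implement smoothed exceedance counting", {
  null <- structure(list(scores = seq(0, 1, length.out = 10000),
                         n_pairs = 10000L, seed = 1, mode = "absolute"),
                    class = "NullDistribution")
  expect_equal(empirical_q(2, null), 1 / 10001)
  expect_equal(empirical_q(-Inf, null), 1)

  # brute-force scan agreement and monotonicity on random nulls
  for (seed in 1:5) {
    ns <- with_seed_test(seed, runif(500))
    nd <- structure(list(scores = ns, n_pairs = 500L, seed = seed,
                         mode = "signed"), class = "NullDistribution")
    probes <- with_seed_test(seed + 10, runif(50, -0.2, 1.2))
    q <- empirical_q(probes, nd)
    brute <- vapply(probes, function(s) (sum(ns >= s) + 1) / 501, numeric(1))
    expect_equal(q, brute)
    ord <- order(probes)
    expect_true(all(diff(q[ord]) <= 0))
  }

  # mode mismatch is an error
  expect_error(empirical_q(0.5, null, mode = "signed"), "mode")
})

test_that("queries rank the library deterministically with self on top", {
  lib <- make_library(8, seed = 20)
  idx <- build_index(lib)
  sch <- weight_scheme("unweighted")
  null <- suppressMessages(sample_null(idx, n_pairs = 28, seed = 3,
                                       scheme = sch, min_overlap = 10))

  res <- query(idx, lib[[4]], null = null, top_k = 3, scheme = sch,
               min_overlap = 10)
  expect_equal(res$target_id[1], "lib04")
  expect_equal(res$score[1], 1)
  expect_equal(nrow(res), 3L)
  expect_true(all(res$qvalue > 0 & res$qvalue <= 1))
  # contributions of the top hit sum to its signed score
  contr <- attr(res, "contributions")
  expect_equal(sum(contr[["lib04"]]), 1, tolerance = 1e-8)

  # top_k beyond the library returns everything
  expect_equal(nrow(query(idx, lib[[1]], top_k = 100, scheme = sch,
                          min_overlap = 10)), 8L)

  # ranking is invariant to library insertion order
  idx_rev <- build_index(rev(lib))
  res_rev <- query(idx_rev, lib[[4]], null = null, top_k = 8, scheme = sch,
                   min_overlap = 10)
  res_fwd <- query(idx, lib[[4]], null = null, top_k = 8, scheme = sch,
                   min_overlap = 10)
  expect_equal(res_rev$target_id, res_fwd$target_id)
  expect_equal(res_rev$score, res_fwd$score)
})

test_that("a planted near-duplicate is retrieved first across seeds", {
  for (seed in 1:20) {
    base <- with_seed_test(seed, rnorm(200))
    qp <- de_profile("query", sprintf("g%04d", 1:200), base, space = "gene")
    dup <- de_profile("dup", sprintf("g%04d", 1:200),
                      base + with_seed_test(seed + 500, rnorm(200, sd = 0.45)),
                      space = "gene")
    noise <- lapply(1:6, function(i)
      de_profile(sprintf("noise%d", i), sprintf("g%04d", 1:200),
                 with_seed_test(seed + 1000 + i, rnorm(200)), space = "gene"))
    idx <- build_index(c(list(dup), noise))
    res <- query(idx, qp, top_k = 1, scheme = weight_scheme("unweighted"),
                 min_overlap = 50)
    expect_equal(res$target_id, "dup")
  }
})

test_that("similarity networks threshold on q and carry node metadata", {
  lib <- make_library(7, seed = 40)
  idx <- build_index(lib)
  sch <- weight_scheme("unweighted")
  null <- suppressMessages(sample_null(idx, n_pairs = 21, seed = 2,
                                       scheme = sch, min_overlap = 10))

  # q_threshold = 1.01 keeps every pair: complete graph
  net_all <- build_network(idx, null, q_threshold = 1.01, scheme = sch,
                           min_overlap = 10)
  expect_equal(nrow(net_all$edges), choose(7, 2))
  expect_equal(nrow(net_all$nodes), 7L)

  # impossible threshold keeps no pair but lists all nodes
  net_none <- build_network(idx, null, q_threshold = 1 / 1e9, scheme = sch,
                            min_overlap = 10)
  expect_equal(nrow(net_none$edges), 0L)
  expect_equal(nrow(net_none$nodes), 7L)

  dir <- withr::local_tempdir()
  write_network(net_all, file.path(dir, "e.tsv"), file.path(dir, "n.tsv"))
  back <- utils::read.delim(file.path(dir, "e.tsv"))
  expect_equal(nrow(back), choose(7, 2))
})

test_that("empirical q-values are calibrated on a fully null library", {
  lib <- make_library(30, n_feat = 150, seed = 77)
  idx <- build_index(lib)
  sch <- weight_scheme("unweighted")
  null <- suppressMessages(sample_null(idx, n_pairs = 10000, seed = 11,
                                       scheme = sch, absolute = TRUE,
                                       min_overlap = 10))
  q <- empirical_q(null$scores, null)
  for (alpha in c(0.05, 0.01))
    expect_lte(mean(q < alpha), alpha + 2 * sqrt(alpha / null$n_pairs))
})
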