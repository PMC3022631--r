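#' Leave-one-out retrieval over a labeled profile library
#'
#' Each profile in turn queries the remaining profiles; targets are ranked
#' by signed similarity (descending, ties broken by target id) and a binary
#' relevance vector marks targets sharing the query's label. Queries whose
#' label has no other member are skipped with a warning (they have no
#' retrievable positive).
#'
#' @param profiles list of \code{DEProfile}s in a common space.
#' @param labels named character vector: profile_id -> class label.
#' @param scheme,method,min_overlap scoring settings
#'   (\code{\link{similarity_score}}); signed correlation is used, as
#'   comparisons in an evaluation compendium share a fixed direction.
#' @return an object of class \code{"RetrievalResult"}: a list with one
#'   element per query, each carrying \code{query_id}, \code{label},
#'   \code{target_ids}, \code{scores} and logical \code{relevance}, all in
#'   rank order.
#' @export
loocv_retrieval <- function(profiles, labels,
                            scheme = weight_scheme("p_value"),
                            method = "pearson", min_overlap = NULL) {
  ids <- vapply(profiles, function(p) p$profile_id, character(1))
  names(profiles) <- ids
  if (!all(ids %in% names(labels)))
    stop("labels missing for: ",
         paste(setdiff(ids, names(labels)), collapse = ", "))
  labels <- labels[ids]
  counts <- table(labels)
  if (length(counts) < 2L) stop("need at least 2 distinct labels")

  out <- list()
  for (qid in ids) {
    if (counts[[labels[[qid]]]] < 2L) {
      warning("query '", qid, "' skipped: no other profile shares label '",
              labels[[qid]], "'")
      next
    }
    others <- setdiff(ids, qid)
    scores <- vapply(others, function(tid)
      similarity_score(profiles[[qid]], profiles[[tid]], scheme = scheme,
                       method = method, absolute = FALSE,
                       min_overlap = min_overlap)$signed_score,
      numeric(1))
    ord <- order(-scores, others, method = "radix")
    out[[qid]] <- list(query_id = qid,
                       label = labels[[qid]],
                       target_ids = others[ord],
                       scores = unname(scores[ord]),
                       relevance = unname(labels[others[ord]] == labels[[qid]]))
  }
  if (length(out) == 0L) stop("no query had a retrievable positive")
  structure(out, class = "RetrievalResult")
}

#' @export
print.RetrievalResult <- function(x, ...) {
  cat(sprintf("RetrievalResult: %d queries, %d targets each\n",
              length(x), length(x[[1L]]$target_ids)))
  invisible(x)
}

# Mann-Whitney AUC from scores + binary relevance (average-tie ranks give
# tied pairs half credit).
auc_from_scores <- function(scores, relevance) {
  m <- sum(relevance)
  n <- sum(!relevance)
  if (m == 0L || n == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[relevance]) - m * (m + 1) / 2) / (m * n)
}

# Step-ROC points for one ranked list; returns tpr on a common fpr grid
# (linear interpolation across tie groups, matching half-credit AUC).
roc_points <- function(scores, relevance, grid) {
  ord <- order(-scores)
  scores <- scores[ord]; relevance <- relevance[ord]
  grp <- cumsum(!duplicated(scores))
  tp <- cumsum(relevance); fp <- cumsum(!relevance)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / max(tp[length(tp)], 1L))
  fpr <- c(0, fp[last] / max(fp[length(fp)], 1L))
  stats::approx(fpr, tpr, xout = grid, ties = max, rule = 2)$y
}

#' ROC curves and AUC for retrieval results
#'
#' Per query, the area under the ROC curve via the rank (Mann-Whitney)
#' formulation, tied scores receiving half credit; the mean AUC and its
#' standard error are taken over queries, and an average ROC curve is formed
#' by vertical averaging of per-query curves on a common false-positive-rate
#' grid. Queries with no positive or no negative are excluded and reported.
#'
#' @param retrieval a \code{\link{loocv_retrieval}} result (or any list of
#'   elements with \code{scores} and \code{relevance}).
#' @param grid_points number of FPR grid points for curve averaging
#'   (default 101).
#' @return list with \code{per_query} (data.frame \code{query_id},
#'   \code{auc}), \code{mean_auc}, \code{se_auc}, \code{n_queries} and
#'   \code{curve} (data.frame \code{fpr}, \code{mean_tpr}, \code{se_tpr}).
#' @export
roc_auc <- function(retrieval, grid_points = 101L) {
  grid <- seq(0, 1, length.out = grid_points)
  aucs <- numeric(0); qids <- character(0)
  curves <- list()
  for (q in retrieval) {
    a <- auc_from_scores(q$scores, q$relevance)
    if (is.na(a)) {
      msg(sprintf("query '%s' has no positive or no negative; excluded",
                  q$query_id))
      next
    }
    qids <- c(qids, q$query_id)
    aucs <- c(aucs, a)
    curves[[length(curves) + 1L]] <- roc_points(q$scores, q$relevance, grid)
  }
  if (length(aucs) == 0L) stop("no evaluable query")
  cm <- do.call(rbind, curves)
  list(per_query = data.frame(query_id = qids, auc = aucs,
                              stringsAsFactors = FALSE),
       mean_auc = mean(aucs),
       se_auc = stats::sd(aucs) / sqrt(length(aucs)),
       n_queries = length(aucs),
       curve = data.frame(fpr = grid,
                          mean_tpr = colMeans(cm),
                          se_tpr = apply(cm, 2L, stats::sd) / sqrt(nrow(cm))))
}

#' Precision at k
#'
#' Fraction of the top \code{k} ranked targets that are relevant. Lists
#' shorter than \code{k} are scored over their full length (reported).
#'
#' @param relevance logical vector in rank order.
#' @param k cut-off (default 4).
#' @return precision in [0, 1].
#' @export
precision_at_k <- function(relevance, k = 4L) {
  if (length(relevance) < k) {
    msg(sprintf("list of length %d shorter than k = %d; using full list",
                length(relevance), k))
    k <- length(relevance)
  }
  mean(relevance[seq_len(k)])
}

#' Label-permutation null for precision at k
#'
#' Permutes the class labels across all profiles (rankings are fixed — only
#' relevance changes), recomputing each query's precision at k per
#' permutation. For balanced label classes the per-query null mean equals
#' the hypergeometric expectation (m - 1)/(n - 1), where the query's label
#' covers m of the n profiles.
#'
#' @param retrieval a \code{\link{loocv_retrieval}} result.
#' @param labels the named label vector the retrieval was run with.
#' @param k cut-off (default 4).
#' @param n_permutations number of label permutations (default 1000).
#' @param seed integer seed.
#' @return data.frame with per query: \code{query_id}, \code{observed},
#'   \code{null_mean}, \code{null_lo}, \code{null_hi} (central 95%
#'   interval) and \code{significant} (observed above the 97.5th null
#'   percentile).
#' @export
permutation_null_precision <- function(retrieval, labels, k = 4L,
                                       n_permutations = 1000L, seed = 1) {
  stopifnot(inherits(retrieval, "RetrievalResult"))
  qids <- vapply(retrieval, `[[`, character(1), "query_id")
  all_ids <- names(labels)
  perm_prec <- with_seed(seed, {
    sapply(seq_len(n_permutations), function(b) {
      pl <- stats::setNames(sample(unname(labels)), all_ids)
      vapply(retrieval, function(q) {
        kk <- min(k, length(q$target_ids))
        mean(pl[q$target_ids[seq_len(kk)]] == pl[[q$query_id]])
      }, numeric(1))
    })
  })
  perm_prec <- matrix(perm_prec, nrow = length(retrieval))
  obs <- vapply(retrieval, function(q) precision_at_k(q$relevance, k),
                numeric(1))
  lo <- apply(perm_prec, 1L, stats::quantile, probs = 0.025)
  hi <- apply(perm_prec, 1L, stats::quantile, probs = 0.975)
  data.frame(query_id = qids,
             observed = unname(obs),
             null_mean = rowMeans(perm_prec),
             null_lo = unname(lo),
             null_hi = unname(hi),
             significant = unname(obs > hi),
             stringsAsFactors = FALSE)
}

#' Retrieval evaluation over a measure x reduction grid
#'
#' Runs \code{\link{loocv_retrieval}} + \code{\link{roc_auc}} for every
#' combination of correlation method (Pearson, Spearman), weighting scheme
#' (unweighted, inverse-variance, p-value) and supplied feature space, and
#' tabulates mean AUC with standard errors. The inverse-variance scheme
#' weights each feature by the inverse of its score variance across the
#' library itself unless a variance table is supplied in the scheme.
#'
#' @param profiles_by_space named list of profile libraries, e.g.
#'   \code{list(gene = ..., component = ..., module = ...)}; each library is
#'   a list of \code{DEProfile}s in that space describing the same
#'   comparisons.
#' @param labels named character vector: profile_id -> class label.
#' @param methods,schemes subsets of the grid to run.
#' @param C p-value weight scaling (default 2).
#' @param min_overlap forwarded to the similarity computation.
#' @return data.frame with columns \code{reduction}, \code{method},
#'   \code{scheme}, \code{mean_auc}, \code{se_auc}, \code{n_queries}.
#' @export
evaluate_grid <- function(profiles_by_space, labels,
                          methods = c("pearson", "spearman"),
                          schemes = c("unweighted", "inverse_variance", "p_value"),
                          C = 2, min_overlap = NULL) {
  rows <- list()
  for (space_name in names(profiles_by_space)) {
    lib <- profiles_by_space[[space_name]]
    for (method in methods) {
      for (sk in schemes) {
        sch <- if (sk == "inverse_variance") {
          weight_scheme("inverse_variance",
                        compendium_variances = library_feature_variances(lib))
        } else weight_scheme(sk, C = C)
        res <- tryCatch({
          rr <- loocv_retrieval(lib, labels, scheme = sch, method = method,
                                min_overlap = min_overlap)
          roc_auc(rr)
        }, error = function(e) e)
        rows[[length(rows) + 1L]] <- if (inherits(res, "error")) {
          data.frame(reduction = space_name, method = method, scheme = sk,
                     mean_auc = NA_real_, se_auc = NA_real_, n_queries = 0L,
                     stringsAsFactors = FALSE)
        } else {
          data.frame(reduction = space_name, method = method, scheme = sk,
                     mean_auc = res$mean_auc, se_auc = res$se_auc,
                     n_queries = res$n_queries, stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Per-feature score variance across a profile library
#'
#' The compendium variance used by the inverse-variance weighting scheme
#' when no external variance table is available: for each feature, the
#' variance of its score across the library's profiles (features seen in
#' fewer than 2 profiles are dropped).
#'
#' @param profiles list of \code{DEProfile}s in a common space.
#' @return named numeric vector of positive variances.
#' @export
library_feature_variances <- function(profiles) {
  all_feats <- unique(unlist(lapply(profiles, `[[`, "feature_ids")))
  m <- matrix(NA_real_, nrow = length(all_feats), ncol = length(profiles),
              dimnames = list(all_feats, NULL))
  for (j in seq_along(profiles))
    m[profiles[[j]]$feature_ids, j] <- profiles[[j]]$scores
  v <- apply(m, 1L, stats::var, na.rm = TRUE)
  v <- v[!is.na(v) & v > 0]
  v
}
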