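#' Build a searchable index of DE profiles
#'
#' Collects profiles into a common feature space. When a component basis is
#' supplied, gene-space profiles are projected onto it (profiles whose genes
#' do not intersect the basis are excluded). Profiles that cannot enter the
#' index are recorded in an exclusion report with a reason rather than
#' aborting the build.
#'
#' @param profiles list of \code{DEProfile}s (a named list or one with
#'   unique \code{profile_id}s).
#' @param components optional \code{\link{component_matrix}}; when given,
#'   gene-space profiles are projected with \code{\link{project_ica}}
#'   (component-space profiles, e.g. from \code{\link{component_profile}},
#'   pass through unchanged).
#' @return an object of class \code{"ProfileIndex"}: profiles, common
#'   \code{space}, and an \code{exclusions} data.frame
#'   (\code{profile_id}, \code{reason}).
#' @export
build_index <- function(profiles, components = NULL) {
  if (length(profiles) == 0L) stop("cannot index an empty profile library")
  ids <- vapply(profiles, function(p) p$profile_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate profile ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  target_space <- if (is.null(components)) {
    sp <- unique(vapply(profiles, function(p) p$space, character(1)))
    if (length(sp) > 1L)
      stop("profiles span multiple spaces (", paste(sp, collapse = ", "),
           "); supply a component basis or a homogeneous library")
    sp
  } else "component"

  kept <- list()
  excl <- list()
  for (p in profiles) {
    res <- tryCatch({
      if (!is.null(components) && p$space == "gene")
        p <- project_ica(p, components)
      if (p$space != target_space)
        stop("profile is in ", p$space, " space, index is ", target_space)
      p
    }, error = function(e) e)
    if (inherits(res, "error")) {
      excl[[length(excl) + 1L]] <-
        data.frame(profile_id = p$profile_id,
                   reason = conditionMessage(res),
                   stringsAsFactors = FALSE)
    } else {
      kept[[res$profile_id]] <- res
    }
  }
  if (length(kept) == 0L) stop("no profile survived indexing")
  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(profile_id = character(0), reason = character(0),
               stringsAsFactors = FALSE)
  if (nrow(exclusions) > 0L)
    msg(sprintf("excluded %d profiles (see $exclusions)", nrow(exclusions)))
  structure(list(profiles = kept, space = target_space,
                 exclusions = exclusions),
            class = "ProfileIndex")
}

#' @export
print.ProfileIndex <- function(x, ...) {
  cat(sprintf("ProfileIndex: %d profiles in %s space (%d excluded)\n",
              length(x$profiles), x$space, nrow(x$exclusions)))
  invisible(x)
}

#' @export
length.ProfileIndex <- function(x) length(x$profiles)

# Enumerate all C(n,2) unordered index pairs as a 2-column matrix.
all_pairs <- function(n) {
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- sequence((n - 1L):1L, from = 2L:n)
  cbind(i, j)
}

#' Sample a null distribution of similarity scores
#'
#' Scores random pairs of distinct library profiles to serve as the
#' background distribution against which empirical q-values are computed.
#' Self-pairs are excluded; pairs originating from the same source
#' experiment are allowed, which makes downstream q-values conservative
#' (the background can contain genuinely related pairs). If fewer than
#' \code{n_pairs} distinct pairs exist, all of them are used and the
#' shortfall is reported.
#'
#' @param index a \code{\link{build_index}} result.
#' @param n_pairs number of random pairs (default 10000).
#' @param seed integer seed.
#' @param scheme,method,absolute scoring settings, as in
#'   \code{\link{similarity_score}}.
#' @param min_overlap passed to \code{\link{similarity_score}}.
#' @return an object of class \code{"NullDistribution"}: \code{scores},
#'   \code{n_pairs}, \code{seed}, \code{mode} (\code{"signed"} or
#'   \code{"absolute"}).
#' @export
sample_null <- function(index, n_pairs = 10000, seed = 1,
                        scheme = weight_scheme("p_value"),
                        method = "pearson", absolute = TRUE,
                        min_overlap = NULL) {
  stopifnot(inherits(index, "ProfileIndex"))
  n <- length(index$profiles)
  if (n < 2L) stop("need at least 2 indexed profiles to sample a null")
  total <- n * (n - 1L) / 2L
  pairs <- all_pairs(n)
  if (n_pairs >= total) {
    if (n_pairs > total)
      msg(sprintf("only %d distinct pairs available (requested %d); using all",
                  total, n_pairs))
  } else {
    sel <- with_seed(seed, sample.int(total, n_pairs))
    pairs <- pairs[sel, , drop = FALSE]
  }
  prof <- index$profiles
  scores <- vapply(seq_len(nrow(pairs)), function(k) {
    similarity_score(prof[[pairs[k, 1L]]], prof[[pairs[k, 2L]]],
                     scheme = scheme, method = method, absolute = absolute,
                     min_overlap = min_overlap)$score
  }, numeric(1))
  structure(list(scores = scores, n_pairs = length(scores), seed = seed,
                 mode = if (absolute) "absolute" else "signed"),
            class = "NullDistribution")
}

#' @export
print.NullDistribution <- function(x, ...) {
  cat(sprintf("NullDistribution (%s): %d pairs, seed %d\n",
              x$mode, x$n_pairs, x$seed))
  cat(sprintf("  score quantiles: %s\n",
              paste(sprintf("%.3f", stats::quantile(x$scores, c(.5, .95, .99))),
                    collapse = " / ")))
  invisible(x)
}

#' Empirical q-value of a similarity score
#'
#' The (add-one smoothed) fraction of background pairs whose score meets or
#' exceeds the observed one: \code{q = (#\{null >= score\} + 1) /
#' (n_pairs + 1)}. Smoothing keeps q strictly positive even above the
#' background maximum, which is conservative.
#'
#' @param score numeric vector of observed scores.
#' @param null a \code{\link{sample_null}} result.
#' @param mode \code{"signed"} or \code{"absolute"}; must match the mode the
#'   null was sampled in.
#' @return q-values in (0, 1].
#' @export
empirical_q <- function(score, null, mode = null$mode) {
  stopifnot(inherits(null, "NullDistribution"))
  if (!identical(mode, null$mode))
    stop("score mode '", mode, "' does not match null mode '", null$mode, "'")
  n <- null$n_pairs
  vapply(score, function(s) (sum(null$scores >= s) + 1) / (n + 1), numeric(1))
}

#' Query the index with a profile
#'
#' Scores the query against every indexed profile, ranks by score
#' (descending; ties broken lexicographically by target id), attaches
#' empirical q-values when a null distribution is given, and returns the
#' top k with per-feature contribution vectors.
#'
#' @param index a \code{\link{build_index}} result.
#' @param query_profile a \code{DEProfile}; projected onto the index's
#'   component basis space if needed (supply a component-space profile for
#'   p-weighted search in component space).
#' @param null optional \code{\link{sample_null}} result.
#' @param top_k number of hits to return (capped at the library size).
#' @param scheme,method,absolute,min_overlap scoring settings; must match
#'   those used for the null.
#' @return a data.frame of class \code{"SearchResult"} with columns
#'   \code{target_id}, \code{score}, \code{qvalue} (NA without a null) and
#'   attribute \code{contributions} (named list, one vector per hit).
#' @export
query <- function(index, query_profile, null = NULL, top_k = 10,
                  scheme = weight_scheme("p_value"), method = "pearson",
                  absolute = TRUE, min_overlap = NULL) {
  stopifnot(inherits(index, "ProfileIndex"),
            inherits(query_profile, "DEProfile"))
  if (query_profile$space != index$space)
    stop("query is in ", query_profile$space, " space but the index is in ",
         index$space, " space")
  prof <- index$profiles
  res <- lapply(prof, function(p)
    similarity_score(query_profile, p, scheme = scheme, method = method,
                     absolute = absolute, min_overlap = min_overlap))
  scores <- vapply(res, `[[`, numeric(1), "score")
  ids <- names(prof)
  ord <- order(-scores, ids, method = "radix")
  top <- utils::head(ord, min(top_k, length(ord)))
  qv <- if (is.null(null)) rep(NA_real_, length(top)) else
    empirical_q(scores[top], null,
                mode = if (absolute) "absolute" else "signed")
  out <- data.frame(target_id = ids[top],
                    score = unname(scores[top]),
                    qvalue = unname(qv),
                    stringsAsFactors = FALSE)
  attr(out, "query_id") <- query_profile$profile_id
  attr(out, "contributions") <-
    stats::setNames(lapply(res[top], `[[`, "contributions"), ids[top])
  class(out) <- c("SearchResult", "data.frame")
  out
}

#' @export
print.SearchResult <- function(x, ...) {
  cat(sprintf("SearchResult for query '%s' (%d hits)\n",
              attr(x, "query_id"), nrow(x)))
  print.data.frame(cbind(rank = seq_len(nrow(x)),
                         x[, c("target_id", "score", "qvalue")]),
                   row.names = FALSE, digits = 4)
  invisible(x)
}

#' Similarity network at an empirical-FDR threshold
#'
#' Scores every pair of indexed profiles and keeps undirected edges whose
#' empirical q-value is below \code{q_threshold}. Node attributes carry each
#' profile's source experiment and comparison for downstream coloring.
#'
#' @param index a \code{\link{build_index}} result.
#' @param null a \code{\link{sample_null}} result (same scoring settings).
#' @param q_threshold edge inclusion threshold (default 0.001).
#' @param scheme,method,absolute,min_overlap scoring settings.
#' @return an object of class \code{"SimilarityNetwork"}: \code{edges}
#'   (data.frame \code{profile_a}, \code{profile_b}, \code{score},
#'   \code{qvalue}) and \code{nodes} (data.frame \code{profile_id},
#'   \code{source_experiment}, \code{comparison}).
#' @export
build_network <- function(index, null, q_threshold = 0.001,
                          scheme = weight_scheme("p_value"),
                          method = "pearson", absolute = TRUE,
                          min_overlap = NULL) {
  stopifnot(inherits(index, "ProfileIndex"),
            inherits(null, "NullDistribution"))
  prof <- index$profiles
  n <- length(prof)
  ids <- names(prof)
  pairs <- all_pairs(n)
  scores <- vapply(seq_len(nrow(pairs)), function(k) {
    similarity_score(prof[[pairs[k, 1L]]], prof[[pairs[k, 2L]]],
                     scheme = scheme, method = method, absolute = absolute,
                     min_overlap = min_overlap)$score
  }, numeric(1))
  qv <- empirical_q(scores, null,
                    mode = if (absolute) "absolute" else "signed")
  keep <- qv < q_threshold
  edges <- data.frame(profile_a = ids[pairs[keep, 1L]],
                      profile_b = ids[pairs[keep, 2L]],
                      score = scores[keep], qvalue = qv[keep],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$qvalue, -edges$score), ]
  rownames(edges) <- NULL
  nodes <- data.frame(
    profile_id = ids,
    source_experiment = vapply(prof, function(p)
      as.character(p$source_experiment), character(1)),
    comparison = vapply(prof, function(p)
      paste(p$comparison, collapse = " vs "), character(1)),
    stringsAsFactors = FALSE)
  rownames(nodes) <- NULL
  structure(list(edges = edges, nodes = nodes, q_threshold = q_threshold),
            class = "SimilarityNetwork")
}

#' @export
print.SimilarityNetwork <- function(x, ...) {
  cat(sprintf("SimilarityNetwork: %d nodes, %d edges at q < %g\n",
              nrow(x$nodes), nrow(x$edges), x$q_threshold))
  invisible(x)
}

#' Write a similarity network as tab-separated edge and node lists
#'
#' @param network a \code{\link{build_network}} result.
#' @param edges_path,nodes_path output file paths.
#' @return the network, invisibly.
#' @export
write_network <- function(network, edges_path, nodes_path = NULL) {
  utils::write.table(network$edges, edges_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(nodes_path))
    utils::write.table(network$nodes, nodes_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(network)
}
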