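#' Weighting scheme for profile similarity
#'
#' Three schemes: \code{"unweighted"} (all features equal);
#' \code{"inverse_variance"} (each feature weighted by the inverse of its
#' variance across the compendium, supplied via
#' \code{compendium_variances}); and \code{"p_value"} (Eq.-2-style weights
#' \code{w_i = (-log(p_i1 * p_i2))^(1/C)} built from the two profiles'
#' FDR-adjusted p-values, natural log, default scaling \code{C = 2}).
#'
#' @param kind one of \code{"p_value"}, \code{"unweighted"},
#'   \code{"inverse_variance"}.
#' @param C positive scaling exponent for the p-value weights (default 2).
#' @param compendium_variances named positive numeric vector, required for
#'   \code{"inverse_variance"}.
#' @return an object of class \code{"WeightScheme"}.
#' @export
weight_scheme <- function(kind = c("p_value", "unweighted", "inverse_variance"),
                          C = 2, compendium_variances = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(C), length(C) == 1L, C > 0)
  if (kind == "inverse_variance") {
    if (is.null(compendium_variances) || is.null(names(compendium_variances)))
      stop("inverse_variance weighting requires named compendium_variances")
    if (any(compendium_variances <= 0))
      stop("compendium variances must be positive")
  }
  structure(list(kind = kind, C = C,
                 compendium_variances = compendium_variances),
            class = "WeightScheme")
}

#' @export
print.WeightScheme <- function(x, ...) {
  cat(sprintf("WeightScheme: %s (C = %g)\n", x$kind, x$C))
  invisible(x)
}

#' Significance weights from two p-value vectors
#'
#' \code{w_i = (-log(p_i1 * p_i2))^(1/C)} with the natural log; a feature at
#' p = 1 in both profiles gets weight 0, and smaller p-values in either
#' profile increase the weight monotonically.
#'
#' @param p1,p2 aligned numeric vectors of FDR-adjusted p-values in (0, 1]
#'   (floor exact zeros upstream, e.g. at 1e-300).
#' @param C positive scaling exponent (default 2).
#' @return non-negative numeric vector of weights.
#' @export
p_weights <- function(p1, p2, C = 2) {
  if (length(p1) != length(p2)) stop("p1 and p2 must be aligned")
  if (any(p1 <= 0 | p1 > 1) || any(p2 <= 0 | p2 > 1))
    stop("p-values must lie in (0, 1]")
  stopifnot(C > 0)
  (-(log(p1) + log(p2)))^(1 / C)
}

#' Weighted Pearson or Spearman correlation
#'
#' Weighted Pearson uses weighted means and a weighted covariance:
#' \code{r = sum(w*(x - xw)*(y - yw)) / sqrt(sum(w*(x - xw)^2) *
#' sum(w*(y - yw)^2))} with \code{xw = sum(w*x)/sum(w)}. The Spearman
#' variant replaces x and y by average-tie ranks (computed unweighted)
#' before applying the same formula. Features with a missing value in x, y
#' or w are dropped; at least 3 complete features and positive total weight
#' are required.
#'
#' @param x,y aligned numeric vectors.
#' @param w non-negative weights.
#' @param method \code{"pearson"} or \code{"spearman"}.
#' @return correlation in [-1, 1].
#' @export
weighted_correlation <- function(x, y, w = rep(1, length(x)),
                                 method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y) || length(x) != length(w))
    stop("x, y and w must be aligned")
  ok <- is.finite(x) & is.finite(y) & is.finite(w)
  x <- x[ok]; y <- y[ok]; w <- w[ok]
  if (length(x) < 3L) stop("need at least 3 complete features")
  if (any(w < 0)) stop("weights must be non-negative")
  if (sum(w) <= 0) stop("total weight must be positive")
  if (method == "spearman") {
    x <- avg_rank(x)
    y <- avg_rank(y)
  }
  sw <- sum(w)
  xw <- sum(w * x) / sw
  yw <- sum(w * y) / sw
  vx <- sum(w * (x - xw)^2)
  vy <- sum(w * (y - yw)^2)
  if (vx <= 0 || vy <= 0)
    stop("zero weighted variance: correlation undefined")
  sum(w * (x - xw) * (y - yw)) / sqrt(vx * vy)
}

#' Similarity between two DE profiles
#'
#' Aligns the profiles on their shared features (requiring at least
#' \code{min_overlap} of them), builds weights according to the scheme, and
#' returns the weighted correlation together with the per-feature
#' contribution decomposition
#' \code{contrib_i = w_i*(x_i - xw)*(y_i - yw) / sqrt(vx * vy)}, which sums
#' exactly to the signed correlation. In absolute mode (used when the
#' direction of a comparison is arbitrary) the reported score is |r| but
#' contributions stay signed.
#'
#' @param profile_a,profile_b \code{DEProfile}s in the same space.
#' @param scheme a \code{\link{weight_scheme}}.
#' @param method \code{"pearson"} or \code{"spearman"}.
#' @param absolute report |r| instead of r.
#' @param min_overlap minimum shared-feature count; defaults to 100 in gene
#'   space and 10 otherwise.
#' @return list with \code{score}, \code{signed_score}, \code{n_shared},
#'   \code{weights} and \code{contributions} (both named by feature).
#' @export
similarity_score <- function(profile_a, profile_b,
                             scheme = weight_scheme("p_value"),
                             method = c("pearson", "spearman"),
                             absolute = FALSE, min_overlap = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(profile_a, "DEProfile"), inherits(profile_b, "DEProfile"),
            inherits(scheme, "WeightScheme"))
  if (profile_a$space != profile_b$space)
    stop("profiles are in different spaces: ", profile_a$space, " vs ",
         profile_b$space)
  if (is.null(min_overlap))
    min_overlap <- if (profile_a$space == "gene") 100L else 10L
  common <- intersect(profile_a$feature_ids, profile_b$feature_ids)
  if (length(common) < min_overlap)
    stop(sprintf("only %d features shared between '%s' and '%s' (minimum %d)",
                 length(common), profile_a$profile_id, profile_b$profile_id,
                 min_overlap))
  x <- profile_a$scores[common]
  y <- profile_b$scores[common]
  w <- switch(scheme$kind,
    unweighted = rep(1, length(common)),
    p_value = {
      if (is.null(profile_a$pvalues) || is.null(profile_b$pvalues))
        stop("p_value weighting requires p-values on both profiles")
      p_weights(profile_a$pvalues[common], profile_b$pvalues[common],
                C = scheme$C)
    },
    inverse_variance = {
      cv <- scheme$compendium_variances[common]
      if (any(is.na(cv)))
        stop("compendium variances missing for ",
             sum(is.na(cv)), " shared features")
      1 / cv
    })
  ok <- is.finite(x) & is.finite(y) & is.finite(w)
  x <- x[ok]; y <- y[ok]; w <- w[ok]
  if (length(x) < min_overlap)
    stop(sprintf("only %d complete shared features between '%s' and '%s' (minimum %d)",
                 length(x), profile_a$profile_id, profile_b$profile_id,
                 min_overlap))
  if (sum(w) <= 0) stop("total weight is zero; correlation undefined")
  if (method == "spearman") {
    x <- avg_rank(x)
    y <- avg_rank(y)
  }
  sw <- sum(w)
  xw <- sum(w * x) / sw
  yw <- sum(w * y) / sw
  vx <- sum(w * (x - xw)^2)
  vy <- sum(w * (y - yw)^2)
  if (vx <= 0 || vy <= 0)
    stop("zero weighted variance: correlation undefined")
  contrib <- w * (x - xw) * (y - yw) / sqrt(vx * vy)
  r <- sum(contrib)
  list(score = if (absolute) abs(r) else r,
       signed_score = r,
       n_shared = length(x),
       weights = w,
       contributions = contrib)
}
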