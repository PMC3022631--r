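#' Aggregate probes to genes by the fixed-effect meta-estimate
#'
#' Each probe's variance is estimated across all samples of the experiment
#' (floored at \code{var_floor} for constant probes); per gene and sample the
#' aggregated value is the inverse-variance weighted mean of its probes, and
#' the reported per-gene variance is \code{1 / sum(1/v_p)} — the standard
#' fixed-effect meta-analysis estimate applied to probe sets.
#'
#' @param experiment a log-scale probe-level \code{ExpressionExperiment}.
#' @param probe_map named character vector (names = probe ids, values = gene
#'   ids) or a data.frame with columns \code{probe_id}, \code{gene_id}.
#'   Probes absent from the map are dropped.
#' @param var_floor lower bound for probe variances (default \code{1e-8}).
#' @return a gene-level \code{ExpressionExperiment} whose
#'   \code{feature_variances} carry the per-gene meta-variance.
#' @export
aggregate_probes_fixed_effects <- function(experiment, probe_map,
                                           var_floor = 1e-8) {
  stopifnot(inherits(experiment, "ExpressionExperiment"))
  probe_map <- as_probe_map(probe_map)
  v <- experiment$values
  common <- intersect(rownames(v), names(probe_map))
  if (length(common) == 0L)
    stop("no probes of the experiment are present in the probe map")
  v <- v[common, , drop = FALSE]
  genes <- unname(probe_map[common])

  pv <- apply(v, 1L, stats::var, na.rm = TRUE)
  pv[is.na(pv) | pv < var_floor] <- var_floor
  w <- 1 / pv

  obs <- !is.na(v)
  vw <- v * w
  vw[!obs] <- 0
  num <- rowsum(vw, genes)
  den <- rowsum(w * obs, genes)
  agg <- num / den
  agg[den == 0] <- NA_real_

  gene_var <- 1 / as.vector(rowsum(w, genes))
  names(gene_var) <- rownames(rowsum(w, genes))

  expression_experiment(agg,
                        groups = experiment$groups,
                        experiment_id = experiment$experiment_id,
                        factor_name = experiment$factor,
                        species = experiment$species,
                        is_log_scale = experiment$is_log_scale,
                        feature_variances = gene_var[rownames(agg)])
}

as_probe_map <- function(probe_map) {
  if (is.data.frame(probe_map)) {
    if (!all(c("probe_id", "gene_id") %in% names(probe_map)))
      stop("probe map data.frame needs columns probe_id, gene_id")
    probe_map <- stats::setNames(as.character(probe_map$gene_id),
                                 as.character(probe_map$probe_id))
  }
  if (is.null(names(probe_map))) stop("probe map must be named by probe id")
  probe_map
}

#' Read a probe -> gene map
#'
#' Tab-separated file with columns \code{probe_id}, \code{gene_id}.
#' @param path file path.
#' @return named character vector (probe id -> gene id).
#' @export
read_probe_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  as_probe_map(df)
}

group_columns <- function(experiment, group) {
  idx <- which(experiment$groups == group)
  if (length(idx) == 0L)
    stop("unknown group label '", group, "' in experiment '",
         experiment$experiment_id, "'")
  idx
}

#' Log fold-change profile
#'
#' Per feature, the difference of group mean log2 values:
#' \code{mean(group_a) - mean(group_b)} (missing values excluded per group).
#'
#' @param experiment a gene-level, log-scale \code{ExpressionExperiment}.
#' @param group_a,group_b group labels; scores are a minus b.
#' @return a gene-space \code{DEProfile}; per-feature variances are carried
#'   over from probe aggregation when present.
#' @export
logfc_profile <- function(experiment, group_a, group_b) {
  stopifnot(inherits(experiment, "ExpressionExperiment"))
  ia <- group_columns(experiment, group_a)
  ib <- group_columns(experiment, group_b)
  v <- experiment$values
  scores <- rowMeans(v[, ia, drop = FALSE], na.rm = TRUE) -
    rowMeans(v[, ib, drop = FALSE], na.rm = TRUE)
  de_profile(profile_id = paste0(experiment$experiment_id, ":",
                                 group_a, "_vs_", group_b),
             feature_ids = rownames(v), scores = scores, space = "gene",
             variances = experiment$feature_variances,
             comparison = c(group_a, group_b),
             source_experiment = experiment$experiment_id)
}

#' Empirical-Bayes moderated t-test for a two-group comparison
#'
#' Per feature, the pooled within-group variance \code{s_g^2} on
#' \code{d_g = n_a + n_b - 2} residual degrees of freedom is shrunk toward a
#' prior: \code{s_tilde^2 = (d0*s0^2 + d_g*s_g^2) / (d0 + d_g)}, and the
#' moderated statistic \code{t = diff / (s_tilde * sqrt(1/n_a + 1/n_b))} is
#' referred to a t distribution on \code{d0 + d_g} degrees of freedom. The
#' prior \code{(d0, s0^2)} is estimated by method of moments on
#' \code{log s_g^2} using digamma/trigamma matching; features with no
#' residual degrees of freedom are excluded from the fit and assigned p = 1.
#' Adjusted p-values use Benjamini-Hochberg (\code{\link{bh_adjust}}).
#'
#' @inheritParams logfc_profile
#' @param prior_df optional override for the prior degrees of freedom
#'   \code{d0}; \code{0} reproduces the ordinary pooled-variance t-test,
#'   \code{Inf} forces full shrinkage to the prior variance.
#' @return an object of class \code{"ModeratedTestResult"}: a list with
#'   per-feature \code{logfc}, \code{s2}, \code{df}, \code{t},
#'   \code{p_value}, \code{adj_p_value}, and global \code{prior_df},
#'   \code{prior_var}.
#' @export
moderated_t_pvalues <- function(experiment, group_a, group_b,
                                prior_df = NULL) {
  stopifnot(inherits(experiment, "ExpressionExperiment"))
  ia <- group_columns(experiment, group_a)
  ib <- group_columns(experiment, group_b)
  va <- experiment$values[, ia, drop = FALSE]
  vb <- experiment$values[, ib, drop = FALSE]

  na <- rowSums(!is.na(va))
  nb <- rowSums(!is.na(vb))
  ma <- rowMeans(va, na.rm = TRUE)
  mb <- rowMeans(vb, na.rm = TRUE)
  delta <- ma - mb
  ssa <- rowSums((va - ma)^2, na.rm = TRUE)
  ssb <- rowSums((vb - mb)^2, na.rm = TRUE)
  dg <- pmax(na + nb - 2, 0)
  s2 <- ifelse(dg > 0, (ssa + ssb) / pmax(dg, 1), NA_real_)

  fit_ok <- dg > 0 & is.finite(s2) & s2 > 0
  if (is.null(prior_df)) {
    if (sum(fit_ok) < 2L)
      stop("fewer than 2 features with positive residual df: prior inestimable")
    fit <- fit_f_dist(s2[fit_ok], dg[fit_ok])
    d0 <- fit$df_prior
    s02 <- fit$var_prior
  } else {
    stopifnot(length(prior_df) == 1L, prior_df >= 0)
    d0 <- prior_df
    s02 <- if (any(fit_ok)) stats::median(s2[fit_ok]) else 1
  }

  s2_use <- ifelse(is.na(s2), 0, s2)
  if (is.infinite(d0)) {
    s2_tilde <- rep(s02, length(s2_use))
  } else {
    s2_tilde <- (d0 * s02 + dg * s2_use) / (d0 + dg)
    s2_tilde[d0 + dg == 0] <- NA_real_
  }
  se <- sqrt(s2_tilde * (1 / pmax(na, 1) + 1 / pmax(nb, 1)))
  tstat <- delta / se
  tstat[delta == 0] <- 0
  df_total <- d0 + dg
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  p[!is.finite(tstat) & delta != 0] <- 1e-300
  p[df_total == 0 | na == 0 | nb == 0] <- 1
  p[is.na(p)] <- 1
  p <- pmax(p, 1e-300)
  adj <- bh_adjust(p)

  structure(
    list(feature_ids = rownames(experiment$values),
         logfc = delta, s2 = s2, df = dg,
         n_a = na, n_b = nb,
         prior_df = d0, prior_var = s02,
         s2_posterior = s2_tilde,
         t = tstat, p_value = p, adj_p_value = adj,
         comparison = c(group_a, group_b),
         source_experiment = experiment$experiment_id),
    class = "ModeratedTestResult")
}

#' @export
print.ModeratedTestResult <- function(x, ...) {
  cat(sprintf("ModeratedTestResult (%s vs %s): %d features\n",
              x$comparison[1L], x$comparison[2L], length(x$feature_ids)))
  cat(sprintf("  prior df d0 = %.4g, prior variance s0^2 = %.4g\n",
              x$prior_df, x$prior_var))
  cat(sprintf("  %d features at adjusted p < 0.05\n",
              sum(x$adj_p_value < 0.05)))
  invisible(x)
}

# Moment estimator for the scaled-F model of sample variances: given s2 on
# df degrees of freedom where s2 ~ s0^2 * F(df, d0), match mean and variance
# of log(s2) via digamma/trigamma.
fit_f_dist <- function(s2, df) {
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- sum((e - emean)^2) / (n - 1L) - mean(trigamma(df / 2))
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- exp(emean)
  }
  list(df_prior = d0, var_prior = s02)
}

# Solve trigamma(x) = y by Newton iteration on 1/trigamma (monotone convex).
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (-dif / x < 1e-8) break
  }
  x
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Validates that p-values lie in (0, 1] and applies the standard step-up
#' FDR correction, returned in the input order.
#'
#' @param pvalues numeric vector of raw p-values in (0, 1].
#' @return adjusted p-values, elementwise at or above the input.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues <= 0 | pvalues > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' P-value DE profile
#'
#' Builds a gene-space profile from \code{\link{moderated_t_pvalues}}: the
#' scores are the log2 fold-changes and the attached p-values are the
#' FDR-adjusted moderated-t p-values (floored at 1e-300), as required by the
#' p-value-weighted correlation.
#'
#' @inheritParams moderated_t_pvalues
#' @return a gene-space \code{DEProfile} with \code{pvalues} and
#'   \code{variances} (squared standard error of the fold-change).
#' @export
pvalue_profile <- function(experiment, group_a, group_b) {
  res <- moderated_t_pvalues(experiment, group_a, group_b)
  vars <- experiment$feature_variances
  if (is.null(vars))
    vars <- res$s2_posterior * (1 / pmax(res$n_a, 1) + 1 / pmax(res$n_b, 1))
  de_profile(profile_id = paste0(experiment$experiment_id, ":",
                                 group_a, "_vs_", group_b),
             feature_ids = res$feature_ids,
             scores = res$logfc, space = "gene",
             pvalues = pmax(res$adj_p_value, 1e-300),
             variances = vars,
             comparison = c(group_a, group_b),
             source_experiment = experiment$experiment_id)
}

#' Rank-based DE profile
#'
#' Works from the raw probe-level matrix: per sample, probes are ranked
#' ascending (average ties); ranks are averaged within each group; per gene,
#' the score is the median over all ordered probe pairs (p, q) of that gene
#' of group_a's mean rank of p minus group_b's mean rank of q. Invariant to
#' any strictly increasing per-sample transform of the raw values.
#'
#' @param experiment probe-level \code{ExpressionExperiment} (raw values).
#' @param group_a,group_b group labels.
#' @param probe_map probe -> gene map as in
#'   \code{\link{aggregate_probes_fixed_effects}}.
#' @return a gene-space \code{DEProfile} (no p-values or variances).
#' @export
rank_profile <- function(experiment, group_a, group_b, probe_map) {
  stopifnot(inherits(experiment, "ExpressionExperiment"))
  probe_map <- as_probe_map(probe_map)
  v <- experiment$values
  common <- intersect(rownames(v), names(probe_map))
  if (length(common) == 0L)
    stop("no probes of the experiment are present in the probe map")
  # rank over all probes of the experiment, then restrict to mapped ones
  ranks <- apply(v, 2L, avg_rank)[common, , drop = FALSE]
  ia <- group_columns(experiment, group_a)
  ib <- group_columns(experiment, group_b)
  ra <- rowMeans(ranks[, ia, drop = FALSE], na.rm = TRUE)
  rb <- rowMeans(ranks[, ib, drop = FALSE], na.rm = TRUE)
  genes <- unname(probe_map[common])
  split_a <- split(ra, genes)
  split_b <- split(rb, genes)
  scores <- mapply(function(a, b) stats::median(outer(a, b, `-`)),
                   split_a, split_b)
  de_profile(profile_id = paste0(experiment$experiment_id, ":",
                                 group_a, "_vs_", group_b),
             feature_ids = names(scores), scores = unname(scores),
             space = "gene",
             comparison = c(group_a, group_b),
             source_experiment = experiment$experiment_id)
}

#' Map a profile to human gene identifiers
#'
#' Renames features to their human homologs, keeping only genes with a
#' one-to-one homolog (the count of dropped features is reported). Human
#' profiles pass through unchanged.
#'
#' @param profile a gene-space \code{DEProfile}.
#' @param homologs a \code{\link{homolog_map}}.
#' @param species source species of the profile.
#' @return the mapped \code{DEProfile}.
#' @export
map_to_human <- function(profile, homologs, species) {
  stopifnot(inherits(profile, "DEProfile"))
  if (profile$space != "gene") stop("homolog mapping applies to gene-space profiles")
  if (identical(species, "human")) return(profile)
  hm <- homologs[homologs$species == species & homologs$one_to_one, ]
  idx <- match(profile$feature_ids, hm$source_gene_id)
  keep <- !is.na(idx)
  if (!any(keep))
    stop("profile '", profile$profile_id, "' failed to map to human genes")
  dropped <- sum(!keep)
  if (dropped > 0L)
    msg(sprintf("'%s': dropped %d/%d features without one-to-one human homologs",
                profile$profile_id, dropped, length(keep)))
  de_profile(profile_id = profile$profile_id,
             feature_ids = hm$human_gene_id[idx[keep]],
             scores = profile$scores[keep], space = "gene",
             pvalues = profile$pvalues[keep],
             variances = profile$variances[keep],
             comparison = profile$comparison,
             source_experiment = profile$source_experiment)
}

#' Enumerate two-group comparisons within an experiment
#'
#' All unordered pairs of group labels of the experiment's factor, ordered
#' lexicographically (within a pair the smaller label comes first), e.g.
#' groups \{1 hr, 2 hr, 4 hr\} yield (1 hr, 2 hr), (1 hr, 4 hr), (2 hr, 4 hr).
#'
#' @param experiment an \code{ExpressionExperiment}.
#' @return data.frame with columns \code{group_a}, \code{group_b}.
#' @export
enumerate_comparisons <- function(experiment) {
  stopifnot(inherits(experiment, "ExpressionExperiment"))
  g <- sort(unique(unname(experiment$groups)), method = "radix")
  if (length(g) < 2L) stop("need at least 2 groups to form a comparison")
  pairs <- utils::combn(g, 2L)
  data.frame(group_a = pairs[1L, ], group_b = pairs[2L, ],
             stringsAsFactors = FALSE)
}
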