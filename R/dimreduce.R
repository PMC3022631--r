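#' Project a gene-space profile onto a component basis
#'
#' The reduced profile is the loadings-weighted sum of gene scores over the
#' genes common to the profile and the basis: for component c,
#' \code{A[c] = sum_g S[c, g] * X[g]}. Genes present in the basis but absent
#' from the profile contribute zero (intersection semantics).
#'
#' @param profile a gene-space \code{DEProfile}.
#' @param components a \code{\link{component_matrix}}.
#' @return a component-space \code{DEProfile} (no p-values; to obtain
#'   per-component p-values project the sample-level data with
#'   \code{\link{component_profile}}).
#' @export
project_ica <- function(profile, components) {
  stopifnot(inherits(profile, "DEProfile"),
            inherits(components, "ComponentMatrix"))
  if (profile$space != "gene") stop("projection applies to gene-space profiles")
  common <- intersect(profile$feature_ids, components$gene_ids)
  if (length(common) == 0L)
    stop("no genes shared between profile '", profile$profile_id,
         "' and the component matrix")
  s <- components$loadings[, common, drop = FALSE]
  x <- profile$scores[common]
  a <- as.vector(s %*% x)
  de_profile(profile_id = profile$profile_id,
             feature_ids = components$component_ids,
             scores = a, space = "component",
             comparison = profile$comparison,
             source_experiment = profile$source_experiment)
}

#' Component-space profile with moderated-t p-values
#'
#' Projects each sample's (gene-level, log-scale) expression onto the
#' component basis, then applies the moderated t-test to the projected
#' values. Because projection is linear, the resulting component scores
#' equal the projection of the gene-space log fold-change; the p-values
#' measure differential expression of each component.
#'
#' @param experiment gene-level log-scale \code{ExpressionExperiment}.
#' @param components a \code{\link{component_matrix}}.
#' @param group_a,group_b group labels (scores = a minus b).
#' @return a component-space \code{DEProfile} with FDR-adjusted p-values and
#'   per-component variances.
#' @export
component_profile <- function(experiment, components, group_a, group_b) {
  stopifnot(inherits(experiment, "ExpressionExperiment"),
            inherits(components, "ComponentMatrix"))
  common <- intersect(rownames(experiment$values), components$gene_ids)
  if (length(common) == 0L)
    stop("no genes shared between experiment '", experiment$experiment_id,
         "' and the component matrix")
  s <- components$loadings[, common, drop = FALSE]
  v <- experiment$values[common, , drop = FALSE]
  v[is.na(v)] <- 0  # missing gene contributes nothing to the projection
  proj <- s %*% v
  pe <- expression_experiment(proj, groups = experiment$groups,
                              experiment_id = experiment$experiment_id,
                              factor_name = experiment$factor,
                              species = experiment$species,
                              is_log_scale = TRUE)
  res <- moderated_t_pvalues(pe, group_a, group_b)
  de_profile(profile_id = paste0(experiment$experiment_id, ":",
                                 group_a, "_vs_", group_b),
             feature_ids = res$feature_ids,
             scores = res$logfc, space = "component",
             pvalues = pmax(res$adj_p_value, 1e-300),
             variances = res$s2_posterior *
               (1 / pmax(res$n_a, 1) + 1 / pmax(res$n_b, 1)),
             comparison = c(group_a, group_b),
             source_experiment = experiment$experiment_id)
}

#' Derive a component basis from an expression compendium
#'
#' Four steps: (1) balance over-represented conditions by hierarchical
#' clustering of samples on correlation distance, cutting at
#' \code{balance_height} and keeping one medoid representative per cluster;
#' (2) run fixed-point ICA (logcosh contrast, PCA whitening)
#' \code{n_runs} times from different random starts; (3) pool all estimated
#' components, unit-normalized and sign-oriented so the heavier loading tail
#' is positive, and cluster them into \code{n_components} groups by
#' partitioning around medoids on \code{1 - |Pearson r|} distance (so
#' sign-flipped duplicates cluster together); (4) return the medoid of each
#' cluster.
#'
#' @param compendium numeric matrix, samples x genes (column names = gene
#'   ids).
#' @param n_components number of components to return.
#' @param n_runs number of ICA restarts pooled before clustering
#'   (default 20); with \code{n_runs = 1} the single run is returned
#'   directly.
#' @param seed integer seed controlling all randomness.
#' @param balance_height cut height on the correlation-distance dendrogram
#'   for the balancing step (default 0.05); near-duplicate samples collapse
#'   to one representative.
#' @param maxit,tol fixed-point iteration controls.
#' @return a \code{\link{component_matrix}} with unit-L2 rows.
#' @export
derive_components <- function(compendium, n_components, n_runs = 20,
                              seed = 1, balance_height = 0.05,
                              maxit = 200, tol = 1e-6) {
  x <- as.matrix(compendium)
  if (is.null(colnames(x))) stop("compendium must carry gene column names")

  # (1) balance: collapse clusters of near-identical samples to medoids
  if (nrow(x) > 2L) {
    dmat <- 1 - stats::cor(t(x))
    dmat[dmat < 0] <- 0
    hc <- stats::hclust(stats::as.dist(dmat), method = "average")
    cl <- stats::cutree(hc, h = balance_height)
    reps <- vapply(split(seq_len(nrow(x)), cl), function(idx) {
      if (length(idx) == 1L) return(idx)
      idx[which.min(rowSums(dmat[idx, idx, drop = FALSE]))]
    }, integer(1))
    reps <- sort(unname(reps))
    if (length(reps) < nrow(x))
      msg(sprintf("balancing kept %d of %d samples", length(reps), nrow(x)))
    x <- x[reps, , drop = FALSE]
  }
  if (n_components > min(dim(x)))
    stop("n_components exceeds the available rank after balancing")

  runs <- lapply(seq_len(n_runs), function(r) {
    orient_components(fastica_logcosh(x, n_components, seed = seed + r - 1L,
                                      maxit = maxit, tol = tol))
  })
  if (n_runs == 1L) {
    s <- runs[[1L]]
    rownames(s) <- sprintf("IC%03d", seq_len(nrow(s)))
    return(component_matrix(s))
  }

  pooled <- do.call(rbind, runs)
  dd <- 1 - abs(stats::cor(t(pooled)))
  dd[dd < 0] <- 0
  pm <- cluster::pam(stats::as.dist(dd), k = n_components,
                     pamonce = 5, cluster.only = FALSE)
  s <- orient_components(pooled[pm$id.med, , drop = FALSE])
  rownames(s) <- sprintf("IC%03d", seq_len(nrow(s)))
  component_matrix(s)
}

#' Stack experiments into a samples x genes compendium matrix
#'
#' Binds the samples of several gene-level experiments into one matrix over
#' the union of their genes, for component derivation. Genes absent from an
#' experiment's platform are imputed at the gene's mean across the samples
#' that do measure it (so they carry no differential signal), and genes
#' measured nowhere are dropped.
#'
#' @param experiments list of gene-level, log-scale
#'   \code{ExpressionExperiment}s with a shared gene namespace (map
#'   non-human experiments to human ids first).
#' @return numeric matrix, samples x genes, with gene column names.
#' @export
stack_experiments <- function(experiments) {
  genes <- unique(unlist(lapply(experiments, function(e) rownames(e$values))))
  mats <- lapply(experiments, function(e) {
    m <- matrix(NA_real_, nrow = ncol(e$values), ncol = length(genes),
                dimnames = list(colnames(e$values), genes))
    m[, rownames(e$values)] <- t(e$values)
    m
  })
  x <- do.call(rbind, mats)
  mu <- colMeans(x, na.rm = TRUE)
  seen <- is.finite(mu)
  x <- x[, seen, drop = FALSE]
  mu <- mu[seen]
  for (j in which(colSums(is.na(x)) > 0L))
    x[is.na(x[, j]), j] <- mu[j]
  x
}

#' Extract gene modules from a component basis
#'
#' Per component, the module is the set of genes whose loading exceeds the
#' component's mean loading by more than \code{n_sd} standard deviations
#' (positive direction only; components are oriented so the heavy tail is
#' positive). Components yielding an empty module are dropped with a
#' warning.
#'
#' @param components a \code{\link{component_matrix}}.
#' @param n_sd threshold in SD units (default 3).
#' @return a \code{\link{gene_set_collection}}.
#' @export
ica_modules <- function(components, n_sd = 3) {
  stopifnot(inherits(components, "ComponentMatrix"))
  l <- components$loadings
  sets <- list()
  for (i in seq_len(nrow(l))) {
    row <- l[i, ]
    s <- stats::sd(row, na.rm = TRUE)
    thr <- mean(row, na.rm = TRUE) + n_sd * s
    genes <- if (is.na(s) || s == 0) character(0) else
      colnames(l)[!is.na(row) & row > thr]
    if (length(genes) == 0L) {
      warning("component '", rownames(l)[i], "' yields an empty module; dropped")
      next
    }
    sets[[rownames(l)[i]]] <-
      list(description = sprintf("genes > %g SD above mean loading", n_sd),
           genes = genes)
  }
  gene_set_collection(sets)
}

#' Gene-set meta-scores for a profile
#'
#' Per gene set, the fixed-effect meta-estimate over member genes present in
#' the profile: meta-score = \code{sum(score/v) / sum(1/v)}, meta-variance =
#' \code{1 / sum(1/v)} — the same inverse-variance weighting used for
#' probe aggregation. Sets with no member present are dropped.
#'
#' @param profile a gene-space \code{DEProfile} carrying per-gene variances.
#' @param gene_sets a \code{\link{gene_set_collection}}.
#' @param var_floor lower bound applied to gene variances.
#' @return a module-space \code{DEProfile} with scores and variances.
#' @export
module_meta_scores <- function(profile, gene_sets, var_floor = 1e-8) {
  stopifnot(inherits(profile, "DEProfile"),
            inherits(gene_sets, "GeneSetCollection"))
  if (is.null(profile$variances))
    stop("profile '", profile$profile_id, "' lacks per-gene variances")
  v <- pmax(profile$variances, var_floor)
  ids <- character(0); sc <- numeric(0); vr <- numeric(0)
  for (nm in names(gene_sets)) {
    members <- intersect(gene_sets[[nm]]$genes, profile$feature_ids)
    if (length(members) == 0L) next
    m <- fixed_effect_meta(profile$scores[members], v[members])
    ids <- c(ids, nm); sc <- c(sc, m$estimate); vr <- c(vr, m$variance)
  }
  if (length(ids) == 0L)
    stop("no gene set overlaps profile '", profile$profile_id, "'")
  de_profile(profile_id = profile$profile_id,
             feature_ids = ids, scores = sc, space = "module",
             variances = vr,
             comparison = profile$comparison,
             source_experiment = profile$source_experiment)
}
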