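#' Expression experiment container
#'
#' Bundles a features x samples expression matrix with the sample -> group
#' annotation needed to form two-group comparisons: the experimental factor
#' (e.g. \code{"disease state"} or \code{"time"}), the species, and a flag
#' recording whether values are on the log2 scale.
#'
#' @param values numeric matrix, features in rows, samples in columns.
#' @param feature_ids,sample_ids character vectors naming rows/columns; taken
#'   from \code{dimnames(values)} when omitted.
#' @param groups named character vector mapping every sample id to a group
#'   label.
#' @param experiment_id single string identifying the experiment.
#' @param factor_name the experimental variable the groups enumerate.
#' @param species species of origin (\code{"human"} needs no homolog mapping).
#' @param is_log_scale \code{TRUE}/\code{FALSE}/\code{NA}; \code{NA} means
#'   undecided, see \code{\link{ensure_log_scale}}.
#' @param feature_variances optional per-feature variances (e.g. from probe
#'   aggregation), named by feature id.
#'
#' @return an object of class \code{"ExpressionExperiment"}.
#' @seealso [read_expression_matrix()], [ensure_log_scale()]
#' @export
expression_experiment <- function(values, groups,
                                  experiment_id = "experiment",
                                  factor_name = "group",
                                  species = "human",
                                  is_log_scale = NA,
                                  feature_ids = rownames(values),
                                  sample_ids = colnames(values),
                                  feature_variances = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(feature_ids) || is.null(sample_ids))
    stop("values must have feature and sample identifiers")
  if (anyDuplicated(feature_ids)) {
    dup <- unique(feature_ids[duplicated(feature_ids)])
    stop("duplicate feature ids: ", paste(dup, collapse = ", "))
  }
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  rownames(values) <- feature_ids
  colnames(values) <- sample_ids
  groups <- groups[sample_ids]
  if (any(is.na(groups)) || is.null(names(groups)))
    stop("every sample must have exactly one group label")
  groups <- stats::setNames(as.character(groups), sample_ids)
  check_character_scalar(experiment_id, "experiment_id")
  check_character_scalar(factor_name, "factor_name")
  check_character_scalar(species, "species")
  if (!is.null(feature_variances)) {
    feature_variances <- feature_variances[feature_ids]
    names(feature_variances) <- feature_ids
  }
  structure(
    list(experiment_id = experiment_id,
         values = values,
         groups = groups,
         factor = factor_name,
         species = species,
         is_log_scale = is_log_scale,
         feature_variances = feature_variances),
    class = "ExpressionExperiment")
}

#' @export
print.ExpressionExperiment <- function(x, ...) {
  cat(sprintf("ExpressionExperiment '%s': %d features x %d samples\n",
              x$experiment_id, nrow(x$values), ncol(x$values)))
  tab <- table(x$groups)
  cat(sprintf("  factor '%s': %s\n", x$factor,
              paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
                    collapse = ", ")))
  cat(sprintf("  species: %s; log2 scale: %s\n", x$species,
              ifelse(is.na(x$is_log_scale), "undecided", x$is_log_scale)))
  invisible(x)
}

#' @export
dim.ExpressionExperiment <- function(x) dim(x$values)

#' Read an expression matrix and its sample annotation
#'
#' The matrix file is tab-separated with a \code{feature_id} column followed
#' by one column per sample; the annotation file is tab-separated with
#' columns \code{sample_id}, \code{group} and \code{factor}. Samples present
#' in the matrix but absent from the annotation are dropped with a warning.
#'
#' @param path path to the expression matrix.
#' @param annotation_path path to the sample annotation.
#' @param experiment_id identifier for the resulting experiment.
#' @param species species label stored on the experiment.
#' @return an \code{\link{expression_experiment}} with \code{is_log_scale}
#'   left undecided (\code{NA}); pass the result through
#'   \code{\link{ensure_log_scale}} before analysis.
#' @export
read_expression_matrix <- function(path, annotation_path,
                                   experiment_id = basename(path),
                                   species = "human") {
  mat <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(mat) < 2L) stop("expression matrix must have at least one sample column")
  feats <- as.character(mat[[1L]])
  if (anyDuplicated(feats)) {
    dup <- unique(feats[duplicated(feats)])
    stop("duplicate feature ids: ", paste(dup, collapse = ", "))
  }
  values <- as.matrix(mat[, -1L, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- feats

  ann <- utils::read.delim(annotation_path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "factor")
  if (!all(need %in% names(ann)))
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  keep <- colnames(values) %in% ann$sample_id
  if (!any(keep)) stop("no overlapping samples between matrix and annotation")
  if (!all(keep)) {
    warning("dropping samples absent from annotation: ",
            paste(colnames(values)[!keep], collapse = ", "))
    values <- values[, keep, drop = FALSE]
  }
  ann <- ann[match(colnames(values), ann$sample_id), ]
  expression_experiment(values,
                        groups = stats::setNames(ann$group, ann$sample_id),
                        experiment_id = experiment_id,
                        factor_name = ann$factor[1L],
                        species = species,
                        is_log_scale = NA)
}

#' Write an expression experiment to tab-separated files
#'
#' @param experiment an \code{ExpressionExperiment}.
#' @param path output path for the matrix.
#' @param annotation_path output path for the sample annotation.
#' @return the experiment, invisibly.
#' @export
write_expression_matrix <- function(experiment, path, annotation_path) {
  v <- experiment$values
  df <- data.frame(feature_id = rownames(v), check.names = FALSE,
                   stringsAsFactors = FALSE)
  for (j in seq_len(ncol(v))) df[[colnames(v)[j]]] <- format_full(v[, j])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ann <- data.frame(sample_id = names(experiment$groups),
                    group = unname(experiment$groups),
                    factor = experiment$factor,
                    stringsAsFactors = FALSE)
  utils::write.table(ann, annotation_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(experiment)
}

#' Decide and apply the log2 scale
#'
#' Microarray intensities arrive on either a linear or a log scale and the
#' two must not be mixed in fold-change computations. The decision rule:
#' any negative value, or a maximum at or below \code{linear_threshold},
#' marks the data as already log-scale (log2 intensities rarely exceed ~20,
#' linear ones exceed 50). Otherwise values at or below zero are floored at
#' \code{floor_value} and log2 is applied.
#'
#' The operation is idempotent: once \code{is_log_scale} is \code{TRUE} the
#' experiment is returned unchanged.
#'
#' @param experiment an \code{ExpressionExperiment}.
#' @param linear_threshold maximum value at or below which data are deemed
#'   log-scale already (default 50).
#' @param floor_value positive constant replacing non-positive values before
#'   log2 (default 1, i.e. log2 of 0).
#' @return the experiment with \code{is_log_scale = TRUE}.
#' @export
ensure_log_scale <- function(experiment, linear_threshold = 50,
                             floor_value = 1.0) {
  stopifnot(inherits(experiment, "ExpressionExperiment"))
  if (isTRUE(experiment$is_log_scale)) return(experiment)
  v <- experiment$values
  if (all(is.na(v))) stop("all expression values are missing")
  mn <- min(v, na.rm = TRUE)
  mx <- max(v, na.rm = TRUE)
  if (mn < 0 || mx <= linear_threshold) {
    msg(sprintf("'%s': values in [%.3g, %.3g] deemed already log2 (threshold %g)",
                experiment$experiment_id, mn, mx, linear_threshold))
  } else {
    msg(sprintf("'%s': max %.3g > %g, applying log2 (non-positive values floored at %g)",
                experiment$experiment_id, mx, linear_threshold, floor_value))
    v <- log2(pmax(v, floor_value))
    experiment$values <- v
  }
  experiment$is_log_scale <- TRUE
  experiment
}
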