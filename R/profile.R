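#' Differential-expression profile
#'
#' A DE profile condenses one two-group comparison to a vector of per-feature
#' scores (log2 fold-change by convention: first comparison group minus
#' second), optionally with FDR-adjusted p-values and per-feature variances.
#' The feature space is \code{"gene"}, \code{"component"} (scores projected
#' onto an ICA basis) or \code{"module"} (gene-set meta-scores).
#'
#' @param profile_id single string.
#' @param feature_ids unique character vector.
#' @param scores numeric vector aligned with \code{feature_ids}.
#' @param space one of \code{"gene"}, \code{"component"}, \code{"module"}.
#' @param pvalues optional numeric vector in (0, 1], FDR-adjusted.
#' @param variances optional non-negative numeric vector.
#' @param comparison length-2 character: the ordered group labels
#'   (\code{scores} = first minus second).
#' @param source_experiment id of the originating experiment.
#' @return an object of class \code{"DEProfile"}.
#' @export
de_profile <- function(profile_id, feature_ids, scores,
                       space = c("gene", "component", "module"),
                       pvalues = NULL, variances = NULL,
                       comparison = c(NA_character_, NA_character_),
                       source_experiment = NA_character_) {
  space <- match.arg(space)
  check_character_scalar(profile_id, "profile_id")
  feature_ids <- as.character(feature_ids)
  if (anyDuplicated(feature_ids))
    stop("duplicate feature ids in profile: ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))
  scores <- as.numeric(scores)
  if (length(scores) != length(feature_ids))
    stop("scores and feature_ids must have the same length")
  if (!is.null(pvalues)) {
    pvalues <- as.numeric(pvalues)
    if (length(pvalues) != length(feature_ids))
      stop("pvalues must align with feature_ids")
    if (any(!is.na(pvalues) & (pvalues <= 0 | pvalues > 1)))
      stop("pvalues must lie in (0, 1]")
  }
  if (!is.null(variances)) {
    variances <- as.numeric(variances)
    if (length(variances) != length(feature_ids))
      stop("variances must align with feature_ids")
    if (any(!is.na(variances) & variances < 0))
      stop("variances must be non-negative")
  }
  names(scores) <- feature_ids
  if (!is.null(pvalues)) names(pvalues) <- feature_ids
  if (!is.null(variances)) names(variances) <- feature_ids
  structure(
    list(profile_id = profile_id, space = space,
         feature_ids = feature_ids, scores = scores,
         pvalues = pvalues, variances = variances,
         comparison = as.character(comparison),
         source_experiment = source_experiment),
    class = "DEProfile")
}

#' @export
print.DEProfile <- function(x, ...) {
  cat(sprintf("DEProfile '%s' (%s space): %d features\n",
              x$profile_id, x$space, length(x$feature_ids)))
  if (!any(is.na(x$comparison)))
    cat(sprintf("  comparison: %s vs %s (source: %s)\n",
                x$comparison[1L], x$comparison[2L], x$source_experiment))
  cat(sprintf("  scores in [%.3g, %.3g]; p-values: %s; variances: %s\n",
              min(x$scores, na.rm = TRUE), max(x$scores, na.rm = TRUE),
              if (is.null(x$pvalues)) "absent" else "present",
              if (is.null(x$variances)) "absent" else "present"))
  invisible(x)
}

#' @export
length.DEProfile <- function(x) length(x$feature_ids)

#' Read / write DE profiles
#'
#' Profiles are stored as a tab-separated table with columns
#' \code{feature_id}, \code{score}, \code{pvalue}, \code{variance}, preceded
#' by \code{#key\tvalue} metadata lines carrying the profile id, space,
#' comparison and source experiment. Numeric values are written with 17
#' significant digits so a write/read cycle is bit-identical.
#'
#' @param profile a \code{DEProfile}.
#' @param path file path.
#' @return \code{read_profile} returns a \code{DEProfile};
#'   \code{write_profile} its input, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "DEProfile"))
  meta <- c(profile_id = profile$profile_id,
            space = profile$space,
            group_a = profile$comparison[1L],
            group_b = profile$comparison[2L],
            source_experiment = profile$source_experiment)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#%s\t%s", names(meta), meta), con)
  df <- data.frame(feature_id = profile$feature_ids,
                   score = format_full(profile$scores),
                   pvalue = if (is.null(profile$pvalues)) "NA" else format_full(profile$pvalues),
                   variance = if (is.null(profile$variances)) "NA" else format_full(profile$variances),
                   stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(profile)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  meta <- do.call(rbind, strsplit(sub("^#", "", lines[hdr]), "\t", fixed = TRUE))
  meta <- stats::setNames(meta[, 2L], meta[, 1L])
  df <- utils::read.delim(text = lines[!hdr], stringsAsFactors = FALSE)
  pv <- if (all(is.na(df$pvalue))) NULL else df$pvalue
  vr <- if (all(is.na(df$variance))) NULL else df$variance
  de_profile(profile_id = meta[["profile_id"]],
             feature_ids = df$feature_id,
             scores = df$score,
             space = meta[["space"]],
             pvalues = pv, variances = vr,
             comparison = c(meta[["group_a"]], meta[["group_b"]]),
             source_experiment = meta[["source_experiment"]])
}

#' Component matrix (ICA basis)
#'
#' A components x genes loading matrix defining a reduced feature space.
#' Gene-space profiles are projected onto it with \code{\link{project_ica}}.
#'
#' @param loadings numeric matrix, components in rows (rownames = component
#'   ids), genes in columns (colnames = gene ids).
#' @return an object of class \code{"ComponentMatrix"}.
#' @export
component_matrix <- function(loadings) {
  loadings <- as.matrix(loadings)
  storage.mode(loadings) <- "double"
  if (is.null(rownames(loadings)) || is.null(colnames(loadings)))
    stop("loadings must carry component (row) and gene (column) names")
  if (anyDuplicated(rownames(loadings))) stop("duplicate component ids")
  if (anyDuplicated(colnames(loadings))) stop("duplicate gene ids")
  zero <- rowSums(loadings != 0, na.rm = TRUE) == 0
  if (any(zero))
    stop("all-zero component rows: ", paste(rownames(loadings)[zero], collapse = ", "))
  structure(list(loadings = loadings,
                 component_ids = rownames(loadings),
                 gene_ids = colnames(loadings)),
            class = "ComponentMatrix")
}

#' @export
print.ComponentMatrix <- function(x, ...) {
  cat(sprintf("ComponentMatrix: %d components x %d genes\n",
              nrow(x$loadings), ncol(x$loadings)))
  invisible(x)
}

#' @export
dim.ComponentMatrix <- function(x) dim(x$loadings)

#' @rdname component_matrix
#' @param path file path (tab-separated; first column \code{component_id},
#'   remaining columns one per gene).
#' @export
read_component_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1L]])
  component_matrix(m)
}

#' @rdname component_matrix
#' @param components a \code{ComponentMatrix} to write.
#' @export
write_component_matrix <- function(components, path) {
  stopifnot(inherits(components, "ComponentMatrix"))
  m <- components$loadings
  df <- data.frame(component_id = rownames(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  for (j in seq_len(ncol(m))) df[[colnames(m)[j]]] <- format_full(m[, j])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(components)
}

#' Gene-set collections (GMT)
#'
#' A named collection of gene sets, each a description plus a set of member
#' gene ids, read and written in the standard GMT format (one set per line:
#' name, description, then tab-separated members).
#'
#' @param sets named list; each element a list with \code{description} and
#'   \code{genes}.
#' @return an object of class \code{"GeneSetCollection"}.
#' @export
gene_set_collection <- function(sets) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("gene sets must have unique names")
  for (nm in names(sets)) {
    g <- unique(as.character(sets[[nm]]$genes))
    if (length(g) == 0L) stop("gene set '", nm, "' is empty")
    sets[[nm]]$genes <- g
    if (is.null(sets[[nm]]$description)) sets[[nm]]$description <- ""
  }
  structure(sets, class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  sz <- vapply(x, function(s) length(s$genes), integer(1))
  cat(sprintf("GeneSetCollection: %d sets (sizes %d-%d)\n",
              length(x), min(sz), max(sz)))
  invisible(x)
}

#' @rdname gene_set_collection
#' @param path GMT file path.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) {
    if (length(p) < 3L) stop("malformed GMT line: ", p[1L])
    list(description = p[2L], genes = unique(p[-c(1L, 2L)]))
  })
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  gene_set_collection(sets)
}

#' @rdname gene_set_collection
#' @param collection a \code{GeneSetCollection} to write.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  lines <- vapply(names(collection), function(nm) {
    s <- collection[[nm]]
    paste(c(nm, s$description, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(collection)
}

#' Cross-species homolog map
#'
#' Maps source-species gene ids to human gene ids (Homologene-style).
#' Entries are flagged \code{one_to_one} when, within a species, the source
#' gene maps to exactly one human gene and that human gene is reached from
#' exactly one source gene; only such entries are used by
#' \code{\link{map_to_human}}.
#'
#' @param map data.frame with columns \code{species}, \code{source_gene_id},
#'   \code{human_gene_id} (and optionally a logical \code{one_to_one}, which
#'   is recomputed if absent).
#' @return an object of class \code{"HomologMap"} (a data.frame).
#' @export
homolog_map <- function(map) {
  need <- c("species", "source_gene_id", "human_gene_id")
  if (!all(need %in% names(map)))
    stop("homolog map needs columns: ", paste(need, collapse = ", "))
  map <- unique(map[, intersect(c(need, "one_to_one"), names(map))])
  if (is.null(map$one_to_one)) {
    key_s <- paste(map$species, map$source_gene_id, sep = "\r")
    key_h <- paste(map$species, map$human_gene_id, sep = "\r")
    map$one_to_one <- !(key_s %in% key_s[duplicated(key_s)]) &
      !(key_h %in% key_h[duplicated(key_h)])
  }
  class(map) <- c("HomologMap", "data.frame")
  map
}

#' @rdname homolog_map
#' @param path tab-separated file with columns \code{species},
#'   \code{source_gene_id}, \code{human_gene_id}.
#' @export
read_homolog_map <- function(path) {
  homolog_map(utils::read.delim(path, stringsAsFactors = FALSE,
                                colClasses = "character"))
}

#' @rdname homolog_map
#' @param map_obj a \code{HomologMap} to write.
#' @export
write_homolog_map <- function(map_obj, path) {
  utils::write.table(map_obj[, c("species", "source_gene_id", "human_gene_id")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(map_obj)
}
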