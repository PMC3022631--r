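#' Configuration for the synthetic compendium generator
#'
#' Describes a multi-experiment expression compendium: a set of
#' "conditions" (diseases/perturbations), each measured by several
#' independent "experiments" on distinct simulated platforms. Every
#' experiment compares a case group against a control group; each condition
#' plants a fixed signed differential program on a subset of genes, on top
#' of independent Gaussian noise and experiment-level batch shifts, with
#' platform-specific gene dropout and probe-per-gene multiplicities.
#'
#' Defaults describe the reference simulation used throughout the package's
#' evaluation: 3 conditions x 8 experiments, 5000 genes, 200-gene programs
#' with a 1.0 log2-unit mean shift, unit noise SD, 0.25 batch SD, 20%
#' platform dropout and 5 samples per group.
#'
#' @param n_conditions number of distinct conditions.
#' @param experiments_per_condition experiments simulated per condition.
#' @param n_genes genes in the universe.
#' @param probes_per_gene integer range \code{c(min, max)}; each platform
#'   draws a probe multiplicity per gene uniformly from it.
#' @param samples_per_group samples in each of the case/control groups.
#' @param program_size differentially expressed genes per condition.
#' @param effect_size mean log2 shift of program genes in cases.
#' @param noise_sd SD of per-sample Gaussian noise (log2 units).
#' @param batch_sd SD of the per-experiment gene-wise batch offset.
#' @param platform_dropout fraction of genes absent from each simulated
#'   platform, in [0, 1).
#' @param probe_offset_sd SD of the fixed per-probe offset.
#' @param probe_noise_sd SD of probe-level measurement noise.
#' @param species_mix fraction of experiments labeled as a non-human
#'   species (with a generated one-to-one homolog map).
#' @param seed integer seed.
#' @return an object of class \code{"SimulationConfig"}.
#' @export
simulation_config <- function(n_conditions = 3L,
                              experiments_per_condition = 8L,
                              n_genes = 5000L,
                              probes_per_gene = c(1L, 3L),
                              samples_per_group = 5L,
                              program_size = 200L,
                              effect_size = 1.0,
                              noise_sd = 1.0,
                              batch_sd = 0.25,
                              platform_dropout = 0.2,
                              probe_offset_sd = 0.5,
                              probe_noise_sd = 0.2,
                              species_mix = 0,
                              seed = 1L) {
  cfg <- list(n_conditions = as.integer(n_conditions),
              experiments_per_condition = as.integer(experiments_per_condition),
              n_genes = as.integer(n_genes),
              probes_per_gene = as.integer(probes_per_gene),
              samples_per_group = as.integer(samples_per_group),
              program_size = as.integer(program_size),
              effect_size = effect_size,
              noise_sd = noise_sd,
              batch_sd = batch_sd,
              platform_dropout = platform_dropout,
              probe_offset_sd = probe_offset_sd,
              probe_noise_sd = probe_noise_sd,
              species_mix = species_mix,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_conditions >= 1L, experiments_per_condition >= 1L,
              n_genes >= 1L, samples_per_group >= 1L,
              program_size >= 1L, program_size <= n_genes,
              length(probes_per_gene) == 2L,
              probes_per_gene[1L] >= 1L,
              probes_per_gene[2L] >= probes_per_gene[1L],
              noise_sd > 0, batch_sd >= 0,
              platform_dropout >= 0, platform_dropout < 1,
              species_mix >= 0, species_mix <= 1)
  })
  structure(cfg, class = "SimulationConfig")
}

#' @export
print.SimulationConfig <- function(x, ...) {
  cat(sprintf(paste0("SimulationConfig: %d conditions x %d experiments, ",
                     "%d genes\n  program %d genes @ effect %.2g, noise SD ",
                     "%.2g, batch SD %.2g, dropout %.2g, seed %d\n"),
              x$n_conditions, x$experiments_per_condition, x$n_genes,
              x$program_size, x$effect_size, x$noise_sd, x$batch_sd,
              x$platform_dropout, x$seed))
  invisible(x)
}

#' Simulate a multi-experiment expression compendium
#'
#' See \code{\link{simulation_config}} for the generative model. Values are
#' produced directly on the log2 scale (\code{is_log_scale = TRUE}): probe
#' value = gene value + fixed probe offset + probe noise, where gene value =
#' baseline + batch offset + sample noise (+ effect x program sign for case
#' samples on program genes). Experiments assigned a non-human species carry
#' species-prefixed probe/gene identifiers together with a generated
#' one-to-one homolog map back to the human gene ids.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return list with \code{experiments} (named list of probe-level
#'   \code{ExpressionExperiment}s), \code{probe_maps} (named list, probe ->
#'   gene per experiment, in the experiment's species identifiers),
#'   \code{homologs} (a \code{\link{homolog_map}}, or NULL when
#'   \code{species_mix = 0}), \code{labels} (profile-ready named condition
#'   labels per experiment) and \code{truth} (condition programs, signs and
#'   the config).
#' @export
simulate_compendium <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  with_seed(config$seed, {
    genes <- sprintf("g%05d", seq_len(config$n_genes))
    baseline <- stats::rnorm(config$n_genes, mean = 7, sd = 1)
    names(baseline) <- genes

    programs <- lapply(seq_len(config$n_conditions), function(ci) {
      pg <- sample(genes, config$program_size)
      list(genes = pg,
           signs = stats::setNames(sample(c(-1, 1), config$program_size,
                                          replace = TRUE), pg))
    })
    names(programs) <- sprintf("condition%02d", seq_len(config$n_conditions))

    n_exp_total <- config$n_conditions * config$experiments_per_condition
    n_nonhuman <- floor(config$species_mix * n_exp_total)
    exp_idx <- 0L

    experiments <- list()
    probe_maps <- list()
    labels <- character(0)
    homolog_rows <- list()

    for (ci in seq_len(config$n_conditions)) {
      cond <- names(programs)[ci]
      prog <- programs[[ci]]
      for (ei in seq_len(config$experiments_per_condition)) {
        exp_idx <- exp_idx + 1L
        eid <- sprintf("%s_exp%02d", cond, ei)
        species <- if (exp_idx <= n_nonhuman) "mouse" else "human"

        keep <- genes[stats::runif(config$n_genes) >= config$platform_dropout]
        n_keep <- length(keep)
        nspg <- config$samples_per_group
        n_samp <- 2L * nspg

        batch <- stats::rnorm(n_keep, 0, config$batch_sd)
        gmat <- matrix(baseline[keep] + batch, nrow = n_keep, ncol = n_samp) +
          matrix(stats::rnorm(n_keep * n_samp, 0, config$noise_sd),
                 n_keep, n_samp)
        on_prog <- intersect(keep, prog$genes)
        case_cols <- seq_len(nspg) + nspg
        gmat[match(on_prog, keep), case_cols] <-
          gmat[match(on_prog, keep), case_cols] +
          config$effect_size * prog$signs[on_prog]

        multip <- sample(seq(config$probes_per_gene[1L],
                             config$probes_per_gene[2L]),
                         n_keep, replace = TRUE)
        probe_gene <- rep.int(keep, multip)
        n_probes <- length(probe_gene)
        probe_ids <- paste0(probe_gene, "_p",
                            sequence(multip))
        offs <- stats::rnorm(n_probes, 0, config$probe_offset_sd)
        pmat <- gmat[match(probe_gene, keep), , drop = FALSE] + offs +
          matrix(stats::rnorm(n_probes * n_samp, 0, config$probe_noise_sd),
                 n_probes, n_samp)

        gene_ids_local <- keep
        probe_ids_local <- probe_ids
        if (species != "human") {
          gene_ids_local <- paste0("mmu:", keep)
          probe_ids_local <- paste0("mmu:", probe_ids)
          homolog_rows[[length(homolog_rows) + 1L]] <-
            data.frame(species = species,
                       source_gene_id = gene_ids_local,
                       human_gene_id = keep,
                       stringsAsFactors = FALSE)
        }
        rownames(pmat) <- probe_ids_local
        sample_ids <- sprintf("%s_s%02d", eid, seq_len(n_samp))
        colnames(pmat) <- sample_ids
        groups <- stats::setNames(rep(c("control", "case"), each = nspg),
                                  sample_ids)

        experiments[[eid]] <- expression_experiment(
          pmat, groups = groups, experiment_id = eid,
          factor_name = "condition status", species = species,
          is_log_scale = TRUE)
        probe_maps[[eid]] <- stats::setNames(rep.int(gene_ids_local, multip),
                                             probe_ids_local)
        labels[eid] <- cond
      }
    }

    homologs <- if (length(homolog_rows))
      homolog_map(unique(do.call(rbind, homolog_rows))) else NULL

    list(experiments = experiments,
         probe_maps = probe_maps,
         homologs = homologs,
         labels = labels,
         truth = list(programs = programs,
                      condition_of = labels,
                      config = config))
  })
}

#' Build DE profiles for every experiment of a simulated compendium
#'
#' Convenience wrapper running the standard pipeline on each experiment:
#' probe aggregation by the fixed-effect meta-estimate, then the requested
#' representation (p-value profiles by default, so that p-weighted search is
#' available), then homolog mapping to human identifiers where needed.
#'
#' @param compendium a \code{\link{simulate_compendium}} result.
#' @param representation \code{"pvalue"}, \code{"logfc"} or \code{"rank"}.
#' @param components optional \code{\link{component_matrix}}; when given,
#'   component-space profiles with component-level p-values are built via
#'   \code{\link{component_profile}}.
#' @return named list of \code{DEProfile}s (one per experiment, comparing
#'   case vs control).
#' @export
compendium_profiles <- function(compendium,
                                representation = c("pvalue", "logfc", "rank"),
                                components = NULL) {
  representation <- match.arg(representation)
  out <- list()
  for (eid in names(compendium$experiments)) {
    ex <- compendium$experiments[[eid]]
    if (representation == "rank") {
      p <- rank_profile(ex, "case", "control", compendium$probe_maps[[eid]])
      if (ex$species != "human")
        p <- map_to_human(p, compendium$homologs, ex$species)
      out[[p$profile_id]] <- p
      next
    }
    gex <- aggregate_probes_fixed_effects(ex, compendium$probe_maps[[eid]])
    if (gex$species != "human")
      gex <- map_experiment_to_human(gex, compendium$homologs)
    p <- if (!is.null(components)) {
      component_profile(gex, components, "case", "control")
    } else if (representation == "pvalue") {
      pvalue_profile(gex, "case", "control")
    } else {
      logfc_profile(gex, "case", "control")
    }
    out[[p$profile_id]] <- p
  }
  out
}

# Rename a gene-level experiment's features to one-to-one human homologs,
# dropping the rest (experiment-level counterpart of map_to_human, needed
# before component projection of sample-level data).
map_experiment_to_human <- function(experiment, homologs) {
  hm <- homologs[homologs$species == experiment$species & homologs$one_to_one, ]
  idx <- match(rownames(experiment$values), hm$source_gene_id)
  keep <- !is.na(idx)
  if (!any(keep))
    stop("experiment '", experiment$experiment_id,
         "' failed to map to human genes")
  v <- experiment$values[keep, , drop = FALSE]
  rownames(v) <- hm$human_gene_id[idx[keep]]
  fv <- experiment$feature_variances
  if (!is.null(fv)) {
    fv <- fv[keep]
    names(fv) <- rownames(v)
  }
  expression_experiment(v, groups = experiment$groups,
                        experiment_id = experiment$experiment_id,
                        factor_name = experiment$factor,
                        species = "human",
                        is_log_scale = experiment$is_log_scale,
                        feature_variances = fv)
}

#' Simulate a compendium for component derivation
#'
#' Generates sparse, heavy-tailed gene-loading source vectors, mixes them
#' linearly across samples and adds Gaussian noise at a given signal-to-
#' noise ratio — a fixture with known ground truth for testing ICA source
#' recovery.
#'
#' @param n_samples,n_genes data dimensions.
#' @param n_sources number of latent sources (at most
#'   \code{min(n_samples, n_genes)}).
#' @param sparsity fraction of genes active per source (default 0.05).
#' @param snr signal-to-noise variance ratio; \code{Inf} for noise-free.
#' @param seed integer seed.
#' @return list with \code{data} (samples x genes, gene column names),
#'   \code{mixing} (samples x sources) and \code{sources} (sources x genes).
#' @export
simulate_component_compendium <- function(n_samples, n_genes, n_sources,
                                          sparsity = 0.05, snr = 10,
                                          seed = 1L) {
  stopifnot(n_sources <= min(n_samples, n_genes), sparsity > 0, sparsity <= 1)
  with_seed(seed, {
    genes <- sprintf("g%05d", seq_len(n_genes))
    s <- matrix(0, n_sources, n_genes, dimnames = list(
      sprintf("S%02d", seq_len(n_sources)), genes))
    n_active <- max(1L, round(sparsity * n_genes))
    for (i in seq_len(n_sources)) {
      idx <- sample.int(n_genes, n_active)
      s[i, idx] <- stats::rnorm(n_active, mean = 3, sd = 1) *
        sample(c(-1, 1), n_active, replace = TRUE)
    }
    m <- matrix(stats::rnorm(n_samples * n_sources), n_samples, n_sources)
    signal <- m %*% s
    x <- if (is.infinite(snr)) signal else {
      noise_sd <- sqrt(stats::var(as.vector(signal)) / snr)
      signal + matrix(stats::rnorm(n_samples * n_genes, 0, noise_sd),
                      n_samples, n_genes)
    }
    colnames(x) <- genes
    rownames(x) <- sprintf("sample%03d", seq_len(n_samples))
    list(data = x, mixing = m, sources = s)
  })
}
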