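# Configuration and the end-to-end pipeline runner:
# simulate -> chemotype -> mdn -> census -> diversity -> asca -> qpcr ->
# ordinate.

#' Default pipeline configuration
#'
#' All tunable parameters of the analysis chain with their defaults:
#' census m/z tolerance 0.02 Da, chemotyping tolerance 0.05 Da, co-elution
#' window 0.1 min, association threshold 0.75, 1000 permutations for the
#' ASCA validation, and the synthetic design settings.
#'
#' @param ... Named overrides of default entries (unknown keys are
#'   rejected).
#' @return Named list of class \code{sg_config}.
#' @export
sg_config <- function(...) {
  cfg <- list(
    out_dir = tempfile("sgchem_run_"),
    seed = 1L,
    # synthetic design
    sigma = 0.3, scan_k = 2, decoys_per_scan = 3, decoy_features = 5,
    replicates = 1,
    # tolerances and thresholds
    mz_tol_census = 0.02, mz_tol_chemotype = 0.05, rt_window = 0.1,
    association_threshold = 0.75, presence_threshold = NULL,
    # losses used for networking
    losses = c("hexose", "deoxyhexose", "pentose", "malonylhexoside",
               "hydroxylation", "saturation", "acetylation"),
    # statistics
    asca_terms = c("organ", "chemotype", "organ:chemotype"),
    n_perm = 1000, n_perm_screen = 99,
    # qPCR
    cq1 = 37, qpcr_mode = "soft", reference_genes = c("EXP", "SAND"),
    qpcr_condition = c("chemotype", "organ"),
    # TIC_SG exclusion
    exclude_mz = 329.32)
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(overrides)] <- overrides
  validate_config(structure(cfg, class = "sg_config"))
}

#' Read a pipeline configuration from a YAML file
#'
#' Missing keys take their defaults; unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return An \code{sg_config} list.
#' @export
read_config <- function(path) {
  do.call(sg_config, yaml::read_yaml(path))
}

#' @rdname sg_config
#' @param config Configuration to validate.
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "sg_config"))
  with(config, {
    stopifnot(mz_tol_census > 0, mz_tol_chemotype > 0, rt_window > 0,
              association_threshold > 0.5, association_threshold <= 1,
              n_perm >= 99, cq1 > 0, seed == as.integer(seed))
  })
  config
}

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  plain <- unclass(config)
  plain$out_dir <- NULL   # the hash identifies the analysis, not its location
  plain <- lapply(plain, function(x) if (is.null(x)) "null" else x)
  yaml::write_yaml(plain[order(names(plain))], tmp)
  unname(tools::md5sum(tmp))
}

#' Load pipeline inputs from disk
#'
#' Reads and schema-validates the feature table, spectra, sample metadata
#' and Cq table written by a previous \code{simulate} stage (or supplied
#' by the user in the same formats).
#'
#' @param dir Directory containing \code{features.tsv},
#'   \code{spectra.mgf}, \code{metadata.tsv}, \code{qpcr_wells.tsv} and
#'   \code{qpcr_dilution.tsv}.
#' @return List with \code{features}, \code{spectra}, \code{metadata},
#'   \code{wells}, \code{dilution}.
#' @export
load_inputs <- function(dir) {
  features <- read_feature_table(file.path(dir, "features.tsv"))
  metadata <- read_metadata(file.path(dir, "metadata.tsv"))
  sample_cols <- setdiff(names(features), c("feature_id", "mz", "rt"))
  missing <- setdiff(sample_cols, metadata$sample)
  if (length(missing)) {
    stop("feature-table samples missing from metadata: ",
         paste(missing, collapse = ", "))
  }
  list(features = features,
       spectra = read_spectra_mgf(file.path(dir, "spectra.mgf")),
       metadata = metadata,
       wells = read_cq_table(file.path(dir, "qpcr_wells.tsv")),
       dilution = utils::read.delim(file.path(dir, "qpcr_dilution.tsv"),
                                    stringsAsFactors = FALSE))
}

#' Run the full synthetic-to-results pipeline
#'
#' Executes the analysis chain on data simulated under the configured
#' design, writing every intermediate artifact plus a run manifest
#' (configuration hash, seed, package version) to \code{config$out_dir}.
#' Reruns with the same configuration are reproducible.
#'
#' @param config An [sg_config()].
#' @param stages Subset of
#'   \code{c("simulate", "chemotype", "mdn", "census", "diversity",
#'   "asca", "qpcr", "ordinate")}; earlier stage outputs must exist when a
#'   later stage is run alone.
#' @return Invisible list with the in-memory results of each executed
#'   stage.
#' @export
run_pipeline <- function(config = sg_config(),
                         stages = c("simulate", "chemotype", "mdn",
                                    "census", "diversity", "asca", "qpcr",
                                    "ordinate")) {
  config <- validate_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list(config = config)
  design <- sg_design(sigma = config$sigma, scan_k = config$scan_k,
                      decoys_per_scan = config$decoys_per_scan,
                      decoy_features = config$decoy_features,
                      replicates = config$replicates, seed = config$seed)

  if ("simulate" %in% stages) {
    library <- build_compound_library(design)
    spec <- simulate_spectra(library, design)
    feat <- simulate_feature_table(library, design)
    qpcr <- simulate_qpcr_dataset(design, cq1 = config$cq1)
    write_feature_table(feat$features, file.path(config$out_dir,
                                                 "features.tsv"))
    write_spectra_mgf(spec$spectra, file.path(config$out_dir,
                                              "spectra.mgf"))
    write_metadata(spec$metadata, file.path(config$out_dir, "metadata.tsv"))
    write_cq_table(qpcr$wells, file.path(config$out_dir, "qpcr_wells.tsv"))
    utils::write.table(qpcr$dilution,
                       file.path(config$out_dir, "qpcr_dilution.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(sample = rownames(spec$truth$species_counts),
                 spec$truth$species_counts, check.names = FALSE),
      file.path(config$out_dir, "truth_species_counts.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    res$library <- library
    res$qpcr_data <- qpcr
    res$truth <- list(spectra = spec$truth, features = feat$truth)
  }
  inputs <- load_inputs(config$out_dir)
  res$inputs <- inputs

  if ("chemotype" %in% stages) {
    leaf <- inputs$metadata$sample[inputs$metadata$organ == "leaf"]
    leaf_spectra <- Filter(function(sc) sc$sample %in% leaf, inputs$spectra)
    res$chemotypes <- chemotype_samples(
      leaf_spectra, tol = config$mz_tol_chemotype,
      presence_threshold = config$presence_threshold)
    utils::write.table(res$chemotypes,
                       file.path(config$out_dir, "chemotypes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if ("mdn" %in% stages) {
    losses <- mdn_default_losses(config$losses)
    g <- build_mdn(inputs$features, losses, mz_tol = config$mz_tol_census,
                   rt_window = config$rt_window)
    g <- prune_singletons(g)
    g <- annotate_associations(g, inputs$features, inputs$metadata,
                               grouping = "chemotype",
                               threshold = config$association_threshold)
    export_graphml(g, file.path(config$out_dir, "mdn.graphml"))
    res$mdn <- g
  }
  if ("census" %in% stages) {
    res$counts <- census_spectra(inputs$spectra, tol = config$mz_tol_census,
                                 samples = inputs$metadata$sample)
    utils::write.table(
      data.frame(sample = rownames(res$counts), unclass(res$counts),
                 check.names = FALSE),
      file.path(config$out_dir, "sg_counts.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if ("diversity" %in% stages) {
    if (is.null(res$counts)) stop("diversity stage requires census results")
    tic <- if (!is.null(res$mdn)) {
      tic_sg(inputs$features, igraph::V(res$mdn)$name,
             exclude_mz = config$exclude_mz)
    } else NULL
    res$diversity <- diversity_table(res$counts, tic = tic,
                                     metadata = inputs$metadata)
    utils::write.table(res$diversity,
                       file.path(config$out_dir, "diversity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if ("asca" %in% stages) {
    if (is.null(res$counts)) stop("asca stage requires census results")
    res$asca <- asca(res$counts, inputs$metadata, config$asca_terms,
                     n_perm = config$n_perm, seed = config$seed,
                     n_perm_screen = config$n_perm_screen)
    utils::write.table(summary(res$asca),
                       file.path(config$out_dir, "asca_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if ("qpcr" %in% stages) {
    eff <- vapply(split(inputs$dilution, inputs$dilution$gene),
                  function(d) efficiency_from_dilution(d$dilution, d$cq),
                  numeric(1))
    eff[config$reference_genes] <- 2   # assumed for references
    counts <- wells_to_counts(inputs$wells, eff, cq1 = config$cq1)
    res$qpcr_efficiencies <- eff
    res$expression <- fit_expression_model(
      counts, inputs$metadata, mode = config$qpcr_mode,
      reference_genes = config$reference_genes,
      condition = config$qpcr_condition)
    res$contrasts <- pairwise_contrasts(res$expression)
    utils::write.table(res$contrasts,
                       file.path(config$out_dir, "qpcr_contrasts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if ("ordinate" %in% stages) {
    m <- preprocess_features(inputs$features)
    res$pca <- pca(m)
    d <- stats::dist(m, method = "manhattan")
    res$pcoa <- pcoa(d)
    res$permanova <- permanova(
      d, inputs$metadata$organ[match(rownames(m),
                                     inputs$metadata$sample)],
      n_perm = config$n_perm, seed = config$seed)
    utils::write.table(
      data.frame(sample = rownames(res$pca$scores),
                 res$pca$scores[, seq_len(min(3, ncol(res$pca$scores)))]),
      file.path(config$out_dir, "pca_scores.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- list(package = "sgchem",
                   version = as.character(utils::packageVersion("sgchem")),
                   seed = config$seed,
                   config_hash = .config_hash(config),
                   stages = stages)
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
  res$manifest <- manifest
  invisible(res)
}
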