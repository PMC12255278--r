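# Mass-difference networking: features as nodes, neutral-loss matches under
# co-elution as edges.

#' Default neutral-loss table for mass-difference networking
#'
#' The biotransformation mass differences used to draw edges:
#' glycosylations (hexose, deoxyhexose, pentose, malonylhexoside),
#' hydroxylation (O), acetylation, and the saturation difference H2
#' (2.016 Da) that links saturated/unsaturated analogue pairs.
#'
#' @param names Residue names/aliases to include.
#' @param residues Residue table.
#' @return data.frame with columns \code{name}, \code{mass}.
#' @export
mdn_default_losses <- function(names = c("hexose", "deoxyhexose", "pentose",
                                         "malonylhexoside", "hydroxylation",
                                         "saturation", "acetylation"),
                               residues = default_residue_table()) {
  data.frame(name = names,
             mass = vapply(names, residue_mass, numeric(1),
                           residues = residues),
             stringsAsFactors = FALSE)
}

#' Build a mass-difference network from a feature table
#'
#' An undirected edge joins features i and j when their absolute m/z
#' difference matches a neutral-loss mass within \code{mz_tol} and the
#' features co-elute (|rt_i - rt_j| <= \code{rt_window}); in-source
#' fragments of one compound co-elute exactly, so the window is tight by
#' default. When several losses match, the one with the smallest mass
#' error wins.
#'
#' @param features Feature table: data.frame with \code{feature_id},
#'   \code{mz}, \code{rt} and one intensity column per sample.
#' @param losses Neutral-loss table, see [mdn_default_losses()].
#' @param mz_tol Absolute m/z tolerance in Da.
#' @param rt_window Co-elution window in minutes.
#' @return An \code{igraph} graph; vertices carry \code{name} (feature id),
#'   \code{mz}, \code{rt} and \code{total_intensity}, edges carry
#'   \code{loss}, \code{delta_mz} and \code{mass_error}. Vertex
#'   \code{component} ids are precomputed.
#' @export
build_mdn <- function(features, losses = mdn_default_losses(),
                      mz_tol = 0.02, rt_window = 0.1) {
  stopifnot(is.data.frame(features), nrow(features) >= 2,
            mz_tol > 0, rt_window > 0)
  sample_cols <- setdiff(names(features), c("feature_id", "mz", "rt"))
  n <- nrow(features)
  edges <- list()
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      if (abs(features$rt[i] - features$rt[j]) > rt_window) next
      d <- abs(features$mz[i] - features$mz[j])
      err <- abs(d - losses$mass)
      k <- which.min(err)
      if (err[k] <= mz_tol) {
        edges[[length(edges) + 1L]] <- data.frame(
          from = features$feature_id[i], to = features$feature_id[j],
          loss = losses$name[k], delta_mz = d,
          mass_error = d - losses$mass[k], stringsAsFactors = FALSE)
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(0), to = character(0),
               loss = character(0), delta_mz = numeric(0),
               mass_error = numeric(0))
  vertices <- data.frame(name = features$feature_id, mz = features$mz,
                         rt = features$rt,
                         total_intensity =
                           rowSums(features[, sample_cols, drop = FALSE]),
                         stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = vertices)
  igraph::V(g)$component <- igraph::components(g)$membership
  g
}

#' Remove singleton nodes from a mass-difference network
#'
#' @param g An MDN graph from [build_mdn()].
#' @return The graph with all degree-zero vertices removed; edges unchanged.
#' @export
prune_singletons <- function(g) {
  stopifnot(inherits(g, "igraph"))
  igraph::delete_vertices(g, igraph::V(g)[igraph::degree(g) == 0])
}

#' Annotate MDN nodes with group intensity fractions and association labels
#'
#' For each node, the fraction of its summed intensity contributed by each
#' level of a grouping variable (chemotype, organ or ontogeny) is computed
#' from the feature table; for two-level groupings a node is labelled with
#' a level when its fraction reaches \code{threshold}, else
#' \code{"neutral"}.
#'
#' @param g MDN graph.
#' @param features Feature table the graph was built from.
#' @param metadata Sample metadata covering every intensity column.
#' @param grouping One of \code{"chemotype"}, \code{"organ"},
#'   \code{"ontogeny"}.
#' @param threshold Association threshold, in (0.5, 1].
#' @return The graph with vertex attributes \code{frac_<level>} per group
#'   level and \code{label}.
#' @export
annotate_associations <- function(g, features, metadata,
                                  grouping = c("chemotype", "organ",
                                               "ontogeny"),
                                  threshold = 0.75) {
  grouping <- match.arg(grouping)
  stopifnot(threshold > 0.5, threshold <= 1)
  sample_cols <- setdiff(names(features), c("feature_id", "mz", "rt"))
  missing <- setdiff(sample_cols, metadata$sample)
  if (length(missing)) {
    stop("samples missing from metadata: ", paste(missing, collapse = ", "))
  }
  groups <- metadata[[grouping]][match(sample_cols, metadata$sample)]
  levels_g <- sort(unique(groups))
  idx <- match(igraph::V(g)$name, features$feature_id)
  intens <- as.matrix(features[idx, sample_cols, drop = FALSE])
  total <- rowSums(intens)
  frac <- sapply(levels_g, function(lv)
    rowSums(intens[, groups == lv, drop = FALSE]) / pmax(total, .Machine$double.eps))
  frac <- matrix(frac, ncol = length(levels_g),
                 dimnames = list(NULL, levels_g))
  for (lv in levels_g) {
    g <- igraph::set_vertex_attr(g, paste0("frac_", lv),
                                 value = frac[, lv])
  }
  label <- apply(frac, 1, function(fr) {
    top <- which.max(fr)
    if (fr[top] >= threshold) levels_g[top] else "neutral"
  })
  igraph::set_vertex_attr(g, "label", value = label)
}

#' Export a mass-difference network to GraphML
#'
#' Standard GraphML via igraph; node and edge attributes round-trip
#' losslessly through [igraph::read_graph()].
#'
#' @param g MDN graph.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
export_graphml <- function(g, path) {
  stopifnot(inherits(g, "igraph"))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
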