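# Synthetic LC-MS and qPCR data with known ground truth.
#
# The generator emulates the factorial study design: two leaf chemotypes
# (S = saturated, U = unsaturated steroidal aglycones), organs root/leaf
# plus stems of flowering plants, two ontogenetic stages, clonally
# propagated genotypes. Compounds are steroidal glycosides built as
# aglycone + glycosyl chain; in-source fragmentation emits the full
# neutral-loss ladder of every compound.

#' Simulation design for the synthetic datasets
#'
#' Encodes the factorial structure and noise model used by all
#' \code{simulate_*} generators. Defaults mirror the study conditions:
#' three S and four U chemo-genotypes, roots and leaves sampled on
#' vegetative plants, roots, leaves and stems on flowering plants, and a
#' chromatographic window of 0.75-11 minutes.
#'
#' @param n_genotypes Named vector, genotypes per chemotype.
#' @param replicates Clonal replicates per genotype x organ x stage.
#' @param sigma Log-normal noise (sd of log intensity/abundance).
#' @param scan_k Scan-density constant: a compound at abundance A emits
#'   \code{max(1, round(scan_k * log10(A)))} scans per sample.
#' @param decoys_per_scan Number of decoy peaks added to each scan.
#' @param decoy_features Number of random decoy feature rows in the feature
#'   table (a fixed artifact feature at m/z 329.32 is always included).
#' @param decoy_intensity Intensity range for decoy peaks/features.
#' @param rt_range Retention-time window (min).
#' @param seed Integer seed fixing all randomness.
#' @return Object of class \code{sg_design} (a list).
#' @export
sg_design <- function(n_genotypes = c(S = 3, U = 4), replicates = 1,
                      sigma = 0.3, scan_k = 2, decoys_per_scan = 3,
                      decoy_features = 5, decoy_intensity = c(1e3, 1e4),
                      rt_range = c(0.75, 11), seed = 1L) {
  stopifnot(all(n_genotypes >= 1), replicates >= 1, sigma >= 0, scan_k > 0,
            decoys_per_scan >= 0, decoy_features >= 0,
            rt_range[1] < rt_range[2])
  structure(list(n_genotypes = n_genotypes, replicates = replicates,
                 sigma = sigma, scan_k = scan_k,
                 decoys_per_scan = decoys_per_scan,
                 decoy_features = decoy_features,
                 decoy_intensity = decoy_intensity,
                 rt_range = rt_range, seed = as.integer(seed)),
            class = "sg_design")
}

#' Sample sheet implied by a simulation design
#'
#' @param design An [sg_design()].
#' @return data.frame with columns \code{sample}, \code{genotype},
#'   \code{chemotype}, \code{organ}, \code{ontogeny}, \code{replicate}.
#'   Stems appear only on flowering plants.
#' @export
design_samples <- function(design) {
  stopifnot(inherits(design, "sg_design"))
  rows <- list()
  for (ct in names(design$n_genotypes)) {
    for (g in seq_len(design$n_genotypes[[ct]])) {
      geno <- paste0(ct, g)
      for (stage in c("vegetative", "flowering")) {
        organs <- if (stage == "flowering") c("root", "leaf", "stem")
                  else c("root", "leaf")
        for (org in organs) {
          for (r in seq_len(design$replicates)) {
            rows[[length(rows) + 1L]] <- data.frame(
              sample = paste(geno, org, substr(stage, 1, 4), paste0("r", r),
                             sep = "_"),
              genotype = geno, chemotype = ct, organ = org, ontogeny = stage,
              replicate = r, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# one compound spec; multipliers indexed [chemotype, organ, ontogeny]
.compound <- function(name, aglycone_mz, losses, rt, base_intensity, mult) {
  m <- array(0, dim = c(2, 3, 2),
             dimnames = list(chemotype = c("S", "U"),
                             organ = c("root", "leaf", "stem"),
                             ontogeny = c("vegetative", "flowering")))
  for (rule in mult) m[rule$chemotype, rule$organ, rule$ontogeny] <- rule$x
  residues <- default_residue_table()
  loss_mass <- unname(vapply(losses, residue_mass, numeric(1),
                             residues = residues))
  ions <- aglycone_mz + rev(cumsum(rev(c(loss_mass, 0))))
  list(name = name, aglycone_mz = aglycone_mz, losses = losses,
       ions = ions, molecular_mz = ions[1], rt = rt,
       base_intensity = base_intensity, mult = m)
}

#' Build the synthetic steroidal-glycoside compound library
#'
#' Returns specifications for 17 glycosides covering all 12 steroidal
#' aglycone (SA) species. The library encodes the chemotype rule: leaf
#' compounds of the U chemotype carry unsaturated aglycones (2.016 Da
#' lighter than their saturated S analogues), and roots of both chemotypes
#' share the unsaturated compounds. It includes analogues of the six worked
#' compounds: the saturated leaf tetraoside (aglycone 416.35, Hex3Pen,
#' molecular ion 1034.55), two saturated leaf triosides, the root-only
#' malonylated glycoalkaloid (molecular ion 954.51), the unsaturated
#' saponin pentoside (molecular ion 1195.5662) and its saturated analogue.
#' Saturation analogue pairs co-elute (retention times 0.05 min apart) so
#' their ladders connect through the H2 biotransformation edge; unrelated
#' compounds are spaced at least 0.3 min apart.
#'
#' @param design An [sg_design()] (reserved for future library scaling; the
#'   default library does not depend on it).
#' @return Object of class \code{sg_library}: list with \code{compounds}
#'   (list of compound specs), \code{species} (SA species m/z assigned per
#'   compound) and \code{families} (integer family id per compound; families
#'   group compounds whose planted ions are linked by co-eluting
#'   neutral-loss or biotransformation mass differences).
#' @export
build_compound_library <- function(design = sg_design()) {
  A416 <- 416.35
  A414 <- A416 - residue_mass("saturation")      # unsaturated leaf analogue
  cmp <- list(
    .compound("soladulcine_B_sat", A416, c("Hex", "Pen", "Hex", "Hex"),
              6.80, 8e5,
              list(list(chemotype = "S", organ = "leaf",
                        ontogeny = "vegetative", x = 1),
                   list(chemotype = "S", organ = "leaf",
                        ontogeny = "flowering", x = 0.6),
                   list(chemotype = "S", organ = "stem",
                        ontogeny = "flowering", x = 0.3))),
    .compound("soladulcine_B_unsat", A414, c("Hex", "Pen", "Hex", "Hex"),
              6.75, 8e5,
              list(list(chemotype = "U", organ = "leaf",
                        ontogeny = "vegetative", x = 1),
                   list(chemotype = "U", organ = "leaf",
                        ontogeny = "flowering", x = 0.7),
                   list(chemotype = "U", organ = "stem",
                        ontogeny = "flowering", x = 0.3),
                   list(chemotype = "S", organ = "root",
                        ontogeny = "vegetative", x = 0.5),
                   list(chemotype = "U", organ = "root",
                        ontogeny = "vegetative", x = 0.5),
                   list(chemotype = "S", organ = "root",
                        ontogeny = "flowering", x = 0.4),
                   list(chemotype = "U", organ = "root",
                        ontogeny = "flowering", x = 0.4))),
    .compound("soladulcine_A_sat", A416, c("Hex", "dHex", "Hex"),
              5.90, 1e6,
              list(list(chemotype = "S", organ = "leaf",
                        ontogeny = "vegetative", x = 1),
                   list(chemotype = "S", organ = "leaf",
                        ontogeny = "flowering", x = 0.7),
                   list(chemotype = "S", organ = "stem",
                        ontogeny = "flowering", x = 0.4))),
    .compound("soladulcine_A_unsat", A414, c("Hex", "dHex", "Hex"),
              5.85, 1e6,
              list(list(chemotype = "U", organ = "leaf",
                        ontogeny = "vegetative", x = 1),
                   list(chemotype = "U", organ = "leaf",
                        ontogeny = "flowering", x = 0.7),
                   list(chemotype = "U", organ = "stem",
                        ontogeny = "flowering", x = 0.4),
                   list(chemotype = "S", organ = "root",
                        ontogeny = "vegetative", x = 0.6),
                   list(chemotype = "U", organ = "root",
                        ontogeny = "vegetative", x = 0.6),
                   list(chemotype = "S", organ = "root",
                        ontogeny = "flowering", x = 0.5),
                   list(chemotype = "U", organ = "root",
                        ontogeny = "flowering", x = 0.5))),
    .compound("triose_dhex_sat", A416, c("dHex", "dHex", "Hex"),
              5.40, 5e5,
              list(list(chemotype = "S", organ = "leaf",
                        ontogeny = "vegetative", x = 1),
                   list(chemotype = "S", organ = "leaf",
                        ontogeny = "flowering", x = 0.6))),
    .compound("triose_dhex_unsat", A414, c("dHex", "dHex", "Hex"),
              5.35, 5e5,
              list(list(chemotype = "U", organ = "leaf",
                        ontogeny = "vegetative", x = 1),
                   list(chemotype = "U", organ = "leaf",
                        ontogeny = "flowering", x = 0.6),
                   list(chemotype = "S", organ = "root",
                        ontogeny = "vegetative", x = 0.4),
                   list(chemotype = "U", organ = "root",
                        ontogeny = "vegetative", x = 0.4),
                   list(chemotype = "S", organ = "root",
                        ontogeny = "flowering", x = 0.3),
                   list(chemotype = "U", organ = "root",
                        ontogeny = "flowering", x = 0.3))),
    .compound("malonyl_sga_root", 954.51 - 2 * residue_mass("dHex") -
                residue_mass("malonylhexoside"),
              c("dHex", "dHex", "MalHex"), 3.20, 6e5,
              list(list(chemotype = "S", organ = "root",
                        ontogeny = "vegetative", x = 1),
                   list(chemotype = "U", organ = "root",
                        ontogeny = "vegetative", x = 1),
                   list(chemotype = "S", organ = "root",
                        ontogeny = "flowering", x = 0.35),
                   list(chemotype = "U", organ = "root",
                        ontogeny = "flowering", x = 0.35))),
    .compound("ssg_pentoside_unsat",
              1195.5662 - 4 * residue_mass("Hex") - residue_mass("Pen"),
              c("Hex", "Pen", "Hex", "Hex", "Hex"), 4.60, 1.2e6,
              list(list(chemotype = "U", organ = "leaf",
                        ontogeny = "vegetative", x = 1),
                   list(chemotype = "U", organ = "leaf",
                        ontogeny = "flowering", x = 0.8),
                   list(chemotype = "U", organ = "root",
                        ontogeny = "vegetative", x = 1),
                   list(chemotype = "U", organ = "root",
                        ontogeny = "flowering", x = 0.8),
                   list(chemotype = "S", organ = "root",
                        ontogeny = "vegetative", x = 0.9),
                   list(chemotype = "S", organ = "root",
                        ontogeny = "flowering", x = 0.8),
                   list(chemotype = "S", organ = "leaf",
                        ontogeny = "vegetative", x = 0.08),
                   list(chemotype = "S", organ = "leaf",
                        ontogeny = "flowering", x = 0.1),
                   list(chemotype = "U", organ = "stem",
                        ontogeny = "flowering", x = 0.4),
                   list(chemotype = "S", organ = "stem",
                        ontogeny = "flowering", x = 0.2))),
    .compound("ssg_pentoside_sat",
              1195.5662 - 4 * residue_mass("Hex") - residue_mass("Pen") +
                residue_mass("saturation"),
              c("Hex", "Pen", "Hex", "Hex", "Hex"), 4.65, 6e5,
              list(list(chemotype = "S", organ = "leaf",
                        ontogeny = "flowering", x = 0.7),
                   list(chemotype = "S", organ = "stem",
                        ontogeny = "flowering", x = 0.5))),
    .compound("oh_sga_sat", A416 + residue_mass("hydroxylation"),
              c("Hex", "dHex"), 5.05, 3e5,
              list(list(chemotype = "S", organ = "leaf",
                        ontogeny = "vegetative", x = 0.8),
                   list(chemotype = "S", organ = "leaf",
                        ontogeny = "flowering", x = 0.5),
                   list(chemotype = "S", organ = "stem",
                        ontogeny = "flowering", x = 0.3))),
    .compound("oh_sga_unsat", A414 + residue_mass("hydroxylation"),
              c("Hex", "dHex"), 5.00, 3e5,
              list(list(chemotype = "U", organ = "leaf",
                        ontogeny = "vegetative", x = 0.8),
                   list(chemotype = "U", organ = "leaf",
                        ontogeny = "flowering", x = 0.5),
                   list(chemotype = "S", organ = "root",
                        ontogeny = "vegetative", x = 0.4),
                   list(chemotype = "U", organ = "root",
                        ontogeny = "vegetative", x = 0.4),
                   list(chemotype = "S", organ = "root",
                        ontogeny = "flowering", x = 0.4),
                   list(chemotype = "U", organ = "root",
                        ontogeny = "flowering", x = 0.4))),
    .compound("dioh_sga_sat", A416 + 2 * residue_mass("hydroxylation"),
              c("Hex", "Hex"), 8.60, 2e5,
              list(list(chemotype = "S", organ = "leaf",
                        ontogeny = "vegetative", x = 0.3),
                   list(chemotype = "S", organ = "leaf",
                        ontogeny = "flowering", x = 0.5),
                   list(chemotype = "S", organ = "stem",
                        ontogeny = "flowering", x = 0.5))),
    .compound("dioh_sga_unsat", A414 + 2 * residue_mass("hydroxylation"),
              c("Hex", "Hex"), 8.55, 2e5,
              list(list(chemotype = "U", organ = "leaf",
                        ontogeny = "vegetative", x = 0.6),
                   list(chemotype = "U", organ = "leaf",
                        ontogeny = "flowering", x = 0.3),
                   list(chemotype = "S", organ = "root",
                        ontogeny = "vegetative", x = 0.3),
                   list(chemotype = "U", organ = "root",
                        ontogeny = "vegetative", x = 0.3),
                   list(chemotype = "S", organ = "root",
                        ontogeny = "flowering", x = 0.2),
                   list(chemotype = "U", organ = "root",
                        ontogeny = "flowering", x = 0.2))),
    .compound("rdbe8_sga", A414 - residue_mass("saturation"),
              c("Hex", "dHex"), 7.40, 4e5,
              list(list(chemotype = "S", organ = "root",
                        ontogeny = "flowering", x = 1),
                   list(chemotype = "U", organ = "root",
                        ontogeny = "flowering", x = 1),
                   list(chemotype = "S", organ = "root",
                        ontogeny = "vegetative", x = 0.4),
                   list(chemotype = "U", organ = "root",
                        ontogeny = "vegetative", x = 0.4),
                   list(chemotype = "U", organ = "leaf",
                        ontogeny = "vegetative", x = 0.3),
                   list(chemotype = "U", organ = "leaf",
                        ontogeny = "flowering", x = 0.3))),
    .compound("rdbe8_oh_sga",
              A414 - residue_mass("saturation") + residue_mass("hydroxylation"),
              c("Hex", "Hex"), 8.10, 2e5,
              list(list(chemotype = "S", organ = "root",
                        ontogeny = "vegetative", x = 0.5),
                   list(chemotype = "U", organ = "root",
                        ontogeny = "vegetative", x = 0.5),
                   list(chemotype = "S", organ = "root",
                        ontogeny = "flowering", x = 0.6),
                   list(chemotype = "U", organ = "root",
                        ontogeny = "flowering", x = 0.6))),
    .compound("ssg_oh_sat",
              1195.5662 - 4 * residue_mass("Hex") - residue_mass("Pen") +
                residue_mass("saturation") + residue_mass("hydroxylation"),
              c("Hex", "Hex", "Hex"), 9.20, 5e5,
              list(list(chemotype = "S", organ = "root",
                        ontogeny = "vegetative", x = 0.4),
                   list(chemotype = "U", organ = "root",
                        ontogeny = "vegetative", x = 0.4),
                   list(chemotype = "S", organ = "root",
                        ontogeny = "flowering", x = 1),
                   list(chemotype = "U", organ = "root",
                        ontogeny = "flowering", x = 1),
                   list(chemotype = "S", organ = "leaf",
                        ontogeny = "vegetative", x = 0.3),
                   list(chemotype = "U", organ = "leaf",
                        ontogeny = "vegetative", x = 0.3),
                   list(chemotype = "S", organ = "leaf",
                        ontogeny = "flowering", x = 0.5),
                   list(chemotype = "U", organ = "leaf",
                        ontogeny = "flowering", x = 0.5))),
    .compound("sga_rdbe5", 434.36, c("Hex", "dHex"), 9.80, 2e5, list())
  )
  # sga_rdbe5 is a shared ("grey") compound present in every group
  cmp[[length(cmp)]]$mult[] <- 0.3
  names(cmp) <- vapply(cmp, `[[`, character(1), "name")

  sa <- sa_species_table()
  species <- vapply(cmp, function(co) {
    d <- abs(sa$mz - co$aglycone_mz)
    if (min(d) > 0.02) NA_real_ else sa$mz[which.min(d)]
  }, numeric(1))

  families <- .compound_families(cmp, mz_tol = 0.02, rt_window = 0.1)
  structure(list(compounds = cmp, species = species, families = families),
            class = "sg_library")
}

# ground-truth family partition: union compounds whose planted ions co-elute
# and are related by a neutral-loss/biotransformation mass difference
.compound_families <- function(cmp, mz_tol = 0.02, rt_window = 0.1,
                               losses = mdn_default_losses()) {
  n <- length(cmp)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  loss_mass <- losses$mass
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    if (abs(cmp[[i]]$rt - cmp[[j]]$rt) > rt_window) next
    d <- abs(outer(cmp[[i]]$ions, cmp[[j]]$ions, "-"))
    if (any(abs(outer(as.vector(d), loss_mass, "-")) <= mz_tol)) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

.ladder_rel_intensity <- function(n) {
  rel <- rep(0.7, n)
  rel[1] <- 0.6               # molecular ion
  if (n > 1) rel[2] <- 1      # base peak: first fragment
  rel[n] <- 0.9               # aglycone ion
  rel
}

# abundance of each compound in each sample (deterministic part)
.compound_abundance <- function(library, meta) {
  vapply(meta$sample, function(s) {
    i <- match(s, meta$sample)
    vapply(library$compounds, function(co)
      co$base_intensity *
        co$mult[meta$chemotype[i], meta$organ[i], meta$ontogeny[i]],
      numeric(1))
  }, numeric(length(library$compounds)))
}

#' Simulate in-source fragmentation spectra
#'
#' Every compound emits, in each sample where its group multiplier is
#' positive, a number of centroided scans proportional to
#' \code{log10(abundance)}; each scan contains the compound's full fragment
#' ladder (molecular ion down to the aglycone ion) plus optional decoy
#' peaks drawn uniformly over m/z 100-1300, excluding +/- 0.05 Da around any
#' true library ion. The per-compound scan counts are the quantity the SG
#' census recovers.
#'
#' @param library An [build_compound_library()] result.
#' @param design An [sg_design()].
#' @return List with \code{spectra} (list of scans: \code{sample},
#'   \code{scan_id}, \code{rt}, \code{mz}, \code{intensity}),
#'   \code{metadata} (sample sheet) and \code{truth} (per-sample,
#'   per-compound scan counts and per-sample, per-SA-species counts).
#' @export
simulate_spectra <- function(library, design = sg_design()) {
  stopifnot(inherits(library, "sg_library"), inherits(design, "sg_design"))
  meta <- design_samples(design)
  set.seed(design$seed + 1L)
  true_ions <- sort(unique(unlist(lapply(library$compounds, `[[`, "ions"))))
  sa <- sa_species_table()
  scan_counts <- matrix(0L, nrow(meta), length(library$compounds),
                        dimnames = list(meta$sample,
                                        names(library$compounds)))
  species_counts <- matrix(0L, nrow(meta), nrow(sa),
                           dimnames = list(meta$sample,
                                           sprintf("%.2f", sa$mz)))
  spectra <- list()
  for (i in seq_len(nrow(meta))) {
    for (k in seq_along(library$compounds)) {
      co <- library$compounds[[k]]
      mult <- co$mult[meta$chemotype[i], meta$organ[i], meta$ontogeny[i]]
      if (mult <= 0) next
      abundance <- co$base_intensity * mult *
        exp(stats::rnorm(1, 0, design$sigma))
      n_scan <- max(1L, as.integer(round(design$scan_k * log10(abundance))))
      scan_counts[i, k] <- n_scan
      sp_idx <- match(sprintf("%.2f", library$species[k]),
                      colnames(species_counts))
      if (!is.na(sp_idx)) {
        species_counts[i, sp_idx] <- species_counts[i, sp_idx] + n_scan
      }
      rel <- .ladder_rel_intensity(length(co$ions))
      for (s in seq_len(n_scan)) {
        mz <- co$ions
        intensity <- abundance * rel
        if (design$decoys_per_scan > 0) {
          dmz <- .draw_decoy_mz(design$decoys_per_scan, true_ions)
          mz <- c(mz, dmz)
          intensity <- c(intensity,
                         stats::runif(length(dmz), design$decoy_intensity[1],
                                      design$decoy_intensity[2]))
        }
        ord <- order(mz, decreasing = TRUE)
        spectra[[length(spectra) + 1L]] <- list(
          sample = meta$sample[i],
          scan_id = sprintf("%s_%s_%02d", meta$sample[i], co$name, s),
          rt = co$rt + stats::runif(1, -0.02, 0.02),
          mz = mz[ord], intensity = intensity[ord])
      }
    }
  }
  list(spectra = spectra, metadata = meta,
       truth = list(scan_counts = scan_counts,
                    species_counts = species_counts))
}

.draw_decoy_mz <- function(n, true_ions, guard = 0.05) {
  out <- numeric(0)
  while (length(out) < n) {
    cand <- stats::runif(n, 100, 1300)
    ok <- vapply(cand, function(x) all(abs(x - true_ions) > guard),
                 logical(1))
    out <- c(out, cand[ok])
  }
  out[seq_len(n)]
}

#' Simulate an LC-MS feature table
#'
#' One feature per distinct (ladder ion m/z, retention time); intensities
#' are log-normal around the group mean (baseline x group multiplier x
#' relative ladder intensity). A fixed artifact feature at m/z 329.32 and
#' optional random decoy features are appended.
#'
#' @inheritParams simulate_spectra
#' @return List with \code{features} (data.frame: \code{feature_id},
#'   \code{mz}, \code{rt}, one intensity column per sample),
#'   \code{metadata}, and \code{truth} (feature-to-compound map, compound
#'   family ids, expected group-mean intensities).
#' @export
simulate_feature_table <- function(library, design = sg_design()) {
  stopifnot(inherits(library, "sg_library"), inherits(design, "sg_design"))
  meta <- design_samples(design)
  set.seed(design$seed + 2L)
  rows <- list()
  for (k in seq_along(library$compounds)) {
    co <- library$compounds[[k]]
    rel <- .ladder_rel_intensity(length(co$ions))
    for (j in seq_along(co$ions)) {
      rows[[length(rows) + 1L]] <- list(compound = co$name, ion = j,
                                        mz = co$ions[j], rt = co$rt,
                                        rel = rel[j])
    }
  }
  n_feat <- length(rows)
  ids <- sprintf("F%03d", seq_len(n_feat))
  mat <- matrix(0, n_feat, nrow(meta),
                dimnames = list(ids, meta$sample))
  mean_mat <- mat
  for (i in seq_len(nrow(meta))) {
    for (f in seq_len(n_feat)) {
      co <- library$compounds[[rows[[f]]$compound]]
      mult <- co$mult[meta$chemotype[i], meta$organ[i], meta$ontogeny[i]]
      if (mult <= 0) next
      mu <- co$base_intensity * mult * rows[[f]]$rel
      mean_mat[f, i] <- mu
      mat[f, i] <- mu * exp(stats::rnorm(1, 0, design$sigma))
    }
  }
  features <- data.frame(feature_id = ids,
                         mz = vapply(rows, `[[`, numeric(1), "mz"),
                         rt = vapply(rows, `[[`, numeric(1), "rt"),
                         stringsAsFactors = FALSE)
  features <- cbind(features, as.data.frame(mat))
  feature_map <- data.frame(
    feature_id = ids,
    compound = vapply(rows, `[[`, character(1), "compound"),
    ion_mz = features$mz, stringsAsFactors = FALSE)

  # artifact feature excluded from TIC_SG, plus random decoy features
  true_ions <- sort(unique(features$mz))
  artifact <- data.frame(feature_id = "ARTIFACT_329", mz = 329.32, rt = 2.00,
                         stringsAsFactors = FALSE)
  artifact <- cbind(artifact, as.data.frame(
    matrix(stats::runif(nrow(meta), design$decoy_intensity[1],
                        design$decoy_intensity[2]), 1,
           dimnames = list(NULL, meta$sample))))
  features <- rbind(features, artifact)
  if (design$decoy_features > 0) {
    dmz <- .draw_decoy_mz(design$decoy_features, c(true_ions, 329.32))
    dec <- data.frame(
      feature_id = sprintf("DECOY%02d", seq_len(design$decoy_features)),
      mz = dmz,
      rt = stats::runif(design$decoy_features, design$rt_range[1],
                        design$rt_range[2]),
      stringsAsFactors = FALSE)
    dec <- cbind(dec, as.data.frame(
      matrix(stats::runif(design$decoy_features * nrow(meta),
                          design$decoy_intensity[1],
                          design$decoy_intensity[2]),
             design$decoy_features, dimnames = list(NULL, meta$sample))))
    features <- rbind(features, dec)
  }
  rownames(features) <- NULL
  list(features = features, metadata = meta,
       truth = list(feature_map = feature_map,
                    families = library$families,
                    mean_intensity = mean_mat))
}

#' Default qPCR generating model
#'
#' Gene-wise baseline log counts and condition effects (natural-log scale)
#' emulating the study's expression patterns: the saturation-pathway gene
#' \code{GAME25} is silenced in U-chemotype leaves (near the detection
#' limit), \code{GAME4} is leaf-enriched and higher in the S chemotype,
#' \code{DPS} is root-enriched, and the references \code{EXP} and
#' \code{SAND} are stable across conditions.
#'
#' @return List with \code{base} (named vector of baseline log counts) and
#'   \code{effects} (data.frame gene/chemotype/organ/ontogeny/effect, with
#'   \code{"*"} as wildcard).
#' @export
default_qpcr_coefficients <- function() {
  base <- c(GAME9 = 7, GAME4 = 7, GAME25 = 7, S5aR2 = 7, DPS = 9,
            EXP = 10, SAND = 10)
  effects <- rbind(
    data.frame(gene = "GAME25", chemotype = "U", organ = "leaf",
               ontogeny = "*", effect = -6.5),
    data.frame(gene = "GAME4", chemotype = "*", organ = "leaf",
               ontogeny = "*", effect = 0.8),
    data.frame(gene = "GAME4", chemotype = "U", organ = "root",
               ontogeny = "vegetative", effect = -0.32),
    data.frame(gene = "GAME4", chemotype = "U", organ = "root",
               ontogeny = "flowering", effect = -1.06),
    data.frame(gene = "GAME4", chemotype = "U", organ = "leaf",
               ontogeny = "flowering", effect = -0.22),
    data.frame(gene = "DPS", chemotype = "*", organ = "root",
               ontogeny = "*", effect = 2.8),
    data.frame(gene = "DPS", chemotype = "U", organ = "root",
               ontogeny = "flowering", effect = -1.5),
    data.frame(gene = "S5aR2", chemotype = "U", organ = "root",
               ontogeny = "*", effect = -0.4),
    data.frame(gene = "S5aR2", chemotype = "U", organ = "leaf",
               ontogeny = "flowering", effect = -0.3))
  list(base = base, effects = effects)
}

#' Simulate an RT-qPCR dataset from a Poisson count model
#'
#' True per-sample transcript counts are drawn Poisson from a log-linear
#' gene x chemotype x organ (x ontogeny) model with genotype and sample
#' random effects. Quantification cycles follow
#' \code{Cq = cq1 - log(count) / log(E)} plus technical noise, measured in
#' three technical replicates; a zero count is emitted as not-detected
#' (\code{NA}). A 1-1000x dilution series per gene supports efficiency
#' estimation.
#'
#' @param design An [sg_design()].
#' @param coefficients Generating model, see [default_qpcr_coefficients()].
#' @param efficiencies Named per-gene amplification efficiencies in (1, 2].
#' @param cq1 Single-molecule baseline cycle.
#' @param tech_sd Technical Cq noise sd.
#' @param sample_sd,genotype_sd Random-effect sds (natural-log scale).
#' @param n_tech Technical replicates per well group.
#' @param dilution_base Template count at dilution 1 for the series.
#' @return List with \code{wells} (gene, sample, replicate, cq),
#'   \code{metadata}, \code{efficiencies}, \code{reference_genes},
#'   \code{dilution} (gene, dilution, replicate, cq), \code{cq1} and
#'   \code{truth} (counts, effects, random effects).
#' @export
simulate_qpcr_dataset <- function(design = sg_design(),
                                  coefficients = default_qpcr_coefficients(),
                                  efficiencies = c(GAME9 = 1.95,
                                                   GAME4 = 1.90,
                                                   GAME25 = 1.92,
                                                   S5aR2 = 1.88, DPS = 1.97,
                                                   EXP = 2, SAND = 2),
                                  cq1 = 37, tech_sd = 0.15, sample_sd = 0.25,
                                  genotype_sd = 0.15, n_tech = 3,
                                  dilution_base = 1e6) {
  stopifnot(all(efficiencies > 1), all(efficiencies <= 2))
  meta <- design_samples(design)
  set.seed(design$seed + 3L)
  genes <- names(coefficients$base)
  genos <- unique(meta$genotype)
  v_geno <- stats::setNames(stats::rnorm(length(genos), 0, genotype_sd),
                            genos)
  u_sample <- stats::setNames(stats::rnorm(nrow(meta), 0, sample_sd),
                              meta$sample)
  eff_lookup <- function(g, ct, org, ont) {
    e <- coefficients$effects
    hit <- e$gene == g &
      (e$chemotype == "*" | e$chemotype == ct) &
      (e$organ == "*" | e$organ == org) &
      (e$ontogeny == "*" | e$ontogeny == ont)
    sum(e$effect[hit])
  }
  wells <- list(); counts <- list()
  for (i in seq_len(nrow(meta))) {
    for (g in genes) {
      eta <- coefficients$base[[g]] +
        eff_lookup(g, meta$chemotype[i], meta$organ[i], meta$ontogeny[i]) +
        u_sample[[meta$sample[i]]] + v_geno[[meta$genotype[i]]]
      count <- stats::rpois(1, exp(eta))
      counts[[length(counts) + 1L]] <- data.frame(
        gene = g, sample = meta$sample[i], count = count, eta = eta,
        stringsAsFactors = FALSE)
      E <- efficiencies[[g]]
      for (r in seq_len(n_tech)) {
        cq <- if (count >= 1) {
          cq1 - log(count) / log(E) + stats::rnorm(1, 0, tech_sd)
        } else NA_real_
        wells[[length(wells) + 1L]] <- data.frame(
          gene = g, sample = meta$sample[i], replicate = r, cq = cq,
          stringsAsFactors = FALSE)
      }
    }
  }
  dilution <- list()
  for (g in genes) {
    E <- efficiencies[[g]]
    for (d in c(1, 10, 100, 1000)) {
      for (r in 1:2) {
        dilution[[length(dilution) + 1L]] <- data.frame(
          gene = g, dilution = d, replicate = r,
          cq = cq1 - log(dilution_base / d) / log(E) +
            stats::rnorm(1, 0, tech_sd / 3),
          stringsAsFactors = FALSE)
      }
    }
  }
  list(wells = do.call(rbind, wells), metadata = meta,
       efficiencies = efficiencies, reference_genes = c("EXP", "SAND"),
       dilution = do.call(rbind, dilution), cq1 = cq1,
       truth = list(counts = do.call(rbind, counts),
                    coefficients = coefficients,
                    sample_effects = u_sample, genotype_effects = v_geno))
}
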