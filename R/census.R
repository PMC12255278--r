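# Steroidal-glycoside census: count SGs per steroidal-aglycone species from
# in-source fragmentation spectra.

#' The twelve steroidal aglycone (SA) species
#'
#' Census categories: the aglycone fragment m/z values used to classify
#' steroidal glycosides. Even nominal mass marks a nitrogen-containing
#' glycoalkaloid aglycone (SGA), odd nominal mass an oxygen-only sapogenin
#' (SSG).
#'
#' @return data.frame with columns \code{mz}, \code{class} (\code{"SGA"} or
#'   \code{"SSG"}).
#' @export
sa_species_table <- function() {
  mz <- c(412.32, 414.35, 416.35, 428.32, 430.33, 432.35,
          415.32, 417.33, 433.33, 434.36, 446.33, 448.34)
  data.frame(mz = mz,
             class = ifelse(round(mz) %% 2 == 0, "SGA", "SSG"),
             stringsAsFactors = FALSE)
}

#' Detect a glycosylation signature above an aglycone peak
#'
#' A scan supports a glycosylated aglycone when some peak connects down to
#' the aglycone peak through a chain of one or more glycosyl-residue
#' neutral losses (hexose, deoxyhexose or pentose; a malonylhexoside loss
#' is allowed as the terminal step onto the aglycone). The search is a
#' depth-first walk over the scan's peaks, preferring the heaviest
#' compatible precursor, and returns the longest ladder found from it.
#'
#' @param scan A scan: list with numeric \code{mz} (and optionally
#'   \code{intensity}, \code{rt}); rules are m/z-based only.
#' @param sa_mz Aglycone ion m/z; a peak within \code{tol} must be present
#'   (the caller gates on the extracted ion chromatogram).
#' @param tol Absolute m/z tolerance in Da.
#' @param residues Residue table.
#' @return List with \code{found} (logical), \code{ladder} (m/z chain from
#'   precursor down to the aglycone peak; length 0 when not found) and
#'   \code{losses} (matched residue names).
#' @export
detect_glycosylation_signature <- function(scan, sa_mz, tol = 0.02,
                                           residues = default_residue_table()) {
  mz <- sort(unique(scan$mz), decreasing = TRUE)
  sa_hit <- which(abs(mz - sa_mz) <= tol)
  if (length(sa_hit) == 0L) {
    stop("no peak within ", tol, " Da of aglycone m/z ", sa_mz)
  }
  sa_peak <- mz[sa_hit[which.min(abs(mz[sa_hit] - sa_mz))]]
  glyco <- c("hexose", "deoxyhexose", "pentose")
  glyco_mass <- vapply(glyco, residue_mass, numeric(1), residues = residues)
  mal_mass <- residue_mass("malonylhexoside", residues)
  above <- mz[mz > sa_peak + min(glyco_mass) - tol]

  # longest descending ladder from peak p down to the aglycone peak
  best <- list(ladder = numeric(0), losses = character(0))
  walk <- function(p, ladder, losses) {
    # terminal steps onto the aglycone peak
    d <- p - sa_peak
    step <- c(glyco_mass, malonylhexoside = mal_mass)
    hit <- which(abs(d - step) <= tol)
    if (length(hit)) {
      cand_l <- c(ladder, sa_peak)
      cand_n <- c(losses, names(step)[hit[which.min(abs(d - step[hit]))]])
      if (length(cand_l) > length(best$ladder)) {
        best <<- list(ladder = cand_l, losses = cand_n)
      }
    }
    # intermediate glycosyl steps to other peaks
    for (q in above[above < p]) {
      d <- p - q
      hit <- which(abs(d - glyco_mass) <= tol)
      if (length(hit)) {
        walk(q, c(ladder, q),
             c(losses, glyco[hit[which.min(abs(d - glyco_mass[hit]))]]))
      }
    }
  }
  for (p in above) {
    walk(p, p, character(0))
  }
  list(found = length(best$ladder) >= 2, ladder = best$ladder,
       losses = best$losses)
}

#' Census of steroidal glycosides per SA species
#'
#' For every scan, the SA species present with a glycosylation signature
#' are identified; the scan is attributed to the single heaviest qualifying
#' species (so a saturated aglycone pre-empts its in-source dehydration
#' artifact) and adds one count to that (sample, species) cell. Counting is
#' per retained scan, so the grand total equals the number of scans with a
#' qualifying signature.
#'
#' @param spectra List of scans, each with \code{sample} and \code{mz}.
#' @param sa_table SA species table, see [sa_species_table()].
#' @param tol Absolute m/z tolerance in Da.
#' @param samples Optional character vector fixing the row set/order (so
#'   samples with zero counts are kept).
#' @param residues Residue table.
#' @return Integer matrix (class \code{sg_counts}) samples x species, with
#'   attribute \code{grand_total}.
#' @export
census_spectra <- function(spectra, sa_table = sa_species_table(),
                           tol = 0.02, samples = NULL,
                           residues = default_residue_table()) {
  if (is.null(samples)) {
    samples <- unique(vapply(spectra, `[[`, character(1), "sample"))
  }
  counts <- matrix(0L, length(samples), nrow(sa_table),
                   dimnames = list(samples, sprintf("%.2f", sa_table$mz)))
  for (scan in spectra) {
    present <- sa_table$mz[vapply(sa_table$mz, function(m)
      any(abs(scan$mz - m) <= tol), logical(1))]
    if (length(present) == 0L) next
    qualifying <- present[vapply(present, function(m)
      detect_glycosylation_signature(scan, m, tol, residues)$found,
      logical(1))]
    if (length(qualifying) == 0L) next
    winner <- max(qualifying)   # heaviest-fragment rule
    counts[scan$sample, sprintf("%.2f", winner)] <-
      counts[scan$sample, sprintf("%.2f", winner)] + 1L
  }
  structure(counts, grand_total = sum(counts), class = "sg_counts")
}

#' @export
print.sg_counts <- function(x, ...) {
  cat("SG count matrix:", nrow(x), "samples x", ncol(x),
      "SA species; grand total", attr(x, "grand_total"), "\n")
  print(unclass(x)[seq_len(min(6L, nrow(x))), , drop = FALSE])
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}
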