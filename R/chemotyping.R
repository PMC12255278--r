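# Leaf chemotype assignment from extracted ion chromatograms.

#' Extract an ion chromatogram
#'
#' Per scan, sums the intensities of peaks within \code{tol} of the target
#' m/z; the trace is ordered by retention time. An absent ion yields an
#' all-zero trace, never an error. The default tolerance (0.05 Da) mirrors
#' the coarser one-decimal chemotyping window; the census uses its own,
#' tighter tolerance.
#'
#' @param spectra List of scans (\code{rt}, \code{mz}, \code{intensity}).
#' @param target_mz Target m/z.
#' @param tol Absolute m/z tolerance in Da.
#' @return Object of class \code{eic}: data.frame with columns \code{rt}
#'   and \code{intensity}, plus attributes \code{target_mz} and \code{tol}.
#' @export
extract_eic <- function(spectra, target_mz, tol = 0.05) {
  stopifnot(length(spectra) > 0)
  rt <- vapply(spectra, `[[`, numeric(1), "rt")
  # small epsilon guards the boundary case target 416.3 vs peak 416.35
  intensity <- vapply(spectra, function(sc) {
    sum(sc$intensity[abs(sc$mz - target_mz) <= tol + 1e-9])
  }, numeric(1))
  ord <- order(rt)
  structure(data.frame(rt = rt[ord], intensity = intensity[ord]),
            target_mz = target_mz, tol = tol, class = c("eic", "data.frame"))
}

#' Assign the leaf chemotype from the 414.3 / 416.3 ion chromatograms
#'
#' The decision rule: a sample is the saturated (S) chemotype when the
#' m/z 416.3 trace shows a peak (presence of 416.3 dominates, regardless of
#' 414.3); it is the unsaturated (U) chemotype when 414.3 is present in the
#' absence of 416.3; otherwise it is undetermined.
#'
#' Presence means the EIC maximum reaches \code{presence_threshold}. When
#' the threshold is \code{NULL}, a relative rule is used: 5 percent of the
#' larger of the two EIC maxima (peak presence in a chromatogram is judged
#' relative to the dominant signal). Raising the threshold can only move
#' labels toward undetermined.
#'
#' @param eic414,eic416 EICs of the same sample, from [extract_eic()].
#' @param presence_threshold Absolute intensity threshold, or \code{NULL}
#'   for the relative default.
#' @return \code{"S"}, \code{"U"} or \code{"undetermined"}.
#' @export
assign_chemotype <- function(eic414, eic416, presence_threshold = NULL) {
  max414 <- max(eic414$intensity, 0)
  max416 <- max(eic416$intensity, 0)
  if (is.null(presence_threshold)) {
    top <- max(max414, max416)
    if (top <= 0) return("undetermined")
    presence_threshold <- 0.05 * top
  }
  if (max416 >= presence_threshold && max416 > 0) return("S")
  if (max414 >= presence_threshold && max414 > 0) return("U")
  "undetermined"
}

#' Chemotype every sample of a spectra collection
#'
#' Convenience wrapper: splits scans by sample, extracts the 414.3 and
#' 416.3 chromatograms and applies [assign_chemotype()].
#'
#' @param spectra List of scans with \code{sample} fields.
#' @param tol EIC tolerance in Da.
#' @param presence_threshold Passed to [assign_chemotype()].
#' @return data.frame with columns \code{sample}, \code{chemotype},
#'   \code{max414}, \code{max416}.
#' @export
chemotype_samples <- function(spectra, tol = 0.05,
                              presence_threshold = NULL) {
  by_sample <- split(spectra, vapply(spectra, `[[`, character(1), "sample"))
  out <- lapply(names(by_sample), function(s) {
    e414 <- extract_eic(by_sample[[s]], 414.3, tol)
    e416 <- extract_eic(by_sample[[s]], 416.3, tol)
    data.frame(sample = s,
               chemotype = assign_chemotype(e414, e416, presence_threshold),
               max414 = max(e414$intensity, 0),
               max416 = max(e416$intensity, 0), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
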