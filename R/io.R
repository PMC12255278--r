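# Readers and writers for the package's plain-text formats: feature tables,
# MGF-like spectra, sample metadata and Cq well tables.

#' Write / read a feature table
#'
#' Tab-separated: \code{feature_id}, \code{mz}, \code{rt}, one intensity
#' column per sample.
#'
#' @param features Feature table data.frame.
#' @param path File path.
#' @return \code{read_feature_table} returns the data.frame; duplicate
#'   feature ids are an error.
#' @export
write_feature_table <- function(features, path) {
  utils::write.table(features, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  required <- c("feature_id", "mz", "rt")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("feature table ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  dup <- tab$feature_id[duplicated(tab$feature_id)]
  if (length(dup)) {
    stop("duplicate feature id(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  }
  tab
}

#' Write / read spectra in an MGF-like text format
#'
#' One block per scan: \code{BEGIN IONS}, \code{TITLE=} scan id,
#' \code{SAMPLE=}, \code{RTMINUTES=}, then one \code{m/z<TAB>intensity}
#' line per peak, \code{END IONS}.
#'
#' @param spectra List of scans (\code{sample}, \code{scan_id}, \code{rt},
#'   \code{mz}, \code{intensity}).
#' @param path File path.
#' @return \code{read_spectra_mgf} returns the list of scans.
#' @export
write_spectra_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sc in spectra) {
    writeLines(c("BEGIN IONS",
                 paste0("TITLE=", sc$scan_id),
                 paste0("SAMPLE=", sc$sample),
                 sprintf("RTMINUTES=%.6f", sc$rt),
                 sprintf("%.6f\t%.6f", sc$mz, sc$intensity),
                 "END IONS"), con)
  }
  invisible(path)
}

#' @rdname write_spectra_mgf
#' @export
read_spectra_mgf <- function(path) {
  lines <- readLines(path)
  starts <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(starts) != length(ends)) {
    stop("malformed spectra file ", path, ": unbalanced BEGIN/END IONS")
  }
  lapply(seq_along(starts), function(i) {
    block <- lines[(starts[i] + 1L):(ends[i] - 1L)]
    header <- grepl("=", block, fixed = TRUE)
    kv <- strsplit(block[header], "=", fixed = TRUE)
    keys <- vapply(kv, `[[`, character(1), 1)
    vals <- vapply(kv, function(x) paste(x[-1], collapse = "="),
                   character(1))
    peaks <- do.call(rbind, strsplit(block[!header], "\t", fixed = TRUE))
    list(sample = vals[keys == "SAMPLE"],
         scan_id = vals[keys == "TITLE"],
         rt = as.numeric(vals[keys == "RTMINUTES"]),
         mz = as.numeric(peaks[, 1]),
         intensity = as.numeric(peaks[, 2]))
  })
}

#' Write / read a sample metadata table
#'
#' @param metadata data.frame with at least a \code{sample} column.
#' @param path File path.
#' @return \code{read_metadata} returns the data.frame.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_metadata
#' @export
read_metadata <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"sample" %in% names(tab)) {
    stop("metadata ", path, " lacks a 'sample' column")
  }
  tab
}

#' Write / read a Cq well table
#'
#' Tab-separated columns \code{gene}, \code{sample}, \code{replicate},
#' \code{cq}; not-detected wells are written as \code{ND} and read back as
#' \code{NA}.
#'
#' @param wells Well table data.frame.
#' @param path File path.
#' @return \code{read_cq_table} returns the data.frame with numeric
#'   \code{cq}.
#' @export
write_cq_table <- function(wells, path) {
  out <- wells
  out$cq <- ifelse(is.na(out$cq), "ND", sprintf("%.4f", out$cq))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_cq_table
#' @export
read_cq_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("gene", "sample", "replicate", "cq")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("Cq table ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  tab$cq[tab$cq %in% c("ND", "nd")] <- NA
  tab$cq <- as.numeric(tab$cq)
  tab
}
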