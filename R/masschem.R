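# Monoisotopic mass arithmetic for glycosyl residues and steroidal aglycones.

# CHNO monoisotopic masses (Da); proton mass used for [M+H]+ <-> neutral.
.ELEMENT_MASS <- c(C = 12, H = 1.00782503207, N = 14.0030740048, O = 15.9949146196)
.PROTON_MASS <- 1.00728

#' Mass of a proton
#'
#' Ions throughout the package are treated as singly protonated \code{[M+H]+};
#' subtracting this constant from an ion m/z yields the neutral monoisotopic
#' mass. Multiply charged ions are not modelled.
#'
#' @return Proton mass in Da.
#' @export
proton_mass <- function() .PROTON_MASS

#' Parse a CHNO elemental composition string
#'
#' @param x A composition string such as \code{"C6H10O5"} or \code{"H2O1"}.
#'   Element symbols restricted to C, H, N, O; a missing count means 1.
#' @return Named integer vector with components C, H, N, O.
#' @examples
#' parse_formula("C6H10O5")
#' @export
parse_formula <- function(x) {
  stopifnot(is.character(x), length(x) == 1L, nzchar(x))
  if (grepl("[^CHNO0-9]", x)) {
    stop("composition '", x, "' contains symbols outside C, H, N, O")
  }
  counts <- c(C = 0L, H = 0L, N = 0L, O = 0L)
  m <- gregexpr("([CHNO])([0-9]*)", x)[[1]]
  parts <- regmatches(x, gregexpr("([CHNO])([0-9]*)", x))[[1]]
  if (sum(nchar(parts)) != nchar(x)) stop("cannot parse composition '", x, "'")
  for (p in parts) {
    el <- substr(p, 1, 1)
    n <- substr(p, 2, nchar(p))
    counts[el] <- counts[el] + if (nzchar(n)) as.integer(n) else 1L
  }
  if (sum(counts) == 0L) stop("composition '", x, "' has no atoms")
  counts
}

#' Monoisotopic mass of a CHNO formula
#'
#' @param formula Composition string or named numeric vector (names among
#'   C, H, N, O).
#' @return Monoisotopic mass in Da.
#' @examples
#' formula_mass("H2O1")
#' @export
formula_mass <- function(formula) {
  f <- .as_formula_vector(formula)
  sum(f * .ELEMENT_MASS[names(f)])
}

.as_formula_vector <- function(formula) {
  if (is.character(formula)) formula <- parse_formula(formula)
  stopifnot(is.numeric(formula), !is.null(names(formula)))
  bad <- setdiff(names(formula), names(.ELEMENT_MASS))
  if (length(bad)) stop("unknown elements: ", paste(bad, collapse = ", "))
  full <- c(C = 0, H = 0, N = 0, O = 0)
  full[names(formula)] <- formula
  if (any(full < 0)) stop("negative atom counts")
  if (sum(full) == 0) stop("formula has no atoms")
  full
}

#' Ring-double-bond equivalent of a CHNO formula
#'
#' RDBE = C - H/2 + N/2 + 1; the sum of rings and double bonds for a neutral
#' even-electron molecule. Half-integer values indicate a radical or an ion
#' and are returned as-is.
#'
#' @inheritParams formula_mass
#' @return RDBE (possibly half-integer).
#' @examples
#' rdbe("C27H45NO2") # soladulcidine, 6
#' @export
rdbe <- function(formula) {
  f <- .as_formula_vector(formula)
  unname(f["C"] - f["H"] / 2 + f["N"] / 2 + 1)
}

#' Table of glycosyl residues and biotransformation mass differences
#'
#' Reads the residue table shipped with the package (or a user-supplied file
#' in the same three-column tab-separated layout: \code{name},
#' \code{composition}, \code{aliases} separated by \code{";"}). Monoisotopic
#' masses are computed from the elemental compositions, so the table is
#' consistent by construction. Entries cover the neutral losses commonly
#' observed for steroidal glycosides: hexose (162.0528), deoxyhexose
#' (146.0579), pentose (132.0423), malonylhexoside (248.0532), hydroxylation
#' (O), saturation (H2), acetylation and water.
#'
#' @param path Optional path to an alternative residue table.
#' @return A data.frame with columns \code{name}, \code{composition},
#'   \code{mass} and \code{aliases}.
#' @examples
#' default_residue_table()
#' @export
default_residue_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "glyco_residues.tsv", package = "sgchem")
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "composition") %in% names(tab)))
  if (is.null(tab$aliases)) tab$aliases <- ""
  tab$mass <- vapply(tab$composition, formula_mass, numeric(1))
  if (any(tab$mass <= 0)) stop("residue masses must be positive")
  tab[, c("name", "composition", "mass", "aliases")]
}

.resolve_residue <- function(name, residues) {
  if (name == "proton") return("proton")
  hit <- match(name, residues$name)
  if (is.na(hit)) {
    aliases <- strsplit(residues$aliases, ";", fixed = TRUE)
    hit <- which(vapply(aliases, function(a) name %in% a, logical(1)))[1]
  }
  if (is.na(hit) || length(hit) == 0L) {
    stop("unknown residue name: '", name, "'")
  }
  residues$name[hit]
}

#' Monoisotopic mass of a named residue or biotransformation
#'
#' @param name Residue name or alias (e.g. \code{"hexose"}, \code{"Hex"},
#'   \code{"dHex"}, \code{"Pen"}, \code{"malonylhexoside"}, \code{"O"},
#'   \code{"H2"}); \code{"proton"} returns the proton mass.
#' @param residues Residue table, see [default_residue_table()].
#' @return Monoisotopic mass in Da.
#' @examples
#' residue_mass("hexose")
#' residue_mass("dHex")
#' @export
residue_mass <- function(name, residues = default_residue_table()) {
  stopifnot(is.character(name), length(name) == 1L)
  resolved <- .resolve_residue(name, residues)
  if (resolved == "proton") return(.PROTON_MASS)
  residues$mass[match(resolved, residues$name)]
}

#' Assign the best elemental formula to a neutral monoisotopic mass
#'
#' Exhaustive search over a bounded CHNO composition space. Candidates are
#' restricted to valid neutral even-electron molecules: integer RDBE (even
#' H + N parity, the nitrogen rule) and RDBE >= 0; this prevents radical
#' compositions from outranking chemically possible ones. The best candidate
#' has smallest absolute mass error; ties are broken by smaller |RDBE - 7|
#' (steroidal aglycones cluster near RDBE 5-8), then lexicographically on
#' (C, H, N, O).
#'
#' @param neutral_mass Neutral monoisotopic mass in Da (for a protonated ion,
#'   subtract [proton_mass()] first).
#' @param tolerance Absolute mass tolerance in Da (> 0).
#' @param bounds Named list of \code{c(min, max)} per element; default covers
#'   the steroidal aglycone space C 20-35, H 10-60, N 0-1, O 0-6.
#' @param require_integer_rdbe Apply the neutral even-electron filter
#'   (default \code{TRUE}).
#' @return Object of class \code{formula_assignment}: a list with
#'   \code{found}, \code{formula} (named integer vector), \code{mass},
#'   \code{error} and \code{rdbe}. When no composition matches,
#'   \code{found} is \code{FALSE} (no error is thrown).
#' @examples
#' assign_formula(433.3556, tolerance = 0.005)
#' @export
assign_formula <- function(neutral_mass, tolerance = 0.005,
                           bounds = list(C = c(20, 35), H = c(10, 60),
                                         N = c(0, 1), O = c(0, 6)),
                           require_integer_rdbe = TRUE) {
  stopifnot(is.numeric(neutral_mass), length(neutral_mass) == 1L,
            tolerance > 0, length(bounds) > 0)
  for (el in c("C", "H", "N", "O")) {
    if (is.null(bounds[[el]])) bounds[[el]] <- c(0, 0)
  }
  grid <- expand.grid(C = bounds$C[1]:bounds$C[2],
                      H = bounds$H[1]:bounds$H[2],
                      N = bounds$N[1]:bounds$N[2],
                      O = bounds$O[1]:bounds$O[2])
  mass <- grid$C * .ELEMENT_MASS["C"] + grid$H * .ELEMENT_MASS["H"] +
    grid$N * .ELEMENT_MASS["N"] + grid$O * .ELEMENT_MASS["O"]
  err <- mass - neutral_mass
  rdbe_v <- grid$C - grid$H / 2 + grid$N / 2 + 1
  keep <- abs(err) <= tolerance
  if (require_integer_rdbe) {
    keep <- keep & ((grid$H + grid$N) %% 2 == 0) & rdbe_v >= 0
  }
  n_space <- nrow(grid)
  if (!any(keep)) {
    return(structure(list(found = FALSE, formula = NULL, mass = NA_real_,
                          error = NA_real_, rdbe = NA_real_,
                          n_candidates = n_space),
                     class = "formula_assignment"))
  }
  grid <- grid[keep, , drop = FALSE]
  ord <- order(abs(err[keep]), abs(rdbe_v[keep] - 7),
               grid$C, grid$H, grid$N, grid$O)
  best <- grid[ord[1L], ]
  f <- c(C = best$C, H = best$H, N = best$N, O = best$O)
  structure(list(found = TRUE, formula = f, mass = formula_mass(f),
                 error = formula_mass(f) - neutral_mass, rdbe = rdbe(f),
                 n_candidates = n_space),
            class = "formula_assignment")
}

#' @export
print.formula_assignment <- function(x, ...) {
  if (!x$found) {
    cat("formula assignment: no composition within tolerance\n")
    return(invisible(x))
  }
  f <- x$formula
  lab <- paste0(names(f)[f > 0], ifelse(f[f > 0] > 1, f[f > 0], ""),
                collapse = "")
  cat(sprintf("formula %s  mass %.4f Da  error %+.4f Da  RDBE %.1f\n",
              lab, x$mass, x$error, x$rdbe))
  invisible(x)
}

#' Predict an in-source fragment ladder from sequential neutral losses
#'
#' Starting from a molecular ion m/z, subtracts the named residue masses in
#' order; the terminal value is the predicted aglycone ion m/z.
#'
#' @param molecular_ion_mz Molecular ion m/z (assumed \code{[M+H]+}).
#' @param losses Non-empty character vector of residue names/aliases, in
#'   cleavage order.
#' @param residues Residue table.
#' @return Object of class \code{ion_ladder}: list with \code{ions}
#'   (descending m/z, length \code{length(losses) + 1}), \code{losses}
#'   (resolved names) and \code{aglycone} (terminal ion m/z).
#' @examples
#' predict_fragment_ladder(886.52, c("Hex", "dHex", "Hex"))
#' @export
predict_fragment_ladder <- function(molecular_ion_mz, losses,
                                    residues = default_residue_table()) {
  stopifnot(is.numeric(molecular_ion_mz), length(molecular_ion_mz) == 1L)
  if (length(losses) == 0L) stop("'losses' must be non-empty")
  resolved <- vapply(losses, .resolve_residue, character(1),
                     residues = residues)
  masses <- unname(vapply(resolved, residue_mass, numeric(1),
                          residues = residues))
  ions <- molecular_ion_mz - cumsum(c(0, masses))
  if (any(ions <= 0)) stop("predicted ion m/z <= 0; losses exceed precursor")
  structure(list(ions = ions, losses = unname(resolved),
                 aglycone = ions[length(ions)]),
            class = "ion_ladder")
}

#' @export
print.ion_ladder <- function(x, ...) {
  cat("ion ladder:", paste(sprintf("%.4f", x$ions), collapse = " -> "), "\n")
  cat("losses:    ", paste(x$losses, collapse = ", "), "\n")
  cat(sprintf("aglycone ion m/z %.4f\n", x$aglycone))
  invisible(x)
}

#' Decompose a glycoside chain mass into residue compositions
#'
#' Bounded enumeration over counts of hexose, deoxyhexose, pentose,
#' malonylhexoside and acetyl residues whose summed mass matches the
#' difference between a molecular ion and its aglycone ion.
#'
#' @param molecular_ion_mz,aglycone_ion_mz Ion m/z values (same charge
#'   state); molecular ion must exceed the aglycone ion.
#' @param tolerance Absolute mass tolerance in Da.
#' @param max_per_residue Upper bound on hexose/deoxyhexose/pentose counts
#'   (observed chains carry at most five sugars; default 6 leaves headroom).
#' @param max_acyl Upper bound on malonylhexoside and acetyl counts.
#' @param residues Residue table.
#' @return data.frame with one row per matching composition (columns
#'   \code{hexose}, \code{deoxyhexose}, \code{pentose},
#'   \code{malonylhexoside}, \code{acetylation}, \code{mass}, \code{error}),
#'   ordered by absolute mass error; zero rows when nothing matches.
#' @examples
#' decompose_glycan(1034.55, 416.35)
#' @export
decompose_glycan <- function(molecular_ion_mz, aglycone_ion_mz,
                             tolerance = 0.02, max_per_residue = 6,
                             max_acyl = 1,
                             residues = default_residue_table()) {
  stopifnot(molecular_ion_mz > aglycone_ion_mz, tolerance > 0)
  delta <- molecular_ion_mz - aglycone_ion_mz
  res_names <- c("hexose", "deoxyhexose", "pentose", "malonylhexoside",
                 "acetylation")
  rm <- vapply(res_names, residue_mass, numeric(1), residues = residues)
  grid <- expand.grid(hexose = 0:max_per_residue,
                      deoxyhexose = 0:max_per_residue,
                      pentose = 0:max_per_residue,
                      malonylhexoside = 0:max_acyl,
                      acetylation = 0:max_acyl)
  grid <- grid[rowSums(grid) > 0, , drop = FALSE]
  mass <- as.matrix(grid) %*% rm
  err <- mass - delta
  keep <- abs(err) <= tolerance
  out <- grid[keep, , drop = FALSE]
  out$mass <- mass[keep]
  out$error <- err[keep]
  out <- out[order(abs(out$error)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
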