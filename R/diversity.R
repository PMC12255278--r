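# Chemodiversity indices on SG count vectors.

#' Margalef richness of an SG count vector
#'
#' \eqn{D_{mg} = (S - 1) / \ln N} where S is the number of SA species with
#' a positive count and N the total SG count. N = 1 is defined as 0 by
#' continuity of the numerator; an all-zero vector is undefined
#' (\code{NA}).
#'
#' @param counts Non-negative integer vector of SG counts per SA species.
#' @return Margalef richness, or \code{NA_real_} when undefined.
#' @examples
#' margalef(c(5, 5, rep(0, 10)))   # 1 / log(10)
#' @export
margalef <- function(counts) {
  stopifnot(is.numeric(counts), all(counts >= 0))
  N <- sum(counts)
  if (N < 1) return(NA_real_)
  S <- sum(counts > 0)
  if (N == 1) return(0)
  (S - 1) / log(N)
}

#' Shannon index and Pielou evenness of an SG count vector
#'
#' \eqn{H' = -\sum_i p_i \ln p_i} over occupied species
#' (\eqn{p_i = n_i / N}) and \eqn{J = H' / \ln S}. J is undefined
#' (\code{NA}) for S = 1 (\eqn{\ln S = 0}); an all-zero vector is
#' undefined for both.
#'
#' @inheritParams margalef
#' @return List with \code{H} (Shannon index, natural log) and \code{J}
#'   (Pielou evenness).
#' @examples
#' pielou(c(9, 1, rep(0, 10)))
#' @export
pielou <- function(counts) {
  stopifnot(is.numeric(counts), all(counts >= 0))
  N <- sum(counts)
  if (N < 1) return(list(H = NA_real_, J = NA_real_))
  p <- counts[counts > 0] / N
  H <- -sum(p * log(p))
  S <- length(p)
  list(H = H, J = if (S == 1) NA_real_ else H / log(S))
}

#' Summed intensity of SG-associated network features per sample
#'
#' TIC_SG: the per-sample sum of intensities over mass-difference-network
#' node features, excluding designated artifact signals (default
#' m/z 329.32).
#'
#' @param features Feature table (with per-sample intensity columns).
#' @param node_ids Feature ids of the network nodes.
#' @param exclude_mz m/z values to exclude.
#' @param tol Exclusion tolerance in Da.
#' @return Named numeric vector of TIC_SG per sample.
#' @export
tic_sg <- function(features, node_ids, exclude_mz = 329.32, tol = 0.02) {
  stopifnot(all(node_ids %in% features$feature_id))
  sample_cols <- setdiff(names(features), c("feature_id", "mz", "rt"))
  sub <- features[features$feature_id %in% node_ids, , drop = FALSE]
  if (length(exclude_mz)) {
    keep <- vapply(sub$mz, function(m) all(abs(m - exclude_mz) > tol),
                   logical(1))
    sub <- sub[keep, , drop = FALSE]
  }
  colSums(as.matrix(sub[, sample_cols, drop = FALSE]))
}

#' Pearson correlation between two per-sample quantities
#'
#' Standard Pearson r with the two-sided t-test p-value, overall and
#' optionally per group. Degenerate inputs (zero variance) yield \code{NA}.
#'
#' @param x,y Paired numeric vectors (at least 3 complete pairs).
#' @param groups Optional grouping factor for per-group correlations.
#' @return data.frame with columns \code{group} (\code{"overall"} first),
#'   \code{r}, \code{p}, \code{n}.
#' @export
correlate <- function(x, y, groups = NULL) {
  stopifnot(length(x) == length(y))
  one <- function(xs, ys, label) {
    ok <- stats::complete.cases(xs, ys)
    xs <- xs[ok]; ys <- ys[ok]
    if (length(xs) < 3 || stats::sd(xs) == 0 || stats::sd(ys) == 0) {
      return(data.frame(group = label, r = NA_real_, p = NA_real_,
                        n = length(xs), stringsAsFactors = FALSE))
    }
    ct <- stats::cor.test(xs, ys, method = "pearson")
    data.frame(group = label, r = unname(ct$estimate), p = ct$p.value,
               n = length(xs), stringsAsFactors = FALSE)
  }
  out <- one(x, y, "overall")
  if (!is.null(groups)) {
    for (g in sort(unique(groups))) {
      out <- rbind(out, one(x[groups == g], y[groups == g], g))
    }
  }
  rownames(out) <- NULL
  out
}

#' Per-sample chemodiversity table
#'
#' Computes S (occupied SA species), N (total SG count), Margalef richness,
#' Shannon index and Pielou evenness for every row of an SG count matrix,
#' optionally joined with TIC_SG and sample metadata.
#'
#' @param counts SG count matrix (samples x species), e.g. from
#'   [census_spectra()].
#' @param tic Optional named TIC_SG vector from [tic_sg()].
#' @param metadata Optional sample metadata to join on \code{sample}.
#' @return data.frame with one row per sample.
#' @export
diversity_table <- function(counts, tic = NULL, metadata = NULL) {
  out <- data.frame(
    sample = rownames(counts),
    S = apply(counts, 1, function(x) sum(x > 0)),
    N = rowSums(counts),
    Dmg = apply(counts, 1, margalef),
    H = apply(counts, 1, function(x) pielou(x)$H),
    J = apply(counts, 1, function(x) pielou(x)$J),
    stringsAsFactors = FALSE)
  if (!is.null(tic)) out$TIC_SG <- unname(tic[out$sample])
  if (!is.null(metadata)) {
    out <- merge(out, metadata, by = "sample", sort = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Descriptive group summaries of diversity indices
#'
#' Mean and sd of a diversity index per factor combination (default
#' chemotype x organ x ontogeny).
#'
#' @param div Table from [diversity_table()] joined with metadata.
#' @param index Column to summarise (e.g. \code{"Dmg"}, \code{"J"}).
#' @param by Grouping columns.
#' @return data.frame of group means, sds and sizes (undefined index
#'   values excluded).
#' @export
diversity_summary <- function(div, index = "Dmg",
                              by = c("chemotype", "organ", "ontogeny")) {
  stopifnot(index %in% names(div), all(by %in% names(div)))
  agg <- stats::aggregate(div[[index]],
                          by = lapply(by, function(b) div[[b]]),
                          FUN = function(v) c(mean = mean(v, na.rm = TRUE),
                                              sd = stats::sd(v, na.rm = TRUE),
                                              n = sum(!is.na(v))))
  out <- data.frame(agg[, seq_along(by), drop = FALSE],
                    mean = agg$x[, "mean"], sd = agg$x[, "sd"],
                    n = agg$x[, "n"])
  names(out)[seq_along(by)] <- by
  out
}
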