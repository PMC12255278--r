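# Multivariate descriptive chain: feature preprocessing + PCA, principal
# coordinates analysis of a distance matrix, and PERMANOVA.

#' Preprocess a feature table for ordination
#'
#' Sum-normalization (each sample scaled to unit total), log10 transform
#' with a pseudo-count of half the smallest positive normalized value, and
#' per-feature mean-centering.
#'
#' @param features Feature table (data.frame with \code{feature_id},
#'   \code{mz}, \code{rt} and per-sample intensity columns) or a numeric
#'   matrix samples x features.
#' @return Numeric matrix samples x features, centered columns.
#' @export
preprocess_features <- function(features) {
  if (is.data.frame(features)) {
    sample_cols <- setdiff(names(features), c("feature_id", "mz", "rt"))
    m <- t(as.matrix(features[, sample_cols, drop = FALSE]))
    colnames(m) <- features$feature_id
  } else {
    m <- as.matrix(features)
  }
  stopifnot(all(m >= 0))
  totals <- rowSums(m)
  if (any(totals == 0)) {
    stop("all-zero sample(s): ",
         paste(rownames(m)[totals == 0], collapse = ", "))
  }
  m <- m / totals
  eps <- min(m[m > 0]) / 2
  m <- log10(m + eps)
  scale(m, center = TRUE, scale = FALSE)
}

#' Principal components analysis
#'
#' SVD-based PCA of a preprocessed matrix (samples x variables).
#'
#' @param x Numeric matrix, samples in rows.
#' @return Object of class \code{ordination}: \code{method},
#'   \code{scores}, \code{loadings}, \code{expvar} (percent per axis),
#'   \code{eig}.
#' @export
pca <- function(x) {
  x <- as.matrix(x)
  stopifnot(nrow(x) >= 2)
  xc <- scale(x, center = TRUE, scale = FALSE)
  if (sum(xc^2) < 1e-12) stop("input has rank 0 after centering")
  sv <- svd(xc)
  pos <- sv$d > sv$d[1] * 1e-8
  d <- sv$d[pos]
  scores <- sv$u[, pos, drop = FALSE] %*% diag(d, length(d))
  rownames(scores) <- rownames(x)
  colnames(scores) <- paste0("PC", seq_along(d))
  loadings <- sv$v[, pos, drop = FALSE]
  rownames(loadings) <- colnames(x)
  colnames(loadings) <- colnames(scores)
  structure(list(method = "PCA", scores = scores, loadings = loadings,
                 expvar = 100 * d^2 / sum(d^2), eig = d^2 / (nrow(x) - 1)),
            class = "ordination")
}

#' Principal coordinates analysis (classical MDS)
#'
#' Gower double-centering of \eqn{-D^2/2} followed by an
#' eigendecomposition; axes are returned for positive eigenvalues,
#' negative eigenvalues are reported but not corrected.
#'
#' @param distances Square symmetric distance matrix (or \code{dist}).
#' @return Object of class \code{ordination}: \code{scores},
#'   \code{expvar} (percent of the positive eigenvalue total),
#'   \code{eig} (all eigenvalues).
#' @export
pcoa <- function(distances) {
  D <- as.matrix(distances)
  if (nrow(D) != ncol(D) || any(abs(D - t(D)) > 1e-8)) {
    stop("distance matrix must be square and symmetric")
  }
  if (any(abs(diag(D)) > 1e-8)) stop("distance matrix diagonal must be zero")
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D^2) %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  pos <- e$values > max(abs(e$values)) * 1e-8
  scores <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), sum(pos))
  rownames(scores) <- rownames(D)
  colnames(scores) <- paste0("PCo", seq_len(sum(pos)))
  structure(list(method = "PCoA", scores = scores,
                 expvar = 100 * e$values[pos] / sum(e$values[pos]),
                 eig = e$values),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  k <- min(3L, length(x$expvar))
  cat(x$method, "ordination:", nrow(x$scores), "samples,",
      length(x$expvar), "axes\n")
  cat("explained variance:",
      paste(sprintf("%.1f%%", x$expvar[seq_len(k)]), collapse = ", "),
      if (length(x$expvar) > k) "..." else "", "\n")
  invisible(x)
}

#' Permutational multivariate analysis of variance
#'
#' Partitions the total sum of squared inter-point distances into between-
#' and within-group components; the pseudo-F statistic is calibrated by
#' free permutation of the group labels,
#' \code{p = (1 + #\{F_perm >= F\}) / (n_perm + 1)}.
#'
#' @param distances Square symmetric distance matrix (or \code{dist}).
#' @param grouping Group labels, length = number of rows; at least two
#'   groups with at least two members each.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return List with \code{F}, \code{p}, \code{R2}, \code{df} and the
#'   permutation distribution.
#' @export
permanova <- function(distances, grouping, n_perm = 999, seed = 1L) {
  D <- as.matrix(distances)
  grouping <- as.factor(grouping)
  stopifnot(nrow(D) == length(grouping))
  if (nlevels(droplevels(grouping)) < 2) stop("need at least two groups")
  if (any(table(grouping) < 2)) stop("singleton group(s) not allowed")
  n <- nrow(D)
  a <- nlevels(grouping)
  ss_total <- sum(D^2) / (2 * n)
  f_stat <- function(gr) {
    ss_within <- 0
    for (lv in levels(gr)) {
      idx <- which(gr == lv)
      ss_within <- ss_within +
        sum(D[idx, idx]^2) / (2 * length(idx))
    }
    ((ss_total - ss_within) / (a - 1)) / (ss_within / (n - a))
  }
  f_obs <- f_stat(grouping)
  set.seed(seed)
  f_perm <- vapply(seq_len(n_perm), function(b)
    f_stat(grouping[sample.int(n)]), numeric(1))
  ss_within <- ss_total - (a - 1) * f_obs * ss_total /
    ((a - 1) * f_obs + (n - a))
  list(F = f_obs, p = (1 + sum(f_perm >= f_obs)) / (n_perm + 1),
       R2 = (a - 1) * f_obs / ((a - 1) * f_obs + (n - a)),
       df = c(between = a - 1, within = n - a),
       permutations = f_perm)
}
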