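# Variation partitioning of SG counts: per-species Poisson GLMs, term-wise
# effect-matrix decomposition (GLM-ASCA), permutation validation and a
# pseudo-R2 variable screen.
#
# Effect matrices live on the linear-predictor (log) scale, the only scale
# on which term contributions are additive. Factors are coded with
# sum-to-zero contrasts so that, for a balanced design under the Gaussian
# family with identity link, each term's effect matrix equals the classical
# ASCA group-mean deviation matrix.

.asca_model_matrix <- function(metadata, terms) {
  f <- stats::reformulate(terms)
  vars <- all.vars(f)
  data <- metadata[, vars, drop = FALSE]
  for (v in vars) data[[v]] <- factor(data[[v]])
  contr <- stats::setNames(replicate(length(vars), "contr.sum",
                                     simplify = FALSE), vars)
  X <- stats::model.matrix(f, data, contrasts.arg = contr)
  if (qr(X)$rank < ncol(X)) stop("design is not full rank after encoding")
  list(X = X, assign = attr(X, "assign"),
       term_labels = attr(stats::terms(f), "term.labels"))
}

.fit_species <- function(X, y, family) {
  fit <- suppressWarnings(stats::glm.fit(X, y, family = family))
  ok <- fit$converged && all(is.finite(fit$coefficients))
  # on the log link, fitted means collapsing to zero signal separation
  # (e.g. a structurally zero factor cell): the MLE sits at the boundary.
  # Such fits are flagged but kept -- chemotype-defining species are
  # exactly the ones with structural zeros -- while genuine
  # non-convergence excludes the species downstream.
  boundary <- family$link == "log" &&
    (any(fit$fitted.values < 1e-7) || any(abs(fit$coefficients) > 20))
  list(coef = fit$coefficients, deviance = fit$deviance,
       null_deviance = fit$null.deviance, converged = ok,
       boundary = boundary)
}

#' Fit per-species count GLMs for ASCA
#'
#' One log-link Poisson regression per SA species (column of the count
#' matrix) on the design factors, fitted by iteratively reweighted least
#' squares. Non-converged fits are excluded from the decomposition with a
#' warning; boundary (separable) fits -- structurally zero factor cells,
#' typical of chemotype-defining species -- are flagged via a message but
#' retained.
#'
#' @param counts Samples x species count matrix.
#' @param metadata Sample metadata (rows aligned with \code{counts}).
#' @param terms Character vector of model terms, e.g.
#'   \code{c("organ", "chemotype", "organ:chemotype")}.
#' @param family A [stats::family()]; \code{poisson()} by default
#'   (\code{gaussian()} recovers classical ASCA).
#' @return Object of class \code{sg_glm_fits}: list with the model matrix,
#'   term assignment, per-species coefficients, deviances and convergence
#'   flags.
#' @export
fit_poisson_glms <- function(counts, metadata, terms, family = stats::poisson()) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == nrow(metadata), all(counts >= 0))
  mm <- .asca_model_matrix(metadata, terms)
  fits <- lapply(seq_len(ncol(counts)), function(j)
    .fit_species(mm$X, counts[, j], family))
  converged <- vapply(fits, `[[`, logical(1), "converged")
  boundary <- vapply(fits, `[[`, logical(1), "boundary")
  if (any(!converged)) {
    warning("excluding non-converged species: ",
            paste(colnames(counts)[!converged], collapse = ", "))
  }
  if (any(boundary & converged)) {
    message("boundary (separable) fits retained for species: ",
            paste(colnames(counts)[boundary & converged], collapse = ", "))
  }
  structure(list(X = mm$X, assign = mm$assign,
                 term_labels = mm$term_labels,
                 coef = vapply(fits, `[[`, numeric(ncol(mm$X)), "coef"),
                 deviance = vapply(fits, `[[`, numeric(1), "deviance"),
                 null_deviance = vapply(fits, `[[`, numeric(1),
                                        "null_deviance"),
                 converged = converged, boundary = boundary,
                 species = colnames(counts),
                 family = family$family),
            class = "sg_glm_fits")
}

#' Decompose fitted linear predictors into per-term effect matrices
#'
#' Each term's effect matrix is its additive contribution to the linear
#' predictor across samples (per species), column-centered; a singular
#' value decomposition per term yields latent variables: sample scores,
#' species loadings and percent explained variance.
#'
#' @param fits From [fit_poisson_glms()].
#' @return Object of class \code{glm_asca}: list of per-term results
#'   (\code{effects}, \code{scores}, \code{loadings}, \code{expvar} in
#'   percent) plus the intercept and residual parts of the linear
#'   predictor.
#' @export
decompose_effects <- function(fits) {
  stopifnot(inherits(fits, "sg_glm_fits"))
  keep <- fits$converged
  if (!any(keep)) stop("no converged species to decompose")
  B <- fits$coef[, keep, drop = FALSE]
  X <- fits$X
  species <- fits$species[keep]
  eta <- X %*% B
  out <- list()
  for (t in seq_along(fits$term_labels)) {
    cols <- which(fits$assign == t)
    E <- X[, cols, drop = FALSE] %*% B[cols, , drop = FALSE]
    Ec <- sweep(E, 2, colMeans(E))
    sv <- svd(Ec)
    pos <- sv$d > max(sv$d[1], 0) * 1e-8
    if (sum(Ec^2) < 1e-12 || !any(pos)) {
      out[[fits$term_labels[t]]] <- list(effects = Ec, scores = NULL,
                                         loadings = NULL,
                                         expvar = numeric(0))
      next
    }
    d <- sv$d[pos]
    scores <- sv$u[, pos, drop = FALSE] %*% diag(d, sum(pos))
    loadings <- sv$v[, pos, drop = FALSE]
    rownames(scores) <- rownames(eta)
    rownames(loadings) <- species
    colnames(scores) <- colnames(loadings) <- paste0("LV", seq_len(sum(pos)))
    out[[fits$term_labels[t]]] <- list(effects = Ec, scores = scores,
                                       loadings = loadings,
                                       expvar = 100 * d^2 / sum(d^2))
  }
  intercept <- X[, fits$assign == 0, drop = FALSE] %*%
    B[fits$assign == 0, , drop = FALSE]
  contributions <- Reduce(`+`, lapply(seq_along(fits$term_labels),
    function(t) X[, fits$assign == t, drop = FALSE] %*%
      B[fits$assign == t, , drop = FALSE]))
  structure(list(terms = out, species = species, eta = eta,
                 intercept = intercept,
                 residual = eta - intercept - contributions,
                 family = fits$family),
            class = "glm_asca")
}

#' @export
print.glm_asca <- function(x, ...) {
  cat("GLM-ASCA decomposition (", x$family, " family), ",
      length(x$species), " species\n", sep = "")
  for (nm in names(x$terms)) {
    ev <- x$terms[[nm]]$expvar
    cat(sprintf("  %-22s %s\n", nm,
                if (length(ev)) paste0("LV expl. var: ",
                  paste(sprintf("%.1f%%", ev[seq_len(min(3, length(ev)))]),
                        collapse = ", "))
                else "zero effect matrix"))
  }
  if (!is.null(attr(x, "p_values"))) {
    p <- attr(x, "p_values")
    cat("permutation p-values:",
        paste(names(p), sprintf("%.4g", p), collapse = ", "), "\n")
  }
  invisible(x)
}

# refit all species on a model matrix and return one term's centered
# effect-matrix squared Frobenius norm
.term_norm <- function(X, counts, cols, family) {
  stat <- 0
  for (j in seq_len(ncol(counts))) {
    fit <- suppressWarnings(stats::glm.fit(X, counts[, j], family = family))
    e <- X[, cols, drop = FALSE] %*% fit$coefficients[cols]
    stat <- stat + sum((e - mean(e))^2)
  }
  stat
}

#' Permutation validation of GLM-ASCA terms
#'
#' Per term, the test statistic is the squared Frobenius norm of the
#' centered effect matrix. The null distribution is generated by permuting
#' the rows of that term's design-matrix columns (other terms fixed) and
#' refitting; \code{p = (1 + #\{null >= observed\}) / (n_perm + 1)}. For a
#' single-factor model this is an exact label permutation.
#'
#' @inheritParams fit_poisson_glms
#' @param n_perm Number of permutations (>= 99).
#' @param seed Integer seed.
#' @return Named vector of per-term p-values.
#' @export
permutation_validation <- function(counts, metadata, terms, n_perm = 999,
                                   seed = 1L, family = stats::poisson()) {
  stopifnot(n_perm >= 99)
  counts <- as.matrix(counts)
  mm <- .asca_model_matrix(metadata, terms)
  set.seed(seed)
  n <- nrow(counts)
  p <- stats::setNames(numeric(length(mm$term_labels)), mm$term_labels)
  for (t in seq_along(mm$term_labels)) {
    cols <- which(mm$assign == t)
    obs <- .term_norm(mm$X, counts, cols, family)
    null <- numeric(n_perm)
    for (b in seq_len(n_perm)) {
      Xp <- mm$X
      Xp[, cols] <- mm$X[sample.int(n), cols, drop = FALSE]
      null[b] <- .term_norm(Xp, counts, cols, family)
    }
    p[t] <- (1 + sum(null >= obs)) / (n_perm + 1)
  }
  p
}

#' Pseudo-R2 screen of SG count variables
#'
#' Per species, the pseudo-R2 is one minus the ratio of residual to null
#' deviance. The null reference is the median pseudo-R2 over refits with
#' the sample-to-design assignment permuted; a species is retained when
#' its observed pseudo-R2 exceeds the reference. With
#' \code{null = "intercept"} the screen instead retains species whose
#' pseudo-R2 is positive.
#'
#' @inheritParams permutation_validation
#' @param null \code{"permutation"} (default) or \code{"intercept"}.
#' @return List with \code{pseudo_r2}, \code{null_reference} and
#'   \code{retained} (logical per species).
#' @export
pseudo_r2_screen <- function(counts, metadata, terms, n_perm = 99,
                             seed = 1L, family = stats::poisson(),
                             null = c("permutation", "intercept")) {
  null <- match.arg(null)
  counts <- as.matrix(counts)
  mm <- .asca_model_matrix(metadata, terms)
  r2 <- function(X, y) {
    fit <- suppressWarnings(stats::glm.fit(X, y, family = family))
    if (fit$null.deviance <= 0) return(0)
    1 - fit$deviance / fit$null.deviance
  }
  obs <- apply(counts, 2, function(y) r2(mm$X, y))
  if (null == "intercept") {
    ref <- stats::setNames(rep(0, ncol(counts)), colnames(counts))
  } else {
    set.seed(seed)
    null_mat <- matrix(NA_real_, n_perm, ncol(counts))
    for (b in seq_len(n_perm)) {
      idx <- sample.int(nrow(counts))
      null_mat[b, ] <- apply(counts[idx, , drop = FALSE], 2,
                             function(y) r2(mm$X, y))
    }
    ref <- apply(null_mat, 2, stats::median)
    names(ref) <- colnames(counts)
  }
  list(pseudo_r2 = obs, null_reference = ref, retained = obs > ref)
}

#' GLM-ASCA of an SG count matrix
#'
#' The full chain: optional pseudo-R2 screen, per-species Poisson GLM
#' fits, term-wise effect-matrix decomposition and permutation validation.
#'
#' @inheritParams permutation_validation
#' @param screen Apply [pseudo_r2_screen()] before decomposition.
#' @param n_perm_screen Permutations for the screen.
#' @return A \code{glm_asca} object (see [decompose_effects()]) with
#'   attributes \code{p_values} and \code{screen}.
#' @export
asca <- function(counts, metadata, terms, family = stats::poisson(),
                 n_perm = 999, seed = 1L, screen = TRUE,
                 n_perm_screen = 99) {
  counts <- as.matrix(counts)
  scr <- NULL
  kept <- rep(TRUE, ncol(counts))
  if (screen) {
    scr <- pseudo_r2_screen(counts, metadata, terms, n_perm = n_perm_screen,
                            seed = seed, family = family)
    kept <- scr$retained
    if (!any(kept)) {
      warning("pseudo-R2 screen retained no species; decomposing all")
      kept <- rep(TRUE, ncol(counts))
    }
  }
  fits <- fit_poisson_glms(counts[, kept, drop = FALSE], metadata, terms,
                           family = family)
  dec <- decompose_effects(fits)
  attr(dec, "p_values") <- permutation_validation(
    counts[, kept, drop = FALSE], metadata, terms, n_perm = n_perm,
    seed = seed, family = family)
  attr(dec, "screen") <- scr
  dec
}

#' @export
summary.glm_asca <- function(object, ...) {
  tab <- data.frame(
    term = names(object$terms),
    n_lv = vapply(object$terms, function(t) length(t$expvar), integer(1)),
    lv1_expvar = vapply(object$terms, function(t)
      if (length(t$expvar)) t$expvar[1] else NA_real_, numeric(1)),
    effect_ss = vapply(object$terms, function(t) sum(t$effects^2),
                       numeric(1)))
  p <- attr(object, "p_values")
  if (!is.null(p)) tab$p_value <- unname(p[tab$term])
  rownames(tab) <- NULL
  tab
}
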