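# Count-based qPCR expression modelling: efficiency estimation, Cq-to-count
# transform, hierarchical Poisson log-linear model with reference-gene soft
# normalization, and FDR-adjusted pairwise contrasts.

#' Amplification efficiency from a dilution series
#'
#' Least-squares regression of Cq on log10 relative template amount
#' (1 / dilution factor); the slope b gives \code{E = 10^(-1/b)}. A perfect
#' doubling series has slope -3.3219 and E = 2. The estimate is clipped to
#' (1, 2.2] and a warning is issued outside the plausible range (1.6, 2.1)
#' or when the series is not monotone in dilution.
#'
#' @param dilution Fold-dilution factors (1 = undiluted); at least 3
#'   distinct values.
#' @param cq Observed quantification cycles (same length).
#' @return Estimated efficiency E (per-cycle amplification factor).
#' @examples
#' efficiency_from_dilution(c(1, 10, 100, 1000),
#'                          20 + log2(c(1, 10, 100, 1000)))
#' @export
efficiency_from_dilution <- function(dilution, cq) {
  stopifnot(length(dilution) == length(cq))
  if (length(unique(dilution)) < 3) {
    stop("need at least 3 distinct dilutions")
  }
  mean_cq <- tapply(cq, dilution, mean)
  d_sorted <- sort(unique(dilution))
  if (any(diff(mean_cq[as.character(d_sorted)]) < -0.5)) {
    warning("dilution series not monotone beyond noise tolerance")
  }
  b <- unname(stats::coef(stats::lm(cq ~ log10(1 / dilution)))[2])
  E <- 10^(-1 / b)
  if (!is.finite(E) || E <= 1) {
    warning("implausible slope; efficiency clipped to just above 1")
    E <- 1 + 1e-6
  }
  if (E > 2.2) {
    warning("efficiency ", round(E, 3), " clipped to 2.2")
    E <- 2.2
  } else if (E < 1.6 || E > 2.1) {
    warning("efficiency ", round(E, 3), " outside the plausible range (1.6, 2.1)")
  }
  E
}

#' Transform quantification cycles to molecule counts
#'
#' \code{count = round(E^(cq1 - Cq))} with a single-molecule baseline cycle
#' \code{cq1}; not-detected (\code{NA}) wells yield 0.
#'
#' @param cq Numeric Cq values (\code{NA} = not detected).
#' @param E Amplification efficiency (> 1), scalar or per-value.
#' @param cq1 Single-molecule baseline cycle (count 1 at \code{Cq = cq1}).
#' @return Integer counts (>= 0).
#' @examples
#' cq_to_counts(27, E = 2, cq1 = 37)  # 1024
#' @export
cq_to_counts <- function(cq, E, cq1 = 37) {
  stopifnot(all(E > 1))
  out <- round(E^(cq1 - cq))
  out[is.na(cq)] <- 0
  pmax(as.integer(out), 0L)
}

#' Apply the Cq-to-count transform to a well table
#'
#' @param wells data.frame with columns \code{gene}, \code{sample},
#'   \code{replicate}, \code{cq} (\code{NA} or \code{"ND"} = not detected).
#' @param efficiencies Named per-gene efficiencies; genes absent from the
#'   vector fall back to \code{default_efficiency}.
#' @param cq1 Single-molecule baseline cycle.
#' @param default_efficiency Assumed efficiency for genes without a
#'   dilution series (2 = perfect doubling, the convention for reference
#'   genes).
#' @return The well table with a \code{count} column.
#' @export
wells_to_counts <- function(wells, efficiencies, cq1 = 37,
                            default_efficiency = 2) {
  cq <- wells$cq
  if (is.character(cq)) cq <- suppressWarnings(as.numeric(cq))
  E <- efficiencies[wells$gene]
  E[is.na(E)] <- default_efficiency
  wells$count <- cq_to_counts(cq, unname(E), cq1)
  wells
}

# ---- hierarchical Poisson model (penalized ML with Laplace intervals) ----

.qpcr_design <- function(data, condition_cols, mode, reference_genes,
                         sample_sigma2, genotype_sigma2, ref_sigma2) {
  gene <- factor(data$gene)
  cond <- factor(do.call(paste, c(data[condition_cols], list(sep = "."))))
  sample_f <- factor(data$sample)
  has_geno <- "genotype" %in% names(data) && genotype_sigma2 > 0
  base_level <- levels(cond)[1]

  Xg <- stats::model.matrix(~ 0 + gene)
  colnames(Xg) <- paste0("gene:", levels(gene))
  blocks <- list(Xg)
  penal <- list(rep(0, ncol(Xg)))

  # gene x condition effects, baseline condition absorbed in gene intercept
  gc_cols <- character(0); gc_pen <- numeric(0)
  Xgc <- NULL
  for (g in levels(gene)) for (cl in levels(cond)[-1]) {
    col <- as.numeric(gene == g & cond == cl)
    Xgc <- cbind(Xgc, col)
    gc_cols <- c(gc_cols, paste0("fx:", g, ":", cl))
    gc_pen <- c(gc_pen,
                if (mode == "soft" && g %in% reference_genes)
                  1 / ref_sigma2 else 0)
  }
  colnames(Xgc) <- gc_cols
  blocks <- c(blocks, list(Xgc)); penal <- c(penal, list(gc_pen))

  if (sample_sigma2 > 0) {
    Xs <- stats::model.matrix(~ 0 + sample_f)
    colnames(Xs) <- paste0("sample:", levels(sample_f))
    blocks <- c(blocks, list(Xs))
    penal <- c(penal, list(rep(1 / sample_sigma2, ncol(Xs))))
  }
  if (has_geno) {
    geno <- factor(data$genotype)
    Xv <- stats::model.matrix(~ 0 + geno)
    colnames(Xv) <- paste0("genotype:", levels(geno))
    blocks <- c(blocks, list(Xv))
    penal <- c(penal, list(rep(1 / genotype_sigma2, ncol(Xv))))
  }
  X <- do.call(cbind, blocks)
  list(X = X, penalty = unlist(penal), gene_levels = levels(gene),
       cond_levels = levels(cond), base_level = base_level)
}

.penalized_poisson <- function(X, y, penalty, max_iter = 50, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  gene_cols <- grepl("^gene:", colnames(X))
  beta[gene_cols] <- log(mean(y) + 0.5)
  P <- diag(penalty, ncol(X))
  dev_old <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    eta <- pmin(pmax(eta, -30), 30)
    mu <- exp(eta)
    W <- mu
    z <- eta + (y - mu) / mu
    A <- crossprod(X, X * W) + P
    beta <- drop(solve(A, crossprod(X, W * z)))
    dev <- -2 * sum(stats::dpois(y, exp(pmin(drop(X %*% beta), 30)),
                                 log = TRUE)) + sum(penalty * beta^2)
    if (is.finite(dev_old) && abs(dev_old - dev) < tol * (abs(dev) + 1)) {
      converged <- TRUE
      break
    }
    dev_old <- dev
  }
  eta <- pmin(pmax(drop(X %*% beta), -30), 30)
  A <- crossprod(X, X * exp(eta)) + diag(penalty, ncol(X))
  list(beta = stats::setNames(beta, colnames(X)), vcov = solve(A),
       converged = converged, deviance = dev_old)
}

#' Fit the count-based qPCR expression model
#'
#' Hierarchical log-linear Poisson model for transcript counts: fixed
#' gene and gene-by-condition effects, with sample and genotype effects
#' absorbed as ridge-penalized (Gaussian random) terms so that per-sample
#' loading differences do not masquerade as expression. In \code{"soft"}
#' mode the reference genes' condition effects carry a tight penalty
#' (prior variance \code{ref_sigma2}), which pulls sample effects toward
#' values that hold the references stable across conditions; \code{"naive"}
#' mode leaves all condition effects free. Estimation is penalized maximum
#' likelihood with Laplace (inverse penalized Fisher information)
#' intervals; a random-walk MCMC refinement is optional. Technical
#' replicates enter as repeated count observations, without averaging.
#'
#' @param counts Long data.frame with \code{gene}, \code{sample},
#'   \code{count} (one row per technical replicate), e.g. from
#'   [wells_to_counts()].
#' @param metadata Sample metadata with \code{sample}, the condition
#'   columns and optionally \code{genotype}.
#' @param mode \code{"soft"} or \code{"naive"}.
#' @param reference_genes Reference genes (required in soft mode).
#' @param condition Metadata columns defining the expression groups.
#' @param sample_sigma2,genotype_sigma2 Prior variances of the sample and
#'   genotype effects (log scale); 0 removes the term.
#' @param ref_sigma2 Prior variance of reference-gene condition effects in
#'   soft mode (small = stable references).
#' @param mcmc \code{NULL}, or a list with \code{iterations},
#'   \code{thin}, \code{burnin} to refine estimates by random-walk
#'   Metropolis around the Laplace fit.
#' @return Object of class \code{sg_expression}: coefficient vector,
#'   covariance, per-gene-by-condition log2 abundances with 95 percent
#'   intervals, convergence flag and (if run) MCMC diagnostics.
#' @export
fit_expression_model <- function(counts, metadata, mode = c("soft", "naive"),
                                 reference_genes = character(0),
                                 condition = c("chemotype", "organ"),
                                 sample_sigma2 = 0.0625,
                                 genotype_sigma2 = 0.0225,
                                 ref_sigma2 = 0.01, mcmc = NULL) {
  mode <- match.arg(mode)
  if (mode == "soft" && length(reference_genes) == 0) {
    stop("soft mode requires at least one reference gene")
  }
  data <- merge(counts, metadata, by = "sample", sort = FALSE)
  all_zero <- tapply(data$count, data$gene, function(x) all(x == 0))
  if (any(all_zero)) {
    warning("excluding all-zero genes: ",
            paste(names(all_zero)[all_zero], collapse = ", "))
    data <- data[!(data$gene %in% names(all_zero)[all_zero]), , drop = FALSE]
  }
  des <- .qpcr_design(data, condition, mode, reference_genes,
                      sample_sigma2, genotype_sigma2, ref_sigma2)
  fit <- .penalized_poisson(des$X, data$count, des$penalty)
  if (!fit$converged) warning("penalized IRLS did not converge")

  mcmc_out <- NULL
  if (!is.null(mcmc)) {
    mcmc_out <- .qpcr_mcmc(des$X, data$count, des$penalty, fit,
                           iterations = mcmc$iterations %||% 11000,
                           thin = mcmc$thin %||% 10,
                           burnin = mcmc$burnin %||% 1000)
    fit$beta <- mcmc_out$posterior_mean
    fit$vcov <- mcmc_out$posterior_vcov
  }

  # group abundances on the log2 scale with Laplace intervals
  grid <- expand.grid(gene = des$gene_levels, condition = des$cond_levels,
                      stringsAsFactors = FALSE)
  est <- t(apply(grid, 1, function(row) {
    v <- rep(0, length(fit$beta))
    names(v) <- names(fit$beta)
    v[paste0("gene:", row[["gene"]])] <- 1
    fx <- paste0("fx:", row[["gene"]], ":", row[["condition"]])
    if (fx %in% names(v)) v[fx] <- 1
    mu <- sum(v * fit$beta)
    se <- sqrt(drop(t(v) %*% fit$vcov %*% v))
    c(log2 = mu / log(2), se_log2 = se / log(2),
      lwr = (mu - 1.96 * se) / log(2), upr = (mu + 1.96 * se) / log(2))
  }))
  abundances <- cbind(grid, as.data.frame(est))
  structure(list(beta = fit$beta, vcov = fit$vcov, mode = mode,
                 reference_genes = reference_genes,
                 condition_cols = condition,
                 gene_levels = des$gene_levels,
                 cond_levels = des$cond_levels,
                 base_level = des$base_level,
                 abundances = abundances, converged = fit$converged,
                 mcmc = mcmc_out),
            class = "sg_expression")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random-walk Metropolis around the Laplace mode; proposal scaled by the
# Laplace covariance Cholesky factor
.qpcr_mcmc <- function(X, y, penalty, fit, iterations, thin, burnin) {
  logpost <- function(beta) {
    eta <- pmin(pmax(drop(X %*% beta), -30), 30)
    sum(stats::dpois(y, exp(eta), log = TRUE)) - 0.5 * sum(penalty * beta^2)
  }
  p <- length(fit$beta)
  L <- t(chol(fit$vcov + diag(1e-10, p)))
  scale <- 2.38 / sqrt(p)
  beta <- fit$beta
  lp <- logpost(beta)
  keep <- floor((iterations - burnin) / thin)
  draws <- matrix(NA_real_, keep, p, dimnames = list(NULL, names(fit$beta)))
  k <- 0L; acc <- 0L
  for (it in seq_len(iterations)) {
    prop <- beta + scale * drop(L %*% stats::rnorm(p))
    lp_prop <- logpost(prop)
    if (log(stats::runif(1)) < lp_prop - lp) {
      beta <- prop; lp <- lp_prop; acc <- acc + 1L
    }
    if (it > burnin && (it - burnin) %% thin == 0 && k < keep) {
      k <- k + 1L
      draws[k, ] <- beta
    }
  }
  draws <- draws[seq_len(k), , drop = FALSE]
  ess <- apply(draws, 2, .effective_size)
  list(draws = draws, acceptance = acc / iterations,
       posterior_mean = colMeans(draws), posterior_vcov = stats::cov(draws),
       effective_size = ess)
}

# initial-positive-sequence estimator of effective sample size
.effective_size <- function(x) {
  n <- length(x)
  if (n < 10 || stats::sd(x) == 0) return(n)
  rho <- stats::acf(x, lag.max = min(n - 1, 100), plot = FALSE)$acf[-1]
  s <- 0
  for (r in rho) {
    if (r < 0.05) break
    s <- s + r
  }
  n / (1 + 2 * s)
}

#' @export
print.sg_expression <- function(x, ...) {
  cat("qPCR expression model (", x$mode, " mode), ",
      length(x$gene_levels), " genes x ", length(x$cond_levels),
      " conditions\n", sep = "")
  if (x$mode == "soft") {
    cat("reference genes:", paste(x$reference_genes, collapse = ", "), "\n")
  }
  print(utils::head(x$abundances, 8))
  if (nrow(x$abundances) > 8) cat("...\n")
  invisible(x)
}

#' Pairwise expression contrasts between condition groups
#'
#' All pairwise group differences per gene on the log2 scale; two-sided
#' p-values from the normal sampling distribution of the difference, with
#' Benjamini-Hochberg false-discovery-rate adjustment across the whole
#' table.
#'
#' @param model An \code{sg_expression} fit.
#' @param fdr_method Adjustment method, see [stats::p.adjust()].
#' @return data.frame with \code{gene}, \code{group1}, \code{group2},
#'   \code{diff_log2}, \code{se}, \code{p}, \code{p_adj}.
#' @export
pairwise_contrasts <- function(model, fdr_method = "BH") {
  stopifnot(inherits(model, "sg_expression"))
  levs <- model$cond_levels
  rows <- list()
  for (g in model$gene_levels) {
    for (i in seq_along(levs)) for (j in seq_along(levs)) {
      if (j <= i) next
      v <- rep(0, length(model$beta))
      names(v) <- names(model$beta)
      f1 <- paste0("fx:", g, ":", levs[i])
      f2 <- paste0("fx:", g, ":", levs[j])
      if (f1 %in% names(v)) v[f1] <- 1
      if (f2 %in% names(v)) v[f2] <- -1
      diff <- sum(v * model$beta) / log(2)
      se <- sqrt(drop(t(v) %*% model$vcov %*% v)) / log(2)
      z <- if (se > 0) diff / se else 0
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, group1 = levs[i], group2 = levs[j],
        diff_log2 = diff, se = se, p = 2 * stats::pnorm(-abs(z)),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = fdr_method)
  rownames(out) <- NULL
  out
}
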