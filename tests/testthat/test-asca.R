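# GLM-ASCA: fits, effect-matrix decomposition, permutation validation and
# the pseudo-R2 screen.

balanced_2x2 <- function(reps = 3, seed = 21) {
  set.seed(seed)
  meta <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2"))
  meta <- meta[rep(seq_len(4), each = reps), ]
  rownames(meta) <- NULL
  y <- matrix(rpois(nrow(meta) * 4, 20), nrow(meta), 4,
              dimnames = list(NULL, paste0("sp", 1:4)))
  list(meta = meta, y = y)
}

test_that("constant counts give intercept-only fits with null slopes", {
  meta <- data.frame(organ = rep(c("leaf", "root"), each = 6))
  y <- matrix(7, 12, 2, dimnames = list(NULL, c("sp1", "sp2")))
  f <- fit_poisson_glms(y, meta, "organ")
  expect_true(all(f$converged))
  expect_equal(unname(f$coef[1, ]), rep(log(7), 2), tolerance = 1e-8)
  expect_equal(unname(f$coef[2, ]), c(0, 0), tolerance = 1e-8)
})

test_that("a planted two-fold organ effect is recovered on the log scale", {
  set.seed(31)
  meta <- data.frame(organ = rep(c("leaf", "root"), each = 60))
  y <- cbind(sp1 = rpois(120, ifelse(meta$organ == "leaf", 80, 40)))
  f <- fit_poisson_glms(y, meta, "organ")
  # sum-to-zero coding: the coefficient is half the log fold-change
  expect_equal(unname(abs(f$coef[2, 1])), log(2) / 2, tolerance = 0.1)
})

test_that("separable all-zero groups are flagged, not fatal", {
  set.seed(19)
  meta <- data.frame(organ = rep(c("leaf", "root"), each = 6))
  y <- cbind(sp1 = c(rep(0L, 6), rpois(6, 20)),
             sp2 = rpois(12, 5))
  expect_message(f <- fit_poisson_glms(y, meta, "organ"),
                 "boundary.*sp1")
  expect_true(f$boundary[1])
  expect_false(f$boundary[2])
  # boundary fits are flagged but retained: the structurally zero cell is
  # real signal (chemotype-defining species are exactly of this kind)
  expect_true(all(f$converged))
  dec <- decompose_effects(f)
  expect_equal(dec$species, c("sp1", "sp2"))
})

test_that("Gaussian identity decomposition equals classical group-mean ASCA", {
  d <- balanced_2x2()
  f <- fit_poisson_glms(d$y, d$meta, c("A", "B", "A:B"),
                        family = stats::gaussian())
  dec <- decompose_effects(f)
  grand <- colMeans(d$y)
  a_means <- apply(d$y, 2, function(v) tapply(v, d$meta$A, mean))
  b_means <- apply(d$y, 2, function(v) tapply(v, d$meta$B, mean))
  ab_means <- apply(d$y, 2, function(v)
    tapply(v, interaction(d$meta$A, d$meta$B), mean))
  EA <- a_means[as.character(d$meta$A), ] -
    matrix(grand, nrow(d$y), 4, byrow = TRUE)
  EB <- b_means[as.character(d$meta$B), ] -
    matrix(grand, nrow(d$y), 4, byrow = TRUE)
  EAB <- ab_means[as.character(interaction(d$meta$A, d$meta$B)), ] -
    matrix(grand, nrow(d$y), 4, byrow = TRUE) - EA - EB
  expect_equal(unname(dec$terms[["A"]]$effects), unname(EA))
  expect_equal(unname(dec$terms[["B"]]$effects), unname(EB))
  expect_equal(unname(dec$terms[["A:B"]]$effects), unname(EAB))
})

test_that("decomposition identities hold: additivity, orthogonality, variance", {
  d <- balanced_2x2(seed = 22)
  f <- fit_poisson_glms(d$y, d$meta, c("A", "B", "A:B"))
  dec <- decompose_effects(f)
  # intercept + term contributions + residual reproduce the linear predictor
  recon <- dec$intercept + dec$residual
  for (t in names(dec$terms)) {
    E <- f$X[, f$assign == match(t, f$term_labels), drop = FALSE] %*%
      f$coef[f$assign == match(t, f$term_labels), , drop = FALSE]
    recon <- recon + E
  }
  expect_equal(recon, dec$eta)
  for (t in names(dec$terms)) {
    term <- dec$terms[[t]]
    if (length(term$expvar) == 0) next
    expect_equal(sum(term$expvar), 100)
    expect_true(all(diff(term$expvar) <= 1e-8))
    if (ncol(term$scores) > 1) {
      cp <- crossprod(term$scores)
      expect_lt(max(abs(cp[upper.tri(cp)])), 1e-8 * max(diag(cp)))
    }
  }
})

test_that("a single-species binary effect loads on one latent variable", {
  meta <- data.frame(g = rep(c("x", "y"), each = 6))
  y <- cbind(hit = rep(c(40L, 10L), each = 6),
             flat = rep(20L, 12))
  f <- fit_poisson_glms(y, meta, "g")
  dec <- decompose_effects(f)
  term <- dec$terms[["g"]]
  expect_equal(term$expvar[1], 100)
  expect_gt(abs(term$loadings["hit", 1]), 0.99)
  expect_lt(abs(term$loadings["flat", 1]), 0.1)
})

test_that("permutation validation flags strong effects and checks n_perm", {
  set.seed(41)
  meta <- data.frame(g = rep(c("x", "y"), each = 8))
  y <- cbind(sp1 = rpois(16, ifelse(meta$g == "x", 60, 15)),
             sp2 = rpois(16, 10))
  p <- permutation_validation(y, meta, "g", n_perm = 199, seed = 5)
  expect_equal(unname(p["g"]), 1 / 200)
  expect_true(all(p > 0 & p <= 1))
  expect_error(permutation_validation(y, meta, "g", n_perm = 50), "n_perm")
  expect_silent(permutation_validation(y, meta, "g", n_perm = 99, seed = 1))
})

test_that("pseudo-R2 screen separates structured from flat species", {
  set.seed(51)
  meta <- data.frame(g = rep(c("x", "y"), each = 10))
  keep_effect <- logical(20); keep_null <- logical(20)
  for (i in 1:20) {
    y <- cbind(effect = rpois(20, ifelse(meta$g == "x", 60, 15)),
               null = rpois(20, 20))
    scr <- pseudo_r2_screen(y, meta, "g", n_perm = 49, seed = i)
    keep_effect[i] <- scr$retained["effect"]
    keep_null[i] <- scr$retained["null"]
  }
  expect_true(all(keep_effect))
  # a null species beats the permutation median only about half the time
  expect_lt(mean(keep_null), 0.9)
  # intercept-null variant retains positive pseudo-R2 species
  y <- cbind(effect = rpois(20, ifelse(meta$g == "x", 60, 15)))
  scr2 <- pseudo_r2_screen(y, meta, "g", null = "intercept")
  expect_true(scr2$retained["effect"])
})

test_that("an all-flat count matrix degrades gracefully in asca()", {
  meta <- data.frame(g = rep(c("x", "y"), each = 6))
  y <- matrix(5L, 12, 3, dimnames = list(NULL, paste0("sp", 1:3)))
  expect_warning(res <- asca(y, meta, "g", n_perm = 99, seed = 2),
                 "retained no species")
  expect_s3_class(res, "glm_asca")
  s <- summary(res)
  expect_true(all(c("term", "p_value") %in% names(s)))
})
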