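# Monoisotopic residue masses, RDBE, formula assignment, fragment ladders
# and glycan decomposition.

test_that("residue table is internally consistent and matches printed masses", {
  tab <- default_residue_table()
  expect_true(all(tab$mass > 0))
  recomputed <- vapply(tab$composition, formula_mass, numeric(1))
  expect_true(all(abs(recomputed - tab$mass) < 1e-4))

  expect_equal(residue_mass("hexose"), 162.0528, tolerance = 1e-4)
  # printed neutral-loss values: deoxyhexose 146.05, malonylhexoside 248.05
  expect_lt(abs(residue_mass("deoxyhexose") - 146.05), 0.01)
  expect_lt(abs(residue_mass("malonylhexoside") - 248.05), 0.01)
  expect_equal(residue_mass("Hex"), residue_mass("hexose"))
  expect_error(residue_mass("nonsense"), "unknown residue")
})

test_that("rdbe follows C - H/2 + N/2 + 1", {
  expect_equal(rdbe("C27H45NO2"), 6)   # soladulcidine
  expect_equal(rdbe("CH4"), 0)
  expect_equal(rdbe("C27H47NO3"), 5)
  # integer-valued for even-electron CHNO formulas with even H + N parity
  set.seed(1)
  for (i in 1:50) {
    C <- sample(1:40, 1); N <- sample(0:2, 1)
    H <- 2 * sample(1:25, 1) - N    # even H + N
    if (H < 0) next
    v <- rdbe(c(C = C, H = H, N = N, O = sample(0:8, 1)))
    expect_equal(v, round(v))
  }
})

test_that("assign_formula finds the printed aglycone formulas", {
  a <- assign_formula(433.3556, tolerance = 0.005)
  expect_true(a$found)
  expect_equal(unname(a$formula), c(27, 47, 1, 3))
  expect_equal(a$rdbe, 5)

  w <- assign_formula(18.0106, tolerance = 0.001,
                      bounds = list(C = c(0, 2), H = c(0, 4), N = c(0, 0),
                                    O = c(0, 2)))
  expect_equal(unname(w$formula), c(0, 2, 0, 1))

  # neutral of protonated 412.32: unsaturated aglycone with RDBE 8
  a8 <- assign_formula(412.32 - proton_mass(), tolerance = 0.01)
  expect_equal(unname(a8$formula), c(27, 41, 1, 2))
  expect_equal(a8$rdbe, 8)

  none <- assign_formula(433.3556, tolerance = 1e-7)
  expect_false(none$found)
  expect_s3_class(none, "formula_assignment")
})

test_that("assign_formula agrees with an independent brute-force oracle", {
  em <- c(C = 12, H = 1.00782503207, N = 14.0030740048, O = 15.9949146196)
  oracle <- function(m, tol) {
    g <- expand.grid(C = 20:35, H = 10:60, N = 0:1, O = 0:6)
    g$mass <- g$C * em["C"] + g$H * em["H"] + g$N * em["N"] + g$O * em["O"]
    g$err <- abs(g$mass - m)
    g$rdbe <- g$C - g$H / 2 + g$N / 2 + 1
    g <- g[g$err <= tol & (g$H + g$N) %% 2 == 0 & g$rdbe >= 0, ]
    if (nrow(g) == 0) return(NULL)
    g <- g[order(g$err, abs(g$rdbe - 7), g$C, g$H, g$N, g$O), ]
    as.integer(g[1, c("C", "H", "N", "O")])
  }
  set.seed(7)
  n_checked <- 0
  while (n_checked < 100) {
    f <- c(C = sample(20:35, 1), H = sample(10:60, 1), N = sample(0:1, 1),
           O = sample(0:6, 1))
    m <- formula_mass(f) + stats::runif(1, -0.004, 0.004)
    expected <- oracle(m, 0.005)
    got <- assign_formula(m, tolerance = 0.005)
    if (is.null(expected)) {
      expect_false(got$found)
    } else {
      expect_equal(unname(got$formula), expected)
    }
    n_checked <- n_checked + 1
  }
})

test_that("fragment ladders reproduce the printed in-source series", {
  # triose with molecular ion 886.52: printed fragments 724.46, 578.40, 416.35
  l <- predict_fragment_ladder(886.52, c("Hex", "dHex", "Hex"))
  expect_true(all(abs(l$ions - c(886.52, 724.46, 578.40, 416.35)) < 0.02))
  expect_true(all(diff(l$ions) < 0))

  # root-only malonylated glycoalkaloid, molecular ion 954.51
  l4 <- predict_fragment_ladder(954.51, c("dHex", "dHex", "malonylhexoside"))
  expect_lt(abs(l4$aglycone - 414.34), 0.02)

  expect_error(predict_fragment_ladder(500, character(0)), "non-empty")
  expect_equal(predict_fragment_ladder(500, "H2O")$aglycone, 500 - 18.0106,
               tolerance = 1e-4)
  expect_error(predict_fragment_ladder(100, c("Hex", "Hex")), "<= 0")
})

test_that("glycan decomposition recovers printed chain compositions", {
  # saponin pentoside: molecular 1195.5662, aglycone 415.3126 -> Hex4 Pen1
  d <- decompose_glycan(1195.5662, 415.3126, tolerance = 0.02)
  expect_gt(nrow(d), 0)
  expect_equal(as.integer(d[1, 1:5]), c(4L, 0L, 1L, 0L, 0L))

  # tetraoside: molecular 1034.55, aglycone 416.35 -> Hex3 Pen1
  d2 <- decompose_glycan(1034.55, 416.35, tolerance = 0.02)
  expect_equal(as.integer(d2[1, 1:5]), c(3L, 0L, 1L, 0L, 0L))

  # single-residue case
  d3 <- decompose_glycan(578.40, 416.35, tolerance = 0.02)
  expect_equal(as.integer(d3[1, 1:5]), c(1L, 0L, 0L, 0L, 0L))

  expect_equal(nrow(decompose_glycan(1000, 416.35, tolerance = 1e-6)), 0)
  expect_error(decompose_glycan(400, 416.35))
})

test_that("ladder prediction and decomposition are mutually consistent", {
  residues <- c("hexose", "deoxyhexose", "pentose")
  set.seed(11)
  for (i in 1:25) {
    chain <- sample(residues, sample(1:5, 1), replace = TRUE)
    # malonylhexoside allowed once, terminally
    if (stats::runif(1) < 0.3) chain <- c(chain, "malonylhexoside")
    mol <- stats::runif(1, 800, 1300)
    lad <- predict_fragment_ladder(mol, chain)
    dec <- decompose_glycan(mol, lad$aglycone, tolerance = 0.001)
    expect_gt(nrow(dec), 0)
    got <- dec[1, c("hexose", "deoxyhexose", "pentose", "malonylhexoside")]
    expect_equal(as.integer(got),
                 as.integer(table(factor(chain,
                   levels = c("hexose", "deoxyhexose", "pentose",
                              "malonylhexoside")))))
  }
})
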