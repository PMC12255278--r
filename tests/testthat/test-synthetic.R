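# The synthetic-data generator: library structure, determinism, noise model
# and the qPCR count generator.

test_that("compound library covers all 12 SA species and the worked compounds", {
  lib <- build_compound_library()
  expect_length(lib$compounds, 17)
  expect_setequal(round(unique(lib$species), 2), sa_species_table()$mz)

  mol <- vapply(lib$compounds, `[[`, numeric(1), "molecular_mz")
  # saturated leaf tetraoside at 1034.55 and saponin pentoside at 1195.5662
  expect_true(any(abs(mol - 1034.55) < 0.02))
  expect_true(any(abs(mol - 1195.5662) < 0.001))

  # root-only malonylated glycoalkaloid: molecular ion 954.51, absent
  # outside roots
  iv <- lib$compounds[[which(abs(mol - 954.51) < 0.001)]]
  expect_true(all(iv$mult[, c("leaf", "stem"), ] == 0))
  expect_true(all(iv$mult[, "root", "vegetative"] > 0))

  # chemotype rule: unsaturated analogues are 2.016 Da lighter
  expect_equal(lib$compounds$soladulcine_B_sat$aglycone_mz -
                 lib$compounds$soladulcine_B_unsat$aglycone_mz,
               residue_mass("saturation"), tolerance = 1e-6)
  # U-chemotype leaves carry the unsaturated, not the saturated, analogue
  expect_equal(unname(lib$compounds$soladulcine_B_sat$mult["U", "leaf", ]),
               c(0, 0))
  expect_gt(lib$compounds$soladulcine_B_unsat$mult["U", "leaf", "vegetative"], 0)
  # roots of both chemotypes share the unsaturated compound
  expect_true(all(lib$compounds$soladulcine_A_unsat$mult[, "root", ] > 0))
})

test_that("sample sheet has stems only on flowering plants", {
  meta <- design_samples(sg_design())
  expect_equal(sum(meta$organ == "stem" & meta$ontogeny == "vegetative"), 0)
  expect_equal(nrow(meta), 7 * 5)   # 7 genotypes x (2 + 3) organ-stages
  expect_equal(anyDuplicated(meta$sample), 0)
})

test_that("fixed seed makes every emitted artifact identical", {
  d <- sg_design(seed = 99)
  lib <- build_compound_library(d)
  s1 <- simulate_spectra(lib, d)
  s2 <- simulate_spectra(lib, d)
  expect_identical(s1, s2)
  f1 <- simulate_feature_table(lib, d)
  f2 <- simulate_feature_table(lib, d)
  expect_identical(f1, f2)
  q1 <- simulate_qpcr_dataset(d)
  q2 <- simulate_qpcr_dataset(d)
  expect_identical(q1, q2)
})

test_that("zero-noise intensities equal group means exactly", {
  zn <- fixture_zero_noise()
  ft <- zn$features
  sample_cols <- setdiff(names(ft$features), c("feature_id", "mz", "rt"))
  planted <- ft$features$feature_id %in% ft$truth$feature_map$feature_id
  got <- as.matrix(ft$features[planted, sample_cols])
  dimnames(got) <- dimnames(ft$truth$mean_intensity)
  expect_equal(got, ft$truth$mean_intensity)
})

test_that("ladder ions appear in scans and absent groups emit no scans", {
  zn <- fixture_zero_noise()
  # saponin pentoside scan contains the full printed ladder incl. 739.42
  v_scans <- Filter(function(s) grepl("ssg_pentoside_unsat", s$scan_id),
                    zn$spectra$spectra)
  expect_gt(length(v_scans), 0)
  sc <- v_scans[[1]]
  for (target in c(1195.5662, 739.4221, 415.3126)) {
    expect_true(any(abs(sc$mz - target) < 0.02))
  }
  # zero-multiplier groups emit nothing: saturated tetraoside in U leaves
  u_leaf <- zn$spectra$metadata$sample[
    zn$spectra$metadata$chemotype == "U" &
      zn$spectra$metadata$organ == "leaf"]
  bad <- Filter(function(s) grepl("soladulcine_B_sat", s$scan_id) &&
                  s$sample %in% u_leaf, zn$spectra$spectra)
  expect_length(bad, 0)
})

test_that("S and U leaves differ exactly at chemotype-dependent features", {
  zn <- fixture_zero_noise()
  mi <- zn$features$truth$mean_intensity
  meta <- zn$features$metadata
  s_leaf <- meta$sample[meta$chemotype == "S" & meta$organ == "leaf" &
                          meta$ontogeny == "vegetative"][1]
  u_leaf <- meta$sample[meta$chemotype == "U" & meta$organ == "leaf" &
                          meta$ontogeny == "vegetative"][1]
  differs <- mi[, s_leaf] != mi[, u_leaf]
  fm <- zn$features$truth$feature_map
  lib <- zn$library
  cmp_differs <- vapply(fm$compound, function(cn) {
    m <- lib$compounds[[cn]]$mult
    m["S", "leaf", "vegetative"] != m["U", "leaf", "vegetative"]
  }, logical(1))
  expect_equal(unname(differs), unname(cmp_differs))
})

test_that("scan counts are constant when multiplier and noise are fixed", {
  zn <- fixture_zero_noise()
  sc <- zn$spectra$truth$scan_counts
  meta <- zn$spectra$metadata
  # shared compound with equal multipliers everywhere -> equal counts
  expect_equal(length(unique(sc[, "sga_rdbe5"])), 1)
  # root-only compound: zero scans outside roots
  expect_true(all(sc[meta$organ != "root", "malonyl_sga_root"] == 0))
  expect_true(all(sc[meta$organ == "root", "malonyl_sga_root"] > 0))
})

test_that("qPCR generator honours the count-to-Cq identity and the dilution law", {
  d <- zero_noise_design(seed = 5)
  q <- simulate_qpcr_dataset(d, tech_sd = 0)
  truth <- q$truth$counts
  wells <- q$wells
  one <- merge(wells[wells$replicate == 1, ], truth, by = c("gene", "sample"))
  detected <- one$count >= 1
  E <- unname(q$efficiencies[one$gene])
  expect_equal(one$cq[detected],
               (q$cq1 - log(one$count) / log(E))[detected], tolerance = 1e-10)
  expect_true(all(is.na(one$cq[!detected])))

  # noiseless dilution series recovers the generating efficiency within 0.02
  for (g in names(q$efficiencies)) {
    ser <- q$dilution[q$dilution$gene == g, ]
    cq_clean <- q$cq1 - log(1e6 / ser$dilution) / log(q$efficiencies[[g]])
    expect_lt(abs(efficiency_from_dilution(ser$dilution, cq_clean) -
                    q$efficiencies[[g]]), 0.02)
  }

  # GAME25 is near the detection limit in U leaves only
  meta <- q$metadata
  g25 <- truth[truth$gene == "GAME25", ]
  g25 <- merge(g25, meta, by = "sample")
  expect_lt(max(g25$count[g25$chemotype == "U" & g25$organ == "leaf"]), 50)
  expect_gt(min(g25$count[!(g25$chemotype == "U" & g25$organ == "leaf")]), 200)
})
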