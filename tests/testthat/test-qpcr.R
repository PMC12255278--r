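# qPCR: efficiency estimation, Cq-to-count transform and the count-based
# expression model.

test_that("efficiency estimation matches the closed form", {
  d <- c(1, 10, 100, 1000)
  # perfect doubling: slope -3.3219 on log10 template
  expect_equal(efficiency_from_dilution(d, 20 + log2(d)), 2,
               tolerance = 1e-10)
  # slope -3.5 gives E = 10^(1/3.5)
  expect_equal(suppressWarnings(
    efficiency_from_dilution(d, 20 + 3.5 * log10(d))),
    10^(1 / 3.5), tolerance = 1e-10)
  expect_error(efficiency_from_dilution(c(1, 10), c(20, 23.3)),
               "3 distinct")
  expect_warning(efficiency_from_dilution(d, 20 + 5 * log10(d)),
                 "outside the plausible range")
  expect_warning(efficiency_from_dilution(d, c(20, 19, 26.6, 30)),
                 "not monotone")
})

test_that("cq_to_counts implements the count transform with ND as zero", {
  expect_equal(cq_to_counts(27, E = 2, cq1 = 37), 1024L)
  expect_equal(cq_to_counts(37, E = 2, cq1 = 37), 1L)
  expect_equal(cq_to_counts(30, E = 1.93, cq1 = 37), 100L)
  expect_equal(cq_to_counts(NA, E = 2), 0L)
  expect_equal(cq_to_counts(60, E = 2, cq1 = 37), 0L)
  expect_error(cq_to_counts(20, E = 1))
})

test_that("count -> Cq -> count round trip is the identity up to rounding", {
  for (E in c(2, 1.93, 1.88)) {
    counts <- c(1L, 7L, 101L, 1024L, 99999L)
    cq <- 37 - log(counts) / log(E)
    expect_equal(cq_to_counts(cq, E, 37), counts)
  }
  # through the generator: noiseless wells decode to the true counts
  q <- simulate_qpcr_dataset(zero_noise_design(seed = 9), tech_sd = 0)
  wells <- wells_to_counts(q$wells[q$wells$replicate == 1, ],
                           q$efficiencies, cq1 = q$cq1)
  truth <- q$truth$counts
  m <- merge(wells, truth, by = c("gene", "sample"))
  expect_equal(m$count.x, m$count.y)
})

test_that("naive mode with no random effects reduces to log mean counts", {
  md <- data.frame(sample = paste0("s", 1:8),
                   chemotype = rep(c("S", "U"), 4),
                   organ = rep(c("leaf", "root"), each = 4),
                   stringsAsFactors = FALSE)
  set.seed(13)
  cnt <- expand.grid(gene = c("A", "B"), sample = md$sample,
                     stringsAsFactors = FALSE)
  cnt$count <- rpois(nrow(cnt), 400)
  m <- fit_expression_model(cnt, md, mode = "naive",
                            sample_sigma2 = 0, genotype_sigma2 = 0)
  joined <- merge(cnt, md, by = "sample")
  joined$cond <- paste(joined$chemotype, joined$organ, sep = ".")
  for (i in seq_len(nrow(m$abundances))) {
    row <- m$abundances[i, ]
    cell <- joined$count[joined$gene == row$gene & joined$cond == row$condition]
    expect_equal(row$log2, log2(mean(cell)), tolerance = 1e-6)
  }
})

test_that("doubling all counts shifts log2 abundances by one, contrasts fixed", {
  md <- data.frame(sample = paste0("s", 1:8),
                   chemotype = rep(c("S", "U"), 4),
                   organ = rep(c("leaf", "root"), each = 4),
                   genotype = rep(c("g1", "g2"), 4),
                   stringsAsFactors = FALSE)
  set.seed(14)
  cnt <- expand.grid(gene = c("A", "B", "REF"), sample = md$sample,
                     stringsAsFactors = FALSE)
  cnt$count <- rpois(nrow(cnt), 300)
  m1 <- fit_expression_model(cnt, md, mode = "soft",
                             reference_genes = "REF")
  cnt2 <- cnt
  cnt2$count <- cnt2$count * 2L
  m2 <- fit_expression_model(cnt2, md, mode = "soft",
                             reference_genes = "REF")
  expect_equal(m2$abundances$log2, m1$abundances$log2 + 1,
               tolerance = 0.02)
  c1 <- pairwise_contrasts(m1)
  c2 <- pairwise_contrasts(m2)
  expect_equal(c2$diff_log2, c1$diff_log2, tolerance = 0.02)
})

test_that("soft normalization keeps stable reference genes flat", {
  q <- simulate_qpcr_dataset(sg_design(seed = 17), tech_sd = 0.05)
  cnt <- wells_to_counts(q$wells, q$efficiencies, cq1 = q$cq1)
  m <- fit_expression_model(cnt, q$metadata, mode = "soft",
                            reference_genes = q$reference_genes)
  ref <- m$abundances[m$abundances$gene %in% q$reference_genes, ]
  spread <- tapply(ref$log2, ref$gene, function(x) diff(range(x)))
  expect_true(all(spread < 0.5))
  # the planted silenced gene shows up only in U leaves
  g25 <- m$abundances[m$abundances$gene == "GAME25", ]
  low <- g25$log2[g25$condition == "U.leaf"]
  rest <- g25$log2[g25$condition != "U.leaf"]
  expect_lt(low, min(rest) - 5)
})

test_that("identical groups give near-unity adjusted p-values", {
  md <- data.frame(sample = paste0("s", 1:12),
                   chemotype = rep(c("S", "U"), 6),
                   organ = rep(c("leaf", "root"), each = 6),
                   stringsAsFactors = FALSE)
  set.seed(15)
  cnt <- expand.grid(gene = c("A", "REF"), sample = md$sample,
                     stringsAsFactors = FALSE)
  cnt$count <- rpois(nrow(cnt), 500)
  m <- fit_expression_model(cnt, md, mode = "soft", reference_genes = "REF")
  ctr <- pairwise_contrasts(m)
  expect_true(all(ctr$p_adj >= ctr$p))
  expect_gt(min(ctr$p_adj[ctr$gene == "A"]), 0.1)
  # a planted ~2.9-fold difference is detected with the right sign
  cnt2 <- cnt
  boost <- md$sample[md$chemotype == "S" & md$organ == "leaf"]
  idx <- cnt2$gene == "A" & cnt2$sample %in% boost
  cnt2$count[idx] <- rpois(sum(idx), 500 * 2.9)
  m2 <- fit_expression_model(cnt2, md, mode = "soft",
                             reference_genes = "REF")
  ctr2 <- pairwise_contrasts(m2)
  hit <- ctr2[ctr2$gene == "A" & ctr2$group1 == "S.leaf" &
                ctr2$group2 == "U.leaf", ]
  expect_lt(hit$p_adj, 0.05)
  expect_gt(hit$diff_log2, 0)
})

test_that("the optional MCMC refinement runs and reports diagnostics", {
  md <- data.frame(sample = paste0("s", 1:8),
                   chemotype = rep(c("S", "U"), 4),
                   organ = rep(c("leaf", "root"), each = 4),
                   stringsAsFactors = FALSE)
  set.seed(16)
  cnt <- expand.grid(gene = c("A", "REF"), sample = md$sample,
                     stringsAsFactors = FALSE)
  cnt$count <- rpois(nrow(cnt), 200)
  m <- fit_expression_model(cnt, md, mode = "soft", reference_genes = "REF",
                            mcmc = list(iterations = 2000, thin = 5,
                                        burnin = 500))
  expect_false(is.null(m$mcmc))
  expect_true(all(is.finite(m$mcmc$effective_size)))
  expect_gt(m$mcmc$acceptance, 0.01)
  expect_equal(nrow(m$mcmc$draws), 300)
})
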