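test_that("generators are deterministic under a fixed configuration", {
  cfg <- sim_config(n_genes = 50, effect_table = default_rna_effects(4),
                    seed = 11)
  a <- simulate_rnaseq_counts(cfg)
  b <- simulate_rnaseq_counts(cfg)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$truth, b$truth)
  pa <- simulate_psm_table(cfg)
  pb <- simulate_psm_table(cfg)
  expect_identical(pa$psms, pb$psms)
  st <- data.frame(id = 1:3, father = c(0, 0, 1), mother = c(0, 0, 2))
  expect_identical(
    as.data.frame(simulate_pedigree(st, 0.1, c(0.5, 0.5), 0.2, seed = 4)),
    as.data.frame(simulate_pedigree(st, 0.1, c(0.5, 0.5), 0.2, seed = 4)))
  g <- data.frame(label = c("a", "b"), true_fold = c(1, 2), n = 3)
  expect_identical(simulate_ct_table(g, seed = 9),
                   simulate_ct_table(g, seed = 9))
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(sim_config(0), "n_genes")
  expect_error(sim_config(10, n_replicates = 1), "n_replicates")
  expect_error(sim_config(10, dispersion = 0), "dispersion")
  expect_error(sim_config(10, background_fraction = 1.2),
               "background_fraction")
  expect_error(sim_config(10, effect_table = data.frame(x = 1)),
               "effect_table")
  expect_error(
    simulate_rnaseq_counts(sim_config(
      10, effect_table = data.frame(feature_id = "nope", log2_effect = 1))),
    "effect_table")
  expect_error(
    simulate_pedigree(data.frame(id = 1:2, father = c(0, 1),
                                 mother = c(0, 0)),
                      0.1, c(0.5, 0.5), 0.1),
    "one parent")
  expect_error(simulate_ct_table(data.frame(label = "a", true_fold = 0,
                                            n = 2)),
               "true_fold")
})

test_that("counts follow the negative-binomial mean-variance relationship", {
  # flat baseline, no library jitter: every wild-type count shares one mu
  cfg <- sim_config(n_genes = 2000, baseline_sd_log = 0, dispersion = 0.1,
                    size_factor_sd = 0, seed = 21)
  sim <- simulate_rnaseq_counts(cfg)
  wt <- sim$counts$counts[, sim$counts$samples$condition == "wildtype"]
  mu <- mean(wt)
  expected_var <- mu + 0.1 * mu^2
  expect_lt(abs(mean(row_vars_test(wt)) / expected_var - 1), 0.1)
})

test_that("planted effects set the raw mutant/wild-type mean ratio", {
  # 1,000 genes all planted at -2, low dispersion: mean ratio near 0.25
  eff <- data.frame(feature_id = sprintf("gene%05d", 1:1000),
                    log2_effect = -2)
  cfg <- sim_config(n_genes = 1000, dispersion = 0.005,
                    effect_table = eff, seed = 31)
  sim <- simulate_rnaseq_counts(cfg)
  cond <- sim$counts$samples$condition
  ratio <- rowMeans(sim$counts$counts[, cond == "mutant"]) /
    rowMeans(sim$counts$counts[, cond == "wildtype"])
  expect_lt(abs(median(ratio) / 0.25 - 1), 0.1)
  # no planted effect: all tiers null, ratio near 1
  sim0 <- simulate_rnaseq_counts(sim_config(n_genes = 1000, seed = 32,
                                            dispersion = 0.005))
  expect_true(all(sim0$truth$tier == "null"))
  cond0 <- sim0$counts$samples$condition
  r0 <- rowMeans(sim0$counts$counts[, cond0 == "mutant"]) /
    rowMeans(sim0$counts$counts[, cond0 == "wildtype"])
  expect_lt(abs(median(r0) - 1), 0.1)
})

test_that("PSM tables honour layout and contamination fractions", {
  cfg <- sim_config(n_genes = 100, interference_exceed_fraction = 0,
                    qvalue_exceed_fraction = 0, rank_exceed_fraction = 0,
                    seed = 41)
  psms <- simulate_psm_table(cfg)$psms
  expect_true(all(psms$interference_pct < 30))
  expect_true(all(psms$q_value <= 0.01))
  expect_true(all(psms$rank == 1L))
  expect_identical(nrow(filter_psms(psms)), nrow(psms))
  chan <- attr(psms, "channel_map")
  expect_identical(table(chan$condition)[c("wildtype", "mutant", "control")],
                   table(factor(c(rep("wildtype", 3), rep("mutant", 3),
                                  rep("control", 2))))[
                     c("wildtype", "mutant", "control")])
  # requested contamination fractions are matched empirically
  cfg2 <- sim_config(n_genes = 300, interference_exceed_fraction = 0.2,
                     seed = 42)
  psms2 <- simulate_psm_table(cfg2)$psms
  expect_lt(abs(mean(psms2$interference_pct >= 30) - 0.2), 0.03)
  # spectra per peptide and peptides per protein stay in range
  per_pep <- table(psms2$peptide_seq)
  expect_true(all(per_pep >= 1 & per_pep <= 5))
  per_prot <- tapply(psms2$peptide_seq, psms2$protein_id,
                     function(p) length(unique(p)))
  expect_true(all(per_prot >= 1 & per_prot <= 10))
})

test_that("no planted protein effect centres the log2FC distribution at 0", {
  pq <- run_proteome_quant(
    simulate_psm_table(sim_config(n_genes = 400, seed = 43))$psms)
  expect_lt(abs(mean(pq$result$log2fc)), 0.05)
})

test_that("joint truth assigns tiers consistently across the two layers", {
  jf <- make_joint_fixture(1)
  both <- jf$truth$feature_id[jf$truth$tier == "both"]
  expect_length(both, 8)
  rt <- jf$rna$truth; pt <- jf$psm$truth
  for (id in both) {
    r <- rt$true_log2fc[rt$feature_id == id]
    p <- pt$true_log2fc[pt$feature_id == id]
    expect_true(r != 0 && p != 0 && sign(r) == sign(p))
  }
  only_t <- jf$truth$feature_id[jf$truth$tier == "transcript_only"]
  expect_true(all(pt$true_log2fc[match(only_t, pt$feature_id)] == 0))
  bad_r <- data.frame(feature_id = "x", true_log2fc = 1, tier = "both")
  bad_p <- data.frame(feature_id = "x", true_log2fc = -1, tier = "both")
  expect_error(joint_truth(bad_r, bad_p), "opposite-sign")
})

test_that("gene drop respects theta and full recessive penetrance", {
  st <- data.frame(id = seq_len(402),
                   father = c(0, 0, rep(1, 400)),
                   mother = c(0, 0, rep(2, 400)))
  ped0 <- simulate_pedigree(st, theta = 0, c(0.5, 0.5), 0.3, seed = 51)
  expect_identical(attr(ped0, "n_recombinations"), 0L)
  dg <- attr(ped0, "disease_genotype")
  expect_true(all((ped0$affection == 2) == (dg == 2)))
  # theta = 0.5: recombinant meioses are a fair coin (800 meioses here)
  ped5 <- simulate_pedigree(st, theta = 0.5, c(0.5, 0.5), 0.3, seed = 52)
  nrec <- attr(ped5, "n_recombinations")
  expect_lt(abs(nrec - 400), 4 * sqrt(800 * 0.25))
})

test_that("disease and marker transmissions are independent at theta 0.5", {
  # many meioses from one couple; chi-square of child disease-allele count
  # against marker genotype should be non-significant
  st <- data.frame(id = seq_len(2002),
                   father = c(0, 0, rep(1, 2000)),
                   mother = c(0, 0, rep(2, 2000)))
  ped <- simulate_pedigree(st, theta = 0.5, c(0.5, 0.5), 0.5, seed = 53)
  dg <- attr(ped, "disease_genotype")[-(1:2)]
  mk <- paste(pmin(ped$a1, ped$a2), pmax(ped$a1, ped$a2))[-(1:2)]
  keep <- table(mk) > 0
  suppressWarnings(p <- stats::chisq.test(table(dg, mk))$p.value)
  expect_gt(p, 0.001)
})

test_that("Ct tables invert exactly without noise", {
  g <- data.frame(label = c("cal", "trt"), true_fold = c(1, 3), n = 4)
  ct <- simulate_ct_table(g, noise_sd = 0, seed = 61)
  expect_equal(unique(ct$ct_reference), 18)
  dd <- delta_delta_ct(ct, "cal")
  expect_equal(dd$fold[dd$group == "trt"], 3, tolerance = 1e-12)
  expect_equal(dd$ddct[dd$group == "trt"], -log2(3), tolerance = 1e-12)
  # true_fold 1 with no noise: identical Ct across groups
  g1 <- data.frame(label = c("a", "b"), true_fold = 1, n = 3)
  ct1 <- simulate_ct_table(g1, noise_sd = 0, seed = 62)
  expect_equal(length(unique(ct1$ct_target)), 1L)
})
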