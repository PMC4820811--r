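make_cm <- function(counts, lengths = NULL,
                    condition = NULL, replicate = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("s%02d", seq_len(ncol(counts)))
  count_matrix(counts, lengths %||% rep(1000L, nrow(counts)),
               data.frame(sample_id = colnames(counts),
                          condition = condition %||%
                            rep("wildtype", ncol(counts)),
                          replicate = replicate %||% seq_len(ncol(counts)),
                          stringsAsFactors = FALSE))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("RPKM follows its defining formula and scale invariance", {
  cm <- make_cm(rbind(c(650), c(6.5e6 - 650)), lengths = c(1000L, 2000L))
  expr <- compute_rpkm(cm)
  expect_equal(expr$rpkm[1, 1], 100)
  cm0 <- make_cm(rbind(0, 10), lengths = c(777L, 50L))
  expect_equal(compute_rpkm(cm0)$rpkm[1, 1], 0)
  # doubling every count of one sample leaves that sample's RPKM unchanged
  set.seed(71)
  x <- matrix(rpois(300, 40) + 1, 50, 6)
  cm1 <- make_cm(x)
  x2 <- x; x2[, 3] <- 2 * x2[, 3]
  cm2 <- make_cm(x2)
  expect_equal(compute_rpkm(cm1)$rpkm[, 3], compute_rpkm(cm2)$rpkm[, 3])
})

test_that("condition means match brute-force recomputation", {
  sim <- make_rna_fixture(72, n_genes = 100)
  expr <- compute_rpkm(sim$counts)
  for (cond in c("control", "wildtype", "mutant")) {
    idx <- which(sim$counts$samples$condition == cond)
    brute <- apply(expr$rpkm[, idx], 1, function(r) sum(r) / length(r))
    expect_equal(condition_means(expr, cond), brute)
  }
  expect_error(condition_means(expr, "treated"), "unknown")
  one <- make_cm(matrix(1:4, 4, 1), condition = "mutant")
  e1 <- compute_rpkm(one)
  expect_equal(unname(condition_means(e1, "mutant")), unname(e1$rpkm[, 1]))
})

test_that("background subtraction clamps at zero and checks alignment", {
  a <- c(g1 = 5, g2 = 1, g3 = 7)
  b <- c(g1 = 2, g2 = 4, g3 = 0)
  expect_equal(subtract_background(a, b), c(g1 = 3, g2 = 0, g3 = 7))
  zero <- c(g1 = 0, g2 = 0, g3 = 0)
  expect_equal(subtract_background(a, zero), a)
  expect_error(subtract_background(a, b[c(2, 1, 3)]), "mismatch")
})

test_that("log2 fold change validity follows the both-positive rule", {
  lfc <- compute_log2fc(c(a = 2, b = 0, c = 4), c(a = 8, b = 5, c = 4))
  expect_equal(lfc$log2fc[1], -2)
  expect_false(lfc$valid[2])
  expect_true(is.na(lfc$log2fc[2]))
  expect_equal(lfc$log2fc[3], 0)
  # a pseudocount keeps every comparison finite but validity is unchanged
  lfc2 <- compute_log2fc(c(a = 2, b = 0), c(a = 8, b = 5), pseudocount = 1)
  expect_false(lfc2$valid[2])
  expect_true(is.finite(lfc2$log2fc[2]))
})

test_that("sigma about zero dominates the s.d. about the mean", {
  expect_equal(estimate_sigma_zero(c(1, -1))$sigma, 1)
  expect_equal(estimate_sigma_zero(c(3, 4))$sigma, sqrt(25 / 2),
               tolerance = 1e-12)
  set.seed(73)
  for (i in 1:20) {
    x <- rnorm(50, mean = runif(1, -2, 2))
    est <- estimate_sigma_zero(x)
    expect_gte(est$sigma + 1e-12, est$sd_about_mean)
  }
  # equality iff the mean is zero
  x <- c(-2, -1, 0, 1, 2)
  est <- estimate_sigma_zero(x)
  expect_equal(est$sigma, est$sd_about_mean)
  expect_error(estimate_sigma_zero(c(1, NA)), "at least 2")
})

test_that("sigma-to-fold reproduces the published threshold equivalences", {
  expect_equal(round(sigma_to_fold(0.2321, 3), 2), 1.62)
  expect_equal(round(sigma_to_fold(0.1787, 3), 2), 1.45)
  expect_equal(sigma_to_fold(0.4, 0), 1)
})

test_that("k-sigma detection thresholds strictly and nests", {
  x <- c(f1 = 0.9, f2 = -0.8, f3 = 0.1)
  hits <- detect_by_sigma(x, 0.2, 3)
  expect_equal(hits$feature_id[hits$direction == "up"], "f1")
  expect_equal(hits$feature_id[hits$direction == "down"], "f2")
  expect_false("f3" %in% hits$feature_id)
  # exact ties at the threshold are not hits
  expect_equal(nrow(detect_by_sigma(c(a = 0.6, b = -0.6), 0.2, 3)), 0L)
  # invalid entries are never flagged
  expect_equal(nrow(detect_by_sigma(c(a = NA_real_), 0.1, 3)), 0L)
  expect_error(detect_by_sigma(x, 0.2, 0), "k must be")
  set.seed(74)
  for (i in 1:10) {
    y <- setNames(rnorm(200, sd = 0.3), paste0("g", 1:200))
    s <- estimate_sigma_zero(y)
    h3 <- detect_by_sigma(y, s, 3)
    h6 <- detect_by_sigma(y, s, 6)
    expect_true(all(h6$feature_id %in% h3$feature_id))
  }
})

test_that("null flag rate at 3 sigma matches the Gaussian tail", {
  set.seed(75)
  flagged <- 0L; total <- 0L
  for (i in 1:5) {
    y <- setNames(rnorm(10000, sd = 0.25), sprintf("g%05d", 1:10000))
    hits <- detect_by_sigma(y, estimate_sigma_zero(y), 3)
    flagged <- flagged + nrow(hits); total <- total + length(y)
  }
  p <- 2 * pnorm(-3)
  expect_lt(abs(flagged / total - p), 3 * sqrt(p * (1 - p) / total))
})

test_that("subtractive route flags planted effects and not identical data", {
  sim <- make_rna_fixture(76, n_genes = 500,
                          effect_table = default_rna_effects(10))
  expr <- compute_rpkm(sim$counts)
  res <- route_subtractive(expr)
  planted <- default_rna_effects(10)
  found <- res[match(planted$feature_id, res$feature_id), ]
  expect_true(all(found$hit))
  expect_equal(found$direction, ifelse(planted$log2_effect > 0,
                                       "up", "down"))
  # identical mutant and wild-type replicates: zero hits
  cnt <- sim$counts$counts
  cond <- sim$counts$samples$condition
  cnt[, cond == "mutant"] <- cnt[, cond == "wildtype"]
  cm_same <- count_matrix(cnt, sim$counts$length_bp, sim$counts$samples)
  expect_equal(sum(route_subtractive(compute_rpkm(cm_same))$hit), 0L)
})

test_that("count-route size factors and nulls behave as defined", {
  sim <- make_rna_fixture(77, n_genes = 300, effect_table = NULL)
  cm <- sim$counts
  res <- route_count_test(cm)
  expect_equal(sum(res$hit), 0L)
  # doubling one sample's counts doubles its size factor relative to the
  # others (size factors are defined up to the geometric-mean reference)
  sf1 <- attr(res, "size_factors")
  cnt2 <- cm$counts; cnt2[, 5] <- cnt2[, 5] * 2L
  cm2 <- count_matrix(cnt2, cm$length_bp, cm$samples)
  sf2 <- attr(route_count_test(cm2), "size_factors")
  rel <- sf2 / sf1
  expect_equal(unname(rel[5] / rel[1]), 2, tolerance = 1e-9)
  expect_equal(unname(rel[-5] / rel[1]), rep(1, ncol(cnt2) - 1L),
               tolerance = 1e-9)
  # normalized counts are invariant up to that common factor
  norm1 <- sweep(cm$counts, 2, sf1, `/`)
  norm2 <- sweep(cnt2, 2, sf2, `/`)
  pos <- norm1 > 0
  expect_equal(unname((norm2 / norm1)[pos]),
               rep(1 / unname(rel[1]), sum(pos)), tolerance = 1e-9)
})

test_that("count route recovers planted effects with controlled FDR", {
  recalls <- fdrs <- numeric(10)
  for (i in 1:10) {
    eff <- default_rna_effects(20, magnitude = 1.5)
    sim <- make_rna_fixture(780 + i, effect_table = eff)
    res <- suppressMessages(route_count_test(sim$counts))
    hits <- res$feature_id[res$hit]
    recalls[i] <- mean(eff$feature_id %in% hits)
    fdrs[i] <- if (length(hits)) mean(!hits %in% eff$feature_id) else 0
  }
  expect_gte(mean(recalls), 0.8)
  expect_lte(mean(fdrs), 0.1)
})

test_that("consensus requires every route to agree in direction", {
  r1 <- data.frame(feature_id = c("A", "B", "C"), direction = "down")
  r2 <- data.frame(feature_id = c("B", "C", "D"), direction = "down")
  r3 <- data.frame(feature_id = c("B", "C"), direction = "down")
  cons <- consensus_hits(list(r1, r2, r3))
  expect_equal(cons$feature_id, c("B", "C"))
  # opposite direction excludes a feature
  r2b <- r2; r2b$direction[r2b$feature_id == "B"] <- "up"
  expect_equal(consensus_hits(list(r1, r2b, r3))$feature_id, "C")
  expect_error(consensus_hits(list(r1)), "at least 2")
})

test_that("a canonical three-route scenario intersects to its shared hits", {
  subtractive <- data.frame(
    feature_id = c("DNAJB1", "PYGM", "COL3A1", "HSPA1A", "DNAJB4"),
    direction = "down")
  sigma6 <- data.frame(
    feature_id = c("DNAJB1", "PYGM", "COL3A1", "DIAPH3"),
    direction = c("down", "down", "down", "up"))
  count_route <- data.frame(
    feature_id = c("DNAJB1", "PYGM", "COL3A1", "HSPE1", "HSPA6"),
    direction = "down")
  cons <- consensus_hits(list(subtractive, sigma6, count_route))
  expect_setequal(cons$feature_id, c("DNAJB1", "PYGM", "COL3A1"))
  expect_true(all(cons$direction == "down"))
})

test_that("full transcript pipeline recovers planted truth by consensus", {
  eff <- default_rna_effects()
  hit_all <- 0
  for (i in 1:3) {
    sim <- make_rna_fixture(790 + i)
    de <- suppressMessages(run_rnaseq_de(sim$counts))
    expect_true(all(de$consensus$feature_id %in% eff$feature_id))
    hit_all <- hit_all + mean(eff$feature_id %in% de$consensus$feature_id)
    # threshold nesting holds inside the assembled result
    k6 <- de$result$feature_id[de$result$sigma_k6 != "none"]
    k3 <- de$result$feature_id[de$result$sigma_k3 != "none"]
    expect_true(all(k6 %in% k3))
  }
  expect_gte(hit_all / 3, 0.9)
})

test_that("QC summary reproduces the published derived cells", {
  qc <- read_qc_table(system.file("extdata", "rnaseq_qc_readcounts.tsv",
                                  package = "crossomics"))
  out <- qc_summary(qc)
  cell <- function(id, col) {
    round(out$samples[[col]][out$samples$sample_id == id], 2)
  }
  expect_equal(cell("CNT-A4", "pct_mapped_wo_dup"), 84.63)
  expect_equal(cell("MUT-A3", "pct_mapped_wo_dup"), 81.10)
  expect_equal(cell("MUT-B2", "pct_mapped_wo_dup"), 81.71)
  expect_equal(cell("WT-A3", "pct_mapped_wo_dup"), 82.49)
  expect_equal(cell("MUT-A2", "pct_properly_paired"), 80.30)
  # the published combined totals are the sums of the printed lane totals
  lanes <- read_qc_table(system.file("extdata", "rnaseq_qc_lane_totals.tsv",
                                     package = "crossomics"))
  comb <- qc_summary(lanes)$totals
  expect_equal(round(comb$total_reads, 2), 712.48)
  expect_equal(round(comb$mapped_wo_dup, 2), 586.52)
  # coverage column: sequenced Mb over the 65 Mb transcriptome
  expect_equal(out$samples$coverage_x,
               out$samples$properly_paired * 100 / 65)
})

test_that("QC summary enforces the read-count hierarchy", {
  bad <- data.frame(sample_id = "s1", total_reads = 10, mapped_reads = 11,
                    mapped_wo_dup = 9, properly_paired = 5)
  expect_error(qc_summary(bad), "s1")
  ok <- data.frame(sample_id = "s1", total_reads = 10, mapped_reads = 8,
                   mapped_wo_dup = 5, properly_paired = 4)
  expect_equal(qc_summary(ok)$samples$pct_mapped_wo_dup, 50)
})
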