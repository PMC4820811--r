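#' Gene-level count matrix with lengths and a sample sheet
#'
#' The container for the transcript stage: an integer matrix of read counts
#' (genes in rows, samples in columns), per-gene transcript lengths in bp,
#' and a sample sheet assigning each column a condition
#' (`control`/`wildtype`/`mutant`) and replicate index.
#'
#' @param counts non-negative integer matrix with rownames (feature ids)
#'   and colnames (sample ids).
#' @param length_bp positive integer vector, one length per gene.
#' @param samples data frame with columns `sample_id`, `condition`,
#'   `replicate`; `sample_id` must match `colnames(counts)`.
#' @return an object of class `count_matrix`.
#' @export
count_matrix <- function(counts, length_bp, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    stop("feature ids must be unique rownames of the count matrix",
         call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (length(length_bp) != nrow(counts) || any(length_bp <= 0))
    stop("length_bp must be positive, one value per gene", call. = FALSE)
  samples <- as.data.frame(samples)
  if (!identical(samples$sample_id, colnames(counts)))
    stop("sample sheet does not match count matrix columns", call. = FALSE)
  if (!all(samples$condition %in% c("control", "wildtype", "mutant")))
    stop("condition must be one of control/wildtype/mutant", call. = FALSE)
  tot <- colSums(counts)
  if (any(tot == 0))
    stop(sprintf("sample '%s' has total count 0",
                 colnames(counts)[which(tot == 0)[1]]), call. = FALSE)
  structure(list(counts = counts, length_bp = as.numeric(length_bp),
                 samples = samples),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(table(x$samples$condition), collapse = "/")))
  invisible(x)
}

#' Reads per kilobase of transcript per million mapped reads
#'
#' `RPKM = 1e9 * count / (library_size * length_bp)`, with the library size
#' taken as the per-sample total count.
#'
#' @param counts a [count_matrix()].
#' @return an `expression_matrix`: a list with the RPKM matrix (`rpkm`) and
#'   the sample sheet.
#' @export
compute_rpkm <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  n <- colSums(counts$counts)
  if (any(n == 0))
    stop(sprintf("sample '%s' has zero total count",
                 colnames(counts$counts)[which(n == 0)[1]]), call. = FALSE)
  rpkm <- 1e9 * sweep(counts$counts / counts$length_bp, 2L, n, `/`)
  structure(list(rpkm = rpkm, samples = counts$samples),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (RPKM)\n",
              nrow(x$rpkm), ncol(x$rpkm)))
  invisible(x)
}

expr_condition_cols <- function(expr, condition) {
  idx <- which(expr$samples$condition == condition)
  if (!length(idx))
    stop(sprintf("unknown or empty condition '%s'", condition),
         call. = FALSE)
  idx
}

#' Per-feature mean expression of one condition's replicates
#'
#' @param expr an `expression_matrix` from [compute_rpkm()].
#' @param condition one of `"control"`, `"wildtype"`, `"mutant"`.
#' @return named numeric vector of per-feature means.
#' @export
condition_means <- function(expr, condition) {
  idx <- expr_condition_cols(expr, condition)
  rowMeans(expr$rpkm[, idx, drop = FALSE])
}

#' Subtract the control background from a condition mean, clamped at zero
#'
#' @param cond_mean,control_mean aligned named vectors of normalized means.
#' @return `pmax(cond_mean - control_mean, 0)`, elementwise.
#' @export
subtract_background <- function(cond_mean, control_mean) {
  if (length(cond_mean) != length(control_mean) ||
      !identical(names(cond_mean), names(control_mean)))
    stop("feature index mismatch between condition and control vectors",
         call. = FALSE)
  pmax(cond_mean - control_mean, 0)
}

#' Mutant-over-wild-type log2 fold change with validity flags
#'
#' A comparison is *valid* when both background-adjusted means are strictly
#' positive; at the default pseudocount 0 the log2 fold change of invalid
#' features is `NA`.
#'
#' @param mut_adj,wt_adj aligned background-adjusted mean vectors.
#' @param pseudocount non-negative value added to both terms of the ratio.
#' @return data frame `feature_id`, `log2fc`, `valid`.
#' @export
compute_log2fc <- function(mut_adj, wt_adj, pseudocount = 0) {
  if (length(mut_adj) != length(wt_adj) ||
      !identical(names(mut_adj), names(wt_adj)))
    stop("feature index mismatch", call. = FALSE)
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)
  valid <- mut_adj > 0 & wt_adj > 0
  lfc <- rep(NA_real_, length(mut_adj))
  use <- if (pseudocount > 0) rep(TRUE, length(mut_adj)) else valid
  lfc[use] <- log2((mut_adj[use] + pseudocount) /
                   (wt_adj[use] + pseudocount))
  data.frame(feature_id = names(mut_adj) %||% seq_along(mut_adj),
             log2fc = lfc, valid = valid, stringsAsFactors = FALSE)
}

#' Standard deviation of log2 fold changes about zero
#'
#' The thresholding dispersion of the pipeline is the root-mean-square
#' deviation of the valid log2 fold changes from 0 ("no change"), not from
#' the sample mean; the s.d. about the mean is also reported for
#' transparency. The RMS about zero always dominates the s.d. about the
#' mean, with equality iff the mean is 0.
#'
#' @param log2fc numeric vector of valid log2 fold changes (`NA`s dropped).
#' @return object of class `sigma_estimate`: `sigma`, `n_valid`,
#'   `sd_about_mean`.
#' @export
estimate_sigma_zero <- function(log2fc) {
  x <- log2fc[!is.na(log2fc)]
  if (length(x) < 2L)
    stop("need at least 2 valid log2 fold changes", call. = FALSE)
  structure(list(sigma = sqrt(mean(x^2)), n_valid = length(x),
                 sd_about_mean = sqrt(mean((x - mean(x))^2))),
            class = "sigma_estimate")
}

#' @export
print.sigma_estimate <- function(x, ...) {
  cat(sprintf(
    "sigma (RMS about 0) = %.4f over %d valid comparisons (s.d. %.4f)\n",
    x$sigma, x$n_valid, x$sd_about_mean))
  cat(sprintf("  3 s.d. fold %.2f, 6 s.d. fold %.2f\n",
              sigma_to_fold(x$sigma, 3), sigma_to_fold(x$sigma, 6)))
  invisible(x)
}

#' Fold change corresponding to a k-sigma log2 threshold
#'
#' @param sigma positive s.d.-about-zero of log2 fold changes.
#' @param k multiplier (integer >= 0).
#' @return `2^(k * sigma)`.
#' @export
sigma_to_fold <- function(sigma, k) {
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (k < 0) stop("k must be >= 0", call. = FALSE)
  2^(k * sigma)
}

#' Flag features beyond a k-sigma log2 fold-change threshold
#'
#' A feature is `up` if `log2fc > k * sigma`, `down` if
#' `log2fc < -k * sigma` (strict inequalities; ties at the threshold are
#' not hits). Invalid (`NA`) features are never flagged.
#'
#' @param log2fc named numeric vector, or the data frame from
#'   [compute_log2fc()].
#' @param sigma a `sigma_estimate` (or a positive number) computed from the
#'   same vector.
#' @param k threshold multiplier (>= 1).
#' @return data frame `feature_id`, `direction` of the flagged features.
#' @export
detect_by_sigma <- function(log2fc, sigma, k = 3L) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (is.data.frame(log2fc))
    log2fc <- stats::setNames(log2fc$log2fc, log2fc$feature_id)
  s <- if (inherits(sigma, "sigma_estimate")) sigma$sigma else sigma
  up <- !is.na(log2fc) & log2fc > k * s
  dn <- !is.na(log2fc) & log2fc < -k * s
  data.frame(
    feature_id = c(names(log2fc)[up], names(log2fc)[dn]),
    direction = c(rep("up", sum(up)), rep("down", sum(dn))),
    stringsAsFactors = FALSE)
}

#' Background-subtraction route: replicate t-test plus fold filter
#'
#' The control-condition mean RPKM is subtracted from every wild-type and
#' mutant replicate (clamped at zero); a two-sided pooled-variance
#' Student's t-test then compares the log2 adjusted values between mutant
#' and wild-type replicates. A feature is a hit when `p <= alpha` and the
#' adjusted-mean fold change is at least `min_fold` in either direction.
#'
#' @param expr an `expression_matrix`.
#' @param pseudocount added before taking log2 of adjusted replicate values.
#' @param alpha t-test significance cutoff.
#' @param min_fold minimum fold change (linear scale).
#' @return data frame `feature_id`, `log2fc`, `p`, `hit`, `direction`.
#' @export
route_subtractive <- function(expr, pseudocount = 0.5, alpha = 0.05,
                              min_fold = 1.5) {
  ctl <- condition_means(expr, "control")
  wt_idx <- expr_condition_cols(expr, "wildtype")
  mut_idx <- expr_condition_cols(expr, "mutant")
  if (length(wt_idx) < 2L || length(mut_idx) < 2L)
    stop("need >= 2 replicates per condition", call. = FALSE)
  adj <- function(idx) log2(pmax(expr$rpkm[, idx, drop = FALSE] - ctl, 0) +
                            pseudocount)
  tt <- row_t_test(adj(wt_idx), adj(mut_idx))
  wt_adj <- subtract_background(condition_means(expr, "wildtype"), ctl)
  mut_adj <- subtract_background(condition_means(expr, "mutant"), ctl)
  lfc <- log2((mut_adj + pseudocount) / (wt_adj + pseudocount))
  hit <- tt$p <= alpha & abs(lfc) >= log2(min_fold)
  data.frame(feature_id = rownames(expr$rpkm), log2fc = lfc, p = tt$p,
             hit = hit,
             direction = ifelse(!hit, "none",
                                ifelse(lfc > 0, "up", "down")),
             stringsAsFactors = FALSE, row.names = NULL)
}

# Median-of-ratios size factors (geometric-mean reference over genes
# expressed in every sample).
size_factors_mor <- function(counts) {
  lg <- log(counts)
  ref <- rowMeans(lg)
  use <- is.finite(ref)
  if (!any(use)) stop("no gene is expressed in every sample", call. = FALSE)
  apply(lg[use, , drop = FALSE], 2L, function(col)
    exp(stats::median(col - ref[use])))
}

# Wald-type NB test on normalized counts: method-of-moments pooled
# dispersion, normal approximation on the log2 fold change of group means.
nb_wald_test <- function(norm_a, norm_b, inv_sf_mean) {
  na <- ncol(norm_a); nb <- ncol(norm_b)
  ma <- rowMeans(norm_a); mb <- rowMeans(norm_b)
  pooled_var <- ((na - 1) * row_vars(norm_a) + (nb - 1) * row_vars(norm_b)) /
    (na + nb - 2)
  mall <- (na * ma + nb * mb) / (na + nb)
  disp <- pmax((pooled_var - mall * inv_sf_mean) / mall^2, 0)
  pc <- 0.5
  lfc <- log2((mb + pc) / (ma + pc))
  var_mean <- function(m, n) (m * inv_sf_mean + disp * m^2) / n
  se <- sqrt((var_mean(ma, na) / (ma + pc)^2 +
              var_mean(mb, nb) / (mb + pc)^2)) / log(2)
  z <- lfc / se
  p <- 2 * stats::pnorm(-abs(z))
  p[se == 0] <- 1
  data.frame(log2fc = lfc, p = p)
}

#' Two-step count-based route (simplified DESeq-style test)
#'
#' Counts are normalized by median-of-ratios size factors. Step 1 tests
#' wild type against control and keeps genes with Benjamini-Hochberg
#' `q < fdr_alpha` whose wild-type expression is at least
#' `min_abs_log2fc` log2 units above control. Step 2 applies the same test
#' to mutant versus wild type restricted to the step-1 survivors; hits are
#' survivors with step-2 `q < fdr_alpha`. The per-gene test is an openly
#' simplified negative-binomial Wald test (method-of-moments pooled
#' dispersion, normal approximation on the log fold change); it is not a
#' DESeq reimplementation.
#'
#' @param counts a [count_matrix()].
#' @param fdr_alpha Benjamini-Hochberg threshold for both steps.
#' @param min_abs_log2fc step-1 above-background log2 fold-change floor.
#' @return data frame `feature_id`, `step1_pass`, `log2fc`, `p`, `q`,
#'   `hit`, `direction` (step-2 quantities); genes with all-zero counts are
#'   excluded and listed in the `excluded` attribute.
#' @export
route_count_test <- function(counts, fdr_alpha = 0.05,
                             min_abs_log2fc = 1) {
  stopifnot(inherits(counts, "count_matrix"))
  cm <- counts$counts
  zero <- rowSums(cm) == 0
  excluded <- rownames(cm)[zero]
  if (any(zero)) {
    message(sprintf("route_count_test: excluding %d all-zero gene(s)",
                    sum(zero)))
    cm <- cm[!zero, , drop = FALSE]
  }
  sf <- size_factors_mor(cm)
  norm <- sweep(cm, 2L, sf, `/`)
  cols <- function(cond) counts$samples$condition == cond
  if (sum(cols("control")) < 2L || sum(cols("wildtype")) < 2L ||
      sum(cols("mutant")) < 2L)
    stop("need >= 2 replicates per condition", call. = FALSE)
  inv_sf_mean <- mean(1 / sf)
  s1 <- nb_wald_test(norm[, cols("control"), drop = FALSE],
                     norm[, cols("wildtype"), drop = FALSE], inv_sf_mean)
  s1$q <- stats::p.adjust(s1$p, method = "BH")
  step1 <- s1$q < fdr_alpha & s1$log2fc >= min_abs_log2fc
  s2 <- nb_wald_test(norm[, cols("wildtype"), drop = FALSE],
                     norm[, cols("mutant"), drop = FALSE], inv_sf_mean)
  out <- data.frame(feature_id = rownames(cm), step1_pass = step1,
                    log2fc = s2$log2fc, p = s2$p, q = NA_real_,
                    hit = FALSE, direction = "none",
                    stringsAsFactors = FALSE, row.names = NULL)
  if (any(step1)) {
    out$q[step1] <- stats::p.adjust(s2$p[step1], method = "BH")
    out$hit <- step1 & !is.na(out$q) & out$q < fdr_alpha
    out$direction[out$hit] <- ifelse(out$log2fc[out$hit] > 0, "up", "down")
  }
  attr(out, "excluded") <- excluded
  attr(out, "size_factors") <- sf
  out
}

#' Direction-consistent consensus over several detection routes
#'
#' @param route_results named list (>= 2 entries) of hit data frames with
#'   columns `feature_id` and `direction` (`up`/`down`; rows with
#'   `direction == "none"` are ignored).
#' @return data frame `feature_id`, `direction` of features flagged by
#'   every route with the same direction.
#' @export
consensus_hits <- function(route_results) {
  if (!is.list(route_results) || length(route_results) < 2L)
    stop("need at least 2 routes for a consensus", call. = FALSE)
  sets <- lapply(route_results, function(r) {
    r <- r[r$direction %in% c("up", "down"), c("feature_id", "direction")]
    r
  })
  out <- Reduce(function(a, b) merge(a, b, by = c("feature_id", "direction")),
                sets)
  out <- out[order(out$feature_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full three-route transcript stage on a count matrix
#'
#' Computes RPKM, mutant-over-wild-type log2 fold changes with validity
#' (from the unsubtracted RPKM condition means, the input of the
#' sigma-threshold route), the s.d.-about-zero estimate, the three
#' detection routes (background-subtraction t-test, k-sigma thresholds at
#' `k = 3` and `k = 6`, and the two-step count test), and the
#' direction-consistent consensus over `consensus_routes`.
#'
#' @param counts a [count_matrix()].
#' @param pseudocount for [compute_log2fc()] on the condition means.
#' @param sub_pseudocount,alpha,min_fold parameters of
#'   [route_subtractive()].
#' @param fdr_alpha,min_abs_log2fc parameters of [route_count_test()].
#' @param consensus_routes which route flags enter the consensus; a subset
#'   of `c("subtractive", "sigma_k3", "sigma_k6", "count_test")`.
#' @return list with `result` (per-feature table: `feature_id`, `log2fc`,
#'   `valid`, one direction column per route, `consensus`), `sigma`
#'   (the `sigma_estimate`), `consensus` (the hit set) and the raw
#'   per-route outputs.
#' @export
run_rnaseq_de <- function(counts, pseudocount = 0, sub_pseudocount = 0.5,
                          alpha = 0.05, min_fold = 1.5, fdr_alpha = 0.05,
                          min_abs_log2fc = 1,
                          consensus_routes = c("subtractive", "sigma_k6",
                                               "count_test")) {
  expr <- compute_rpkm(counts)
  lfc <- compute_log2fc(condition_means(expr, "mutant"),
                        condition_means(expr, "wildtype"), pseudocount)
  sigma <- estimate_sigma_zero(lfc$log2fc[lfc$valid])
  routes <- list(
    subtractive = route_subtractive(expr, sub_pseudocount, alpha, min_fold),
    sigma_k3 = detect_by_sigma(lfc, sigma, 3L),
    sigma_k6 = detect_by_sigma(lfc, sigma, 6L),
    count_test = route_count_test(counts, fdr_alpha, min_abs_log2fc))
  dir_col <- function(r) {
    d <- stats::setNames(rep("none", nrow(lfc)), lfc$feature_id)
    hits <- r[r$direction %in% c("up", "down"), ]
    d[hits$feature_id] <- hits$direction
    unname(d)
  }
  result <- data.frame(
    feature_id = lfc$feature_id, log2fc = lfc$log2fc, valid = lfc$valid,
    subtractive = dir_col(routes$subtractive),
    sigma_k3 = dir_col(routes$sigma_k3),
    sigma_k6 = dir_col(routes$sigma_k6),
    count_test = dir_col(routes$count_test),
    stringsAsFactors = FALSE)
  cons <- consensus_hits(lapply(consensus_routes, function(r)
    data.frame(feature_id = result$feature_id, direction = result[[r]],
               stringsAsFactors = FALSE)))
  result$consensus <- result$feature_id %in% cons$feature_id
  list(result = result, sigma = sigma, consensus = cons, routes = routes)
}

#' Sequencing QC summary with derived percentage, yield and coverage columns
#'
#' Takes the raw per-sample read accounting of a paired-end RNA-Seq run
#' (all counts in units of 10^6 reads) and derives the standard summary
#' columns: percentage of total reads mapped after duplicate removal,
#' percentage of deduplicated mapped reads properly paired, sequenced bases
#' in Mb (`properly_paired x read_length_bp`), and approximate transcriptome
#' coverage (sequenced Mb divided by `transcriptome_size_mb`). Per-lane and
#' combined totals sum the count columns and recompute the derived columns
#' from the sums.
#'
#' @param rows data frame with columns `sample_id`, `total_reads`,
#'   `mapped_reads`, `mapped_wo_dup`, `properly_paired` and optionally
#'   `lane`.
#' @param read_length_bp read length in bp.
#' @param transcriptome_size_mb denominator for the coverage column; the
#'   default 65 Mb is the effective human transcriptome size used by the
#'   summary.
#' @return list with `samples` (per-sample table with derived columns) and
#'   `totals` (per-lane and combined rows).
#' @export
qc_summary <- function(rows, read_length_bp = 100,
                       transcriptome_size_mb = 65) {
  rows <- as.data.frame(rows)
  req <- c("sample_id", "total_reads", "mapped_reads", "mapped_wo_dup",
           "properly_paired")
  if (!all(req %in% names(rows)))
    stop("missing required QC columns", call. = FALSE)
  bad <- !(rows$properly_paired >= 0 &
           rows$properly_paired <= rows$mapped_wo_dup &
           rows$mapped_wo_dup <= rows$mapped_reads &
           rows$mapped_reads <= rows$total_reads)
  if (any(bad))
    stop(sprintf("QC count hierarchy violated for sample '%s'",
                 rows$sample_id[which(bad)[1]]), call. = FALSE)
  derive <- function(d) {
    d$pct_mapped_wo_dup <- 100 * d$mapped_wo_dup / d$total_reads
    d$pct_properly_paired <- 100 * d$properly_paired / d$mapped_wo_dup
    d$sequenced_mb <- d$properly_paired * read_length_bp
    d$coverage_x <- d$sequenced_mb / transcriptome_size_mb
    d
  }
  samples <- derive(rows)
  sum_rows <- function(d, label) {
    derive(data.frame(sample_id = label,
                      total_reads = sum(d$total_reads),
                      mapped_reads = sum(d$mapped_reads),
                      mapped_wo_dup = sum(d$mapped_wo_dup),
                      properly_paired = sum(d$properly_paired),
                      stringsAsFactors = FALSE))
  }
  totals <- if ("lane" %in% names(rows)) {
    per_lane <- do.call(rbind, lapply(split(rows, rows$lane), function(d)
      sum_rows(d[req], paste0("lane_", d$lane[1], "_total"))))
    rbind(per_lane, sum_rows(rows[req], "combined_total"))
  } else sum_rows(rows[req], "combined_total")
  rownames(totals) <- NULL
  list(samples = samples, totals = totals)
}
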