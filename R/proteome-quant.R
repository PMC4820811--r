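#' Filter peptide-spectrum matches on interference, FDR and rank
#'
#' Retains rows with isolation interference strictly below
#' `max_interference` percent, q-value at or below `max_q` (the
#' conventional inclusive reading of a "1 percent FDR cutoff") and, when
#' `top_rank_only`, peptide rank 1. An empty survivor set is a valid
#' (warned) outcome.
#'
#' @param psms data frame with columns `protein_id`, `peptide_seq`,
#'   `spectrum_id`, `rank`, `q_value`, `interference_pct` and the channel
#'   intensity columns.
#' @param max_interference strict upper bound on interference percent.
#' @param max_q inclusive upper bound on the q-value.
#' @param top_rank_only keep only rank-1 PSMs.
#' @return the surviving rows, with a `filter_report` attribute listing the
#'   input and surviving counts and the per-criterion failure counts.
#' @export
filter_psms <- function(psms, max_interference = 30, max_q = 0.01,
                        top_rank_only = TRUE) {
  fail_int <- !(psms$interference_pct < max_interference)
  fail_q <- !(psms$q_value <= max_q)
  fail_rank <- if (top_rank_only) psms$rank != 1L else rep(FALSE, nrow(psms))
  keep <- !(fail_int | fail_q | fail_rank)
  out <- psms[keep, , drop = FALSE]
  if (!nrow(out)) warning("no PSMs survive the filter")
  attr(out, "channel_map") <- attr(psms, "channel_map")
  attr(out, "platform") <- attr(psms, "platform")
  attr(out, "filter_report") <- list(
    n_input = nrow(psms), n_retained = nrow(out),
    n_fail_interference = sum(fail_int), n_fail_q = sum(fail_q),
    n_fail_rank = sum(fail_rank))
  out
}

#' Aggregate surviving PSMs to one value per protein and channel
#'
#' For each protein and channel the aggregated value is the median over all
#' of that protein's surviving spectra (even counts average the two central
#' values, the usual median convention).
#'
#' @param psms filtered PSM data frame.
#' @param channel_cols channel column names; defaults to columns named
#'   `ch1`, `ch2`, ...
#' @return data frame `protein_id`, one column per channel,
#'   `n_spectra_used`, `n_peptides_used`.
#' @export
aggregate_to_protein <- function(psms, channel_cols = NULL) {
  channel_cols <- channel_cols %||% grep("^ch[0-9]+$", names(psms),
                                         value = TRUE)
  if (!length(channel_cols)) stop("no channel columns found", call. = FALSE)
  mat <- as.matrix(psms[channel_cols])
  sp <- split(seq_len(nrow(psms)), psms$protein_id)
  med <- t(vapply(sp, function(i) {
    sub <- mat[i, , drop = FALSE]
    vapply(seq_along(channel_cols),
           function(j) stats::median(sub[, j]), numeric(1))
  }, numeric(length(channel_cols))))
  out <- data.frame(protein_id = names(sp), med,
                    n_spectra_used = lengths(sp),
                    n_peptides_used = vapply(sp, function(i)
                      length(unique(psms$peptide_seq[i])), integer(1)),
                    stringsAsFactors = FALSE, row.names = NULL)
  names(out)[seq_along(channel_cols) + 1L] <- channel_cols
  attr(out, "channel_map") <- attr(psms, "channel_map")
  attr(out, "platform") <- attr(psms, "platform")
  out
}

#' Quantile normalization across sample columns
#'
#' Every column is forced onto the common distribution whose r-th order
#' statistic is the mean of the r-th order statistics across columns; tied
#' values within a column receive the mean of the values their ranks span.
#' Applying the transform twice gives the same result as applying it once.
#'
#' @param x numeric matrix (features in rows, samples in columns), no
#'   missing values.
#' @return matrix of the same shape with identical sorted columns.
#' @export
quantile_normalize <- function(x) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("missing values are not supported", call. = FALSE)
  if (ncol(x) < 2L) {
    warning("single column: quantile normalization is the identity")
    return(x)
  }
  n <- nrow(x)
  ref <- rowMeans(apply(x, 2L, sort))
  out <- apply(x, 2L, function(col) {
    rk <- rank(col, ties.method = "average")
    stats::approx(seq_len(n), ref, xout = rk)$y
  })
  dimnames(out) <- dimnames(x)
  out
}

#' Per-protein Student's t-test between mutant and wild-type channels
#'
#' Two-sided pooled-variance t-test on log2 quantile-normalized values;
#' `log2fc = mean(mutant) - mean(wildtype)`. Proteins with zero variance in
#' both groups and equal means get `p = 1` by convention.
#'
#' @param log2_mat log2 matrix with proteins in rows, channels in columns.
#' @param mutant_channels,wildtype_channels column names of the two groups
#'   (>= 2 each).
#' @return data frame `protein_id`, `log2fc`, `p`, `q` (Benjamini-Hochberg).
#' @export
protein_t_test <- function(log2_mat, mutant_channels, wildtype_channels) {
  if (length(mutant_channels) < 2L || length(wildtype_channels) < 2L)
    stop("need >= 2 channels per group", call. = FALSE)
  tt <- row_t_test(log2_mat[, wildtype_channels, drop = FALSE],
                   log2_mat[, mutant_channels, drop = FALSE])
  data.frame(protein_id = rownames(log2_mat), log2fc = tt$estimate,
             p = tt$p, q = stats::p.adjust(tt$p, method = "BH"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Flag proteins beyond a k-sigma log2 fold-change threshold
#'
#' Same contract as [detect_by_sigma()]; the s.d. about zero is estimated
#' from the supplied protein log2 fold-change vector itself.
#'
#' @param log2fc named vector, or data frame with `protein_id` and
#'   `log2fc`.
#' @param k threshold multiplier.
#' @return hit data frame (`feature_id`, `direction`) with the
#'   `sigma_estimate` attached as attribute `sigma`.
#' @export
detect_proteins_by_sigma <- function(log2fc, k = 3L) {
  if (is.data.frame(log2fc))
    log2fc <- stats::setNames(log2fc$log2fc, log2fc$protein_id)
  sigma <- estimate_sigma_zero(log2fc)
  hits <- detect_by_sigma(log2fc, sigma, k)
  attr(hits, "sigma") <- sigma
  hits
}

#' Concordance of differential-expression calls between two MS platforms
#'
#' @param hits_a,hits_b hit data frames (`feature_id`, `direction`) from
#'   the two platforms.
#' @param universe optional character vector of proteins quantified on both
#'   platforms (reported as `n_universe`).
#' @return list with `concordant` (same protein, same direction),
#'   `discordant` (same protein, opposite directions, with both directions
#'   reported) and `n_universe`.
#' @export
cross_platform_concordance <- function(hits_a, hits_b, universe = NULL) {
  shared <- merge(hits_a, hits_b, by = "feature_id",
                  suffixes = c("_a", "_b"))
  conc <- shared[shared$direction_a == shared$direction_b, ]
  disc <- shared[shared$direction_a != shared$direction_b, ]
  rownames(conc) <- rownames(disc) <- NULL
  list(concordant = data.frame(feature_id = conc$feature_id,
                               direction = conc$direction_a,
                               stringsAsFactors = FALSE),
       discordant = disc,
       n_universe = if (is.null(universe)) NA_integer_
                    else length(unique(universe)))
}

#' Run the full proteome stage on a PSM table
#'
#' Filters PSMs, aggregates to protein medians, quantile-normalizes the
#' test channels (wild type and mutant; the non-transfected control
#' channels are carried in the protein matrix but take no part in
#' normalization or testing), converts to log2, runs the per-protein
#' t-test between mutant and wild-type channels, and flags proteins beyond
#' the k-sigma threshold. Proteins with a non-positive aggregated channel
#' value are dropped before normalization rather than imputed.
#'
#' @param psms PSM data frame (see [simulate_psm_table()] for the layout).
#' @param channel_map data frame `channel`, `condition`, `replicate`;
#'   defaults to the map attached to `psms` or [default_channel_map()].
#' @param max_interference,max_q,top_rank_only passed to [filter_psms()].
#' @param k sigma multiplier for [detect_proteins_by_sigma()].
#' @return list with `result` (protein table with `log2fc`, `p`, `q`,
#'   `sigma_hit`, `direction`), `hits`, `sigma`, `protein_matrix`,
#'   `filter_report`.
#' @export
run_proteome_quant <- function(psms, channel_map = NULL,
                               max_interference = 30, max_q = 0.01,
                               top_rank_only = TRUE, k = 3L) {
  channel_map <- channel_map %||% attr(psms, "channel_map") %||%
    default_channel_map()
  kept <- filter_psms(psms, max_interference, max_q, top_rank_only)
  report <- attr(kept, "filter_report")
  prot <- aggregate_to_protein(kept, channel_map$channel)
  mut_ch <- channel_map$channel[channel_map$condition == "mutant"]
  wt_ch <- channel_map$channel[channel_map$condition == "wildtype"]
  test_ch <- c(wt_ch, mut_ch)
  mat <- as.matrix(prot[, test_ch, drop = FALSE])
  rownames(mat) <- prot$protein_id
  ok <- apply(mat, 1L, function(r) all(is.finite(r) & r > 0))
  mat <- mat[ok, , drop = FALSE]
  lmat <- log2(quantile_normalize(mat))
  de <- protein_t_test(lmat, mut_ch, wt_ch)
  hits <- detect_proteins_by_sigma(de, k)
  hits$log2fc <- de$log2fc[match(hits$feature_id, de$protein_id)]
  de$sigma_hit <- de$protein_id %in% hits$feature_id
  de$direction <- "none"
  de$direction[match(hits$feature_id, de$protein_id)] <- hits$direction
  list(result = de, hits = hits, sigma = attr(hits, "sigma"),
       protein_matrix = prot, filter_report = report)
}
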