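#' Delta-delta Ct relative quantification
#'
#' Per record, `dCt = Ct_target - Ct_reference`; per group,
#' `ddCt = mean(dCt) - mean(dCt of the calibrator group)` and the relative
#' expression is `2^(-ddCt)`. Dispersion is propagated from the replicate
#' s.d. of dCt as the fold range `2^-(ddCt +/- s.d.)`. Ct values above 40
#' cycles (or `NA`) encode undetected expression and are treated as
#' missing, never imputed; an undetected target in the calibrator group is
#' an error because the fold is then undefined.
#'
#' @param records data frame with columns `group`, `ct_target`,
#'   `ct_reference`.
#' @param calibrator_group group label the folds are relative to.
#' @param undetected_ct Ct threshold above which a reading counts as
#'   undetected (default 40 cycles).
#' @return data frame per group: `group`, `n`, `delta_ct_mean`,
#'   `delta_ct_sd`, `ddct`, `fold`, `fold_lo`, `fold_hi`.
#' @export
delta_delta_ct <- function(records, calibrator_group, undetected_ct = 40) {
  records <- as.data.frame(records)
  if (!calibrator_group %in% records$group)
    stop(sprintf("calibrator group '%s' not present", calibrator_group),
         call. = FALSE)
  mask <- function(x) ifelse(is.na(x) | x > undetected_ct, NA_real_, x)
  dct <- mask(records$ct_target) - mask(records$ct_reference)
  by_group <- split(dct, records$group)
  cal <- by_group[[calibrator_group]]
  if (all(is.na(cal)))
    stop("target undetected in the calibrator group: fold undefined",
         call. = FALSE)
  cal_mean <- mean(cal, na.rm = TRUE)
  out <- do.call(rbind, lapply(names(by_group), function(g) {
    x <- by_group[[g]][!is.na(by_group[[g]])]
    m <- mean(x); s <- if (length(x) > 1L) stats::sd(x) else 0
    ddct <- m - cal_mean
    data.frame(group = g, n = length(x), delta_ct_mean = m,
               delta_ct_sd = s, ddct = ddct, fold = 2^(-ddct),
               fold_lo = 2^(-(ddct + s)), fold_hi = 2^(-(ddct - s)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Dual-reporter (luciferase/alkaline-phosphatase) normalization
#'
#' The secreted luciferase signal is divided by the co-transfected
#' alkaline-phosphatase signal to normalize for transfection efficiency;
#' fold is the normalized activity relative to the control pair. The fold
#' is invariant to rescaling both channels of a sample by a common factor.
#'
#' @param gluc,seap luciferase and phosphatase readouts (vectors allowed;
#'   `seap` must be positive).
#' @param control_gluc,control_seap the control pair.
#' @return data frame `activity`, `fold`.
#' @export
reporter_normalize <- function(gluc, seap, control_gluc, control_seap) {
  if (any(seap <= 0) || control_seap <= 0)
    stop("SEAP readout must be > 0", call. = FALSE)
  activity <- gluc / seap
  data.frame(activity = activity,
             fold = activity / (control_gluc / control_seap))
}

#' Percent-positive fold comparison between two groups of replicates
#'
#' Converts positive/total event counts per replicate into percentages,
#' reports the ratio of group mean percentages (second group over first)
#' and a two-sided pooled-variance Student's t-test on the replicate
#' percentages. Swapping the groups inverts the fold.
#'
#' @param counts_pos,counts_total integer vectors per replicate
#'   (`0 <= pos <= total`, totals > 0).
#' @param group group label per replicate (exactly two distinct labels,
#'   >= 2 replicates each); the first label in order of appearance is the
#'   reference.
#' @return list with `percents` (per-replicate table), `groups`, `fold`
#'   (mean percent of group 2 over group 1) and `p`.
#' @export
percent_positive_fold <- function(counts_pos, counts_total, group) {
  if (any(counts_total <= 0))
    stop("zero-total replicate", call. = FALSE)
  if (any(counts_pos < 0 | counts_pos > counts_total))
    stop("positives must lie in [0, total]", call. = FALSE)
  labs <- unique(group)
  if (length(labs) != 2L)
    stop("exactly two groups are required", call. = FALSE)
  pct <- 100 * counts_pos / counts_total
  a <- pct[group == labs[1]]; b <- pct[group == labs[2]]
  if (length(a) < 2L || length(b) < 2L)
    stop("need >= 2 replicates per group", call. = FALSE)
  tt <- row_t_test(matrix(a, nrow = 1), matrix(b, nrow = 1))
  list(percents = data.frame(group = group, percent = pct,
                             stringsAsFactors = FALSE),
       groups = labs, fold = mean(b) / mean(a), p = tt$p)
}
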