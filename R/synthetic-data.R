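#' Simulation configuration for the synthetic cross-omics study
#'
#' Bundles and validates every knob of the synthetic-data generators. The
#' defaults emulate the design of the motivating study: three conditions
#' (non-transfected control, wild-type construct, mutant construct) with
#' eight biological replicates each on the transcript side, and an 8-plex
#' reporter-ion experiment (3 wild-type + 3 mutant + 2 control channels) on
#' the protein side. Planted mutant-vs-wild-type effects are supplied as an
#' `effect_table` and echoed back in a truth table so downstream detection
#' can be scored against known truth.
#'
#' @param n_genes number of features (genes, or proteins for the PSM
#'   generator).
#' @param n_replicates biological replicates per condition (>= 2).
#' @param baseline_mean_log mean of the log-scale baseline expression (the
#'   expected wild-type count is roughly `exp(baseline_mean_log)` times the
#'   lognormal correction).
#' @param baseline_sd_log s.d. of the log-scale baseline, controlling the
#'   spread of expression levels across genes.
#' @param dispersion negative-binomial dispersion `d` in
#'   `var = mu + d * mu^2` (> 0).
#' @param background_fraction share of a construct-responsive gene's
#'   wild-type mean present in the non-transfected control (in [0, 1]);
#'   genes without a planted effect are background transcripts, present
#'   identically in every condition.
#' @param effect_table `NULL` or a data frame with columns `feature_id`,
#'   `log2_effect` and optionally `tier`; planted mutant-vs-wild-type
#'   effects. Mutant means equal wild-type means scaled by
#'   `2^log2_effect`.
#' @param gene_length_range integer interval (bp) for simulated transcript
#'   lengths.
#' @param size_factor_sd lognormal s.d. of per-sample library-size jitter.
#' @param psm_base_log log-scale mean reporter intensity of a protein.
#' @param n_peptides_range,n_spectra_range integer ranges for peptides per
#'   protein and spectra per peptide.
#' @param spectrum_noise_sd s.d. of the lognormal multiplicative noise
#'   applied per spectrum and channel.
#' @param spectrum_efficiency_sd s.d. of the lognormal per-spectrum
#'   ionization-efficiency factor shared across channels.
#' @param effect_abundance_quantiles interval of the abundance
#'   distribution from which planted proteins' baselines are drawn.
#'   Construct-responsive signal proteins are modelled as mid-abundance
#'   (the default central 80 percent): rank-based quantile normalization
#'   erases fold changes of proteins pinned at the extreme ranks of the
#'   dynamic range, so planting effects there would simulate a signal the
#'   quantification method cannot, even in principle, see.
#' @param interference_exceed_fraction fraction of PSM rows whose
#'   isolation interference is drawn at or above 30 percent (and so fail
#'   the strict `< 30` filter downstream).
#' @param qvalue_exceed_fraction fraction of PSM rows with q-value above
#'   0.01.
#' @param rank_exceed_fraction fraction of PSM rows with peptide rank > 1.
#' @param seed integer seed; identical configurations give bitwise
#'   identical output.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_genes,
                       n_replicates = 8L,
                       baseline_mean_log = log(500),
                       baseline_sd_log = 1,
                       dispersion = 0.05,
                       background_fraction = 0.1,
                       effect_table = NULL,
                       gene_length_range = c(500L, 5000L),
                       size_factor_sd = 0.1,
                       psm_base_log = log(1e5),
                       n_peptides_range = c(1L, 10L),
                       n_spectra_range = c(1L, 5L),
                       spectrum_noise_sd = 0.25,
                       spectrum_efficiency_sd = 0.5,
                       interference_exceed_fraction = 0.1,
                       qvalue_exceed_fraction = 0.03,
                       rank_exceed_fraction = 0.02,
                       effect_abundance_quantiles = c(0.1, 0.9),
                       seed = 1L) {
  if (!is.numeric(n_genes) || length(n_genes) != 1L || n_genes < 1)
    stop_config("n_genes", "must be a positive integer")
  if (!is.numeric(n_replicates) || n_replicates < 2)
    stop_config("n_replicates", "must be >= 2 (tests need replicates)")
  if (!is.numeric(dispersion) || dispersion <= 0)
    stop_config("dispersion", "must be > 0")
  if (!is.numeric(background_fraction) ||
      background_fraction < 0 || background_fraction > 1)
    stop_config("background_fraction", "must lie in [0, 1]")
  if (length(gene_length_range) != 2L || any(gene_length_range < 1) ||
      gene_length_range[1] > gene_length_range[2])
    stop_config("gene_length_range", "must be a positive increasing interval")
  for (f in c("interference_exceed_fraction", "qvalue_exceed_fraction",
              "rank_exceed_fraction")) {
    v <- get(f)
    if (!is.numeric(v) || v < 0 || v > 1) stop_config(f, "must lie in [0, 1]")
  }
  if (!is.null(effect_table)) {
    if (!is.data.frame(effect_table) ||
        !all(c("feature_id", "log2_effect") %in% names(effect_table)))
      stop_config("effect_table",
                  "needs columns 'feature_id' and 'log2_effect'")
    if (anyDuplicated(effect_table$feature_id))
      stop_config("effect_table", "duplicated feature_id")
  }
  cfg <- list(
    n_genes = as.integer(n_genes), n_replicates = as.integer(n_replicates),
    baseline_mean_log = baseline_mean_log, baseline_sd_log = baseline_sd_log,
    dispersion = dispersion, background_fraction = background_fraction,
    effect_table = effect_table,
    gene_length_range = as.integer(gene_length_range),
    size_factor_sd = size_factor_sd, psm_base_log = psm_base_log,
    n_peptides_range = as.integer(n_peptides_range),
    n_spectra_range = as.integer(n_spectra_range),
    spectrum_noise_sd = spectrum_noise_sd,
    spectrum_efficiency_sd = spectrum_efficiency_sd,
    interference_exceed_fraction = interference_exceed_fraction,
    qvalue_exceed_fraction = qvalue_exceed_fraction,
    rank_exceed_fraction = rank_exceed_fraction,
    effect_abundance_quantiles = effect_abundance_quantiles,
    seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

sim_feature_ids <- function(n) sprintf("gene%05d", seq_len(n))

check_effect_ids <- function(cfg, ids) {
  if (is.null(cfg$effect_table)) return(invisible())
  bad <- setdiff(cfg$effect_table$feature_id, ids)
  if (length(bad))
    stop_config("effect_table", paste0(
      "feature_id not among generated features: ",
      paste(utils::head(bad, 3), collapse = ", ")))
}

truth_from_effects <- function(ids, effect_table, layer_tier) {
  truth <- data.frame(feature_id = ids, true_log2fc = 0,
                      tier = "null", stringsAsFactors = FALSE)
  if (!is.null(effect_table)) {
    i <- match(effect_table$feature_id, ids)
    truth$true_log2fc[i] <- effect_table$log2_effect
    truth$tier[i] <- if ("tier" %in% names(effect_table))
      as.character(effect_table$tier) else layer_tier
    truth$tier[i][effect_table$log2_effect == 0] <- "null"
  }
  truth
}

#' Simulate a negative-binomial RNA-Seq count matrix with planted effects
#'
#' Gene baselines are lognormal; wild-type sample means equal the baseline
#' and mutant means equal the wild-type means scaled by `2^log2_effect`.
#' The non-transfected control emulates a background transcriptome: genes
#' without a planted effect are the cell's own transcripts and are present
#' identically in all three conditions, while construct-responsive genes
#' (the rows of `effect_table`) are present in the control at only
#' `background_fraction` of their wild-type mean. This is what makes
#' background subtraction and the "above background" filter of the count
#' route meaningful: after any per-sample normalization the unchanged
#' majority pins the scale, and responsive genes stand above control.
#' Counts are negative binomial with `var = mu + dispersion * mu^2` after
#' per-sample lognormal library-size jitter.
#'
#' @param cfg a [sim_config()].
#' @return a list with `counts` (a [count_matrix()]) and `truth` (a data
#'   frame `feature_id`, `true_log2fc`, `tier`).
#' @export
simulate_rnaseq_counts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  ids <- sim_feature_ids(cfg$n_genes)
  check_effect_ids(cfg, ids)
  with_seed(cfg$seed, {
    nrep <- cfg$n_replicates
    base <- exp(stats::rnorm(cfg$n_genes, cfg$baseline_mean_log,
                             cfg$baseline_sd_log))
    eff <- rep(0, cfg$n_genes)
    ctrl_share <- rep(1, cfg$n_genes)
    if (!is.null(cfg$effect_table)) {
      planted <- match(cfg$effect_table$feature_id, ids)
      eff[planted] <- cfg$effect_table$log2_effect
      ctrl_share[planted] <- cfg$background_fraction
    }
    mu <- cbind(
      matrix(base * ctrl_share, cfg$n_genes, nrep),              # control
      matrix(base, cfg$n_genes, nrep),                           # wild type
      matrix(base * 2^eff, cfg$n_genes, nrep))                   # mutant
    sf <- exp(stats::rnorm(3L * nrep, 0, cfg$size_factor_sd))
    mu <- sweep(mu, 2L, sf, `*`)
    counts <- matrix(
      stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$dispersion),
      nrow = cfg$n_genes)
    samples <- data.frame(
      sample_id = paste0(rep(c("CNT", "WT", "MUT"), each = nrep),
                         "-", rep(seq_len(nrep), 3L)),
      condition = rep(c("control", "wildtype", "mutant"), each = nrep),
      replicate = rep(seq_len(nrep), 3L), stringsAsFactors = FALSE)
    dimnames(counts) <- list(ids, samples$sample_id)
    lengths <- as.integer(round(stats::runif(
      cfg$n_genes, cfg$gene_length_range[1], cfg$gene_length_range[2])))
    list(counts = count_matrix(counts, lengths, samples),
         truth = truth_from_effects(ids, cfg$effect_table, "transcript_only"))
  })
}

#' Default 8-plex channel layout
#'
#' Three wild-type, three mutant and two non-transfected control channels,
#' the layout of the simulated reporter-ion experiments.
#' @return data frame with columns `channel`, `condition`, `replicate`.
#' @export
default_channel_map <- function() {
  data.frame(
    channel = paste0("ch", 1:8),
    condition = c(rep("wildtype", 3), rep("mutant", 3), rep("control", 2)),
    replicate = c(1:3, 1:3, 1:2), stringsAsFactors = FALSE)
}

#' Simulate a PSM-level reporter-intensity table with planted effects
#'
#' Each protein gets 1-10 peptides with 1-5 spectra each. Channel-level true
#' abundances follow the condition layout of [default_channel_map()];
#' planted effects scale the mutant channels multiplicatively at the protein
#' level, while noise is lognormal at the spectrum level, so median
#' aggregation over spectra is the natural de-noiser. Configurable fractions
#' of rows carry >= 30 percent isolation interference, q-values above 0.01,
#' or peptide rank > 1, to exercise the PSM filter.
#'
#' @param cfg a [sim_config()]; `n_genes` is the number of proteins.
#' @param platform_label label stored on the output (e.g. `"itraq"`).
#' @return list with `psms` (data frame, one row per PSM) and `truth`.
#' @export
simulate_psm_table <- function(cfg, platform_label = "itraq") {
  stopifnot(inherits(cfg, "sim_config"))
  ids <- sim_feature_ids(cfg$n_genes)
  check_effect_ids(cfg, ids)
  chan <- default_channel_map()
  with_seed(cfg$seed + 1L, {
    eff <- rep(0, cfg$n_genes)
    u <- stats::runif(cfg$n_genes)
    if (!is.null(cfg$effect_table)) {
      planted <- match(cfg$effect_table$feature_id, ids)
      eff[planted] <- cfg$effect_table$log2_effect
      qr <- cfg$effect_abundance_quantiles
      u[planted] <- qr[1] + (qr[2] - qr[1]) * u[planted]
    }
    base <- exp(cfg$psm_base_log + stats::qnorm(u))
    npep <- sample(seq(cfg$n_peptides_range[1], cfg$n_peptides_range[2]),
                   cfg$n_genes, replace = TRUE)
    nspec <- sample(seq(cfg$n_spectra_range[1], cfg$n_spectra_range[2]),
                    sum(npep), replace = TRUE)
    pep_protein <- rep(seq_len(cfg$n_genes), npep)     # protein per peptide
    pep_idx <- sequence(npep)
    row_protein <- rep(pep_protein, nspec)             # protein per PSM row
    n <- length(row_protein)
    spec_idx <- sequence(as.vector(rowsum(nspec, pep_protein)))
    chmean <- outer(base, rep(1, 8L))                  # protein x channel
    chmean[, chan$condition == "mutant"] <-
      base * 2^eff
    chmean[, chan$condition == "control"] <-
      base * cfg$background_fraction
    effic <- exp(stats::rnorm(n, 0, cfg$spectrum_efficiency_sd))
    noise <- matrix(exp(stats::rnorm(n * 8L, 0, cfg$spectrum_noise_sd)),
                    n, 8L)
    intens <- chmean[row_protein, , drop = FALSE] * effic * noise
    colnames(intens) <- chan$channel
    psms <- data.frame(
      protein_id = ids[row_protein],
      peptide_seq = sprintf("%s_pep%02d", ids[rep(pep_protein, nspec)],
                            rep(pep_idx, nspec)),
      spectrum_id = sprintf("%s_sp%03d", ids[row_protein], spec_idx),
      stringsAsFactors = FALSE)
    psms <- cbind(psms, as.data.frame(intens))
    exceed <- stats::runif(n) < cfg$interference_exceed_fraction
    psms$interference_pct <- ifelse(exceed, stats::runif(n, 30, 100),
                                    stats::runif(n, 0, 30))
    qx <- stats::runif(n) < cfg$qvalue_exceed_fraction
    psms$q_value <- ifelse(qx, stats::runif(n, 0.0101, 0.2),
                           stats::runif(n, 0, 0.01))
    psms$rank <- ifelse(stats::runif(n) < cfg$rank_exceed_fraction, 2L, 1L)
    psms <- psms[c("protein_id", "peptide_seq", "spectrum_id", "rank",
                   "q_value", "interference_pct", chan$channel)]
    attr(psms, "channel_map") <- chan
    attr(psms, "platform") <- platform_label
    list(psms = psms,
         truth = truth_from_effects(ids, cfg$effect_table, "protein_only"))
  })
}

#' Merge per-layer truth tables into joint cross-omics tiers
#'
#' Features with nonzero planted effects in both layers (and equal sign)
#' become tier `both`; effects in a single layer become `transcript_only`
#' or `protein_only`; everything else is `null`. Opposite-sign effects in
#' the two layers raise an error, since such a feature has no consistent
#' joint truth.
#'
#' @param rna_truth,psm_truth truth tables from the two generators.
#' @return joint truth table over the union of feature ids.
#' @export
joint_truth <- function(rna_truth, psm_truth) {
  ids <- union(rna_truth$feature_id, psm_truth$feature_id)
  r <- rna_truth$true_log2fc[match(ids, rna_truth$feature_id)]
  p <- psm_truth$true_log2fc[match(ids, psm_truth$feature_id)]
  r[is.na(r)] <- 0; p[is.na(p)] <- 0
  if (any(r * p < 0))
    stop("opposite-sign planted effects in the two layers", call. = FALSE)
  tier <- ifelse(r != 0 & p != 0, "both",
          ifelse(r != 0, "transcript_only",
          ifelse(p != 0, "protein_only", "null")))
  data.frame(feature_id = ids,
             true_log2fc = ifelse(r != 0, r, p),
             tier = tier, stringsAsFactors = FALSE)
}

#' Gene-drop simulation of a pedigree under a linked diallelic disease locus
#'
#' Founder haplotypes (disease allele, marker allele) are drawn from the
#' stated population frequencies in linkage equilibrium; each transmission
#' picks a parental haplotype for the disease locus at random and carries
#' the same haplotype's marker allele with probability `1 - theta`,
#' recombining with probability `theta`. Affection status is deterministic
#' under full recessive penetrance: affected iff homozygous for the disease
#' allele.
#'
#' @param structure data frame with columns `id`, `father`, `mother`
#'   (0 = founder) and optionally `sex` (1 male, 2 female).
#' @param theta recombination fraction in [0, 0.5].
#' @param marker_allele_freqs probability vector over marker alleles.
#' @param disease_allele_freq population frequency of the disease allele.
#' @param seed integer seed.
#' @return a `linkage_pedigree` (see [parse_linkage_ped()]) with attributes
#'   `n_recombinations` (count of recombinant meioses) and
#'   `disease_genotype` (copies of the disease allele per individual).
#' @export
simulate_pedigree <- function(structure, theta, marker_allele_freqs,
                              disease_allele_freq, seed = 1L) {
  if (theta < 0 || theta > 0.5)
    stop_config("theta", "must lie in [0, 0.5]")
  if (abs(sum(marker_allele_freqs) - 1) > 1e-9)
    stop_config("marker_allele_freqs", "must sum to 1")
  if (disease_allele_freq <= 0 || disease_allele_freq >= 1)
    stop_config("disease_allele_freq", "must lie in (0, 1)")
  st <- as.data.frame(structure)
  if (is.null(st$sex)) st$sex <- 0L
  one_parent <- xor(st$father == 0, st$mother == 0)
  if (any(one_parent))
    stop(sprintf("pedigree error: individual '%s' has exactly one parent",
                 st$id[which(one_parent)[1]]), call. = FALSE)
  ord <- pedigree_topological_order(st$id, st$father, st$mother)
  m <- length(marker_allele_freqs)
  with_seed(seed + 2L, {
    hap_d <- hap_m <- matrix(NA_integer_, nrow(st), 2,
                             dimnames = list(st$id, NULL))
    nrec <- 0L
    for (i in ord) {
      if (st$father[i] == 0) {                      # founder
        hap_d[i, ] <- stats::rbinom(2, 1, disease_allele_freq)
        hap_m[i, ] <- sample.int(m, 2, replace = TRUE,
                                 prob = marker_allele_freqs)
      } else {
        for (k in 1:2) {
          par <- match(if (k == 1) st$father[i] else st$mother[i], st$id)
          pick <- sample.int(2, 1)
          rec <- stats::runif(1) < theta
          other <- 3L - pick
          hap_d[i, k] <- hap_d[par, pick]
          hap_m[i, k] <- hap_m[par, if (rec) other else pick]
          if (rec) nrec <- nrec + 1L
        }
      }
    }
    disease_copies <- rowSums(hap_d)
    ped <- data.frame(
      famid = 1L, id = st$id, father = st$father, mother = st$mother,
      sex = st$sex,
      affection = ifelse(disease_copies == 2L, 2L, 1L),
      a1 = hap_m[, 1], a2 = hap_m[, 2], stringsAsFactors = FALSE)
    ped <- new_linkage_pedigree(ped)
    attr(ped, "n_recombinations") <- nrec
    attr(ped, "disease_genotype") <- stats::setNames(disease_copies, st$id)
    ped
  })
}

#' Simulate a qPCR Ct table with a planted fold change
#'
#' Target Ct equals the calibrator-group target Ct minus `log2(true_fold)`
#' plus Gaussian noise on the cycle scale; reference-gene Ct is
#' `ct_ref_mean` plus noise. The first group in `groups` is the calibrator.
#'
#' @param groups data frame with columns `label`, `true_fold` (> 0), `n`.
#' @param ct_ref_mean mean reference-gene Ct (cycles).
#' @param ct_target_mean calibrator-group mean target Ct (cycles).
#' @param noise_sd Gaussian noise s.d. on the Ct scale.
#' @param seed integer seed.
#' @return data frame `sample`, `group`, `ct_target`, `ct_reference`.
#' @export
simulate_ct_table <- function(groups, ct_ref_mean = 18,
                              ct_target_mean = 25, noise_sd = 0.2,
                              seed = 1L) {
  groups <- as.data.frame(groups)
  if (any(groups$true_fold <= 0))
    stop_config("true_fold", "must be > 0")
  with_seed(seed + 3L, {
    out <- lapply(seq_len(nrow(groups)), function(i) {
      n <- groups$n[i]
      data.frame(
        sample = sprintf("%s_%d", groups$label[i], seq_len(n)),
        group = groups$label[i],
        ct_target = ct_target_mean - log2(groups$true_fold[i]) +
          stats::rnorm(n, 0, noise_sd),
        ct_reference = ct_ref_mean + stats::rnorm(n, 0, noise_sd),
        stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}
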