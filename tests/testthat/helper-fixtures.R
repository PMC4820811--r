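# Shared fixture builders. Everything is generated in code at test time.

# 20 planted mutant-vs-wild-type effects at +/-2 log2 among 2,000 genes:
# the default transcript study conditions.
default_rna_effects <- function(n_effects = 20, magnitude = 2) {
  data.frame(feature_id = sprintf("gene%05d", seq_len(n_effects)),
             log2_effect = rep(c(magnitude, -magnitude),
                               length.out = n_effects),
             stringsAsFactors = FALSE)
}

make_rna_fixture <- function(seed, n_genes = 2000, dispersion = 0.05,
                             effect_table = default_rna_effects()) {
  cfg <- sim_config(n_genes = n_genes, effect_table = effect_table,
                    dispersion = dispersion, seed = seed)
  simulate_rnaseq_counts(cfg)
}

# Joint cross-omics fixture: 8 tier-both, 6 transcript-only and 6
# protein-only planted features at +/-2; clean PSMs (the low-noise joint
# conditions) so no planted protein is lost to the contamination filter.
make_joint_fixture <- function(seed) {
  ids <- sprintf("gene%05d", 1:2000)
  both <- ids[1:8]; tonly <- ids[9:14]; ponly <- ids[15:20]
  sgn <- rep(c(2, -2), length.out = 8)
  eff_rna <- data.frame(feature_id = c(both, tonly),
                        log2_effect = c(sgn, rep(c(2, -2), 3)),
                        tier = c(rep("both", 8), rep("transcript_only", 6)))
  eff_psm <- data.frame(feature_id = c(both, ponly),
                        log2_effect = c(sgn, rep(c(2, -2), 3)),
                        tier = c(rep("both", 8), rep("protein_only", 6)))
  rna <- simulate_rnaseq_counts(
    sim_config(2000, effect_table = eff_rna, dispersion = 0.02,
               seed = seed))
  psm <- simulate_psm_table(
    sim_config(500, effect_table = eff_psm, spectrum_noise_sd = 0.15,
               interference_exceed_fraction = 0,
               qvalue_exceed_fraction = 0, rank_exceed_fraction = 0,
               seed = seed + 500))
  list(rna = rna, psm = psm, truth = joint_truth(rna$truth, psm$truth))
}

# Phase-known double-backcross under a fully penetrant dominant model:
# affected grandfather homozygous for marker allele 1, unaffected
# grandmother 2/2, so the affected parent is D-1 / d-2 with known phase;
# the spouse is unaffected 3/3. Children with marker 1/3 + affected or
# 2/3 + unaffected are non-recombinant meioses; `recomb` children are
# made obligate recombinants (affected with marker 2/3).
backcross_pedigree <- function(n, recomb = 0) {
  kids <- data.frame(famid = 1, id = 5:(4 + n), father = 3, mother = 4,
                     sex = 1, affection = 2, a1 = 1, a2 = 3)
  if (recomb > 0) kids$a1[seq_len(recomb)] <- 2
  new_linkage_pedigree(rbind(
    data.frame(famid = 1, id = 1, father = 0, mother = 0, sex = 1,
               affection = 2, a1 = 1, a2 = 1),
    data.frame(famid = 1, id = 2, father = 0, mother = 0, sex = 2,
               affection = 1, a1 = 2, a2 = 2),
    data.frame(famid = 1, id = 3, father = 1, mother = 2, sex = 1,
               affection = 2, a1 = 1, a2 = 2),
    data.frame(famid = 1, id = 4, father = 0, mother = 0, sex = 2,
               affection = 1, a1 = 3, a2 = 3),
    kids))
}

dominant_model <- function() disease_model(0.001, c(0, 1, 1))

# Random small pedigree with genotypes from a gene drop, for the
# peeling-vs-enumeration equivalence checks. Resamples (deterministically)
# until the pruned enumeration space is small enough to brute-force.
random_typed_pedigree <- function(seed, max_members = 8) {
  templates <- list(
    data.frame(id = 1:3, father = c(0, 0, 1), mother = c(0, 0, 2)),
    data.frame(id = 1:5, father = c(0, 0, 1, 1, 1),
               mother = c(0, 0, 2, 2, 2)),
    data.frame(id = 1:6, father = c(0, 0, 1, 0, 3, 3),
               mother = c(0, 0, 2, 0, 4, 4)),
    data.frame(id = 1:8, father = c(0, 0, 1, 1, 0, 3, 4, 4),
               mother = c(0, 0, 2, 2, 0, 5, 5, 5)),
    data.frame(id = 1:7, father = c(0, 0, 0, 1, 1, 3, 3),
               mother = c(0, 0, 0, 2, 2, 4, 4)))
  for (try in 0:200) {
    s <- seed * 131L + try * 17L
    tpl <- templates[[1 + (s %% length(templates))]]
    m <- 2 + (s %% 3)                       # 2-4 marker alleles
    freqs <- rep(1 / m, m)
    dfreq <- c(0.2, 0.35, 0.5)[1 + (s %% 3)]
    ped <- simulate_pedigree(tpl, theta = 0.1 * (s %% 5), freqs, dfreq,
                             seed = s)
    # hide some genotypes/affections to exercise marginalization
    hide <- withr::with_seed(s, stats::runif(nrow(ped)) < 0.15)
    ped$a1[hide] <- ped$a2[hide] <- 0
    ped$affection[withr::with_seed(s + 1, stats::runif(nrow(ped)) < 0.1)] <- 0
    ped <- new_linkage_pedigree(as.data.frame(ped))
    # pruned support size per member (fully penetrant recessive model)
    n_states <- vapply(seq_len(nrow(ped)), function(i) {
      typed <- ped$a1[i] != 0
      het <- typed && ped$a1[i] != ped$a2[i]
      mk <- if (!typed) m^2 else if (het) 2 else 1
      dis <- switch(as.character(ped$affection[i]),
                    "2" = 1, "1" = 3, 4)
      mk * dis
    }, numeric(1))
    if (prod(n_states) <= 5e5 && length(attr(ped, "loops")) == 0)
      return(list(ped = ped, marker_freqs = freqs,
                  dmodel = disease_model(dfreq, c(0, 0, 1))))
  }
  stop("could not build a tractable random pedigree")
}

# Brute-force middle-of-sorted-values median, independent of stats::median.
median_oracle <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

# independent per-row variance for moment checks
row_vars_test <- function(x) apply(x, 1, stats::var)
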