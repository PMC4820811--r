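#' Single-locus disease model for parametric linkage
#'
#' @param disease_allele_freq population frequency of the disease allele,
#'   in (0, 1). The default 0.001 with penetrances `c(0, 0, 1)` is the
#'   fully penetrant autosomal recessive model.
#' @param penetrance probabilities of affection given 0, 1 or 2 copies of
#'   the disease allele.
#' @return object of class `disease_model`.
#' @export
disease_model <- function(disease_allele_freq = 0.001,
                          penetrance = c(0, 0, 1)) {
  if (disease_allele_freq <= 0 || disease_allele_freq >= 1)
    stop("disease_allele_freq must lie in (0, 1)", call. = FALSE)
  if (length(penetrance) != 3L || any(penetrance < 0 | penetrance > 1))
    stop("penetrance must be 3 probabilities", call. = FALSE)
  structure(list(disease_allele_freq = disease_allele_freq,
                 penetrance = as.numeric(penetrance)),
            class = "disease_model")
}

# Order individuals so parents precede children; detects self-ancestry.
pedigree_topological_order <- function(id, father, mother) {
  n <- length(id)
  placed <- rep(FALSE, n)
  ord <- integer(0)
  repeat {
    ready <- !placed & (father == 0 | father %in% id[placed]) &
      (mother == 0 | mother %in% id[placed])
    if (!any(ready)) break
    ord <- c(ord, which(ready))
    placed[ready] <- TRUE
  }
  if (!all(placed))
    stop(sprintf("pedigree error: cyclic parentage involving '%s'",
                 id[which(!placed)[1]]), call. = FALSE)
  ord
}

pedigree_ancestors <- function(ped) {
  ids <- ped$id
  anc <- stats::setNames(vector("list", length(ids)), ids)
  ord <- pedigree_topological_order(ped$id, ped$father, ped$mother)
  for (i in ord) {
    parents <- c(ped$father[i], ped$mother[i])
    parents <- parents[parents != 0]
    anc[[i]] <- unique(c(parents,
                         unlist(anc[as.character(parents)], use.names = FALSE)))
  }
  anc
}

# Consanguinity loops: a mating pair sharing a common ancestor.
pedigree_loops <- function(ped) {
  nf <- ped$father != 0
  pairs <- unique(data.frame(f = ped$father[nf], m = ped$mother[nf]))
  if (!nrow(pairs)) return(list())
  anc <- pedigree_ancestors(ped)
  loops <- list()
  for (k in seq_len(nrow(pairs))) {
    fa <- c(pairs$f[k], anc[[as.character(pairs$f[k])]])
    mo <- c(pairs$m[k], anc[[as.character(pairs$m[k])]])
    shared <- intersect(fa, mo)
    if (length(shared))
      loops[[length(loops) + 1L]] <-
        list(couple = c(pairs$f[k], pairs$m[k]), common_ancestors = shared)
  }
  loops
}

#' Construct and validate a pedigree with marker genotypes
#'
#' @param df data frame with columns `famid`, `id`, `father`, `mother`
#'   (0 = founder), `sex` (1 male, 2 female, 0 unknown), `affection`
#'   (0 unknown, 1 unaffected, 2 affected) and marker alleles `a1`, `a2`
#'   (0 = missing).
#' @return object of class `linkage_pedigree` with attributes `founders`
#'   and `loops` (consanguineous matings with their shared ancestors).
#' @export
new_linkage_pedigree <- function(df) {
  req <- c("famid", "id", "father", "mother", "sex", "affection", "a1", "a2")
  if (!all(req %in% names(df)))
    stop("pedigree needs columns ", paste(req, collapse = ", "),
         call. = FALSE)
  df <- as.data.frame(df)[req]
  if (anyDuplicated(df$id))
    stop("pedigree error: duplicated individual id", call. = FALSE)
  one <- xor(df$father == 0, df$mother == 0)
  if (any(one))
    stop(sprintf("pedigree error: individual '%s' has exactly one parent",
                 df$id[which(one)[1]]), call. = FALSE)
  missing_parent <- setdiff(c(df$father, df$mother), c(0, df$id))
  if (length(missing_parent))
    stop(sprintf("pedigree error: unknown parent id '%s'",
                 missing_parent[1]), call. = FALSE)
  if (any((df$a1 == 0) != (df$a2 == 0)))
    stop("pedigree error: half-missing marker genotype", call. = FALSE)
  pedigree_topological_order(df$id, df$father, df$mother)
  structure(df, class = c("linkage_pedigree", "data.frame"),
            founders = df$id[df$father == 0],
            loops = pedigree_loops(df))
}

#' Parse a pre-makeped LINKAGE pedigree file
#'
#' Whitespace-delimited columns `famid id father mother sex affection
#' allele1 allele2`, one individual per row, 0 for missing values.
#'
#' @param path path to the `.ped` file.
#' @return a `linkage_pedigree` (see [new_linkage_pedigree()]).
#' @export
parse_linkage_ped <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 8L))
    stop(sprintf("malformed pedigree row at line %d: %d fields (need 8)",
                 which(nf < 8L)[1], nf[which(nf < 8L)[1]]), call. = FALSE)
  num <- lapply(fields, function(f) suppressWarnings(as.numeric(f[1:8])))
  badline <- which(vapply(num, anyNA, logical(1)))
  if (length(badline))
    stop(sprintf("malformed pedigree row at line %d", badline[1]),
         call. = FALSE)
  m <- do.call(rbind, num)
  df <- data.frame(famid = m[, 1], id = m[, 2], father = m[, 3],
                   mother = m[, 4], sex = m[, 5], affection = m[, 6],
                   a1 = m[, 7], a2 = m[, 8])
  if (length(unique(df$famid)) != 1L)
    stop("one family per file is supported", call. = FALSE)
  new_linkage_pedigree(df)
}

#' Write a pedigree in pre-makeped LINKAGE format
#'
#' @param ped a `linkage_pedigree`.
#' @param path output path.
#' @export
write_linkage_ped <- function(ped, path) {
  utils::write.table(as.data.frame(ped), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- two-locus likelihood machinery ---------------------------------------
#
# State: ordered two-locus genotypes. A haplotype pairs a disease-locus
# allele (1 = wild type, 2 = disease) with a marker allele (1..m); an
# ordered genotype is (paternal haplotype, maternal haplotype). Founder
# priors are Hardy-Weinberg with linkage equilibrium; transmission
# recombines between the two loci with probability theta; penetrance
# depends on the number of disease alleles.

locus_space <- function(m) {
  nh <- 2L * m
  hap_d <- rep(1:2, each = m)
  hap_a <- rep(seq_len(m), times = 2)
  ng <- nh * nh
  g_pat <- rep(seq_len(nh), each = nh)
  g_mat <- rep(seq_len(nh), times = nh)
  list(m = m, nh = nh, ng = ng, hap_d = hap_d, hap_a = hap_a,
       g_pat = g_pat, g_mat = g_mat,
       n_dis = (hap_d[g_pat] == 2L) + (hap_d[g_mat] == 2L),
       mk1 = hap_a[g_pat], mk2 = hap_a[g_mat],
       hap_index = function(d, a) (d - 1L) * m + a)
}

# P(transmitted haplotype | parent ordered genotype), nh x ng.
transmission_matrix <- function(sp, theta) {
  T <- matrix(0, sp$nh, sp$ng)
  p <- sp$g_pat; q <- sp$g_mat
  add <- function(T, rows, val) {
    idx <- cbind(rows, seq_len(sp$ng))
    T[idx] <- T[idx] + val
    T
  }
  T <- add(T, p, (1 - theta) / 2)
  T <- add(T, q, (1 - theta) / 2)
  T <- add(T, sp$hap_index(sp$hap_d[p], sp$hap_a[q]), theta / 2)
  T <- add(T, sp$hap_index(sp$hap_d[q], sp$hap_a[p]), theta / 2)
  T
}

# Per-individual penetrance x marker-observation weight over all states.
pen_obs_vector <- function(sp, affection, a1, a2, penetrance) {
  pen <- switch(as.character(affection),
                "2" = penetrance[sp$n_dis + 1L],
                "1" = 1 - penetrance[sp$n_dis + 1L],
                rep(1, sp$ng))
  if (a1 == 0 && a2 == 0) return(pen)
  obs <- (sp$mk1 == a1 & sp$mk2 == a2) | (sp$mk1 == a2 & sp$mk2 == a1)
  pen * as.numeric(obs)
}

likelihood_inputs <- function(ped, dmodel, marker_freqs, theta) {
  stopifnot(inherits(ped, "linkage_pedigree"),
            inherits(dmodel, "disease_model"))
  if (theta < 0 || theta > 0.5)
    stop("theta must lie in [0, 0.5]", call. = FALSE)
  if (abs(sum(marker_freqs) - 1) > 1e-9)
    stop("marker allele frequencies must sum to 1", call. = FALSE)
  m <- length(marker_freqs)
  alleles <- c(ped$a1, ped$a2)
  if (any(alleles > m))
    stop("observed marker allele exceeds the frequency vector", call. = FALSE)
  sp <- locus_space(m)
  f <- dmodel$disease_allele_freq
  hap_freq <- c(1 - f, f)[sp$hap_d] * marker_freqs[sp$hap_a]
  prior <- hap_freq[sp$g_pat] * hap_freq[sp$g_mat]
  penobs <- lapply(seq_len(nrow(ped)), function(i)
    pen_obs_vector(sp, ped$affection[i], ped$a1[i], ped$a2[i],
                   dmodel$penetrance))
  support <- lapply(penobs, function(v) which(v > 0))
  list(sp = sp, prior = prior, penobs = penobs, support = support,
       T = transmission_matrix(sp, theta))
}

# ---- Elston-Stewart peeling as greedy min-cost variable elimination -------

f_product <- function(fa, fb, sizes) {
  if (!length(fa$vars))
    return(list(vars = fb$vars, tab = fb$tab * as.numeric(fa$tab)))
  if (!length(fb$vars))
    return(list(vars = fa$vars, tab = fa$tab * as.numeric(fb$tab)))
  vars <- union(fa$vars, fb$vars)
  expand <- function(f) {
    cur <- f$vars
    arr <- f$tab
    miss <- setdiff(vars, cur)
    if (length(miss)) {
      arr <- array(arr, dim = c(sizes[cur], sizes[miss]))
      cur <- c(cur, miss)
    }
    aperm(array(arr, dim = sizes[cur]), match(vars, cur))
  }
  list(vars = vars, tab = expand(fa) * expand(fb))
}

f_sum_out <- function(f, v, sizes) {
  i <- match(v, f$vars)
  if (length(f$vars) == 1L)
    return(list(vars = integer(0), tab = sum(f$tab)))
  keep <- setdiff(seq_along(f$vars), i)
  tab <- apply(array(f$tab, dim = sizes[f$vars]), keep, sum)
  list(vars = f$vars[keep], tab = array(tab, dim = sizes[f$vars[keep]]))
}

peel_likelihood <- function(ped, inp) {
  sup <- inp$support
  if (any(lengths(sup) == 0L)) return(-Inf)
  sizes <- lengths(sup)
  factors <- list()
  for (i in seq_len(nrow(ped))) {
    if (ped$father[i] == 0) {
      factors[[length(factors) + 1L]] <- list(
        vars = i, tab = (inp$prior * inp$penobs[[i]])[sup[[i]]])
    } else {
      fi <- match(ped$father[i], ped$id)
      mi <- match(ped$mother[i], ped$id)
      Tp <- inp$T[inp$sp$g_pat[sup[[i]]], sup[[fi]], drop = FALSE]
      Tm <- inp$T[inp$sp$g_mat[sup[[i]]], sup[[mi]], drop = FALSE]
      u <- inp$penobs[[i]][sup[[i]]]
      tab <- array(0, c(sizes[fi], sizes[mi], sizes[i]))
      for (x in seq_len(sizes[i]))
        tab[, , x] <- outer(Tp[x, ], Tm[x, ]) * u[x]
      factors[[length(factors) + 1L]] <- list(vars = c(fi, mi, i), tab = tab)
    }
  }
  logscale <- 0
  active <- seq_len(nrow(ped))
  while (length(active)) {
    cost <- vapply(active, function(v) {
      vars <- unique(unlist(lapply(factors, function(f)
        if (v %in% f$vars) f$vars else NULL)))
      prod(sizes[vars])
    }, numeric(1))
    v <- active[which.min(cost)]
    touch <- vapply(factors, function(f) v %in% f$vars, logical(1))
    merged <- Reduce(function(a, b) f_product(a, b, sizes), factors[touch])
    merged <- f_sum_out(merged, v, sizes)
    mx <- max(merged$tab)
    if (mx == 0) return(-Inf)
    merged$tab <- merged$tab / mx
    logscale <- logscale + log(mx)
    factors <- c(factors[!touch], list(merged))
    active <- setdiff(active, v)
  }
  scalars <- vapply(factors, function(f) as.numeric(f$tab), numeric(1))
  if (any(scalars == 0)) return(-Inf)
  logscale + sum(log(scalars))
}

# ---- exhaustive enumeration over pruned genotype combinations -------------

enumerate_likelihood <- function(ped, inp, max_combos = 2e6) {
  sup <- inp$support
  if (any(lengths(sup) == 0L)) return(-Inf)
  n_combos <- prod(lengths(sup))
  if (n_combos > max_combos)
    stop(sprintf(
      "enumeration capacity exceeded (%.3g genotype combinations)",
      n_combos), call. = FALSE)
  combos <- as.matrix(expand.grid(sup, KEEP.OUT.ATTRS = FALSE))
  ll <- rep(0, nrow(combos))
  for (i in seq_len(nrow(ped))) {
    gi <- combos[, i]
    if (ped$father[i] == 0) {
      ll <- ll + log(inp$prior[gi] * inp$penobs[[i]][gi])
    } else {
      fi <- match(ped$father[i], ped$id)
      mi <- match(ped$mother[i], ped$id)
      ll <- ll + log(inp$T[cbind(inp$sp$g_pat[gi], combos[, fi])]) +
        log(inp$T[cbind(inp$sp$g_mat[gi], combos[, mi])]) +
        log(inp$penobs[[i]][gi])
    }
  }
  mx <- max(ll)
  if (mx == -Inf) return(-Inf)
  mx + log(sum(exp(ll - mx)))
}

#' Two-locus pedigree likelihood under a parametric disease model
#'
#' Computes the likelihood of the observed affection statuses and marker
#' genotypes, summing over unobserved ordered two-locus genotypes: founder
#' priors are Hardy-Weinberg with linkage equilibrium between disease and
#' marker locus, transmissions recombine with probability `theta`, and
#' penetrance comes from the [disease_model()]. Loopless pedigrees are
#' evaluated by Elston-Stewart peeling (greedy minimum-cost elimination
#' order, log-domain rescaling); pedigrees with consanguinity loops fall
#' back to exhaustive enumeration over support-pruned genotypes, refusing
#' looped problems with more than 10 untyped individuals.
#'
#' @param ped a `linkage_pedigree`.
#' @param dmodel a [disease_model()].
#' @param marker_freqs marker allele frequency vector (sums to 1).
#' @param theta recombination fraction in [0, 0.5].
#' @param method `"auto"` (peeling unless the pedigree has loops),
#'   `"peeling"` or `"enumeration"`.
#' @return natural-log likelihood (`-Inf` for impossible data).
#' @export
pedigree_likelihood <- function(ped, dmodel, marker_freqs, theta,
                                method = c("auto", "peeling",
                                           "enumeration")) {
  method <- match.arg(method)
  inp <- likelihood_inputs(ped, dmodel, marker_freqs, theta)
  looped <- length(attr(ped, "loops")) > 0L
  if (method == "auto") method <- if (looped) "enumeration" else "peeling"
  if (method == "enumeration" && looped) {
    untyped <- sum(ped$a1 == 0 & ped$a2 == 0)
    if (untyped > 10L)
      stop(sprintf(
        "capacity error: looped pedigree with %d untyped individuals",
        untyped), call. = FALSE)
  }
  switch(method,
         peeling = peel_likelihood(ped, inp),
         enumeration = enumerate_likelihood(ped, inp))
}

#' Two-point LOD score and LOD profile
#'
#' `Z(theta) = log10 L(theta) - log10 L(0.5)`: the base-10 log likelihood
#' ratio of linkage at recombination fraction `theta` against free
#' recombination. `Z(0.5)` is exactly 0; `Z(0)` is `-Inf` in the presence
#' of an obligate recombinant.
#'
#' @param ped a `linkage_pedigree`.
#' @param dmodel a [disease_model()].
#' @param marker_freqs marker allele frequency vector.
#' @param theta recombination fraction.
#' @param method likelihood evaluation method, see
#'   [pedigree_likelihood()].
#' @return `lod_score`: the LOD at `theta`.
#' @export
lod_score <- function(ped, dmodel, marker_freqs, theta, method = "auto") {
  l1 <- pedigree_likelihood(ped, dmodel, marker_freqs, theta, method)
  l0 <- pedigree_likelihood(ped, dmodel, marker_freqs, 0.5, method)
  (l1 - l0) / log(10)
}

#' @rdname lod_score
#' @param theta_grid recombination fractions to profile over.
#' @return `lod_profile`: data frame `theta`, `lod`, with attributes
#'   `max_lod` and `argmax_theta`.
#' @export
lod_profile <- function(ped, dmodel, marker_freqs,
                        theta_grid = c(0, 0.01, 0.05, 0.1, 0.2, 0.3,
                                       0.4, 0.5),
                        method = "auto") {
  l0 <- pedigree_likelihood(ped, dmodel, marker_freqs, 0.5, method)
  if (!is.finite(l0))
    warning("observed data are impossible under the model ",
            "(zero likelihood at free recombination)")
  lods <- vapply(theta_grid, function(th)
    (pedigree_likelihood(ped, dmodel, marker_freqs, th, method) - l0) /
      log(10), numeric(1))
  out <- data.frame(theta = theta_grid, lod = lods)
  imax <- which.max(lods)
  attr(out, "max_lod") <- lods[imax]
  attr(out, "argmax_theta") <- theta_grid[imax]
  out
}
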