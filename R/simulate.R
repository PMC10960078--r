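#' Simulation configuration
#'
#' A full recipe for the synthetic-data generator: a structured wild
#' metapopulation (Balding-Nichols model), one of two marker regimes, a
#' garden collection drawn from the wild, per-genotype missingness and
#' sample-private error alleles.
#'
#' Marker regimes mirror the two marker families of ex situ genetic
#' assessments: `"multiallelic"` emulates microsatellite panels (tens of
#' loci, many alleles each, skewed frequency spectra), `"biallelic"`
#' emulates reduced-representation SNP panels (thousands of loci, minor
#' allele frequencies drawn from a Beta skewed toward rare variants so the
#' rare class is populated).
#'
#' @param n_populations number of wild populations.
#' @param n_per_pop diploid individuals per wild population (the classic
#'   seed-sampling standard is framed around 50 per population).
#' @param fst target differentiation F in (0, 1) among wild populations.
#' @param regime `"multiallelic"` or `"biallelic"`.
#' @param n_loci number of loci; defaults to 20 (multiallelic) or 3000
#'   (biallelic).
#' @param k_alleles alleles per multiallelic locus (>= 2).
#' @param dirichlet_alpha symmetric Dirichlet concentration for
#'   multiallelic base frequencies (small values skew the spectrum).
#' @param beta_shape1,beta_shape2 Beta parameters of the biallelic
#'   minor-allele-frequency spectrum; the default Beta(0.3, 3) places
#'   appreciable mass below 1%.
#' @param garden_scheme `"random"`, `"stratified"` (equal per population) or
#'   `"skewed"` (per-population `garden_weights`).
#' @param garden_size number of garden accessions (founder copies).
#' @param garden_weights per-population sampling weights for the skewed
#'   scheme.
#' @param missing_rate overall expected fraction of missing cells.
#' @param missing_heterogeneity Beta concentration of per-sample missing
#'   rates (small = more variable "sequencing depth" across samples).
#' @param error_allele_rate per (sample, locus) probability of a private
#'   artifact allele replacing one copy.
#' @param artifact_locus_rate per (sample, real locus) probability of a
#'   spurious sample-private locus (see [inject_artifact_loci()]).
#' @param min_base_freq reject base-frequency draws with any allele below
#'   this value (0 = off); used to build populations in which every allele
#'   is at least, say, 5% frequent.
#' @param seed integer seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_populations = 4, n_per_pop = 50, fst = 0.10,
                       regime = c("multiallelic", "biallelic"),
                       n_loci = NULL, k_alleles = 8,
                       dirichlet_alpha = 0.5,
                       beta_shape1 = 0.3, beta_shape2 = 3,
                       garden_scheme = c("random", "stratified", "skewed"),
                       garden_size = 50, garden_weights = NULL,
                       missing_rate = 0, missing_heterogeneity = 20,
                       error_allele_rate = 0, artifact_locus_rate = 0,
                       min_base_freq = 0, seed = 1) {
  regime <- match.arg(regime)
  garden_scheme <- match.arg(garden_scheme)
  if (is.null(n_loci))
    n_loci <- if (regime == "multiallelic") 20L else 3000L
  stopifnot(fst > 0, fst < 1, k_alleles >= 2,
            missing_rate >= 0, missing_rate <= 1,
            error_allele_rate >= 0, error_allele_rate <= 1)
  structure(list(n_populations = n_populations, n_per_pop = n_per_pop,
                 fst = fst, regime = regime, n_loci = n_loci,
                 k_alleles = k_alleles, dirichlet_alpha = dirichlet_alpha,
                 beta_shape1 = beta_shape1, beta_shape2 = beta_shape2,
                 garden_scheme = garden_scheme, garden_size = garden_size,
                 garden_weights = garden_weights,
                 missing_rate = missing_rate,
                 missing_heterogeneity = missing_heterogeneity,
                 error_allele_rate = error_allele_rate,
                 artifact_locus_rate = artifact_locus_rate,
                 min_base_freq = min_base_freq, seed = seed),
            class = "sim_config")
}

rdirichlet <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha)
  if (sum(x) == 0) x[which.max(alpha)] <- 1 # degenerate guard
  x / sum(x)
}

#' Ancestral (base) allele frequencies per locus
#'
#' Multiallelic regime: symmetric Dirichlet over `k_alleles` codes per
#' locus (microsatellite-style 3-digit fragment codes). Biallelic regime:
#' minor allele frequency from Beta(`beta_shape1`, `beta_shape2`), so a
#' tunable share of variants is rare (< 1%).
#'
#' @param config a [sim_config()].
#' @return named list (per locus) of named frequency vectors; names are
#'   allele codes.
#' @export
simulate_base_frequencies <- function(config) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  out <- vector("list", config$n_loci)
  names(out) <- sprintf("loc%04d", seq_len(config$n_loci))
  for (j in seq_len(config$n_loci)) {
    repeat {
      if (config$regime == "multiallelic") {
        p <- rdirichlet(rep(config$dirichlet_alpha, config$k_alleles))
        names(p) <- as.character(seq(101, by = 4,
                                     length.out = config$k_alleles))
      } else {
        maf <- stats::rbeta(1, config$beta_shape1, config$beta_shape2)
        maf <- min(maf, 1 - maf) # minor by construction
        maf <- max(maf, 1e-4)    # keep both alleles present
        p <- c(`1` = 1 - maf, `2` = maf)
      }
      if (min(p) >= config$min_base_freq) break
    }
    out[[j]] <- p
  }
  out
}

#' Population frequencies under the Balding-Nichols model
#'
#' For each population and locus, frequencies are drawn from
#' Dirichlet(alpha_a = p_a (1 - F) / F): expectation equals the base
#' frequencies and the expected differentiation among populations is F.
#'
#' @param base output of [simulate_base_frequencies()].
#' @param F differentiation parameter in (0, 1).
#' @param n_populations number of populations.
#' @param seed integer seed.
#' @return list (per population) of lists (per locus) of frequency vectors.
#' @export
simulate_population_frequencies <- function(base, F, n_populations,
                                            seed = 1) {
  stopifnot(F > 0, F < 1)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  scale <- (1 - F) / F
  lapply(seq_len(n_populations), function(k)
    lapply(base, function(p) {
      q <- rdirichlet(p * scale)
      names(q) <- names(p)
      q
    }))
}

#' Draw diploid genotypes under Hardy-Weinberg within populations
#'
#' @param pop_freqs output of [simulate_population_frequencies()].
#' @param n_per_pop individuals per population.
#' @param seed integer seed.
#' @return list with `gm` (a [genotype_matrix()], all individuals wild) and
#'   `partition` (a [sample_partition()] with population labels).
#' @export
simulate_genotypes <- function(pop_freqs, n_per_pop, seed = 1) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  K <- length(pop_freqs)
  L <- length(pop_freqs[[1]])
  N <- K * n_per_pop
  a1 <- matrix(NA_character_, N, L)
  a2 <- matrix(NA_character_, N, L)
  ids <- character(N); popl <- character(N)
  row <- 0L
  for (k in seq_len(K)) {
    for (i in seq_len(n_per_pop)) {
      row <- row + 1L
      ids[row] <- sprintf("W%d_%03d", k, i)
      popl[row] <- paste0("pop", k)
    }
  }
  for (l in seq_len(L)) {
    for (k in seq_len(K)) {
      p <- pop_freqs[[k]][[l]]
      rows <- ((k - 1) * n_per_pop + 1):(k * n_per_pop)
      a1[rows, l] <- sample(names(p), n_per_pop, replace = TRUE, prob = p)
      a2[rows, l] <- sample(names(p), n_per_pop, replace = TRUE, prob = p)
    }
  }
  rownames(a1) <- rownames(a2) <- ids
  colnames(a1) <- colnames(a2) <- names(pop_freqs[[1]])
  gm <- genotype_matrix(a1, a2)
  part <- sample_partition(stats::setNames(rep("wild", N), ids),
                           wild_population = stats::setNames(popl, ids))
  list(gm = gm, partition = part)
}

#' Build a garden collection from wild founders
#'
#' Garden accessions are clonal copies of sampled wild founders (most
#' accessions in living collections are wild-collected individuals; no
#' meiosis is simulated), appended to the matrix as new rows with IDs
#' `G_<founder>`. Founders are drawn without replacement under one of three
#' schemes: uniform `random`, `stratified` (as equal as possible per
#' population) or `skewed` (per-population weights, e.g. weight 0 to leave
#' a population unsampled).
#'
#' @param gm_wild a [genotype_matrix()] of wild individuals.
#' @param partition their [sample_partition()] (wild labels required for
#'   stratified/skewed schemes).
#' @param scheme `"random"`, `"stratified"` or `"skewed"`.
#' @param size number of garden accessions.
#' @param weights per-population weights for `"skewed"` (named or in
#'   population order).
#' @param seed integer seed.
#' @return list with `gm` (wild + garden rows) and `partition` (origins,
#'   wild population labels and `founders`, the map garden ID -> founder).
#' @export
sample_garden <- function(gm_wild, partition,
                          scheme = c("random", "stratified", "skewed"),
                          size, weights = NULL, seed = 1) {
  scheme <- match.arg(scheme)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  w <- wild_ids(gm_wild, partition)
  if (size > length(w))
    stop("garden size exceeds available wild founders (without replacement)")
  if (scheme == "random") {
    founders <- sample(w, size)
  } else {
    pops <- partition$wild_population[w]
    pop_names <- unique(pops)
    if (scheme == "stratified") {
      wt <- stats::setNames(rep(1, length(pop_names)), pop_names)
    } else {
      if (is.null(weights)) stop("skewed scheme needs weights")
      wt <- if (is.null(names(weights)))
        stats::setNames(weights, pop_names) else weights[pop_names]
    }
    # largest-remainder apportionment of `size` among populations
    quota <- size * wt / sum(wt)
    base_n <- floor(quota)
    rem <- size - sum(base_n)
    if (rem > 0) {
      extra <- order(quota - base_n, decreasing = TRUE)[seq_len(rem)]
      base_n[extra] <- base_n[extra] + 1
    }
    founders <- character(0)
    for (p in pop_names) {
      avail <- w[pops == p]
      need <- base_n[[p]]
      if (need > length(avail))
        stop("population ", p, " has too few individuals for its quota")
      if (need > 0) founders <- c(founders, sample(avail, need))
    }
  }
  gids <- paste0("G_", founders)
  ridx <- match(founders, individuals(gm_wild))
  a1 <- rbind(gm_wild$a1, gm_wild$a1[ridx, , drop = FALSE])
  a2 <- rbind(gm_wild$a2, gm_wild$a2[ridx, , drop = FALSE])
  rownames(a1) <- rownames(a2) <- c(individuals(gm_wild), gids)
  gm <- genotype_matrix(a1, a2, source_group = gm_wild$source_group)
  origin <- c(stats::setNames(rep("wild", length(w)), w),
              stats::setNames(rep("garden", length(gids)), gids))
  part <- sample_partition(origin,
                           wild_population = partition$wild_population,
                           excluded = partition$excluded)
  part$founders <- stats::setNames(founders, gids)
  list(gm = gm, partition = part)
}

#' Inject missing genotypes
#'
#' Each sample receives its own missing rate drawn from a Beta with mean
#' `rate` and concentration `heterogeneity` (emulating variable sequencing
#' depth across samples); each cell of that sample is then set missing
#' independently. `rate = 0` is the identity.
#'
#' @param gm a [genotype_matrix()].
#' @param rate expected overall missing fraction in `[0, 1]`.
#' @param heterogeneity Beta concentration (larger = more uniform samples).
#' @param seed integer seed.
#' @return a [genotype_matrix()].
#' @export
inject_missingness <- function(gm, rate, heterogeneity = 20, seed = 1) {
  stopifnot(rate >= 0, rate <= 1)
  if (rate == 0) return(gm)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- n_individuals(gm); L <- n_loci(gm)
  pr <- if (rate >= 1) rep(1, n)
        else stats::rbeta(n, rate * heterogeneity,
                          (1 - rate) * heterogeneity)
  a1 <- gm$a1; a2 <- gm$a2
  drop <- matrix(stats::runif(n * L) < pr, n, L) # recycles pr by row
  a1[drop] <- NA_character_
  a2[drop] <- NA_character_
  genotype_matrix(a1, a2, source_group = gm$source_group, pop = gm$pop)
}

#' Inject sample-private error alleles
#'
#' The de novo assembly artifact mechanism: with probability
#' `error_allele_rate` per (sample, typed locus), one allele copy is
#' replaced by a brand-new code unique to that event, so every artifact is
#' a singleton and (in any reasonably sized sample) lands in the rare
#' (< 1%) frequency class. Injected alleles are recorded in a truth table
#' for downstream evaluation.
#'
#' @param gm a [genotype_matrix()].
#' @param error_allele_rate per (sample, locus) probability.
#' @param seed integer seed.
#' @return a [genotype_matrix()] with attribute `error_truth`, a data frame
#'   (`individual`, `locus`, `allele`) of injected artifacts.
#' @export
inject_error_alleles <- function(gm, error_allele_rate, seed = 1) {
  stopifnot(error_allele_rate >= 0, error_allele_rate <= 1)
  if (error_allele_rate == 0) {
    attr(gm, "error_truth") <- data.frame(individual = character(),
                                          locus = character(),
                                          allele = character())
    return(gm)
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  a1 <- gm$a1; a2 <- gm$a2
  typed <- !is.na(a1)
  hit <- typed & matrix(stats::runif(length(a1)) < error_allele_rate,
                        nrow(a1), ncol(a1))
  idx <- which(hit)
  codes <- paste0("e", seq_along(idx))
  slot1 <- stats::runif(length(idx)) < 0.5
  a1[idx[slot1]] <- codes[slot1]
  a2[idx[!slot1]] <- codes[!slot1]
  out <- genotype_matrix(a1, a2, source_group = gm$source_group,
                         pop = gm$pop)
  rc <- arrayInd(idx, dim(a1))
  attr(out, "error_truth") <- data.frame(
    individual = individuals(gm)[rc[, 1]],
    locus = loci(gm)[rc[, 2]],
    allele = codes)
  out
}

#' Inject sample-private artifact loci
#'
#' The locus-level de novo assembly artifact: sample-specific sequencing
#' error assembled into a spurious new locus, typed only in the sample
#' that generated it and missing everywhere else ("loci largely unshared
#' with other samples"). Each such locus carries a homozygous private
#' allele. Because its presence is 1/N, any missing-data filter with
#' r > 1/N removes it, while an unfiltered (R0) dataset keeps it — the
#' mechanism by which unfiltered de novo datasets deflate ex situ
#' representation and inflate minimum-sample-size estimates.
#'
#' The number of artifact loci per sample is Binomial(`n_loci(gm)`, rate),
#' tying the artifact load to panel size as observed in real de novo
#' datasets.
#'
#' @param gm a [genotype_matrix()].
#' @param rate per (sample, real locus) probability of a spurious locus.
#' @param seed integer seed.
#' @return a [genotype_matrix()] with artifact loci appended; attribute
#'   `artifact_truth` is a data frame (`individual`, `locus`, `allele`).
#' @export
inject_artifact_loci <- function(gm, rate, seed = 1) {
  stopifnot(rate >= 0, rate <= 1)
  empty <- data.frame(individual = character(), locus = character(),
                      allele = character())
  if (rate == 0) {
    attr(gm, "artifact_truth") <- empty
    return(gm)
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- n_individuals(gm); L <- n_loci(gm)
  counts <- stats::rbinom(n, L, rate)
  total <- sum(counts)
  if (total == 0) {
    attr(gm, "artifact_truth") <- empty
    return(gm)
  }
  owner <- rep(seq_len(n), counts)
  locus_id <- sprintf("art%05d", seq_len(total))
  code <- paste0("a", seq_len(total))
  e1 <- matrix(NA_character_, n, total,
               dimnames = list(individuals(gm), locus_id))
  e1[cbind(owner, seq_len(total))] <- code
  a1 <- cbind(gm$a1, e1)
  a2 <- cbind(gm$a2, e1) # homozygous private genotype
  out <- genotype_matrix(a1, a2,
                         source_group = c(gm$source_group,
                                          rep(NA_character_, total)),
                         pop = gm$pop)
  attr(out, "artifact_truth") <- data.frame(
    individual = individuals(gm)[owner],
    locus = locus_id,
    allele = code)
  out
}

#' End-to-end synthetic dataset
#'
#' Chains the generator stages under a single configuration: base
#' frequencies, Balding-Nichols population frequencies, Hardy-Weinberg
#' genotypes, garden sampling, missingness and error alleles. Stage seeds
#' are derived deterministically from `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with `gm`, `partition`, `error_truth`, `config`.
#' @export
simulate_dataset <- function(config) {
  s <- config$seed
  base <- simulate_base_frequencies(config)
  pf <- simulate_population_frequencies(base, config$fst,
                                        config$n_populations,
                                        seed = s + 1L)
  sim <- simulate_genotypes(pf, config$n_per_pop, seed = s + 2L)
  gar <- sample_garden(sim$gm, sim$partition,
                       scheme = config$garden_scheme,
                       size = config$garden_size,
                       weights = config$garden_weights, seed = s + 3L)
  gm <- inject_missingness(gar$gm, config$missing_rate,
                           config$missing_heterogeneity, seed = s + 4L)
  gm <- inject_error_alleles(gm, config$error_allele_rate, seed = s + 5L)
  err <- attr(gm, "error_truth")
  gm <- inject_artifact_loci(gm, config$artifact_locus_rate, seed = s + 6L)
  list(gm = gm, partition = gar$partition,
       error_truth = err,
       artifact_truth = attr(gm, "artifact_truth"),
       config = config)
}
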