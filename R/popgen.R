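# per-locus allele frequency list for a set of individuals
locus_freqs <- function(gm, ids = NULL) {
  g <- if (is.null(ids)) gm else gm_subset(gm, individuals = ids)
  out <- vector("list", n_loci(g))
  names(out) <- loci(g)
  for (j in seq_len(n_loci(g))) {
    v <- c(g$a1[, j], g$a2[, j])
    v <- v[!is.na(v)]
    if (!length(v)) next
    tb <- table(v)
    out[[j]] <- list(p = as.numeric(tb) / sum(tb),
                     counts = as.integer(tb),
                     labels = names(tb),
                     n_ind = length(v) / 2)
  }
  out
}

#' Expected heterozygosity (gene diversity)
#'
#' Per locus h = 1 - sum(p^2) from missing-aware allele frequencies of the
#' chosen group; the reported He is the mean of h over loci with data.
#' The small-sample correction 2n/(2n-1) (n = typed individuals at the
#' locus) is opt-in, since published values mix both conventions.
#'
#' @param gm a [genotype_matrix()].
#' @param ids sample IDs defining the group (`NULL` = all individuals).
#' @param unbiased apply the 2n/(2n-1) correction per locus.
#' @return mean expected heterozygosity in `[0, 1]`, or `NA` if no locus has
#'   data.
#' @export
expected_heterozygosity <- function(gm, ids = NULL, unbiased = FALSE) {
  lf <- locus_freqs(gm, ids)
  h <- vapply(lf, function(x) {
    if (is.null(x)) return(NA_real_)
    hh <- 1 - sum(x$p^2)
    if (unbiased) hh <- hh * 2 * x$n_ind / (2 * x$n_ind - 1)
    hh
  }, 0)
  if (all(is.na(h))) return(NA_real_)
  mean(h, na.rm = TRUE)
}

#' Rarefied allelic richness
#'
#' Expected number of distinct alleles in a random without-replacement
#' draw of g gene copies from a locus's typed copies:
#' AR = sum_a (1 - C(N - N_a, g) / C(N, g)) with N = typed copies and N_a =
#' copies of allele a; group AR is the mean over loci. Loci with fewer than
#' g typed copies in a group are skipped (with a message). The default g is
#' the smallest per-locus typed copy count across the compared groups, the
#' usual rarefy-to-smallest convention.
#'
#' @param gm a [genotype_matrix()].
#' @param groups named list of sample-ID vectors.
#' @param g rarefaction size in gene copies (>= 2).
#' @return named numeric vector of mean rarefied richness per group.
#' @export
allelic_richness <- function(gm, groups, g = NULL) {
  lfs <- lapply(groups, function(ids) locus_freqs(gm, ids))
  if (is.null(g)) {
    copies <- unlist(lapply(lfs, function(lf)
      vapply(lf, function(x) if (is.null(x)) NA_real_ else 2 * x$n_ind, 0)))
    g <- min(copies, na.rm = TRUE)
  }
  if (g < 2) stop("g must be >= 2 gene copies")
  skipped <- 0L
  ar <- vapply(lfs, function(lf) {
    per <- vapply(lf, function(x) {
      if (is.null(x)) return(NA_real_)
      N <- sum(x$counts)
      if (N < g) {
        skipped <<- skipped + 1L
        return(NA_real_)
      }
      sum(1 - exp(lchoose(N - x$counts, g) - lchoose(N, g)))
    }, 0)
    mean(per, na.rm = TRUE)
  }, 0)
  if (skipped > 0)
    message(skipped, " locus-group combinations too sparse for g = ", g,
            "; skipped")
  ar
}

#' Nei pairwise FST among wild populations
#'
#' For every pair of wild populations, per shared typed locus:
#' Hs = mean of the two within-population gene diversities (1 - sum p^2),
#' Ht = gene diversity of the unweighted mean (pooled) allele frequencies;
#' FST = (mean_l Ht - mean_l Hs) / mean_l Ht, a ratio of locus averages
#' rather than an average of per-locus ratios. Slightly negative estimates
#' are reported as computed, not clamped, so means stay unbiased. A
#' sample-size-corrected variant (Nei's Hs correction 2n/(2n-1) per
#' population) is available behind `corrected`.
#'
#' @param gm a [genotype_matrix()].
#' @param partition a [sample_partition()] with `wild_population` labels.
#' @param corrected apply the small-sample gene-diversity correction.
#' @return object of class `fst_result`: list with `matrix` (symmetric, NA
#'   diagonal), `mean` (mean over defined pairs), `estimator` string.
#' @export
pairwise_nei_fst <- function(gm, partition, corrected = FALSE) {
  if (is.null(partition$wild_population))
    stop("partition has no wild_population labels")
  w <- wild_ids(gm, partition)
  pops <- partition$wild_population[w]
  pop_names <- unique(pops)
  if (length(pop_names) < 2) stop("need at least 2 wild populations")
  lf <- lapply(pop_names, function(p) locus_freqs(gm, w[pops == p]))
  names(lf) <- pop_names

  K <- length(pop_names)
  M <- matrix(NA_real_, K, K, dimnames = list(pop_names, pop_names))
  for (i in seq_len(K - 1)) for (j in (i + 1):K) {
    hs <- ht <- numeric(0)
    for (l in seq_len(n_loci(gm))) {
      xi <- lf[[i]][[l]]; xj <- lf[[j]][[l]]
      if (is.null(xi) || is.null(xj)) next
      gd <- function(x) {
        h <- 1 - sum(x$p^2)
        if (corrected) h * 2 * x$n_ind / (2 * x$n_ind - 1) else h
      }
      labs <- union(xi$labels, xj$labels)
      pi_ <- stats::setNames(numeric(length(labs)), labs)
      pj_ <- pi_
      pi_[xi$labels] <- xi$p; pj_[xj$labels] <- xj$p
      pool <- (pi_ + pj_) / 2
      hs <- c(hs, (gd(xi) + gd(xj)) / 2)
      ht <- c(ht, 1 - sum(pool^2))
    }
    if (!length(hs)) next # pair shares no typed locus: undefined
    M[i, j] <- M[j, i] <- (mean(ht) - mean(hs)) / mean(ht)
  }
  structure(list(matrix = M,
                 mean = mean(M[upper.tri(M)], na.rm = TRUE),
                 estimator = paste0("Nei Gst-style (Htbar-Hsbar)/Htbar, ",
                                    "locus-averaged",
                                    if (corrected) ", 2n/(2n-1)-corrected"
                                    else ", uncorrected")),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat("Pairwise FST among wild populations [", x$estimator, "]\n", sep = "")
  print(round(x$matrix, 4))
  cat(sprintf("mean pairwise FST: %.4f\n", x$mean))
  invisible(x)
}

#' Total allele count
#'
#' Number of distinct (locus, allele) pairs with at least one non-missing
#' call among the non-excluded samples.
#'
#' @param gm a [genotype_matrix()].
#' @param partition optional [sample_partition()]; when given, excluded
#'   samples are dropped first.
#' @return integer count.
#' @export
allele_count <- function(gm, partition = NULL) {
  if (!is.null(partition)) gm <- drop_samples(gm, partition)
  sum(lengths(allele_labels(gm)))
}

#' Population-genetic summary table
#'
#' The layout of published marker-comparison statistics tables: per dataset
#' label, sample counts, total allele count, per-group (garden/wild)
#' rarefied allelic richness and expected heterozygosity, and mean pairwise
#' wild FST.
#'
#' @param gm a [genotype_matrix()].
#' @param partition a [sample_partition()].
#' @param g rarefaction size for [allelic_richness()] (`NULL` = auto).
#' @param unbiased_he passed to [expected_heterozygosity()].
#' @param corrected_fst passed to [pairwise_nei_fst()].
#' @return one-row data frame of class `popgen_summary`.
#' @export
popgen_summary <- function(gm, partition, g = NULL, unbiased_he = FALSE,
                           corrected_fst = FALSE) {
  gmx <- drop_samples(gm, partition)
  gard <- garden_ids(gmx, partition)
  wild <- wild_ids(gmx, partition)
  groups <- list(garden = gard, wild = wild)
  groups <- groups[lengths(groups) > 0]
  ar <- suppressMessages(allelic_richness(gmx, groups, g = g))
  fst <- if (!is.null(partition$wild_population) &&
             length(unique(partition$wild_population[wild])) >= 2)
    pairwise_nei_fst(gmx, partition, corrected = corrected_fst)$mean
  else NA_real_
  out <- data.frame(
    n_garden = length(gard),
    n_wild = length(wild),
    allele_count = allele_count(gmx),
    ar_garden = if ("garden" %in% names(ar)) ar[["garden"]] else NA_real_,
    ar_wild = if ("wild" %in% names(ar)) ar[["wild"]] else NA_real_,
    he_garden = if (length(gard))
      expected_heterozygosity(gmx, gard, unbiased = unbiased_he) else NA_real_,
    he_wild = if (length(wild))
      expected_heterozygosity(gmx, wild, unbiased = unbiased_he) else NA_real_,
    mean_pairwise_fst_wild = fst)
  class(out) <- c("popgen_summary", class(out))
  out
}
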