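# Carrier index: for each distinct (locus, allele) of the matrix, the set of
# individuals with at least one non-missing copy. This is the only view of
# the data the resampling engine needs.
carrier_index <- function(gm) {
  n <- n_individuals(gm)
  alleles <- list(); carriers <- list(); k <- 0L
  for (j in seq_len(n_loci(gm))) {
    x1 <- gm$a1[, j]; x2 <- gm$a2[, j]
    labs <- unique(c(x1[!is.na(x1)], x2[!is.na(x2)]))
    for (a in labs) {
      k <- k + 1L
      alleles[[k]] <- c(loci(gm)[j], a)
      carriers[[k]] <- which((!is.na(x1) & x1 == a) |
                             (!is.na(x2) & x2 == a))
    }
  }
  list(alleles = if (k) do.call(rbind, alleles) else
         matrix(character(), 0, 2),
       carriers = carriers, n_individuals = n)
}

#' Allele capture curves by resampling wild individuals
#'
#' For each replicate a uniform random permutation of the wild individuals
#' is drawn; the subsample of size n is the permutation's first n
#' individuals, so subsamples are nested within a replicate and capture is
#' non-decreasing in n. Capture at size n is the percentage of the total
#' wild allele set observed in at least one non-missing call of the
#' subsample. An independent-draws-per-size mode is available for
#' sensitivity analysis.
#'
#' @param gm_wild a [genotype_matrix()] restricted to wild individuals (see
#'   [wild_matrix()]).
#' @param n_replicates number of resampling replicates (the field's
#'   convention is 5000).
#' @param seed integer seed; identical (data, seed, n_replicates) give
#'   bit-identical results.
#' @param nested `TRUE` (default) for nested prefix subsamples; `FALSE`
#'   draws an independent subsample for every size.
#' @return object of class `resampling_curve`: list with `sizes` (2..N),
#'   `capture` (replicates x sizes matrix, percent), `summary` (per-size
#'   mean and SD), `n_replicates`, `seed`, `nested`, and `first_capture`
#'   (alleles x replicates matrix of the subsample size at which each
#'   allele is first captured; nested mode only, used for per-category
#'   curves).
#' @export
capture_curve <- function(gm_wild, n_replicates = 5000, seed = 1,
                          nested = TRUE) {
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  idx <- carrier_index(gm_wild)
  N <- idx$n_individuals
  if (N < 2) stop("need at least 2 wild individuals")
  A <- length(idx$carriers)
  if (A == 0) stop("no alleles observed in wild matrix")
  sizes <- 2:N
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  if (nested) {
    # position of each individual in each replicate's permutation
    pos <- matrix(0L, N, n_replicates)
    for (r in seq_len(n_replicates)) pos[sample.int(N), r] <- seq_len(N)
    first <- matrix(0L, A, n_replicates)
    for (a in seq_len(A)) {
      ca <- idx$carriers[[a]]
      m <- pos[ca[1], ]
      if (length(ca) > 1)
        for (i in ca[-1]) m <- pmin(m, pos[i, ])
      first[a, ] <- m
    }
    capture <- matrix(0, n_replicates, length(sizes))
    for (r in seq_len(n_replicates)) {
      cum <- cumsum(tabulate(first[, r], nbins = N))
      capture[r, ] <- 100 * cum[sizes] / A
    }
  } else {
    first <- NULL
    # individual x allele incidence for subset counting
    carr <- matrix(FALSE, N, A)
    for (a in seq_len(A)) carr[idx$carriers[[a]], a] <- TRUE
    capture <- matrix(0, n_replicates, length(sizes))
    for (r in seq_len(n_replicates)) {
      for (s in seq_along(sizes)) {
        sub <- sample.int(N, sizes[s])
        capture[r, s] <- 100 *
          sum(colSums(carr[sub, , drop = FALSE]) > 0L) / A
      }
    }
  }
  summ <- data.frame(size = sizes,
                     mean = colMeans(capture),
                     sd = apply(capture, 2, stats::sd))
  structure(list(sizes = sizes, capture = capture, summary = summ,
                 n_replicates = n_replicates, seed = seed, nested = nested,
                 n_wild = N, n_alleles = A, alleles = idx$alleles,
                 first_capture = first),
            class = "resampling_curve")
}

#' @export
print.resampling_curve <- function(x, ...) {
  cat(sprintf(
    "resampling_curve: %d wild individuals, %d alleles, %d replicates (%s)\n",
    x$n_wild, x$n_alleles, x$n_replicates,
    if (x$nested) "nested" else "independent per size"))
  cat("  mean capture at selected sizes:\n")
  sel <- unique(round(stats::quantile(seq_along(x$sizes), c(0, .25, .5, .75, 1))))
  print(x$summary[sel, ], row.names = FALSE, digits = 4)
  invisible(x)
}

#' Exact expected capture under without-replacement sampling
#'
#' Closed-form oracle for the mean of the resampling capture curve: for an
#' allele carried by c of N wild individuals, a without-replacement sample
#' of n individuals misses it with hypergeometric probability
#' C(N-c, n)/C(N, n); expected capture is the mean over alleles of one
#' minus that. No randomness is involved.
#'
#' @param gm_wild a [genotype_matrix()] of wild individuals.
#' @param n subsample size, `1 <= n <= N`.
#' @return expected captured fraction of the total wild allele set, in
#'   `[0, 1]`.
#' @export
analytic_expected_capture <- function(gm_wild, n) {
  idx <- carrier_index(gm_wild)
  N <- idx$n_individuals
  if (n > N) stop("n exceeds the number of wild individuals")
  if (n < 1) stop("n must be >= 1")
  cc <- lengths(idx$carriers)
  miss <- exp(lchoose(N - cc, n) - lchoose(N, n))
  miss[N - cc < n] <- 0 # lchoose(<n, n) is -Inf anyway; keep explicit
  mean(1 - miss)
}

#' Minimum wild sample size reaching a capture threshold
#'
#' Per replicate, the smallest subsample size whose capture reaches
#' `100 * threshold` percent of total wild allelic diversity (well-defined
#' under nested subsampling: capture is monotone and reaches 100% at N).
#' The headline statistic is the mean and sample standard deviation (n-1
#' denominator) of these per-replicate minima.
#'
#' @param curve a [capture_curve()] result.
#' @param threshold capture fraction in (0, 1]; default 0.95.
#' @return object of class `min_sample_estimate`: list with `threshold`,
#'   `per_replicate` (integer vector), `mean`, `sd` (NA for a single
#'   replicate), `n_wild`.
#' @export
min_sample_size <- function(curve, threshold = 0.95) {
  if (threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1]")
  target <- 100 * threshold - 1e-9 # guard float representation of percents
  per <- apply(curve$capture, 1, function(v)
    curve$sizes[which(v >= target)[1]])
  structure(list(threshold = threshold,
                 per_replicate = as.integer(per),
                 mean = mean(per),
                 sd = if (length(per) > 1) stats::sd(per) else NA_real_,
                 n_wild = curve$n_wild,
                 n_replicates = curve$n_replicates),
            class = "min_sample_estimate")
}

#' Format a minimum-sample-size cell
#'
#' The conventional "mean ± SD (N)" table cell: integer-rounded mean,
#' 2-decimal SD, number of wild samples in parentheses.
#'
#' @param est a [min_sample_size()] result.
#' @return character scalar, e.g. `"64 ± 0.36 (91)"`.
#' @export
format_min_sample <- function(est) {
  sd_txt <- if (is.na(est$sd)) "NA" else sprintf("%.2f", est$sd)
  sprintf("%d ± %s (%d)", round(est$mean), sd_txt, est$n_wild)
}

#' @export
print.min_sample_estimate <- function(x, ...) {
  cat(sprintf("minimum sample size for %.0f%% of total wild allelic diversity:\n",
              100 * x$threshold))
  cat("  ", format_min_sample(x), "  [", x$n_replicates, " replicates]\n",
      sep = "")
  invisible(x)
}

#' Restrict a matrix to wild, non-excluded individuals
#'
#' @param gm a [genotype_matrix()].
#' @param partition a [sample_partition()].
#' @return a [genotype_matrix()] of the wild samples.
#' @export
wild_matrix <- function(gm, partition) {
  w <- wild_ids(gm, partition)
  if (!length(w)) stop("no wild, non-excluded individuals in matrix")
  gm_subset(gm, individuals = w)
}

#' Resampling report: capture curves per frequency category
#'
#' Runs [capture_curve()] on the wild samples, computes per-size mean
#' capture separately for each frequency category of the wild allele
#' spectrum (the coloured curves of the field's resampling figures), and
#' the "mean ± SD (N)" minimum-sample-size cell for the total category.
#' Categories with zero alleles are omitted with a message.
#'
#' @param gm a [genotype_matrix()].
#' @param partition a [sample_partition()].
#' @param categories a [frequency_categories()] list.
#' @param n_replicates,seed passed to [capture_curve()].
#' @param threshold capture fraction for the minimum-size estimate.
#' @return list with `curve` (the total-category [capture_curve()]),
#'   `category_means` (data frame: size, category, mean_percent),
#'   `min_sample` ([min_sample_size()] result), `cell`
#'   (formatted table cell), `omitted_categories`.
#' @export
resampling_report <- function(gm, partition,
                              categories = frequency_categories(),
                              n_replicates = 5000, seed = 1,
                              threshold = 0.95) {
  gw <- wild_matrix(gm, partition)
  freqs <- wild_allele_frequencies(gm, partition)
  curve <- capture_curve(gw, n_replicates = n_replicates, seed = seed)
  akey <- paste(curve$alleles[, 1], curve$alleles[, 2], sep = "\r")
  fkey <- paste(freqs$locus, freqs$allele, sep = "\r")
  p <- freqs$freq[match(akey, fkey)]

  omitted <- character()
  cm <- list()
  for (cat_ in categories) {
    sel <- in_category(p, cat_)
    if (!any(sel)) {
      omitted <- c(omitted, cat_$name)
      next
    }
    # mean capture of this category's alleles, from first-capture sizes
    counts <- vapply(seq_len(curve$n_replicates), function(r)
      cumsum(tabulate(curve$first_capture[sel, r], nbins = curve$n_wild)),
      numeric(curve$n_wild))
    m <- 100 * rowMeans(counts)[curve$sizes] / sum(sel)
    cm[[cat_$name]] <- data.frame(size = curve$sizes, category = cat_$name,
                                  mean_percent = m)
  }
  if (length(omitted))
    message("categories with zero alleles omitted: ",
            paste(omitted, collapse = ", "))
  est <- min_sample_size(curve, threshold)
  list(curve = curve,
       category_means = do.call(rbind, cm),
       min_sample = est,
       cell = format_min_sample(est),
       omitted_categories = omitted)
}

#' Write resampling outputs
#'
#' Long-format per-size curve file (size, category, mean_percent) plus a
#' one-line summary file carrying the formatted minimum-size cell and run
#' metadata (replicates, seed, threshold, subsampling mode).
#'
#' @param report a [resampling_report()] result.
#' @param path output path for the curve file; summary goes to
#'   `paste0(path, ".summary.tsv")`.
#' @return `path`, invisibly.
#' @export
write_resampling_report <- function(report, path) {
  utils::write.table(report$category_means, path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  summ <- data.frame(threshold = report$min_sample$threshold,
                     mean = report$min_sample$mean,
                     sd = report$min_sample$sd,
                     n_wild = report$min_sample$n_wild,
                     n_replicates = report$curve$n_replicates,
                     seed = report$curve$seed,
                     mode = if (report$curve$nested) "nested" else
                       "independent",
                     cell = report$cell)
  utils::write.table(summ, paste0(path, ".summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# save/restore .Random.seed so seeded engines do not disturb the caller's RNG
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv())
}
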