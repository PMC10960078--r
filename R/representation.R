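#' Wild allele frequencies
#'
#' Counts allele copies among wild, non-excluded individuals only; a
#' homozygote contributes two copies, a missing cell contributes none.
#' Denominators are locus-specific (copies actually typed at that locus),
#' which matters under unfiltered (R0) data where per-locus typing varies
#' widely. Loci with zero typed wild individuals have no defined frequency;
#' they are excluded from the wild allele universe and listed in the
#' `dropped_loci` attribute.
#'
#' @param gm a [genotype_matrix()].
#' @param partition a [sample_partition()].
#' @return data frame of class `wild_allele_freqs` with columns `locus`,
#'   `allele`, `count`, `total`, `freq`; attribute `dropped_loci` lists loci
#'   untyped in the wild sample.
#' @export
wild_allele_frequencies <- function(gm, partition) {
  w <- wild_ids(gm, partition)
  if (!length(w)) stop("no wild, non-excluded individuals in matrix")
  gw <- gm_subset(gm, individuals = w)
  tab <- allele_count_table(gw)
  dropped <- setdiff(loci(gw), unique(tab$locus))
  structure(tab, dropped_loci = dropped, class = c("wild_allele_freqs",
                                                   class(tab)))
}

# per-locus allele copy counts for a matrix (all its individuals)
allele_count_table <- function(gm) {
  res <- vector("list", n_loci(gm))
  for (j in seq_len(n_loci(gm))) {
    v <- c(gm$a1[, j], gm$a2[, j])
    v <- v[!is.na(v)]
    if (!length(v)) next
    tb <- table(v)
    res[[j]] <- data.frame(locus = loci(gm)[j],
                           allele = names(tb),
                           count = as.integer(tb),
                           total = length(v),
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(locus = character(), allele = character(),
                      count = integer(), total = integer())
  out$freq <- out$count / out$total
  rownames(out) <- NULL
  out
}

#' Allele frequency categories
#'
#' The field's conventional, deliberately overlapping classes of wild allele
#' frequency p: very common (p > 0.10), common (p > 0.05), low frequency
#' (0.01 <= p <= 0.10), rare (p < 0.01) and total (p > 0). An allele at
#' p = 0.08 is both common and low frequency; disjointifying would make
#' published category tables irreproducible. Exact boundary assignment
#' (p = 0.01, p = 0.10 fall in low frequency) is a convention of this
#' package, overridable here and echoed in report headers.
#'
#' @param very_common,common,low_frequency,rare,total numeric length-2
#'   vectors `c(lower, upper)`; bounds interpretation per category is fixed:
#'   very_common/common/total are open below and closed above, low_frequency
#'   is closed on both ends, rare is closed below and open above.
#' @return list of category definitions, class `frequency_categories`.
#' @export
frequency_categories <- function(very_common = c(0.10, 1),
                                 common = c(0.05, 1),
                                 low_frequency = c(0.01, 0.10),
                                 rare = c(0, 0.01),
                                 total = c(0, 1)) {
  mk <- function(name, b, lo_inc, hi_inc)
    list(name = name, lower = b[1], upper = b[2],
         lower_inclusive = lo_inc, upper_inclusive = hi_inc)
  structure(list(
    very_common  = mk("very_common", very_common, FALSE, TRUE),
    common       = mk("common", common, FALSE, TRUE),
    low_frequency = mk("low_frequency", low_frequency, TRUE, TRUE),
    rare         = mk("rare", rare, TRUE, FALSE),
    total        = mk("total", total, FALSE, TRUE)),
    class = "frequency_categories")
}

category_label <- function(cat) {
  sprintf("%s: p %s %g and %s %g", cat$name,
          if (cat$lower_inclusive) ">=" else ">", cat$lower,
          if (cat$upper_inclusive) "<=" else "<", cat$upper)
}

in_category <- function(p, cat) {
  lo <- if (cat$lower_inclusive) p >= cat$lower else p > cat$lower
  hi <- if (cat$upper_inclusive) p <= cat$upper else p < cat$upper
  lo & hi
}

#' Assign alleles to frequency categories
#'
#' @param freqs a [wild_allele_frequencies()] table.
#' @param categories a [frequency_categories()] list.
#' @return named list mapping category name to a data frame of
#'   `(locus, allele, freq)` rows belonging to it (possibly overlapping
#'   across categories).
#' @export
categorize <- function(freqs, categories = frequency_categories()) {
  out <- lapply(categories, function(cat) {
    freqs[in_category(freqs$freq, cat), c("locus", "allele", "freq")]
  })
  names(out) <- vapply(categories, `[[`, "", "name")
  out
}

#' Ex situ representation by frequency category
#'
#' For each frequency category of wild alleles, the fraction observed at
#' least once in a non-missing garden call. Alleles present in garden
#' samples but absent from the wild sample ("garden-only") are counted
#' separately and never enter any percentage.
#'
#' @param gm a [genotype_matrix()] holding garden and wild individuals.
#' @param partition a [sample_partition()].
#' @param categories a [frequency_categories()] list.
#' @return object of class `representation_result`: data frame with one row
#'   per category (`category`, `n_wild_alleles`, `n_captured`, `percent`;
#'   `percent` is `NA` for empty categories), attributes `garden_only_alleles`
#'   (count) and `categories` (the bound convention used).
#' @export
exsitu_representation <- function(gm, partition,
                                  categories = frequency_categories()) {
  g <- garden_ids(gm, partition)
  if (!length(g)) stop("no garden, non-excluded individuals in matrix")
  freqs <- wild_allele_frequencies(gm, partition)
  gg <- gm_subset(gm, individuals = g)
  gtab <- allele_count_table(gg)
  gkey <- paste(gtab$locus, gtab$allele, sep = "\r")
  wkey <- paste(freqs$locus, freqs$allele, sep = "\r")
  captured <- wkey %in% gkey
  garden_only <- sum(!(gkey %in% wkey))

  bycat <- lapply(categories, function(cat) in_category(freqs$freq, cat))
  rows <- lapply(names(bycat), function(nm) {
    sel <- bycat[[nm]]
    nw <- sum(sel); nc <- sum(captured & sel)
    data.frame(category = nm, n_wild_alleles = nw, n_captured = nc,
               percent = if (nw > 0) 100 * nc / nw else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  structure(out, garden_only_alleles = garden_only,
            categories = categories,
            class = c("representation_result", class(out)))
}

#' @export
print.representation_result <- function(x, ...) {
  cat("Ex situ representation of wild alleles\n")
  cats <- attr(x, "categories")
  for (cat_ in cats) cat("  ", category_label(cat_), "\n", sep = "")
  df <- as.data.frame(x)
  df$percent <- ifelse(is.na(df$percent), "undefined",
                       sprintf("%.2f%%", df$percent))
  print(df, row.names = FALSE)
  cat(sprintf("garden-only alleles (absent from wild): %d\n",
              attr(x, "garden_only_alleles")))
  invisible(x)
}

#' Write a representation table
#'
#' Emits the category-percentage layout of published representation tables
#' (one row per dataset label, columns = categories), plus a companion file
#' of raw allele counts. The boundary convention is written as comment
#' headers so every report is auditable.
#'
#' @param results named list of `representation_result` objects (names are
#'   dataset labels).
#' @param path output path for the percentage table (tab-delimited); raw
#'   counts are written to `paste0(path, ".counts.tsv")`.
#' @return `path`, invisibly.
#' @export
write_representation_table <- function(results, path) {
  stopifnot(length(results) > 0, !is.null(names(results)))
  cats <- attr(results[[1]], "categories")
  hdr <- paste0("# ", vapply(cats, category_label, ""))
  pct <- t(vapply(results, function(r) {
    v <- r$percent; names(v) <- r$category
    v
  }, numeric(nrow(results[[1]]))))
  df <- data.frame(dataset = names(results),
                   round(pct, 2), check.names = FALSE)
  con <- file(path, "w")
  writeLines(hdr, con)
  suppressWarnings(utils::write.table(df, con, sep = "\t", quote = FALSE,
                                      row.names = FALSE))
  close(con)
  cnt <- do.call(rbind, lapply(names(results), function(nm) {
    r <- as.data.frame(results[[nm]])
    cbind(dataset = nm, r,
          garden_only_alleles = attr(results[[nm]], "garden_only_alleles"))
  }))
  utils::write.table(cnt, paste0(path, ".counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
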