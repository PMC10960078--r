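#' Keep the first variant of each locus group
#'
#' Reduced-representation pipelines call several SNPs on the same assembled
#' locus; keeping only the first avoids tight linkage between analysed
#' variants. For each non-empty `source_group`, only the locus appearing
#' first in file order is kept; loci without a group are always kept and
#' the input order is preserved.
#'
#' @param gm a [genotype_matrix()] with `source_group` populated.
#' @return a [genotype_matrix()].
#' @export
first_variant_per_group <- function(gm) {
  grp <- gm$source_group
  keep <- is.na(grp) | !duplicated(grp, incomparables = NA)
  gm_subset(gm, loci = keep)
}

#' Missing-data locus filter (R0/R80 style)
#'
#' Drops every locus typed in strictly fewer than `r * N` individuals, where
#' presence means a non-missing call. `r = 0` is the identity (no filter on
#' missing data, "R0"); `r = 0.8` keeps loci present in at least 80% of all
#' samples ("R80"). Allele labels are implicitly recomputed on the
#' survivors.
#'
#' @param gm a [genotype_matrix()].
#' @param r minimum presence fraction in `[0, 1]`.
#' @return a [genotype_matrix()] containing the surviving loci.
#' @export
apply_missing_filter <- function(gm, r) {
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || r < 0 || r > 1)
    stop("r must be a single number in [0, 1]")
  keep <- locus_presence(gm) >= r * n_individuals(gm)
  gm_subset(gm, loci = keep)
}

#' Restrict two datasets to their shared samples
#'
#' Used to build "Subset" datasets that control for sample-size differences
#' between marker studies: both matrices are restricted to the intersection
#' of their sample IDs (matched after trimming whitespace and case-folding),
#' locus sets untouched. Row order follows `gm_a`.
#'
#' @param gm_a,gm_b two [genotype_matrix()] objects.
#' @return list with elements `a` and `b`, the restricted matrices.
#' @export
subset_shared <- function(gm_a, gm_b) {
  norm <- function(x) tolower(trimws(x))
  na <- norm(individuals(gm_a)); nb <- norm(individuals(gm_b))
  shared <- intersect(na, nb)
  if (!length(shared)) stop("no shared sample IDs between datasets")
  list(a = gm_subset(gm_a, individuals = which(na %in% shared)),
       b = gm_subset(gm_b, individuals = match(na[na %in% shared], nb)))
}

#' Drop excluded samples
#'
#' Removes the partition's excluded individuals (e.g. known interspecific
#' hybrids) from the matrix. Alleles private to excluded samples vanish from
#' the allele labels because labels are recomputed from the remaining calls.
#' Unknown IDs in the exclusion list warn and are ignored.
#'
#' @param gm a [genotype_matrix()].
#' @param partition a [sample_partition()].
#' @return a [genotype_matrix()] without the excluded rows.
#' @export
drop_samples <- function(gm, partition) {
  excl <- partition$excluded
  unknown <- setdiff(excl, individuals(gm))
  if (length(unknown))
    warning("exclusion list contains unknown sample IDs (ignored): ",
            paste(unknown, collapse = ", "))
  keep <- !(individuals(gm) %in% excl)
  gm_subset(gm, individuals = keep)
}
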