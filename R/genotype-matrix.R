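#' Diploid genotype matrix
#'
#' The universal substrate of the package: an individuals x loci table of
#' co-dominant diploid calls. Each cell holds either two allele codes
#' (possibly identical, i.e. a homozygote) or is missing as a whole;
#' half-called genotypes are collapsed to missing on construction because
#' every downstream frequency and presence computation treats a cell as
#' all-or-nothing.
#'
#' @param a1,a2 character matrices of identical dimension holding the two
#'   allele codes per cell; `NA` marks a missing call. Row names are sample
#'   IDs, column names are locus IDs (generated when absent).
#' @param source_group optional character vector (length = number of loci)
#'   carrying a grouping key per locus, e.g. the RAD-locus ID used by the
#'   first-variant-per-locus reduction; `NA` = no group.
#' @param pop optional character vector (length = number of individuals) of
#'   provisional population labels, e.g. from Genepop POP blocks.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(a1, a2, source_group = NULL, pop = NULL) {
  if (!is.matrix(a1) || !is.matrix(a2) || !identical(dim(a1), dim(a2)))
    stop("a1 and a2 must be matrices of identical dimension")
  mode(a1) <- "character"
  mode(a2) <- "character"
  if (is.null(rownames(a1)) && nrow(a1) > 0)
    rownames(a1) <- rownames(a2) <- paste0("ind", seq_len(nrow(a1)))
  if (is.null(colnames(a1)) && ncol(a1) > 0)
    colnames(a1) <- colnames(a2) <- paste0("loc", seq_len(ncol(a1)))
  if (anyDuplicated(rownames(a1)))
    stop("duplicate sample IDs: ",
         paste(unique(rownames(a1)[duplicated(rownames(a1))]), collapse = ", "))
  # collapse half-calls: a cell is typed only if both slots are non-missing
  half <- xor(is.na(a1), is.na(a2))
  if (any(half)) {
    a1[half] <- NA_character_
    a2[half] <- NA_character_
  }
  dimnames(a2) <- dimnames(a1)
  if (!is.null(source_group) && length(source_group) != ncol(a1))
    stop("source_group must have one entry per locus")
  if (!is.null(pop) && length(pop) != nrow(a1))
    stop("pop must have one entry per individual")
  structure(
    list(a1 = a1, a2 = a2,
         source_group = if (is.null(source_group)) rep(NA_character_, ncol(a1))
                        else as.character(source_group),
         pop = if (is.null(pop)) NULL else as.character(pop)),
    class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d loci (%.1f%% missing)\n",
              n_individuals(x), n_loci(x),
              100 * mean(is.na(x$a1))))
  labs <- allele_labels(x)
  cat(sprintf("  alleles per locus: min %d, median %s, max %d; %d alleles total\n",
              min(lengths(labs)), stats::median(lengths(labs)),
              max(lengths(labs)), sum(lengths(labs))))
  if (!all(is.na(x$source_group)))
    cat(sprintf("  source groups present for %d/%d loci\n",
                sum(!is.na(x$source_group)), n_loci(x)))
  invisible(x)
}

#' @rdname genotype_matrix
#' @param gm a `genotype_matrix`
#' @export
n_individuals <- function(gm) nrow(gm$a1)

#' @rdname genotype_matrix
#' @export
n_loci <- function(gm) ncol(gm$a1)

#' @rdname genotype_matrix
#' @export
individuals <- function(gm) rownames(gm$a1)

#' @rdname genotype_matrix
#' @export
loci <- function(gm) colnames(gm$a1)

#' Allele labels observed at each locus
#'
#' Recomputed from the current calls, so any subsetting or filtering is
#' automatically reflected: the labels are exactly the set of codes appearing
#' in non-missing calls, in order of first appearance down the sample list.
#'
#' @param gm a `genotype_matrix`
#' @return named list (per locus) of character vectors of allele codes.
#' @export
allele_labels <- function(gm) {
  nm <- loci(gm)
  out <- lapply(seq_along(nm), function(j) {
    v <- as.vector(rbind(gm$a1[, j], gm$a2[, j]))
    unique(v[!is.na(v)])
  })
  names(out) <- nm
  out
}

#' Subset a genotype matrix by individuals and/or loci
#'
#' @param gm a `genotype_matrix`
#' @param individuals character vector of sample IDs or integer/logical index;
#'   `NULL` keeps all.
#' @param loci character vector of locus IDs or integer/logical index; `NULL`
#'   keeps all.
#' @return a `genotype_matrix`; allele labels are implicitly recomputed.
#' @export
gm_subset <- function(gm, individuals = NULL, loci = NULL) {
  ri <- if (is.null(individuals)) seq_len(n_individuals(gm)) else individuals
  ci <- if (is.null(loci)) seq_len(n_loci(gm)) else loci
  if (is.character(ri)) {
    miss <- setdiff(ri, rownames(gm$a1))
    if (length(miss))
      stop("unknown sample IDs: ", paste(miss, collapse = ", "))
  }
  if (is.character(ci)) {
    miss <- setdiff(ci, colnames(gm$a1))
    if (length(miss))
      stop("unknown locus IDs: ", paste(miss, collapse = ", "))
  }
  a1 <- gm$a1[ri, ci, drop = FALSE]
  a2 <- gm$a2[ri, ci, drop = FALSE]
  cidx <- if (is.character(ci)) match(ci, colnames(gm$a1)) else
          seq_len(n_loci(gm))[ci]
  ridx <- if (is.character(ri)) match(ri, rownames(gm$a1)) else
          seq_len(n_individuals(gm))[ri]
  genotype_matrix(a1, a2,
                  source_group = gm$source_group[cidx],
                  pop = if (is.null(gm$pop)) NULL else gm$pop[ridx])
}

# locus-wise count of typed (non-missing) individuals
locus_presence <- function(gm) colSums(!is.na(gm$a1))

#' Sample partition: origin, wild population, exclusions
#'
#' Assigns each individual an origin (`garden` or `wild`), optionally a wild
#' population label, and optionally flags individuals for exclusion (e.g.
#' known hybrids dropped before any analysis).
#'
#' @param origin named character vector mapping sample ID to `"garden"` or
#'   `"wild"`.
#' @param wild_population optional named character vector mapping wild sample
#'   IDs to population labels.
#' @param excluded character vector of sample IDs to drop before analysis.
#' @return an object of class `sample_partition`.
#' @export
sample_partition <- function(origin, wild_population = NULL,
                             excluded = character()) {
  origin <- vapply(origin, as.character, "", USE.NAMES = TRUE)
  bad <- setdiff(unique(origin), c("garden", "wild"))
  if (length(bad))
    stop("origin values must be 'garden' or 'wild'; got: ",
         paste(bad, collapse = ", "))
  if (is.null(names(origin)) || any(names(origin) == ""))
    stop("origin must be a fully named vector")
  if (!is.null(wild_population)) {
    notw <- setdiff(names(wild_population),
                    names(origin)[origin == "wild"])
    if (length(notw))
      stop("wild_population labels given for non-wild samples: ",
           paste(notw, collapse = ", "))
  }
  structure(list(origin = origin,
                 wild_population = wild_population,
                 excluded = as.character(excluded)),
            class = "sample_partition")
}

#' @export
print.sample_partition <- function(x, ...) {
  cat(sprintf("sample_partition: %d garden, %d wild, %d excluded\n",
              sum(x$origin == "garden"), sum(x$origin == "wild"),
              length(x$excluded)))
  if (!is.null(x$wild_population)) {
    tb <- table(x$wild_population)
    cat("  wild populations:",
        paste(sprintf("%s(%d)", names(tb), tb), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read a sample metadata table
#'
#' Delimited table with columns `sample_id`, `origin` (garden|wild), optional
#' `population` and optional `excluded` (0/1).
#'
#' @param path path to a tab- or comma-delimited file (delimiter sniffed from
#'   the header line).
#' @return a `sample_partition`.
#' @export
read_metadata <- function(path) {
  hdr <- readLines(path, n = 1L)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", strip.white = TRUE)
  need <- c("sample_id", "origin")
  if (!all(need %in% names(df)))
    stop("metadata must have columns sample_id and origin")
  origin <- stats::setNames(trimws(df$origin), trimws(df$sample_id))
  excl <- character()
  if ("excluded" %in% names(df))
    excl <- trimws(df$sample_id)[df$excluded %in% c("1", "TRUE", "true")]
  wp <- NULL
  if ("population" %in% names(df)) {
    wild <- names(origin)[origin == "wild"]
    pops <- stats::setNames(trimws(df$population), trimws(df$sample_id))[wild]
    pops <- pops[!is.na(pops) & pops != ""]
    if (length(pops)) wp <- pops
  }
  sample_partition(origin, wild_population = wp, excluded = excl)
}

# wild, non-excluded sample IDs present in gm (helper shared across modules)
wild_ids <- function(gm, partition) {
  ids <- names(partition$origin)[partition$origin == "wild"]
  ids <- setdiff(ids, partition$excluded)
  intersect(individuals(gm), ids)
}

garden_ids <- function(gm, partition) {
  ids <- names(partition$origin)[partition$origin == "garden"]
  ids <- setdiff(ids, partition$excluded)
  intersect(individuals(gm), ids)
}
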