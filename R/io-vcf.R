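#' Read genotypes from a VCF file
#'
#' Wraps `VariantAnnotation::readVcf` and converts the GT field of each
#' record into a diploid call on allele labels (REF/ALT nucleotides).
#' Multi-allelic sites are supported; phased (`|`) and unphased (`/`)
#' separators are treated identically; `./.` (and any half-call) becomes
#' missing. One locus is created per VCF record, named `CHROM_POS` (made
#' unique if needed).
#'
#' The RAD-locus grouping used by [first_variant_per_group()] is taken from
#' the ID column when present, or from an INFO key named by `group_info_key`.
#' `readVcf` fabricates `chrom:pos_ref/alt` names for records whose ID is
#' `.`; such names are treated as "no ID".
#'
#' @param path path to an uncompressed or bgzipped VCF.
#' @param group_info_key optional INFO field name holding the locus group.
#' @return a [genotype_matrix()] with `source_group` populated where known.
#' @export
read_vcf <- function(path, group_info_key = NULL) {
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field in FORMAT")
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt <- VariantAnnotation::alt(vcf)
  alt <- lapply(seq_along(alt), function(i) as.character(alt[[i]]))
  nloc <- nrow(gt); nsam <- ncol(gt)

  ids <- names(rr)
  fabricated <- paste0(as.character(GenomicRanges::seqnames(rr)), ":",
                       GenomicRanges::start(rr), "_", ref)
  has_id <- !is.na(ids) & ids != "" & ids != "." &
    substr(ids, 1, nchar(fabricated)) != fabricated
  group <- ifelse(has_id, ids, NA_character_)
  if (!is.null(group_info_key)) {
    inf <- VariantAnnotation::info(vcf)[[group_info_key]]
    if (is.null(inf)) stop("INFO key not found in VCF: ", group_info_key)
    group <- as.character(inf)
  }

  locus_ids <- make.unique(paste0(as.character(GenomicRanges::seqnames(rr)),
                                  "_", GenomicRanges::start(rr)))
  a1 <- matrix(NA_character_, nsam, nloc)
  a2 <- matrix(NA_character_, nsam, nloc)
  for (j in seq_len(nloc)) {
    labels <- c(ref[j], alt[[j]])
    g <- gt[j, ]
    parts <- strsplit(g, "[/|]")
    for (i in seq_len(nsam)) {
      p <- parts[[i]]
      if (length(p) == 1L && p %in% c(".", "")) next
      if (length(p) != 2L)
        stop(sprintf("non-diploid GT '%s' (sample '%s', site '%s')",
                     g[i], colnames(gt)[i], locus_ids[j]))
      if (any(p == ".")) next # half-call -> missing
      idx <- suppressWarnings(as.integer(p)) + 1L
      if (anyNA(idx) || any(idx < 1L) || any(idx > length(labels)))
        stop(sprintf("invalid GT allele index '%s' (sample '%s', site '%s')",
                     g[i], colnames(gt)[i], locus_ids[j]))
      a1[i, j] <- labels[idx[1]]
      a2[i, j] <- labels[idx[2]]
    }
  }
  rownames(a1) <- rownames(a2) <- colnames(gt)
  colnames(a1) <- colnames(a2) <- locus_ids
  genotype_matrix(a1, a2, source_group = group)
}

#' Write biallelic genotypes as a minimal VCF
#'
#' Export path for simulated data. Every locus must have at most two allele
#' labels; the first observed label becomes REF. GT-only, unphased.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf_biallelic <- function(gm, path) {
  labs <- allele_labels(gm)
  if (any(lengths(labs) > 2L))
    stop("write_vcf_biallelic requires <= 2 alleles per locus")
  nuc <- function(x, default) if (grepl("^[ACGT]$", x)) x else default
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", individuals(gm)), collapse = "\t")),
             con)
  for (j in seq_len(n_loci(gm))) {
    al <- labs[[j]]
    refl <- if (length(al) >= 1) al[1] else "N"
    altl <- if (length(al) >= 2) al[2] else "."
    gt <- vapply(seq_len(n_individuals(gm)), function(i) {
      x <- c(gm$a1[i, j], gm$a2[i, j])
      if (anyNA(x)) "./." else
        paste(match(x, al) - 1L, collapse = "/")
    }, "")
    writeLines(paste(c("1", j, loci(gm)[j], nuc(refl, "A"),
                       if (altl == ".") "." else nuc(altl, "T"),
                       ".", "PASS", ".", "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}
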