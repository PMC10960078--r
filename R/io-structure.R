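#' Read a STRUCTURE file
#'
#' Supports the two common layouts: two rows per individual (one allele per
#' row) or one row per individual with two adjacent columns per locus.
#' An optional header row of locus names is auto-detected (a first line with
#' fewer fields than the data rows, or non-numeric fields only).
#'
#' @param path path to a whitespace-delimited STRUCTURE file.
#' @param one_row_per_individual `TRUE` for the one-row, two-columns-per-locus
#'   layout; `FALSE` (default) for two rows per individual.
#' @param missing_code allele code representing missing data (default `"-9"`).
#' @return a [genotype_matrix()].
#' @export
read_structure <- function(path, one_row_per_individual = FALSE,
                           missing_code = "-9") {
  ln <- readLines(path, warn = FALSE)
  ln <- ln[trimws(ln) != ""]
  toks <- lapply(ln, function(x) strsplit(trimws(x), "[ \t]+")[[1]])
  nf <- lengths(toks)
  header <- NULL
  if (length(unique(nf)) > 1L) {
    if (nf[1] != nf[2] && length(unique(nf[-1])) == 1L) {
      header <- toks[[1]]
      toks <- toks[-1]; nf <- nf[-1]
    } else {
      stop("ragged rows: row ", which(nf != stats::median(nf))[1],
           " has ", nf[which(nf != stats::median(nf))[1]], " fields")
    }
  } else if (all(!grepl("^-?[0-9]+$", toks[[1]][-1]))) {
    header <- toks[[1]]
    toks <- toks[-1]; nf <- nf[-1]
  }
  if (!length(toks)) stop("no data rows")

  if (one_row_per_individual) {
    nl <- (nf[1] - 1L) / 2L
    if (nl != floor(nl)) stop("one-row layout needs an odd field count (id + 2 per locus)")
    ids <- vapply(toks, `[`, "", 1L)
    g <- t(vapply(toks, function(x) x[-1], character(2L * nl)))
    a1 <- g[, seq(1L, 2L * nl, by = 2L), drop = FALSE]
    a2 <- g[, seq(2L, 2L * nl, by = 2L), drop = FALSE]
  } else {
    if (length(toks) %% 2L != 0L)
      stop("odd row count in two-rows-per-individual mode")
    nl <- nf[1] - 1L
    ids1 <- vapply(toks[seq(1, length(toks), 2)], `[`, "", 1L)
    ids2 <- vapply(toks[seq(2, length(toks), 2)], `[`, "", 1L)
    if (!identical(ids1, ids2))
      stop("row pairs disagree on sample ID near: ",
           ids1[which(ids1 != ids2)[1]])
    ids <- ids1
    a1 <- t(vapply(toks[seq(1, length(toks), 2)],
                   function(x) x[-1], character(nl)))
    a2 <- t(vapply(toks[seq(2, length(toks), 2)],
                   function(x) x[-1], character(nl)))
  }
  a1[a1 == missing_code] <- NA_character_
  a2[a2 == missing_code] <- NA_character_
  rownames(a1) <- rownames(a2) <- ids
  locn <- if (!is.null(header)) {
    h <- header[header != ""]
    if (length(h) == ncol(a1)) h else paste0("loc", seq_len(ncol(a1)))
  } else paste0("loc", seq_len(ncol(a1)))
  colnames(a1) <- colnames(a2) <- locn
  genotype_matrix(a1, a2)
}

#' Write a STRUCTURE file
#'
#' Two-rows-per-individual layout with a locus-name header, suitable as input
#' for external clustering tools. Non-integer allele labels are re-encoded as
#' consecutive integers.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @param missing_code code written for missing alleles (default `"-9"`).
#' @return `path`, invisibly.
#' @export
write_structure <- function(gm, path, missing_code = "-9") {
  codes <- genepop_codes(gm)
  enc <- function(m) {
    v <- as.character(codes$int[match(m, codes$label)])
    v[is.na(v)] <- missing_code
    matrix(v, nrow(m), ncol(m))
  }
  e1 <- enc(gm$a1); e2 <- enc(gm$a2)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(loci(gm), collapse = "\t"), con)
  for (i in seq_len(n_individuals(gm))) {
    writeLines(paste(c(individuals(gm)[i], e1[i, ]), collapse = "\t"), con)
    writeLines(paste(c(individuals(gm)[i], e2[i, ]), collapse = "\t"), con)
  }
  invisible(path)
}
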