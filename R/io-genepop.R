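#' Read a Genepop file
#'
#' Parses the classic Genepop dialect: a title line, locus names (one per
#' line or comma-separated), `POP` separators, then one row per individual
#' `"id , a1a2 a1a2 ..."` with 2- or 3-digit allele coding. `00`/`000`
#' encodes a missing allele; a cell with either allele missing is collapsed
#' to a missing call. Digit width is auto-detected from the first genotype
#' token and must be uniform across the file.
#'
#' @param path path to a Genepop text file.
#' @return a [genotype_matrix()] with POP-block labels in `$pop`.
#' @export
read_genepop <- function(path) {
  ln <- trimws(readLines(path, warn = FALSE))
  ln <- ln[ln != ""]
  if (length(ln) < 3) stop("not a Genepop file: too few lines")
  is_pop <- toupper(ln) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("not a Genepop file: no POP separator")
  # locus names: lines 2..(first POP - 1), possibly comma-separated
  loc <- unlist(strsplit(ln[2:(first_pop - 1)], ","))
  loc <- trimws(loc)
  loc <- loc[loc != ""]
  if (anyDuplicated(loc)) stop("duplicate locus names in header")

  body <- ln[first_pop:length(ln)]
  popline <- toupper(body) == "POP"
  pop_id <- cumsum(popline)
  rows <- body[!popline]
  pop_of_row <- pop_id[!popline]

  width <- NA_integer_
  ids <- character(length(rows))
  a1 <- matrix(NA_character_, length(rows), length(loc))
  a2 <- matrix(NA_character_, length(rows), length(loc))
  for (i in seq_along(rows)) {
    parts <- strsplit(rows[i], ",")[[1]]
    if (length(parts) < 2)
      stop("malformed Genepop row (no comma after sample ID) at line: ",
           rows[i])
    ids[i] <- trimws(parts[1])
    toks <- strsplit(trimws(paste(parts[-1], collapse = " ")), "[ \t]+")[[1]]
    if (length(toks) != length(loc))
      stop(sprintf("sample '%s' has %d genotype fields, expected %d",
                   ids[i], length(toks), length(loc)))
    for (j in seq_along(toks)) {
      tk <- toks[j]
      if (nchar(tk) %% 2L != 0L)
        stop(sprintf("odd-length allele field '%s' (sample '%s', locus '%s')",
                     tk, ids[i], loc[j]))
      w <- nchar(tk) / 2L
      if (!w %in% c(2L, 3L))
        stop(sprintf("allele coding must be 2 or 3 digits, got %d (locus '%s')",
                     w, loc[j]))
      if (is.na(width)) width <- w
      if (w != width)
        stop(sprintf("mixed digit widths: locus '%s' uses %d digits, file uses %d",
                     loc[j], w, width))
      x1 <- substr(tk, 1L, width)
      x2 <- substr(tk, width + 1L, 2L * width)
      zero <- strrep("0", width)
      if (x1 != zero && x2 != zero) {
        a1[i, j] <- x1
        a2[i, j] <- x2
      } # any zero half -> whole cell missing (half-call collapse)
    }
  }
  if (anyDuplicated(ids))
    stop("duplicate sample IDs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  rownames(a1) <- rownames(a2) <- ids
  colnames(a1) <- colnames(a2) <- loc
  genotype_matrix(a1, a2, pop = paste0("pop", pop_of_row))
}

#' Write a Genepop file
#'
#' Allele codes must be non-negative integers; the digit width (2 or 3) is
#' chosen from the largest code. Individuals are grouped into POP blocks by
#' `pop` (or `gm$pop`, or a single block).
#'
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @param pop optional character vector of population labels per individual.
#' @param title title line (first line of the file).
#' @return `path`, invisibly.
#' @export
write_genepop <- function(gm, path, pop = NULL, title = "exsitu export") {
  codes <- genepop_codes(gm)
  width <- if (max(codes$int, 0L) > 99L) 3L else 2L
  if (max(codes$int, 0L) > 999L)
    stop("allele codes exceed 3-digit Genepop range after encoding")
  enc <- function(m) {
    v <- codes$int[match(m, codes$label)]
    v[is.na(v)] <- 0L
    matrix(formatC(v, width = width, flag = "0"), nrow(m), ncol(m))
  }
  e1 <- enc(gm$a1); e2 <- enc(gm$a2)
  if (is.null(pop)) pop <- if (is.null(gm$pop)) rep("pop1", n_individuals(gm))
                           else gm$pop
  out <- c(title, loci(gm))
  for (p in unique(pop)) {
    out <- c(out, "POP")
    for (i in which(pop == p))
      out <- c(out, paste0(individuals(gm)[i], " ,  ",
                           paste0(e1[i, ], e2[i, ], collapse = " ")))
  }
  writeLines(out, path)
  invisible(path)
}

# integer encoding for allele labels; numeric labels pass through unchanged
genepop_codes <- function(gm) {
  labs <- unique(unlist(allele_labels(gm), use.names = FALSE))
  if (length(labs) == 0) return(list(label = character(), int = integer()))
  if (all(grepl("^[0-9]+$", labs))) {
    list(label = labs, int = as.integer(labs))
  } else {
    list(label = labs, int = seq_along(labs))
  }
}
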