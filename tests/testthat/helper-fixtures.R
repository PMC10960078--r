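# shared fixture builders; everything is generated in code, no stored data

# build a genotype_matrix from a list of per-individual genotype strings,
# e.g. toy_gm(ind1 = c("A/A", "A/B", "-"), ...); "-" = missing
toy_gm <- function(..., loci_names = NULL, source_group = NULL) {
  rows <- list(...)
  L <- length(rows[[1]])
  a1 <- matrix(NA_character_, length(rows), L,
               dimnames = list(names(rows), loci_names))
  a2 <- a1
  for (i in seq_along(rows)) {
    for (j in seq_len(L)) {
      g <- rows[[i]][j]
      if (g != "-") {
        al <- strsplit(g, "/", fixed = TRUE)[[1]]
        a1[i, j] <- al[1]
        a2[i, j] <- al[2]
      }
    }
  }
  genotype_matrix(a1, a2, source_group = source_group)
}

# random integer-coded matrix with controlled missingness
random_gm <- function(n = 10, L = 8, k = 3, miss = 0.2, seed = 1) {
  set.seed(seed)
  codes <- as.character(seq(101, by = 2, length.out = k))
  a1 <- matrix(sample(codes, n * L, replace = TRUE), n, L)
  a2 <- matrix(sample(codes, n * L, replace = TRUE), n, L)
  drop <- matrix(runif(n * L) < miss, n, L)
  a1[drop] <- NA_character_
  a2[drop] <- NA_character_
  rownames(a1) <- rownames(a2) <- sprintf("s%02d", seq_len(n))
  colnames(a1) <- colnames(a2) <- sprintf("L%02d", seq_len(L))
  genotype_matrix(a1, a2)
}

# partition that marks every individual of a matrix wild
all_wild_partition <- function(gm, pops = NULL) {
  ids <- individuals(gm)
  sample_partition(
    stats::setNames(rep("wild", length(ids)), ids),
    wild_population = if (!is.null(pops)) stats::setNames(pops, ids))
}

# brute-force capture average over all subsets of size n: the independent
# oracle for analytic_expected_capture / capture_curve, computed straight
# from the calls without touching the package's carrier index
exhaustive_capture <- function(gm, n) {
  N <- n_individuals(gm)
  per_ind <- lapply(seq_len(N), function(i) {
    v <- c(gm$a1[i, ], gm$a2[i, ])
    paste(rep(loci(gm), 2), v)[!is.na(v)]
  })
  universe <- unique(unlist(per_ind))
  subsets <- utils::combn(N, n)
  mean(apply(subsets, 2, function(s)
    length(unique(unlist(per_ind[s]))) / length(universe)))
}

write_lines_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# minimal Genepop fixture: 2 pops x 2 samples x 3 loci, 2-digit coding
genepop_toy_lines <- function() {
  c("toy dataset",
    "L1", "L2", "L3",
    "POP",
    "a1 , 0101 0202 0303",
    "a2 , 0102 0000 0303",
    "POP",
    "b1 , 0101 0203 0101",
    "b2 , 0303 0202 0102")
}

vcf_toy_lines <- function() {
  c("##fileformat=VCFv4.2",
    "##INFO=<ID=LG,Number=1,Type=String,Description=\"locus group\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2", "s3"), collapse = "\t"),
    paste(c("1", "100", "locus7", "A", "G", ".", "PASS", "LG=g1", "GT",
            "0/0", "0/1", "./."), collapse = "\t"),
    paste(c("1", "150", "locus7", "C", "T,G", ".", "PASS", "LG=g1", "GT",
            "1|2", "0/0", "./1"), collapse = "\t"),
    paste(c("2", "10", ".", "T", "A", ".", "PASS", "LG=g2", "GT",
            "0/0", "1/1", "0/1"), collapse = "\t"))
}
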