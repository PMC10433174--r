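# Readers/writers for the package's plain-text dialects: genotype TSV
# (rows = clones, columns = SNP IDs), minimal VCF, and the plot-phenotype
# CSV.

#' Write / read a genotype matrix as TSV
#'
#' Rows are clones, columns SNP IDs (`"S{chr}_{pos}"`); first column
#' `clone_id`.
#'
#' @param geno genotype matrix.
#' @param path output file.
#' @export
write_genotype_tsv <- function(geno, path) {
  df <- data.frame(clone_id = rownames(geno), unclass(geno),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotype_tsv
#' @export
read_genotype_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- df[[1]]
  M <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(M) <- "integer"
  rownames(M) <- ids
  structure(M, map = parse_snp_ids(colnames(M)), class = "genotype_matrix")
}

#' Write a minimal VCF for a pseudo-diploid genotype matrix
#'
#' CHROM/POS/ID/REF/ALT plus unphased diploid GT calls (0/0, 0/1, 1/1).
#' Alleles are placeholders (A/T) since the simulator tracks dosages only.
#'
#' @param geno genotype matrix.
#' @param path output file.
#' @export
write_genotype_vcf <- function(geno, path) {
  map <- snp_map(geno)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(geno)), collapse = "\t")),
             con)
  gt <- c("0/0", "0/1", "1/1")
  M <- unclass(geno)
  for (j in seq_len(ncol(M))) {
    calls <- ifelse(is.na(M[, j]), "./.", gt[M[, j] + 1L])
    writeLines(paste(c(map$chrom[j], map$pos[j], map$snp_id[j], "A", "T",
                       ".", "PASS", ".", "GT", calls), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a minimal VCF into a genotype matrix
#'
#' Uses `vcfR` when available, otherwise a plain-text fallback for the
#' minimal dialect written by [write_genotype_vcf()]. Only biallelic GT
#' fields are interpreted; dosage = count of alternate alleles.
#'
#' @param path VCF file.
#' @return `genotype_matrix` (clones x SNPs).
#' @export
read_genotype_vcf <- function(path) {
  if (requireNamespace("vcfR", quietly = TRUE)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    M <- apply(gt, c(1, 2), function(g) {
      if (is.na(g) || g %in% c("./.", ".")) return(NA_integer_)
      sum(as.integer(strsplit(g, "[/|]")[[1]]) > 0)
    })
    M <- t(M)
    ids <- v@fix[, "ID"]
  } else {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "##")]
    hdr <- strsplit(sub("^#", "", lines[1]), "\t")[[1]]
    body <- strsplit(lines[-1], "\t")
    ids <- vapply(body, `[`, "", 3L)
    samp <- hdr[-(1:9)]
    M <- matrix(NA_integer_, length(samp), length(body),
                dimnames = list(samp, ids))
    for (j in seq_along(body)) {
      g <- body[[j]][-(1:9)]
      M[, j] <- vapply(g, function(x) {
        if (x %in% c("./.", ".")) return(NA_integer_)
        sum(as.integer(strsplit(x, "[/|]")[[1]]) > 0L)
      }, 1L, USE.NAMES = FALSE)
    }
  }
  colnames(M) <- ids
  structure(M, map = parse_snp_ids(colnames(M)), class = "genotype_matrix")
}

#' Write / read the plot-phenotype CSV dialect
#'
#' One row per plot per cycle, header `cycle, replicate, row, column,
#' entry_id, population_class, SP, SW, brix, pol, fiber, moisture`.
#'
#' @param pheno plot-phenotype data.frame.
#' @param path file path.
#' @export
write_phenotype_csv <- function(pheno, path) {
  write.csv(pheno, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_phenotype_csv
#' @export
read_phenotype_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("cycle", "replicate", "row", "column", "entry_id",
           "population_class")
  if (!all(req %in% names(df)))
    stop("phenotype file missing columns: ",
         paste(setdiff(req, names(df)), collapse = ", "))
  class(df) <- c("plot_phenotypes", "data.frame")
  df
}
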