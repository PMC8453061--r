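# File I/O: FASTA via Biostrings, TSV via base, VCF v4.2 (GT only)
# written directly and read back through vcfR.

#' Write named sequences to FASTA
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#' @param path FASTA file.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write a data.frame as TSV
#' @param x data.frame.
#' @param path output file.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path input file.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

# intensity matrices travel as TSV with a probe_id first column
write_matrix_tsv <- function(m, path, id_col = "probe_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write_tsv(df, path)
}

read_matrix_tsv <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[-1])
  rownames(m) <- df[[1]]
  m
}

#' Write a genotype matrix as a minimal VCF v4.2 (GT field only)
#'
#' Dosages 0/1/2 become 0/0, 0/1, 1/1; missing becomes ./. . Synthetic
#' SNPs carry placeholder positions on a single contig.
#'
#' @param g SNPs x samples matrix with calls in \{0, 1, 2, NA\}.
#' @param path output file.
#' @export
write_vcf <- function(g, path) {
  check_genotypes(g)
  gt <- matrix(c("0/0", "0/1", "1/1")[g + 1L], nrow(g), ncol(g))
  gt[is.na(g)] <- "./."
  header <- c("##fileformat=VCFv4.2",
              "##contig=<ID=1>",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", colnames(g)), collapse = "\t"))
  body <- paste(
    "1", seq_len(nrow(g)), rownames(g), "A", "G", ".", "PASS", ".", "GT",
    apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a GT-only VCF into a dosage matrix
#'
#' Uses vcfR; alternate-allele dosage, NA for missing.
#'
#' @param path VCF file.
#' @return SNPs x samples integer matrix.
#' @export
read_vcf_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dose <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  dose[clean == "0/0"] <- 0L
  dose[clean %in% c("0/1", "1/0")] <- 1L
  dose[clean == "1/1"] <- 2L
  dose
}

#' Read a genotype TSV dialect (rows SNPs, columns samples, cells 0/1/2/NA)
#' @param path input file.
#' @export
read_genotype_tsv <- function(path) {
  m <- read_matrix_tsv(path)
  storage.mode(m) <- "integer"
  check_genotypes(m)
  m
}
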