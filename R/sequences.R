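DNA_BASES <- c("A", "C", "G", "T")

#' Validate a DNA sequence string
#'
#' Sequences are restricted to the unambiguous alphabet A/C/G/T;
#' ambiguity codes (including N) are rejected so that mismatch counts
#' stay exact.
#'
#' @param x character scalar.
#' @param what label used in error messages (e.g. a probe id).
#' @return invisibly, `x` uppercased.
#' @keywords internal
check_dna <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x) || nchar(x) == 0L) {
    stop(sprintf("%s must be a non-empty character scalar", what), call. = FALSE)
  }
  x <- toupper(x)
  if (grepl("[^ACGT]", x)) {
    bad <- unique(strsplit(gsub("[ACGT]", "", x), "")[[1]])
    stop(sprintf("%s contains non-ACGT character(s): %s", what,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

#' Reverse complement of a DNA string
#' @param x character scalar over ACGT.
#' @return character scalar.
#' @export
revcomp <- function(x) {
  x <- check_dna(x)
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

#' GC fraction of a DNA string
#' @param x character scalar over ACGT.
#' @return proportion of G and C bases in `[0, 1]`.
#' @export
gc_fraction <- function(x) {
  x <- check_dna(x)
  v <- strsplit(x, "")[[1]]
  mean(v %in% c("G", "C"))
}

# integer encoding used by the window scans (A=1 C=2 G=3 T=4)
encode_dna <- function(x) {
  match(strsplit(toupper(x), "")[[1]], DNA_BASES)
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# substitute k positions (within positions `at` if given) to a different base
substitute_bases <- function(x, k, at = NULL) {
  v <- strsplit(x, "")[[1]]
  if (is.null(at)) at <- seq_along(v)
  pos <- sample(at, k)
  for (p in pos) {
    v[p] <- sample(setdiff(DNA_BASES, v[p]), 1)
  }
  list(sequence = paste(v, collapse = ""), positions = sort(pos))
}
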