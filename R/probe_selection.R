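#' Reference set for probe specificity screening
#'
#' Bundles one mitochondrial reference sequence (treated as circular)
#' with a set of linear nuclear sequences. Probes are screened for an
#' exact match to the mitochondrial sequence and for their minimum
#' Hamming distance to any same-length nuclear window on either strand,
#' mirroring the specificity requirement that mtDNA probes match the
#' mitochondrial genome perfectly while sitting as far as possible from
#' nuclear near-copies (NUMTs).
#'
#' @param mito character scalar, the mitochondrial sequence (ACGT only).
#' @param nuclear named character vector of nuclear sequences.
#' @return an object of class `reference_set`.
#' @export
reference_set <- function(mito, nuclear) {
  mito <- check_dna(mito, "mitochondrial sequence")
  if (length(nuclear) < 1L) stop("at least one nuclear sequence required")
  if (is.null(names(nuclear))) {
    names(nuclear) <- sprintf("nuc%02d", seq_along(nuclear))
  }
  ids <- names(nuclear)
  nuclear <- vapply(seq_along(nuclear), function(i) {
    check_dna(nuclear[[i]], sprintf("nuclear sequence '%s'", ids[i]))
  }, character(1))
  names(nuclear) <- ids
  structure(list(mito = mito, nuclear = nuclear), class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("reference_set: mito %d bp (circular), %d nuclear sequence(s), %s bp total\n",
              nchar(x$mito), length(x$nuclear),
              format(sum(nchar(x$nuclear)), big.mark = ",")))
  invisible(x)
}

# Hamming mismatch counts of `probe_enc` (integer-encoded) against every
# ungapped window of `seq_enc`; one vectorised pass per probe position.
window_mismatches <- function(probe_enc, seq_enc) {
  w <- length(probe_enc)
  n_off <- length(seq_enc) - w + 1L
  if (n_off < 1L) return(integer(0))
  m <- integer(n_off)
  for (j in seq_len(w)) {
    m <- m + (seq_enc[j:(j + n_off - 1L)] != probe_enc[j])
  }
  m
}

#' Minimum Hamming distance from a probe to the nuclear references
#'
#' Scans every ungapped window of every nuclear sequence, on both the
#' forward strand and the reverse complement, and returns the smallest
#' Hamming distance found. A probe with distance 0 has a perfect nuclear
#' hit (e.g. a NUMT) and cannot be used for mtDNA quantification.
#'
#' @param probe character scalar (ACGT only).
#' @param refs a [reference_set()].
#' @return nonnegative integer; `nchar(probe)` if no nuclear sequence is
#'   long enough to contribute a window.
#' @export
min_mismatch_to_nuclear <- function(probe, refs) {
  stopifnot(inherits(refs, "reference_set"))
  probe <- check_dna(probe, "probe")
  enc_f <- encode_dna(probe)
  enc_r <- encode_dna(revcomp(probe))
  best <- nchar(probe)
  for (s in refs$nuclear) {
    se <- encode_dna(s)
    mm <- c(window_mismatches(enc_f, se), window_mismatches(enc_r, se))
    if (length(mm)) best <- min(best, mm)
    if (best == 0L) break
  }
  as.integer(best)
}

#' Does a probe match the mitochondrial reference exactly?
#'
#' Exact (100% identity) occurrence on either strand. The mitochondrial
#' genome is circular, so windows may wrap the origin; circularity is
#' handled by scanning the sequence doubled up to the last
#' `probe length - 1` bases.
#'
#' @inheritParams min_mismatch_to_nuclear
#' @return logical flag.
#' @export
is_exact_mito_match <- function(probe, refs) {
  stopifnot(inherits(refs, "reference_set"))
  probe <- check_dna(probe, "probe")
  w <- nchar(probe)
  L <- nchar(refs$mito)
  if (w > L) stop("probe longer than mitochondrial sequence")
  doubled <- paste0(refs$mito, substr(refs$mito, 1L, w - 1L))
  de <- encode_dna(doubled)
  for (p in c(probe, revcomp(probe))) {
    mm <- window_mismatches(encode_dna(p), de)
    # offsets 1..L are the distinct circular windows
    if (any(mm[seq_len(L)] == 0L)) return(TRUE)
  }
  FALSE
}

#' Annotate probes with specificity scores
#'
#' @param probes data.frame with columns `probe_id` and `sequence`
#'   (a `gc_fraction` column is recomputed from the sequence).
#' @param refs a [reference_set()].
#' @return the input with columns `gc_fraction`, `mito_exact_match` and
#'   `min_nuclear_mismatch` filled in.
#' @export
annotate_probes <- function(probes, refs) {
  stopifnot(is.data.frame(probes), all(c("probe_id", "sequence") %in% names(probes)))
  if (anyDuplicated(probes$probe_id)) stop("duplicate probe ids")
  probes$gc_fraction <- vapply(probes$sequence, gc_fraction, numeric(1),
                               USE.NAMES = FALSE)
  probes$mito_exact_match <- vapply(probes$sequence, is_exact_mito_match,
                                    logical(1), refs = refs, USE.NAMES = FALSE)
  probes$min_nuclear_mismatch <- vapply(probes$sequence, min_mismatch_to_nuclear,
                                        integer(1), refs = refs, USE.NAMES = FALSE)
  probes
}

#' Select mitochondrial probes by specificity
#'
#' Keeps probes that match the mitochondrial reference with 100%
#' identity AND whose minimum Hamming distance to any nuclear window is
#' at least `min_mm`. Selected probes are ordered by descending nuclear
#' mismatch distance (most specific first), ties broken by probe id.
#'
#' @param probes data.frame as returned by [annotate_probes()] (it is
#'   annotated here if the score columns are absent).
#' @param refs a [reference_set()].
#' @param min_mm minimum nuclear mismatch distance required (default 2).
#' @return list with `selected` (data.frame of kept probes, ordered) and
#'   `report` (every probe with `selected` flag and exclusion `reason`).
#' @export
select_mtdna_probes <- function(probes, refs, min_mm = 2L) {
  if (min_mm < 1L) stop("min_mm must be >= 1")
  if (!all(c("mito_exact_match", "min_nuclear_mismatch") %in% names(probes))) {
    probes <- annotate_probes(probes, refs)
  }
  reason <- rep("", nrow(probes))
  reason[!probes$mito_exact_match] <- "no exact mitochondrial match"
  ns <- probes$mito_exact_match & probes$min_nuclear_mismatch < min_mm
  reason[ns] <- sprintf("nuclear mismatch %d < %d",
                        probes$min_nuclear_mismatch[ns], min_mm)
  keep <- reason == ""
  report <- probes[c("probe_id", "gc_fraction", "mito_exact_match",
                     "min_nuclear_mismatch")]
  report$selected <- keep
  report$reason <- ifelse(keep, "selected", reason)
  sel <- probes[keep, , drop = FALSE]
  sel <- sel[order(-sel$min_nuclear_mismatch, sel$probe_id), , drop = FALSE]
  rownames(sel) <- NULL
  if (nrow(sel) == 0L) {
    warning("no probes passed the specificity screen")
  }
  list(selected = sel, report = report)
}
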