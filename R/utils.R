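#' @keywords internal
"_PACKAGE"

#' @importFrom stats pchisq p.adjust chisq.test rbinom rpois runif setNames
#' @importFrom utils read.table write.table head
NULL

VALID_NT <- c("A", "C", "G", "T", "U", "N")

## Normalize a nucleotide string: uppercase, RNA U -> DNA T.
## Errors on anything outside the ACGTUN alphabet.
normalize_nt <- function(x, what = "sequence") {
  x <- toupper(x)
  bad <- grepl("[^ACGTUN]", x)
  if (any(bad)) {
    stop(sprintf("non-nucleotide characters in %s (first offender: '%s')",
                 what, x[bad][1L]), call. = FALSE)
  }
  chartr("U", "T", x)
}

## Render an internal DNA-alphabet sequence with U (RNA convention) for reports.
as_rna <- function(x) chartr("T", "U", x)

revcomp <- function(x) {
  vapply(x, function(s) {
    chars <- rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1L]])
    paste(chars, collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

## Split sequences into character vectors, preserving names.
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x == floor(x)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
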