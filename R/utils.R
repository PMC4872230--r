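#' @useDynLib mirseed, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Internal sequence alphabet is RNA: T is transposed to U on the way in and
# back-transposed where DNA output is required.

rna_norm <- function(x, what = "sequence") {
  x <- toupper(x)
  x <- chartr("T", "U", x)
  bad <- grepl("[^ACGU]", x)
  if (any(bad)) {
    stop(sprintf("non-RNA characters in %s: %s", what,
                 paste(utils::head(x[bad], 3), collapse = ", ")))
  }
  x
}

dna_norm <- function(x) chartr("U", "T", toupper(x))

encode_rna <- function(seq) {
  codes <- match(strsplit(seq, "")[[1]], c("A", "C", "G", "U")) - 1L
  if (anyNA(codes)) stop("non-RNA characters in sequence")
  codes
}

revcomp_rna <- function(x) {
  vapply(x, function(s) {
    chartr("ACGU", "UGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# Round half away from zero, the convention used by the report tables
# (base round() rounds half to even).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

pct <- function(num, den, digits = 2) {
  if (den == 0) return(0)
  round_half_up(100 * num / den, digits)
}
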