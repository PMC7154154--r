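#' Round half away from zero
#'
#' Base R's \code{round()} rounds half to even; printed percentages in
#' reports conventionally round half up. Only used for display values.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Canonical variant identifier
#'
#' @param variants a variants data frame (see [make_variants()]).
#' @return character vector "chrom:pos:ref:alt".
#' @export
variant_id <- function(variants) {
  paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = ":")
}

#' Normalize chromosome name style
#'
#' Input files in the wild mix "chr5" and "5" dialects; all internal joins
#' are by exact string match, so callers can force one style at the I/O
#' boundary.
#'
#' @param x character vector of chromosome names.
#' @param style "chr" to ensure the prefix, "plain" to strip it.
#' @return character vector in the requested style.
#' @export
normalize_chrom <- function(x, style = c("chr", "plain")) {
  style <- match.arg(style)
  bare <- sub("^chr", "", x)
  if (style == "chr") paste0("chr", bare) else bare
}

#' Reverse complement of a DNA string
#'
#' @param x character vector of sequences over A/C/G/T/N.
#' @return reverse-complemented sequences.
#' @export
reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Stable 32-char hash of an R object, used to stamp reports so a run can
# be tied to its configuration. Serializes to a temp file and md5sums it.
config_hash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf), add = TRUE)
  writeLines(paste(deparse(x[order(names(unlist(x)))]), collapse = ""), tf)
  unname(tools::md5sum(tf))
}

# set.seed wrapper: NULL leaves the RNG stream alone
with_seed_maybe <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
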