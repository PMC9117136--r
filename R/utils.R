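# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @noRd
.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Build a canonical variant key string
#'
#' Keys have the form \code{chrom:pos:ref:alt} and are used wherever variant
#' identity matters (harmonization, projection, site concordance).
#'
#' @param chrom,pos,ref,alt vectors of equal length.
#' @return character vector of keys.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

# Deterministic per-stage sub-seeds so that, for a fixed top-level seed,
# adding draws in one stage (e.g. more variants) never perturbs another
# stage (e.g. disease labels). Offsets are fixed salts; results stay
# below 2^31 - 1.
.substream <- function(seed, stage) {
  offsets <- c(
    alleles     = 101L,
    weights     = 211L,
    frequencies = 307L,
    genotypes   = 401L,
    disease     = 503L,
    misc        = 601L
  )
  off <- offsets[[stage]]
  if (is.null(off)) .stopf("unknown RNG substream '%s'", stage)
  as.integer((as.numeric(seed) * 1009 + off) %% .Machine$integer.max)
}

# Reverse complement for plain ACGT alleles; non-ACGT strings (indels,
# symbolic alleles) are returned as NA so callers can skip strand logic.
.complement_allele <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x) & grepl("^[ACGT]+$", x)
  out[ok] <- vapply(strsplit(x[ok], ""), function(ch) {
    paste(rev(unname(comp[ch])), collapse = "")
  }, character(1))
  out
}

# A/T and C/G SNVs: the same pair of alleles on both strands, so array
# strand cannot be verified from alleles alone.
.is_palindromic <- function(a1, a2) {
  !is.na(a1) & !is.na(a2) &
    nchar(a1) == 1 & nchar(a2) == 1 &
    a1 == .complement_allele(a2)
}

# Full-precision numeric formatting for the plain-text reference bundle.
.fmt_num <- function(x) sprintf("%.17g", x)

.read_tsv <- function(path, ...) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, colClasses = NA, ...)
}

.write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], .fmt_num)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
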