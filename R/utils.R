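#' @keywords internal
"_PACKAGE"

# Closed vocabulary of target region classes, in precedence order: when a
# base falls in several classes the first listed wins.
REGION_CLASSES <- c("CDS", "UTR5", "UTR3", "upstream", "intronic_flank", "other")

EFFECT_CATEGORIES <- c(
  "frameshift_deletion", "frameshift_insertion",
  "nonframeshift_deletion", "nonframeshift_insertion",
  "nonsynonymous_SNV", "synonymous_SNV", "stopgain_SNV", "stoploss_SNV",
  "splicing", "UTR5", "UTR3", "upstream", "intronic", "intergenic",
  "ncRNA", "unknown"
)

NON_SILENT_CATEGORIES <- c(
  "frameshift_deletion", "frameshift_insertion",
  "nonframeshift_deletion", "nonframeshift_insertion",
  "nonsynonymous_SNV", "stopgain_SNV", "stoploss_SNV", "splicing"
)

# Severity used when one variant hits several transcripts (most severe wins).
EFFECT_SEVERITY <- c(
  "frameshift_deletion", "frameshift_insertion",
  "nonframeshift_deletion", "nonframeshift_insertion",
  "stopgain_SNV", "stoploss_SNV", "nonsynonymous_SNV", "splicing",
  "synonymous_SNV", "UTR5", "UTR3", "upstream", "intronic", "ncRNA",
  "intergenic", "unknown"
)

#' Complement DNA bases
#'
#' Vectorized base-wise complement; accepts multi-base allele strings.
#' @param x character vector of DNA strings (A/C/G/T/N).
#' @return complemented strings, same lengths.
#' @export
comp_dna <- function(x) chartr("ACGTNacgtn", "TGCANtgcan", x)

#' Reverse-complement DNA strings
#'
#' @param x character vector of DNA strings.
#' @return reverse complements.
#' @export
revcomp <- function(x) {
  out <- vapply(strsplit(comp_dna(x), "", fixed = TRUE), function(b) {
    paste(rev(b), collapse = "")
  }, character(1))
  unname(out)
}

#' Derive the variant kind from allele lengths
#'
#' SNV if both alleles are one base, MNV if equal multi-base lengths,
#' insertion/deletion otherwise.
#' @param ref,alt allele strings.
#' @return character vector in \{"SNV","MNV","insertion","deletion"\}.
#' @export
variant_kind <- function(ref, alt) {
  lr <- nchar(ref)
  la <- nchar(alt)
  out <- character(length(lr))
  out[lr == la & lr == 1L] <- "SNV"
  out[lr == la & lr > 1L] <- "MNV"
  out[la > lr] <- "insertion"
  out[lr > la] <- "deletion"
  out
}

is_indel <- function(ref, alt) nchar(ref) != nchar(alt)

check_alleles <- function(ref, alt, allow_dash = FALSE) {
  pat <- if (allow_dash) "^([ACGT]+|-)$" else "^[ACGT]+$"
  bad <- !grepl(pat, ref) | !grepl(pat, alt) | (ref == alt)
  if (any(bad)) {
    stop("malformed alleles at entries: ", paste(which(bad), collapse = ", "))
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
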