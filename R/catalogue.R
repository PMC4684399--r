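# Matching called variants against a COSMIC-style somatic mutation
# catalogue: exact matching after canonical (left-aligned, trimmed)
# representation, and loose matching (small positional shifts, and
# multi-nucleotide substitutions split into adjacent SNV calls).

#' Normalize variant representations
#'
#' Converts COSMIC-style `-` alleles to anchored form, trims shared
#' prefix/suffix bases, and left-aligns indels against the reference so
#' that equivalent representations become identical.
#'
#' @param chrom,pos,ref,alt parallel vectors (pos 1-based).
#' @param reference `ref_seq` accessor.
#' @return data frame with normalized chrom, pos, ref, alt.
#' @export
normalize_variants <- function(chrom, pos, ref, alt, reference) {
  n <- length(pos)
  pos <- as.integer(pos)
  for (i in seq_len(n)) {
    r <- ref[i]; a <- alt[i]; p <- pos[i]
    if (identical(r, "-")) {           # pure insertion after p - 1
      anchor <- ref_fetch(reference, chrom[i], p - 2L, p - 1L)
      r <- anchor; a <- paste0(anchor, a); p <- p - 1L
    } else if (identical(a, "-")) {    # pure deletion of bases p..p+len-1
      anchor <- ref_fetch(reference, chrom[i], p - 2L, p - 1L)
      a <- anchor; r <- paste0(anchor, r); p <- p - 1L
    }
    # left-align + trim (vt-style)
    repeat {
      lr <- nchar(r); la <- nchar(a)
      if (lr > 0 && la > 0 && substr(r, lr, lr) == substr(a, la, la)) {
        r <- substr(r, 1, lr - 1L); a <- substr(a, 1, la - 1L)
      } else if (lr == 0 || la == 0) {
        if (p <= 1L) { # cannot extend; re-anchor with first base
          b <- ref_fetch(reference, chrom[i], p - 1L, p)
          r <- paste0(b, r); a <- paste0(b, a)
          break
        }
        b <- ref_fetch(reference, chrom[i], p - 2L, p - 1L)
        r <- paste0(b, r); a <- paste0(b, a); p <- p - 1L
      } else {
        break
      }
    }
    while (nchar(r) > 1 && nchar(a) > 1 && substr(r, 1, 1) == substr(a, 1, 1)) {
      r <- substr(r, 2, nchar(r)); a <- substr(a, 2, nchar(a)); p <- p + 1L
    }
    ref[i] <- r; alt[i] <- a; pos[i] <- p
  }
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

variant_key <- function(df) paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")

#' Exact catalogue matching
#'
#' A call matches a catalogue entry when chrom, pos, ref and alt are all
#' equal after normalization of both sides.
#'
#' @param variants data frame with chrom, pos, ref, alt.
#' @param catalogue catalogue data frame (see [read_catalogue()]).
#' @param reference `ref_seq` used for normalization.
#' @return character vector of matched `catalogue_id` (NA when unmatched).
#' @export
match_exact <- function(variants, catalogue, reference) {
  if (nrow(variants) == 0) return(character(0))
  vn <- normalize_variants(variants$chrom, variants$pos, variants$ref,
                           variants$alt, reference)
  cn <- normalize_variants(catalogue$chrom, catalogue$pos, catalogue$ref,
                           catalogue$alt, reference)
  idx <- match(variant_key(vn), variant_key(cn))
  ifelse(is.na(idx), NA_character_, as.character(catalogue$catalogue_id[idx]))
}

# Is the reference context between two representations of the same allele
# repeat-supported (homopolymer or tandem repeat of the shifted unit)?
shift_context_supported <- function(reference, chrom, pos_a, pos_b, ref_allele, alt_allele) {
  unit <- if (nchar(ref_allele) > nchar(alt_allele)) {
    substr(ref_allele, 2, nchar(ref_allele))
  } else if (nchar(alt_allele) > nchar(ref_allele)) {
    substr(alt_allele, 2, nchar(alt_allele))
  } else {
    ref_allele
  }
  lo <- min(pos_a, pos_b)
  hi <- max(pos_a, pos_b) + nchar(unit)
  ctx <- ref_fetch(reference, chrom, lo - 1L, min(hi, nchar(reference[[chrom]])))
  bases <- strsplit(ctx, "")[[1]]
  if (length(unique(bases)) == 1L) return(TRUE)      # homopolymer
  # tandem repeat with period = unit length
  k <- nchar(unit)
  if (k >= 1 && length(bases) > k) {
    all(bases[seq_len(length(bases) - k)] == bases[seq_len(length(bases) - k) + k])
  } else {
    FALSE
  }
}

#' Loose catalogue matching
#'
#' Two loose criteria: *shifted* — same alleles on the same chromosome with
#' a position difference strictly below `window`; flagged
#' `context_supported` when the intervening reference is a homopolymer or a
#' tandem repeat of the shifted unit (representation-equivalent), otherwise
#' `positional_only`. *split_mnv* — a catalogue multi-nucleotide
#' substitution is matched when the call set contains SNVs that jointly
#' reconstruct it at the constituent positions.
#'
#' @param variants data frame of calls (chrom, pos, ref, alt).
#' @param catalogue catalogue data frame.
#' @param reference `ref_seq` accessor.
#' @param window maximum positional shift, exclusive (default 5).
#' @return data frame with columns catalogue_id, match_kind
#'   (`shifted`/`split_mnv`, NA when unmatched) and context flag.
#' @export
match_loose <- function(variants, catalogue, reference, window = 5L) {
  n <- nrow(variants)
  out <- data.frame(catalogue_id = rep(NA_character_, n),
                    match_kind = rep(NA_character_, n),
                    context = rep(NA_character_, n),
                    stringsAsFactors = FALSE)
  if (n == 0 || nrow(catalogue) == 0) return(out)
  vn <- normalize_variants(variants$chrom, variants$pos, variants$ref,
                           variants$alt, reference)
  cn <- normalize_variants(catalogue$chrom, catalogue$pos, catalogue$ref,
                           catalogue$alt, reference)
  # shifted matches
  for (i in seq_len(n)) {
    hit <- which(cn$chrom == vn$chrom[i] & cn$ref == vn$ref[i] &
                   cn$alt == vn$alt[i] & abs(cn$pos - vn$pos[i]) < window)
    if (length(hit)) {
      j <- hit[which.min(abs(cn$pos[hit] - vn$pos[i]))]
      out$catalogue_id[i] <- as.character(catalogue$catalogue_id[j])
      out$match_kind[i] <- "shifted"
      supported <- vn$pos[i] == cn$pos[j] ||
        shift_context_supported(reference, vn$chrom[i], vn$pos[i], cn$pos[j],
                                vn$ref[i], vn$alt[i])
      out$context[i] <- if (supported) "context_supported" else "positional_only"
    }
  }
  # split MNV matches: catalogue MNV reconstructed from adjacent SNV calls
  is_mnv <- nchar(cn$ref) > 1 & nchar(cn$ref) == nchar(cn$alt)
  snv <- nchar(vn$ref) == 1 & nchar(vn$alt) == 1
  for (j in which(is_mnv)) {
    len <- nchar(cn$ref[j])
    rb <- strsplit(cn$ref[j], "")[[1]]
    ab <- strsplit(cn$alt[j], "")[[1]]
    need <- which(rb != ab)
    members <- integer(0)
    ok <- TRUE
    for (k in need) {
      m <- which(snv & vn$chrom == cn$chrom[j] & vn$pos == cn$pos[j] + k - 1L &
                   vn$ref == rb[k] & vn$alt == ab[k])
      if (!length(m)) { ok <- FALSE; break }
      members <- c(members, m[1])
    }
    if (ok && length(members) >= 2) {
      fill <- members[is.na(out$match_kind[members])]
      out$catalogue_id[fill] <- as.character(catalogue$catalogue_id[j])
      out$match_kind[fill] <- "split_mnv"
    }
  }
  out
}

#' Flag variants as known or novel against a catalogue
#'
#' A variant is novel when it matches neither exactly nor loosely. Exact
#' matches take precedence over loose ones in the reported status.
#'
#' @inheritParams match_loose
#' @return `variants` with added columns match_status
#'   (`exact`/`loose_shifted`/`loose_split`/`novel`), catalogue_id, novel.
#' @export
flag_novel <- function(variants, catalogue, reference, window = 5L) {
  ex <- match_exact(variants, catalogue, reference)
  lo <- match_loose(variants, catalogue, reference, window)
  status <- rep("novel", nrow(variants))
  cid <- rep(NA_character_, nrow(variants))
  shifted <- !is.na(lo$match_kind) & lo$match_kind == "shifted"
  split <- !is.na(lo$match_kind) & lo$match_kind == "split_mnv"
  status[split] <- "loose_split"; cid[split] <- lo$catalogue_id[split]
  status[shifted] <- "loose_shifted"; cid[shifted] <- lo$catalogue_id[shifted]
  status[!is.na(ex)] <- "exact"; cid[!is.na(ex)] <- ex[!is.na(ex)]
  variants$match_status <- status
  variants$catalogue_id <- cid
  variants$novel <- status == "novel"
  variants
}
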