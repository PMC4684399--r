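# Effect categorization of variants against gene models.

GENETIC_CODE <- Biostrings::GENETIC_CODE

translate_codons <- function(seq) {
  n <- nchar(seq) %/% 3L
  codons <- substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  paste(unname(GENETIC_CODE[codons]), collapse = "")
}

# Spliced CDS of a transcript on the coding strand.
transcript_cds <- function(tx, reference) {
  s <- tx$exon_starts[[1]]; e <- tx$exon_ends[[1]]
  cs <- tx$cds_start; ce <- tx$cds_end
  ks <- pmax(s, cs); ke <- pmin(e, ce)
  keep <- ks < ke
  parts <- mapply(function(a, b) ref_fetch(reference, tx$chrom, a, b),
                  ks[keep], ke[keep])
  cds <- paste(parts, collapse = "")
  if (tx$strand == "-") cds <- revcomp(cds)
  cds
}

# 0-based CDS coordinate (coding strand) of genomic 0-based position p0,
# NA when p0 is not an exonic CDS base.
cds_coord <- function(tx, p0) {
  s <- tx$exon_starts[[1]]; e <- tx$exon_ends[[1]]
  cs <- tx$cds_start; ce <- tx$cds_end
  if (p0 < cs || p0 >= ce) return(NA_integer_)
  ks <- pmax(s, cs); ke <- pmin(e, ce)
  keep <- ks < ke
  ks <- ks[keep]; ke <- ke[keep]
  idx <- which(p0 >= ks & p0 < ke)
  if (!length(idx)) return(NA_integer_)
  plus <- sum(ke[seq_len(idx - 1)] - ks[seq_len(idx - 1)]) + (p0 - ks[idx])
  if (tx$strand == "+") return(as.integer(plus))
  total <- sum(ke - ks)
  as.integer(total - 1L - plus)
}

in_exon <- function(tx, p0) {
  any(p0 >= tx$exon_starts[[1]] & p0 < tx$exon_ends[[1]])
}

in_splice_window <- function(tx, p0, w) {
  s <- tx$exon_starts[[1]]; e <- tx$exon_ends[[1]]
  k <- length(s)
  if (k < 2) return(FALSE)
  donor <- unlist(lapply(e[-k], function(x) x + seq_len(w) - 1L))
  accept <- unlist(lapply(s[-1], function(x) x - seq_len(w)))
  p0 %in% c(donor, accept)
}

# Classify one variant against one transcript; returns list(category, cdot, pdot).
effect_on_transcript <- function(chrom, pos, ref, alt, tx, reference,
                                 splice_window, upstream_len) {
  none <- list(category = NA_character_, cdot = NA_character_, pdot = NA_character_)
  if (chrom != tx$chrom) return(none)
  p0 <- pos - 1L
  kind <- variant_kind(ref, alt)
  tx_start <- tx$exon_starts[[1]][1]
  tx_end <- tx$exon_ends[[1]][length(tx$exon_ends[[1]])]
  coding_tx <- tx$cds_start < tx$cds_end

  # span of reference bases affected (deletions affect bases after anchor)
  if (kind == "deletion") {
    aff0 <- p0 + 1L
    aff1 <- p0 + nchar(ref) - 1L
  } else if (kind == "insertion") {
    aff0 <- p0; aff1 <- p0
  } else {
    aff0 <- p0; aff1 <- p0 + nchar(ref) - 1L
  }
  affected <- aff0:aff1

  if (coding_tx) {
    cds_hit <- any(vapply(affected, function(p) !is.na(cds_coord(tx, p)), TRUE))
    if (cds_hit) {
      if (kind %in% c("insertion", "deletion")) {
        len <- abs(nchar(ref) - nchar(alt))
        cat <- if (len %% 3L == 0L) {
          if (kind == "deletion") "nonframeshift_deletion" else "nonframeshift_insertion"
        } else {
          if (kind == "deletion") "frameshift_deletion" else "frameshift_insertion"
        }
        return(list(category = cat, cdot = NA_character_, pdot = NA_character_))
      }
      # substitution: mutate the affected codon range on the coding strand
      cds <- transcript_cds(tx, reference)
      idx <- vapply(affected, function(p) cds_coord(tx, p), integer(1))
      sub_ref <- strsplit(ref, "")[[1]]
      sub_alt <- strsplit(alt, "")[[1]]
      if (tx$strand == "-") {
        sub_ref <- comp_dna(sub_ref)
        sub_alt <- comp_dna(sub_alt)
      }
      keep <- !is.na(idx)
      idx <- idx[keep]; sub_ref <- sub_ref[keep]; sub_alt <- sub_alt[keep]
      c0 <- min(idx) %/% 3L
      c1 <- max(idx) %/% 3L
      win0 <- 3L * c0 + 1L
      win1 <- min(nchar(cds), 3L * (c1 + 1L))
      old <- strsplit(substr(cds, win0, win1), "")[[1]]
      new <- old
      new[idx - 3L * c0 + 1L] <- sub_alt
      old_aa <- translate_codons(paste(old, collapse = ""))
      new_aa <- translate_codons(paste(new, collapse = ""))
      cat <- if (identical(old_aa, new_aa)) {
        "synonymous_SNV"
      } else if (grepl("\\*", new_aa) && !grepl("\\*", old_aa)) {
        "stopgain_SNV"
      } else if (grepl("\\*", old_aa) && !grepl("\\*", new_aa)) {
        "stoploss_SNV"
      } else {
        "nonsynonymous_SNV"
      }
      cdot <- pdot <- NA_character_
      if (kind == "SNV") {
        cdot <- sprintf("c.%s%d%s", sub_ref[1], idx[1] + 1L, sub_alt[1])
        pdot <- sprintf("p.%s%d%s", substr(old_aa, 1, 1), c0 + 1L,
                        substr(new_aa, 1, 1))
      }
      return(list(category = cat, cdot = cdot, pdot = pdot))
    }
    if (any(vapply(affected, function(p) in_splice_window(tx, p, splice_window), TRUE))) {
      return(list(category = "splicing", cdot = NA_character_, pdot = NA_character_))
    }
  }
  exonic <- any(vapply(affected, function(p) in_exon(tx, p), TRUE))
  if (exonic) {
    if (!coding_tx) return(list(category = "ncRNA", cdot = NA_character_,
                                pdot = NA_character_))
    before_cds <- aff1 < tx$cds_start
    after_cds <- aff0 >= tx$cds_end
    utr <- if (tx$strand == "+") {
      if (before_cds) "UTR5" else "UTR3"
    } else {
      if (after_cds) "UTR5" else "UTR3"
    }
    return(list(category = utr, cdot = NA_character_, pdot = NA_character_))
  }
  if (p0 >= tx_start && p0 < tx_end) {
    return(list(category = "intronic", cdot = NA_character_, pdot = NA_character_))
  }
  upstream <- if (tx$strand == "+") {
    p0 >= tx_start - upstream_len && p0 < tx_start
  } else {
    p0 >= tx_end && p0 < tx_end + upstream_len
  }
  if (upstream) {
    return(list(category = "upstream", cdot = NA_character_, pdot = NA_character_))
  }
  none
}

#' Annotate variant effects against gene models
#'
#' Each variant is classified against every transcript it touches; when
#' several transcripts give different categories the most severe wins
#' (frameshift highest, then nonframeshift indels, stopgain, stoploss,
#' nonsynonymous, splicing, synonymous, UTRs, upstream, intronic, ncRNA).
#' CDS substitutions are judged by translating the affected codon(s) on the
#' coding strand before and after the change; CDS indels by length
#' divisibility by 3; variants within `splice_window` bases inside an intron
#' of a coding transcript are splicing; the remainder fall back to
#' UTR5/UTR3/upstream (within `upstream_len` of the transcription start) /
#' intronic / intergenic. c. and p. descriptors are emitted for CDS SNVs.
#'
#' @param variants data frame with chrom, pos (1-based), ref, alt.
#' @param gene_models gene model data frame (see [read_gene_models()]).
#' @param reference `ref_seq` accessor.
#' @param splice_window intronic bases from an exon boundary called splicing
#'   (default 2, the canonical donor/acceptor dinucleotide).
#' @param upstream_len upstream annotation window in bp (default 1000).
#' @return `variants` with added columns category, gene, cdot, pdot.
#' @export
annotate_effects <- function(variants, gene_models, reference,
                             splice_window = 2L, upstream_len = 1000L) {
  n <- nrow(variants)
  category <- rep("intergenic", n)
  gene <- rep(NA_character_, n)
  cdot <- rep(NA_character_, n)
  pdot <- rep(NA_character_, n)
  sev <- function(cat) match(cat, EFFECT_SEVERITY)
  tx_list <- split(gene_models, seq_len(nrow(gene_models)))
  for (i in seq_len(n)) {
    best <- NULL
    best_gene <- NA_character_
    for (tx in tx_list) {
      res <- effect_on_transcript(variants$chrom[i], variants$pos[i],
                                  variants$ref[i], variants$alt[i],
                                  tx, reference, splice_window, upstream_len)
      if (is.na(res$category)) next
      if (is.null(best) || sev(res$category) < sev(best$category)) {
        best <- res
        best_gene <- tx$gene
      }
    }
    if (!is.null(best)) {
      category[i] <- best$category
      gene[i] <- best_gene
      cdot[i] <- best$cdot
      pdot[i] <- best$pdot
    }
  }
  variants$category <- category
  variants$gene <- gene
  variants$cdot <- cdot
  variants$pdot <- pdot
  variants
}

#' Is an effect category non-silent?
#'
#' Non-silent mutations are exonic indels, nonsynonymous, stopgain and
#' stoploss SNVs, and splicing variants.
#' @param category character vector of effect categories.
#' @return logical vector.
#' @export
is_non_silent <- function(category) {
  bad <- setdiff(unique(category), EFFECT_CATEGORIES)
  if (length(bad)) stop("unknown effect category: ", paste(bad, collapse = ", "))
  category %in% NON_SILENT_CATEGORIES
}
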