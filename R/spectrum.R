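# Strand-collapsed substitution spectra, trinucleotide contexts,
# composition denominators, and coding vs non-coding enrichment statistics.

SUBSTITUTION_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

trinuc_labels <- function() {
  b <- c("A", "C", "G", "T")
  out <- character(0)
  for (center in c("C", "T")) {
    for (l in b) for (r in b) out <- c(out, paste0(l, "[", center, "]", r))
  }
  out
}
TRINUC_CONTEXTS <- trinuc_labels()

#' Collapse a substitution to its pyrimidine-centered class
#'
#' Purine-centered substitutions are mapped to the complementary
#' pyrimidine-centered class (G>A becomes C>T, A>G becomes T>C, ...).
#'
#' @param ref,alt single reference/alternate bases (vectors).
#' @return factor-like character vector over the six classes.
#' @export
collapse_substitution <- function(ref, alt) {
  if (any(!ref %in% c("A", "C", "G", "T")) || any(!alt %in% c("A", "C", "G", "T"))) {
    stop("non-ACGT base in substitution")
  }
  if (any(ref == alt)) stop("ref == alt is not a substitution")
  flip <- ref %in% c("A", "G")
  r <- ifelse(flip, comp_dna(ref), ref)
  a <- ifelse(flip, comp_dna(alt), alt)
  paste0(r, ">", a)
}

#' Render a collapsed class in paired (both-strand) notation
#' @param cls class label like `"C>T"`.
#' @return label like `"C/G>T/A"`.
#' @export
format_substitution <- function(cls) {
  r <- substr(cls, 1, 1)
  a <- substr(cls, 3, 3)
  paste0(r, "/", comp_dna(r), ">", a, "/", comp_dna(a))
}

#' Pyrimidine-collapsed trinucleotide context of SNVs
#'
#' Fetches the reference base on each side of the mutated base; contexts
#' with a purine center are stored as the reverse complement. Variants at a
#' contig edge or with an N in the window get NA.
#'
#' @param chrom,pos vectors (pos 1-based) of SNV sites.
#' @param reference `ref_seq` accessor.
#' @return character vector of 32 collapsed context labels (`X[Y]Z`).
#' @export
trinuc_context <- function(chrom, pos, reference) {
  n <- length(pos)
  out <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    len <- nchar(reference[[chrom[i]]])
    p0 <- pos[i] - 1L
    if (p0 < 1L || p0 > len - 2L) next
    tri <- ref_fetch(reference, chrom[i], p0 - 1L, p0 + 2L)
    if (grepl("N", tri)) next
    center <- substr(tri, 2, 2)
    if (center %in% c("A", "G")) tri <- revcomp(tri)
    out[i] <- paste0(substr(tri, 1, 1), "[", substr(tri, 2, 2), "]",
                     substr(tri, 3, 3))
  }
  out
}

#' Render a collapsed context in paired notation
#' @param ctx label like `"T[C]T"`.
#' @return label like `"T[C]T/A[G]A"`.
#' @export
format_context <- function(ctx) {
  tri <- paste0(substr(ctx, 1, 1), substr(ctx, 3, 3), substr(ctx, 5, 5))
  rc <- revcomp(tri)
  paste0(ctx, "/", substr(rc, 1, 1), "[", substr(rc, 2, 2), "]",
         substr(rc, 3, 3))
}

# 0-based positions of a stratum's bases, resolved by class precedence.
stratum_positions <- function(regions, stratum = c("coding", "non_coding"),
                              include_flank = TRUE) {
  stratum <- match.arg(stratum)
  res <- list()
  for (ch in unique(regions$chrom)) {
    rs <- regions[regions$chrom == ch, , drop = FALSE]
    pos <- sort(unique(unlist(mapply(function(s, e) s:(e - 1L), rs$start, rs$end,
                                     SIMPLIFY = FALSE))))
    cls <- resolve_region_class(rs, rep(ch, length(pos)), pos)
    keep <- if (stratum == "coding") {
      cls == "CDS"
    } else if (include_flank) {
      !is.na(cls) & cls != "CDS"
    } else {
      !is.na(cls) & !cls %in% c("CDS", "intronic_flank")
    }
    res[[ch]] <- pos[keep]
  }
  res
}

#' Base and trinucleotide composition of a stratum
#'
#' Tallies G/C and A/T bases over the stratum's bases (coding = CDS bases,
#' non-coding = all other targeted bases, by class precedence), and the 32
#' collapsed trinucleotide counts over every window whose center base lies
#' in the stratum (flanks may extend outside it). N bases are excluded from
#' the base tallies and windows containing N are skipped.
#'
#' @param regions `region_set`.
#' @param reference `ref_seq`.
#' @param stratum `"coding"` or `"non_coding"`.
#' @param include_flank count intronic-flank bases in the non-coding
#'   stratum (default TRUE).
#' @return object of class `stratum_composition`: list with stratum,
#'   total_bases, gc_bases, at_bases, trinuc (named integer vector of 32).
#' @export
stratum_composition <- function(regions, reference,
                                stratum = c("coding", "non_coding"),
                                include_flank = TRUE) {
  stratum <- match.arg(stratum)
  posl <- stratum_positions(regions, stratum, include_flank)
  gc <- 0L; at <- 0L
  tri_counts <- stats::setNames(integer(length(TRINUC_CONTEXTS)), TRINUC_CONTEXTS)
  for (ch in names(posl)) {
    pos <- posl[[ch]]
    if (!length(pos)) next
    seq_ch <- reference[[ch]]
    bases <- substring(seq_ch, pos + 1L, pos + 1L)
    gc <- gc + sum(bases %in% c("G", "C"))
    at <- at + sum(bases %in% c("A", "T"))
    inb <- pos >= 1L & pos <= nchar(seq_ch) - 2L
    p <- pos[inb]
    tris <- substring(seq_ch, p, p + 2L)
    tris <- tris[!grepl("N", tris)]
    centers <- substr(tris, 2, 2)
    pur <- centers %in% c("A", "G")
    tris[pur] <- revcomp(tris[pur])
    lab <- paste0(substr(tris, 1, 1), "[", substr(tris, 2, 2), "]",
                  substr(tris, 3, 3))
    tb <- table(factor(lab, levels = TRINUC_CONTEXTS))
    tri_counts <- tri_counts + as.integer(tb)
  }
  structure(list(stratum = stratum, total_bases = gc + at, gc_bases = gc,
                 at_bases = at, trinuc = tri_counts),
            class = "stratum_composition")
}

#' @export
print.stratum_composition <- function(x, ...) {
  cat(sprintf("stratum %s: %d bases (GC %.1f%%), %d trinucleotide windows\n",
              x$stratum, x$total_bases,
              100 * x$gc_bases / max(1, x$total_bases), sum(x$trinuc)))
  invisible(x)
}

#' Transition/transversion ratio
#'
#' Transitions are A<->G and C<->T; everything else is a transversion.
#' @param ref,alt single-base vectors.
#' @return ratio; NaN (flagged undefined) when there are no transversions.
#' @export
titv_ratio <- function(ref, alt) {
  cls <- collapse_substitution(ref, alt)
  ti <- sum(cls %in% c("C>T", "T>C"))
  tv <- sum(!cls %in% c("C>T", "T>C"))
  if (tv == 0) return(NaN)
  ti / tv
}

#' Mutations per megabase
#' @param variant_count number of mutations.
#' @param stratum_bases eligible bases (> 0).
#' @return mutations per Mbp.
#' @export
mutation_rate <- function(variant_count, stratum_bases) {
  if (any(stratum_bases <= 0)) stop("stratum_bases must be > 0")
  variant_count / (stratum_bases / 1e6)
}

#' Coding vs non-coding enrichment test for one class or context
#'
#' Builds the 2x2 table (mutated vs eligible-minus-mutated, coding vs
#' non-coding). The odds ratio is (a/b)/(c/d) with a 95% Woolf (log-OR
#' normal approximation) confidence interval; the raw p-value is the Wald
#' test of the stratum coefficient in a binomial logistic regression on the
#' aggregated counts; Bonferroni adjustment multiplies by `m_tests`, capped
#' at 1. Any zero margin or zero cell leaves the OR/CI flagged undefined
#' without raising an error.
#'
#' @param label class or context label.
#' @param mutated_coding,eligible_coding,mutated_noncoding,eligible_noncoding
#'   counts; eligible counts are the stratum's source-base (or context)
#'   totals.
#' @param m_tests Bonferroni family size.
#' @return object of class `enrichment_result` (a one-row data frame with
#'   label, counts, odds_ratio, ci_low, ci_high, se_log_or, p_raw,
#'   p_adjusted, m_tests, defined).
#' @export
enrichment_test <- function(label, mutated_coding, eligible_coding,
                            mutated_noncoding, eligible_noncoding,
                            m_tests = 1L) {
  a <- mutated_coding
  b <- eligible_coding - mutated_coding
  c <- mutated_noncoding
  d <- eligible_noncoding - mutated_noncoding
  defined <- all(c(a, b, c, d) > 0)
  or <- ci_lo <- ci_hi <- se <- p_raw <- NA_real_
  if (defined) {
    or <- (a / b) / (c / d)
    se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
    ci_lo <- exp(log(or) - 1.96 * se)
    ci_hi <- exp(log(or) + 1.96 * se)
    fit <- suppressWarnings(
      stats::glm(cbind(c(a, c), c(b, d)) ~ factor(c("coding", "noncoding"),
                                                  levels = c("noncoding", "coding")),
                 family = stats::binomial()))
    p_raw <- summary(fit)$coefficients[2, 4]
  }
  res <- data.frame(label = label, mutated_coding = a,
                    eligible_coding = eligible_coding,
                    mutated_noncoding = c,
                    eligible_noncoding = eligible_noncoding,
                    odds_ratio = or, ci_low = ci_lo, ci_high = ci_hi,
                    se_log_or = se, p_raw = p_raw,
                    p_adjusted = if (is.na(p_raw)) NA_real_ else min(1, m_tests * p_raw),
                    m_tests = m_tests, defined = defined,
                    stringsAsFactors = FALSE)
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' @export
print.enrichment_result <- function(x, ...) {
  need <- c("label", "defined", "odds_ratio", "ci_low", "ci_high",
            "p_raw", "p_adjusted")
  if (!all(need %in% names(x))) return(NextMethod())
  for (i in seq_len(nrow(x))) {
    if (x$defined[i]) {
      cat(sprintf("%-12s OR %.2f (95%% CI %.2f-%.2f), p = %.3g (adj %.3g)\n",
                  x$label[i], x$odds_ratio[i], x$ci_low[i], x$ci_high[i],
                  x$p_raw[i], x$p_adjusted[i]))
    } else {
      cat(sprintf("%-12s OR undefined (zero cell)\n", x$label[i]))
    }
  }
  invisible(x)
}

#' Per-sample heterogeneity diagnostic for an enrichment comparison
#'
#' Likelihood-ratio test of the stratum-by-sample interaction in a binomial
#' logistic model on per-sample aggregated counts. Reported as a
#' diagnostic; the headline odds ratio pools samples.
#'
#' @param counts data frame with columns sample, stratum
#'   (coding/noncoding), mutated, eligible.
#' @return list with p_interaction and the fitted deviances.
#' @export
enrichment_heterogeneity <- function(counts) {
  if (length(unique(counts$sample)) < 2) {
    return(list(p_interaction = NA_real_, deviance_null = NA_real_,
                deviance_full = NA_real_))
  }
  f0 <- suppressWarnings(
    stats::glm(cbind(mutated, eligible - mutated) ~ stratum + sample,
               family = stats::binomial(), data = counts))
  f1 <- suppressWarnings(
    stats::glm(cbind(mutated, eligible - mutated) ~ stratum * sample,
               family = stats::binomial(), data = counts))
  lrt <- stats::anova(f0, f1, test = "LRT")
  list(p_interaction = lrt$`Pr(>Chi)`[2],
       deviance_null = stats::deviance(f0), deviance_full = stats::deviance(f1))
}

#' Spectrum report: class and context tables with enrichment statistics
#'
#' Restricts to high-confidence somatic SNVs whose stratum resolves to
#' coding or non-coding, then tabulates per-class and per-context counts
#' per sample and pooled, G/C-replacement fractions, Ti/Tv per stratum, and
#' one [enrichment_test()] row per class (eligible = GC bases for
#' C-centered classes, AT bases for T-centered) and per context (eligible =
#' that context's trinucleotide count). Forest-plot export uses marker
#' size proportional to 1/SE of ln OR.
#'
#' @param variants classified variant data frame with columns sample, ref,
#'   alt, chrom, pos, kind, somatic, confidence, stratum.
#' @param comp_coding,comp_noncoding [stratum_composition()] objects.
#' @param reference `ref_seq` (for contexts).
#' @param m_classes,m_contexts Bonferroni family sizes (defaults 6 and 32).
#' @return list with class_counts, context_counts, gc_fraction, titv,
#'   class_enrichment, context_enrichment, forest, heterogeneity.
#' @export
spectrum_report <- function(variants, comp_coding, comp_noncoding, reference,
                            m_classes = 6L, m_contexts = 32L) {
  keep <- variants$kind == "SNV" & variants$somatic &
    !is.na(variants$confidence) & variants$confidence == "high" &
    !is.na(variants$stratum)
  v <- variants[keep, , drop = FALSE]
  v$class <- if (nrow(v)) collapse_substitution(v$ref, v$alt) else character(0)
  v$context <- trinuc_context(v$chrom, v$pos, reference)
  v$str2 <- ifelse(v$stratum == "CDS", "coding", "non_coding")

  samples <- sort(unique(v$sample))
  tab <- function(values, levels) {
    out <- list()
    for (st in c("coding", "non_coding")) {
      sub <- v$str2 == st
      per <- sapply(samples, function(s) {
        table(factor(values[sub & v$sample == s], levels = levels))
      })
      if (length(samples) == 0) per <- matrix(0L, nrow = length(levels), ncol = 0)
      pooled <- table(factor(values[sub], levels = levels))
      out[[st]] <- cbind(as.data.frame.matrix(t(t(per))), pooled = as.integer(pooled))
    }
    out
  }
  class_counts <- tab(v$class, SUBSTITUTION_CLASSES)
  context_counts <- tab(v$context, TRINUC_CONTEXTS)

  gc_fraction <- vapply(c(coding = "coding", non_coding = "non_coding"), function(st) {
    sub <- v$str2 == st
    if (!sum(sub)) return(NA_real_)
    mean(substr(v$class[sub], 1, 1) == "C")
  }, numeric(1))
  titv <- vapply(c(coding = "coding", non_coding = "non_coding"), function(st) {
    sub <- v$str2 == st
    if (!sum(sub)) return(NA_real_)
    titv_ratio(v$ref[sub], v$alt[sub])
  }, numeric(1))

  eligible_class <- function(comp, cls) {
    if (substr(cls, 1, 1) == "C") comp$gc_bases else comp$at_bases
  }
  class_enrich <- do.call(rbind, lapply(SUBSTITUTION_CLASSES, function(cls) {
    enrichment_test(format_substitution(cls),
                    sum(v$class == cls & v$str2 == "coding"),
                    eligible_class(comp_coding, cls),
                    sum(v$class == cls & v$str2 == "non_coding"),
                    eligible_class(comp_noncoding, cls),
                    m_tests = m_classes)
  }))
  ctx_enrich <- do.call(rbind, lapply(TRINUC_CONTEXTS, function(ctx) {
    enrichment_test(format_context(ctx),
                    sum(!is.na(v$context) & v$context == ctx & v$str2 == "coding"),
                    comp_coding$trinuc[[ctx]],
                    sum(!is.na(v$context) & v$context == ctx & v$str2 == "non_coding"),
                    comp_noncoding$trinuc[[ctx]],
                    m_tests = m_contexts)
  }))
  forest <- rbind(
    data.frame(family = "class", label = class_enrich$label,
               odds_ratio = class_enrich$odds_ratio,
               ci_low = class_enrich$ci_low, ci_high = class_enrich$ci_high,
               se_log_or = class_enrich$se_log_or,
               marker_size = 1 / class_enrich$se_log_or,
               p_adjusted = class_enrich$p_adjusted, stringsAsFactors = FALSE),
    data.frame(family = "context", label = ctx_enrich$label,
               odds_ratio = ctx_enrich$odds_ratio,
               ci_low = ctx_enrich$ci_low, ci_high = ctx_enrich$ci_high,
               se_log_or = ctx_enrich$se_log_or,
               marker_size = 1 / ctx_enrich$se_log_or,
               p_adjusted = ctx_enrich$p_adjusted, stringsAsFactors = FALSE)
  )
  het <- if (length(samples) >= 2 && nrow(v) > 0) {
    counts <- do.call(rbind, lapply(samples, function(s) {
      data.frame(sample = s,
                 stratum = c("coding", "noncoding"),
                 mutated = c(sum(v$sample == s & v$str2 == "coding"),
                             sum(v$sample == s & v$str2 == "non_coding")),
                 eligible = c(comp_coding$total_bases, comp_noncoding$total_bases),
                 stringsAsFactors = FALSE)
    }))
    enrichment_heterogeneity(counts)
  } else {
    list(p_interaction = NA_real_)
  }
  list(n_snvs = nrow(v), class_counts = class_counts,
       context_counts = context_counts, gc_fraction = gc_fraction,
       titv = titv, class_enrichment = class_enrich,
       context_enrichment = ctx_enrich, forest = forest, heterogeneity = het)
}
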