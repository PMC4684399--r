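# Somatic classification: hard filters and the tumor/normal decision rule.

#' Hard-filter and somatic-confidence thresholds
#'
#' Defaults reproduce a GATK UnifiedGenotyper-era filtering scheme for
#' targeted panels: emit threshold 10; SNV/MNV rule set
#' (QUAL < 40, QD < 5.0, HRun > 5, FS > 200.0 each fail); indel rule set
#' (QUAL < 40, QD < 2.0, ReadPosRankSum < -20.0, FS > 200.0); and the
#' high-confidence somatic evidence rule (normal informative depth >= 10,
#' normal alternate reads <= 1, tumor alternate reads >= 3).
#'
#' @param min_call_quality_emit minimum call quality to consider at all.
#' @param snv list of SNV/MNV filter thresholds.
#' @param indel list of indel filter thresholds.
#' @param somatic_high list of high-confidence evidence thresholds.
#' @return object of class `filter_thresholds`.
#' @export
filter_thresholds <- function(min_call_quality_emit = 10,
                              snv = list(min_quality = 40, min_qd = 5.0,
                                         max_hrun = 5, max_fs = 200.0),
                              indel = list(min_quality = 40, min_qd = 2.0,
                                           min_read_pos_rank_sum = -20.0,
                                           max_fs = 200.0),
                              somatic_high = list(min_normal_depth = 10,
                                                  max_normal_alt_reads = 1,
                                                  min_tumor_alt_reads = 3)) {
  structure(list(min_call_quality_emit = min_call_quality_emit,
                 snv = snv, indel = indel, somatic_high = somatic_high),
            class = "filter_thresholds")
}

#' Apply hard variant-call filters
#'
#' SNVs and MNVs are judged by the SNV rule set, insertions and deletions by
#' the indel rule set. All comparisons are strict, so boundary values pass.
#' Missing annotations (NA) pass the corresponding criterion, mirroring the
#' semantics of `value < threshold` being false for an absent value. Calls
#' below the emit threshold fail with reason `below_emit`.
#'
#' @param calls data frame of paired calls (see [read_vcf_pairs()]).
#' @param thresholds a [filter_thresholds()] object.
#' @return list with logical vector `pass` and list `reasons` of violated
#'   criteria per call (empty character vector means pass).
#' @export
apply_hard_filters <- function(calls, thresholds = filter_thresholds()) {
  n <- nrow(calls)
  kind <- variant_kind(calls$ref, calls$alt)
  indel <- kind %in% c("insertion", "deletion")
  th <- thresholds
  lt <- function(x, cut) !is.na(x) & x < cut
  gt <- function(x, cut) !is.na(x) & x > cut

  reasons <- vector("list", n)
  below_emit <- lt(calls$qual, th$min_call_quality_emit) | is.na(calls$qual)
  fail_qual <- ifelse(indel, lt(calls$qual, th$indel$min_quality),
                      lt(calls$qual, th$snv$min_quality))
  fail_qd <- ifelse(indel, lt(calls$qd, th$indel$min_qd),
                    lt(calls$qd, th$snv$min_qd))
  fail_hrun <- !indel & gt(calls$hrun, th$snv$max_hrun)
  fail_rprs <- indel & lt(calls$read_pos_rank_sum, th$indel$min_read_pos_rank_sum)
  fail_fs <- ifelse(indel, gt(calls$fs, th$indel$max_fs),
                    gt(calls$fs, th$snv$max_fs))

  for (i in seq_len(n)) {
    if (below_emit[i]) {
      reasons[[i]] <- "below_emit"
      next
    }
    r <- character(0)
    if (fail_qual[i]) r <- c(r, "QUAL")
    if (fail_qd[i]) r <- c(r, "QD")
    if (fail_hrun[i]) r <- c(r, "HRun")
    if (fail_rprs[i]) r <- c(r, "ReadPosRankSum")
    if (fail_fs[i]) r <- c(r, "FS")
    reasons[[i]] <- r
  }
  list(pass = lengths(reasons) == 0L, reasons = reasons)
}

#' Classify paired calls as somatic with a confidence tier
#'
#' A call is somatic when the tumor genotype includes the alternate allele
#' while the normal genotype is homozygous reference. Somatic calls are
#' high confidence when they pass the hard filters, the normal informative
#' depth (AD ref + alt) is >= 10 with <= 1 alternate-supporting read, and
#' the tumor has >= 3 alternate-supporting reads; otherwise low confidence.
#' Zygosity is homozygous when both tumor alleles equal the alternate.
#'
#' @param calls data frame of paired calls.
#' @param thresholds a [filter_thresholds()] object.
#' @return `calls` with added columns: kind, passed_filters, filter_reasons,
#'   somatic, zygosity, confidence (NA for non-somatic rows).
#' @export
classify_somatic <- function(calls, thresholds = filter_thresholds()) {
  flt <- apply_hard_filters(calls, thresholds)
  sh <- thresholds$somatic_high
  tumor_has_alt <- calls$tumor_a1 == calls$alt | calls$tumor_a2 == calls$alt
  normal_refref <- calls$normal_a1 == calls$ref & calls$normal_a2 == calls$ref
  somatic <- tumor_has_alt & normal_refref
  hom <- calls$tumor_a1 == calls$alt & calls$tumor_a2 == calls$alt
  normal_depth <- calls$normal_ref_reads + calls$normal_alt_reads
  high <- flt$pass &
    normal_depth >= sh$min_normal_depth &
    calls$normal_alt_reads <= sh$max_normal_alt_reads &
    calls$tumor_alt_reads >= sh$min_tumor_alt_reads

  out <- calls
  out$kind <- variant_kind(calls$ref, calls$alt)
  out$passed_filters <- flt$pass
  out$filter_reasons <- vapply(flt$reasons, paste, "", collapse = ";")
  out$somatic <- somatic
  out$zygosity <- ifelse(somatic, ifelse(hom, "homozygous", "heterozygous"),
                         NA_character_)
  out$confidence <- ifelse(somatic, ifelse(high, "high", "low"), NA_character_)
  out
}

#' Summarize classified variants into study-style count tables
#'
#' Produces per-sample and pooled counts of called SNVs/indels, heterozygous
#' and homozygous high-confidence somatic variants, per-effect-category
#' counts, the non-silent count (exonic indels + nonsynonymous + stopgain +
#' stoploss + splicing) and novel counts when a `novel` column is present.
#' The mean column is the pooled count divided by the number of samples.
#'
#' @param variants classified (and effect-annotated) variant data frame with
#'   columns sample, kind, somatic, zygosity, confidence and, for the
#'   category rows, category (and optionally novel).
#' @return data frame with one row per metric and one column per sample plus
#'   `mean` and `total`.
#' @export
summarize_counts <- function(variants) {
  if (!is.null(variants$category)) {
    bad <- setdiff(unique(variants$category), EFFECT_CATEGORIES)
    if (length(bad)) stop("unknown effect category: ", paste(bad, collapse = ", "))
  }
  samples <- sort(unique(as.character(variants$sample %||% character(0))))
  if (length(samples) == 0) samples <- character(0)

  count_by <- function(mask) {
    v <- table(factor(variants$sample[mask], levels = samples))
    as.integer(v)
  }
  high <- !is.na(variants$confidence) & variants$confidence == "high" &
    variants$somatic
  metrics <- list(
    snvs_called = count_by(variants$kind %in% c("SNV", "MNV")),
    indels_called = count_by(variants$kind %in% c("insertion", "deletion")),
    somatic_heterozygous_high = count_by(high & variants$zygosity == "heterozygous"),
    somatic_homozygous_high = count_by(high & variants$zygosity == "homozygous"),
    somatic_high_total = count_by(high)
  )
  if (!is.null(variants$category)) {
    for (cat in EFFECT_CATEGORIES) {
      metrics[[paste0("category_", cat)]] <- count_by(high & variants$category == cat)
    }
    metrics$non_silent <- count_by(high & variants$category %in% NON_SILENT_CATEGORIES)
    if (!is.null(variants$novel)) {
      metrics$novel_total <- count_by(high & variants$novel)
      metrics$novel_non_silent <- count_by(high & variants$novel &
                                             variants$category %in% NON_SILENT_CATEGORIES)
    }
  }
  m <- do.call(rbind, metrics)
  colnames(m) <- samples
  total <- rowSums(m)
  mean_v <- if (length(samples)) total / length(samples) else total * NA_real_
  out <- data.frame(metric = rownames(m), m, mean = mean_v, total = total,
                    check.names = FALSE, row.names = NULL,
                    stringsAsFactors = FALSE)
  out
}
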