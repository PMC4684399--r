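# Worked-example count tables: published per-sample high-confidence
# somatic variant counts and orthogonal (Sanger) validation counts for a
# panel screen of six basal-like breast cancer cell lines (HCC38, HCC1143,
# HCC1187, HCC1395, HCC1937, HCC1954). These exercise the aggregation and
# concordance arithmetic without any sequence-level data.

#' Per-sample somatic variant category counts for six cell lines
#'
#' High-confidence somatic counts per effect category with the novel
#' (not-in-catalogue) subset, plus heterozygous/homozygous marginals.
#' @return list with `categories` and `zygosity` data frames.
#' @export
example_cohort_counts <- function() {
  list(
    categories = utils::read.delim(system.file("extdata", "cellline_somatic_counts.tsv",
                                               package = "panelscreen")),
    zygosity = utils::read.delim(system.file("extdata", "cellline_zygosity_counts.tsv",
                                             package = "panelscreen"))
  )
}

#' Expand per-category counts to one row per classified variant
#'
#' Produces the classified-variant data frame consumed by
#' [summarize_counts()]: one row per variant with sample, kind, somatic,
#' zygosity, confidence, category and novel flag. Zygosity is assigned to
#' match the per-sample heterozygous/homozygous marginals.
#'
#' @param counts list from [example_cohort_counts()] (or same shape).
#' @return data frame of classified variants.
#' @export
expand_variant_counts <- function(counts = example_cohort_counts()) {
  cat_tab <- counts$categories
  zyg <- counts$zygosity
  rows <- lapply(seq_len(nrow(cat_tab)), function(i) {
    n <- cat_tab$count[i]
    if (n == 0) return(NULL)
    data.frame(sample = cat_tab$sample[i],
               category = cat_tab$category[i],
               novel = seq_len(n) <= cat_tab$novel_count[i],
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  indel_cats <- c("frameshift_deletion", "nonframeshift_deletion")
  ins_cats <- c("frameshift_insertion", "nonframeshift_insertion")
  df$kind <- ifelse(df$category %in% indel_cats, "deletion",
                    ifelse(df$category %in% ins_cats, "insertion", "SNV"))
  df$somatic <- TRUE
  df$confidence <- "high"
  df$zygosity <- NA_character_
  for (s in unique(df$sample)) {
    idx <- which(df$sample == s)
    n_hom <- zyg$homozygous_high[zyg$sample == s]
    df$zygosity[idx] <- c(rep("homozygous", n_hom),
                          rep("heterozygous", length(idx) - n_hom))
  }
  rownames(df) <- NULL
  df
}

#' Orthogonal validation counts per sample and confidence tier
#' @return data frame sample, tier, validated, analyzed.
#' @export
example_sanger_counts <- function() {
  utils::read.delim(system.file("extdata", "sanger_validation_counts.tsv",
                                package = "panelscreen"))
}

#' Expand validation counts to one row per assayed variant
#'
#' Validated variants get outcome `somatic`, the remainder `wildtype`
#' (sufficient for rate bookkeeping, which counts only `somatic` as
#' validated).
#' @param counts data frame from [example_sanger_counts()].
#' @return data frame sample, tier, category, outcome for
#'   [sanger_concordance()].
#' @export
expand_sanger_counts <- function(counts = example_sanger_counts()) {
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    n <- counts$analyzed[i]
    if (n == 0) return(NULL)
    data.frame(sample = counts$sample[i], tier = counts$tier[i],
               category = "unspecified",
               outcome = ifelse(seq_len(n) <= counts$validated[i],
                                "somatic", "wildtype"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
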