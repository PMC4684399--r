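# End-to-end orchestration, recurrence matrices, and orthogonal-validation
# (Sanger) concordance bookkeeping.

#' Run the full screening pipeline
#'
#' Stages: classify -> annotate -> catalogue match -> spectra/enrichment ->
#' CNV -> report. The config is a list (or YAML file path) with either a
#' `simulate` block (seed, optional generator overrides, cnv_events) or
#' explicit input paths (vcfs + tumor/normal sample names, reference, bed,
#' genes, catalogue, optional segments), plus `out_dir` and optional
#' threshold overrides. A machine-readable manifest (versions, seed,
#' thresholds, input digests) is written alongside the tables. Any stage
#' failure aborts with the stage name and removes partial outputs.
#'
#' @param config list or path to a YAML file.
#' @return invisible list of in-memory results.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$out_dir %||% stop("config$out_dir is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, p)
    p
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE)
    })
  }
  th <- do.call(filter_thresholds, config$thresholds %||% list())

  inputs <- stage("io", {
    if (!is.null(config$simulate)) {
      sim <- config$simulate
      cfg <- do.call(sim_config, sim[setdiff(names(sim), "cnv_events")])
      panel <- simulate_panel(cfg)
      cohort <- simulate_cohort(panel, cfg)
      cov <- simulate_coverage(panel, cfg, events = sim$cnv_events)
      calls <- rbind(cohort$calls, cohort$calls_extra)
      list(reference = panel$reference, regions = panel$regions,
           genes = panel$genes, catalogue = cohort$catalogue,
           calls = calls, coverage = cov$windows, segments = NULL,
           seed = cfg$seed, digests = list(simulated = TRUE))
    } else {
      for (key in c("reference", "bed", "genes")) {
        if (is.null(config[[key]])) stop("config missing input: ", key)
      }
      reference <- read_fasta(config$reference)
      regions <- read_regions(config$bed, flank = config$flank %||% 30L)
      genes <- read_gene_models(config$genes)
      catalogue <- if (!is.null(config$catalogue)) read_catalogue(config$catalogue)
      calls <- do.call(rbind, lapply(seq_along(config$vcfs), function(i) {
        v <- read_vcf_pairs(config$vcfs[[i]], config$tumor %||% "TUMOR",
                            config$normal %||% "NORMAL")
        v$sample <- names(config$vcfs)[i] %||% basename(config$vcfs[[i]])
        v
      }))
      segments <- if (!is.null(config$segments)) read_segments(config$segments)
      digests <- lapply(unlist(c(config$reference, config$bed, config$genes,
                                 config$catalogue, config$vcfs)),
                        function(p) unname(tools::md5sum(p)))
      list(reference = reference, regions = regions, genes = genes,
           catalogue = catalogue, calls = calls, coverage = NULL,
           segments = segments, seed = config$seed %||% NA,
           digests = digests)
    }
  })

  classified <- stage("classify", {
    cl <- classify_somatic(inputs$calls, th)
    cl$stratum <- resolve_region_class(inputs$regions, cl$chrom, cl$pos - 1L)
    cl
  })
  annotated <- stage("annotate", {
    annotate_effects(classified, inputs$genes, inputs$reference,
                     splice_window = config$splice_window %||% 2L)
  })
  matched <- stage("match", {
    if (is.null(inputs$catalogue)) {
      annotated$match_status <- NA_character_
      annotated$novel <- NA
      annotated
    } else {
      flag_novel(annotated, inputs$catalogue, inputs$reference,
                 window = config$loose_window %||% 5L)
    }
  })
  emit(matched[, setdiff(names(matched), character(0))], "variants.tsv")
  summary_tab <- stage("summarize", summarize_counts(matched))
  emit(summary_tab, "summary.tsv")

  spectra <- stage("spectrum", {
    comp_c <- stratum_composition(inputs$regions, inputs$reference, "coding")
    comp_n <- stratum_composition(inputs$regions, inputs$reference, "non_coding")
    rep <- spectrum_report(matched, comp_c, comp_n, inputs$reference)
    emit(rep$class_enrichment, "class_enrichment.tsv")
    emit(rep$context_enrichment, "context_enrichment.tsv")
    emit(rep$forest, "forest.tsv")
    rep
  })

  cnv <- stage("cnv", {
    if (!is.null(inputs$segments)) {
      segs <- inputs$segments
    } else if (!is.null(inputs$coverage)) {
      w <- window_log_ratios(inputs$coverage)
      w <- filter_low_coverage(w, config$min_normal_depth %||% 20)
      segs <- segment_windows(w, config$merge_tolerance %||% 0.4)
    } else {
      segs <- NULL
    }
    if (is.null(segs)) {
      NULL
    } else {
      calls <- gene_cnv_calls(segs, inputs$genes)
      emit(segs, "segments.tsv")
      emit(calls, "gene_cnv.tsv")
      list(segments = segs, gene_calls = calls)
    }
  })

  report <- stage("report", {
    mut_only <- recurrence_matrix(matched, NULL,
                                  min_samples = config$min_samples %||% 2L)
    integ <- recurrence_matrix(matched, cnv$gene_calls,
                               min_samples = config$min_samples %||% 2L)
    if (nrow(mut_only)) emit(as.data.frame(mut_only), "recurrence_mutation.tsv")
    if (nrow(integ)) emit(as.data.frame(integ), "recurrence_integrated.tsv")
    sanger <- NULL
    if (!is.null(config$sanger_table)) {
      sanger <- sanger_concordance(utils::read.delim(config$sanger_table))
      emit(sanger$by_tier, "sanger_concordance.tsv")
    }
    list(mutation_matrix = mut_only, integrated_matrix = integ,
         sanger = sanger)
  })

  manifest <- list(package = "panelscreen",
                   version = as.character(utils::packageVersion("panelscreen")),
                   r_version = R.version.string,
                   seed = inputs$seed,
                   thresholds = unclass(th),
                   inputs = inputs$digests,
                   outputs = basename(written))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(classified = matched, summary = summary_tab,
                 spectra = spectra, cnv = cnv, report = report,
                 manifest = manifest))
}

ABERRATION_SEVERITY <- c("homozygous_deletion", "amplification",
                         "hom_stopgain_or_indel", "het_stopgain_or_indel",
                         "hom_nonsyn_SNV", "het_nonsyn_SNV", "none")

variant_cell_category <- function(category, zygosity) {
  trunc_like <- category %in% c("stopgain_SNV", "stoploss_SNV", "splicing",
                                "frameshift_deletion", "frameshift_insertion",
                                "nonframeshift_deletion", "nonframeshift_insertion")
  nonsyn <- category == "nonsynonymous_SNV"
  out <- rep(NA_character_, length(category))
  out[trunc_like & zygosity == "homozygous"] <- "hom_stopgain_or_indel"
  out[trunc_like & zygosity == "heterozygous"] <- "het_stopgain_or_indel"
  out[nonsyn & zygosity == "homozygous"] <- "hom_nonsyn_SNV"
  out[nonsyn & zygosity == "heterozygous"] <- "het_nonsyn_SNV"
  out
}

#' Gene-by-sample recurrence matrix of somatic aberrations
#'
#' Cells take one aberration category per gene and sample; when several
#' apply the most severe is shown (copy-number events > homozygous
#' stopgain/indel > heterozygous stopgain/indel > homozygous nonsynonymous
#' > heterozygous nonsynonymous). Genes are retained when aberrant in at
#' least `min_samples` samples. Mutation-only matrices ignore
#' `gene_cnv_calls`; the integrated variant includes amplifications and
#' homozygous deletions.
#'
#' @param variants classified, annotated variants (sample, gene, category,
#'   zygosity, confidence, somatic).
#' @param gene_cnv_calls optional per-sample CNV calls: data frame with
#'   sample, gene, status; or a single-sample data frame from
#'   [gene_cnv_calls()] plus a `sample` column.
#' @param min_samples recurrence threshold (default 2).
#' @return character matrix genes x samples with category labels or
#'   `"none"`.
#' @export
recurrence_matrix <- function(variants, gene_cnv_calls = NULL,
                              min_samples = 2L) {
  v <- variants[variants$somatic & !is.na(variants$confidence) &
                  variants$confidence == "high" & !is.na(variants$gene), ,
                drop = FALSE]
  v$cell <- variant_cell_category(v$category, v$zygosity)
  v <- v[!is.na(v$cell), , drop = FALSE]
  cells <- v[, c("sample", "gene", "cell")]
  if (!is.null(gene_cnv_calls)) {
    cn <- gene_cnv_calls[gene_cnv_calls$status %in%
                           c("amplification", "homozygous_deletion"), ,
                         drop = FALSE]
    if (nrow(cn)) {
      if (is.null(cn$sample)) cn$sample <- "S01"
      cells <- rbind(cells, data.frame(sample = cn$sample, gene = cn$gene,
                                       cell = cn$status))
    }
  }
  samples <- sort(unique(c(variants$sample,
                           if (!is.null(gene_cnv_calls)) gene_cnv_calls$sample)))
  if (!nrow(cells)) {
    return(matrix(character(0), nrow = 0, ncol = length(samples),
                  dimnames = list(NULL, samples)))
  }
  genes <- sort(unique(cells$gene))
  m <- matrix("none", nrow = length(genes), ncol = length(samples),
              dimnames = list(genes, samples))
  sev <- function(x) match(x, ABERRATION_SEVERITY)
  for (i in seq_len(nrow(cells))) {
    g <- cells$gene[i]; s <- cells$sample[i]
    if (sev(cells$cell[i]) < sev(m[g, s])) m[g, s] <- cells$cell[i]
  }
  aberrant <- rowSums(m != "none")
  m[aberrant >= min_samples, , drop = FALSE]
}

#' Orthogonal validation (Sanger) concordance rates
#'
#' Takes a per-variant validation table and reports validated/analyzed
#' counts and percentages per confidence tier, per category, per sample and
#' pooled. A variant counts as validated when its outcome is `somatic`;
#' allowed outcomes are somatic, germline, wildtype, different_mutation.
#' Pooled percentages are ratios of summed counts (never means of
#' per-sample rates), rounded to one decimal.
#'
#' @param tbl data frame with columns sample, tier, category, outcome.
#' @return list with by_tier, by_category, by_sample data frames (columns
#'   validated, analyzed, rate_pct; rate is NA when nothing was analyzed).
#' @export
sanger_concordance <- function(tbl) {
  ok <- c("somatic", "germline", "wildtype", "different_mutation")
  bad <- setdiff(unique(tbl$outcome), ok)
  if (length(bad)) stop("unknown outcome label: ", paste(bad, collapse = ", "))
  rate <- function(split_var) {
    parts <- split(tbl, tbl[[split_var]])
    out <- do.call(rbind, lapply(names(parts), function(k) {
      p <- parts[[k]]
      data.frame(group = k, validated = sum(p$outcome == "somatic"),
                 analyzed = nrow(p), stringsAsFactors = FALSE)
    }))
    pooled <- data.frame(group = "pooled",
                         validated = sum(tbl$outcome == "somatic"),
                         analyzed = nrow(tbl))
    out <- rbind(out, pooled)
    out$rate_pct <- ifelse(out$analyzed > 0,
                           round(100 * out$validated / out$analyzed, 1), NA_real_)
    out
  }
  res <- list(by_tier = rate("tier"), by_sample = rate("sample"))
  if (!is.null(tbl$category)) res$by_category <- rate("category")
  # per tier x category breakdown
  res$by_tier_category <- do.call(rbind, lapply(split(tbl, tbl$tier), function(p) {
    r <- rate_sub(p)
    r
  }))
  res
}

rate_sub <- function(p) {
  parts <- split(p, p$category)
  out <- do.call(rbind, lapply(names(parts), function(k) {
    q <- parts[[k]]
    data.frame(tier = p$tier[1], category = k,
               validated = sum(q$outcome == "somatic"), analyzed = nrow(q),
               stringsAsFactors = FALSE)
  }))
  out$rate_pct <- ifelse(out$analyzed > 0,
                         round(100 * out$validated / out$analyzed, 1), NA_real_)
  out
}
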