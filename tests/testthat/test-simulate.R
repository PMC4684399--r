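test_that("panel generation is deterministic and hits stratum GC targets", {
  cfg <- sim_config(seed = 1, n_genes = 10)
  p1 <- simulate_panel(cfg)
  p2 <- simulate_panel(cfg)
  expect_identical(p1$reference, p2$reference)
  expect_identical(as.data.frame(p1$regions), as.data.frame(p2$regions))
  cc <- stratum_composition(p1$regions, p1$reference, "coding")
  gc <- cc$gc_bases / cc$total_bases
  expect_gte(gc, 0.501); expect_lte(gc, 0.521)
  nc <- stratum_composition(p1$regions, p1$reference, "non_coding")
  gcn <- nc$gc_bases / nc$total_bases
  expect_gte(gcn, 0.460); expect_lte(gcn, 0.480)
  # every CDS starts with ATG, ends with a stop, and has no internal stop
  for (i in seq_len(nrow(p1$genes))) {
    cds <- panelscreen:::transcript_cds(p1$genes[i, ], p1$reference)
    expect_equal(nchar(cds) %% 3, 0)
    aa <- panelscreen:::translate_codons(cds)
    expect_equal(substr(cds, 1, 3), "ATG")
    expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("[*]", substr(aa, 1, nchar(aa) - 1)))
  }
  # empty panel is valid
  p0 <- simulate_panel(sim_config(seed = 1, n_genes = 0L))
  expect_equal(length(p0$reference), 0L)
  expect_equal(nrow(p0$regions), 0L)
})

test_that("cohort ground truth maps one-to-one onto emitted calls", {
  cfg <- sim_config(seed = 5, coding_rate = 1e-3, noncoding_rate = 5e-4)
  panel <- simulate_panel(cfg)
  co <- simulate_cohort(panel, cfg)
  expect_equal(nrow(co$calls), nrow(co$truth))
  key <- function(df) paste(df$sample, df$chrom, df$pos, df$ref, df$alt)
  expect_setequal(key(co$calls), key(co$truth))
  expect_equal(anyDuplicated(key(co$calls)), 0L)
  # determinism
  co2 <- simulate_cohort(panel, cfg)
  expect_identical(co$calls, co2$calls)
})

test_that("evidence lands on the intended side of each classifier threshold", {
  cfg <- sim_config(seed = 6, coding_rate = 2e-3, noncoding_rate = 1e-3,
                    germline_rate = 2e-4)
  panel <- simulate_panel(cfg)
  co <- simulate_cohort(panel, cfg)
  cl <- classify_somatic(co$calls)
  tr <- co$truth
  # germline plants carry the alt in the normal: never somatic
  germ <- tr$origin == "germline"
  expect_true(all(!cl$somatic[germ]))
  som <- tr$origin == "somatic"
  expect_true(all(cl$somatic[som]))
  # intended high-confidence variants classify high with matching zygosity
  hi <- som & tr$intended_confidence == "high"
  expect_true(all(cl$confidence[hi] == "high"))
  expect_equal(cl$zygosity[hi], tr$zygosity[hi])
  expect_true(all(cl$normal_ref_reads[hi] + cl$normal_alt_reads[hi] >= 10))
  expect_true(all(cl$normal_alt_reads[hi] <= 1))
  expect_true(all(cl$tumor_alt_reads[hi] >= 3))
  lo <- som & tr$intended_confidence == "low"
  expect_true(all(cl$confidence[lo] == "low"))
  # zero germline rate yields no normal-alt records
  cfg0 <- sim_config(seed = 6, coding_rate = 1e-3, noncoding_rate = 5e-4,
                     germline_rate = 0)
  co0 <- simulate_cohort(simulate_panel(cfg0), cfg0)
  expect_true(all(co0$truth$origin == "somatic"))
  expect_true(all(classify_somatic(co0$calls)$somatic))
})

test_that("realized class counts stay within 3 binomial sd of expectation", {
  cfg <- sim_config(seed = 8, coding_rate = 2e-3, noncoding_rate = 1e-3)
  panel <- simulate_panel(cfg)
  co <- simulate_cohort(panel, cfg)
  cc <- stratum_composition(panel$regions, panel$reference, "coding")
  snv <- co$truth[co$truth$origin == "somatic" & !is.na(co$truth$class) &
                    co$truth$stratum == "coding", ]
  total <- cc$total_bases * cfg$n_samples
  for (cls in names(cfg$class_props_coding)) {
    expected <- cfg$coding_rate * cfg$class_props_coding[[cls]] * total
    sd3 <- 3 * sqrt(expected)
    expect_lt(abs(sum(snv$class == cls) - expected), sd3 + 1e-9,
              label = paste("class", cls))
  }
})

test_that("simulated coverage recovers planted events and is reproducible", {
  cfg <- sim_config(seed = 12, n_genes = 12)
  panel <- simulate_panel(cfg)
  ev <- data.frame(gene = "GENE03", log2 = 2.5)
  cov <- simulate_coverage(panel, cfg, events = ev)
  cov2 <- simulate_coverage(panel, cfg, events = ev)
  expect_identical(cov$windows, cov2$windows)
  expect_true(all(cov$windows$end - cov$windows$start <= cfg$window_max))
  # no-event coverage normalizes to ~0 everywhere
  cov0 <- simulate_coverage(panel, cfg)
  w0 <- window_log_ratios(cov0$windows)
  expect_lt(max(abs(w0$log2)), 1)
  expect_equal(unique(cov0$truth$log2), 0)
  # planted amplification is called
  w <- suppressMessages(filter_low_coverage(window_log_ratios(cov$windows)))
  segs <- segment_windows(w)
  calls <- gene_cnv_calls(segs, panel$genes)
  expect_equal(calls$status[calls$gene == "GENE03"], "amplification")
  # overlapping events are rejected
  expect_error(simulate_coverage(panel, cfg,
                                 events = data.frame(gene = c("GENE03", "GENE03"),
                                                     log2 = c(2, -2))),
               "overlapping")
})

test_that("written panel and VCFs round-trip through the readers", {
  cfg <- sim_config(seed = 14, n_samples = 2L, coding_rate = 1e-3,
                    noncoding_rate = 5e-4)
  panel <- simulate_panel(cfg)
  co <- simulate_cohort(panel, cfg)
  dir <- withr::local_tempdir()
  write_panel(panel, dir)
  ref2 <- read_fasta(file.path(dir, "panel.fa"))
  expect_equal(unclass(ref2), unclass(panel$reference))
  reg2 <- read_regions(file.path(dir, "targets.bed"), flank = 0)
  expect_equal(as.data.frame(reg2), as.data.frame(panel$regions))
  g2 <- read_gene_models(file.path(dir, "genes.tsv"))
  expect_equal(g2$exon_starts, panel$genes$exon_starts)

  write_cohort_vcf(co, dir)
  s <- co$samples[1]
  back <- read_vcf_pairs(file.path(dir, paste0(s, ".vcf")), "TUMOR", "NORMAL")
  all_calls <- rbind(co$calls, co$calls_extra)
  orig <- all_calls[all_calls$sample == s, ]
  orig <- orig[order(orig$chrom, orig$pos), ]
  expect_equal(nrow(back), nrow(orig))
  expect_equal(back$pos, orig$pos)
  expect_equal(back$ref, orig$ref)
  expect_equal(back$alt, orig$alt)
  expect_equal(back$qd, orig$qd)
  expect_equal(back$tumor_alt_reads, orig$tumor_alt_reads)
  expect_equal(back$normal_ref_reads, orig$normal_ref_reads)
})
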