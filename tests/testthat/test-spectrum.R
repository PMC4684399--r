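test_that("all 12 ordered substitutions collapse per the complement table", {
  # independent hand-built table over the full enumeration
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  bases <- c("A", "C", "G", "T")
  for (r in bases) {
    for (a in setdiff(bases, r)) {
      want <- if (r %in% c("C", "T")) paste0(r, ">", a)
              else paste0(comp[[r]], ">", comp[[a]])
      expect_equal(collapse_substitution(r, a), want, info = paste(r, a))
    }
  }
  expect_equal(collapse_substitution("G", "T"), "C>A")
  expect_equal(format_substitution("C>T"), "C/G>T/A")
  expect_error(collapse_substitution("N", "A"), "non-ACGT")
})

test_that("trinucleotide contexts collapse purine centers and render paired", {
  ref <- ref_seq(c(c1 = "TGA", c2 = "TCT", c3 = "ACGTN"))
  expect_equal(trinuc_context("c1", 2, ref), "T[C]A")
  expect_equal(format_context("T[C]A"), "T[C]A/T[G]A")
  expect_equal(trinuc_context("c2", 2, ref), "T[C]T")
  expect_equal(format_context("T[C]T"), "T[C]T/A[G]A")
  # contig edge and N flank are excluded
  expect_true(is.na(trinuc_context("c1", 1, ref)))
  expect_true(is.na(trinuc_context("c1", 3, ref)))
  expect_true(is.na(trinuc_context("c3", 4, ref)))
})

test_that("stratum composition tallies bases and windows by hand enumeration", {
  ref <- ref_seq(c(chr1 = "ACGTA"))
  rs <- regions_from_df(data.frame(chrom = "chr1", start = 0L, end = 4L,
                                   region_class = "CDS", gene = "G"))
  comp <- stratum_composition(rs, ref, "coding")
  expect_equal(comp$gc_bases, 2L)
  expect_equal(comp$at_bases, 2L)
  # windows centered on stratum bases: centers 1..3 (0-based), i.e. ACG,
  # CGT, GTA; CGT center G collapses to reverse complement ACG
  expect_equal(comp$trinuc[["A[C]G"]], 2L)
  expect_equal(comp$trinuc[["G[T]A"]], 1L)
  expect_equal(sum(comp$trinuc), 3L)
  # N excluded from tallies and windows skipped
  refN <- ref_seq(c(chr1 = "ACNTA"))
  compN <- stratum_composition(rs, refN, "coding")
  expect_equal(compN$total_bases, 3L)
  expect_equal(sum(compN$trinuc), 0L)
})

test_that("Ti/Tv ratio classifies the full enumeration", {
  expect_equal(titv_ratio(c("A", "C", "A"), c("G", "T", "C")), 2.0)
  expect_equal(titv_ratio(c("A", "C"), c("C", "G")), 0.0)
  # one of each ordered substitution: 4 transitions / 8 transversions
  bases <- c("A", "C", "G", "T")
  pairs <- expand.grid(ref = bases, alt = bases, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  expect_equal(titv_ratio(pairs$ref, pairs$alt), 0.5)
  expect_true(is.nan(titv_ratio("C", "T")))  # no transversions: undefined
})

test_that("mutation rate is count per megabase", {
  expect_equal(mutation_rate(10, 2e6), 5.0)
  expect_equal(mutation_rate(0, 1e6), 0.0)
  expect_equal(round(mutation_rate(21, 1019417), 1), 20.6)
  expect_error(mutation_rate(1, 0), "> 0")
})

test_that("enrichment OR/CI match the 2x2 oracle and p tracks Fisher", {
  set.seed(401)
  for (i in 1:50) {
    ec <- sample(1500:5000, 1); en <- sample(1500:5000, 1)
    p0 <- runif(1, 0.005, 0.02); ratio <- runif(1, 0.7, 1.5)
    a <- max(5, rbinom(1, ec, p0 * ratio)); c_ <- max(5, rbinom(1, en, p0))
    et <- enrichment_test("x", a, ec, c_, en, m_tests = 6)
    orc <- oracle_or_ci(a, ec - a, c_, en - c_)
    expect_equal(et$odds_ratio, orc$or, tolerance = 1e-9)
    expect_equal(et$ci_low, orc$lo, tolerance = 1e-9)
    expect_equal(et$ci_high, orc$hi, tolerance = 1e-9)
    # Wald p from the logistic fit equals the 2x2 Wald p
    expect_equal(et$p_raw, 2 * pnorm(-abs(orc$z)), tolerance = 1e-5)
    expect_equal(et$p_adjusted, min(1, 6 * et$p_raw))
  }
  # Wald p tracks Fisher's exact p within 10% in the regime where the
  # normal approximation is valid (adequate cell counts, exact p away from
  # the deep tail, where the two are known to diverge without bound)
  n_checked <- 0
  while (n_checked < 40) {
    ec <- sample(50000:100000, 1); en <- sample(50000:100000, 1)
    p0 <- runif(1, 0.005, 0.02)
    a <- rbinom(1, ec, p0); c_ <- rbinom(1, en, p0)
    if (min(a, c_) < 100) next
    fp <- fisher.test(matrix(c(a, ec - a, c_, en - c_), 2))$p.value
    if (fp < 0.05) next
    n_checked <- n_checked + 1
    et <- enrichment_test("x", a, ec, c_, en)
    expect_lt(abs(et$p_raw - fp), 0.1 * fp)
  }
  # worked example: 10/1000 coding vs 5/2000 non-coding
  et <- enrichment_test("x", 10, 1000, 5, 2000)
  expect_equal(et$odds_ratio, (10 / 990) / (5 / 1995), tolerance = 1e-12)
  expect_equal(round(et$odds_ratio, 3), 4.030)
  # equal proportions: OR 1, p ~ 1, Bonferroni identity at m = 1
  eq <- enrichment_test("x", 10, 1000, 20, 2000, m_tests = 1)
  expect_equal(eq$odds_ratio, (10 / 990) / (20 / 1980), tolerance = 1e-12)
  expect_equal(eq$p_adjusted, eq$p_raw)
  # zero cell flagged undefined, no error
  z <- enrichment_test("x", 0, 1000, 5, 2000)
  expect_false(z$defined)
  expect_true(is.na(z$odds_ratio))
})

test_that("spectrum report conserves counts and flags GC fractions", {
  cfg <- sim_config(seed = 21, coding_rate = 1.5e-3, noncoding_rate = 8e-4)
  panel <- simulate_panel(cfg)
  co <- simulate_cohort(panel, cfg)
  cl <- classify_somatic(co$calls)
  cl$stratum <- resolve_region_class(panel$regions, cl$chrom, cl$pos - 1L)
  cc <- stratum_composition(panel$regions, panel$reference, "coding")
  nc <- stratum_composition(panel$regions, panel$reference, "non_coding")
  rep <- spectrum_report(cl, cc, nc, panel$reference)
  # conservation: class counts sum to the SNV count per stratum
  n_coding <- sum(cl$kind == "SNV" & cl$somatic & cl$confidence == "high" &
                    !is.na(cl$stratum) & cl$stratum == "CDS")
  expect_equal(sum(rep$class_counts$coding$pooled), n_coding)
  n_non <- rep$n_snvs - n_coding
  expect_equal(sum(rep$class_counts$non_coding$pooled), n_non)
  # context counts sum to the SNV count minus excluded-flank variants
  expect_lte(sum(rep$context_counts$coding$pooled) +
               sum(rep$context_counts$non_coding$pooled), rep$n_snvs)
  # forest export has marker size 1/SE
  ok <- rep$forest$family == "class" & !is.na(rep$forest$se_log_or)
  expect_equal(rep$forest$marker_size[ok], 1 / rep$forest$se_log_or[ok])
})

test_that("class and context counts are invariant under reverse complement", {
  cfg <- sim_config(seed = 31, coding_rate = 2e-3, noncoding_rate = 1e-3)
  panel <- simulate_panel(cfg)
  co <- simulate_cohort(panel, cfg)
  snv <- co$truth[co$truth$origin == "somatic" &
                    nchar(co$truth$ref) == 1 & nchar(co$truth$alt) == 1, ]
  cls <- collapse_substitution(snv$ref, snv$alt)
  ctx <- trinuc_context(snv$chrom, snv$pos, panel$reference)
  # reverse-complement every contig and mirror the variants
  lens <- vapply(names(panel$reference), function(ch) nchar(panel$reference[[ch]]),
                 integer(1))
  rc_ref <- ref_seq(setNames(revcomp(unname(unlist(panel$reference))),
                             names(panel$reference)))
  rc_pos <- lens[snv$chrom] - snv$pos + 1L
  cls_rc <- collapse_substitution(comp_dna(snv$ref), comp_dna(snv$alt))
  ctx_rc <- trinuc_context(snv$chrom, rc_pos, rc_ref)
  cnt <- function(x, lv) as.integer(table(factor(x, levels = lv)))
  cls_lv <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  expect_equal(cnt(cls, cls_lv), cnt(cls_rc, cls_lv))
  ctx_lv <- sort(unique(c(ctx, ctx_rc)))
  expect_equal(cnt(ctx, ctx_lv), cnt(ctx_rc, ctx_lv))
  expect_equal(sum(is.na(ctx)), sum(is.na(ctx_rc)))
})
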