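base_call <- function(...) {
  defaults <- list(chrom = "chr1", pos = 100L, ref = "C", alt = "T",
                   qual = 60, qd = 10, hrun = 1, fs = 5,
                   read_pos_rank_sum = NA_real_,
                   tumor_a1 = "C", tumor_a2 = "T",
                   normal_a1 = "C", normal_a2 = "C",
                   tumor_ref_reads = 20L, tumor_alt_reads = 10L,
                   normal_ref_reads = 20L, normal_alt_reads = 0L)
  args <- modifyList(defaults, list(...))
  as.data.frame(args, stringsAsFactors = FALSE)
}

test_that("hard filters fire on strict inequalities only, per rule set", {
  flt <- function(call) apply_hard_filters(call)
  # SNV boundary: all values exactly at threshold pass
  expect_true(flt(base_call(qual = 40, qd = 5.0, hrun = 5, fs = 200.0))$pass)
  expect_equal(flt(base_call(qd = 4.9))$reasons[[1]], "QD")
  expect_equal(flt(base_call(qual = 39.99))$reasons[[1]], "QUAL")
  expect_equal(flt(base_call(hrun = 6))$reasons[[1]], "HRun")
  expect_equal(flt(base_call(fs = 200.01))$reasons[[1]], "FS")
  # indel rule set: deletion judged by QD < 2 and ReadPosRankSum < -20
  del <- base_call(ref = "CAT", alt = "C", qd = 2.5, read_pos_rank_sum = -25)
  expect_equal(flt(del)$reasons[[1]], "ReadPosRankSum")
  del2 <- base_call(ref = "CAT", alt = "C", qd = 2.0, read_pos_rank_sum = -20.0)
  expect_true(flt(del2)$pass)
  del3 <- base_call(ref = "CAT", alt = "C", qd = 4.9)  # SNV QD rule must not apply
  expect_true(flt(del3)$pass)
  # hrun never fails indels
  expect_true(flt(base_call(ref = "CAT", alt = "C", hrun = 9))$pass)
  # missing annotations pass; below emit threshold fails with its own reason
  expect_true(flt(base_call(qd = NA, hrun = NA, fs = NA))$pass)
  expect_equal(flt(base_call(qual = 9.9))$reasons[[1]], "below_emit")
  # multiple violations all reported
  expect_setequal(flt(base_call(qual = 20, qd = 1, fs = 300))$reasons[[1]],
                  c("QUAL", "QD", "FS"))
})

test_that("somatic rule requires tumor alt and homozygous-reference normal", {
  cl <- function(call) classify_somatic(call)
  v <- cl(base_call(tumor_alt_reads = 4L, normal_ref_reads = 12L))
  expect_true(v$somatic)
  expect_equal(v$zygosity, "heterozygous")
  expect_equal(v$confidence, "high")
  # normal carries the alt: germline, not somatic
  g <- cl(base_call(normal_a2 = "T"))
  expect_false(g$somatic)
  expect_true(is.na(g$confidence))
  # homozygous tumor, normal depth 9 < 10: somatic but low confidence
  h <- cl(base_call(tumor_a1 = "T", tumor_a2 = "T", tumor_alt_reads = 9L,
                    normal_ref_reads = 9L, normal_alt_reads = 0L))
  expect_true(h$somatic)
  expect_equal(h$zygosity, "homozygous")
  expect_equal(h$confidence, "low")
  # boundary: normal depth exactly 10 is high
  b <- cl(base_call(normal_ref_reads = 9L, normal_alt_reads = 1L))
  expect_equal(b$confidence, "high")
  # tumor support below 3 demotes
  t <- cl(base_call(tumor_alt_reads = 2L))
  expect_equal(t$confidence, "low")
  # failed filters demote even with good evidence
  f <- cl(base_call(qd = 3))
  expect_equal(f$confidence, "low")
})

test_that("classification partitions calls and matches the straight-line oracle", {
  calls <- random_calls(10000, seed = 301)
  got <- classify_somatic(calls)
  verdict <- ifelse(!got$somatic, "non_somatic",
                    ifelse(got$confidence == "high", "somatic_high", "somatic_low"))
  want <- vapply(seq_len(nrow(calls)),
                 function(i) oracle_classify_one(calls[i, ]), "")
  expect_identical(verdict, want)
  # partition: exactly one state per call
  expect_true(all(table(verdict) >= 1))
  expect_equal(length(verdict), nrow(calls))
})

test_that("raising any high-confidence threshold never increases the count", {
  calls <- random_calls(2000, seed = 302)
  n_high <- function(th) {
    v <- classify_somatic(calls, th)
    sum(v$somatic & v$confidence == "high")
  }
  base <- n_high(filter_thresholds())
  expect_lte(n_high(filter_thresholds(somatic_high = list(
    min_normal_depth = 14, max_normal_alt_reads = 1, min_tumor_alt_reads = 3))), base)
  expect_lte(n_high(filter_thresholds(somatic_high = list(
    min_normal_depth = 10, max_normal_alt_reads = 0, min_tumor_alt_reads = 3))), base)
  expect_lte(n_high(filter_thresholds(somatic_high = list(
    min_normal_depth = 10, max_normal_alt_reads = 1, min_tumor_alt_reads = 6))), base)
})

test_that("summarize_counts pools, averages, and flags non-silent correctly", {
  nonsilent <- c(41, 58, 146, 53, 37, 43)
  rows <- do.call(rbind, lapply(seq_along(nonsilent), function(i) {
    data.frame(sample = sprintf("S%d", i), kind = "SNV", somatic = TRUE,
               zygosity = "heterozygous", confidence = "high",
               category = "nonsynonymous_SNV", novel = FALSE)[rep(1, nonsilent[i]), ]
  }))
  tab <- summarize_counts(rows)
  expect_equal(tab$total[tab$metric == "non_silent"], 378)
  expect_equal(tab$mean[tab$metric == "non_silent"], 63)
  # a synonymous variant is silent
  syn <- rows[1, ]; syn$category <- "synonymous_SNV"
  tab2 <- summarize_counts(syn)
  expect_equal(tab2$total[tab2$metric == "non_silent"], 0)
  # empty input: all-zero totals
  tab3 <- summarize_counts(rows[0, ])
  expect_true(all(tab3$total == 0))
  # unknown category is fatal
  bad <- rows[1, ]; bad$category <- "mystery"
  expect_error(summarize_counts(bad), "unknown effect category")
})
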