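test_that("CDS substitutions are translated to the right category", {
  tp <- toy_panel()
  # toy CDS: ATG CAT GAA GCT TGG TAA  (M H E A W *)
  # chrP CDS1 covers codons 1-3 at 0-based 10..18
  v <- function(pos, ref, alt) data.frame(chrom = "chrP", pos = pos,
                                          ref = ref, alt = alt)
  ann <- annotate_effects(v(15, "A", "G"), tp$genes, tp$reference)  # CAT -> CGT
  expect_equal(ann$category, "nonsynonymous_SNV")
  expect_equal(ann$gene, "TOYP")
  expect_equal(ann$cdot, "c.A5G")
  expect_equal(ann$pdot, "p.H2R")
  # CAT -> CAC: synonymous (His)
  ann <- annotate_effects(v(16, "T", "C"), tp$genes, tp$reference)
  expect_equal(ann$category, "synonymous_SNV")
  # GAA -> TAA: stopgain
  ann <- annotate_effects(v(17, "G", "T"), tp$genes, tp$reference)
  expect_equal(ann$category, "stopgain_SNV")
  # stop codon TAA -> CAA: stoploss (codon 6 at 0-based 31..33 -> pos 32)
  ann <- annotate_effects(v(32, "T", "C"), tp$genes, tp$reference)
  expect_equal(ann$category, "stoploss_SNV")
})

test_that("CDS indel length determines frameshift vs nonframeshift", {
  tp <- toy_panel()
  del2 <- data.frame(chrom = "chrP", pos = 13, ref = "GCA", alt = "G")
  expect_equal(annotate_effects(del2, tp$genes, tp$reference)$category,
               "frameshift_deletion")
  del3 <- data.frame(chrom = "chrP", pos = 13, ref = "GCAT", alt = "G")
  expect_equal(annotate_effects(del3, tp$genes, tp$reference)$category,
               "nonframeshift_deletion")
  ins1 <- data.frame(chrom = "chrP", pos = 13, ref = "G", alt = "GG")
  expect_equal(annotate_effects(ins1, tp$genes, tp$reference)$category,
               "frameshift_insertion")
  ins3 <- data.frame(chrom = "chrP", pos = 13, ref = "G", alt = "GGGG")
  expect_equal(annotate_effects(ins3, tp$genes, tp$reference)$category,
               "nonframeshift_insertion")
})

test_that("splice window, UTRs, upstream, intronic and intergenic resolve", {
  tp <- toy_panel()
  v <- function(pos, chrom = "chrP") data.frame(chrom = chrom, pos = pos,
                                                ref = "G", alt = "C")
  # first intronic base after CDS1 (0-based 19 -> 1-based 20), window 2
  got <- annotate_effects(data.frame(chrom = "chrP", pos = 20, ref = "G", alt = "A"),
                          tp$genes, tp$reference)
  expect_equal(got$category, "splicing")
  # third intronic base is intronic
  got <- annotate_effects(data.frame(chrom = "chrP", pos = 22, ref = "T", alt = "C"),
                          tp$genes, tp$reference)
  expect_equal(got$category, "intronic")
  # widen the window and it becomes splicing
  got <- annotate_effects(data.frame(chrom = "chrP", pos = 22, ref = "T", alt = "C"),
                          tp$genes, tp$reference, splice_window = 3)
  expect_equal(got$category, "splicing")
  # UTR5 (0-based 5..9 -> 1-based 7) and UTR3 (0-based 34..39)
  got <- annotate_effects(data.frame(chrom = "chrP", pos = 7, ref = "C", alt = "T"),
                          tp$genes, tp$reference)
  expect_equal(got$category, "UTR5")
  got <- annotate_effects(data.frame(chrom = "chrP", pos = 36, ref = "C", alt = "G"),
                          tp$genes, tp$reference)
  expect_equal(got$category, "UTR3")
  # upstream of the transcription start (within 1000 bp)
  got <- annotate_effects(data.frame(chrom = "chrP", pos = 3, ref = "T", alt = "A"),
                          tp$genes, tp$reference)
  expect_equal(got$category, "upstream")
  # beyond the transcript on the 3' side: intergenic
  got <- annotate_effects(data.frame(chrom = "chrP", pos = 43, ref = "G", alt = "T"),
                          tp$genes, tp$reference)
  expect_equal(got$category, "intergenic")
})

test_that("minus-strand annotation equals the plus-strand construct", {
  tp <- toy_panel()
  len <- nchar(tp$reference[["chrP"]])
  # every CDS position of the plus gene, each with every alt base
  plus_tx <- tp$genes[1, ]
  cds_pos0 <- c(10:18, 25:33)
  for (p0 in cds_pos0) {
    refb <- ref_fetch(tp$reference, "chrP", p0, p0 + 1)
    for (altb in setdiff(c("A", "C", "G", "T"), refb)) {
      plus <- annotate_effects(data.frame(chrom = "chrP", pos = p0 + 1,
                                          ref = refb, alt = altb),
                               tp$genes, tp$reference)
      # mirrored coordinates on the minus-strand contig
      m0 <- 44L - p0
      mref <- comp_dna(refb); malt <- comp_dna(altb)
      expect_equal(ref_fetch(tp$reference, "chrM", m0, m0 + 1), mref)
      minus <- annotate_effects(data.frame(chrom = "chrM", pos = m0 + 1,
                                           ref = mref, alt = malt),
                                tp$genes, tp$reference)
      expect_equal(minus$category, plus$category,
                   info = sprintf("pos0 %d %s>%s", p0, refb, altb))
    }
  }
})

test_that("non-silent definition covers exactly the exonic-indel/stopgain set", {
  expect_true(all(is_non_silent(c("frameshift_deletion", "frameshift_insertion",
                                  "nonframeshift_deletion", "nonframeshift_insertion",
                                  "nonsynonymous_SNV", "stopgain_SNV",
                                  "stoploss_SNV", "splicing"))))
  expect_false(any(is_non_silent(c("synonymous_SNV", "UTR3", "UTR5", "upstream",
                                   "intronic", "intergenic", "ncRNA", "unknown"))))
  expect_error(is_non_silent("nonsense_category"), "unknown")
})
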