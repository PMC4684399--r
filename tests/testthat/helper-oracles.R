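# Independent straight-line oracles and small fixture builders. These
# re-derive the expected behaviour without touching the package internals
# they check.

# -- classifier oracle: literal transcription of the three rule sets -------
oracle_classify_one <- function(row) {
  is_ind <- nchar(row$ref) != nchar(row$alt)
  failed <- FALSE
  if (is.na(row$qual) || row$qual < 10) {
    failed <- TRUE
  } else if (is_ind) {
    if (row$qual < 40) failed <- TRUE
    if (!is.na(row$qd) && row$qd < 2.0) failed <- TRUE
    if (!is.na(row$read_pos_rank_sum) && row$read_pos_rank_sum < -20.0) failed <- TRUE
    if (!is.na(row$fs) && row$fs > 200.0) failed <- TRUE
  } else {
    if (row$qual < 40) failed <- TRUE
    if (!is.na(row$qd) && row$qd < 5.0) failed <- TRUE
    if (!is.na(row$hrun) && row$hrun > 5) failed <- TRUE
    if (!is.na(row$fs) && row$fs > 200.0) failed <- TRUE
  }
  somatic <- (row$tumor_a1 == row$alt || row$tumor_a2 == row$alt) &&
    row$normal_a1 == row$ref && row$normal_a2 == row$ref
  if (!somatic) return("non_somatic")
  high <- !failed &&
    (row$normal_ref_reads + row$normal_alt_reads) >= 10 &&
    row$normal_alt_reads <= 1 &&
    row$tumor_alt_reads >= 3
  if (high) "somatic_high" else "somatic_low"
}

# random paired calls stressing every threshold boundary
random_calls <- function(n, seed) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  ind <- runif(n) < 0.3
  ref[ind] <- paste0(ref[ind], sample(bases, sum(ind), replace = TRUE))
  swap <- ind & runif(n) < 0.5   # half of indels become insertions
  tmp <- ref[swap]; ref[swap] <- alt[swap]; alt[swap] <- tmp
  gt_pick <- function(r, a) {
    i <- sample(3, length(r), replace = TRUE)
    list(a1 = ifelse(i == 3, a, r), a2 = ifelse(i == 1, r, a))
  }
  tg <- gt_pick(ref, alt)
  ng <- gt_pick(ref, alt)
  na_mix <- function(x, p = 0.15) { x[runif(length(x)) < p] <- NA; x }
  data.frame(
    chrom = "chr1", pos = seq_len(n), ref = ref, alt = alt,
    qual = sample(c(5, 9.99, 10, 39.99, 40, 40.01, 60, 120), n, replace = TRUE),
    qd = na_mix(sample(c(1.9, 2, 2.1, 4.99, 5, 5.01, 8, 15), n, replace = TRUE)),
    hrun = na_mix(sample(c(0:7), n, replace = TRUE)),
    fs = na_mix(sample(c(0, 10, 199.99, 200, 200.01, 300), n, replace = TRUE)),
    read_pos_rank_sum = na_mix(sample(c(-25, -20.01, -20, -19.99, 0, 5), n,
                                      replace = TRUE), 0.3),
    tumor_a1 = tg$a1, tumor_a2 = tg$a2, normal_a1 = ng$a1, normal_a2 = ng$a2,
    tumor_ref_reads = sample(0:40, n, replace = TRUE),
    tumor_alt_reads = sample(c(0:4, 10, 20), n, replace = TRUE),
    normal_ref_reads = sample(c(0:12, 30), n, replace = TRUE),
    normal_alt_reads = sample(0:3, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

# -- brute-force effect oracle: full-CDS translation before/after ----------
oracle_codon_table <- Biostrings::GENETIC_CODE

oracle_translate <- function(seq) {
  n <- nchar(seq) %/% 3
  paste(oracle_codon_table[substring(seq, 3 * seq_len(n) - 2, 3 * seq_len(n))],
        collapse = "")
}

oracle_rc <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# full spliced CDS of transcript tx from a raw chromosome string
oracle_cds_seq <- function(chrom_seq, tx) {
  s <- tx$exon_starts[[1]]; e <- tx$exon_ends[[1]]
  ks <- pmax(s, tx$cds_start); ke <- pmin(e, tx$cds_end)
  keep <- ks < ke
  cds <- paste(substring(chrom_seq, ks[keep] + 1, ke[keep]), collapse = "")
  if (tx$strand == "-") cds <- oracle_rc(cds)
  cds
}

# expected category for a CDS SNV by editing the chromosome and fully
# re-translating
oracle_cds_snv_effect <- function(chrom_seq, tx, pos, alt) {
  before <- oracle_cds_seq(chrom_seq, tx)
  edited <- paste0(substr(chrom_seq, 1, pos - 1), alt,
                   substr(chrom_seq, pos + 1, nchar(chrom_seq)))
  after <- oracle_cds_seq(edited, tx)
  p_before <- oracle_translate(before)
  p_after <- oracle_translate(after)
  if (identical(p_before, p_after)) return("synonymous_SNV")
  has_stop <- function(p) grepl("\\*", p)
  if (has_stop(p_after) && !has_stop(p_before)) return("stopgain_SNV")
  if (has_stop(p_before) && !has_stop(p_after)) return("stoploss_SNV")
  # both have stops: compare at the changed position
  d <- which(strsplit(p_before, "")[[1]] != strsplit(p_after, "")[[1]])[1]
  b <- substr(p_before, d, d); a <- substr(p_after, d, d)
  if (a == "*") "stopgain_SNV" else if (b == "*") "stoploss_SNV" else "nonsynonymous_SNV"
}

# -- 2x2 enrichment oracle -------------------------------------------------
oracle_or_ci <- function(a, b, c, d) {
  or <- (a / b) / (c / d)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(or = or, lo = exp(log(or) - 1.96 * se), hi = exp(log(or) + 1.96 * se),
       z = log(or) / se)
}

# -- tiny hand-built fixtures ----------------------------------------------
# one plus-strand and one minus-strand toy gene on short contigs
toy_panel <- function() {
  # chrP: pad(5) UTR5[5,10) CDS1[10,19) intron[19,25) CDS2[25,34) UTR3[34,40) pad
  # CDS: 18 bases = 6 codons, ATG ... TAA
  cds_plus <- "ATGCATGAAGCTTGGTAA"
  seq_p <- paste0("TTTTT", "GCGCA", substr(cds_plus, 1, 9), "GTTTAG",
                  substr(cds_plus, 10, 18), "ACACAC", "GGGGG")
  genes_p <- data.frame(gene = "TOYP", transcript_id = "TXP", chrom = "chrP",
                        strand = "+", cds_start = 10L, cds_end = 34L,
                        stringsAsFactors = FALSE)
  genes_p$exon_starts <- list(c(5L, 25L))
  genes_p$exon_ends <- list(c(19L, 40L))
  # chrM: mirrored minus-strand gene with the same coding sequence
  inner_p <- substr(seq_p, 6, 40)
  seq_m <- paste0("TTTTT", paste(rev(strsplit(chartr("ACGT", "TGCA", inner_p),
                                              "")[[1]]), collapse = ""), "GGGGG")
  genes_m <- data.frame(gene = "TOYM", transcript_id = "TXM", chrom = "chrM",
                        strand = "-", cds_start = 11L, cds_end = 35L,
                        stringsAsFactors = FALSE)
  genes_m$exon_starts <- list(c(5L, 26L))
  genes_m$exon_ends <- list(c(20L, 40L))
  reference <- ref_seq(c(chrP = seq_p, chrM = seq_m))
  list(reference = reference, genes = rbind(genes_p, genes_m))
}
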