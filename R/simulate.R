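# Self-contained synthetic panels, cohorts and coverage tracks with known
# ground truth. The generator emulates a targeted-capture design: per gene,
# 300 bp upstream of the transcript, the 5'UTR, coding exons with introns,
# and the leading portion of the 3'UTR, with stratum GC targets of 51.1%
# (coding) and 47.0% (non-coding) matching a cancer-gene capture panel.

#' Simulation configuration
#'
#' Defaults describe the emulated study conditions: six tumor/normal pairs,
#' mean tumor coverage 127x and normal 98x, somatic burdens of 20.6
#' mutations/Mbp in coding and 8.7/Mbp in non-coding targeted sequence with
#' class proportions dominated by C/G>T/A, a germline heterozygous SNP rate
#' of 8e-4 per targeted base, and coding/non-coding GC targets of 0.511 and
#' 0.470.
#'
#' @param seed mandatory integer seed; all generator randomness derives
#'   from it.
#' @param n_samples number of tumor/normal pairs.
#' @param n_genes,exons_per_gene,cds_exon_bp,intron_bp panel structure.
#' @param utr5_bp,utr3_bp,upstream_bp,pad_bp per-gene non-coding structure
#'   (300 bp upstream; 3'UTR capped at 1200 bp).
#' @param gc_coding,gc_noncoding stratum GC targets.
#' @param coding_rate,noncoding_rate somatic SNV burden per base per sample.
#' @param class_props_coding,class_props_noncoding length-6 named
#'   proportions over the collapsed substitution classes.
#' @param indel_rate somatic indel rate per targeted base per sample.
#' @param germline_rate heterozygous germline SNP rate per targeted base.
#' @param germline_transition_prob probability a germline SNP is a
#'   transition (default 0.727, i.e. a known-SNP Ti/Tv of 2.66).
#' @param hom_fraction fraction of somatic variants planted homozygous.
#' @param frac_low_confidence fraction planted with low-confidence evidence.
#' @param tumor_depth,normal_depth mean depths; `dispersion` switches the
#'   depth noise from Poisson to negative binomial (size = dispersion).
#' @param vaf_het,vaf_hom tumor variant allele fractions.
#' @param catalogue_fraction fraction of planted somatic variants copied
#'   into the synthetic catalogue as exact entries.
#' @param n_shift_decoys,n_split_decoys catalogue decoys exercising loose
#'   matching (position-shifted entries; MNV entries split into two
#'   adjacent SNV calls).
#' @param window_target,window_max coverage window sizing (100 / 150 bp).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_samples = 6L,
                       n_genes = 12L,
                       exons_per_gene = 4L,
                       cds_exon_bp = 198L,
                       intron_bp = 300L,
                       utr5_bp = 150L,
                       utr3_bp = 400L,
                       upstream_bp = 300L,
                       pad_bp = 100L,
                       gc_coding = 0.511,
                       gc_noncoding = 0.470,
                       coding_rate = 20.6e-6,
                       noncoding_rate = 8.7e-6,
                       class_props_coding = c("C>A" = 0.150, "C>G" = 0.249,
                                              "C>T" = 0.365, "T>A" = 0.070,
                                              "T>C" = 0.120, "T>G" = 0.046),
                       class_props_noncoding = c("C>A" = 0.130, "C>G" = 0.129,
                                                 "C>T" = 0.351, "T>A" = 0.097,
                                                 "T>C" = 0.218, "T>G" = 0.075),
                       indel_rate = 0.3e-6,
                       germline_rate = 8e-4,
                       germline_transition_prob = 0.727,
                       hom_fraction = 0.25,
                       frac_low_confidence = 0.15,
                       tumor_depth = 127,
                       normal_depth = 98,
                       dispersion = NULL,
                       vaf_het = 0.5,
                       vaf_hom = 0.95,
                       catalogue_fraction = 0.3,
                       n_shift_decoys = 2L,
                       n_split_decoys = 2L,
                       window_target = 100L,
                       window_max = 150L) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  if (cds_exon_bp %% 3L != 0L) stop("cds_exon_bp must be a multiple of 3")
  cfg <- as.list(environment())
  stopifnot(abs(sum(class_props_coding) - 1) < 1e-6,
            abs(sum(class_props_noncoding) - 1) < 1e-6)
  structure(cfg, class = "sim_config")
}

sample_bases <- function(n, gc) {
  pool_gc <- c("G", "C"); pool_at <- c("A", "T")
  is_gc <- stats::runif(n) < gc
  out <- character(n)
  out[is_gc] <- sample(pool_gc, sum(is_gc), replace = TRUE)
  out[!is_gc] <- sample(pool_at, sum(!is_gc), replace = TRUE)
  out
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# Sample n_codons coding-strand codons with per-base GC probability gc,
# rejecting stop codons (real CDS has no internal stops).
sample_codons <- function(n_codons, gc) {
  out <- character(n_codons)
  todo <- seq_len(n_codons)
  while (length(todo)) {
    cand <- vapply(todo, function(i) paste(sample_bases(3L, gc), collapse = ""),
                   character(1))
    ok <- !cand %in% STOP_CODONS
    out[todo[ok]] <- cand[ok]
    todo <- todo[!ok]
  }
  out
}

# GC adjustment for CDS bases that never creates an internal stop codon.
# codons: character vector of coding-strand codons (start/stop excluded);
# returns the adjusted codons.
adjust_gc_codons <- function(codons, target, tol = 0.002) {
  bases <- strsplit(paste(codons, collapse = ""), "")[[1]]
  n <- length(bases)
  if (!n) return(codons)
  cur <- mean(bases %in% c("G", "C"))
  need <- round((target - cur) * n)
  if (need == 0) return(codons)
  dir_gc <- need > 0
  pool <- if (dir_gc) which(!bases %in% c("G", "C")) else which(bases %in% c("G", "C"))
  pool <- safe_sample(pool, length(pool))   # random order
  flips <- 0L
  for (p in pool) {
    if (flips >= abs(need)) break
    repl <- if (dir_gc) sample(c("G", "C"), 1) else sample(c("A", "T"), 1)
    ci <- (p - 1L) %/% 3L
    cod <- bases[(3L * ci + 1L):(3L * ci + 3L)]
    cod[p - 3L * ci] <- repl
    if (paste(cod, collapse = "") %in% STOP_CODONS) next
    bases[p] <- repl
    flips <- flips + 1L
  }
  n_cod <- n %/% 3L
  substring(paste(bases, collapse = ""), 3L * seq_len(n_cod) - 2L,
            3L * seq_len(n_cod))
}

# sample() without the scalar-x surprise
safe_sample <- function(x, n) x[sample.int(length(x), n)]

# Flip bases at free positions until realized GC is within tol of target.
adjust_gc <- function(bases, idx, target, tol = 0.002) {
  if (!length(idx)) return(bases)
  cur <- mean(bases[idx] %in% c("G", "C"))
  need <- round((target - cur) * length(idx))
  if (need > 0) {
    at <- idx[!bases[idx] %in% c("G", "C")]
    pick <- safe_sample(at, min(need, length(at)))
    bases[pick] <- sample(c("G", "C"), length(pick), replace = TRUE)
  } else if (need < 0) {
    gc <- idx[bases[idx] %in% c("G", "C")]
    pick <- safe_sample(gc, min(-need, length(gc)))
    bases[pick] <- sample(c("A", "T"), length(pick), replace = TRUE)
  }
  bases
}

#' Simulate a targeted-capture panel
#'
#' Builds one contig per gene: padding, 300 bp upstream, 5'UTR, coding
#' exons separated by introns, and the leading 3'UTR, with genes on
#' alternating strands. CDS lengths are multiples of 3 with start and stop
#' codons; realized stratum GC is adjusted to within +-0.01 of target.
#' Deterministic under the config seed.
#'
#' @param config a [sim_config()].
#' @return list with reference (`ref_seq`), regions (`region_set`),
#'   genes (gene model data frame), config.
#' @export
simulate_panel <- function(config) {
  set.seed(config$seed)
  refs <- stats::setNames(character(0), character(0))
  region_rows <- list()
  gene_rows <- list()
  coding_idx_all <- list(); noncoding_idx_all <- list()
  for (g in seq_len(config$n_genes)) {
    chrom <- paste0("chr", g)
    gene <- sprintf("GENE%02d", g)
    strand <- if (g %% 2L == 1L) "+" else "-"
    E <- config$exons_per_gene
    # plus-strand geometry; mirrored interpretation for minus strand
    cur <- config$pad_bp
    blocks <- list()
    add <- function(cls, len) {
      b <- list(cls = cls, start = cur, end = cur + len)
      blocks[[length(blocks) + 1L]] <<- b
      cur <<- cur + len
    }
    if (strand == "+") {
      add("upstream", config$upstream_bp)
      add("UTR5", config$utr5_bp)
      for (e in seq_len(E)) {
        add("CDS", config$cds_exon_bp)
        if (e < E) add("intron", config$intron_bp)
      }
      add("UTR3", config$utr3_bp)
    } else {
      add("UTR3", config$utr3_bp)
      for (e in seq_len(E)) {
        add("CDS", config$cds_exon_bp)
        if (e < E) add("intron", config$intron_bp)
      }
      add("UTR5", config$utr5_bp)
      add("upstream", config$upstream_bp)
    }
    total <- cur + config$pad_bp
    cls_of <- rep("pad", total)
    for (b in blocks) cls_of[(b$start + 1L):b$end] <- b$cls
    coding_pos <- which(cls_of == "CDS")            # 1-based
    noncoding_pos <- which(cls_of %in% c("UTR5", "UTR3", "upstream"))
    bases <- character(total)
    other <- setdiff(seq_len(total), coding_pos)
    bases[other] <- sample_bases(length(other), config$gc_noncoding)
    bases <- adjust_gc(bases, noncoding_pos, config$gc_noncoding)

    cds_blocks <- Filter(function(b) b$cls == "CDS", blocks)
    cds_start <- cds_blocks[[1]]$start
    cds_end <- cds_blocks[[length(cds_blocks)]]$end
    # coding-strand CDS: ATG + stop-free interior codons + TAA, with the
    # interior GC target compensating for the fixed terminal codons
    n_codons <- length(coding_pos) %/% 3L
    n_cds <- length(coding_pos)
    gc_interior <- (config$gc_coding * n_cds - 1) / (n_cds - 6)
    interior <- sample_codons(n_codons - 2L, gc_interior)
    interior <- adjust_gc_codons(interior, gc_interior)
    coding_seq <- paste0("ATG", paste(interior, collapse = ""), "TAA")
    genomic_cds <- if (strand == "+") coding_seq else revcomp(coding_seq)
    bases[coding_pos] <- strsplit(genomic_cds, "")[[1]]
    refs[chrom] <- paste(bases, collapse = "")

    for (b in blocks) {
      if (b$cls == "intron" || b$cls == "pad") next
      region_rows[[length(region_rows) + 1L]] <- data.frame(
        chrom = chrom, start = b$start, end = b$end,
        region_class = b$cls, gene = gene, stringsAsFactors = FALSE)
    }
    # transcript exons: terminal exons fuse UTR with flanking CDS chunk
    utr5 <- Filter(function(b) b$cls == "UTR5", blocks)[[1]]
    utr3 <- Filter(function(b) b$cls == "UTR3", blocks)[[1]]
    ex_s <- vapply(cds_blocks, function(b) b$start, numeric(1))
    ex_e <- vapply(cds_blocks, function(b) b$end, numeric(1))
    if (strand == "+") {
      ex_s[1] <- utr5$start
      ex_e[length(ex_e)] <- utr3$end
    } else {
      ex_s[1] <- utr3$start
      ex_e[length(ex_e)] <- utr5$end
    }
    gene_rows[[length(gene_rows) + 1L]] <- data.frame(
      gene = gene, transcript_id = paste0("TX_", gene), chrom = chrom,
      strand = strand, cds_start = cds_start, cds_end = cds_end,
      stringsAsFactors = FALSE)
    gene_rows[[length(gene_rows)]]$exon_starts <- list(as.integer(ex_s))
    gene_rows[[length(gene_rows)]]$exon_ends <- list(as.integer(ex_e))
  }
  genes <- if (length(gene_rows)) do.call(rbind, gene_rows) else
    data.frame(gene = character(), transcript_id = character(),
               chrom = character(), strand = character(),
               cds_start = integer(), cds_end = integer())
  regions <- if (length(region_rows)) {
    regions_from_df(do.call(rbind, region_rows), flank = 0L)
  } else {
    regions_from_df(data.frame(chrom = character(), start = integer(),
                               end = integer(), region_class = character(),
                               gene = character()))
  }
  list(reference = ref_seq(refs), regions = regions, genes = genes,
       config = config)
}

rdepth <- function(n, mean, dispersion) {
  if (is.null(dispersion)) stats::rpois(n, mean)
  else stats::rnbinom(n, size = dispersion, mu = mean)
}

class_alt <- function(ref_base, cls) {
  # cls is pyrimidine-centered; purine reference takes the complement alt
  target <- substr(cls, 3, 3)
  ifelse(ref_base %in% c("C", "T"), target, comp_dna(target))
}

#' Simulate a paired tumor/normal cohort over a panel
#'
#' Plants germline heterozygous SNPs, somatic SNVs per stratum and class at
#' the configured per-eligible-base rates, and somatic indels, then
#' generates per-sample genotype/read-depth evidence landing on the
#' intended side of every classifier threshold. A configured fraction of
#' planted somatic variants is copied into a synthetic catalogue, with
#' position-shifted and split-MNV decoys to exercise loose matching.
#'
#' @param panel output of [simulate_panel()].
#' @param config the same [sim_config()] (or an override).
#' @param rate_multiplier named list of per-class multipliers applied to
#'   the coding-stratum rates (used to plant known enrichment, e.g.
#'   `list("C>T" = 2)`).
#' @return list with calls (data frame, all samples), truth, catalogue,
#'   samples.
#' @export
simulate_cohort <- function(panel, config = panel$config,
                            rate_multiplier = NULL) {
  set.seed(config$seed + 1L)
  ref <- panel$reference
  regions <- panel$regions
  samples <- sprintf("S%02d", seq_len(config$n_samples))

  # eligible positions per stratum and base group (0-based)
  elig <- list()
  for (st in c("coding", "non_coding")) {
    posl <- stratum_positions(regions, st, include_flank = FALSE)
    gcp <- list(); atp <- list()
    for (ch in names(posl)) {
      p <- posl[[ch]]
      b <- substring(ref[[ch]], p + 1L, p + 1L)
      gcp[[ch]] <- p[b %in% c("G", "C")]
      atp[[ch]] <- p[b %in% c("A", "T")]
    }
    elig[[st]] <- list(gc = gcp, at = atp,
                       all = posl,
                       n_gc = sum(lengths(gcp)), n_at = sum(lengths(atp)))
  }
  draw_positions <- function(pool_list, n) {
    # pool_list: per-chrom 0-based positions; returns data.frame chrom,pos0
    flat_ch <- rep(names(pool_list), lengths(pool_list))
    flat_p <- unlist(pool_list, use.names = FALSE)
    if (n > length(flat_p)) stop("mutation rate too high for panel size")
    k <- sample.int(length(flat_p), n)
    data.frame(chrom = flat_ch[k], pos0 = flat_p[k], stringsAsFactors = FALSE)
  }

  truth <- list(); call_rows <- list()
  cat_pool <- list()
  for (s in samples) {
    used <- character(0)   # "chrom:pos0" occupancy per sample
    take <- function(df) {
      key <- paste(df$chrom, df$pos0)
      df <- df[!key %in% used, , drop = FALSE]
      used <<- c(used, paste(df$chrom, df$pos0))
      df
    }
    plant <- list()
    for (st in c("coding", "non_coding")) {
      overall <- if (st == "coding") config$coding_rate else config$noncoding_rate
      props <- if (st == "coding") config$class_props_coding else config$class_props_noncoding
      total_bases <- elig[[st]]$n_gc + elig[[st]]$n_at
      for (cls in SUBSTITUTION_CLASSES) {
        pool <- if (substr(cls, 1, 1) == "C") elig[[st]]$gc else elig[[st]]$at
        n_elig <- if (substr(cls, 1, 1) == "C") elig[[st]]$n_gc else elig[[st]]$n_at
        if (n_elig == 0) next
        rate <- overall * props[[cls]] * total_bases / n_elig
        if (st == "coding" && !is.null(rate_multiplier) &&
            !is.null(rate_multiplier[[cls]])) {
          rate <- rate * rate_multiplier[[cls]]
        }
        n <- stats::rbinom(1, n_elig, min(1, rate))
        if (n == 0) next
        df <- take(draw_positions(pool, n))
        if (!nrow(df)) next
        df$ref <- substring(vapply(df$chrom, function(ch) ref[[ch]], ""),
                            df$pos0 + 1L, df$pos0 + 1L)
        df$alt <- class_alt(df$ref, cls)
        df$origin <- "somatic"; df$class <- cls; df$stratum <- st
        plant[[length(plant) + 1L]] <- df
      }
      # somatic indels
      n_ind <- stats::rbinom(1, total_bases, min(1, config$indel_rate))
      if (n_ind > 0) {
        df <- take(draw_positions(elig[[st]]$all, n_ind))
        if (nrow(df)) {
          alleles <- lapply(seq_len(nrow(df)), function(i) {
            len <- sample(1:4, 1)
            chlen <- nchar(ref[[df$chrom[i]]])
            if (stats::runif(1) < 0.5 && df$pos0[i] + len + 1L <= chlen) {
              r <- ref_fetch(ref, df$chrom[i], df$pos0[i], df$pos0[i] + len + 1L)
              list(ref = r, alt = substr(r, 1, 1))
            } else {
              anchor <- ref_fetch(ref, df$chrom[i], df$pos0[i], df$pos0[i] + 1L)
              list(ref = anchor,
                   alt = paste0(anchor, paste(sample(c("A", "C", "G", "T"),
                                                     len, replace = TRUE),
                                              collapse = "")))
            }
          })
          df$ref <- vapply(alleles, `[[`, "", "ref")
          df$alt <- vapply(alleles, `[[`, "", "alt")
          df$origin <- "somatic"; df$class <- NA_character_; df$stratum <- st
          plant[[length(plant) + 1L]] <- df
        }
      }
    }
    # germline heterozygous SNPs over all targeted bases
    all_pool <- mapply(function(a, b) sort(c(a, b)),
                       elig$coding$all, elig$non_coding$all, SIMPLIFY = FALSE)
    n_bases <- sum(lengths(all_pool))
    n_germ <- stats::rbinom(1, n_bases, min(1, config$germline_rate))
    if (n_germ > 0) {
      df <- take(draw_positions(all_pool, n_germ))
      if (nrow(df)) {
        df$ref <- substring(vapply(df$chrom, function(ch) ref[[ch]], ""),
                            df$pos0 + 1L, df$pos0 + 1L)
        transition <- c(A = "G", G = "A", C = "T", T = "C")
        tv <- stats::runif(nrow(df)) > config$germline_transition_prob
        df$alt <- transition[df$ref]
        if (any(tv)) {
          df$alt[tv] <- vapply(df$ref[tv], function(r) {
            sample(setdiff(c("A", "C", "G", "T"), c(r, transition[[r]])), 1)
          }, "")
        }
        df$origin <- "germline"; df$class <- NA_character_; df$stratum <- NA_character_
        plant[[length(plant) + 1L]] <- df
      }
    }
    if (!length(plant)) next
    pl <- do.call(rbind, plant)
    pl$sample <- s
    pl$pos <- pl$pos0 + 1L
    somatic <- pl$origin == "somatic"
    pl$zygosity <- NA_character_
    pl$zygosity[somatic] <- ifelse(stats::runif(sum(somatic)) < config$hom_fraction,
                                   "homozygous", "heterozygous")
    pl$intended_confidence <- NA_character_
    pl$intended_confidence[somatic] <-
      ifelse(stats::runif(sum(somatic)) < config$frac_low_confidence, "low", "high")
    call_rows[[s]] <- build_evidence(pl, config)
    truth[[s]] <- pl
  }
  truth <- if (length(truth)) do.call(rbind, truth) else NULL
  calls <- if (length(call_rows)) do.call(rbind, call_rows) else NULL
  if (!is.null(truth)) rownames(truth) <- NULL
  if (!is.null(calls)) rownames(calls) <- NULL

  catalogue <- build_catalogue(truth, calls, ref, config)
  list(calls = calls, truth = truth, catalogue = catalogue$catalogue,
       calls_extra = catalogue$extra_calls, samples = samples)
}

# Generate per-call genotype and read evidence landing on the intended side
# of every classifier threshold.
build_evidence <- function(pl, config) {
  n <- nrow(pl)
  qual <- round(stats::runif(n, 60, 250), 1)
  qd <- round(stats::runif(n, 6, 18), 2)
  hrun <- sample(0:3, n, replace = TRUE)
  fs <- round(stats::runif(n, 0, 30), 2)
  rprs <- ifelse(is_indel(pl$ref, pl$alt), round(stats::runif(n, -5, 5), 2),
                 NA_real_)
  tumor_depth <- pmax(6L, rdepth(n, config$tumor_depth, config$dispersion))
  normal_depth <- pmax(12L, rdepth(n, config$normal_depth, config$dispersion))
  vaf <- ifelse(!is.na(pl$zygosity) & pl$zygosity == "homozygous",
                config$vaf_hom, config$vaf_het)
  tumor_alt <- stats::rbinom(n, tumor_depth, vaf)
  normal_alt <- integer(n)

  somatic <- pl$origin == "somatic"
  tumor_alt[somatic] <- pmax(3L, tumor_alt[somatic])
  germ <- !somatic
  if (any(germ)) {
    normal_alt[germ] <- pmax(1L, stats::rbinom(sum(germ), normal_depth[germ], 0.5))
  }
  low <- somatic & pl$intended_confidence == "low"
  if (any(low)) {
    kind <- sample(c("normal_depth", "tumor_support", "filter_qd"),
                   sum(low), replace = TRUE)
    idx <- which(low)
    nd <- idx[kind == "normal_depth"]
    normal_depth[nd] <- sample(3:9, length(nd), replace = TRUE)
    ts <- idx[kind == "tumor_support"]
    tumor_alt[ts] <- sample(1:2, length(ts), replace = TRUE)
    fq <- idx[kind == "filter_qd"]
    qd[fq] <- round(stats::runif(length(fq), 3, 4.9), 2)
  }
  ta1 <- ifelse(somatic & pl$zygosity == "homozygous", pl$alt, pl$ref)
  ta1[germ] <- pl$ref[germ]
  ta2 <- pl$alt
  na1 <- pl$ref
  na2 <- ifelse(germ, pl$alt, pl$ref)

  data.frame(chrom = pl$chrom, pos = pl$pos, ref = pl$ref, alt = pl$alt,
             qual = qual, qd = qd, hrun = hrun, fs = fs,
             read_pos_rank_sum = rprs,
             tumor_a1 = ta1, tumor_a2 = ta2, normal_a1 = na1, normal_a2 = na2,
             tumor_ref_reads = pmax(0L, tumor_depth - tumor_alt),
             tumor_alt_reads = tumor_alt,
             normal_ref_reads = pmax(0L, normal_depth - normal_alt),
             normal_alt_reads = normal_alt,
             sample = pl$sample, stringsAsFactors = FALSE)
}

build_catalogue <- function(truth, calls, ref, config) {
  empty <- data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), gene = character(),
                      catalogue_id = character(), stringsAsFactors = FALSE)
  if (is.null(truth)) return(list(catalogue = empty, extra_calls = NULL))
  som <- truth[truth$origin == "somatic", , drop = FALSE]
  if (!nrow(som)) return(list(catalogue = empty, extra_calls = NULL))
  n_exact <- stats::rbinom(1, nrow(som), config$catalogue_fraction)
  pick <- if (n_exact > 0) sample(seq_len(nrow(som)), n_exact) else integer(0)
  entries <- som[pick, c("chrom", "pos", "ref", "alt"), drop = FALSE]
  entries$decoy <- "exact"
  snv_rows <- som[nchar(som$ref) == 1 & nchar(som$alt) == 1, , drop = FALSE]
  # position-shifted decoys (same alleles a few bases away)
  n_shift <- min(config$n_shift_decoys, nrow(snv_rows))
  if (n_shift > 0) {
    sh <- snv_rows[sample(seq_len(nrow(snv_rows)), n_shift), , drop = FALSE]
    sh$pos <- sh$pos + sample(1:4, n_shift, replace = TRUE)
    e <- sh[, c("chrom", "pos", "ref", "alt")]
    e$decoy <- "shifted"
    entries <- rbind(entries, e)
  }
  # split-MNV decoys: one MNV entry spanning a planted SNV plus a synthetic
  # adjacent SNV call added to the same sample's call set
  extra <- NULL
  n_split <- min(config$n_split_decoys, nrow(snv_rows))
  if (n_split > 0 && !is.null(calls)) {
    sp <- snv_rows[sample(seq_len(nrow(snv_rows)), n_split), , drop = FALSE]
    rows <- list(); mnv <- list()
    for (i in seq_len(n_split)) {
      ch <- sp$chrom[i]; p <- sp$pos[i]
      if (p + 1L > nchar(ref[[ch]])) next
      r2 <- ref_fetch(ref, ch, p, p + 1L)  # base after the SNV (1-based p+1)
      a2 <- setdiff(c("A", "C", "G", "T"), r2)[1]
      mnv[[i]] <- data.frame(chrom = ch, pos = p,
                             ref = paste0(sp$ref[i], r2),
                             alt = paste0(sp$alt[i], a2),
                             decoy = "split_mnv", stringsAsFactors = FALSE)
      tmpl <- calls[calls$sample == sp$sample[i] & calls$chrom == ch &
                      calls$pos == p, , drop = FALSE][1, ]
      tmpl$pos <- p + 1L; tmpl$ref <- r2; tmpl$alt <- a2
      tmpl$tumor_a1 <- r2; tmpl$tumor_a2 <- a2
      tmpl$normal_a1 <- r2; tmpl$normal_a2 <- r2
      rows[[i]] <- tmpl
    }
    if (length(mnv)) entries <- rbind(entries, do.call(rbind, mnv))
    if (length(rows)) extra <- do.call(rbind, rows)
  }
  entries$gene <- ""
  entries$catalogue_id <- sprintf("CAT%04d", seq_len(nrow(entries)))
  list(catalogue = entries[, c("chrom", "pos", "ref", "alt", "gene",
                               "catalogue_id", "decoy")],
       extra_calls = extra)
}

#' Simulate tumor/normal coverage windows with planted copy-number events
#'
#' Tiles the panel's target regions into windows (target size 100 bp,
#' maximum 150), draws Poisson (or negative-binomial) depths around the
#' configured means, and scales tumor depth by `2^log2` inside planted
#' events. Events must not overlap.
#'
#' @param panel output of [simulate_panel()].
#' @param config [sim_config()].
#' @param events data frame with columns gene, log2 (event spans the
#'   gene's transcript); NULL for none.
#' @return list with windows (chrom, start, end, gc, tumor_depth,
#'   normal_depth), truth (segment track of planted log2, 0 elsewhere),
#'   events.
#' @export
simulate_coverage <- function(panel, config = panel$config, events = NULL) {
  set.seed(config$seed + 2L)
  regions <- panel$regions
  genes <- panel$genes
  ev <- NULL
  if (!is.null(events) && nrow(events)) {
    idx <- match(events$gene, genes$gene)
    if (anyNA(idx)) stop("event gene not in panel: ",
                         paste(events$gene[is.na(idx)], collapse = ", "))
    ev <- data.frame(chrom = genes$chrom[idx],
                     start = vapply(idx, function(i) genes$exon_starts[[i]][1], numeric(1)),
                     end = vapply(idx, function(i) utils::tail(genes$exon_ends[[i]], 1), numeric(1)),
                     log2 = events$log2, gene = events$gene,
                     stringsAsFactors = FALSE)
    for (ch in unique(ev$chrom)) {
      e <- ev[ev$chrom == ch, , drop = FALSE]
      e <- e[order(e$start), , drop = FALSE]
      if (nrow(e) > 1 && any(e$start[-1] < e$end[-nrow(e)])) {
        stop("overlapping CNV events on ", ch)
      }
    }
  }
  wins <- list()
  for (i in seq_len(nrow(regions))) {
    L <- regions$end[i] - regions$start[i]
    nwin <- max(1L, ceiling(L / config$window_target))
    if (ceiling(L / nwin) > config$window_max) nwin <- ceiling(L / config$window_max)
    bounds <- round(seq(regions$start[i], regions$end[i], length.out = nwin + 1L))
    wins[[i]] <- data.frame(chrom = regions$chrom[i],
                            start = as.integer(bounds[-length(bounds)]),
                            end = as.integer(bounds[-1]),
                            stringsAsFactors = FALSE)
  }
  w <- do.call(rbind, wins)
  w <- w[w$start < w$end, , drop = FALSE]
  w <- w[order(w$chrom, w$start), , drop = FALSE]
  rownames(w) <- NULL
  w$gc <- vapply(seq_len(nrow(w)), function(i) {
    s <- ref_fetch(panel$reference, w$chrom[i], w$start[i], w$end[i])
    b <- strsplit(s, "")[[1]]
    mean(b %in% c("G", "C"))
  }, numeric(1))
  scale <- rep(1, nrow(w))
  if (!is.null(ev)) {
    for (j in seq_len(nrow(ev))) {
      mid <- (w$start + w$end) / 2
      hit <- w$chrom == ev$chrom[j] & mid >= ev$start[j] & mid < ev$end[j]
      scale[hit] <- 2^ev$log2[j]
    }
  }
  w$tumor_depth <- rdepth(nrow(w), config$tumor_depth * scale, config$dispersion)
  w$normal_depth <- rdepth(nrow(w), config$normal_depth, config$dispersion)

  truth <- list()
  for (ch in unique(w$chrom)) {
    lo <- min(w$start[w$chrom == ch]); hi <- max(w$end[w$chrom == ch])
    e <- if (is.null(ev)) NULL else ev[ev$chrom == ch, , drop = FALSE]
    if (is.null(e) || !nrow(e)) {
      truth[[ch]] <- data.frame(chrom = ch, start = lo, end = hi, log2 = 0)
    } else {
      e <- e[order(e$start), ]
      segs <- list(); cur <- lo
      for (j in seq_len(nrow(e))) {
        if (e$start[j] > cur) {
          segs[[length(segs) + 1L]] <- data.frame(chrom = ch, start = cur,
                                                  end = e$start[j], log2 = 0)
        }
        segs[[length(segs) + 1L]] <- data.frame(chrom = ch, start = e$start[j],
                                                end = e$end[j], log2 = e$log2[j])
        cur <- e$end[j]
      }
      if (cur < hi) {
        segs[[length(segs) + 1L]] <- data.frame(chrom = ch, start = cur,
                                                end = hi, log2 = 0)
      }
      truth[[ch]] <- do.call(rbind, segs)
    }
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(windows = w, truth = truth, events = ev)
}

#' Write a simulated panel to FASTA/BED/TSV files
#' @param panel output of [simulate_panel()].
#' @param dir output directory (created if needed).
#' @return invisible named vector of paths.
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "panel.fa")
  bed <- file.path(dir, "targets.bed")
  tsv <- file.path(dir, "genes.tsv")
  write_fasta(panel$reference, fa)
  write_regions(panel$regions, bed)
  g <- panel$genes
  out <- data.frame(gene = g$gene, transcript_id = g$transcript_id,
                    chrom = g$chrom, strand = g$strand,
                    exon_starts = vapply(g$exon_starts, paste, "", collapse = ","),
                    exon_ends = vapply(g$exon_ends, paste, "", collapse = ","),
                    cds_start = g$cds_start, cds_end = g$cds_end)
  utils::write.table(out, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fa, bed = bed, genes = tsv))
}

#' Write per-sample paired VCFs for a simulated cohort
#'
#' One VCF per sample with TUMOR and NORMAL columns, GT:AD FORMAT and
#' QD/HRun/FS/ReadPosRankSum INFO keys.
#' @param cohort output of [simulate_cohort()].
#' @param dir output directory.
#' @return invisible vector of VCF paths.
#' @export
write_cohort_vcf <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  calls <- rbind(cohort$calls,
                 if (!is.null(cohort$calls_extra)) cohort$calls_extra)
  gt_of <- function(a1, a2, ref, alt) {
    g <- function(a) ifelse(a == ref, 0L, 1L)
    paste0(pmin(g(a1), g(a2)), "/", pmax(g(a1), g(a2)))
  }
  for (s in unique(calls$sample)) {
    v <- calls[calls$sample == s, , drop = FALSE]
    v <- v[order(v$chrom, v$pos), , drop = FALSE]
    info <- sprintf("QD=%g;HRun=%d;FS=%g", v$qd, v$hrun, v$fs)
    has_rprs <- !is.na(v$read_pos_rank_sum)
    info[has_rprs] <- paste0(info[has_rprs], ";ReadPosRankSum=",
                             v$read_pos_rank_sum[has_rprs])
    lines <- c(
      "##fileformat=VCFv4.2",
      "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
      "##INFO=<ID=HRun,Number=1,Type=Integer,Description=\"Homopolymer run\">",
      "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Fisher strand bias\">",
      "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"Read position rank sum\">",
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
      "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tTUMOR\tNORMAL",
      sprintf("%s\t%d\t.\t%s\t%s\t%g\t.\t%s\tGT:AD\t%s:%d,%d\t%s:%d,%d",
              v$chrom, v$pos, v$ref, v$alt, v$qual, info,
              gt_of(v$tumor_a1, v$tumor_a2, v$ref, v$alt),
              v$tumor_ref_reads, v$tumor_alt_reads,
              gt_of(v$normal_a1, v$normal_a2, v$ref, v$alt),
              v$normal_ref_reads, v$normal_alt_reads)
    )
    p <- file.path(dir, paste0(s, ".vcf"))
    writeLines(lines, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
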