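# Readers and writers for the formats the pipeline touches.
#
# Coordinate contract: VCF/variant positions are 1-based; BED and all
# internal intervals are 0-based half-open. Conversion happens here, at the
# boundary, and nowhere else.

#' Read a reference FASTA into an indexed accessor
#'
#' Sequences are uppercased; names are truncated at the first whitespace.
#' @param path FASTA file.
#' @return named character vector of sequences with class `ref_seq`.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(names(seqs))) stop("duplicate sequence names in ", path)
  structure(seqs, class = "ref_seq")
}

#' Build a reference accessor from in-memory sequences
#' @param seqs named character vector of DNA sequences.
#' @return `ref_seq` object.
#' @export
ref_seq <- function(seqs) {
  stopifnot(!is.null(names(seqs)), !anyDuplicated(names(seqs)))
  structure(toupper(unlist(seqs)), class = "ref_seq")
}

#' Fetch a reference substring
#'
#' @param ref `ref_seq` accessor.
#' @param chrom sequence name.
#' @param start,end 0-based half-open interval.
#' @return the substring, uppercase.
#' @export
ref_fetch <- function(ref, chrom, start, end) {
  if (!chrom %in% names(ref)) stop("unknown sequence: ", chrom)
  n <- nchar(ref[[chrom]])
  if (any(start < 0) || any(end > n) || any(start > end)) {
    stop(sprintf("fetch %s:[%d,%d) outside sequence of length %d",
                 chrom, start[1], end[1], n))
  }
  substring(ref[[chrom]], start + 1L, end)
}

#' Write a reference to FASTA
#' @param ref `ref_seq` object.
#' @param path output file.
#' @export
write_fasta <- function(ref, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(ref)) {
    writeLines(c(paste0(">", nm), ref[[nm]]), con)
  }
  invisible(path)
}

new_region_set <- function(df, flank = 0L) {
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("region_set", "data.frame"), flank = flank)
}

#' Read labeled target regions from BED
#'
#' BED is 0-based half-open; the 4th column carries `class|gene`. When
#' `flank > 0` every region is extended on both sides and the extensions are
#' labeled `intronic_flank` (capture regions are analyzed with a 30 bp
#' flank by default). Overlapping intervals of the same (chrom, class, gene)
#' are merged.
#'
#' @param path BED file.
#' @param flank bases of flank to add each side (default 30).
#' @return a `region_set` data frame: chrom, start, end, region_class, gene.
#' @export
read_regions <- function(path, flank = 30L) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(new_region_set(data.frame(chrom = character(), start = integer(),
                                     end = integer(), region_class = character(),
                                     gene = character())))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  n <- length(parts)
  chrom <- vapply(parts, `[`, "", 1L)
  start <- as.integer(vapply(parts, `[`, "", 2L))
  end <- as.integer(vapply(parts, `[`, "", 3L))
  name <- vapply(parts, function(p) if (length(p) >= 4) p[4] else "other|", "")
  bad <- which(is.na(start) | is.na(end) | start >= end)
  if (length(bad)) stop("invalid interval (start >= end) at line ", bad[1])
  cls <- sub("\\|.*$", "", name)
  gene <- sub("^[^|]*\\|?", "", name)
  unknown <- !cls %in% REGION_CLASSES
  if (any(unknown)) stop("unknown region class at line ", which(unknown)[1],
                         ": ", cls[which(unknown)[1]])
  df <- data.frame(chrom = chrom, start = start, end = end,
                   region_class = cls, gene = gene, stringsAsFactors = FALSE)
  regions_from_df(df, flank = flank)
}

#' Build a region set from a data frame
#'
#' Applies flank extension and same-class merging; see [read_regions()].
#' @param df data frame with chrom, start, end, region_class, gene.
#' @param flank flank width in bases.
#' @return `region_set`.
#' @export
regions_from_df <- function(df, flank = 0L) {
  stopifnot(all(c("chrom", "start", "end", "region_class") %in% names(df)))
  if (is.null(df$gene)) df$gene <- character(nrow(df))
  if (nrow(df) == 0) {
    return(new_region_set(df[, c("chrom", "start", "end", "region_class", "gene")],
                          flank = as.integer(flank)))
  }
  if (any(df$start >= df$end)) stop("invalid interval (start >= end)")
  if (any(!df$region_class %in% REGION_CLASSES)) stop("unknown region class")
  if (flank > 0 && nrow(df) > 0) {
    left <- data.frame(chrom = df$chrom, start = pmax(0L, df$start - as.integer(flank)),
                       end = df$start, region_class = "intronic_flank",
                       gene = df$gene, stringsAsFactors = FALSE)
    right <- data.frame(chrom = df$chrom, start = df$end,
                        end = df$end + as.integer(flank),
                        region_class = "intronic_flank", gene = df$gene,
                        stringsAsFactors = FALSE)
    df <- rbind(df, left[left$start < left$end, ], right)
  }
  merged <- do.call(rbind, lapply(split(df, list(df$chrom, df$region_class, df$gene),
                                        drop = TRUE), merge_intervals))
  new_region_set(merged, flank = as.integer(flank))
}

merge_intervals <- function(grp) {
  grp <- grp[order(grp$start, grp$end), , drop = FALSE]
  if (nrow(grp) <= 1) return(grp)
  keep_start <- grp$start[1]
  out <- grp[0, ]
  cur_s <- grp$start[1]; cur_e <- grp$end[1]
  for (i in seq_len(nrow(grp))[-1]) {
    if (grp$start[i] <= cur_e) {
      cur_e <- max(cur_e, grp$end[i])
    } else {
      out <- rbind(out, data.frame(chrom = grp$chrom[1], start = cur_s, end = cur_e,
                                   region_class = grp$region_class[1],
                                   gene = grp$gene[1], stringsAsFactors = FALSE))
      cur_s <- grp$start[i]; cur_e <- grp$end[i]
    }
  }
  rbind(out, data.frame(chrom = grp$chrom[1], start = cur_s, end = cur_e,
                        region_class = grp$region_class[1], gene = grp$gene[1],
                        stringsAsFactors = FALSE))
}

#' Write a region set to BED
#' @param regions `region_set`.
#' @param path output BED file.
#' @export
write_regions <- function(regions, path) {
  lines <- sprintf("%s\t%d\t%d\t%s|%s", regions$chrom, regions$start,
                   regions$end, regions$region_class, regions$gene)
  writeLines(lines, path)
  invisible(path)
}

#' Resolve the region class of genomic positions
#'
#' Applies the class precedence CDS > UTR5 > UTR3 > upstream >
#' intronic_flank > other so that every base has a unique stratum.
#' Positions outside all regions resolve to `NA`.
#'
#' @param regions `region_set`.
#' @param chrom,pos0 vectors of chromosome and 0-based position.
#' @return character vector of region classes (NA when untargeted).
#' @export
resolve_region_class <- function(regions, chrom, pos0) {
  out <- rep(NA_character_, length(pos0))
  for (cls in rev(REGION_CLASSES)) {  # low precedence first, overwritten later
    sub <- regions[regions$region_class == cls, , drop = FALSE]
    if (nrow(sub) == 0) next
    for (ch in unique(sub$chrom)) {
      rs <- sub[sub$chrom == ch, , drop = FALSE]
      idx <- which(chrom == ch)
      if (!length(idx)) next
      j <- findInterval(pos0[idx], rs$start)
      hit <- j >= 1 & pos0[idx] < rs$end[pmax(j, 1L)]
      out[idx[hit]] <- cls
    }
  }
  out
}

#' Read paired tumor/normal variant calls from a VCF
#'
#' Decomposes multi-allelic records into one call per ALT allele. Genotypes
#' are stored as the actual allele strings (unordered, unphased). Site
#' annotations QD, HRun, FS and ReadPosRankSum are taken from INFO when
#' present, `NA` when absent. Records with malformed GT or AD fields are
#' skipped and collected in the `"skipped"` attribute.
#'
#' @param path VCF 4.x file (plain text).
#' @param tumor,normal sample names as they appear in the VCF header.
#' @return data frame of paired calls, one row per ALT allele.
#' @export
read_vcf_pairs <- function(path, tumor, normal) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(v@gt)[-1]
  for (s in c(tumor, normal)) {
    if (!s %in% samples) stop("sample not present in VCF: ", s)
  }
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  n <- nrow(fix)
  empty <- paired_calls_schema()
  if (n == 0) return(empty)

  info_num <- function(key) {
    m <- regmatches(fix$INFO, regexpr(paste0("(^|;)", key, "=[^;]+"), fix$INFO))
    val <- rep(NA_real_, n)
    hit <- grepl(paste0("(^|;)", key, "="), fix$INFO)
    val[hit] <- suppressWarnings(as.numeric(sub(paste0(".*", key, "="), "", m)))
    val
  }
  qd <- info_num("QD"); hrun <- info_num("HRun")
  fs <- info_num("FS"); rprs <- info_num("ReadPosRankSum")

  parse_sample <- function(col) {
    fmt <- strsplit(v@gt[, 1], ":", fixed = TRUE)
    dat <- strsplit(v@gt[, col], ":", fixed = TRUE)
    list(fmt = fmt, dat = dat)
  }
  tu <- strsplit(v@gt[, tumor], ":", fixed = TRUE)
  no <- strsplit(v@gt[, normal], ":", fixed = TRUE)
  fmt <- strsplit(v@gt[, "FORMAT"], ":", fixed = TRUE)

  rows <- vector("list", n)
  skipped <- character(0)
  for (i in seq_len(n)) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    gi <- match("GT", fmt[[i]]); ai <- match("AD", fmt[[i]])
    rec <- try({
      if (is.na(gi) || is.na(ai)) stop("missing GT/AD")
      parse_gt <- function(x) {
        g <- suppressWarnings(as.integer(strsplit(x[gi], "[/|]")[[1]]))
        if (length(g) != 2 || anyNA(g)) stop("bad GT")
        g
      }
      parse_ad <- function(x) {
        a <- suppressWarnings(as.integer(strsplit(x[ai], ",", fixed = TRUE)[[1]]))
        if (anyNA(a) || any(a < 0)) stop("bad AD")
        a
      }
      tg <- parse_gt(tu[[i]]); ng <- parse_gt(no[[i]])
      tad <- parse_ad(tu[[i]]); nad <- parse_ad(no[[i]])
      alleles <- c(fix$REF[i], alts)
      if (max(tg, ng) + 1L > length(alleles)) stop("GT index out of range")
      lapply(seq_along(alts), function(k) {
        data.frame(
          chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
          ref = fix$REF[i], alt = alts[k],
          qual = suppressWarnings(as.numeric(fix$QUAL[i])),
          qd = qd[i], hrun = hrun[i], fs = fs[i], read_pos_rank_sum = rprs[i],
          tumor_a1 = alleles[tg[1] + 1L], tumor_a2 = alleles[tg[2] + 1L],
          normal_a1 = alleles[ng[1] + 1L], normal_a2 = alleles[ng[2] + 1L],
          tumor_ref_reads = tad[1],
          tumor_alt_reads = if (length(tad) > k) tad[k + 1L] else 0L,
          normal_ref_reads = nad[1],
          normal_alt_reads = if (length(nad) > k) nad[k + 1L] else 0L,
          stringsAsFactors = FALSE
        )
      })
    }, silent = TRUE)
    if (inherits(rec, "try-error")) {
      skipped <- c(skipped, sprintf("%s:%s %s", fix$CHROM[i], fix$POS[i],
                                    attr(rec, "condition")$message))
      next
    }
    rows[[i]] <- do.call(rbind, rec)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) out <- empty
  rownames(out) <- NULL
  if (length(skipped)) {
    warning(length(skipped), " record(s) skipped: ",
            paste(utils::head(skipped, 3), collapse = "; "))
  }
  attr(out, "skipped") <- skipped
  out
}

paired_calls_schema <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), qual = numeric(), qd = numeric(),
             hrun = numeric(), fs = numeric(), read_pos_rank_sum = numeric(),
             tumor_a1 = character(), tumor_a2 = character(),
             normal_a1 = character(), normal_a2 = character(),
             tumor_ref_reads = integer(), tumor_alt_reads = integer(),
             normal_ref_reads = integer(), normal_alt_reads = integer(),
             stringsAsFactors = FALSE)
}

#' Read gene models from a refFlat-style TSV
#'
#' Expected header columns: gene, transcript_id, chrom, strand,
#' exon_starts, exon_ends (comma-separated, 0-based half-open),
#' cds_start, cds_end.
#'
#' @param path TSV file.
#' @return data frame with list columns `exon_starts`, `exon_ends`.
#' @export
read_gene_models <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "transcript_id", "chrom", "strand",
            "exon_starts", "exon_ends", "cds_start", "cds_end")
  if (!all(need %in% names(df))) stop("gene model TSV missing columns: ",
                                      paste(setdiff(need, names(df)), collapse = ", "))
  df$exon_starts <- lapply(strsplit(as.character(df$exon_starts), ","), as.integer)
  df$exon_ends <- lapply(strsplit(as.character(df$exon_ends), ","), as.integer)
  validate_gene_models(df)
  df
}

validate_gene_models <- function(df) {
  for (i in seq_len(nrow(df))) {
    s <- df$exon_starts[[i]]; e <- df$exon_ends[[i]]
    if (length(s) != length(e) || any(s >= e)) {
      stop("inconsistent exons for transcript ", df$transcript_id[i])
    }
    if (is.unsorted(s, strictly = TRUE) || any(s[-1] < e[-length(e)])) {
      stop("exons unsorted/overlapping for transcript ", df$transcript_id[i])
    }
    if (!df$strand[i] %in% c("+", "-")) stop("bad strand for ", df$transcript_id[i])
    if (df$cds_start[i] < df$cds_end[i]) {
      if (df$cds_start[i] < s[1] || df$cds_end[i] > e[length(e)]) {
        stop("CDS outside exon span for transcript ", df$transcript_id[i])
      }
      len <- cds_length(s, e, df$cds_start[i], df$cds_end[i])
      if (len %% 3L != 0L) {
        warning("CDS length not a multiple of 3 for ", df$transcript_id[i])
      }
    }
  }
  invisible(df)
}

cds_length <- function(exon_starts, exon_ends, cds_start, cds_end) {
  sum(pmax(0L, pmin(exon_ends, cds_end) - pmax(exon_starts, cds_start)))
}

#' Read a variant catalogue TSV
#'
#' Columns: chrom, pos (1-based), ref, alt, gene, catalogue_id. Indel
#' alleles may use `-` for the empty allele (COSMIC-style); they are
#' converted to anchored form during normalization.
#' @param path TSV file.
#' @return data frame.
#' @export
read_catalogue <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = list(chrom = "character"))
  need <- c("chrom", "pos", "ref", "alt", "gene", "catalogue_id")
  if (!all(need %in% names(df))) stop("catalogue TSV missing columns: ",
                                      paste(setdiff(need, names(df)), collapse = ", "))
  check_alleles(df$ref, df$alt, allow_dash = TRUE)
  df
}

#' Read a segment / window track TSV
#'
#' Columns: chrom, start, end (0-based half-open), log2. Sorted per
#' chromosome on load.
#' @param path TSV file.
#' @return data frame.
#' @export
read_segments <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = list(chrom = "character"))
  need <- c("chrom", "start", "end", "log2")
  if (!all(need %in% names(df))) stop("segment TSV missing columns: ",
                                      paste(setdiff(need, names(df)), collapse = ", "))
  if (any(df$start >= df$end)) stop("invalid segment interval (start >= end)")
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}
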