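# Window log2 ratios, coverage filtering, greedy segmentation, gene-level
# copy-number calls and cross-platform concordance. The normalizer and
# segmenter here are deliberately simple, documented stand-ins; externally
# segmented tracks are accepted verbatim by the downstream steps.

#' Compute per-window tumor/normal log2 ratios
#'
#' Tumor depths are library-size scaled by the total-depth ratio, then
#' `log2((tumor_scaled + eps) / (normal + eps))` with `eps = 0.5` keeps
#' zero-coverage windows finite. Optional GC correction subtracts the
#' median log-ratio per GC decile (requires a `gc` column).
#'
#' @param windows data frame with chrom, start, end, tumor_depth,
#'   normal_depth (and optionally gc).
#' @param gc_correct subtract per-GC-decile median log ratio.
#' @param eps pseudo-depth guard (default 0.5).
#' @return `windows` with a `log2` column.
#' @export
window_log_ratios <- function(windows, gc_correct = FALSE, eps = 0.5) {
  s <- sum(windows$normal_depth) / max(sum(windows$tumor_depth), 1e-9)
  lr <- log2((windows$tumor_depth * s + eps) / (windows$normal_depth + eps))
  if (gc_correct) {
    if (is.null(windows$gc)) stop("gc_correct requires a gc column")
    dec <- cut(windows$gc, breaks = stats::quantile(windows$gc, probs = seq(0, 1, 0.1)),
               include.lowest = TRUE)
    med <- stats::ave(lr, dec, FUN = stats::median)
    lr <- lr - med
  }
  windows$log2 <- lr
  windows
}

#' Remove windows with low normal coverage
#'
#' @param windows data frame with normal_depth.
#' @param min_normal_depth windows with normal depth strictly below this
#'   are removed (default 20).
#' @return filtered windows; the number removed is in attribute `removed`.
#' @export
filter_low_coverage <- function(windows, min_normal_depth = 20) {
  keep <- windows$normal_depth >= min_normal_depth
  out <- windows[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- sum(!keep)
  message(sum(!keep), " window(s) removed for normal coverage < ",
          min_normal_depth)
  out
}

#' Segment windowed log2 ratios by greedy merging
#'
#' Within each chromosome, adjacent windows join the running segment while
#' the absolute difference between the window log2 and the running segment
#' mean is at most `merge_tolerance`; the segment value is the mean of its
#' member windows. Input must be sorted by start within chromosome.
#'
#' @param windows data frame with chrom, start, end, log2.
#' @param merge_tolerance merge threshold (default 0.4).
#' @return segment track data frame: chrom, start, end, log2, n_windows.
#' @export
segment_windows <- function(windows, merge_tolerance = 0.4) {
  out <- list()
  for (ch in unique(windows$chrom)) {
    w <- windows[windows$chrom == ch, , drop = FALSE]
    if (is.unsorted(w$start)) stop("windows unsorted on ", ch)
    seg_start <- w$start[1]; seg_end <- w$end[1]
    vals <- w$log2[1]
    for (i in seq_len(nrow(w))[-1]) {
      if (abs(w$log2[i] - mean(vals)) <= merge_tolerance) {
        vals <- c(vals, w$log2[i])
        seg_end <- w$end[i]
      } else {
        out[[length(out) + 1L]] <- data.frame(chrom = ch, start = seg_start,
                                              end = seg_end, log2 = mean(vals),
                                              n_windows = length(vals))
        seg_start <- w$start[i]; seg_end <- w$end[i]; vals <- w$log2[i]
      }
    }
    out[[length(out) + 1L]] <- data.frame(chrom = ch, start = seg_start,
                                          end = seg_end, log2 = mean(vals),
                                          n_windows = length(vals))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

overlap_len <- function(s1, e1, s2, e2) pmax(0L, pmin(e1, e2) - pmax(s1, s2))

#' Gene-level copy-number calls
#'
#' Per-gene mean log2 is the overlap-length-weighted mean of covering
#' segments over the gene's exons. Genes whose summed exon length is not
#' greater than `min_gene_bp` are `not_evaluable`, as are genes with no
#' covering segments. A gene is an `amplification` when every exon's
#' covering-segment mean exceeds `gain_threshold` (strict); a
#' `homozygous_deletion` when a segment below `del_threshold` (strict) of
#' length at least `min_del_bp` overlaps at least one exonic base.
#'
#' @param segments segment track (chrom, start, end, log2).
#' @param gene_models gene model data frame.
#' @param gain_threshold,del_threshold strict log2 thresholds (defaults
#'   +2 / -2).
#' @param min_gene_bp minimum summed exon length for evaluation (400).
#' @param min_del_bp minimum deletion segment length (400).
#' @return data frame: gene, mean_log2, status, n_segments.
#' @export
gene_cnv_calls <- function(segments, gene_models, gain_threshold = 2,
                           del_threshold = -2, min_gene_bp = 400L,
                           min_del_bp = 400L) {
  rows <- lapply(seq_len(nrow(gene_models)), function(i) {
    g <- gene_models[i, ]
    es <- g$exon_starts[[1]]; ee <- g$exon_ends[[1]]
    exon_len <- sum(ee - es)
    segs <- segments[segments$chrom == g$chrom, , drop = FALSE]
    if (exon_len <= min_gene_bp) {
      return(data.frame(gene = g$gene, mean_log2 = NA_real_,
                        status = "not_evaluable", n_segments = 0L))
    }
    # overlap of each segment with the exon set
    ov <- vapply(seq_len(nrow(segs)), function(j) {
      sum(overlap_len(segs$start[j], segs$end[j], es, ee))
    }, numeric(1))
    covering <- which(ov > 0)
    if (!length(covering)) {
      return(data.frame(gene = g$gene, mean_log2 = NA_real_,
                        status = "not_evaluable", n_segments = 0L))
    }
    mean_log2 <- sum(segs$log2[covering] * ov[covering]) / sum(ov[covering])
    # all-exons rule for gains: each exon's covering-segment weighted mean
    exon_means <- vapply(seq_along(es), function(k) {
      o <- overlap_len(segs$start, segs$end, es[k], ee[k])
      if (sum(o) == 0) return(NA_real_)
      sum(segs$log2 * o) / sum(o)
    }, numeric(1))
    amp <- all(!is.na(exon_means)) && all(exon_means > gain_threshold)
    # pass-threshold deletion regions: runs of consecutive below-threshold
    # segments are coalesced, so a fragmented deletion still counts by its
    # spanned length
    below <- segs$log2 < del_threshold
    runs <- rle(below)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    del_segs <- integer(0)
    for (ri in which(runs$values)) {
      span <- segs$end[ends[ri]] - segs$start[starts[ri]]
      run_idx <- starts[ri]:ends[ri]
      if (span >= min_del_bp && any(ov[run_idx] > 0)) {
        del_segs <- c(del_segs, run_idx)
      }
    }
    status <- if (length(del_segs)) {
      "homozygous_deletion"
    } else if (amp) {
      "amplification"
    } else {
      "neutral"
    }
    data.frame(gene = g$gene, mean_log2 = mean_log2, status = status,
               n_segments = length(covering))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Concordance between two segmented copy-number tracks
#'
#' For each segment of `track_a`, its genomic midpoint is looked up in
#' `track_b`; covered midpoints contribute a pair of log2 values. Reports
#' the Pearson correlation, the number of pairs, and the number of
#' midpoints dropped because `track_b` does not cover them.
#'
#' @param track_a,track_b segment data frames (chrom, start, end, log2).
#' @return list with r, p_value, n, dropped, pairs (data frame).
#' @export
cnv_concordance <- function(track_a, track_b) {
  mid <- (track_a$start + track_a$end) / 2
  b_val <- rep(NA_real_, nrow(track_a))
  for (i in seq_len(nrow(track_a))) {
    hit <- which(track_b$chrom == track_a$chrom[i] &
                   track_b$start <= mid[i] & mid[i] < track_b$end)
    if (length(hit)) b_val[i] <- track_b$log2[hit[1]]
  }
  ok <- !is.na(b_val)
  pairs <- data.frame(chrom = track_a$chrom[ok], midpoint = mid[ok],
                      log2_a = track_a$log2[ok], log2_b = b_val[ok])
  dropped <- sum(!ok)
  if (sum(ok) < 3 || stats::sd(pairs$log2_a) == 0 || stats::sd(pairs$log2_b) == 0) {
    return(list(r = NA_real_, p_value = NA_real_, n = sum(ok),
                dropped = dropped, pairs = pairs, defined = FALSE))
  }
  ct <- stats::cor.test(pairs$log2_a, pairs$log2_b, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = sum(ok),
       dropped = dropped, pairs = pairs, defined = TRUE)
}
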