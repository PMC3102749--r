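#' Flag probes inside annotated repeat elements
#'
#' Probes overlapping Ty/delta repeats cross-hybridize and carry no usable
#' copy-number signal; segmentation masks them before calling.
#'
#' @param probes Probe table (`chrom`, `start`, `end`, ...).
#' @param annotation A [repeat_annotation()] (or NULL for no masking).
#' @return Logical vector, TRUE for masked probes.
#' @export
mask_repeat_probes <- function(probes, annotation) {
  masked <- rep(FALSE, nrow(probes))
  if (is.null(annotation) || nrow(annotation) == 0L) return(masked)
  for (ch in unique(probes$chrom)) {
    pi <- which(probes$chrom == ch)
    el <- annotation[annotation$chrom == ch, , drop = FALSE]
    if (nrow(el) == 0L) next
    ps <- probes$start[pi]; pe <- probes$end[pi]
    hit <- rep(FALSE, length(pi))
    for (j in seq_len(nrow(el))) {
      hit <- hit | (ps < el$end[j] & pe > el$start[j])
    }
    masked[pi] <- hit
  }
  masked
}

check_sorted_probes <- function(probes) {
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(probes))
  if (length(miss)) stopf("probe table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  for (ch in unique(probes$chrom)) {
    s <- probes$start[probes$chrom == ch]
    if (is.unsorted(s)) stopf("probes on %s are not sorted by start", ch)
  }
  invisible(TRUE)
}

empty_segments <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             call = character(), copy_number = numeric(),
             n_probes = integer(), mean_log2 = numeric(),
             stringsAsFactors = FALSE)
}

# group indices of above-threshold probes into runs, absorbing noise dips
# of < min_gap probes, then breaking runs at coordinate gaps > gap_bp
# (e.g. across masked repeat blocks)
threshold_runs <- function(above, starts, ends, min_gap, gap_bp) {
  idx <- which(above)
  if (!length(idx)) return(list())
  # merge across < min_gap below-threshold probes
  brk <- c(FALSE, diff(idx) > min_gap)
  grp <- cumsum(brk)
  runs <- split(idx, grp)
  # break at large coordinate gaps between consecutive member probes
  out <- list()
  for (r in runs) {
    if (length(r) == 1L) { out[[length(out) + 1L]] <- r; next }
    gaps <- starts[r[-1L]] - ends[r[-length(r)]]
    sub <- cumsum(c(0L, as.integer(gaps > gap_bp)))
    out <- c(out, unname(split(r, sub)))
  }
  out
}

#' Call duplicated segments from log2 ratios
#'
#' Finds maximal runs of at least `min_probes` consecutive unmasked probes
#' whose log2 ratio exceeds `tau_log2`, assigns each an integer copy number
#' `round(2^mean_log2)`, and reports them as `duplication` (copy 2) or
#' `triplication_or_higher` (copy >= 3) segments. Runs separated by fewer
#' than `min_gap` below-threshold probes are merged (noise dips); runs are
#' broken at coordinate gaps larger than `gap_bp` (masked repeat blocks)
#' and re-merged when the flanking pieces carry the same copy number, lie
#' within `merge_gap_bp` of each other, and are separated by at most
#' `min_gap` unmasked below-threshold probes -- the same dip rule applied
#' across a masked block -- so one duplication spanning a masked Ty stays
#' one segment while segments separated by genuine normal-copy probes stay
#' apart.
#'
#' @param probes Probe table with `log2_ratio`.
#' @param annotation Optional [repeat_annotation()] used to mask probes.
#' @param tau_log2 Log2-ratio threshold (> 0); default 0.4.
#' @param min_probes Minimum probes per emitted segment; default 10
#'   (about 2 kb at 200 bp spacing).
#' @param min_gap Below-threshold run length that still splits segments.
#' @param gap_bp Coordinate gap that breaks a run.
#' @param merge_gap_bp Maximum gap across which equal-copy segments merge.
#' @return Segment `data.frame` (`chrom`, `start`, `end`, `call`,
#'   `copy_number`, `n_probes`, `mean_log2`).
#' @export
call_duplications <- function(probes, annotation = NULL, tau_log2 = 0.4,
                              min_probes = 10, min_gap = 3, gap_bp = 2000,
                              merge_gap_bp = 10000) {
  check_sorted_probes(probes)
  if (tau_log2 <= 0) stopf("`tau_log2` must be > 0")
  keep <- !mask_repeat_probes(probes, annotation)
  segs <- list()
  for (ch in unique(probes$chrom)) {
    pi <- which(probes$chrom == ch & keep)
    if (!length(pi)) next
    lr <- probes$log2_ratio[pi]
    st <- probes$start[pi]; en <- probes$end[pi]
    runs <- threshold_runs(lr > tau_log2, st, en, min_gap, gap_bp)
    if (!length(runs)) next
    rs <- vapply(runs, function(r) st[r[1L]], numeric(1))
    re <- vapply(runs, function(r) en[r[length(r)]], numeric(1))
    ml <- vapply(runs, function(r) mean(lr[r]), numeric(1))
    np <- lengths(runs)
    o <- order(rs)
    rs <- rs[o]; re <- re[o]; ml <- ml[o]; np <- np[o]
    cn <- round(2^ml)
    # re-merge equal-copy neighbours across masked gaps: the pieces must be
    # separated by at most min_gap unmasked probes (the rest of the gap
    # being masked repeat), mirroring the within-run dip rule
    i <- 1L
    while (i < length(rs)) {
      n_between <- sum(st >= re[i] & st < rs[i + 1L])
      if (cn[i + 1L] == cn[i] && rs[i + 1L] - re[i] <= merge_gap_bp &&
          n_between <= min_gap) {
        ml[i] <- (ml[i] * np[i] + ml[i + 1L] * np[i + 1L]) /
          (np[i] + np[i + 1L])
        re[i] <- re[i + 1L]
        np[i] <- np[i] + np[i + 1L]
        cn[i] <- round(2^ml[i])
        keep_i <- -(i + 1L)
        rs <- rs[keep_i]; re <- re[keep_i]; ml <- ml[keep_i]
        np <- np[keep_i]; cn <- cn[keep_i]
      } else i <- i + 1L
    }
    segs[[length(segs) + 1L]] <- data.frame(
      chrom = ch, start = rs, end = re, copy_number = cn, n_probes = np,
      mean_log2 = ml, stringsAsFactors = FALSE)
  }
  if (!length(segs)) return(empty_segments())
  out <- do.call(rbind, segs)
  out <- out[out$n_probes >= min_probes & out$copy_number >= 2, , drop = FALSE]
  if (!nrow(out)) return(empty_segments())
  out$call <- ifelse(out$copy_number >= 3, "triplication_or_higher",
                     "duplication")
  rownames(out) <- NULL
  out[, c("chrom", "start", "end", "call", "copy_number", "n_probes",
          "mean_log2")]
}

#' Call deleted segments from raw intensities
#'
#' Deletions are maximal runs of at least `min_probes` unmasked probes with
#' raw intensity below `frac_threshold` times the genome-wide median.
#' Interior high-intensity spikes of at most `spike_tolerance` probes
#' (redundant sequences cross-hybridizing inside a deletion) are absorbed.
#' Calls are invariant to a global rescaling of the raw intensities.
#'
#' @param probes Probe table with `raw_intensity`.
#' @param annotation Optional [repeat_annotation()] used to mask probes.
#' @param frac_threshold Fraction of the genome median below which a probe
#'   counts as deleted; default 0.3.
#' @param min_probes Minimum low probes per emitted segment.
#' @param spike_tolerance Maximum run of interior high probes absorbed.
#' @return Segment `data.frame` as in [call_duplications()] with
#'   `call = "deletion"`, `copy_number = 0`.
#' @export
call_deletions <- function(probes, annotation = NULL, frac_threshold = 0.3,
                           min_probes = 10, spike_tolerance = 5) {
  check_sorted_probes(probes)
  keep <- !mask_repeat_probes(probes, annotation)
  raw <- probes$raw_intensity[keep]
  if (!length(raw) || all(raw == 0)) {
    stopf("degenerate input: no usable raw intensities")
  }
  med <- stats::median(raw)
  if (med <= 0) stopf("degenerate input: non-positive median raw intensity")
  thr <- frac_threshold * med
  segs <- list()
  for (ch in unique(probes$chrom)) {
    pi <- which(probes$chrom == ch & keep)
    if (!length(pi)) next
    low <- probes$raw_intensity[pi] < thr
    st <- probes$start[pi]; en <- probes$end[pi]
    idx <- which(low)
    if (!length(idx)) next
    # absorb interior spikes of <= spike_tolerance probes
    grp <- cumsum(c(0L, as.integer(diff(idx) > spike_tolerance + 1L)))
    for (r in split(idx, grp)) {
      if (length(r) < min_probes) next
      lr <- probes$log2_ratio[pi][r]
      segs[[length(segs) + 1L]] <- data.frame(
        chrom = ch, start = st[r[1L]], end = en[r[length(r)]],
        call = "deletion", copy_number = 0, n_probes = length(r),
        mean_log2 = mean(lr), stringsAsFactors = FALSE)
    }
  }
  if (!length(segs)) return(empty_segments())
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}

#' Flag whole-chromosome aneuploidy
#'
#' A chromosome on which at least `frac` of the unmasked probes exceed the
#' duplication threshold is reported as a whole-chromosome gain rather
#' than a segment, and should be excluded from segmental calling.
#'
#' @param probes Probe table with `log2_ratio`.
#' @param annotation Optional [repeat_annotation()].
#' @param tau_log2 Duplication threshold.
#' @param frac Minimum fraction of elevated probes.
#' @return Character vector of aneuploid chromosome names.
#' @export
detect_aneuploidy <- function(probes, annotation = NULL, tau_log2 = 0.4,
                              frac = 0.9) {
  keep <- !mask_repeat_probes(probes, annotation)
  out <- character()
  for (ch in unique(probes$chrom)) {
    lr <- probes$log2_ratio[probes$chrom == ch & keep]
    if (length(lr) && mean(lr > tau_log2) >= frac) out <- c(out, ch)
  }
  out
}

#' Anchor segment boundaries to genomic features
#'
#' Labels each segment boundary `telomere` when within `tol_bp` of a
#' chromosome end, `centromere` when inside the centromere interval, else
#' the nearest repeat cluster within `tol_bp`, else `unanchored`.
#'
#' @param segments Segment table from [call_duplications()] /
#'   [call_deletions()].
#' @param clusters A [cluster_elements()] result.
#' @param map A [chromosome_map()].
#' @param tol_bp Anchor search tolerance; default 2 kb.
#' @return The segment table with added columns `anchor_left`,
#'   `anchor_right` (type labels), `anchor_left_elements`,
#'   `anchor_right_elements` (semicolon-joined ids, `NA` unless a cluster),
#'   `anchor_left_orientation`, `anchor_right_orientation` (cluster
#'   orientation summaries).
#' @export
anchor_boundaries <- function(segments, clusters, map, tol_bp = 2000) {
  n <- nrow(segments)
  res <- data.frame(
    anchor_left = character(n), anchor_right = character(n),
    anchor_left_elements = rep(NA_character_, n),
    anchor_right_elements = rep(NA_character_, n),
    anchor_left_orientation = rep(NA_character_, n),
    anchor_right_orientation = rep(NA_character_, n),
    stringsAsFactors = FALSE
  )
  anchor_one <- function(chrom, pos) {
    mi <- match(chrom, map$name)
    if (is.na(mi)) stopf("segment chromosome %s absent from the map", chrom)
    if (pos <= tol_bp || pos >= map$length[mi] - tol_bp) {
      return(list(type = "telomere", elements = NA_character_,
                  orientation = NA_character_))
    }
    if (pos >= map$cen_start[mi] && pos <= map$cen_end[mi]) {
      return(list(type = "centromere", elements = NA_character_,
                  orientation = NA_character_))
    }
    cl <- clusters[clusters$chrom == chrom, , drop = FALSE]
    if (nrow(cl)) {
      d <- pmax(cl$start - pos, pos - cl$end, 0)
      j <- which.min(d)
      if (d[j] <= tol_bp) {
        return(list(type = "cluster", elements = cl$elements[j],
                    orientation = cl$orientation_summary[j]))
      }
    }
    list(type = "unanchored", elements = NA_character_,
         orientation = NA_character_)
  }
  for (i in seq_len(n)) {
    al <- anchor_one(segments$chrom[i], segments$start[i])
    ar <- anchor_one(segments$chrom[i], segments$end[i])
    res$anchor_left[i] <- al$type
    res$anchor_left_elements[i] <- al$elements
    res$anchor_left_orientation[i] <- al$orientation
    res$anchor_right[i] <- ar$type
    res$anchor_right_elements[i] <- ar$elements
    res$anchor_right_orientation[i] <- ar$orientation
  }
  cbind(segments, res)
}

#' Segment one isolate end to end
#'
#' Convenience wrapper: aneuploidy flags, duplication and deletion calls on
#' non-aneuploid chromosomes, boundary anchoring.
#'
#' @param probes Probe table.
#' @param annotation A [repeat_annotation()].
#' @param map A [chromosome_map()].
#' @param ... Passed to the callers ([call_duplications()] /
#'   [call_deletions()] / [anchor_boundaries()] parameters by name).
#' @return List with `segments` (anchored) and `aneuploid_chroms`.
#' @export
segment_isolate <- function(probes, annotation, map, tau_log2 = 0.4,
                            min_probes = 10, frac_threshold = 0.3,
                            spike_tolerance = 5, tol_bp = 2000, ...) {
  aneu <- detect_aneuploidy(probes, annotation, tau_log2 = tau_log2)
  pr <- probes[!probes$chrom %in% aneu, , drop = FALSE]
  dups <- call_duplications(pr, annotation, tau_log2 = tau_log2,
                            min_probes = min_probes, ...)
  dels <- call_deletions(pr, annotation, frac_threshold = frac_threshold,
                         min_probes = min_probes,
                         spike_tolerance = spike_tolerance)
  segs <- rbind(dups, dels)
  segs <- segs[order(segs$chrom, segs$start), , drop = FALSE]
  rownames(segs) <- NULL
  clusters <- cluster_elements(annotation)
  list(segments = anchor_boundaries(segs, clusters, map, tol_bp = tol_bp),
       aneuploid_chroms = aneu)
}

#' Plot probe signal and calls for one chromosome
#'
#' Base-graphics view of the log2 ratios with called segments overlaid.
#'
#' @param probes Probe table.
#' @param chrom Chromosome to draw.
#' @param segments Optional segment table.
#' @return Invisibly, NULL.
#' @export
plot_probe_signal <- function(probes, chrom, segments = NULL) {
  p <- probes[probes$chrom == chrom, , drop = FALSE]
  graphics::plot(p$start / 1e3, p$log2_ratio, pch = ".", cex = 2,
                 xlab = sprintf("%s position (kb)", chrom),
                 ylab = "log2 ratio")
  graphics::abline(h = 0, col = "grey60")
  if (!is.null(segments)) {
    s <- segments[segments$chrom == chrom, , drop = FALSE]
    for (i in seq_len(nrow(s))) {
      y <- if (s$call[i] == "deletion") -2 else log2(s$copy_number[i])
      graphics::segments(s$start[i] / 1e3, y, s$end[i] / 1e3, y,
                         col = "red", lwd = 3)
    }
  }
  invisible(NULL)
}
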