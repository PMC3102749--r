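anchor_has_element <- function(elements_str, id) {
  !is.na(elements_str) && id %in% strsplit(elements_str, ";", fixed = TRUE)[[1L]]
}

#' Classify an isolate's rearrangement into the Class I-V taxonomy
#'
#' Applies the aCGH class rules to anchored segments:
#' \describe{
#'   \item{I}{a terminal deletion of the assay chromosome's left arm with no
#'     Ty-bounded amplification anywhere (de novo telomere addition).}
#'   \item{II/III/IV}{the Ty912-TEL05L deletion plus exactly one amplified
#'     segment bounded by a telomere and a repeat cluster; the cluster's
#'     orientation summary picks the class (all telomeric -> II, all
#'     centromeric -> III, mixed -> IV).}
#'   \item{V}{the Ty912-TEL05L deletion plus two or more amplified segments,
#'     or any segment at copy number 3 or higher.}
#' }
#' Whole-chromosome gains are excluded from segment counting and reported
#' separately. An isolate with neither a Ty912-anchored nor a terminal
#' deletion yields a `no_call`; an amplified segment with both boundaries
#' unanchored raises an error naming the segment.
#'
#' @param segments Anchored segment table ([anchor_boundaries()]).
#' @param aneuploid_chroms Chromosomes flagged as whole-chromosome gains.
#' @param map A [chromosome_map()].
#' @param assay_chrom,assay_element The assay chromosome and the inserted
#'   Ty element whose deletion defines classes II-V.
#' @param isolate Label carried through to the call.
#' @return A list of class `gcr_call`: `isolate`, `class_label` (`"I"` ...
#'   `"V"` or `"no_call"`), `chrV_deletion` (segment row or NULL),
#'   `amplified_segments`, `aneuploid_chroms`, `evidence` (character),
#'   `mechanism` (filled by [infer_mechanism()], initially `NA`).
#' @export
classify_gcr <- function(segments, aneuploid_chroms = character(), map,
                         assay_chrom = "ChrV", assay_element = "Ty912",
                         isolate = "isolate") {
  need <- c("anchor_left", "anchor_right")
  if (!all(need %in% names(segments))) {
    stopf("segments must be anchored (run anchor_boundaries first)")
  }
  dels <- segments[segments$call == "deletion", , drop = FALSE]
  amps <- segments[segments$call %in% c("duplication", "triplication_or_higher") &
                     !segments$chrom %in% aneuploid_chroms, , drop = FALSE]
  mi <- match(assay_chrom, map$name)
  terminal_left <- dels$chrom == assay_chrom & dels$anchor_left == "telomere" &
    dels$end <= map$cen_start[mi]
  ty_anchored <- terminal_left & vapply(seq_len(nrow(dels)), function(i) {
    dels$anchor_right[i] == "cluster" &&
      anchor_has_element(dels$anchor_right_elements[i], assay_element)
  }, logical(1))
  evidence <- character()
  if (nrow(amps)) {
    both_un <- amps$anchor_left == "unanchored" & amps$anchor_right == "unanchored"
    if (any(both_un)) {
      b <- amps[both_un, ][1, ]
      stopf("unclassifiable: amplified segment %s:%d-%d has no anchored boundary",
            b$chrom, b$start, b$end)
    }
  }
  mk <- function(label, chrV_del, evidence) {
    structure(list(isolate = isolate, class_label = label,
                   chrV_deletion = chrV_del, amplified_segments = amps,
                   aneuploid_chroms = aneuploid_chroms,
                   evidence = evidence, mechanism = NA_character_,
                   assay_chrom = assay_chrom, assay_element = assay_element),
              class = "gcr_call")
  }
  if (!any(terminal_left)) {
    return(mk("no_call", NULL,
              "no terminal deletion of the assay chromosome's left arm"))
  }
  chrV_del <- dels[which(terminal_left)[1L], ]
  if (nrow(amps) == 0L) {
    return(mk("I", chrV_del,
              "terminal deletion only; consistent with de novo telomere addition"))
  }
  if (!any(ty_anchored)) {
    return(mk("no_call", chrV_del,
              sprintf("amplifications present but the deletion is not anchored at %s",
                      assay_element)))
  }
  chrV_del <- dels[which(ty_anchored)[1L], ]
  evidence <- sprintf("%s-anchored terminal deletion of %s", assay_element,
                      assay_chrom)
  if (nrow(amps) >= 2L || any(amps$copy_number >= 3)) {
    return(mk("V", chrV_del, c(evidence, sprintf(
      "%d amplified segment(s), max copy number %d", nrow(amps),
      max(amps$copy_number)))))
  }
  a <- amps[1L, ]
  anchors <- c(a$anchor_left, a$anchor_right)
  if (!("telomere" %in% anchors && "cluster" %in% anchors)) {
    stopf("unclassifiable: single amplified segment %s:%d-%d is not bounded by a telomere and a repeat cluster (anchors: %s, %s)",
          a$chrom, a$start, a$end, a$anchor_left, a$anchor_right)
  }
  orient <- if (a$anchor_left == "cluster") a$anchor_left_orientation
            else a$anchor_right_orientation
  label <- switch(orient, all_telomeric = "II", all_centromeric = "III",
                  mixed = "IV")
  mk(label, chrV_del, c(evidence, sprintf(
    "single amplification bounded by a %s cluster and a telomere", orient)))
}

#' @export
print.gcr_call <- function(x, ...) {
  cat(sprintf("GCR call for %s: Class %s (mechanism: %s)\n", x$isolate,
              x$class_label, x$mechanism))
  if (!is.null(x$chrV_deletion)) {
    cat(sprintf("  deletion %s:%g-%g\n", x$chrV_deletion$chrom,
                x$chrV_deletion$start, x$chrV_deletion$end))
  }
  if (nrow(x$amplified_segments)) {
    with(x$amplified_segments,
         cat(sprintf("  amplification %s:%g-%g (copy %d)\n",
                     chrom, start, end, copy_number), sep = ""))
  }
  if (length(x$aneuploid_chroms)) {
    cat("  aneuploid:", paste(x$aneuploid_chroms, collapse = ", "), "\n")
  }
  invisible(x)
}

# junction orientation verdict for one amplified segment: the entry locus is
# the repeat anchor on the segment's centromeric side (for internal
# segments) or the repeat anchor (for telomere-bounded segments); synthesis
# entering a telomere-oriented locus proceeds toward the target's telomere
# (monocentric-compatible), entering a centromere-oriented locus proceeds
# through the target centromere (dicentric-forming), mixed loci support both
segment_junction_verdict <- function(seg, map) {
  mi <- match(seg$chrom, map$name)
  on_left <- seg$end <= map$cen_start[mi]
  anchors <- list(
    left = list(type = seg$anchor_left, orient = seg$anchor_left_orientation,
                elements = seg$anchor_left_elements),
    right = list(type = seg$anchor_right, orient = seg$anchor_right_orientation,
                 elements = seg$anchor_right_elements)
  )
  entry <- if (anchors$left$type == "telomere") anchors$right
    else if (anchors$right$type == "telomere") anchors$left
    else if (on_left) anchors$right else anchors$left  # centromeric border
  if (entry$type != "cluster") {
    return(list(verdict = "unanchored", elements = NA_character_))
  }
  v <- switch(entry$orient,
              all_telomeric = "monocentric_compatible",
              all_centromeric = "dicentric_forming",
              mixed = "both_viable")
  list(verdict = v, elements = entry$elements)
}

#' Infer the rearrangement mechanism for a classified call
#'
#' Class I events are de novo telomere additions; Class II events are
#' monocentric nonreciprocal translocations mediated by homologous
#' recombination; Class III events require a dicentric intermediate
#' resolved by breakage-fusion-bridge (fusion into a centromere-oriented
#' target copies through the target centromere). For Class V the inferred
#' donor-to-target chain is examined junction by junction: a chain whose
#' junctions are all monocentric-compatible is called template switching,
#' any dicentric-forming junction forces breakage-fusion-bridge, and a
#' chain with junctions into mixed-orientation loci (both interpretations
#' viable) is ambiguous. Class IV targets contain elements in both
#' orientations, so the verdict is ambiguous on copy-number evidence alone.
#'
#' @param call A [classify_gcr()] result.
#' @param map A [chromosome_map()].
#' @param observed_kb Optional observed rearranged-chromosome size; when
#'   given, the size residual is attached as evidence (a positive residual
#'   supports extra Ty content at the junction, but never changes the
#'   class).
#' @param wt_kb Wild-type assay chromosome size used for the size check.
#' @return The call with `mechanism` set and a `junction_verdicts`
#'   data.frame (and `size_prediction` when `observed_kb` is given)
#'   appended.
#' @export
infer_mechanism <- function(call, map, observed_kb = NULL, wt_kb = 624) {
  stopifnot(inherits(call, "gcr_call"))
  label <- call$class_label
  amps <- call$amplified_segments
  verdicts <- if (nrow(amps)) {
    do.call(rbind, lapply(seq_len(nrow(amps)), function(i) {
      v <- segment_junction_verdict(amps[i, ], map)
      data.frame(chrom = amps$chrom[i], start = amps$start[i],
                 end = amps$end[i], verdict = v$verdict,
                 entry_elements = v$elements, stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               verdict = character(), entry_elements = character(),
               stringsAsFactors = FALSE)
  }
  mech <- switch(
    label,
    I = "de_novo_telomere",
    II = "monocentric_HR",
    III = "dicentric_BFB",
    IV = "ambiguous",
    V = {
      vs <- verdicts$verdict
      if (any(vs == "unanchored")) "ambiguous"
      else if (any(vs == "dicentric_forming")) "dicentric_BFB"
      else if (any(vs == "both_viable")) "ambiguous"
      else "template_switch"
    },
    "ambiguous"
  )
  call$mechanism <- mech
  call$junction_verdicts <- verdicts
  if (any(verdicts$verdict == "unanchored")) {
    call$evidence <- c(call$evidence,
                       "junction with no anchored entry locus: evidence gap")
  }
  if (!is.null(observed_kb) && !is.null(call$chrV_deletion)) {
    del_kb <- (call$chrV_deletion$end - call$chrV_deletion$start) / 1000
    dup_kb <- (amps$end - amps$start) * pmax(amps$copy_number - 1, 1) / 1000
    sp <- predict_chromosome_size(del_kb, dup_kb, wt_kb = wt_kb,
                                  observed_kb = observed_kb)
    call$size_prediction <- sp
    if (!is.na(sp$residual_kb) && sp$residual_kb > 0) {
      call$evidence <- c(call$evidence, sprintf(
        "observed size exceeds prediction by %.0f kb: consistent with extra Ty content at the junction",
        sp$residual_kb))
    }
  }
  call
}

#' Translocation size accounting
#'
#' Predicts the size of the rearranged assay chromosome as
#' `wt_kb - deleted_kb + sum(duplicated_kbs)`; for the +Ty912 assay
#' chromosome V the wild-type size is 624 kb. Sizes are reported in kb
#' rounded to integers, with the raw value retained.
#'
#' @param deleted_kb Size of the deleted region (kb, >= 0).
#' @param duplicated_kbs Sizes of the regions of increased copy number
#'   joined to the chromosome (kb; one value per extra copy).
#' @param wt_kb Wild-type chromosome size (kb).
#' @param observed_kb Optional observed size from a Southern blot.
#' @return A list of class `size_prediction`: `wt_kb`, `deleted_kb`,
#'   `duplicated_kb_total`, `predicted_kb` (integer-rounded),
#'   `predicted_kb_raw`, `observed_kb`, `residual_kb`.
#' @examples
#' predict_chromosome_size(36, 261)$predicted_kb  # 849
#' @export
predict_chromosome_size <- function(deleted_kb, duplicated_kbs = numeric(),
                                    wt_kb = 624, observed_kb = NULL) {
  if (deleted_kb < 0 || any(duplicated_kbs < 0) || wt_kb < 0) {
    stopf("sizes must be non-negative")
  }
  raw <- wt_kb - deleted_kb + sum(duplicated_kbs)
  obs <- if (is.null(observed_kb)) NA_real_ else as.numeric(observed_kb)
  structure(list(wt_kb = wt_kb, deleted_kb = deleted_kb,
                 duplicated_kb_total = sum(duplicated_kbs),
                 predicted_kb = round(raw), predicted_kb_raw = raw,
                 observed_kb = obs, residual_kb = obs - round(raw)),
            class = "size_prediction")
}
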