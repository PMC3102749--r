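#' Simulate Luria-Delbruck fluctuation cultures
#'
#' Grows each culture from `n0` to `n_t` cells by doubling; in each
#' generation, new mutants arise as Poisson(mu x cells grown that
#' generation) and pre-existing mutants double. The resulting mutant-count
#' distribution shows the characteristic jackpot skew (variance/mean >> 1).
#'
#' @param mu Per-cell mutation rate (0 <= mu <= 1).
#' @param n0 Initial cells per culture.
#' @param n_t Final cells per culture (>= n0).
#' @param n_cultures Number of parallel cultures.
#' @param seed Optional RNG seed (restores the caller's RNG state).
#' @return Numeric vector of final mutant counts, one per culture.
#' @examples
#' counts <- simulate_fluctuation_cultures(1e-7, 1e3, 2e8, 24, seed = 1)
#' var(counts) / mean(counts)  # jackpot skew
#' @export
simulate_fluctuation_cultures <- function(mu, n0, n_t, n_cultures,
                                          seed = NULL) {
  if (!is.numeric(mu) || mu < 0 || mu > 1) stopf("`mu` must be in [0, 1]")
  if (n0 > n_t) stopf("`n0` must not exceed `n_t`")
  if (n0 <= 0 || n_cultures < 1) stopf("`n0` and `n_cultures` must be positive")
  with_seed(seed, {
    mutants <- numeric(n_cultures)
    gens <- ceiling(log2(n_t / n0))
    n_prev <- n0
    for (g in seq_len(max(gens, 0L))) {
      n_now <- min(n0 * 2^g, n_t)
      grown <- n_now - n_prev
      mutants <- 2 * mutants + stats::rpois(n_cultures, mu * grown)
      n_prev <- n_now
    }
    mutants
  })
}

#' Simulate a synthetic Ty element pair with diagnostic SNPs
#'
#' Generates two Ty1-like sequences of equal length that differ only at a
#' random set of diagnostic SNP positions. The default architecture mirrors
#' a full-length Ty1: 5,917 bp total with 332 bp terminal repeats flanking
#' the internal epsilon sequence; the SNP density default is one diagnostic
#' site per 150 bp.
#'
#' @param length_bp Total element length.
#' @param ltr_bp Terminal repeat length (recorded, not constrained).
#' @param snp_rate Expected diagnostic SNPs per bp.
#' @param seed Optional RNG seed.
#' @return A list of class `ty_pair`: `seq_a`, `seq_b` (character),
#'   `snp_positions` (sorted 1-based positions where they differ),
#'   `ltr_bp`.
#' @export
simulate_ty_pair <- function(length_bp = 5917, ltr_bp = 332,
                             snp_rate = 1 / 150, seed = NULL) {
  if (length_bp < 2) stopf("`length_bp` must be >= 2")
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    a <- sample(bases, length_bp, replace = TRUE)
    n_snp <- max(1L, stats::rbinom(1, length_bp, snp_rate))
    pos <- sort(sample.int(length_bp, n_snp))
    b <- a
    for (p in pos) b[p] <- sample(setdiff(bases, a[p]), 1)
    structure(list(seq_a = paste(a, collapse = ""),
                   seq_b = paste(b, collapse = ""),
                   snp_positions = pos, ltr_bp = ltr_bp),
              class = "ty_pair")
  })
}

#' Synthesize a chimeric junction sequence from two parents
#'
#' Copies from `seq_a` up to the first crossover position, then alternates
#' parents at each crossover (positions are 1-based: a crossover at c means
#' positions <= c come from the current parent, positions > c from the
#' other). The returned truth records, for each crossover, the flanking
#' diagnostic SNPs, which bound the interval a SNP-attribution analysis
#' can recover.
#'
#' @param pair A [simulate_ty_pair()] result.
#' @param crossovers Sorted crossover positions within the sequence.
#' @return A list of class `junction_truth`: `junction` (character),
#'   `crossovers`, and `flanks` (data.frame with `crossover`, `last_before`,
#'   `first_after`: nearest diagnostic SNPs on either side, NA at the ends).
#' @export
synthesize_junction <- function(pair, crossovers) {
  stopifnot(inherits(pair, "ty_pair"))
  a <- as_dna_chars(pair$seq_a)
  b <- as_dna_chars(pair$seq_b)
  n <- length(a)
  if (length(crossovers)) {
    if (is.unsorted(crossovers, strictly = TRUE)) {
      stopf("`crossovers` must be strictly increasing")
    }
    if (any(crossovers < 1 | crossovers >= n)) {
      stopf("crossover position(s) outside the sequence")
    }
  }
  parents <- list(a, b)
  cur <- 1L
  out <- character(n)
  bounds <- c(0L, as.integer(crossovers), n)
  for (i in seq_len(length(bounds) - 1L)) {
    idx <- (bounds[i] + 1L):bounds[i + 1L]
    out[idx] <- parents[[cur]][idx]
    cur <- 3L - cur
  }
  snp <- pair$snp_positions
  flanks <- if (length(crossovers)) {
    data.frame(
      crossover = crossovers,
      last_before = vapply(crossovers, function(cx) {
        p <- snp[snp <= cx]; if (length(p)) max(p) else NA_integer_
      }, numeric(1)),
      first_after = vapply(crossovers, function(cx) {
        p <- snp[snp > cx]; if (length(p)) min(p) else NA_integer_
      }, numeric(1))
    )
  } else {
    data.frame(crossover = numeric(), last_before = numeric(),
               first_after = numeric())
  }
  structure(list(junction = paste(out, collapse = ""),
                 crossovers = crossovers, flanks = flanks),
            class = "junction_truth")
}

# eligible targets for a simulated rearrangement class, as (cluster, element)
# choices; elements on the ChrV left arm telomeric of the centromere are
# excluded (they lie inside the Ty912-TEL05L deleted region)
eligible_target_clusters <- function(genome, summary_label,
                                     assay_chrom = "ChrV",
                                     assay_element = "Ty912",
                                     types = c("full_Ty1", "solo_delta_Ty1",
                                               "solo_delta_Ty2")) {
  ann <- genome$elements
  clusters <- cluster_elements(ann)
  member <- attr(clusters, "membership")
  m <- match(ann$chrom, genome$map$name)
  on_deleted_arm <- ann$chrom == assay_chrom &
    ann$end <= genome$map$cen_start[m]
  ok_el <- ann$element_type %in% types & !on_deleted_arm &
    ann$id != assay_element
  keep <- vapply(seq_len(nrow(clusters)), function(ci) {
    clusters$orientation_summary[ci] == summary_label &&
      any(ok_el[member == ci])
  }, logical(1))
  list(clusters = clusters[keep, , drop = FALSE], all_clusters = clusters,
       membership = member, eligible_elements = ok_el)
}

# duplication interval on the telomeric side of a boundary locus [s, e)
telomeric_side <- function(chrom, s, e, map) {
  mi <- match(chrom, map$name)
  if (e <= map$cen_start[mi]) c(0, e) else c(s, map$length[mi])
}

#' Simulate a gross chromosomal rearrangement event
#'
#' Draws an event of the requested class on the given genome model and
#' returns its ground truth. Classes follow the aCGH taxonomy:
#' \describe{
#'   \item{I}{terminal deletion of the assay arm healed by de novo telomere
#'     addition; no duplication.}
#'   \item{II}{Ty912-TEL05L deletion plus one duplication from a
#'     telomere-oriented Ty/delta locus to its telomere (monocentric HR).}
#'   \item{III}{as II but the bounding locus is centromere-oriented
#'     (dicentric intermediate resolved by breakage-fusion-bridge).}
#'   \item{IV}{as II but the bounding locus is a mixed-orientation multi-Ty
#'     cluster.}
#'   \item{V}{complex: either a duplication plus an adjacent triplicated
#'     segment between two centromere-oriented Ty loci (BFB-style), or a
#'     two-duplication chain across chromosomes (template-switch-style),
#'     chosen at random.}
#' }
#' Targets are chosen uniformly among eligible loci; loci on the deleted
#' ChrV left arm are never targets.
#'
#' @param genome A genome model, e.g. [fixture_genome()].
#' @param event_class `"I"` to `"V"`.
#' @param seed Optional RNG seed.
#' @param aneuploid_chroms Optional chromosomes made disomic in the truth.
#' @return A list of class `gcr_truth` with `event_class`,
#'   `deleted_segments`, `duplicated_segments` (data.frames with `chrom`,
#'   `start`, `end`, `copy_number`), `junctions` (data.frame `donor`,
#'   `target`), `mechanism`, `aneuploid_chroms`.
#' @export
simulate_gcr_event <- function(genome, event_class = c("II", "I", "III", "IV", "V"),
                               seed = NULL, aneuploid_chroms = character()) {
  event_class <- match.arg(event_class)
  map <- genome$map
  ann <- genome$elements
  assay_chrom <- "ChrV"; assay_element <- "Ty912"
  ty912 <- ann[ann$id == assay_element, ]
  if (nrow(ty912) != 1L) stopf("genome lacks the assay element %s", assay_element)
  seg <- function(chrom, start, end, copy) {
    data.frame(chrom = chrom, start = start, end = end, copy_number = copy,
               stringsAsFactors = FALSE)
  }
  no_seg <- seg(character(), numeric(), numeric(), numeric())
  jn <- function(donor, target) {
    data.frame(donor = donor, target = target, stringsAsFactors = FALSE)
  }
  with_seed(seed, {
    if (event_class == "I") {
      bp <- round(stats::runif(1, 12000, ty912$start - 2000))
      truth <- list(event_class = "I",
                    deleted_segments = seg(assay_chrom, 0, bp, 0),
                    duplicated_segments = no_seg,
                    junctions = jn(character(), character()),
                    mechanism = "de_novo_telomere")
    } else {
      del <- seg(assay_chrom, 0, ty912$end, 0)
      if (event_class %in% c("II", "III", "IV")) {
        label <- c(II = "all_telomeric", III = "all_centromeric",
                   IV = "mixed")[[event_class]]
        tg <- eligible_target_clusters(genome, label)
        if (nrow(tg$clusters) == 0L) {
          stopf("no eligible target locus for class %s", event_class)
        }
        ci <- tg$clusters[sample.int(nrow(tg$clusters), 1L), ]
        dup_rng <- telomeric_side(ci$chrom, ci$start, ci$end, map)
        truth <- list(
          event_class = event_class,
          deleted_segments = del,
          duplicated_segments = seg(ci$chrom, dup_rng[1], dup_rng[2], 2),
          junctions = jn(assay_element, ci$elements),
          mechanism = c(II = "monocentric_HR", III = "dicentric_BFB",
                        IV = "monocentric_HR")[[event_class]])
      } else {
        variant <- sample(c("bfb_triplication", "template_chain"), 1L)
        if (variant == "bfb_triplication") {
          # tandem centromere-oriented loci: amplify between them (copy 3)
          # and duplicate from the outer locus to its telomere (copy 2)
          tg <- eligible_target_clusters(genome, "all_centromeric")
          cl <- tg$clusters
          # pairs of centromere-oriented clusters on one chromosome arm
          pair <- NULL
          for (ch in unique(cl$chrom)) {
            cc <- cl[cl$chrom == ch, ]
            if (nrow(cc) >= 2L) {
              cc <- cc[order(cc$start), ]
              i <- sample.int(nrow(cc) - 1L, 1L)
              pair <- cc[c(i, i + 1L), ]
              break
            }
          }
          if (is.null(pair)) stopf("no eligible tandem locus for class V")
          mi <- match(pair$chrom[1], map$name)
          on_left <- pair$end[2] <= map$cen_start[mi]
          # outer = telomere-proximal cluster; inner = centromere-proximal
          outer <- if (on_left) pair[1, ] else pair[2, ]
          inner <- if (on_left) pair[2, ] else pair[1, ]
          dup_rng <- telomeric_side(outer$chrom, outer$start, outer$end, map)
          trip_rng <- if (on_left) c(outer$end, inner$start)
                      else c(inner$end, outer$start)
          truth <- list(
            event_class = "V",
            deleted_segments = del,
            duplicated_segments = rbind(
              seg(outer$chrom, dup_rng[1], dup_rng[2], 2),
              seg(outer$chrom, trip_rng[1], trip_rng[2], 3)),
            junctions = jn(assay_element, outer$elements),
            mechanism = "dicentric_BFB")
        } else {
          # chain: Ty912 -> telomere-oriented locus, copy to a second locus,
          # switch to a telomere-oriented locus on another chromosome, copy
          # to its telomere
          tg <- eligible_target_clusters(genome, "all_telomeric")
          cl <- tg$all_clusters
          downstream <- function(entry) {
            mi <- match(entry$chrom, map$name)
            on_left <- entry$end <= map$cen_start[mi]
            cl[cl$chrom == entry$chrom &
                 (if (on_left) cl$end < entry$start
                  else cl$start > entry$end), , drop = FALSE]
          }
          viable <- vapply(seq_len(nrow(tg$clusters)), function(i) {
            nrow(downstream(tg$clusters[i, ])) > 0L
          }, logical(1))
          cand <- tg$clusters[viable, , drop = FALSE]
          if (nrow(cand) == 0L) stopf("no eligible chain for class V on this genome")
          entry1 <- cand[sample.int(nrow(cand), 1L), ]
          mi <- match(entry1$chrom, map$name)
          on_left <- entry1$end <= map$cen_start[mi]
          same <- downstream(entry1)
          end2 <- tg$clusters[tg$clusters$chrom != entry1$chrom, , drop = FALSE]
          if (nrow(end2) == 0L) {
            stopf("no eligible chain for class V on this genome")
          }
          exit1 <- same[sample.int(nrow(same), 1L), ]
          entry2 <- end2[sample.int(nrow(end2), 1L), ]
          dup1 <- if (on_left) c(exit1$end, entry1$end)
                  else c(entry1$start, exit1$start)
          dup2 <- telomeric_side(entry2$chrom, entry2$start, entry2$end, map)
          truth <- list(
            event_class = "V",
            deleted_segments = del,
            duplicated_segments = rbind(
              seg(entry1$chrom, dup1[1], dup1[2], 2),
              seg(entry2$chrom, dup2[1], dup2[2], 2)),
            junctions = rbind(jn(assay_element, entry1$elements),
                              jn(exit1$elements, entry2$elements)),
            mechanism = "template_switch")
        }
      }
    }
    truth$aneuploid_chroms <- aneuploid_chroms
    class(truth) <- "gcr_truth"
    truth
  })
}

#' Render a simulated rearrangement as probe-level array signal
#'
#' Tiles each chromosome with probes at fixed spacing and emits, per probe,
#' a log2 copy-number ratio with additive Gaussian noise and a raw
#' intensity proportional to copy number with multiplicative noise.
#' Deleted regions drop to near-background raw intensity
#' (`background_frac` of the per-copy signal). Probes overlapping annotated
#' repeat elements report normal-copy signal regardless of the underlying
#' truth, emulating cross-hybridization of repetitive probes (the "signal
#' spikes" seen inside real deletions).
#'
#' @param truth A [simulate_gcr_event()] result.
#' @param genome Genome model with `map` and `elements`.
#' @param spacing_bp Probe spacing (default 200 bp, the typical median
#'   spacing of a yeast tiling array).
#' @param sigma Gaussian noise SD on the log2 ratio (0 for noiseless).
#' @param seed Optional RNG seed.
#' @param base_intensity Raw intensity of a single-copy probe.
#' @param background_frac Fraction of `base_intensity` reported in deleted
#'   regions.
#' @param chroms Optional subset of chromosomes to render.
#' @return A `data.frame` with `chrom`, `start`, `end`, `log2_ratio`,
#'   `raw_intensity`, sorted and non-overlapping per chromosome.
#' @export
render_probe_signal <- function(truth, genome, spacing_bp = 200, sigma = 0.25,
                                seed = NULL, base_intensity = 1000,
                                background_frac = 0.05, chroms = NULL) {
  if (spacing_bp <= 0) stopf("`spacing_bp` must be > 0")
  if (sigma < 0) stopf("`sigma` must be >= 0")
  map <- genome$map
  if (!is.null(chroms)) map <- map[map$name %in% chroms, , drop = FALSE]
  with_seed(seed, {
    per_chrom <- lapply(seq_len(nrow(map)), function(i) {
      len <- map$length[i]
      nm <- map$name[i]
      starts <- seq(0, len - spacing_bp, by = spacing_bp)
      ends <- starts + spacing_bp
      copy <- rep(if (nm %in% truth$aneuploid_chroms) 2 else 1,
                  length(starts))
      apply_seg <- function(segs) {
        segs <- segs[segs$chrom == nm, , drop = FALSE]
        for (j in seq_len(nrow(segs))) {
          hit <- starts < segs$end[j] & ends > segs$start[j]
          copy[hit] <<- segs$copy_number[j]
        }
      }
      apply_seg(truth$duplicated_segments)
      apply_seg(truth$deleted_segments)
      # repetitive probes cross-hybridize: report normal copy
      el <- genome$elements[genome$elements$chrom == nm, , drop = FALSE]
      in_rep <- rep(FALSE, length(starts))
      for (j in seq_len(nrow(el))) {
        in_rep <- in_rep | (starts < el$end[j] & ends > el$start[j])
      }
      copy[in_rep] <- if (nm %in% truth$aneuploid_chroms) 2 else 1
      eff <- ifelse(copy == 0, background_frac, copy)
      noise <- if (sigma > 0) stats::rnorm(length(starts), 0, sigma) else 0
      data.frame(chrom = nm, start = starts, end = ends,
                 log2_ratio = log2(eff) + noise,
                 raw_intensity = base_intensity * eff * 2^noise,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, per_chrom)
  })
}

#' Write a simulated cohort to disk
#'
#' Convenience emitter used by the pipeline: probes as TSV (BedGraph-like),
#' truth as JSON.
#'
#' @param probes Probe table from [render_probe_signal()].
#' @param truth A `gcr_truth`.
#' @param dir Output directory.
#' @param name Basename for the files.
#' @return Invisibly, the paths written.
#' @export
write_simulated_isolate <- function(probes, truth, dir, name) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  probe_path <- file.path(dir, paste0(name, ".probes.tsv"))
  truth_path <- file.path(dir, paste0(name, ".truth.json"))
  utils::write.table(probes, probe_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(unclass(truth), truth_path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(c(probes = probe_path, truth = truth_path))
}
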