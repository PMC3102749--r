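#' Attribute junction SNPs to parental Ty elements
#'
#' Compares a junction sequence against two parental sequences aligned to a
#' common coordinate frame (equal length; alignment is an upstream step).
#' At every diagnostic position (where the parents differ) the junction
#' base is assigned to parent `A`, parent `B`, or `neither`. Maximal blocks
#' of same-parent assignments are reported, and each transition between an
#' A block and a B block yields a crossover interval `(last, first]` with
#' an exclusive lower and inclusive upper bound, the positions being the
#' nearest informative SNPs flanking the crossover. Runs of more than
#' `neither_run_cap` consecutive `neither` assignments are reported as
#' their own blocks (unattributable stretches); shorter runs are absorbed
#' as noise.
#'
#' @param junction,parent_a,parent_b Sequences (character or
#'   `Biostrings::DNAString`) of equal length in a shared frame.
#' @param neither_run_cap Longest `neither` run absorbed inside a block.
#' @param lower_bracket Bracket used for the interval's lower bound:
#'   `"("` (exclusive, default) or `"["` (inclusive).
#' @return A list of class `junction_attribution`: `positions` (1-based
#'   diagnostic positions), `assignments` (`A`/`B`/`neither`), `blocks`
#'   (data.frame `parent`, `start_pos`, `end_pos`, `n_sites`), `intervals`
#'   (data.frame `lower`, `upper`, `from`, `to`, `notation`),
#'   `n_crossovers`, `neither_blocks`.
#' @examples
#' p <- simulate_ty_pair(seed = 1)
#' j <- synthesize_junction(p, crossovers = 3000)
#' attribute_snps(j$junction, p$seq_a, p$seq_b)$intervals
#' @export
attribute_snps <- function(junction, parent_a, parent_b,
                           neither_run_cap = 3, lower_bracket = c("(", "[")) {
  lower_bracket <- match.arg(lower_bracket)
  j <- as_dna_chars(junction, "junction")
  a <- as_dna_chars(parent_a, "parent_a")
  b <- as_dna_chars(parent_b, "parent_b")
  if (length(j) != length(a) || length(a) != length(b)) {
    stopf("junction and parents must have equal aligned length (got %d, %d, %d)",
          length(j), length(a), length(b))
  }
  pos <- which(a != b)
  if (!length(pos)) stopf("parents are identical: no diagnostic positions")
  assign <- ifelse(j[pos] == a[pos], "A",
                   ifelse(j[pos] == b[pos], "B", "neither"))
  inf_idx <- which(assign != "neither")
  blocks <- data.frame(parent = character(), start_pos = integer(),
                       end_pos = integer(), n_sites = integer(),
                       stringsAsFactors = FALSE)
  if (length(inf_idx)) {
    r <- rle(assign[inf_idx])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    blocks <- data.frame(
      parent = r$values,
      start_pos = pos[inf_idx[starts]],
      end_pos = pos[inf_idx[ends]],
      n_sites = r$lengths,
      stringsAsFactors = FALSE)
  }
  # unattributable stretches longer than the noise cap
  neither_blocks <- data.frame(start_pos = integer(), end_pos = integer(),
                               n_sites = integer())
  ni <- which(assign == "neither")
  if (length(ni)) {
    grp <- cumsum(c(0L, as.integer(diff(ni) > 1L)))
    runs <- split(ni, grp)
    runs <- runs[lengths(runs) > neither_run_cap]
    if (length(runs)) {
      neither_blocks <- data.frame(
        start_pos = vapply(runs, function(r) pos[r[1L]], numeric(1)),
        end_pos = vapply(runs, function(r) pos[r[length(r)]], numeric(1)),
        n_sites = lengths(runs), row.names = NULL)
    }
  }
  intervals <- data.frame(lower = integer(), upper = integer(),
                          from = character(), to = character(),
                          notation = character(), stringsAsFactors = FALSE)
  if (nrow(blocks) > 1L) {
    lower <- blocks$end_pos[-nrow(blocks)]
    upper <- blocks$start_pos[-1L]
    intervals <- data.frame(
      lower = lower, upper = upper,
      from = blocks$parent[-nrow(blocks)],
      to = blocks$parent[-1L],
      notation = sprintf("%s%d, %d]", lower_bracket, lower, upper),
      stringsAsFactors = FALSE)
  }
  structure(list(positions = pos, assignments = assign, blocks = blocks,
                 intervals = intervals, n_crossovers = max(nrow(blocks) - 1L, 0L),
                 neither_blocks = neither_blocks),
            class = "junction_attribution")
}

#' Rank candidate parental Ty elements for a junction
#'
#' Scores each candidate as the fraction of its diagnostic positions
#' (where it differs from `parent_a`) at which the junction departs from
#' `parent_a` and matches the candidate. Exact score ties are reported as
#' an ambiguity set, never broken silently: four candidates with identical
#' sequence will tie at the top.
#'
#' @param junction Junction sequence.
#' @param parent_a The known donor (e.g. the assay Ty element).
#' @param candidates Named list/vector of candidate target sequences, all
#'   in the shared frame.
#' @return A `data.frame` ordered by decreasing score: `candidate`,
#'   `n_diagnostic`, `n_informative`, `n_matched`, `score`, `tied_top`
#'   (logical).
#' @export
rank_candidate_parents <- function(junction, parent_a, candidates) {
  if (length(candidates) == 0L) stopf("need at least one candidate")
  if (is.null(names(candidates))) {
    names(candidates) <- paste0("candidate", seq_along(candidates))
  }
  j <- as_dna_chars(junction, "junction")
  a <- as_dna_chars(parent_a, "parent_a")
  rows <- lapply(names(candidates), function(nm) {
    cc <- as_dna_chars(candidates[[nm]], nm)
    if (length(cc) != length(a)) {
      stopf("candidate %s length differs from the shared frame", nm)
    }
    diag <- which(a != cc)
    inf <- diag[j[diag] != a[diag]]
    matched <- sum(j[inf] == cc[inf])
    data.frame(candidate = nm, n_diagnostic = length(diag),
               n_informative = length(inf), n_matched = matched,
               score = if (length(inf)) matched / length(inf) else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$score, out$candidate), , drop = FALSE]
  out$tied_top <- out$score == max(out$score)
  rownames(out) <- NULL
  out
}

#' Detect a multi-Ty fusion junction
#'
#' A fusion junction containing more than one Ty element is flagged when
#' its physical length exceeds `length_factor` times a full-length element,
#' or when at least `min_het_positions` positions carry two distinct
#' high-confidence bases (heterozygous SNPs from co-amplified tandem
#' elements).
#'
#' @param junction_length Junction length in bp.
#' @param base_calls List of per-position observed base sets (character
#'   vectors), or NULL when only the length criterion applies.
#' @param full_ty_length Full-length element size in bp (> 0).
#' @param length_factor Length multiple that triggers the size criterion.
#' @param min_het_positions Heterozygous positions that trigger the
#'   heterozygosity criterion.
#' @return A list: `multi_ty` (logical), `criteria` (named logical:
#'   `length`, `heterozygosity`), `het_positions` (indices).
#' @export
detect_multi_ty_junction <- function(junction_length, base_calls = NULL,
                                     full_ty_length = 5917,
                                     length_factor = 1.5,
                                     min_het_positions = 5) {
  if (full_ty_length <= 0) stopf("`full_ty_length` must be > 0")
  by_length <- junction_length > length_factor * full_ty_length
  het_pos <- integer()
  if (!is.null(base_calls)) {
    het_pos <- which(vapply(base_calls,
                            function(b) length(unique(toupper(b))) >= 2L,
                            logical(1)))
  }
  by_het <- length(het_pos) >= min_het_positions
  list(multi_ty = by_length || by_het,
       criteria = c(length = by_length, heterozygosity = by_het),
       het_positions = het_pos)
}

#' Find microhomology at a non-repeat fusion junction
#'
#' Given the donor context with its breakpoint (sequence retained up to and
#' including `donor_break`), the acceptor context with its breakpoint
#' (sequence retained after `acceptor_break`), and the fused product,
#' returns the maximal sequence shared at the join: the overlap that is
#' simultaneously a suffix of the retained donor and a prefix of the
#' retained acceptor, consistent with the fused sequence carrying it once.
#' A blunt fusion returns the empty string.
#'
#' @param donor_seq,acceptor_seq Context sequences.
#' @param donor_break Last retained donor position (1-based).
#' @param acceptor_break Last non-retained acceptor position (retained part
#'   starts at `acceptor_break + 1`).
#' @param fused The fused junction sequence.
#' @return A list of class `microhomology_result`: `sequence`, `length`,
#'   `fusion_offset` (last donor-derived position in the fused sequence;
#'   the microhomology occupies the `length` positions ending there).
#' @examples
#' find_microhomology("GATTACACTTC", 11, "AACTTCGGTTA", 2, "GATTACACTTCGGTTA")$sequence
#' @export
find_microhomology <- function(donor_seq, donor_break, acceptor_seq,
                               acceptor_break, fused) {
  d_full <- as_dna_chars(donor_seq, "donor_seq")
  a_full <- as_dna_chars(acceptor_seq, "acceptor_seq")
  f <- as_dna_chars(fused, "fused")
  if (donor_break < 1 || donor_break > length(d_full)) {
    stopf("`donor_break` outside the donor context")
  }
  if (acceptor_break < 0 || acceptor_break >= length(a_full)) {
    stopf("`acceptor_break` outside the acceptor context")
  }
  d <- d_full[seq_len(donor_break)]
  a <- a_full[(acceptor_break + 1L):length(a_full)]
  k <- length(d) + length(a) - length(f)
  if (k < 0 || k > min(length(d), length(a))) {
    stopf("fused sequence length inconsistent with the given breakpoints")
  }
  ok <- identical(f, c(d, if (k < length(a)) a[(k + 1L):length(a)])) &&
    (k == 0L || identical(d[(length(d) - k + 1L):length(d)], a[seq_len(k)]))
  if (!ok) stopf("fused sequence inconsistent with the parental contexts")
  structure(list(sequence = paste(if (k) d[(length(d) - k + 1L):length(d)]
                                  else character(), collapse = ""),
                 length = k, fusion_offset = length(d)),
            class = "microhomology_result")
}

#' Read sequences for junction analysis from FASTA
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_junction_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write a junction attribution report
#'
#' Emits the assignments and crossover intervals (in bracket notation) as
#' TSV, plus the full attribution as JSON.
#'
#' @param attribution A [attribute_snps()] result.
#' @param path_tsv,path_json Output paths (NULL to skip either).
#' @return Invisibly, the attribution.
#' @export
write_attribution_report <- function(attribution, path_tsv = NULL,
                                     path_json = NULL) {
  if (!is.null(path_tsv)) {
    utils::write.table(attribution$intervals, path_tsv, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(path_json)) {
    jsonlite::write_json(unclass(attribution), path_json, auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
  }
  invisible(attribution)
}
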