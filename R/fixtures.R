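#' Bundled genome model
#'
#' A compact six-chromosome genome model used throughout the package's
#' examples, simulations, and tests. It carries chromosome V with the
#' telomere-oriented Ty912 assay element ending at the Xba I site at
#' coordinate 35,997 (so the Ty912-TEL05L deletion is 36 kb), plus the
#' named rearrangement-target loci on chromosomes III, X, XII, XIII, and
#' XVI at plausible coordinates: single telomere-oriented Ty1/delta targets,
#' tandem centromere-oriented Ty1s, and mixed-orientation multi-Ty loci.
#' One locus, the unannotated partial delta near the right telomere of
#' chromosome V, is printed in two coordinate conventions in the source
#' survey data (449,317-449,626 one-based inclusive vs 449,316-449,625);
#' the fixture uses 449,316-449,625 in its native 0-based half-open frame.
#' The full reference S288c repeat table is deliberately not bundled;
#' users can supply their own via [read_repeat_annotation()].
#'
#' @return `fixture_chromosome_map()`: a [chromosome_map()];
#'   `fixture_annotation()`: a [repeat_annotation()];
#'   `fixture_genome()`: a list with components `map`, `elements`.
#' @export
fixture_chromosome_map <- function() {
  chromosome_map(
    name = c("ChrIII", "ChrV", "ChrX", "ChrXII", "ChrXIII", "ChrXVI"),
    length = c(316620, 576874, 745751, 1078177, 924431, 948066),
    cen_start = c(114385, 151987, 436307, 150828, 268031, 555957),
    cen_end = c(114501, 152104, 436425, 150947, 268149, 556073)
  )
}

#' @rdname fixture_chromosome_map
#' @export
fixture_annotation <- function() {
  elements <- data.frame(
    id = c(
      "YELWdelta1", "Ty912", "YERWdelta17", "YERCTy1-1", "YERWdelta20B",
      "YERCdelta14",
      "YCRWdelta10", "YCRWdelta11", "YCRWdelta10B",
      "YJRWTy1-1", "YJRWTy1-2",
      "YLRWTy1-3", "YLRCdelta9", "YLRWTy1-2", "YLRCdelta12",
      "YMLWTy1-1", "YMLWTy1-2",
      "YPRWTy1-3", "YPRCdelta22", "YPRCTy1-4"
    ),
    chrom = c(
      rep("ChrV", 6),
      rep("ChrIII", 3),
      rep("ChrX", 2),
      rep("ChrXII", 4),
      rep("ChrXIII", 2),
      rep("ChrXVI", 3)
    ),
    start = c(
      8000, 30080, 438900, 442900, 449316, 431542,
      151500, 152000, 169203,
      478700, 484800,
      651100, 700950, 701500, 707600,
      184000, 196100,
      857000, 863100, 863600
    ),
    end = c(
      8332, 35997, 439232, 448817, 449625, 431874,
      151832, 152332, 169540,
      484617, 490717,
      657017, 701282, 707417, 707932,
      189917, 202017,
      862917, 863432, 869517
    ),
    strand = c(
      "W", "C", "W", "C", "W", "C",
      "W", "W", "W",
      "W", "W",
      "W", "C", "W", "C",
      "W", "W",
      "W", "C", "C"
    ),
    element_type = c(
      "solo_delta_Ty1", "full_Ty1", "solo_delta_Ty1", "full_Ty1",
      "partial_delta", "solo_delta_Ty1",
      "solo_delta_Ty1", "solo_delta_Ty2", "partial_delta",
      "full_Ty1", "full_Ty1",
      "full_Ty1", "solo_delta_Ty1", "full_Ty1", "solo_delta_Ty1",
      "full_Ty1", "full_Ty1",
      "full_Ty1", "solo_delta_Ty1", "full_Ty1"
    ),
    stringsAsFactors = FALSE
  )
  repeat_annotation(elements, fixture_chromosome_map())
}

#' @rdname fixture_chromosome_map
#' @export
fixture_genome <- function() {
  map <- fixture_chromosome_map()
  list(map = map, elements = fixture_annotation())
}
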