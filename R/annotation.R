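#' Chromosome map
#'
#' A chromosome map records, for every chromosome in the genome model, its
#' length and the centromere interval. All coordinates in this package are
#' 0-based, half-open; GFF3 input/output converts from the 1-based inclusive
#' convention of that format.
#'
#' @param name Character vector of unique chromosome identifiers.
#' @param length Chromosome lengths in bp.
#' @param cen_start,cen_end Centromere interval (0-based, half-open).
#' @return A `data.frame` of class `chromosome_map` with columns
#'   `name`, `length`, `cen_start`, `cen_end`.
#' @examples
#' chromosome_map("ChrV", 576874, 151987, 152104)
#' @export
chromosome_map <- function(name, length, cen_start, cen_end) {
  map <- data.frame(
    name = as.character(name),
    length = as.numeric(length),
    cen_start = as.numeric(cen_start),
    cen_end = as.numeric(cen_end),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(map$name)) stopf("chromosome names must be unique")
  bad <- !(map$cen_start >= 0 & map$cen_start < map$cen_end &
             map$cen_end <= map$length)
  if (any(bad)) {
    stopf("invalid centromere interval for chromosome(s): %s",
          paste(map$name[bad], collapse = ", "))
  }
  class(map) <- c("chromosome_map", "data.frame")
  map
}

#' Read / write a chromosome map as TSV
#'
#' The TSV has columns `name`, `length`, `cen_start`, `cen_end`.
#'
#' @param path File path.
#' @return `read_chromosome_map()` returns a [chromosome_map()];
#'   `write_chromosome_map()` returns `path` invisibly.
#' @export
read_chromosome_map <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#")
  need <- c("name", "length", "cen_start", "cen_end")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stopf("chromosome map %s lacks column(s): %s",
                          path, paste(miss, collapse = ", "))
  chromosome_map(tab$name, tab$length, tab$cen_start, tab$cen_end)
}

#' @param map A [chromosome_map()].
#' @rdname read_chromosome_map
#' @export
write_chromosome_map <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

known_element_types <- c("full_Ty1", "full_Ty2", "solo_delta_Ty1",
                         "solo_delta_Ty2", "partial_delta")

#' Repeat element annotation
#'
#' Builds a validated table of Ty/delta repeat elements with derived
#' arm assignment and arm-relative transcriptional orientation.
#' Full-length Ty elements are expected to be about 5.9 kb and solo delta
#' LTRs about 332 bp; lengths outside the tolerance raise a warning, since
#' they usually indicate a unit mix-up in the input.
#'
#' @param elements A `data.frame` with columns `id`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand` (`W`/`C` or `+`/`-`) and `element_type`
#'   (one of `full_Ty1`, `full_Ty2`, `solo_delta_Ty1`, `solo_delta_Ty2`,
#'   `partial_delta`).
#' @param map A [chromosome_map()].
#' @param full_length_bp,solo_delta_bp Expected sizes for full-length and
#'   solo-delta elements.
#' @param length_tol Relative size tolerance for the length warning.
#' @return A `data.frame` of class `repeat_annotation` with additional
#'   derived columns `arm` (`L`/`R`) and `orientation`
#'   (`telomere_oriented`/`centromere_oriented`).
#' @export
repeat_annotation <- function(elements, map, full_length_bp = 5917,
                              solo_delta_bp = 332, length_tol = 0.25) {
  need <- c("id", "chrom", "start", "end", "strand", "element_type")
  miss <- setdiff(need, names(elements))
  if (length(miss)) stopf("annotation lacks column(s): %s",
                          paste(miss, collapse = ", "))
  ann <- data.frame(
    id = as.character(elements$id),
    chrom = as.character(elements$chrom),
    start = as.numeric(elements$start),
    end = as.numeric(elements$end),
    strand = normalize_strand(elements$strand),
    element_type = as.character(elements$element_type),
    stringsAsFactors = FALSE
  )
  if (any(!ann$element_type %in% known_element_types)) {
    stopf("unknown element_type(s): %s",
          paste(setdiff(ann$element_type, known_element_types), collapse = ", "))
  }
  if (any(ann$start >= ann$end)) {
    stopf("element(s) with start >= end: %s",
          paste(ann$id[ann$start >= ann$end], collapse = ", "))
  }
  bad_chrom <- !ann$chrom %in% map$name
  if (any(bad_chrom)) {
    stopf("element(s) on chromosomes absent from the map: %s",
          paste(ann$id[bad_chrom], collapse = ", "))
  }
  m <- match(ann$chrom, map$name)
  if (any(ann$start < 0 | ann$end > map$length[m])) {
    stopf("element(s) outside chromosome bounds: %s",
          paste(ann$id[ann$start < 0 | ann$end > map$length[m]], collapse = ", "))
  }
  spans_cen <- ann$start < map$cen_end[m] & ann$end > map$cen_start[m]
  if (any(spans_cen)) {
    stopf("element(s) overlap the centromere interval (orientation undefined): %s",
          paste(ann$id[spans_cen], collapse = ", "))
  }
  len <- ann$end - ann$start
  expected <- ifelse(grepl("^full", ann$element_type), full_length_bp,
                     ifelse(grepl("^solo", ann$element_type), solo_delta_bp, NA))
  off <- !is.na(expected) & abs(len - expected) > length_tol * expected
  if (any(off)) {
    warning(sprintf("element length(s) outside tolerance of expected size: %s",
                    paste(ann$id[off], collapse = ", ")), call. = FALSE)
  }
  ann$arm <- ifelse(ann$end <= map$cen_start[m], "L", "R")
  ann$orientation <- classify_orientation(ann, map)
  ann <- ann[order(ann$chrom, ann$start), , drop = FALSE]
  rownames(ann) <- NULL
  class(ann) <- c("repeat_annotation", "data.frame")
  ann
}

#' Arm-relative transcriptional orientation of repeat elements
#'
#' An element is *telomere-oriented* when its transcription points toward the
#' telomere of the arm carrying it, and *centromere-oriented* when it points
#' toward the centromere. On a left arm the Crick strand (`C`) is
#' telomere-oriented and Watson (`W`) centromere-oriented; the rule mirrors on
#' a right arm. Elements overlapping the centromere interval have no defined
#' orientation and raise an error.
#'
#' @param elements A `data.frame` with columns `chrom`, `start`, `end`,
#'   `strand` (one row per element; vectorized).
#' @param map A [chromosome_map()].
#' @return Character vector: `"telomere_oriented"` or `"centromere_oriented"`.
#' @examples
#' map <- chromosome_map("ChrV", 576874, 151987, 152104)
#' el <- data.frame(chrom = "ChrV", start = 30080, end = 35997, strand = "C")
#' classify_orientation(el, map)  # telomere_oriented (left arm, Crick)
#' @export
classify_orientation <- function(elements, map) {
  m <- match(as.character(elements$chrom), map$name)
  if (anyNA(m)) stopf("element chromosome(s) absent from the map")
  strand <- normalize_strand(elements$strand)
  spans <- elements$start < map$cen_end[m] & elements$end > map$cen_start[m]
  if (any(spans)) {
    stopf("orientation undefined for element(s) overlapping the centromere")
  }
  left <- elements$end <= map$cen_start[m]
  # left arm: C -> telomere; right arm: W -> telomere
  tel <- (left & strand == "C") | (!left & strand == "W")
  ifelse(tel, "telomere_oriented", "centromere_oriented")
}

#' Count eligible rearrangement targets
#'
#' Counts annotated repeat elements of the requested types in the requested
#' arm-relative orientation, e.g. the pool of telomere-oriented full-length
#' Ty1 and solo Ty1/Ty2 delta elements eligible to seed a simple
#' telomere-ward nonreciprocal translocation.
#'
#' @param annotation A [repeat_annotation()].
#' @param orientation `"telomere_oriented"` or `"centromere_oriented"`.
#' @param types Element types to include.
#' @return Integer count.
#' @export
count_eligible_targets <- function(annotation, orientation,
                                   types = c("full_Ty1", "solo_delta_Ty1",
                                             "solo_delta_Ty2")) {
  if (!orientation %in% c("telomere_oriented", "centromere_oriented")) {
    stopf("unknown orientation label: %s", orientation)
  }
  if (nrow(annotation) == 0L) return(0L)
  sum(annotation$orientation == orientation & annotation$element_type %in% types)
}

#' Cluster repeat elements into loci
#'
#' Merges same-chromosome elements whose pairwise gaps are at most
#' `window_bp` into maximal chains ("multiple Ty loci"). Each cluster carries
#' an orientation summary: `all_telomeric`, `all_centromeric`, or `mixed`.
#' The default 5 kb window merges tandem loci while keeping distant loci
#' apart.
#'
#' @param annotation A [repeat_annotation()].
#' @param window_bp Maximum inter-element gap within a cluster (> 0).
#' @return A `data.frame` of class `repeat_clusters` with one row per cluster:
#'   `cluster_id`, `chrom`, `start`, `end`, `n_elements`, `elements`
#'   (semicolon-joined ids), `orientation_summary`. The element-to-cluster
#'   assignment is attached as attribute `membership` (integer vector parallel
#'   to the annotation rows, which are assumed sorted by chrom/start).
#' @export
cluster_elements <- function(annotation, window_bp = 5000) {
  if (!is.numeric(window_bp) || window_bp <= 0) stopf("`window_bp` must be > 0")
  ann <- annotation[order(annotation$chrom, annotation$start), , drop = FALSE]
  n <- nrow(ann)
  if (n == 0L) {
    out <- data.frame(cluster_id = integer(), chrom = character(),
                      start = numeric(), end = numeric(),
                      n_elements = integer(), elements = character(),
                      orientation_summary = character(),
                      stringsAsFactors = FALSE)
    class(out) <- c("repeat_clusters", "data.frame")
    attr(out, "membership") <- integer()
    return(out)
  }
  new_chrom <- c(TRUE, ann$chrom[-1] != ann$chrom[-n])
  # gap to previous element on the same chromosome; chains use a running
  # maximum of ends so a long element followed by two short ones merges
  run_end <- ann$end
  member <- integer(n)
  cid <- 0L
  cur_end <- -Inf
  for (i in seq_len(n)) {
    gap <- ann$start[i] - cur_end
    if (new_chrom[i] || gap > window_bp) {
      cid <- cid + 1L
      cur_end <- ann$end[i]
    } else {
      cur_end <- max(cur_end, ann$end[i])
    }
    member[i] <- cid
  }
  summ <- function(orients) {
    if (all(orients == "telomere_oriented")) "all_telomeric"
    else if (all(orients == "centromere_oriented")) "all_centromeric"
    else "mixed"
  }
  idx <- split(seq_len(n), member)
  out <- data.frame(
    cluster_id = as.integer(names(idx)),
    chrom = vapply(idx, function(i) ann$chrom[i[1]], character(1)),
    start = vapply(idx, function(i) min(ann$start[i]), numeric(1)),
    end = vapply(idx, function(i) max(ann$end[i]), numeric(1)),
    n_elements = lengths(idx),
    elements = vapply(idx, function(i) paste(ann$id[i], collapse = ";"),
                      character(1)),
    orientation_summary = vapply(idx, function(i) summ(ann$orientation[i]),
                                 character(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("repeat_clusters", "data.frame")
  attr(out, "membership") <- member
  out
}

# ---- BED6 / GFF3 I/O --------------------------------------------------------

gff3_type_for <- function(element_type) {
  ifelse(grepl("^full", element_type), "LTR_retrotransposon",
         "long_terminal_repeat")
}

annotation_to_granges <- function(annotation) {
  GenomicRanges::GRanges(
    seqnames = annotation$chrom,
    ranges = IRanges::IRanges(start = annotation$start + 1L,
                              end = annotation$end),
    strand = ifelse(annotation$strand == "W", "+", "-"),
    ID = annotation$id,
    element_type = annotation$element_type
  )
}

#' Read / write repeat annotation (BED6 or GFF3)
#'
#' BED6 stores the element id and type packed in the name column as
#' `id|element_type`; GFF3 carries `ID` and `element_type` attributes.
#' Internal coordinates are 0-based half-open; conversion from GFF3's
#' 1-based inclusive convention is handled by the reader/writer.
#'
#' @param path File path; format is inferred from the extension
#'   (`.bed` vs `.gff`/`.gff3`) unless given.
#' @param map A [chromosome_map()].
#' @param format `"auto"`, `"bed"` or `"gff3"`.
#' @param ... Passed to [repeat_annotation()].
#' @return A [repeat_annotation()].
#' @export
read_repeat_annotation <- function(path, map, format = c("auto", "bed", "gff3"),
                                   ...) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  }
  gr <- rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF3")
  mc <- S4Vectors::mcols(gr)
  if (format == "bed") {
    parts <- strsplit(as.character(mc$name), "|", fixed = TRUE)
    id <- vapply(parts, `[`, character(1), 1L)
    type <- vapply(parts, function(p) if (length(p) > 1L) p[2L] else NA_character_,
                   character(1))
    if (anyNA(type)) stopf("BED name field must be 'id|element_type'")
  } else {
    id <- as.character(mc$ID)
    type <- as.character(mc$element_type)
    if (anyNA(type)) stopf("GFF3 records lack an element_type attribute")
  }
  elements <- data.frame(
    id = id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    element_type = type,
    stringsAsFactors = FALSE
  )
  repeat_annotation(elements, map, ...)
}

#' @param annotation A [repeat_annotation()].
#' @rdname read_repeat_annotation
#' @export
write_repeat_annotation <- function(annotation, path,
                                    format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  }
  gr <- annotation_to_granges(annotation)
  if (format == "bed") {
    S4Vectors::mcols(gr)$name <- paste(annotation$id, annotation$element_type,
                                       sep = "|")
    S4Vectors::mcols(gr)$ID <- NULL
    S4Vectors::mcols(gr)$element_type <- NULL
    S4Vectors::mcols(gr)$score <- 0L
    rtracklayer::export(gr, path, format = "BED")
  } else {
    S4Vectors::mcols(gr)$type <- gff3_type_for(annotation$element_type)
    rtracklayer::export(gr, path, format = "GFF3")
  }
  invisible(path)
}

#' Validate an annotation file
#'
#' Checks an annotation table row by row against the structural rules
#' (coordinates ordered and in bounds, known strand and element type,
#' no centromere overlap) and reports violations with their line numbers
#' instead of stopping at the first problem.
#'
#' @param path Path to a BED6 or GFF3 annotation file.
#' @param map A [chromosome_map()].
#' @param format Passed to [read_repeat_annotation()].
#' @return A `data.frame` with columns `line`, `id`, `field`, `message`
#'   (zero rows when the file is clean).
#' @export
validate_annotation_file <- function(path, map, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  }
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  rows <- which(keep)
  issues <- list()
  note <- function(line, id, field, message) {
    issues[[length(issues) + 1L]] <<- data.frame(
      line = line, id = id, field = field, message = message,
      stringsAsFactors = FALSE)
  }
  for (ln in rows) {
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1L]]
    if (format == "bed") {
      if (length(f) < 6L) { note(ln, NA, "record", "fewer than 6 BED fields"); next }
      chrom <- f[1]; start <- suppressWarnings(as.numeric(f[2]))
      end <- suppressWarnings(as.numeric(f[3]))
      nm <- strsplit(f[4], "|", fixed = TRUE)[[1L]]
      id <- nm[1]
      type <- if (length(nm) > 1L) nm[2] else NA_character_
      strand <- f[6]
    } else {
      if (length(f) < 9L) { note(ln, NA, "record", "fewer than 9 GFF3 fields"); next }
      chrom <- f[1]
      start <- suppressWarnings(as.numeric(f[4])) - 1
      end <- suppressWarnings(as.numeric(f[5]))
      strand <- f[7]
      attr_str <- f[9]
      id <- sub(".*ID=([^;]+).*", "\\1", attr_str)
      type <- if (grepl("element_type=", attr_str)) {
        sub(".*element_type=([^;]+).*", "\\1", attr_str)
      } else NA_character_
    }
    if (is.na(start) || is.na(end)) {
      note(ln, id, "coordinates", "non-numeric start/end"); next
    }
    if (start >= end) note(ln, id, "coordinates", "start >= end")
    if (!chrom %in% map$name) {
      note(ln, id, "chrom", sprintf("unknown chromosome '%s'", chrom))
    } else {
      mi <- match(chrom, map$name)
      if (start < 0 || end > map$length[mi]) {
        note(ln, id, "coordinates", "outside chromosome bounds")
      }
      if (start < map$cen_end[mi] && end > map$cen_start[mi]) {
        note(ln, id, "coordinates", "overlaps the centromere interval")
      }
    }
    if (!strand %in% c("+", "-", "W", "C")) {
      note(ln, id, "strand", sprintf("invalid strand '%s'", strand))
    }
    if (is.na(type) || !type %in% known_element_types) {
      note(ln, id, "element_type",
           sprintf("missing or unknown element_type '%s'", type))
    }
  }
  if (length(issues)) do.call(rbind, issues) else {
    data.frame(line = integer(), id = character(), field = character(),
               message = character(), stringsAsFactors = FALSE)
  }
}
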