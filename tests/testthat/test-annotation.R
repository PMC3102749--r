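test_that("chromosome_map validates centromere intervals and unique names", {
  m <- chromosome_map("ChrV", 576874, 151987, 152104)
  expect_s3_class(m, "chromosome_map")
  expect_error(chromosome_map(c("A", "A"), c(10, 10), c(1, 1), c(2, 2)),
               "unique")
  expect_error(chromosome_map("A", 100, 50, 40), "centromere")
  expect_error(chromosome_map("A", 100, 50, 120), "centromere")
})

test_that("orientation follows the arm-relative strand rule in all four quadrants", {
  map <- chromosome_map("Chr", 1000, 450, 550)
  quad <- data.frame(
    chrom = "Chr",
    start = c(100, 100, 700, 700),
    end = c(200, 200, 800, 800),
    strand = c("C", "W", "W", "C")
  )
  expect_equal(classify_orientation(quad, map),
               c("telomere_oriented", "centromere_oriented",
                 "telomere_oriented", "centromere_oriented"))
  # +/- aliases for W/C behave identically
  quad$strand <- c("-", "+", "+", "-")
  expect_equal(classify_orientation(quad, map),
               c("telomere_oriented", "centromere_oriented",
                 "telomere_oriented", "centromere_oriented"))
})

test_that("centromere-spanning elements have no orientation", {
  map <- chromosome_map("Chr", 1000, 450, 550)
  el <- data.frame(chrom = "Chr", start = 400, end = 500, strand = "W")
  expect_error(classify_orientation(el, map), "centromere")
  bad <- data.frame(id = "x", chrom = "Chr", start = 400, end = 500,
                    strand = "W", element_type = "full_Ty1")
  expect_error(repeat_annotation(bad, map), "centromere")
})

test_that("repeat_annotation validates structure and warns on length outliers", {
  map <- fixture_chromosome_map()
  ok <- data.frame(id = "t", chrom = "ChrV", start = 30080, end = 35997,
                   strand = "C", element_type = "full_Ty1")
  ann <- repeat_annotation(ok, map)
  expect_equal(ann$arm, "L")
  expect_equal(ann$orientation, "telomere_oriented")
  expect_error(repeat_annotation(transform(ok, element_type = "Ty9"), map),
               "element_type")
  expect_error(repeat_annotation(transform(ok, end = 30080), map), "start >= end")
  expect_error(repeat_annotation(transform(ok, chrom = "ChrXX"), map), "absent")
  expect_error(repeat_annotation(transform(ok, end = 1e9), map), "bounds")
  short <- data.frame(id = "s", chrom = "ChrV", start = 30080, end = 30580,
                      strand = "C", element_type = "full_Ty1")
  expect_warning(repeat_annotation(short, map), "tolerance")
})

test_that("clustering merges within the window and summarizes orientation", {
  g <- test_genome()
  cl <- cluster_elements(g$elements)
  # tandem ChrX Ty1 pair (gap 183 bp) forms one telomere-oriented cluster
  chrx <- cl[cl$chrom == "ChrX", ]
  expect_equal(nrow(chrx), 1L)
  expect_equal(chrx$n_elements, 2L)
  expect_equal(chrx$orientation_summary, "all_telomeric")
  # the two ChrXIII Ty1s are 6,183 bp apart: beyond the 5 kb window
  expect_equal(nrow(cl[cl$chrom == "ChrXIII", ]), 2L)
  # mixed-orientation chain on ChrXVI
  expect_equal(cl$orientation_summary[cl$chrom == "ChrXVI"], "mixed")
  # membership attribute is parallel to the sorted annotation
  expect_length(attr(cl, "membership"), nrow(g$elements))
})

test_that("clustering matches a transitive-closure oracle on random inputs", {
  map <- chromosome_map(c("c1", "c2"), c(5e5, 5e5), c(2e5, 2e5 + 100),
                       c(2.4e5, 2.4e5 + 100))
  set.seed(11)
  for (rep in 1:20) {
    n <- 12
    chrom <- sample(c("c1", "c2"), n, replace = TRUE)
    start <- numeric(n)
    for (i in seq_len(n)) {
      repeat {
        s <- sample(c(1000:190000, 250000:490000), 1)
        if (s < 190000 || s + 400 < 500000) break
      }
      start[i] <- s
    }
    ann <- repeat_annotation(data.frame(
      id = paste0("e", 1:n), chrom = chrom, start = start, end = start + 332,
      strand = sample(c("W", "C"), n, replace = TRUE),
      element_type = "solo_delta_Ty1"), map)
    got <- cluster_elements(ann, window_bp = 5000)
    got <- got[, c("chrom", "start", "end", "n_elements")]
    class(got) <- "data.frame"
    rownames(got) <- NULL
    want <- oracle_clusters(ann, 5000)
    expect_equal(got, want)
  }
})

test_that("eligible-target counting filters by orientation and type", {
  g <- test_genome()
  tel <- count_eligible_targets(g$elements, "telomere_oriented")
  cen <- count_eligible_targets(g$elements, "centromere_oriented")
  all_types <- count_eligible_targets(
    g$elements, "telomere_oriented",
    types = c("full_Ty1", "full_Ty2", "solo_delta_Ty1", "solo_delta_Ty2",
              "partial_delta"))
  expect_true(all_types >= tel)
  # every orientable element is exactly one of the two orientations
  expect_equal(tel + cen,
               sum(g$elements$element_type %in%
                     c("full_Ty1", "solo_delta_Ty1", "solo_delta_Ty2")))
  expect_error(count_eligible_targets(g$elements, "sideways"), "orientation")
})

test_that("BED and GFF3 round trips preserve the annotation", {
  g <- test_genome()
  for (ext in c("bed", "gff3")) {
    path <- tempfile(fileext = paste0(".", ext))
    write_repeat_annotation(g$elements, path)
    back <- read_repeat_annotation(path, g$map)
    cols <- c("id", "chrom", "start", "end", "strand", "element_type",
              "arm", "orientation")
    expect_equal(as.data.frame(back)[, cols],
                 as.data.frame(g$elements)[, cols], ignore_attr = TRUE)
    unlink(path)
  }
})

test_that("GFF3 output is 1-based inclusive on disk", {
  g <- test_genome()
  path <- tempfile(fileext = ".gff3")
  write_repeat_annotation(g$elements, path)
  lines <- grep("Ty912", readLines(path), value = TRUE)
  f <- strsplit(lines[1], "\t")[[1]]
  expect_equal(as.numeric(f[4]), 30081)  # 0-based 30080 -> 1-based 30081
  expect_equal(as.numeric(f[5]), 35997)
  unlink(path)
})

test_that("validate_annotation_file reports line-level issues without stopping", {
  map <- fixture_chromosome_map()
  path <- tempfile(fileext = ".bed")
  writeLines(c(
    "ChrV\t100\t400\tok|solo_delta_Ty1\t0\t+",
    "ChrV\t500\t400\trev|solo_delta_Ty1\t0\t+",     # start >= end
    "ChrQQ\t100\t400\tnochrom|solo_delta_Ty1\t0\t+", # unknown chromosome
    "ChrV\t100\t400\tbadtype|martian\t0\t+",         # unknown type
    "ChrV\t100\t400\tbadstrand|solo_delta_Ty1\t0\t?" # bad strand
  ), path)
  issues <- validate_annotation_file(path, map)
  expect_setequal(unique(issues$id),
                  c("rev", "nochrom", "badtype", "badstrand"))
  expect_true(any(issues$field == "coordinates"))
  expect_true(any(issues$field == "chrom"))
  expect_true(any(issues$field == "element_type"))
  expect_true(any(issues$field == "strand"))
  unlink(path)
})

test_that("chromosome map TSV round trip", {
  g <- test_genome()
  path <- tempfile(fileext = ".tsv")
  write_chromosome_map(g$map, path)
  back <- read_chromosome_map(path)
  expect_equal(as.data.frame(back), as.data.frame(g$map), ignore_attr = TRUE)
  unlink(path)
})

test_that("bundled genome files load and match the in-code fixtures", {
  map <- read_chromosome_map(
    system.file("extdata", "chromosome_map.tsv", package = "tyGCR"))
  ann <- read_repeat_annotation(
    system.file("extdata", "repeat_annotation.gff3", package = "tyGCR"), map)
  g <- test_genome()
  expect_equal(as.data.frame(map), as.data.frame(g$map), ignore_attr = TRUE)
  expect_equal(as.data.frame(ann), as.data.frame(g$elements),
               ignore_attr = TRUE)
})
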