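# synthetic probe tables built by hand: `probe_track` makes a single
# chromosome of `n` probes at 200 bp spacing with log2 ratio `base` and
# raw intensity 1000, then applies overrides

probe_track <- function(n, chrom = "chrA", base = 0) {
  data.frame(chrom = chrom, start = seq(0, by = 200, length.out = n),
             end = seq(200, by = 200, length.out = n),
             log2_ratio = base, raw_intensity = 1000,
             stringsAsFactors = FALSE)
}

test_that("a clean duplication is called with exact boundaries", {
  pr <- probe_track(500)
  pr$log2_ratio[101:200] <- 1
  seg <- call_duplications(pr)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$start, pr$start[101])
  expect_equal(seg$end, pr$end[200])
  expect_equal(seg$copy_number, 2)
  expect_equal(seg$call, "duplication")
  expect_equal(seg$n_probes, 100L)
})

test_that("triplications are labelled and copy numbers rounded from log2 means", {
  pr <- probe_track(300)
  pr$log2_ratio[51:100] <- log2(3)
  seg <- call_duplications(pr)
  expect_equal(seg$copy_number, 3)
  expect_equal(seg$call, "triplication_or_higher")
})

test_that("short runs below min_probes are not called", {
  pr <- probe_track(200)
  pr$log2_ratio[50:58] <- 1   # 9 probes < default 10
  expect_equal(nrow(call_duplications(pr)), 0L)
  pr$log2_ratio[50:59] <- 1   # 10 probes
  expect_equal(nrow(call_duplications(pr)), 1L)
})

test_that("noise dips shorter than min_gap are absorbed", {
  pr <- probe_track(300)
  pr$log2_ratio[101:200] <- 1
  pr$log2_ratio[150:151] <- 0   # 2-probe dip < min_gap 3
  seg <- call_duplications(pr)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$n_probes, 98L)
  pr$log2_ratio[148:152] <- 0   # 5-probe dip splits the run
  seg2 <- call_duplications(pr)
  expect_equal(nrow(seg2), 2L)
})

test_that("a duplication spanning a masked repeat stays one segment", {
  map <- chromosome_map("chrA", 100000, 90000, 90100)
  ann <- repeat_annotation(data.frame(
    id = "ty", chrom = "chrA", start = 20000, end = 25917, strand = "W",
    element_type = "full_Ty1"), map)
  pr <- probe_track(400)  # 0..80000
  dup <- pr$start >= 10000 & pr$end <= 40000
  pr$log2_ratio[dup] <- 1
  seg <- call_duplications(pr, ann)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$start, 10000)
  expect_equal(seg$end, 40000)
})

test_that("equal-copy pieces separated by real normal-copy probes stay apart", {
  map <- chromosome_map("chrA", 100000, 90000, 90100)
  ann <- repeat_annotation(data.frame(
    id = "ty", chrom = "chrA", start = 20000, end = 25917, strand = "W",
    element_type = "full_Ty1"), map)
  pr <- probe_track(400)
  pr$log2_ratio[pr$start >= 10000 & pr$end <= 19000] <- 1
  pr$log2_ratio[pr$start >= 27000 & pr$end <= 40000] <- 1
  # 10 unmasked normal probes (19000-21000 minus none masked there ->
  # 19000..20000 five probes, plus 25917..27000 five probes) separate them
  seg <- call_duplications(pr, ann)
  expect_equal(nrow(seg), 2L)
})

test_that("adjacent duplication and triplication remain distinct segments", {
  map <- chromosome_map("chrA", 100000, 90000, 90100)
  ann <- repeat_annotation(data.frame(
    id = "ty", chrom = "chrA", start = 40000, end = 45917, strand = "W",
    element_type = "full_Ty1"), map)
  pr <- probe_track(400)
  pr$log2_ratio[pr$end <= 40000] <- 1
  pr$log2_ratio[pr$start >= 45917 & pr$end <= 60000] <- log2(3)
  seg <- call_duplications(pr, ann)
  expect_equal(nrow(seg), 2L)
  expect_equal(sort(seg$copy_number), c(2, 3))
})

test_that("deletions are called from raw intensity with spike absorption", {
  pr <- probe_track(500)
  del <- pr$start < 30000
  pr$raw_intensity[del] <- 50
  pr$log2_ratio[del] <- log2(0.05)
  # an interior cross-hybridization spike of 4 probes
  pr$raw_intensity[60:63] <- 1000
  seg <- call_deletions(pr)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$start, 0)
  expect_equal(seg$end, 30000)
  expect_equal(seg$copy_number, 0)
  # a spike longer than spike_tolerance splits the deletion
  pr$raw_intensity[60:66] <- 1000
  expect_equal(nrow(call_deletions(pr)), 2L)
})

test_that("deletion calls are invariant to global intensity rescaling", {
  pr <- probe_track(500)
  pr$raw_intensity[pr$start < 30000] <- 50
  a <- call_deletions(pr)
  pr$raw_intensity <- pr$raw_intensity * 7.3
  b <- call_deletions(pr)
  expect_equal(a[, c("chrom", "start", "end", "n_probes")],
               b[, c("chrom", "start", "end", "n_probes")])
})

test_that("degenerate deletion input errors", {
  pr <- probe_track(50)
  pr$raw_intensity <- 0
  expect_error(call_deletions(pr), "degenerate")
})

test_that("unsorted probes are rejected", {
  pr <- probe_track(50)
  pr <- pr[rev(seq_len(nrow(pr))), ]
  expect_error(call_duplications(pr), "sorted")
})

test_that("whole-chromosome gains are flagged as aneuploidy", {
  pr <- rbind(probe_track(200, "chrA", base = 1),
              probe_track(200, "chrB", base = 0))
  expect_equal(detect_aneuploidy(pr), "chrA")
  # a 50% elevated chromosome is not aneuploid
  pr2 <- probe_track(200, "chrC", base = 0)
  pr2$log2_ratio[1:100] <- 1
  expect_equal(detect_aneuploidy(rbind(pr, pr2)), "chrA")
})

test_that("boundary anchoring labels telomere, centromere, cluster, unanchored", {
  map <- chromosome_map("chrA", 100000, 50000, 50200)
  ann <- repeat_annotation(data.frame(
    id = c("d1", "d2"), chrom = "chrA", start = c(20000, 21000),
    end = c(20332, 21332), strand = c("C", "W"),
    element_type = "solo_delta_Ty1"), map)
  cl <- cluster_elements(ann)
  segs <- data.frame(
    chrom = "chrA",
    start = c(500, 19000, 40000),
    end = c(21000, 50100, 99000),
    call = "duplication", copy_number = 2, n_probes = 50, mean_log2 = 1,
    stringsAsFactors = FALSE)
  out <- anchor_boundaries(segs, cl, map)
  expect_equal(out$anchor_left, c("telomere", "cluster", "unanchored"))
  expect_equal(out$anchor_right, c("cluster", "centromere", "telomere"))
  expect_equal(out$anchor_right_elements[1], "d1;d2")
  expect_equal(out$anchor_right_orientation[1], "mixed")
  expect_error(anchor_boundaries(transform(segs, chrom = "nope"), cl, map),
               "absent")
})

test_that("segment_isolate recovers a noiseless simulated event end to end", {
  g <- test_genome()
  truth <- simulate_gcr_event(g, "II", seed = 10)
  pr <- render_probe_signal(truth, g, sigma = 0, seed = 10)
  res <- segment_isolate(pr, g$elements, g$map)
  dels <- res$segments[res$segments$call == "deletion", ]
  expect_equal(nrow(dels), 1L)
  expect_equal(dels$chrom, "ChrV")
  expect_equal(dels$anchor_left, "telomere")
  expect_equal(dels$anchor_right, "cluster")
  expect_true(grepl("Ty912", dels$anchor_right_elements))
  dups <- res$segments[res$segments$call == "duplication", ]
  expect_equal(nrow(dups), 1L)
  expect_equal(dups$chrom, truth$duplicated_segments$chrom)
  expect_length(res$aneuploid_chroms, 0L)
})
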