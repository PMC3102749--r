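# helpers building anchored segment rows directly, bypassing segmentation

anchored_seg <- function(chrom, start, end, call, copy, al, ar,
                         al_el = NA, ar_el = NA, al_or = NA, ar_or = NA) {
  data.frame(chrom = chrom, start = start, end = end, call = call,
             copy_number = copy, n_probes = 100L, mean_log2 = log2(max(copy, 0.1)),
             anchor_left = al, anchor_right = ar,
             anchor_left_elements = al_el, anchor_right_elements = ar_el,
             anchor_left_orientation = al_or, anchor_right_orientation = ar_or,
             stringsAsFactors = FALSE)
}

ty912_del <- function() {
  anchored_seg("ChrV", 0, 35997, "deletion", 0, "telomere", "cluster",
               ar_el = "Ty912", ar_or = "all_telomeric")
}

test_that("terminal deletion without amplification is Class I", {
  g <- test_genome()
  del <- anchored_seg("ChrV", 0, 20000, "deletion", 0, "telomere", "unanchored")
  call <- classify_gcr(del, character(), g$map)
  expect_equal(call$class_label, "I")
  call <- infer_mechanism(call, g$map)
  expect_equal(call$mechanism, "de_novo_telomere")
})

test_that("single telomere+cluster amplification maps orientation to class", {
  g <- test_genome()
  cases <- list(
    list(or = "all_telomeric", class = "II", mech = "monocentric_HR"),
    list(or = "all_centromeric", class = "III", mech = "dicentric_BFB"),
    list(or = "mixed", class = "IV", mech = "ambiguous")
  )
  for (cs in cases) {
    amp <- anchored_seg("ChrX", 478700, 745751, "duplication", 2,
                        "cluster", "telomere", al_el = "YJRWTy1-1;YJRWTy1-2",
                        al_or = cs$or)
    call <- classify_gcr(rbind(ty912_del(), amp), character(), g$map)
    expect_equal(call$class_label, cs$class)
    call <- infer_mechanism(call, g$map)
    expect_equal(call$mechanism, cs$mech)
  }
})

test_that("two amplifications or copy number three give Class V", {
  g <- test_genome()
  amp1 <- anchored_seg("ChrXIII", 0, 184000, "duplication", 2,
                       "telomere", "cluster", ar_el = "YMLWTy1-1",
                       ar_or = "all_centromeric")
  amp2 <- anchored_seg("ChrXIII", 189917, 196100, "triplication_or_higher", 3,
                       "cluster", "cluster", al_el = "YMLWTy1-1",
                       ar_el = "YMLWTy1-2", al_or = "all_centromeric",
                       ar_or = "all_centromeric")
  call <- classify_gcr(rbind(ty912_del(), amp1, amp2), character(), g$map)
  expect_equal(call$class_label, "V")
  call <- infer_mechanism(call, g$map)
  expect_equal(call$mechanism, "dicentric_BFB")
  # a single copy-3 segment is also Class V
  call2 <- classify_gcr(rbind(ty912_del(), amp2), character(), g$map)
  expect_equal(call2$class_label, "V")
})

test_that("template-switch chains yield all monocentric-compatible junctions", {
  g <- test_genome()
  # internal duplication between two telomere-oriented clusters on ChrXII-R,
  # then a second duplication to the ChrX telomere
  amp1 <- anchored_seg("ChrXII", 657017, 700950, "duplication", 2,
                       "cluster", "cluster", al_el = "YLRWTy1-3",
                       ar_el = "YLRCdelta9;YLRWTy1-2;YLRCdelta12",
                       al_or = "all_telomeric", ar_or = "mixed")
  amp2 <- anchored_seg("ChrX", 478700, 745751, "duplication", 2,
                       "cluster", "telomere", al_el = "YJRWTy1-1;YJRWTy1-2",
                       al_or = "all_telomeric")
  call <- classify_gcr(rbind(ty912_del(), amp1, amp2), character(), g$map)
  expect_equal(call$class_label, "V")
  call <- infer_mechanism(call, g$map)
  # amp1 is internal on a right arm: its entry anchor is the centromeric
  # (left) boundary, the telomere-oriented YLRWTy1-3 cluster
  expect_equal(call$junction_verdicts$verdict,
               rep("monocentric_compatible", 2))
  expect_equal(call$mechanism, "template_switch")
})

test_that("any dicentric-forming junction forces BFB; mixed entries are ambiguous", {
  g <- test_genome()
  amp_cen <- anchored_seg("ChrXIII", 0, 184000, "duplication", 2,
                          "telomere", "cluster", ar_el = "YMLWTy1-1",
                          ar_or = "all_centromeric")
  amp_tel <- anchored_seg("ChrX", 478700, 745751, "duplication", 2,
                          "cluster", "telomere", al_el = "YJRWTy1-1;YJRWTy1-2",
                          al_or = "all_telomeric")
  call <- classify_gcr(rbind(ty912_del(), amp_cen, amp_tel), character(), g$map)
  call <- infer_mechanism(call, g$map)
  expect_equal(call$mechanism, "dicentric_BFB")
  amp_mix <- anchored_seg("ChrXVI", 857000, 948066, "duplication", 2,
                          "cluster", "telomere",
                          al_el = "YPRWTy1-3;YPRCdelta22;YPRCTy1-4",
                          al_or = "mixed")
  call2 <- classify_gcr(rbind(ty912_del(), amp_tel, amp_mix), character(), g$map)
  call2 <- infer_mechanism(call2, g$map)
  expect_equal(call2$mechanism, "ambiguous")
})

test_that("aneuploid chromosomes are excluded from segment counting", {
  g <- test_genome()
  amp <- anchored_seg("ChrX", 478700, 745751, "duplication", 2,
                      "cluster", "telomere", al_el = "YJRWTy1-1;YJRWTy1-2",
                      al_or = "all_telomeric")
  # a fully duplicated ChrXVI segment would normally push the call to V
  aneu_seg <- anchored_seg("ChrXVI", 0, 948066, "duplication", 2,
                           "telomere", "telomere")
  call <- classify_gcr(rbind(ty912_del(), amp, aneu_seg), "ChrXVI", g$map)
  expect_equal(call$class_label, "II")
  expect_equal(call$aneuploid_chroms, "ChrXVI")
})

test_that("degenerate inputs produce no_call or unclassifiable errors", {
  g <- test_genome()
  # no deletion at all
  amp <- anchored_seg("ChrX", 478700, 745751, "duplication", 2,
                      "cluster", "telomere", al_el = "YJRWTy1-1",
                      al_or = "all_telomeric")
  expect_equal(classify_gcr(amp, character(), g$map)$class_label, "no_call")
  # deletion present but not Ty912-anchored, with amplifications
  del <- anchored_seg("ChrV", 0, 20000, "deletion", 0, "telomere", "unanchored")
  expect_equal(classify_gcr(rbind(del, amp), character(), g$map)$class_label,
               "no_call")
  # both-boundaries-unanchored amplification is an error
  bad <- anchored_seg("ChrX", 500000, 600000, "duplication", 2,
                      "unanchored", "unanchored")
  expect_error(classify_gcr(rbind(ty912_del(), bad), character(), g$map),
               "unclassifiable")
  # single amplification not bounded by telomere + cluster is an error
  half <- anchored_seg("ChrX", 478700, 600000, "duplication", 2,
                       "cluster", "unanchored", al_el = "YJRWTy1-1",
                       al_or = "all_telomeric")
  expect_error(classify_gcr(rbind(ty912_del(), half), character(), g$map),
               "unclassifiable")
  # segments must be anchored first
  expect_error(classify_gcr(ty912_del()[, 1:7], character(), g$map),
               "anchored")
})

test_that("size accounting adds duplicated kb and subtracts deleted kb", {
  sp <- predict_chromosome_size(36, 261)
  expect_equal(sp$predicted_kb, 849)
  expect_equal(predict_chromosome_size(36, 427)$predicted_kb, 1015)
  expect_equal(predict_chromosome_size(36, 128)$predicted_kb, 716)
  # multiple duplications (including a triplicated region counted twice)
  expect_equal(predict_chromosome_size(36, c(184, 6.2, 6.2))$predicted_kb, 784)
  with_obs <- predict_chromosome_size(36, 190, observed_kb = 815)
  expect_equal(with_obs$residual_kb, 815 - 778)
  expect_error(predict_chromosome_size(-1, 10), "non-negative")
})

test_that("a positive size residual is reported as extra-Ty evidence", {
  g <- test_genome()
  amp <- anchored_seg("ChrXIII", 0, 184000, "duplication", 2,
                      "telomere", "cluster", ar_el = "YMLWTy1-1",
                      ar_or = "all_centromeric")
  call <- classify_gcr(rbind(ty912_del(), amp), character(), g$map)
  call <- infer_mechanism(call, g$map, observed_kb = 815)
  expect_false(is.null(call$size_prediction))
  expect_gt(call$size_prediction$residual_kb, 0)
  expect_true(any(grepl("extra Ty", call$evidence)))
})
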