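test_that("the Wza_C segment detector counts covered template positions", {
  # 15 covered positions -> segment present
  expect_true(detect_wza_c_segment(
    make_region(t_start = 326, t_end = 340)))
  # 9 covered positions -> below the 10/34 threshold
  expect_false(detect_wza_c_segment(
    make_region(t_start = 326, t_end = 334)))
  # exactly 10 covered positions -> present (boundary)
  expect_true(detect_wza_c_segment(
    make_region(t_start = 326, t_end = 335)))
  # region outside the segment interval does not count
  expect_false(detect_wza_c_segment(
    make_region(t_start = 100, t_end = 320)))
  # overlapping regions are merged, positions counted once
  split_regions <- rbind(make_region(t_start = 326, t_end = 331),
                         make_region(t_start = 329, t_end = 334))
  expect_false(detect_wza_c_segment(split_regions))  # union = 9 positions
  expect_true(detect_wza_c_segment(
    rbind(split_regions, make_region(t_start = 335, t_end = 335))))
  expect_false(detect_wza_c_segment(empty_fold_regions_fixture()))
})

test_that("exemplar architectures classify to their published classes", {
  expect_equal(classify_evidence("wza_ec"), "CLASS1")
  expect_equal(classify_evidence("kpsd_ec"), "CLASS2B")
  expect_equal(classify_evidence("wzax"), "CLASS3")
  expect_equal(classify_evidence("gfcc_first"), "CLASS2C")
  expect_equal(classify_evidence("slbb_only"), "NOT_OPX")
})

test_that("GfcC-before variants with a Wza_C segment give Class 2D", {
  ev <- exemplar_evidence("gfcc_first")
  ev$regions <- rbind(ev$regions,
                      make_region(q_start = 380, q_end = 420,
                                  t_start = 326, t_end = 359))
  expect_equal(classify_opx(resolve_architecture(ev$hits), ev$regions),
               "CLASS2D")
})

test_that("classification is total, deterministic and hit-order invariant", {
  set.seed(7)
  for (kind in c("wza_ec", "kpsd_ec", "wzax", "gfcc_first")) {
    ev <- exemplar_evidence(kind)
    ref <- classify_opx(resolve_architecture(ev$hits), ev$regions)
    for (i in 1:5) {
      perm_hits <- ev$hits[sample(nrow(ev$hits)), ]
      perm_reg <- ev$regions[sample(nrow(ev$regions)), , drop = FALSE]
      expect_equal(classify_opx(resolve_architecture(perm_hits), perm_reg),
                   ref)
    }
  }
})

test_that("SLBB repeat count never changes the class", {
  for (k in c(1L, 5L, 14L)) {
    hits <- rbind(make_hit("p", "Poly_export", 30, 120),
                  do.call(rbind, lapply(seq_len(k), function(i) {
                    s <- 130L + (i - 1L) * 60L
                    make_hit("p", "SLBB", s, s + 49L)
                  })))
    regions <- make_region("p")
    expect_equal(classify_opx(resolve_architecture(hits), regions), "CLASS3")
    arch <- resolve_architecture(hits)
    expect_equal(arch$slbb_count, k)
  }
})

test_that("adding fold evidence moves proteins between classes monotonically", {
  ev <- exemplar_evidence("wzax")
  arch <- resolve_architecture(ev$hits)
  expect_equal(classify_opx(arch, ev$regions), "CLASS3")
  # adding a qualifying Wza_C region reclassifies Class 3 -> Class 1
  with_wza <- rbind(ev$regions,
                    make_region(q_start = 300, q_end = 340,
                                t_start = 326, t_end = 359))
  expect_equal(classify_opx(arch, with_wza), "CLASS1")
  # adding a GfcC (3P42) region moves Class 3 / Class 1 into the Class 2 family
  with_gfcc <- rbind(ev$regions,
                     make_region(template = "GFCC_3P42", q_start = 200,
                                 q_end = 350, t_start = 10, t_end = 160))
  expect_equal(classify_opx(arch, with_gfcc), "CLASS2A")
  expect_equal(classify_opx(arch, rbind(with_wza[-1, ], with_gfcc[-1, ])),
               "CLASS2B")
  # a short 3P42 region (< 30 aa on the query) is not GfcC evidence
  short <- rbind(ev$regions,
                 make_region(template = "GFCC_3P42", q_start = 200,
                             q_end = 220, t_start = 10, t_end = 30))
  expect_equal(classify_opx(arch, short), "CLASS3")
})

test_that("summaries report counts, proportions, lower medians and SPII fractions", {
  classified <- data.frame(
    protein_id = sprintf("p%d", 1:7),
    class = c("CLASS1", "CLASS1", "CLASS1", "CLASS3", "CLASS3",
              "CLASS3", "NOT_OPX"),
    length_aa = c(100L, 200L, 300L, 250L, 260L, 270L, 999L),
    signal_label = c("SPII", "SPII", "SPI", "SPII", "none", "none", "SPI"),
    stringsAsFactors = FALSE)
  s <- summarize_classes(classified)
  expect_equal(s$count[s$class == "CLASS1"], 3L)
  expect_equal(s$median_length_aa[s$class == "CLASS1"], 200)
  expect_equal(s$proportion[s$class == "CLASS1"], 0.5)
  expect_equal(s$spii_fraction[s$class == "CLASS1"], 2 / 3)
  expect_equal(sum(s$proportion), 1, tolerance = 1e-9)
  # lower median for an even count
  even <- classified[classified$class == "CLASS1", ]
  even$length_aa <- c(100L, 200L, 300L)
  even <- rbind(even, transform(even[1, ], length_aa = 400L))
  expect_equal(summarize_classes(even)$median_length_aa[1], 200)
  # all NOT_OPX: zero proportions, no division error
  s0 <- summarize_classes(data.frame(class = rep("NOT_OPX", 3),
                                     length_aa = 1:3,
                                     signal_label = "SPI"))
  expect_equal(sum(s0$count), 0L)
  expect_equal(sum(s0$proportion), 0)
})
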