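test_that("expand_segments honors anchors, flanks and chromosome borders", {
  g <- genome("g", c(chr1 = 12))
  e <- expand_segments(segment_track("chr1", 5, 10), 3, 3, "segment", g)
  expect_equal(c(e$elements$start, e$elements$end), c(2, 12))

  m <- expand_segments(segment_track("chr1", 5, 10), 0, 1, "mid", g)
  expect_equal(c(m$elements$start, m$elements$end), c(7, 8))

  s <- expand_segments(segment_track("chr1", 0, 4), 10, 0, "segment", g)
  expect_equal(c(s$elements$start, s$elements$end), c(0, 4))

  expect_error(expand_segments(point_track("chr1", 5), 0, 0, "start", g),
               class = "invalid_parameter_error")
  expect_error(expand_segments(point_track("chr1", 5), 1, 1, "segment", g),
               class = "type_error")
  # stranded opt-in swaps the flanks on minus elements
  tr <- segment_track("chr1", c(4, 4), c(6, 6), strand = c("+", "-"))
  es <- expand_segments(tr, 2, 0, "segment", g, stranded = TRUE)
  expect_equal(es$elements$start, c(2, 4))
  expect_equal(es$elements$end, c(6, 8))
})

test_that("expand with zero flanks is the identity up to merging", {
  g <- toy_genome(2000)
  tr <- random_track(g, "S", n = 30, seed = 5)
  e <- expand_segments(tr, 0, 0, "segment", g, merge = TRUE)
  m <- merge_overlaps(tr)
  expect_equal(e$elements[c("start", "end")], m$elements[c("start", "end")])
})

test_that("extract_points uses the half-open end convention", {
  tr <- segment_track("chr1", c(5, 5), c(10, 6))
  expect_equal(extract_points(tr, "start")$elements$start, c(5, 5))
  expect_equal(extract_points(tr, "end")$elements$start, c(5, 9))
  expect_equal(extract_points(segment_track("chr1", 5, 6), "mid")$elements$start, 5)
})

test_that("case-control merge conserves elements and splits back exactly", {
  ca <- point_track("chr1", c(1, 5))
  co <- point_track("chr1", 3)
  m <- merge_case_control(ca, co)
  expect_equal(m$type, "VP")
  expect_equal(m$value_kind, "case_control")
  expect_equal(m$elements$start, c(1, 3, 5))
  expect_equal(m$elements$value, c("case", "control", "case"))

  m2 <- merge_case_control(point_track(character(0), numeric(0)),
                           point_track("chr1", 2))
  expect_equal(m2$elements$value, "control")

  # identical segments from both sources are both retained
  seg <- segment_track("chr1", 10, 20)
  ms <- merge_case_control(seg, seg)
  expect_equal(nrow(ms$elements), 2L)
  expect_setequal(ms$elements$value, c("case", "control"))

  expect_error(merge_case_control(point_track("chr1", 1),
                                  segment_track("chr1", 0, 5)),
               class = "type_error")

  g <- toy_genome(5000)
  for (tt in c("P", "S")) {
    a <- random_track(g, tt, 15, seed = 11)
    b <- random_track(g, tt, 9, seed = 12)
    sp <- split_by_label(merge_case_control(a, b))
    expect_equal(sp$case$elements[c("chrom", "start", "end")],
                 a$elements[c("chrom", "start", "end")])
    expect_equal(sp$control$elements[c("chrom", "start", "end")],
                 b$elements[c("chrom", "start", "end")])
  }
})

test_that("categorical merge labels by source and conserves counts", {
  m <- merge_categorical(list(segment_track("chr1", 0, 5),
                              segment_track("chr1", 5, 9)),
                         c("exon", "intron"))
  expect_equal(m$type, "VS")
  expect_setequal(unique(m$elements$value), c("exon", "intron"))

  one <- merge_categorical(list(point_track("chr1", c(2, 4))), "only")
  expect_equal(one$elements$start, c(2, 4))
  expect_equal(unique(one$elements$value), "only")

  empty <- merge_categorical(rep(list(point_track(character(0), numeric(0))), 3),
                             c("a", "b", "c"))
  expect_equal(n_elements(empty), 0L)

  expect_error(merge_categorical(list(point_track("chr1", 1)), c("a", "b")),
               class = "invalid_parameter_error")
})

test_that("distance_to_nearest matches hand profiles and is 1-Lipschitz", {
  g5 <- genome("g", c(chr1 = 5))
  expect_equal(distance_to_nearest(point_track("chr1", 2), g5)$values[[1]],
               c(2, 1, 0, 1, 2))
  expect_equal(distance_to_nearest(segment_track("chr1", 1, 3), g5)$values[[1]],
               c(1, 0, 0, 1, 2))
  expect_equal(distance_to_nearest(point_track("chr1", c(0, 4)), g5)$values[[1]],
               c(0, 1, 2, 1, 0))
  # empty chromosome left uncovered
  g2 <- genome("g", c(chr1 = 5, chr2 = 5))
  d <- distance_to_nearest(point_track("chr1", 2), g2)
  expect_false("chr2" %in% d$elements$chrom)

  g <- toy_genome(800)
  for (s in 1:5) {
    tr <- random_track(g, "S", n = 8, seed = s)
    v <- distance_to_nearest(tr, g)$values[[1]]
    expect_lte(max(abs(diff(v))), 1)
    expect_true(all(v >= 0))
  }
})

test_that("merge_overlaps unions book-ended and overlapping segments", {
  expect_equal(merge_overlaps(segment_track("chr1", c(0, 3), c(5, 8)))$elements$end, 8)
  expect_equal(merge_overlaps(segment_track("chr1", c(0, 5), c(5, 8)))$elements$end, 8)
  dis <- segment_track("chr1", c(0, 10), c(5, 15))
  expect_equal(nrow(merge_overlaps(dis)$elements), 2L)

  skip_if_not_installed("IRanges")
  g <- toy_genome(2000)
  for (s in 1:6) {
    tr <- random_track(g, "S", n = 25, seed = s)
    m <- merge_overlaps(tr)
    expect_equal(sum(m$elements$end - m$elements$start),
                 ir_union_bp(tr$elements$start, tr$elements$end))
    expect_false(m$overlaps_allowed)
  }
})

test_that("intensity tracks estimate target density within confounder strata", {
  g <- toy_genome(1000)
  bins <- bin_set("chr1", 0, 1000)
  targ <- point_track("chr1", c(10, 50, 100, 200, 400))

  const <- function_track("chr1", 0, rep(2, 1000))
  it <- suppressWarnings(make_intensity_track(targ, list(const), g, bins))
  expect_equal(it$track$values[[1]], rep(1 / 1000, 1000))
  expect_warning(make_intensity_track(targ, list(const), g, bins),
                 "constant")

  left <- function_track("chr1", 0, rep(c(1, 0), each = 500))
  it2 <- make_intensity_track(targ, list(left), g, bins)
  w <- it2$track$values[[1]]
  expect_equal(sum(w[501:1000]), 0)       # no target mass in the right half
  expect_equal(sum(w), 1)
  expect_true(all(w >= 0))

  # per-bin normalization with several bins
  bins4 <- make_bins(g, 250)
  it3 <- make_intensity_track(targ, list(left), g, bins4)
  wv <- f_values <- trackstat:::f_values_on_bins(it3$track, bins4)
  for (v in wv) expect_equal(sum(v, na.rm = TRUE), 1, tolerance = 1e-9)

  expect_error(make_intensity_track(targ, list(), g, bins),
               class = "invalid_parameter_error")
  expect_error(make_intensity_track(point_track(character(0), numeric(0)),
                                    list(const), g, bins),
               class = "invalid_parameter_error")
})

test_that("kmer_track finds overlapping and reverse-complement matches", {
  expect_equal(kmer_track(c(chr1 = "ACGTACGT"), "ACGT")$elements$start, c(0, 4))
  expect_equal(kmer_track(c(chr1 = "AAAA"), "AA")$elements$start, c(0, 1, 2))
  # palindromic complement deduplicates (hand enumeration: fwd CG at 1,
  # revcomp(CG) = CG so both strands hit the same position)
  expect_equal(kmer_track(c(chr1 = "ACGT"), "CG", both_strands = TRUE)$elements$start, 1)
  # non-palindromic: AC fwd at 0; revcomp GT at 2
  expect_equal(kmer_track(c(chr1 = "ACGT"), "AC", both_strands = TRUE)$elements$start,
               c(0, 2))
  expect_equal(kmer_track(c(chr1 = "acgt"), "ACGT")$elements$start, 0)
  expect_error(kmer_track(c(chr1 = "ACGT"), "ACN"),
               class = "invalid_parameter_error")
})

test_that("gc_window_track computes truncated centered windows over defined bases", {
  expect_equal(gc_window_track(c(chr1 = "GGCC"), 1)$values[[1]], rep(1, 4))
  expect_equal(gc_window_track(c(chr1 = "ATGC"), 3)$values[[1]],
               c(0, 1 / 3, 2 / 3, 1))
  expect_equal(n_elements(gc_window_track(c(chr1 = "NNNN"), 3)), 0L)
  # N bases drop out of the denominator
  expect_equal(gc_window_track(c(chr1 = "GNA"), 3)$values[[1]],
               c(1, 0.5, 0))
  expect_error(gc_window_track(c(chr1 = "ACGT"), 2),
               class = "invalid_parameter_error")
})

test_that("sequence tracks read FASTA input", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">chr1 some description", "ACGTACGT", ">chr2", "GGGG"), fa)
  k <- kmer_track(fa, "ACGT")
  expect_equal(k$elements$chrom, c("chr1", "chr1"))
  expect_equal(k$elements$start, c(0, 4))
  gc <- gc_window_track(fa, 1)
  expect_equal(gc$values[[2]], rep(1, 4))
})
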