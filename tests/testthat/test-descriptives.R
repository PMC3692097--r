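test_that("point statistics: counts, frequency and within-bin gaps", {
  b <- bin_set("chr1", 0, 20)
  r <- point_stats(point_track("chr1", c(3, 7, 12)), b)
  expect_equal(r$per_bin$count, 3)
  expect_equal(r$per_bin$frequency, 0.15)
  expect_equal(r$per_bin$gap_mean, 4.5)
  expect_equal(r$per_bin$gap_var, 0.5)

  e <- point_stats(point_track(character(0), numeric(0)), b)
  expect_equal(e$per_bin$count, 0)
  expect_equal(e$per_bin$frequency, 0)
  expect_false(e$per_bin$defined)       # gap stats undefined

  # no cross-bin gaps
  b2 <- bin_set(data.frame(chrom = "chr1", start = c(0, 5), end = c(5, 15)))
  r2 <- point_stats(point_track("chr1", c(0, 10)), b2)
  expect_true(all(is.na(r2$per_bin$gap_mean)))
  expect_equal(r2$global$count, 2)
})

test_that("frequency proportion handles empty combinations", {
  b <- bin_set("chr1", 0, 100)
  expect_equal(frequency_proportion(point_track("chr1", c(1, 2, 3)),
                                    point_track("chr1", 9), b)$per_bin$proportion,
               0.75)
  expect_equal(frequency_proportion(point_track(character(0), numeric(0)),
                                    point_track("chr1", 1:5), b)$per_bin$proportion,
               0)
  r <- frequency_proportion(point_track(character(0), numeric(0)),
                            point_track(character(0), numeric(0)), b)
  expect_false(r$per_bin$defined)
})

test_that("nearest distances follow the touch-is-zero gap convention", {
  b <- bin_set("chr1", 0, 100)
  expect_equal(nearest_distances(point_track("chr1", 10),
                                 point_track("chr1", c(0, 25)), b)$per_bin$mean, 10)
  expect_equal(nearest_distances(point_track("chr1", 5),
                                 segment_track("chr1", 3, 8), b)$per_bin$mean, 0)
  expect_equal(nearest_distances(segment_track("chr1", 0, 4),
                                 segment_track("chr1", 6, 9), b)$per_bin$mean, 2)
  r <- nearest_distances(point_track("chr1", 5),
                         point_track(character(0), numeric(0)), b)
  expect_false(r$per_bin$defined)
})

test_that("points in segments respect the half-open containment rule", {
  b <- bin_set("chr1", 0, 100)
  r <- points_in_segments(point_track("chr1", c(1, 5, 12)),
                          segment_track("chr1", 0, 6), b)
  expect_equal(r$per_bin$n_inside, 2)
  expect_equal(r$per_bin$n_outside, 1)
  expect_equal(r$per_bin$prop_inside, 2 / 3)
  # p == end is outside
  r2 <- points_in_segments(point_track("chr1", 6), segment_track("chr1", 0, 6), b)
  expect_equal(r2$per_bin$n_inside, 0)
  r3 <- points_in_segments(point_track("chr1", c(2, 9)),
                           segment_track(character(0), numeric(0), numeric(0)), b)
  expect_equal(r3$per_bin$n_outside, 2)
  # inside + outside == total, always
  g <- toy_genome(2000)
  for (s in 1:5) {
    p <- random_track(g, "P", 30, seed = s)
    seg <- random_track(g, "S", 10, seed = s + 50)
    r <- points_in_segments(p, seg, make_bins(g, 500))
    expect_equal(r$per_bin$n_inside + r$per_bin$n_outside,
                 point_stats(p, make_bins(g, 500))$per_bin$count)
  }
})

test_that("relative positions average over contained points only", {
  expect_equal(relative_positions(point_track("chr1", 25),
                                  segment_track("chr1", 20, 30))$global$mean, 0.5)
  expect_equal(relative_positions(point_track("chr1", 20),
                                  segment_track("chr1", 20, 30))$global$mean, 0.0)
  expect_equal(relative_positions(point_track("chr1", c(21, 29)),
                                  segment_track("chr1", 20, 30))$global$mean, 0.5)
  r <- relative_positions(point_track("chr1", 50),
                          segment_track("chr1", 0, 10))
  expect_equal(r$global$n, 0)
  expect_true(is.na(r$global$mean))
})

test_that("coverage uses clipped union; lengths use raw segments", {
  b <- bin_set("chr1", 0, 100)
  r <- coverage_stats(segment_track("chr1", c(0, 20), c(10, 25)), b)
  expect_equal(r$per_bin$covered_bp, 15)
  expect_equal(r$per_bin$prop_covered, 0.15)
  expect_equal(r$per_bin$mean_length, 7.5)
  expect_equal(coverage_stats(segment_track("chr1", c(0, 3), c(5, 8)),
                              b)$per_bin$covered_bp, 8)
  e <- coverage_stats(segment_track(character(0), numeric(0), numeric(0)), b)
  expect_equal(e$per_bin$covered_bp, 0)
  expect_true(is.na(e$per_bin$mean_length))
})

test_that("enrichment is observed over expected-under-independence", {
  expect_equal(overlap_and_enrichment(segment_track("chr1", 0, 10),
                                      segment_track("chr1", 5, 15),
                                      bin_set("chr1", 0, 20))$per_bin$enrichment, 1)
  r <- overlap_and_enrichment(segment_track("chr1", 0, 10),
                              segment_track("chr1", 0, 10),
                              bin_set("chr1", 0, 100))
  expect_equal(r$per_bin$enrichment, 10)      # identity: L / c1
  expect_equal(overlap_and_enrichment(segment_track("chr1", 0, 10),
                                      segment_track("chr1", 50, 60),
                                      bin_set("chr1", 0, 100))$per_bin$enrichment, 0)
  u <- overlap_and_enrichment(segment_track("chr1", 0, 10),
                              segment_track(character(0), numeric(0), numeric(0)),
                              bin_set("chr1", 0, 100))
  expect_false(u$per_bin$defined)
})

test_that("global additive statistics equal the sum of per-bin values", {
  g <- toy_genome(3000)
  bins <- make_bins(g, 700)
  p <- random_track(g, "P", 40, seed = 3)
  ps <- point_stats(p, bins)
  expect_equal(ps$global$count, sum(ps$per_bin$count))
  s <- random_track(g, "S", 15, seed = 4)
  cs <- coverage_stats(s, bins)
  expect_equal(cs$global$covered_bp, sum(cs$per_bin$covered_bp))
  f <- random_track(g, "F", 10, seed = 5)
  fs <- function_stats(f, bins)
  expect_equal(fs$global$sum, sum(fs$per_bin$sum, na.rm = TRUE))
})

test_that("function statistics over defined bp", {
  b <- bin_set("chr1", 0, 100)
  r <- function_stats(function_track("chr1", 0, c(1, 2, 3)), b)
  expect_equal(unlist(r$global[c("mean", "sum", "var", "min", "max")]),
               c(mean = 2, sum = 6, var = 1, min = 1, max = 3))
  expect_equal(function_stats(function_track("chr1", 0, rep(4, 9)),
                              b)$global$var, 0)
  one <- function_stats(function_track("chr1", 0, 5), b)
  expect_true(is.na(one$global$var))
})

test_that("values at positions split inside/outside and skip undefined", {
  b <- bin_set("chr1", 0, 4)
  f <- function_track("chr1", 0, c(1, 1, 2, 2))
  r <- values_at_positions(f, segment_track("chr1", 0, 2), b)
  expect_equal(r$global$mean_inside, 1)
  expect_equal(r$global$mean_outside, 2)
  rp <- values_at_positions(f, point_track("chr1", c(0, 3)), b)
  expect_equal(rp$global$mean_at_points, 1.5)
  # segment covering everything: outside undefined
  ra <- values_at_positions(f, segment_track("chr1", 0, 4), b)
  expect_true(is.na(ra$global$mean_outside))
  # undefined F positions are skipped and tallied
  f2 <- function_track("chr1", 0, c(1, NA, 3))
  rs <- values_at_positions(f2, point_track("chr1", c(0, 1, 2)),
                            bin_set("chr1", 0, 3))
  expect_equal(rs$global$n_skipped, 1)
  expect_equal(rs$global$mean_at_points, 2)
})

test_that("pearson correlation agrees with the closed form", {
  b <- bin_set("chr1", 0, 3)
  expect_equal(pearson_correlation(function_track("chr1", 0, c(1, 2, 3)),
                                   function_track("chr1", 0, c(1, 2, 3)),
                                   b)$global$r, 1)
  expect_equal(pearson_correlation(function_track("chr1", 0, c(1, 2, 3)),
                                   function_track("chr1", 0, -c(1, 2, 3)),
                                   b)$global$r, -1)
  expect_equal(pearson_correlation(function_track("chr1", 0, c(1, 2, 3)),
                                   function_track("chr1", 0, c(1, 3, 2)),
                                   b)$global$r, 0.5)
  cst <- pearson_correlation(function_track("chr1", 0, rep(1, 3)),
                             function_track("chr1", 0, c(1, 3, 2)), b)
  expect_false(cst$per_bin$defined)

  # brute-force closed form on random <= 10 bp instances
  closed_r <- function(x, y) {
    n <- length(x)
    (n * sum(x * y) - sum(x) * sum(y)) /
      sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  }
  set.seed(42)
  for (i in 1:10) {
    n <- sample(3:10, 1)
    x <- round(rnorm(n), 3); y <- round(rnorm(n), 3)
    r <- pearson_correlation(function_track("chr1", 0, x),
                             function_track("chr1", 0, y),
                             bin_set("chr1", 0, n))
    expect_equal(r$global$r, closed_r(x, y), tolerance = 1e-12)
  }
})

test_that("value distributions restrict to containing segments", {
  b <- bin_set("chr1", 0, 100)
  vp <- point_track("chr1", c(1, 5), value = c(0.1, 0.9))
  r <- value_distributions(vp, segment_track("chr1", 0, 3), b)
  expect_equal(r$values_inside, 0.1)
  r2 <- value_distributions(vp, NULL, b)
  expect_equal(sort(r2$values), c(0.1, 0.9))
  r3 <- value_distributions(point_track(character(0), numeric(0),
                                        value = numeric(0),
                                        value_kind = "number"), NULL, b)
  expect_equal(r3$global$n, 0)
})

test_that("case/control and categorical tables count as declared", {
  seg <- segment_track("chr1", c(0, 5), c(5, 10), value = c("case", "control"))
  r <- case_control_tables(seg, point_track("chr1", c(1, 2, 7)))
  expect_equal(unname(r$table[1, ]), c(2, 1))

  r2 <- case_control_tables(seg, point_track("chr1", c(1, 7),
                                             value = c("case", "control")))
  expect_equal(unname(r2$table), matrix(c(1, 0, 0, 1), 2))

  cat1 <- segment_track("chr1", c(0, 10), c(5, 20),
                        value = c("exon", "intron"), value_kind = "category")
  r3 <- case_control_tables(cat1)
  expect_equal(unname(r3$table["count", ]), c(1, 1))
  expect_equal(unname(r3$table["covered_bp", ]), c(5, 10))

  pts <- point_track("chr1", c(1, 2), value = c("A", "A"),
                     value_kind = "category")
  r4 <- case_control_tables(cat1, pts)
  expect_equal(unname(r4$table["A", "exon"]), 2)
  expect_equal(unname(r4$table["A", "intron"]), 0)

  # a point inside overlapping segments of two labels counts once per label
  ov <- segment_track("chr1", c(0, 2), c(6, 8), value = c("case", "control"))
  r5 <- case_control_tables(ov, point_track("chr1", 4))
  expect_equal(unname(r5$table[1, ]), c(1, 1))
  expect_equal(r5$global$multi_label_points, 1)
})
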