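# Shared fixtures: tiny genomes, random-track helpers and independent
# oracles used across the suite.

toy_genome <- function(len = 1000, chroms = 1) {
  lens <- rep(len, chroms)
  names(lens) <- paste0("chr", seq_len(chroms))
  genome("toy", lens)
}

# Random track of any of the five types, valid on `g` by construction.
random_track <- function(g, type = "P", n = 10, seed = 1, value_kind = "number") {
  vd <- switch(value_kind,
    number = function(n) round(stats::rnorm(n), 3),
    case_control = function(n) sample(c("case", "control"), n, replace = TRUE),
    category = function(n) sample(c("exon", "intron", "utr"), n,
                                  replace = TRUE))
  simulate_track(g, n, type, length_dist = function(k) 3 + stats::rgeom(k, 0.2),
                 clustering = 0.3, value_dist = if (type %in% c("VP", "VS")) vd,
                 seed = seed)
}

# IRanges-backed oracles (independent route for the interval primitives).
ir_of <- function(start, end) IRanges::IRanges(start = start + 1, end = end)

ir_union_bp <- function(start, end) {
  sum(IRanges::width(IRanges::reduce(ir_of(start, end))))
}

ir_intersect_bp <- function(s1, e1, s2, e2) {
  sum(IRanges::width(IRanges::intersect(IRanges::reduce(ir_of(s1, e1)),
                                        IRanges::reduce(ir_of(s2, e2)))))
}

# Exact null distribution of a statistic for a single movable element on a
# tiny genome, by full enumeration of placements.
enumerate_point_placements <- function(L) seq(0, L - 1)

enumerate_segment_placements <- function(L, len) seq(0, L - len)

# Per-bin element slice (tests recompute conservation properties with it)
slice_bin <- function(track, bins, i) {
  el <- track$elements
  el[el$chrom == bins$chrom[i] & el$start >= bins$start[i] &
       el$start < bins$end[i], , drop = FALSE]
}

expect_valid <- function(track, g) {
  expect_identical(validate_track(track, g), character(0))
}
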