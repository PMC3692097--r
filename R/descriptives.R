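# Descriptive statistics ------------------------------------------------------
#
# Every operation reports per-bin values plus a global summary; bins where a
# statistic is undefined are flagged, never dropped. Conventions: frequency
# is points per bp of bin; gaps are within-bin only; coverage of overlapping
# segments counts union bp while length statistics use raw segments (each
# assigned to the bin containing its start); variance is the unbiased (n-1)
# estimator throughout.

new_stat_result <- function(statistic, per_bin, global, params = list()) {
  structure(list(statistic = statistic, per_bin = per_bin, global = global,
                 params = params),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result '%s': %d bin(s)>\nglobal:\n", x$statistic,
              nrow(x$per_bin)))
  g <- x$global[vapply(x$global, function(v) is.numeric(v) &&
                         length(v) == 1L, TRUE)]
  for (nm in names(g)) cat(sprintf("  %s = %g\n", nm, g[[nm]]))
  invisible(x)
}

bin_frame <- function(bins) {
  data.frame(chrom = bins$chrom, start = bins$start, end = bins$end,
             stringsAsFactors = FALSE)
}

# rows of el whose start lies in bin i
rows_in_bin <- function(el, bins, i) {
  which(el$chrom == bins$chrom[i] & el$start >= bins$start[i] &
          el$start < bins$end[i])
}

unbiased_var <- function(x) if (length(x) >= 2L) stats::var(x) else NA_real_

#' Counts, frequency and gap statistics of a point track
#'
#' Per bin: point count, frequency (points per bp of bin), and the mean and
#' unbiased variance of gaps between consecutive points within the bin
#' (gaps never cross bin borders). Bins with fewer than two points have
#' undefined gap statistics and are flagged.
#'
#' @param track A `P` (or `VP`) track.
#' @param regions A [bin_set()].
#' @return A `stat_result`.
#' @examples
#' g <- genome("toy", c(chr1 = 20))
#' point_stats(point_track("chr1", c(3, 7, 12)), make_bins(g, 20))
#' @export
point_stats <- function(track, regions) {
  if (!is_point_type(track)) stop_type("point_stats requires a point track")
  bins <- regions; el <- track$elements
  pb <- bin_frame(bins)
  pb$count <- NA_real_; pb$frequency <- NA_real_
  pb$gap_mean <- NA_real_; pb$gap_var <- NA_real_; pb$defined <- TRUE
  for (i in seq_len(nrow(bins))) {
    p <- sort(el$start[rows_in_bin(el, bins, i)])
    pb$count[i] <- length(p)
    pb$frequency[i] <- length(p) / (bins$end[i] - bins$start[i])
    if (length(p) >= 2L) {
      gaps <- diff(p)
      pb$gap_mean[i] <- mean(gaps)
      pb$gap_var[i] <- unbiased_var(gaps)
    } else {
      pb$defined[i] <- FALSE            # gap stats undefined
    }
  }
  total_bp <- sum(bins$end - bins$start)
  new_stat_result("point_stats", pb,
                  list(count = sum(pb$count),
                       frequency = sum(pb$count) / total_bp))
}

#' Proportion of points arising from the first of two point tracks
#'
#' @param track1,track2 `P` tracks.
#' @param regions A [bin_set()].
#' @return A `stat_result` with per-bin `proportion` (`n1/(n1+n2)`);
#'   undefined where both tracks are empty.
#' @export
frequency_proportion <- function(track1, track2, regions) {
  bins <- regions
  pb <- bin_frame(bins)
  pb$n1 <- NA_real_; pb$n2 <- NA_real_; pb$proportion <- NA_real_
  pb$defined <- TRUE
  for (i in seq_len(nrow(bins))) {
    n1 <- length(rows_in_bin(track1$elements, bins, i))
    n2 <- length(rows_in_bin(track2$elements, bins, i))
    pb$n1[i] <- n1; pb$n2[i] <- n2
    if (n1 + n2 > 0) pb$proportion[i] <- n1 / (n1 + n2) else
      pb$defined[i] <- FALSE
  }
  N1 <- sum(pb$n1); N2 <- sum(pb$n2)
  new_stat_result("frequency_proportion", pb,
                  list(n1 = N1, n2 = N2,
                       proportion = if (N1 + N2 > 0) N1 / (N1 + N2) else NA_real_))
}

# distances from each track1 element to the nearest track2 element within
# one bin; elements are zero-width for points, so the shared convention is
# dist = max(0, s2 - e1, s1 - e2), 0 when overlapping or touching
element_nearest_dists <- function(el1, el2) {
  if (nrow(el2) == 0L) return(rep(NA_real_, nrow(el1)))
  m <- iv_merge(el2$start, pmax(el2$end, el2$start))   # points keep zero width
  # zero-width subjects: merged with end >= start
  iv_nearest_dist(el1$start, el1$end, m$start, m$end)
}

#' Distances from each track1 element to the nearest track2 element
#'
#' Distance is 0 when elements overlap or touch; otherwise the bp gap
#' (points are zero-width positions). Per bin the distances are summarized
#' as mean and median; the full per-element distances are attached.
#'
#' @param track1,track2 `P` or `S` tracks.
#' @param regions A [bin_set()].
#' @return A `stat_result`; `$distances` holds the per-bin distance vectors.
#' @export
nearest_distances <- function(track1, track2, regions) {
  bins <- regions
  # segments spanning a bin border contribute each clipped piece to its bin
  rset <- bin_set(bin_frame(bins))
  if (is_segment_type(track1)) track1 <- clip_track(track1, rset)
  if (is_segment_type(track2)) track2 <- clip_track(track2, rset)
  pb <- bin_frame(bins)
  pb$n <- NA_real_; pb$mean <- NA_real_; pb$median <- NA_real_
  pb$defined <- TRUE
  dists <- vector("list", nrow(bins))
  for (i in seq_len(nrow(bins))) {
    e1 <- track1$elements[rows_in_bin(track1$elements, bins, i), , drop = FALSE]
    e2 <- track2$elements[rows_in_bin(track2$elements, bins, i), , drop = FALSE]
    pb$n[i] <- nrow(e1)
    if (nrow(e1) == 0L || nrow(e2) == 0L) {
      pb$defined[i] <- FALSE
      next
    }
    d <- element_nearest_dists(e1, e2)
    dists[[i]] <- d
    pb$mean[i] <- mean(d); pb$median[i] <- stats::median(d)
  }
  all_d <- unlist(dists)
  res <- new_stat_result("nearest_distances", pb,
                         list(mean = if (length(all_d)) mean(all_d) else NA_real_,
                              median = if (length(all_d))
                                stats::median(all_d) else NA_real_))
  res$distances <- dists
  res
}

#' Points inside and outside segments
#'
#' Containment follows the half-open rule: point `p` is inside `[s, e)` iff
#' `s <= p < e`.
#'
#' @param track1 A `P` track.
#' @param track2 An `S` track.
#' @param regions A [bin_set()].
#' @return A `stat_result` with per-bin `n_inside`, `n_outside`,
#'   `prop_inside`.
#' @export
points_in_segments <- function(track1, track2, regions) {
  bins <- regions
  track2 <- clip_track(track2, bin_set(bin_frame(bins)))   # keep border spans
  pb <- bin_frame(bins)
  pb$n_inside <- NA_real_; pb$n_outside <- NA_real_
  pb$prop_inside <- NA_real_; pb$defined <- TRUE
  for (i in seq_len(nrow(bins))) {
    p <- track1$elements$start[rows_in_bin(track1$elements, bins, i)]
    e2 <- track2$elements[rows_in_bin(track2$elements, bins, i), , drop = FALSE]
    m <- iv_merge(e2$start, e2$end)
    ins <- sum(pt_inside(p, m$start, m$end))
    pb$n_inside[i] <- ins; pb$n_outside[i] <- length(p) - ins
    if (length(p) > 0) pb$prop_inside[i] <- ins / length(p) else
      pb$defined[i] <- FALSE
  }
  ni <- sum(pb$n_inside); no <- sum(pb$n_outside)
  new_stat_result("points_in_segments", pb,
                  list(n_inside = ni, n_outside = no,
                       prop_inside = if (ni + no > 0) ni / (ni + no) else NA_real_))
}

#' Relative position of points within containing segments
#'
#' For each point inside a segment, `relpos = (p - start)/(end - start)` in
#' `[0, 1)`. Only contained points contribute.
#'
#' @param track1 A `P` track.
#' @param track2 An `S` track.
#' @return A `stat_result`; `$relpos` holds the per-point values.
#' @export
relative_positions <- function(track1, track2) {
  rel <- numeric(0)
  el2 <- track2$elements
  for (ch in unique(track1$elements$chrom)) {
    p <- track1$elements$start[track1$elements$chrom == ch]
    seg <- el2[el2$chrom == ch, , drop = FALSE]
    ci <- pt_containing_seg(p, seg$start, seg$end)
    hit <- !is.na(ci)
    rel <- c(rel, (p[hit] - seg$start[ci[hit]]) /
               (seg$end[ci[hit]] - seg$start[ci[hit]]))
  }
  pb <- data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
  res <- new_stat_result("relative_positions", pb,
                         list(n = length(rel),
                              mean = if (length(rel)) mean(rel) else NA_real_))
  res$relpos <- rel
  res
}

#' Coverage and length statistics of a segment track
#'
#' Coverage counts union bp of segments clipped at bin borders; length
#' statistics use raw (pre-union, unclipped) segments, each assigned to the
#' bin containing its start.
#'
#' @param track An `S` track.
#' @param regions A [bin_set()].
#' @return A `stat_result` with per-bin `covered_bp`, `prop_covered`,
#'   `mean_length`, `n_segments`; `$lengths` holds per-bin length vectors.
#' @export
coverage_stats <- function(track, regions) {
  bins <- regions
  pb <- bin_frame(bins)
  pb$covered_bp <- NA_real_; pb$prop_covered <- NA_real_
  pb$mean_length <- NA_real_; pb$n_segments <- NA_real_; pb$defined <- TRUE
  lengths <- vector("list", nrow(bins))
  el <- track$elements
  for (i in seq_len(nrow(bins))) {
    d <- el[el$chrom == bins$chrom[i], , drop = FALSE]
    hits <- iv_intersect_regions(d$start, d$end, bins$start[i], bins$end[i])
    cov <- if (length(hits$q)) iv_total_bp(iv_merge(hits$start, hits$end)$start,
                                           iv_merge(hits$start, hits$end)$end)
      else 0
    pb$covered_bp[i] <- cov
    pb$prop_covered[i] <- cov / (bins$end[i] - bins$start[i])
    rows <- rows_in_bin(el, bins, i)
    lens <- el$end[rows] - el$start[rows]
    lengths[[i]] <- lens
    pb$n_segments[i] <- length(lens)
    if (length(lens)) pb$mean_length[i] <- mean(lens) else pb$defined[i] <- FALSE
  }
  all_len <- unlist(lengths)
  res <- new_stat_result("coverage_stats", pb,
                         list(covered_bp = sum(pb$covered_bp),
                              prop_covered = sum(pb$covered_bp) /
                                sum(bins$end - bins$start),
                              mean_length = if (length(all_len))
                                mean(all_len) else NA_real_))
  res$lengths <- lengths
  res
}

#' Overlap and enrichment of two segment tracks
#'
#' Per bin of length L with covered bp c1, c2 and intersection c12:
#' enrichment = c12 / (c1 * c2 / L), i.e. observed over expected under
#' independence. The global enrichment sums per-bin observed and per-bin
#' expectations, so heterogeneous bins are handled correctly.
#'
#' @param track1,track2 `S` tracks.
#' @param regions A [bin_set()].
#' @return A `stat_result` with per-bin `c1`, `c2`, `c12`, `expected`,
#'   `enrichment`.
#' @export
overlap_and_enrichment <- function(track1, track2, regions) {
  bins <- regions
  pb <- bin_frame(bins)
  pb$c1 <- NA_real_; pb$c2 <- NA_real_; pb$c12 <- NA_real_
  pb$expected <- NA_real_; pb$enrichment <- NA_real_; pb$defined <- TRUE
  for (i in seq_len(nrow(bins))) {
    L <- bins$end[i] - bins$start[i]
    clip1 <- iv_intersect_regions(track1$elements$start, track1$elements$end,
                                  bins$start[i], bins$end[i])
    clip2 <- iv_intersect_regions(track2$elements$start, track2$elements$end,
                                  bins$start[i], bins$end[i])
    keep1 <- track1$elements$chrom[clip1$q] == bins$chrom[i]
    keep2 <- track2$elements$chrom[clip2$q] == bins$chrom[i]
    m1 <- iv_merge(clip1$start[keep1], clip1$end[keep1])
    m2 <- iv_merge(clip2$start[keep2], clip2$end[keep2])
    c1 <- iv_total_bp(m1$start, m1$end)
    c2 <- iv_total_bp(m2$start, m2$end)
    c12 <- iv_intersect_bp(m1$start, m1$end, m2$start, m2$end)
    pb$c1[i] <- c1; pb$c2[i] <- c2; pb$c12[i] <- c12
    pb$expected[i] <- c1 * c2 / L
    if (c1 > 0 && c2 > 0) pb$enrichment[i] <- c12 / pb$expected[i] else
      pb$defined[i] <- FALSE
  }
  tot_exp <- sum(pb$expected)
  new_stat_result("overlap_and_enrichment", pb,
                  list(c1 = sum(pb$c1), c2 = sum(pb$c2), c12 = sum(pb$c12),
                       expected = tot_exp,
                       enrichment = if (tot_exp > 0)
                         sum(pb$c12) / tot_exp else NA_real_))
}

#' Summary statistics of a function track
#'
#' Mean, sum, unbiased variance, min and max over the defined bp of each
#' bin.
#'
#' @param track An `F` track.
#' @param regions A [bin_set()].
#' @return A `stat_result`.
#' @export
function_stats <- function(track, regions) {
  bins <- regions
  pb <- bin_frame(bins)
  vals <- f_values_on_bins(track, bin_set(bin_frame(bins)))
  pb$n_defined <- NA_real_; pb$mean <- NA_real_; pb$sum <- NA_real_
  pb$var <- NA_real_; pb$min <- NA_real_; pb$max <- NA_real_
  pb$defined <- TRUE
  for (i in seq_len(nrow(bins))) {
    v <- vals[[i]][!is.na(vals[[i]])]
    pb$n_defined[i] <- length(v)
    if (length(v) == 0L) { pb$defined[i] <- FALSE; next }
    pb$mean[i] <- mean(v); pb$sum[i] <- sum(v)
    pb$var[i] <- unbiased_var(v)
    pb$min[i] <- min(v); pb$max[i] <- max(v)
  }
  all_v <- unlist(vals); all_v <- all_v[!is.na(all_v)]
  new_stat_result("function_stats", pb,
                  list(n_defined = length(all_v),
                       mean = if (length(all_v)) mean(all_v) else NA_real_,
                       sum = sum(all_v), var = unbiased_var(all_v),
                       min = if (length(all_v)) min(all_v) else NA_real_,
                       max = if (length(all_v)) max(all_v) else NA_real_))
}

#' Function-track values at positions of a second track
#'
#' For a point track: the mean value at the point positions (undefined
#' positions are skipped and tallied). For a segment track: mean value
#' inside vs outside the covered bp.
#'
#' @param track1 An `F` track.
#' @param track2 A `P` or `S` track.
#' @param regions A [bin_set()].
#' @return A `stat_result`.
#' @export
values_at_positions <- function(track1, track2, regions) {
  bins <- regions
  pb <- bin_frame(bins)
  vals <- f_values_on_bins(track1, bin_set(bin_frame(bins)))
  pointy <- is_point_type(track2)
  if (pointy) {
    pb$n <- NA_real_; pb$mean_at_points <- NA_real_; pb$n_skipped <- NA_real_
  } else {
    pb$mean_inside <- NA_real_; pb$mean_outside <- NA_real_
  }
  pb$defined <- TRUE
  acc_in <- numeric(0); acc_out <- numeric(0)
  for (i in seq_len(nrow(bins))) {
    v <- vals[[i]]
    rows <- rows_in_bin(track2$elements, bins, i)
    e2 <- track2$elements[rows, , drop = FALSE]
    if (pointy) {
      off <- e2$start - bins$start[i] + 1
      vv <- v[off]
      pb$n[i] <- length(vv); pb$n_skipped[i] <- sum(is.na(vv))
      vv <- vv[!is.na(vv)]
      if (length(vv)) pb$mean_at_points[i] <- mean(vv) else pb$defined[i] <- FALSE
      acc_in <- c(acc_in, vv)
    } else {
      hits <- iv_intersect_regions(e2$start, e2$end, bins$start[i], bins$end[i])
      inside <- rep(FALSE, length(v))
      for (j in seq_along(hits$q)) {
        inside[(hits$start[j] - bins$start[i] + 1):
                 (hits$end[j] - bins$start[i])] <- TRUE
      }
      vi <- v[inside & !is.na(v)]; vo <- v[!inside & !is.na(v)]
      if (length(vi)) pb$mean_inside[i] <- mean(vi)
      if (length(vo)) pb$mean_outside[i] <- mean(vo)
      if (!length(vi) && !length(vo)) pb$defined[i] <- FALSE
      acc_in <- c(acc_in, vi); acc_out <- c(acc_out, vo)
    }
  }
  g <- if (pointy) {
    list(mean_at_points = if (length(acc_in)) mean(acc_in) else NA_real_,
         n = sum(pb$n), n_skipped = sum(pb$n_skipped))
  } else {
    list(mean_inside = if (length(acc_in)) mean(acc_in) else NA_real_,
         mean_outside = if (length(acc_out)) mean(acc_out) else NA_real_)
  }
  new_stat_result("values_at_positions", pb, g)
}

#' Pearson correlation of two function tracks
#'
#' Computed over bp where both tracks are defined (pairwise-complete), per
#' bin and globally. Bins with fewer than two complete pairs or a constant
#' input are flagged undefined.
#'
#' @param track1,track2 `F` tracks.
#' @param regions A [bin_set()].
#' @return A `stat_result` with per-bin `r` and `n`.
#' @export
pearson_correlation <- function(track1, track2, regions) {
  bins <- regions
  pb <- bin_frame(bins)
  v1 <- f_values_on_bins(track1, bin_set(bin_frame(bins)))
  v2 <- f_values_on_bins(track2, bin_set(bin_frame(bins)))
  pb$n <- NA_real_; pb$r <- NA_real_; pb$defined <- TRUE
  allx <- numeric(0); ally <- numeric(0)
  for (i in seq_len(nrow(bins))) {
    ok <- !is.na(v1[[i]]) & !is.na(v2[[i]])
    x <- v1[[i]][ok]; y <- v2[[i]][ok]
    pb$n[i] <- length(x)
    if (length(x) >= 2L && stats::sd(x) > 0 && stats::sd(y) > 0) {
      pb$r[i] <- stats::cor(x, y)
    } else pb$defined[i] <- FALSE
    allx <- c(allx, x); ally <- c(ally, y)
  }
  g_r <- if (length(allx) >= 2L && stats::sd(allx) > 0 && stats::sd(ally) > 0)
    stats::cor(allx, ally) else NA_real_
  new_stat_result("pearson_correlation", pb, list(r = g_r, n = length(allx)))
}

#' Distribution of element values, optionally restricted to segments
#'
#' @param track1 A `VP` (or `VS`) track with numeric values.
#' @param track2 Optional `S` track; when given, the distribution is also
#'   reported restricted to elements inside its segments.
#' @param regions A [bin_set()].
#' @return A `stat_result`; `$values` and `$values_inside` hold the raw
#'   value vectors, the global summary their quartiles.
#' @export
value_distributions <- function(track1, track2 = NULL, regions) {
  bins <- regions
  el <- track1$elements
  keep <- logical(nrow(el))
  for (i in seq_len(nrow(bins))) keep[rows_in_bin(el, bins, i)] <- TRUE
  vals <- el$value[keep]
  inside_vals <- NULL
  if (!is.null(track2)) {
    ins <- logical(nrow(el))
    for (ch in unique(el$chrom)) {
      seg <- track2$elements[track2$elements$chrom == ch, , drop = FALSE]
      m <- iv_merge(seg$start, seg$end)
      r <- el$chrom == ch
      ins[r] <- pt_inside(el$start[r], m$start, m$end)
    }
    inside_vals <- el$value[keep & ins]
  }
  qs <- function(v) if (length(v)) stats::quantile(as.numeric(v),
                                                   c(0.25, 0.5, 0.75),
                                                   names = FALSE)
    else rep(NA_real_, 3)
  pb <- bin_frame(bins)
  res <- new_stat_result("value_distributions", pb,
                         list(n = length(vals), q25 = qs(vals)[1],
                              median = qs(vals)[2], q75 = qs(vals)[3],
                              n_inside = length(inside_vals %||% numeric(0)),
                              median_inside = qs(inside_vals)[2]))
  res$values <- vals
  res$values_inside <- inside_vals
  res
}

#' Case/control and categorical count tables
#'
#' Dispatches on the supplied value kinds:
#' * `track1` labeled segments (`VS` case/control), `track2` points: counts
#'   of points inside case vs control segments.
#' * `track1` and `track2` both case/control: 2x2 table of case/control
#'   points inside case/control segments.
#' * `track1` categorical alone: per-category element counts and covered bp.
#' * `track1` categorical points, `track2` categorical segments:
#'   category-by-category contingency table of inside counts.
#'
#' A point inside overlapping segments of different labels is counted once
#' per containing label (noted in the result as `multi_label_points`).
#'
#' @param track1,track2 Tracks as above; `track2` may be `NULL`.
#' @return A `stat_result`; `$table` holds the count table.
#' @export
case_control_tables <- function(track1, track2 = NULL) {
  pb <- data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
  if (is.null(track2)) {
    if (!track1$value_kind %in% c("category", "case_control")) {
      stop_type("per-category summaries need a labeled track")
    }
    el <- track1$elements
    labs <- sort(unique(el$value))
    counts <- vapply(labs, function(l) sum(el$value == l), 1)
    cov <- vapply(labs, function(l) {
      d <- el[el$value == l, , drop = FALSE]
      tot <- 0
      for (ch in unique(d$chrom)) {
        m <- iv_merge(d$start[d$chrom == ch], d$end[d$chrom == ch])
        tot <- tot + iv_total_bp(m$start, m$end)
      }
      tot
    }, 1)
    tab <- rbind(count = counts, covered_bp = cov)
    colnames(tab) <- labs
    res <- new_stat_result("category_summary", pb,
                           list(n_categories = length(labs)))
    res$table <- tab
    return(res)
  }
  if (!track1$value_kind %in% c("case_control", "category")) {
    stop_type("track1 must carry case/control or category labels")
  }
  seg_track <- if (is_segment_type(track1)) track1 else track2
  pt_track <- if (is_segment_type(track1)) track2 else track1
  if (!is_segment_type(seg_track) || !is_point_type(pt_track)) {
    stop_type("need one labeled segment track and one point track")
  }
  seg_labs <- sort(unique(seg_track$elements$value))
  pt_labeled <- !is.null(pt_track$elements$value)
  pt_labs <- if (pt_labeled) sort(unique(pt_track$elements$value)) else "points"
  tab <- matrix(0, nrow = length(pt_labs), ncol = length(seg_labs),
                dimnames = list(pt_labs, seg_labs))
  multi <- 0L
  pel <- pt_track$elements
  for (ch in unique(pel$chrom)) {
    p <- pel[pel$chrom == ch, , drop = FALSE]
    seg <- seg_track$elements[seg_track$elements$chrom == ch, , drop = FALSE]
    hit_count <- integer(nrow(p))
    for (sl in seg_labs) {
      d <- seg[seg$value == sl, , drop = FALSE]
      m <- iv_merge(d$start, d$end)
      ins <- pt_inside(p$start, m$start, m$end)
      hit_count <- hit_count + ins
      if (pt_labeled) {
        for (plab in pt_labs) {
          tab[plab, sl] <- tab[plab, sl] + sum(ins & p$value == plab)
        }
      } else {
        tab[1L, sl] <- tab[1L, sl] + sum(ins)
      }
    }
    multi <- multi + sum(hit_count > 1L)
  }
  res <- new_stat_result(
    if (pt_labeled) "label_contingency" else "points_in_labeled_segments",
    pb, list(total_inside = sum(tab), multi_label_points = multi))
  res$table <- tab
  res
}
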