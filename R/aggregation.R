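# Anchor-relative aggregation and per-bin scatter scores ----------------------

#' Aggregate a track around anchor regions
#'
#' Every anchor region is divided into `n_subbins` equal-length sub-bins
#' (remainder bp go to the leftmost sub-bins); a summary statistic is
#' computed per sub-bin per anchor and then averaged across anchors, with
#' a normal-approximation 95% confidence interval. Minus-strand anchors
#' are reversed when `flip_minus_strand` is set, so "left" always means
#' 5-prime. Anchors shorter than `n_subbins` bp are skipped and tallied.
#'
#' @param track The track to profile (`P`/`S` for `count`, `S` for
#'   `coverage`, `F`/`VP` for `mean_value`).
#' @param anchors An `S` track of anchor regions (strand metadata honored).
#' @param n_subbins Number of sub-bins per anchor.
#' @param statistic `"count"` (elements per sub-bin), `"coverage"`
#'   (covered proportion) or `"mean_value"`.
#' @param flip_minus_strand Reverse sub-bin order for minus-strand anchors.
#' @return An `aggregation_profile`: data.frame with per-sub-bin `mean`,
#'   `sd`, `n`, `ci_low`, `ci_high`; skipped anchors in
#'   `attr(, "skipped")`.
#' @export
aggregate_around_anchors <- function(track, anchors, n_subbins,
                                     statistic = c("count", "coverage",
                                                   "mean_value"),
                                     flip_minus_strand = FALSE) {
  statistic <- match.arg(statistic)
  if (n_subbins < 1) stop_invalid_parameter("n_subbins must be >= 1")
  ael <- anchors$elements
  if (nrow(ael) == 0L) stop_invalid_parameter("no anchor regions supplied")
  mat <- matrix(NA_real_, nrow = nrow(ael), ncol = n_subbins)
  skipped <- 0L
  fvals_cache <- NULL
  for (a in seq_len(nrow(ael))) {
    alen <- ael$end[a] - ael$start[a]
    if (alen < n_subbins) { skipped <- skipped + 1L; next }
    base <- alen %/% n_subbins; rem <- alen %% n_subbins
    lens <- rep(base, n_subbins) + (seq_len(n_subbins) <= rem)
    ends <- ael$start[a] + cumsum(lens)
    starts <- c(ael$start[a], ends[-n_subbins])
    vals <- vapply(seq_len(n_subbins), function(j) {
      subbin_stat(track, ael$chrom[a], starts[j], ends[j], statistic)
    }, 1)
    if (flip_minus_strand && !is.null(ael$strand) && ael$strand[a] == "-") {
      vals <- rev(vals)
    }
    mat[a, ] <- vals
  }
  prof <- data.frame(subbin = seq_len(n_subbins))
  prof$n <- colSums(!is.na(mat))
  prof$mean <- colMeans(mat, na.rm = TRUE)
  prof$sd <- apply(mat, 2, function(col) {
    v <- col[!is.na(col)]
    if (length(v) >= 2L) stats::sd(v) else NA_real_
  })
  half <- 1.96 * prof$sd / sqrt(prof$n)
  prof$ci_low <- prof$mean - half
  prof$ci_high <- prof$mean + half
  structure(prof, class = c("aggregation_profile", "data.frame"),
            statistic = statistic, skipped = skipped)
}

subbin_stat <- function(track, chrom, s, e, statistic) {
  el <- track$elements
  d <- el[el$chrom == chrom, , drop = FALSE]
  switch(statistic,
    count = {
      if (is_point_type(track)) sum(d$start >= s & d$start < e)
      else sum(d$start < e & d$end > s)          # overlapping segments
    },
    coverage = {
      if (!is_segment_type(track)) {
        stop_type("coverage statistic requires a segment track")
      }
      hits <- iv_intersect_regions(d$start, d$end, s, e)
      m <- iv_merge(hits$start, hits$end)
      iv_total_bp(m$start, m$end) / (e - s)
    },
    mean_value = {
      if (track$type == "F") {
        v <- f_values_on_bins(track, bin_set(chrom, s, e))[[1L]]
        v <- v[!is.na(v)]
        if (length(v)) mean(v) else NA_real_
      } else if (track$type %in% c("VP", "VS") &&
                 track$value_kind == "number") {
        keep <- d$start >= s & d$start < e
        if (any(keep)) mean(d$value[keep]) else NA_real_
      } else {
        stop_type("mean_value requires an F or numeric-valued track")
      }
    })
}

#' @export
print.aggregation_profile <- function(x, ...) {
  cat(sprintf("<aggregation_profile: %d sub-bin(s), statistic=%s, %d anchor(s) skipped>\n",
              nrow(x), attr(x, "statistic"), attr(x, "skipped")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Per-bin scores of two tracks for a scatter comparison
#'
#' For each analysis bin, one summarizing score per track; the (x, y)
#' pairs expose the relation between the tracks along the genome.
#'
#' @param track1,track2 Tracks.
#' @param regions A [bin_set()].
#' @param summarizer1,summarizer2 `"count"`, `"coverage"`, `"mean_value"`
#'   or a function `(track, chrom, start, end) -> number`.
#' @return Data.frame with `chrom`, `start`, `end`, `x`, `y`, `defined`.
#' @export
bin_scatter <- function(track1, track2, regions, summarizer1 = "count",
                        summarizer2 = summarizer1) {
  bins <- regions
  score <- function(track, summ, i) {
    if (is.function(summ)) {
      summ(track, bins$chrom[i], bins$start[i], bins$end[i])
    } else {
      subbin_stat(track, bins$chrom[i], bins$start[i], bins$end[i], summ)
    }
  }
  out <- bin_frame(bins)
  out$x <- vapply(seq_len(nrow(bins)), function(i) score(track1, summarizer1, i), 1)
  out$y <- vapply(seq_len(nrow(bins)), function(i) score(track2, summarizer2, i), 1)
  out$defined <- !is.na(out$x) & !is.na(out$y)
  out
}
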