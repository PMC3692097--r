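# Track customization and generation operators -------------------------------
#
# These recast proximity/normalization questions as containment/overlap
# questions: e.g. expanding gene segments by flanks turns "near a gene"
# into "inside an expanded gene segment".

#' Expand track elements by upstream/downstream flanks
#'
#' Each element is replaced by `[anchorL - upstream, anchorR + downstream)`
#' where the anchor is the whole segment, its start, midpoint
#' (`floor((start+end)/2)`) or end (last covered bp). Results crossing
#' chromosome borders are clipped. Strand-agnostic by default; with
#' `stranded = TRUE`, upstream/downstream are swapped for minus-strand
#' elements.
#'
#' @param track A `P` or `S` track (also `VP`/`VS`; values are dropped).
#' @param upstream,downstream Flank sizes in bp, non-negative.
#' @param anchor `"segment"`, `"start"`, `"mid"` or `"end"`;
#'   `"segment"` requires a segment track.
#' @param genome A [genome()] for border clipping.
#' @param merge Union overlapping results into non-overlapping segments.
#' @param stranded Swap flanks on minus-strand elements.
#' @return An `S` track.
#' @examples
#' g <- genome("toy", c(chr1 = 12))
#' expand_segments(segment_track("chr1", 5, 10), 3, 3, "segment", g)
#' @export
expand_segments <- function(track, upstream, downstream,
                            anchor = c("segment", "start", "mid", "end"),
                            genome, merge = FALSE, stranded = FALSE) {
  anchor <- match.arg(anchor)
  if (upstream < 0 || downstream < 0) {
    stop_invalid_parameter("flanks must be non-negative")
  }
  if (anchor == "segment" && !is_segment_type(track)) {
    stop_type("anchor='segment' requires a segment track, got %s", track$type)
  }
  el <- track$elements
  if (nrow(el) == 0L) {
    return(segment_track(character(0), numeric(0), numeric(0), name = track$name))
  }
  # For point anchors the result is [a - upstream, a + downstream): downstream
  # counts from the anchor bp inclusive, so 0/0 flanks give an empty interval.
  a <- if (anchor == "segment") list(l = el$start, r = el$end) else {
    p <- switch(anchor,
      start = el$start,
      mid = if (is_point_type(track)) el$start else
        floor((el$start + el$end) / 2),
      end = if (is_point_type(track)) el$start else el$end - 1)
    list(l = p, r = p)
  }
  up <- rep(upstream, nrow(el)); dn <- rep(downstream, nrow(el))
  if (stranded && !is.null(el$strand)) {
    minus <- el$strand == "-"
    up[minus] <- downstream; dn[minus] <- upstream
  }
  s <- a$l - up
  e <- a$r + dn
  lens <- chrom_length(genome, el$chrom)
  s <- pmax(s, 0); e <- pmin(e, lens)
  if (any(e <= s)) stop_invalid_parameter("expansion produced an empty interval")
  out <- segment_track(el$chrom, s, e, name = track$name)
  if (merge) merge_overlaps(out) else out
}

#' Extract anchor points from segments
#'
#' @param track An `S` (or `VS`) track.
#' @param anchor `"start"`, `"mid"` (`floor((start+end)/2)`) or `"end"`
#'   (the last covered bp, `end - 1`).
#' @return A `P` track with one point per segment.
#' @export
extract_points <- function(track, anchor = c("start", "mid", "end")) {
  anchor <- match.arg(anchor)
  if (!is_segment_type(track)) {
    stop_type("extract_points requires a segment track, got %s", track$type)
  }
  el <- track$elements
  pos <- switch(anchor, start = el$start,
                mid = floor((el$start + el$end) / 2), end = el$end - 1)
  point_track(el$chrom, pos, strand = el$strand, name = track$name)
}

#' Combine case and control tracks into one labeled track
#'
#' Elements keep their geometry and gain a `"case"`/`"control"` label
#' recording their source; counts are conserved per label.
#'
#' @param case_track,control_track Two tracks of the same geometric type
#'   (`P` or `S`).
#' @param name Output track label.
#' @return A `VP(case_control)` or `VS(case_control)` track.
#' @export
merge_case_control <- function(case_track, control_track, name = "case_control") {
  merge_categorical(list(case_track, control_track), c("case", "control"),
                    name = name, value_kind = "case_control")
}

#' Combine multiple tracks into one categorical track
#'
#' @param tracks List of tracks, all `P` or all `S`.
#' @param labels One category label per track.
#' @param name Output track label.
#' @param value_kind Label kind of the output (`"category"` or
#'   `"case_control"`).
#' @return A `VP(category)` or `VS(category)` track.
#' @export
merge_categorical <- function(tracks, labels, name = "categorical",
                              value_kind = "category") {
  if (length(tracks) != length(labels)) {
    stop_invalid_parameter("need exactly one label per track (%d tracks, %d labels)",
                           length(tracks), length(labels))
  }
  geo <- vapply(tracks, function(t) if (is_point_type(t)) "P" else
    if (is_segment_type(t)) "S" else t$type, "")
  if (length(unique(geo)) > 1L || any(geo == "F")) {
    stop_type("all tracks must share one geometric type (P or S); got %s",
              paste(geo, collapse = ","))
  }
  els <- mapply(function(t, lab) {
    el <- t$elements[c("chrom", "start", "end")]
    el$value <- rep(lab, nrow(el))
    el
  }, tracks, labels, SIMPLIFY = FALSE)
  el <- do.call(rbind, els)
  if (geo[1L] == "P") {
    point_track(el$chrom, el$start, value = el$value, value_kind = value_kind,
                name = name)
  } else {
    segment_track(el$chrom, el$start, el$end, value = el$value,
                  value_kind = value_kind, name = name)
  }
}

#' Split a labeled track back into per-label tracks
#'
#' Inverse of [merge_case_control()] / [merge_categorical()].
#'
#' @param track A `VP`/`VS` track with `case_control` or `category` values.
#' @return Named list of unlabeled tracks, one per label present.
#' @export
split_by_label <- function(track) {
  el <- track$elements
  labs <- if (track$value_kind == "case_control") c("case", "control") else
    sort(unique(el$value))
  out <- lapply(labs, function(lab) {
    d <- el[el$value == lab, , drop = FALSE]
    if (is_point_type(track)) point_track(d$chrom, d$start, name = lab)
    else segment_track(d$chrom, d$start, d$end, name = lab)
  })
  names(out) <- labs
  out
}

#' Per-bp distance to the nearest track element
#'
#' Generates a function track whose value at each bp is the distance in bp
#' to the nearest element of the input (0 at a point or inside a segment).
#' Chromosomes with no elements are left uncovered.
#'
#' @param track A `P` or `S` track.
#' @param genome A [genome()].
#' @return An `F` track covering every chromosome that has elements.
#' @examples
#' distance_to_nearest(point_track("chr1", 2), genome("toy", c(chr1 = 5)))
#' @export
distance_to_nearest <- function(track, genome) {
  if (!(is_point_type(track) || is_segment_type(track))) {
    stop_type("distance_to_nearest requires points or segments")
  }
  el <- track$elements
  chroms <- intersect(genome$chrom_names, unique(el$chrom))
  vals <- list(); starts <- numeric(0); out_chr <- character(0)
  for (ch in chroms) {
    L <- chrom_length(genome, ch)
    d <- el[el$chrom == ch, , drop = FALSE]
    v <- rep(Inf, L)
    idx0 <- unlist(mapply(function(s, e) seq(s, max(s, e - 1)), d$start, d$end,
                          SIMPLIFY = FALSE))
    v[idx0 + 1] <- 0
    # two linear passes; the cummin trick keeps them vectorized
    i <- seq_len(L)
    v <- cummin(v - i) + i          # forward: dist grows by 1 per bp
    v <- rev(cummin(rev(v) - i) + i)  # backward
    out_chr <- c(out_chr, ch); starts <- c(starts, 0); vals <- c(vals, list(v))
  }
  function_track(out_chr, starts, vals, name = paste0("dist_", track$name))
}

#' Merge overlapping segments into their union
#'
#' Book-ended segments (`[0,5)`, `[5,8)`) merge as well: zero-gap intervals
#' are contiguous. The output never overlaps and conserves covered bp.
#'
#' @param track An `S` track.
#' @return An `S` track with `overlaps_allowed = FALSE`.
#' @export
merge_overlaps <- function(track) {
  if (!is_segment_type(track)) stop_type("merge_overlaps requires segments")
  el <- track$elements
  pieces <- lapply(unique(el$chrom), function(ch) {
    d <- el[el$chrom == ch, , drop = FALSE]
    m <- iv_merge(d$start, d$end, adjacent = TRUE)
    data.frame(chrom = ch, start = m$start, end = m$end,
               stringsAsFactors = FALSE)
  })
  df <- if (length(pieces)) do.call(rbind, pieces) else
    el[0, c("chrom", "start", "end")]
  if (nrow(df) == 0L) {
    return(new_track("S", data.frame(chrom = character(0), start = numeric(0),
                                     end = numeric(0)),
                     name = track$name, overlaps_allowed = FALSE))
  }
  segment_track(df$chrom, df$start, df$end, name = track$name,
                overlaps_allowed = FALSE)
}

# Intensity tracks ------------------------------------------------------------

#' Build an intensity track for confounder-controlled randomization
#'
#' Estimates, for every bp, the probability that a target element lands
#' there during randomization, given a set of confounder tracks. Each
#' confounder (a function track) is discretized into quantile strata; the
#' joint stratum of a bp is the tuple of its per-confounder strata, and the
#' bp weight is proportional to the empirical target-point density within
#' that stratum (points in stratum / bp in stratum). When the joint strata
#' count exceeds `max_joint_strata` the estimator falls back to the product
#' of per-confounder marginal density ratios. Weights are normalized to sum
#' to one within each bin.
#'
#' @param target A `P` track of the elements whose placement is modeled.
#' @param confounders List of `F` tracks (each must cover the analyzed bins).
#' @param genome A [genome()].
#' @param bins A [bin_set()]: the normalization scope.
#' @param strata_per_confounder Number of quantile strata per confounder.
#' @param max_joint_strata Joint-strata limit before the additive fallback.
#' @return An `intensity_track`: an `F` track of weights plus its bins.
#' @export
make_intensity_track <- function(target, confounders, genome, bins,
                                 strata_per_confounder = 10,
                                 max_joint_strata = 1e4) {
  if (length(confounders) < 1L) stop_invalid_parameter("need >= 1 confounder")
  if (n_elements(target) == 0L) stop_invalid_parameter("target track is empty")
  bins <- bin_set(as.data.frame(bins))
  # dense confounder values over the bins, one row set per bin
  conf_vals <- lapply(confounders, function(f) f_values_on_bins(f, bins))
  pts <- clip_track(target, bins)$elements
  # global bp index of each target point within the bins
  pt_bin <- integer(0); pt_off <- numeric(0)
  offsets <- c(0, cumsum(bins$end - bins$start))
  for (i in seq_len(nrow(bins))) {
    d <- pts[pts$chrom == bins$chrom[i] & pts$start >= bins$start[i] &
               pts$start < bins$end[i], , drop = FALSE]
    if (nrow(d)) {
      pt_bin <- c(pt_bin, rep(i, nrow(d)))
      pt_off <- c(pt_off, offsets[i] + d$start - bins$start[i])
    }
  }
  total_bp <- sum(bins$end - bins$start)
  strat <- lapply(conf_vals, function(v) {
    vv <- unlist(v, use.names = FALSE)
    uv <- sort(unique(vv[!is.na(vv)]))
    if (length(uv) <= 1L) {
      if (strata_per_confounder > 1L) {
        warning("confounder has constant values; collapsed to 1 stratum")
      }
      return(rep(1L, total_bp))
    }
    if (length(uv) <= strata_per_confounder) {
      s <- match(vv, uv)                      # few distinct values: exact strata
    } else {
      qs <- unique(stats::quantile(vv, probs = seq(0, 1, length.out =
                                                     strata_per_confounder + 1),
                                   na.rm = TRUE, names = FALSE))
      s <- findInterval(vv, qs, rightmost.closed = TRUE, all.inside = TRUE)
    }
    s[is.na(s)] <- 1L                         # undefined bp join stratum 1
    s
  })
  n_strata <- vapply(strat, max, 1L)
  pt_idx <- pt_off + 1
  w <- if (prod(n_strata) <= max_joint_strata) {
    joint <- strat[[1L]]
    if (length(strat) > 1L) {
      for (k in 2L:length(strat)) {
        joint <- joint + (strat[[k]] - 1L) * prod(n_strata[seq_len(k - 1L)])
      }
    }
    bp_per <- tabulate(joint)
    pts_per <- tabulate(joint[pt_idx], nbins = length(bp_per))
    dens <- ifelse(bp_per > 0, pts_per / bp_per, 0)
    dens[joint]
  } else {
    # additive fallback: product of marginal density ratios
    w0 <- rep(1, total_bp)
    overall <- length(pt_idx) / total_bp
    for (k in seq_along(strat)) {
      bp_per <- tabulate(strat[[k]])
      pts_per <- tabulate(strat[[k]][pt_idx], nbins = length(bp_per))
      dens <- ifelse(bp_per > 0, (pts_per / bp_per) / overall, 0)
      w0 <- w0 * dens[strat[[k]]]
    }
    w0
  }
  # normalize per bin
  vals <- vector("list", nrow(bins))
  for (i in seq_len(nrow(bins))) {
    idx <- (offsets[i] + 1):(offsets[i + 1])
    wi <- w[idx]
    s <- sum(wi)
    vals[[i]] <- if (s > 0) wi / s else rep(1 / length(wi), length(wi))
  }
  ftr <- normalize_f_runs(function_track(bins$chrom, bins$start, vals,
                                         name = "intensity"))
  structure(list(track = ftr, bins = bins), class = "intensity_track")
}

#' @export
print.intensity_track <- function(x, ...) {
  cat(sprintf("<intensity_track over %d bin(s), %s bp>\n", nrow(x$bins),
              format(sum(x$bins$end - x$bins$start), scientific = FALSE)))
  invisible(x)
}

# Dense values of an F track over each bin (list of numeric vectors,
# NA where undefined).
f_values_on_bins <- function(ftrack, bins) {
  el <- ftrack$elements
  lapply(seq_len(nrow(bins)), function(i) {
    L <- bins$end[i] - bins$start[i]
    out <- rep(NA_real_, L)
    d_idx <- which(el$chrom == bins$chrom[i])
    if (length(d_idx)) {
      hits <- iv_intersect_regions(el$start[d_idx], el$end[d_idx],
                                   bins$start[i], bins$end[i])
      for (j in seq_along(hits$q)) {
        row <- d_idx[hits$q[j]]
        v <- ftrack$values[[row]]
        src <- (hits$start[j] - el$start[row] + 1):(hits$end[j] - el$start[row])
        dst <- (hits$start[j] - bins$start[i] + 1):(hits$end[j] - bins$start[i])
        out[dst] <- v[src]
      }
    }
    out
  })
}

# Sequence-derived tracks -----------------------------------------------------

read_sequences <- function(sequence) {
  if (is.character(sequence) && length(sequence) == 1L && file.exists(sequence)) {
    seqs <- Biostrings::readDNAStringSet(sequence)
    out <- toupper(as.character(seqs))
    names(out) <- sub("\\s.*$", "", names(seqs))
    out
  } else if (is.character(sequence) && !is.null(names(sequence))) {
    toupper(sequence)
  } else {
    stop_invalid_parameter("sequence must be a FASTA path or a named character vector")
  }
}

#' Genome-wide occurrence track for a k-mer
#'
#' Emits a point at the start of every (overlapping) match of `kmer` in the
#' sequence, case-insensitively. With `both_strands`, matches of the
#' reverse complement are included and positions hit on both strands are
#' deduplicated to a single point.
#'
#' @param sequence FASTA file path or named character vector of sequences.
#' @param kmer The motif, over `A`/`C`/`G`/`T`.
#' @param both_strands Also match the reverse complement.
#' @return A `P` track.
#' @examples
#' kmer_track(c(chr1 = "ACGTACGT"), "ACGT")
#' @export
kmer_track <- function(sequence, kmer, both_strands = FALSE) {
  kmer <- toupper(kmer)
  if (nchar(kmer) < 1L || grepl("[^ACGT]", kmer)) {
    stop_invalid_parameter("kmer must be non-empty over {A,C,G,T}")
  }
  seqs <- read_sequences(sequence)
  pats <- Biostrings::DNAString(kmer)
  rc <- as.character(Biostrings::reverseComplement(pats))
  chroms <- character(0); pos <- numeric(0)
  for (ch in names(seqs)) {
    subj <- Biostrings::DNAString(seqs[[ch]])
    hits <- Biostrings::start(Biostrings::matchPattern(pats, subj)) - 1
    if (both_strands && rc != kmer) {
      hits <- sort(unique(c(hits,
        Biostrings::start(Biostrings::matchPattern(
          Biostrings::DNAString(rc), subj)) - 1)))
    }
    chroms <- c(chroms, rep(ch, length(hits)))
    pos <- c(pos, hits)
  }
  point_track(chroms, pos, name = sprintf("kmer_%s", kmer))
}

#' Sliding-window GC content track
#'
#' For each bp, the fraction of G/C among the defined (non-N) bases in a
#' centered window of `window` bp, truncated at chromosome ends. Positions
#' whose window holds no defined base are undefined.
#'
#' @param sequence FASTA file path or named character vector of sequences.
#' @param window Odd window width in bp.
#' @return An `F` track.
#' @examples
#' gc_window_track(c(chr1 = "ATGC"), 3)
#' @export
gc_window_track <- function(sequence, window) {
  if (window < 1 || window %% 2 == 0) {
    stop_invalid_parameter("window must be odd and >= 1")
  }
  seqs <- read_sequences(sequence)
  half <- (window - 1) / 2
  chroms <- character(0); starts <- numeric(0); vals <- list()
  for (ch in names(seqs)) {
    b <- strsplit(seqs[[ch]], "", fixed = TRUE)[[1L]]
    L <- length(b)
    gc <- cumsum(c(0, b %in% c("G", "C")))
    defined <- cumsum(c(0, b %in% c("A", "C", "G", "T")))
    i <- seq_len(L)
    lo <- pmax(i - half, 1L); hi <- pmin(i + half, L)
    ngc <- gc[hi + 1] - gc[lo]
    ndef <- defined[hi + 1] - defined[lo]
    v <- ifelse(ndef > 0, ngc / ndef, NA_real_)
    if (all(is.na(v))) next
    chroms <- c(chroms, ch); starts <- c(starts, 0); vals <- c(vals, list(v))
  }
  function_track(chroms, starts, vals, name = sprintf("gc_w%d", window))
}
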