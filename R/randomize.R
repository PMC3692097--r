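# Null-model randomizers ------------------------------------------------------
#
# A null model defines "expected by chance" for hypothesis tests: elements
# are re-placed (or their labels/values shuffled) within each analysis bin,
# preserving declared structure. Placement models:
#
#   uniform_independent   points i.i.d. uniform; segments keep their length
#                         multiset and are placed non-overlapping, uniformly
#                         over all feasible arrangements (gap-composition
#                         sampling)
#   preserve_gaps         inter-element gap and length multisets kept, order
#                         permuted, offset re-drawn uniformly over the slack
#   intensity_guided      points drawn from an intensity track's per-bp
#                         distribution, without replacement
#   permute_labels        positions fixed, case/control or category labels
#                         shuffled
#   permute_values        positions fixed, numeric values shuffled
#   uniform_within_segments  points re-drawn uniformly within their
#                         containing segment of a conditioning track

NULL_MODELS <- c("uniform_independent", "preserve_gaps", "intensity_guided",
                 "permute_labels", "permute_values", "uniform_within_segments")

#' Specify a null model
#'
#' @param model One of `"uniform_independent"`, `"preserve_gaps"`,
#'   `"intensity_guided"`, `"permute_labels"`, `"permute_values"`,
#'   `"uniform_within_segments"`.
#' @param intensity An `intensity_track`; required iff
#'   `model = "intensity_guided"`.
#' @param conditioning A segment track; required iff
#'   `model = "uniform_within_segments"`.
#' @param per_bin Randomize within each analysis bin independently
#'   (default), preserving large-scale structure across bins.
#' @param seed Integer root seed; per-bin child streams are derived from it
#'   deterministically, so results do not depend on bin evaluation order.
#' @return A `null_model_spec`.
#' @export
null_model_spec <- function(model = NULL_MODELS, intensity = NULL,
                            conditioning = NULL, per_bin = TRUE, seed = 1L) {
  model <- match.arg(model)
  if (model == "intensity_guided" && is.null(intensity)) {
    stop_invalid_parameter("intensity_guided requires an intensity track")
  }
  if (model != "intensity_guided" && !is.null(intensity)) {
    stop_invalid_parameter("intensity supplied but model is %s", model)
  }
  if (model == "uniform_within_segments" && is.null(conditioning)) {
    stop_invalid_parameter("uniform_within_segments requires a conditioning track")
  }
  structure(list(model = model, intensity = intensity,
                 conditioning = conditioning, per_bin = isTRUE(per_bin),
                 seed = as.integer(seed)),
            class = "null_model_spec")
}

# Low-level placement samplers. All operate inside a [0, L) bin with the
# RNG already seeded; they return sorted starts (and permuted lengths).

# Uniform i.i.d. integer positions (with replacement).
place_points_uniform <- function(n, L) {
  sort(pmin(floor(stats::runif(n, 0, L)), L - 1))
}

# Non-overlapping segments with the given length multiset, uniform over all
# feasible arrangements: the free space is split uniformly at random among
# the n+1 gaps (composition sampling) and the segment order is permuted.
place_segments_uniform <- function(lens, L) {
  n <- length(lens)
  free <- L - sum(lens)
  if (free < 0) {
    stop_feasibility("segments (total %g bp) do not fit in bin of %g bp",
                     sum(lens), L)
  }
  lens_p <- if (n > 1L) lens[sample.int(n)] else lens
  cuts <- sort(sample.int(free + n, n))
  starts <- (cuts - seq_len(n)) + cumsum(c(0, lens_p))[seq_len(n)]
  list(start = starts, len = lens_p)
}

# Keep gap and length multisets, permute their order, re-draw the leading
# offset uniformly over the slack.
place_preserve_gaps <- function(lens, gaps, L, zero_width = FALSE) {
  n <- length(lens)
  lens_p <- if (n > 1L) lens[sample.int(n)] else lens
  gaps_p <- if (length(gaps) > 1L) gaps[sample.int(length(gaps))] else gaps
  span <- sum(lens_p) + sum(gaps_p)
  slack <- (if (zero_width) L - 1 else L) - span
  if (slack < 0) stop_feasibility("element span exceeds bin length")
  off <- floor(stats::runif(1, 0, slack + 1))
  starts <- off + cumsum(c(0, lens_p[-n] + gaps_p))
  list(start = starts, len = lens_p)
}

# Weighted sampling of n distinct positions in [0, L) from per-bp weights.
place_points_intensity <- function(n, w) {
  if (sum(w) <= 0) {
    stop_feasibility("intensity has zero total mass in a bin containing elements")
  }
  sort(sample.int(length(w), n, replace = FALSE, prob = w) - 1)
}

#' Randomize a track under a null model
#'
#' Elements are re-placed (or labels/values shuffled) within each analysis
#' bin; with `per_bin = FALSE`, within each maximal run of book-ended bins.
#' Positional models preserve the per-bin element count and segment-length
#' multiset exactly; `preserve_gaps` additionally preserves the gap
#' multiset.
#'
#' @param track The track to randomize (clipped to `regions` first).
#' @param spec A [null_model_spec()].
#' @param regions A [bin_set()].
#' @return A track of the same type and per-bin element counts.
#' @export
randomize <- function(track, spec, regions) {
  bins <- if (spec$per_bin) bin_set(as.data.frame(regions)) else
    merge_adjacent_bins(regions)
  track <- clip_track(track, regions)
  el <- track$elements
  pieces <- vector("list", nrow(bins))
  for (i in seq_len(nrow(bins))) {
    st <- with_rng_state(list(seed = child_seed(spec$seed, i)), {
      randomize_bin(track, el, spec, bins$chrom[i], bins$start[i], bins$end[i])
    })
    pieces[[i]] <- st$value
  }
  pieces <- pieces[!vapply(pieces, is.null, TRUE)]
  out <- if (length(pieces)) do.call(rbind, pieces) else
    el[0, , drop = FALSE]
  rownames(out) <- NULL
  new_track(track$type, out, track$value_kind, track$name,
            overlaps_allowed = track$overlaps_allowed)
}

randomize_bin <- function(track, el, spec, chrom, bs, be) {
  d <- el[el$chrom == chrom & el$start >= bs & el$start < be, , drop = FALSE]
  if (nrow(d) == 0L) return(NULL)
  L <- be - bs
  model <- spec$model
  if (model %in% c("permute_labels", "permute_values")) {
    if (is.null(d$value)) stop_type("%s requires a valued track", model)
    if (model == "permute_values" && !is.numeric(d$value)) {
      stop_type("permute_values requires numeric values")
    }
    d$value <- d$value[sample.int(nrow(d))]
    return(d)
  }
  if (is_point_type(track)) {
    pos <- switch(model,
      uniform_independent = place_points_uniform(nrow(d), L) + bs,
      preserve_gaps = {
        p <- place_preserve_gaps(rep(0, nrow(d)), diff(d$start), L,
                                 zero_width = TRUE)
        p$start + bs
      },
      intensity_guided = {
        w <- intensity_weights(spec$intensity, chrom, bs, be)
        place_points_intensity(nrow(d), w) + bs
      },
      uniform_within_segments = {
        seg <- spec$conditioning$elements
        seg <- seg[seg$chrom == chrom, , drop = FALSE]
        ci <- pt_containing_seg(d$start, seg$start, seg$end)
        newpos <- d$start
        hit <- !is.na(ci)
        if (any(hit)) {
          s <- seg$start[ci[hit]]; e <- seg$end[ci[hit]]
          newpos[hit] <- s + floor(stats::runif(sum(hit)) * (e - s))
        }
        newpos
      },
      stop_type("model %s not defined for point tracks", model))
    d_new <- d
    d_new$start <- pos; d_new$end <- pos
    o <- order(d_new$start)
    # values travel with their (re-ordered) elements arbitrarily; positional
    # models make no claim about value-position pairing
    d_new <- d_new[o, , drop = FALSE]
    return(d_new)
  }
  if (is_segment_type(track)) {
    # only segments fully handled per-bin; clipped pieces keep their length
    lens <- d$end - d$start
    p <- switch(model,
      uniform_independent = place_segments_uniform(lens, L),
      preserve_gaps = {
        gaps <- d$start[-1L] - d$end[-nrow(d)]
        place_preserve_gaps(lens, gaps, L)
      },
      stop_type("model %s not defined for segment tracks", model))
    perm <- match_lengths_perm(lens, p$len)
    d_new <- d[perm, , drop = FALSE]
    d_new$start <- bs + p$start
    d_new$end <- d_new$start + p$len
    return(d_new)
  }
  stop_type("cannot randomize track type %s under model %s", track$type, model)
}

# Map permuted lengths back to original rows so values/strand follow their
# segment through the permutation.
match_lengths_perm <- function(orig, permuted) {
  idx <- integer(length(permuted))
  pool <- seq_along(orig)
  for (j in seq_along(permuted)) {
    k <- which(orig[pool] == permuted[j])[1L]
    idx[j] <- pool[k]
    pool <- pool[-k]
  }
  idx
}

intensity_weights <- function(intensity, chrom, bs, be) {
  w <- f_values_on_bins(intensity$track,
                        bin_set(chrom, bs, be))[[1L]]
  w[is.na(w)] <- 0
  w
}

# Synthetic track generation --------------------------------------------------

#' Simulate a synthetic track
#'
#' Fixture generator with controlled structure: element count, length
#' distribution, clustering and value distribution. Gaps between
#' consecutive elements are drawn from a geometric mixture: with
#' probability `clustering` a short within-cluster gap (mean
#' `cluster_gap`), otherwise a long gap sized so that the elements span the
#' chromosome on average. `clustering = 0` gives uniform placement.
#'
#' @param genome A [genome()].
#' @param n_elements Total element count (distributed over chromosomes
#'   proportionally to length).
#' @param track_type `"P"`, `"S"`, `"VP"`, `"VS"` or `"F"`.
#' @param length_dist For segments: a fixed length, or a function `n ->
#'   lengths`.
#' @param clustering Mixture weight in `[0, 1]` for short gaps.
#' @param cluster_gap Mean of the short gap component, bp.
#' @param value_dist For valued tracks: a function `n -> values` (numeric or
#'   labels); defaults to standard normal.
#' @param seed Integer seed; identical seeds reproduce the track exactly.
#' @param name Track label.
#' @return A track of the requested type.
#' @export
simulate_track <- function(genome, n_elements, track_type = "P",
                           length_dist = 10, clustering = 0,
                           cluster_gap = 10, value_dist = NULL, seed = 1L,
                           name = "simulated") {
  track_type <- match.arg(track_type, TRACK_TYPES)
  if (clustering < 0 || clustering > 1) {
    stop_invalid_parameter("clustering must be in [0, 1]")
  }
  len_fun <- if (is.function(length_dist)) length_dist else
    function(n) rep(length_dist, n)
  st <- with_rng_state(list(seed = as.integer(seed)), {
    sim_track_impl(genome, n_elements, track_type, len_fun, clustering,
                   cluster_gap, value_dist, name)
  })
  st$value
}

sim_track_impl <- function(genome, n_elements, track_type, len_fun,
                           clustering, cluster_gap, value_dist, name) {
  glen <- genome_length(genome)
  # apportion counts by chromosome length (largest remainder)
  share <- n_elements * genome$chromosomes / glen
  n_chr <- floor(share)
  rem <- n_elements - sum(n_chr)
  if (rem > 0) {
    extra <- order(share - n_chr, decreasing = TRUE)[seq_len(rem)]
    n_chr[extra] <- n_chr[extra] + 1
  }
  chroms <- character(0); starts <- numeric(0); ends <- numeric(0)
  for (ci in seq_along(genome$chrom_names)) {
    n <- n_chr[ci]
    if (n == 0) next
    L <- genome$chromosomes[ci]
    segish <- track_type %in% c("S", "VS", "F")
    lens <- if (segish) pmax(1, round(len_fun(n))) else rep(0, n)
    if (sum(lens) + n > L) {
      stop_feasibility("infeasible density: %d elements (%g bp) on %s (%g bp)",
                       n, sum(lens), genome$chrom_names[ci], L)
    }
    if (clustering == 0) {
      if (segish) {
        p <- place_segments_uniform(lens, L)
        s <- p$start; lens <- p$len
      } else {
        s <- place_points_uniform(n, L)
      }
    } else {
      # geometric-mixture gaps, then uniform placement of the whole span
      long_mean <- max(1, (L - sum(lens)) / (n + 1))
      short <- stats::runif(max(0, n - 1)) < clustering
      gaps <- ifelse(short, stats::rgeom(max(0, n - 1), 1 / (1 + cluster_gap)),
                     stats::rgeom(max(0, n - 1), 1 / (1 + long_mean)))
      span <- sum(lens) + sum(gaps)
      if (span > L) {                      # rescale long gaps to fit
        gaps <- floor(gaps * (L - sum(lens) - n) / max(1, sum(gaps)))
        span <- sum(lens) + sum(gaps)
      }
      off <- floor(stats::runif(1, 0, L - span - (if (segish) 0 else 1) + 1))
      s <- off + cumsum(c(0, lens[-n] + gaps))
    }
    chroms <- c(chroms, rep(genome$chrom_names[ci], n))
    starts <- c(starts, s)
    ends <- c(ends, s + lens)
  }
  valued <- track_type %in% c("VP", "VS")
  value <- if (valued) {
    vd <- value_dist %||% stats::rnorm
    vd(length(starts))
  }
  switch(track_type,
    P = point_track(chroms, starts, name = name),
    VP = point_track(chroms, starts, value = value, name = name),
    S = segment_track(chroms, starts, ends, name = name),
    VS = segment_track(chroms, starts, ends, value = value, name = name),
    F = {
      vd <- value_dist %||% stats::rnorm
      f <- function_track(chroms, starts,
                          lapply(seq_along(starts), function(i)
                            vd(ends[i] - starts[i])), name)
      normalize_f_runs(f)
    })
}
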