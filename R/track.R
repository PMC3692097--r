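# Typed genomic tracks ------------------------------------------------------
#
# Five geometric types are supported:
#   P  points            (zero-width positions; start == end internally)
#   S  segments          (half-open intervals, length >= 1 bp)
#   VP valued points     (P + value)
#   VS valued segments   (S + value)
#   F  function          (a numeric value for every bp of its covered runs)
# Values come in three kinds: number, case_control ("case"/"control"),
# category (finite label set). All coordinates 0-based half-open.

TRACK_TYPES <- c("P", "S", "VP", "VS", "F")
VALUE_KINDS <- c("none", "number", "case_control", "category")

new_track <- function(type, elements, value_kind = "none", name = "",
                      values = NULL, overlaps_allowed = TRUE) {
  type <- match.arg(type, TRACK_TYPES)
  value_kind <- match.arg(value_kind, VALUE_KINDS)
  o <- order(elements$chrom, elements$start, elements$end)
  elements <- elements[o, , drop = FALSE]
  rownames(elements) <- NULL
  if (type == "F" && !is.null(values)) values <- values[o]
  structure(list(type = type, value_kind = value_kind, name = name,
                 elements = elements, values = values,
                 overlaps_allowed = overlaps_allowed),
            class = "track")
}

infer_value_kind <- function(value) {
  if (is.null(value)) return("none")
  if (is.numeric(value)) return("number")
  v <- as.character(value)
  if (length(v) && all(v %in% c("case", "control"))) return("case_control")
  "category"
}

#' Create a point track
#'
#' Points are single bp positions (not length-1 segments): a point `p` lies
#' inside a segment `[s, e)` iff `s <= p < e`.
#'
#' @param chrom Chromosome name(s), recycled against `pos`.
#' @param pos Integer-valued bp positions (0-based).
#' @param value Optional per-point values; numeric gives a `VP(number)`
#'   track, labels `"case"/"control"` give `VP(case_control)`, any other
#'   labels give `VP(category)`.
#' @param value_kind Override the inferred value kind.
#' @param strand Optional per-point strand (`"+"`/`"-"`); carried as
#'   metadata, ignored by all statistics except anchor aggregation.
#' @param name Track label.
#' @return A `track` of type `P` or `VP`.
#' @examples
#' point_track("chr1", c(3, 7, 12))
#' @export
point_track <- function(chrom, pos, value = NULL, value_kind = NULL,
                        strand = NULL, name = "") {
  n <- length(pos)
  el <- data.frame(chrom = rep_len(as.character(chrom), n),
                   start = as.numeric(pos), end = as.numeric(pos),
                   stringsAsFactors = FALSE)
  vk <- value_kind %||% infer_value_kind(value)
  if (!is.null(value)) {
    el$value <- if (vk == "number") as.numeric(value) else as.character(value)
  }
  if (!is.null(strand)) el$strand <- rep_len(as.character(strand), n)
  new_track(if (is.null(value)) "P" else "VP", el, vk, name)
}

#' Create a segment track
#'
#' @param chrom Chromosome name(s), recycled.
#' @param start,end 0-based half-open interval bounds; `end > start`.
#' @param value Optional per-segment values (see [point_track()]).
#' @param value_kind Override the inferred value kind.
#' @param strand Optional per-segment strand metadata.
#' @param name Track label.
#' @param overlaps_allowed Whether segments may overlap; merging operators
#'   emit tracks with this flag `FALSE`.
#' @return A `track` of type `S` or `VS`.
#' @examples
#' segment_track("chr1", c(0, 20), c(10, 25))
#' @export
segment_track <- function(chrom, start, end, value = NULL, value_kind = NULL,
                          strand = NULL, name = "", overlaps_allowed = TRUE) {
  n <- length(start)
  if (length(end) != n) stop_invalid_parameter("start and end lengths differ")
  if (any(end <= start)) {
    stop_invalid_parameter("segments must have length >= 1 bp")
  }
  el <- data.frame(chrom = rep_len(as.character(chrom), n),
                   start = as.numeric(start), end = as.numeric(end),
                   stringsAsFactors = FALSE)
  vk <- value_kind %||% infer_value_kind(value)
  if (!is.null(value)) {
    el$value <- if (vk == "number") as.numeric(value) else as.character(value)
  }
  if (!is.null(strand)) el$strand <- rep_len(as.character(strand), n)
  new_track(if (is.null(value)) "S" else "VS", el, vk, name,
            overlaps_allowed = overlaps_allowed)
}

#' Create a function (per-bp value) track
#'
#' A function track assigns a numeric value to every bp of its covered runs;
#' positions outside the runs (or with `NA` values) are undefined and are
#' excluded from all means and correlations (pairwise-complete).
#'
#' @param chrom Chromosome of each run.
#' @param start 0-based start of each run.
#' @param values A numeric vector (single run) or list of numeric vectors,
#'   one value per bp of each run.
#' @param name Track label.
#' @return A `track` of type `F`.
#' @examples
#' function_track("chr1", 0, c(0.2, 0.4, 0.6))
#' @export
function_track <- function(chrom, start, values, name = "") {
  if (!is.list(values)) values <- list(as.numeric(values))
  n <- length(values)
  el <- data.frame(chrom = rep_len(as.character(chrom), n),
                   start = as.numeric(start),
                   end = as.numeric(start) + vapply(values, length, 1L),
                   stringsAsFactors = FALSE)
  new_track("F", el, "none", name, values = lapply(values, as.numeric))
}

#' @export
print.track <- function(x, ...) {
  vk <- if (x$value_kind == "none") "" else sprintf("(%s)", x$value_kind)
  cat(sprintf("<track '%s' type %s%s: %d element(s) on %d chromosome(s)>\n",
              x$name, x$type, vk, nrow(x$elements),
              length(unique(x$elements$chrom))))
  invisible(x)
}

#' Number of elements in a track
#' @param track A track.
#' @return Integer count (runs for `F` tracks).
#' @export
n_elements <- function(track) nrow(track$elements)

#' Track type accessor
#' @param track A track.
#' @return One of `"P"`, `"S"`, `"VP"`, `"VS"`, `"F"`.
#' @export
track_type <- function(track) track$type

is_point_type <- function(track) track$type %in% c("P", "VP")
is_segment_type <- function(track) track$type %in% c("S", "VS")

# Split a track's elements by chromosome; returns a named list of
# data.frames (with run values attached for F tracks as a "values" column).
split_by_chrom <- function(track) {
  el <- track$elements
  if (track$type == "F") el$values <- I(track$values)
  split(el, el$chrom)
}

#' Validate a track against a genome
#'
#' Checks every track invariant: known chromosomes, elements within bounds,
#' sorted order, segment lengths, value-kind consistency, and run/value
#' agreement for function tracks. Violations are reported, not raised.
#'
#' @param track A track.
#' @param genome A [genome()] object.
#' @return Character vector of violation descriptions; empty iff valid.
#' @examples
#' g <- genome("toy", c(chr1 = 10))
#' validate_track(segment_track("chr1", 8, 12), g)
#' @export
validate_track <- function(track, genome) {
  v <- character(0)
  el <- track$elements
  if (nrow(el) == 0L) return(v)
  known <- el$chrom %in% genome$chrom_names
  for (i in which(!known)) {
    v <- c(v, sprintf("element %d: unknown chromosome '%s'", i, el$chrom[i]))
  }
  if (any(known)) {
    lens <- rep(NA_real_, nrow(el))
    lens[known] <- chrom_length(genome, el$chrom[known])
    bad <- which(known & (el$start < 0 | el$end > lens |
                            (is_point_type(track) & el$start >= lens)))
    for (i in bad) {
      v <- c(v, sprintf("element %d: [%g,%g) on %s outside [0,%g)",
                        i, el$start[i], el$end[i], el$chrom[i],
                        lens[i]))
    }
  }
  o <- order(el$chrom, el$start, el$end)
  if (!identical(o, seq_len(nrow(el)))) {
    first <- which(o != seq_len(nrow(el)))[1L]
    v <- c(v, sprintf("element %d: elements not sorted by (chrom, start)", first))
  }
  if (is_segment_type(track) || track$type == "F") {
    for (i in which(el$end - el$start < 1)) {
      v <- c(v, sprintf("element %d: segment length < 1 bp on %s",
                        i, el$chrom[i]))
    }
  }
  if (is_point_type(track)) {
    for (i in which(el$start != el$end)) {
      v <- c(v, sprintf("element %d: point with nonzero width", i))
    }
  }
  if (track$value_kind == "case_control" && !is.null(el$value)) {
    for (i in which(!el$value %in% c("case", "control"))) {
      v <- c(v, sprintf("element %d: case/control value '%s' invalid",
                        i, el$value[i]))
    }
  }
  if (track$value_kind %in% c("number") && !is.null(el$value) &&
      !is.numeric(el$value)) {
    v <- c(v, "value column not numeric for value_kind=number")
  }
  if (track$type == "F") {
    nv <- vapply(track$values, length, 1L)
    for (i in which(nv != el$end - el$start)) {
      v <- c(v, sprintf("element %d: run length %g != %d values",
                        i, el$end[i] - el$start[i], nv[i]))
    }
    if (!track$overlaps_allowed || TRUE) {
      # F runs must never overlap (each bp has one value)
      by_chr <- split(el, el$chrom)
      for (ch in names(by_chr)) {
        d <- by_chr[[ch]]
        if (nrow(d) > 1L && any(d$start[-1L] < d$end[-nrow(d)])) {
          v <- c(v, sprintf("overlapping function runs on %s", ch))
        }
      }
    }
  }
  if (!track$overlaps_allowed && is_segment_type(track)) {
    by_chr <- split(el, el$chrom)
    for (ch in names(by_chr)) {
      d <- by_chr[[ch]]
      if (nrow(d) > 1L && any(d$start[-1L] < d$end[-nrow(d)])) {
        v <- c(v, sprintf("overlapping segments on %s but overlaps_allowed=FALSE", ch))
      }
    }
  }
  v
}

#' Restrict a track to a set of analysis regions
#'
#' Points outside the regions are dropped; segments are intersected with the
#' regions (split where they span region borders); function runs are
#' restricted. Values and strand are carried along (duplicated on split).
#'
#' @param track A track.
#' @param regions A [bin_set()].
#' @return A track of the same type.
#' @export
clip_track <- function(track, regions) {
  bins <- as.data.frame(regions)
  el <- track$elements
  if (nrow(el) == 0L) return(track)
  out <- vector("list", 0L)
  out_vals <- list()
  keep_rows <- list()
  pieces <- list()
  for (ch in unique(el$chrom)) {
    b <- bins[bins$chrom == ch, , drop = FALSE]
    d <- el[el$chrom == ch, , drop = FALSE]
    ridx <- which(el$chrom == ch)
    if (nrow(b) == 0L) next
    if (is_point_type(track)) {
      ins <- pt_inside(d$start, b$start, b$end)
      if (any(ins)) pieces[[ch]] <- d[ins, , drop = FALSE]
    } else {
      hits <- iv_intersect_regions(d$start, d$end, b$start, b$end)
      if (length(hits$q)) {
        piece <- d[hits$q, , drop = FALSE]
        if (track$type == "F") {
          vals <- track$values[ridx[hits$q]]
          piece$clip_values <- I(mapply(function(v, os, s, e) {
            v[(s - os + 1):(e - os)]
          }, vals, piece$start, hits$start, hits$end, SIMPLIFY = FALSE))
        }
        piece$start <- hits$start
        piece$end <- hits$end
        pieces[[ch]] <- piece
      }
    }
  }
  if (length(pieces) == 0L) {
    empty <- el[0, , drop = FALSE]
    return(new_track(track$type, empty, track$value_kind, track$name,
                     values = if (track$type == "F") list(),
                     overlaps_allowed = track$overlaps_allowed))
  }
  res <- do.call(rbind, pieces)
  rownames(res) <- NULL
  vals <- NULL
  if (track$type == "F") {
    vals <- res$clip_values
    res$clip_values <- NULL
    attr(vals, "class") <- NULL
  }
  new_track(track$type, res, track$value_kind, track$name, values = vals,
            overlaps_allowed = track$overlaps_allowed)
}
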