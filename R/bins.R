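# Analysis regions (bins) ----------------------------------------------------

#' Create a bin set from explicit regions
#'
#' Bins are the unit of "local" analysis: statistics and local p-values are
#' computed once per bin. Bins must be non-overlapping; they are stored in
#' the order given (use [make_bins()] for a genome-ordered fixed-size split).
#'
#' @param chrom,start,end Region coordinates (0-based half-open), or a
#'   data.frame with those columns as the single first argument.
#' @param genome Optional [genome()] used to check bounds.
#' @param origin Provenance label, `"user"` or `"fixed_size"`.
#' @return An object of class `bin_set`.
#' @export
bin_set <- function(chrom, start = NULL, end = NULL, genome = NULL,
                    origin = "user") {
  if (is.data.frame(chrom)) {
    df <- chrom[c("chrom", "start", "end")]
  } else {
    df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                     end = as.numeric(end), stringsAsFactors = FALSE)
  }
  if (any(df$end <= df$start)) stop_invalid_parameter("empty bin (end <= start)")
  for (ch in unique(df$chrom)) {
    d <- df[df$chrom == ch, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) > 1L && any(d$start[-1L] < d$end[-nrow(d)])) {
      stop_invalid_parameter("bins overlap on %s", ch)
    }
  }
  if (!is.null(genome)) {
    lens <- chrom_length(genome, df$chrom)
    if (any(df$start < 0 | df$end > lens)) {
      stop_validation("bin outside chromosome bounds")
    }
  }
  rownames(df) <- NULL
  structure(df, class = c("bin_set", "data.frame"), origin = origin)
}

#' @export
print.bin_set <- function(x, ...) {
  cat(sprintf("<bin_set: %d bin(s), %s bp total, origin=%s>\n",
              nrow(x), format(sum(x$end - x$start), scientific = FALSE),
              attr(x, "origin")))
  invisible(x)
}

#' Split a genome (or selected regions) into fixed-size bins
#'
#' Each chromosome (or each restriction region) is split into consecutive
#' bins of `bin_size` bp; the final bin of each chromosome or region may be
#' shorter. Bin order follows genome order.
#'
#' @param genome A [genome()] object.
#' @param bin_size Bin width in bp, at least 1.
#' @param restrict_to Optional data.frame of regions (`chrom`, `start`,
#'   `end`) to split instead of whole chromosomes.
#' @return A [bin_set()].
#' @examples
#' make_bins(genome("toy", c(chr1 = 25)), 10)
#' @export
make_bins <- function(genome, bin_size, restrict_to = NULL) {
  if (!is.numeric(bin_size) || length(bin_size) != 1L || bin_size < 1) {
    stop_invalid_parameter("bin_size must be a single number >= 1")
  }
  if (is.null(restrict_to)) {
    restrict_to <- data.frame(chrom = genome$chrom_names, start = 0,
                              end = genome$chromosomes,
                              stringsAsFactors = FALSE)
  } else {
    restrict_to <- as.data.frame(restrict_to)
    lens <- chrom_length(genome, restrict_to$chrom)
    if (any(restrict_to$start < 0 | restrict_to$end > lens)) {
      stop_validation("restriction region outside chromosome bounds")
    }
    ord <- order(match(restrict_to$chrom, genome$chrom_names),
                 restrict_to$start)
    restrict_to <- restrict_to[ord, , drop = FALSE]
  }
  pieces <- lapply(seq_len(nrow(restrict_to)), function(i) {
    s <- restrict_to$start[i]; e <- restrict_to$end[i]
    starts <- s + bin_size * (seq_len(ceiling((e - s) / bin_size)) - 1)
    data.frame(chrom = restrict_to$chrom[i], start = starts,
               end = pmin(starts + bin_size, e), stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, pieces)
  rownames(df) <- NULL
  structure(df, class = c("bin_set", "data.frame"), origin = "fixed_size")
}

# Merge book-ended bins per chromosome (used by per_bin = FALSE
# randomization, which randomizes within maximal contiguous runs of bins).
merge_adjacent_bins <- function(bins) {
  out <- lapply(unique(bins$chrom), function(ch) {
    d <- bins[bins$chrom == ch, , drop = FALSE]
    m <- iv_merge(d$start, d$end, adjacent = TRUE)
    data.frame(chrom = ch, start = m$start, end = m$end,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  structure(df, class = c("bin_set", "data.frame"), origin = "merged")
}
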