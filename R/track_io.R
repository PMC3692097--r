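# Track file formats ---------------------------------------------------------
#
# BED, bedGraph and WIG follow the UCSC dialects (BED 0-based half-open;
# WIG 1-based). GTrack support is a pragmatic subset: '##' header lines
# declaring track type / value type / indexing base, a '###' column line,
# then tab-separated data. All readers normalize to the internal 0-based
# half-open convention and sort elements.

GTRACK_TYPE_NAMES <- c(P = "points", S = "segments", VP = "valued points",
                       VS = "valued segments", F = "function")

#' Read a genomic track file
#'
#' @param path Path to the file.
#' @param format One of `"bed"`, `"bedgraph"`, `"wig"`, `"gtrack"`.
#' @param genome A [genome()]; coordinates are checked against it.
#' @param use_score For BED: interpret column 5 as a numeric value, yielding
#'   a `VS(number)` track. Otherwise the score column is ignored.
#' @param dense For bedGraph: return a function (`F`) track with one value
#'   per covered bp instead of valued segments.
#' @param name Track label; defaults to the file name.
#' @return A `track`.
#' @export
read_track <- function(path, format = c("bed", "bedgraph", "wig", "gtrack"),
                       genome, use_score = FALSE, dense = FALSE,
                       name = basename(path)) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_parse("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  tr <- switch(format,
    bed = parse_bed(lines, use_score, name),
    bedgraph = parse_bedgraph(lines, dense, name),
    wig = parse_wig(lines, name),
    gtrack = parse_gtrack(lines, name))
  check_track_bounds(tr, genome, path)
  tr
}

check_track_bounds <- function(track, genome, path) {
  el <- track$elements
  if (nrow(el) == 0L) return(invisible(track))
  unknown <- !el$chrom %in% genome$chrom_names
  if (any(unknown)) {
    stop_validation("%s: unknown chromosome(s): %s", path,
                    paste(unique(el$chrom[unknown]), collapse = ", "))
  }
  lens <- chrom_length(genome, el$chrom)
  bad <- el$start < 0 | el$end > lens |
    (is_point_type(track) & el$start >= lens)
  if (any(bad)) {
    off <- utils::head(which(bad), 5L)
    stop_validation("%s: %d element(s) outside chromosome bounds (e.g. %s)",
                    path, sum(bad),
                    paste(sprintf("%s:[%g,%g)", el$chrom[off], el$start[off],
                                  el$end[off]), collapse = ", "))
  }
  invisible(track)
}

is_skippable <- function(line) {
  grepl("^(track|browser)\\b", line) || grepl("^#", line) || !nzchar(trimws(line))
}

parse_bed <- function(lines, use_score, name) {
  keep <- !vapply(lines, is_skippable, TRUE, USE.NAMES = FALSE)
  idx <- which(keep)
  rows <- strsplit(lines[keep], "\t", fixed = TRUE)
  ncols <- vapply(rows, length, 1L)
  if (any(ncols < 3L)) {
    stop_parse("BED line %d: fewer than 3 columns", idx[which(ncols < 3L)[1L]])
  }
  chrom <- vapply(rows, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(rows, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(rows, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) stop_parse("BED line %d: non-numeric coordinate", idx[bad[1L]])
  value <- NULL
  if (use_score) {
    if (any(ncols < 5L)) {
      stop_parse("BED line %d: score column requested but absent",
                 idx[which(ncols < 5L)[1L]])
    }
    value <- suppressWarnings(as.numeric(vapply(rows, `[[`, "", 5L)))
    if (anyNA(value)) {
      stop_parse("BED line %d: non-numeric score", idx[which(is.na(value))[1L]])
    }
  }
  strand <- if (length(rows) && all(ncols >= 6L)) vapply(rows, `[[`, "", 6L)
  segment_track(chrom, start, end, value = value, strand = strand, name = name)
}

parse_bedgraph <- function(lines, dense, name) {
  keep <- !vapply(lines, is_skippable, TRUE, USE.NAMES = FALSE)
  idx <- which(keep)
  rows <- strsplit(lines[keep], "[ \t]+")
  if (any(vapply(rows, length, 1L) < 4L)) {
    stop_parse("bedGraph line %d: expected 4 columns",
               idx[which(vapply(rows, length, 1L) < 4L)[1L]])
  }
  chrom <- vapply(rows, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(rows, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(rows, `[[`, "", 3L)))
  value <- suppressWarnings(as.numeric(vapply(rows, `[[`, "", 4L)))
  bad <- which(is.na(start) | is.na(end) | is.na(value))
  if (length(bad)) stop_parse("bedGraph line %d: non-numeric field", idx[bad[1L]])
  if (dense) {
    f <- function_track(rep(chrom, end - start)[0], numeric(0), list(), name)
    if (length(chrom)) {
      vals <- mapply(function(v, s, e) rep(v, e - s), value, start, end,
                     SIMPLIFY = FALSE)
      f <- function_track(chrom, start, vals, name)
    }
    return(normalize_f_runs(f))
  }
  segment_track(chrom, start, end, value = value, value_kind = "number",
                name = name)
}

# Merge book-ended function runs into maximal contiguous runs (normal form;
# applied by every reader so that write/read round trips are structural).
normalize_f_runs <- function(track) {
  el <- track$elements
  if (nrow(el) <= 1L) return(track)
  by_chr <- split(seq_len(nrow(el)), el$chrom)
  chroms <- character(0); starts <- numeric(0); vals <- list()
  for (ch in names(by_chr)) {
    i <- by_chr[[ch]]
    newrun <- c(TRUE, el$start[i][-1L] != el$end[i][-length(i)])
    grp <- cumsum(newrun)
    for (gidx in unique(grp)) {
      rows <- i[grp == gidx]
      chroms <- c(chroms, ch)
      starts <- c(starts, el$start[rows[1L]])
      vals <- c(vals, list(unlist(track$values[rows], use.names = FALSE)))
    }
  }
  function_track(chroms, starts, vals, track$name)
}

parse_wig_decl <- function(line) {
  parts <- strsplit(trimws(line), "[ \t]+")[[1L]]
  kv <- strsplit(parts[-1L], "=", fixed = TRUE)
  vals <- vapply(kv, function(x) x[2L], "")
  names(vals) <- vapply(kv, function(x) x[1L], "")
  list(mode = parts[1L], chrom = vals[["chrom"]],
       start = if ("start" %in% names(vals)) as.numeric(vals[["start"]]) else NA,
       step = if ("step" %in% names(vals)) as.numeric(vals[["step"]]) else 1,
       span = if ("span" %in% names(vals)) as.numeric(vals[["span"]]) else 1)
}

parse_wig <- function(lines, name) {
  mode <- NULL; decl <- NULL
  f_chrom <- character(0); f_start <- numeric(0); f_vals <- list()
  vp_chrom <- character(0); vp_pos <- numeric(0); vp_val <- numeric(0)
  pending <- numeric(0); pending_start <- NA
  flush_fixed <- function() {
    if (length(pending)) {
      f_chrom <<- c(f_chrom, decl$chrom)
      f_start <<- c(f_start, pending_start)
      f_vals <<- c(f_vals, list(pending))
    }
    pending <<- numeric(0)
  }
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (is_skippable(line)) next
    if (grepl("^(fixedStep|variableStep)\\b", line)) {
      flush_fixed()
      decl <- parse_wig_decl(line)
      mode <- decl$mode
      if (mode == "fixedStep") {
        if (decl$step < decl$span) {
          stop_parse("WIG line %d: step < span unsupported", ln)
        }
        pending_start <- decl$start - 1          # to 0-based
      } else if (decl$span != 1) {
        stop_parse("WIG line %d: variableStep span != 1 unsupported", ln)
      }
      next
    }
    if (is.null(mode)) stop_parse("WIG line %d: data before declaration", ln)
    fields <- strsplit(trimws(line), "[ \t]+")[[1L]]
    if (mode == "fixedStep") {
      v <- suppressWarnings(as.numeric(fields[1L]))
      if (is.na(v)) stop_parse("WIG line %d: non-numeric value", ln)
      if (decl$step == 1 && decl$span == 1) {
        pending <- c(pending, v)
      } else {
        # non-contiguous steps become separate runs of `span` bp
        f_chrom <- c(f_chrom, decl$chrom)
        f_start <- c(f_start, decl$start - 1)
        f_vals <- c(f_vals, list(rep(v, decl$span)))
        decl$start <- decl$start + decl$step
      }
    } else {
      if (length(fields) < 2L) stop_parse("WIG line %d: expected pos value", ln)
      pos <- suppressWarnings(as.numeric(fields[1L]))
      v <- suppressWarnings(as.numeric(fields[2L]))
      if (is.na(pos) || is.na(v)) stop_parse("WIG line %d: non-numeric field", ln)
      vp_chrom <- c(vp_chrom, decl$chrom)
      vp_pos <- c(vp_pos, pos - 1)
      vp_val <- c(vp_val, v)
    }
  }
  flush_fixed()
  if (length(vp_pos) && length(f_start)) {
    stop_parse("WIG mixes fixedStep and variableStep; unsupported")
  }
  if (length(vp_pos)) {
    point_track(vp_chrom, vp_pos, value = vp_val, value_kind = "number",
                name = name)
  } else {
    normalize_f_runs(function_track(f_chrom, f_start, f_vals, name))
  }
}

parse_gtrack <- function(lines, name) {
  headers <- list()
  cols <- NULL
  data_rows <- list(); data_ln <- integer(0)
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (!nzchar(trimws(line))) next
    if (startsWith(line, "###")) {
      cols <- strsplit(sub("^###", "", line), "\t", fixed = TRUE)[[1L]]
      next
    }
    if (startsWith(line, "##")) {
      kv <- strsplit(sub("^##", "", line), ":", fixed = TRUE)[[1L]]
      if (length(kv) >= 2L) {
        headers[[trimws(kv[1L])]] <- trimws(paste(kv[-1L], collapse = ":"))
      }
      next
    }
    if (startsWith(line, "#")) next
    data_rows <- c(data_rows, strsplit(line, "\t", fixed = TRUE))
    data_ln <- c(data_ln, ln)
  }
  tt_name <- tolower(headers[["track type"]] %||% "segments")
  type <- names(GTRACK_TYPE_NAMES)[match(tt_name, GTRACK_TYPE_NAMES)]
  if (is.na(type)) stop_parse("GTrack: unsupported track type '%s'", tt_name)
  vk <- switch(tolower(headers[["value type"]] %||% "number"),
               "number" = "number", "case-control" = "case_control",
               "category" = "category",
               stop_parse("GTrack: unsupported value type"))
  one_based <- tolower(headers[["1-indexed"]] %||% "false") == "true"
  end_incl <- tolower(headers[["end inclusive"]] %||% "false") == "true"
  if (is.null(cols)) {
    cols <- switch(type, P = c("seqid", "start"),
                   S = c("seqid", "start", "end"),
                   VP = c("seqid", "start", "value"),
                   VS = c("seqid", "start", "end", "value"),
                   F = c("seqid", "start", "value"))
  }
  need <- switch(type, P = c("seqid", "start"), S = c("seqid", "start", "end"),
                 VP = c("seqid", "start", "value"),
                 VS = c("seqid", "start", "end", "value"),
                 F = c("seqid", "start", "value"))
  if (!all(need %in% cols)) {
    stop_parse("GTrack: column spec (%s) inconsistent with track type %s",
               paste(cols, collapse = ","), tt_name)
  }
  get_col <- function(colname) {
    j <- match(colname, cols)
    vapply(data_rows, function(r) {
      if (length(r) < j) stop_parse("GTrack: short data line")
      r[[j]]
    }, "")
  }
  if (length(data_rows) == 0L) {
    return(switch(type,
      P = point_track(character(0), numeric(0), name = name),
      S = segment_track(character(0), numeric(0), numeric(0) + 1, name = name),
      VP = point_track(character(0), numeric(0),
                       value = if (vk == "number") numeric(0) else character(0),
                       value_kind = vk, name = name),
      VS = segment_track(character(0), numeric(0), numeric(0) + 1,
                         value = if (vk == "number") numeric(0) else character(0),
                         value_kind = vk, name = name),
      F = function_track(character(0), numeric(0), list(), name = name)))
  }
  chrom <- get_col("seqid")
  start <- suppressWarnings(as.numeric(get_col("start")))
  if (anyNA(start)) {
    stop_parse("GTrack line %d: non-numeric start", data_ln[which(is.na(start))[1L]])
  }
  if (one_based) start <- start - 1
  strand <- if ("strand" %in% cols) get_col("strand")
  if (type %in% c("S", "VS")) {
    end <- suppressWarnings(as.numeric(get_col("end")))
    if (anyNA(end)) {
      stop_parse("GTrack line %d: non-numeric end", data_ln[which(is.na(end))[1L]])
    }
    if (one_based) end <- end - 1
    if (end_incl) end <- end + 1
  }
  value <- if (type %in% c("VP", "VS", "F")) {
    raw <- get_col("value")
    if (vk == "number") {
      v <- suppressWarnings(as.numeric(raw))
      if (anyNA(v)) {
        stop_parse("GTrack line %d: non-numeric value",
                   data_ln[which(is.na(v))[1L]])
      }
      v
    } else raw
  }
  switch(type,
    P = point_track(chrom, start, strand = strand, name = name),
    S = segment_track(chrom, start, end, strand = strand, name = name),
    VP = point_track(chrom, start, value = value, value_kind = vk,
                     strand = strand, name = name),
    VS = segment_track(chrom, start, end, value = value, value_kind = vk,
                       strand = strand, name = name),
    F = {
      o <- order(chrom, start)
      normalize_f_runs(function_track(chrom[o], start[o],
                                      as.list(value[o]), name))
    })
}

#' Write a track to a file
#'
#' The format must be able to represent the track type; lossy combinations
#' raise a capability error. For representable combinations the round trip
#' `read_track(write_track(t))` reproduces `t` exactly (numeric values are
#' serialized at full double precision).
#'
#' @param track A track.
#' @param path Output path.
#' @param format One of `"bed"`, `"bedgraph"`, `"wig"`, `"gtrack"`.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path,
                        format = c("bed", "bedgraph", "wig", "gtrack")) {
  format <- match.arg(format)
  el <- track$elements
  lines <- switch(format,
    bed = {
      if (!is_segment_type(track)) {
        stop_capability("BED cannot represent track type %s (needs segments)",
                        track$type)
      }
      if (track$type == "VS" && track$value_kind != "number") {
        stop_capability("BED score column cannot carry %s values",
                        track$value_kind)
      }
      if (track$type == "VS" || !is.null(el$strand)) {
        sprintf("%s\t%s\t%s\t.\t%s\t%s", el$chrom, fmt_coord(el$start),
                fmt_coord(el$end),
                if (track$type == "VS") fmt_num(el$value) else "0",
                el$strand %||% rep(".", nrow(el)))
      } else {
        sprintf("%s\t%s\t%s", el$chrom, fmt_coord(el$start), fmt_coord(el$end))
      }
    },
    bedgraph = {
      if (track$type == "VS" && track$value_kind == "number") {
        sprintf("%s\t%s\t%s\t%s", el$chrom, fmt_coord(el$start),
                fmt_coord(el$end), fmt_num(el$value))
      } else if (track$type == "F") {
        rle_f_lines(track)
      } else {
        stop_capability("bedGraph cannot represent track type %s%s",
                        track$type,
                        if (track$value_kind %in% c("case_control", "category"))
                          sprintf(" with %s values", track$value_kind) else "")
      }
    },
    wig = {
      if (track$type == "F") {
        unlist(lapply(seq_len(nrow(el)), function(i) {
          c(sprintf("fixedStep chrom=%s start=%s step=1 span=1",
                    el$chrom[i], fmt_coord(el$start[i] + 1)),
            fmt_num(track$values[[i]]))
        }))
      } else if (track$type == "VP" && track$value_kind == "number") {
        out <- character(0)
        for (ch in unique(el$chrom)) {
          d <- el[el$chrom == ch, , drop = FALSE]
          out <- c(out, sprintf("variableStep chrom=%s", ch),
                   sprintf("%s\t%s", fmt_coord(d$start + 1), fmt_num(d$value)))
        }
        out
      } else {
        stop_capability("WIG cannot represent track type %s (value kind %s)",
                        track$type, track$value_kind)
      }
    },
    gtrack = gtrack_lines(track))
  writeLines(lines, path)
  invisible(path)
}

fmt_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)

rle_f_lines <- function(track) {
  el <- track$elements
  out <- character(0)
  for (i in seq_len(nrow(el))) {
    v <- track$values[[i]]
    r <- rle(v)
    ends <- el$start[i] + cumsum(r$lengths)
    starts <- c(el$start[i], ends[-length(ends)])
    keep <- !is.na(r$values)
    out <- c(out, sprintf("%s\t%s\t%s\t%s", el$chrom[i], fmt_coord(starts[keep]),
                          fmt_coord(ends[keep]), fmt_num(r$values[keep])))
  }
  out
}

gtrack_lines <- function(track) {
  el <- track$elements
  vk_name <- c(number = "number", case_control = "case-control",
               category = "category")[track$value_kind]
  hdr <- c("##gtrack version: 1.0",
           sprintf("##track type: %s", GTRACK_TYPE_NAMES[[track$type]]),
           if (track$value_kind != "none")
             sprintf("##value type: %s", vk_name),
           "##1-indexed: false")
  has_strand <- !is.null(el$strand)
  cols <- switch(track$type,
    P = c("seqid", "start"), S = c("seqid", "start", "end"),
    VP = c("seqid", "start", "value"), VS = c("seqid", "start", "end", "value"),
    F = c("seqid", "start", "value"))
  if (has_strand) cols <- c(cols, "strand")
  body <- if (track$type == "F") {
    unlist(lapply(seq_len(nrow(el)), function(i) {
      pos <- seq(el$start[i], el$end[i] - 1)
      keep <- !is.na(track$values[[i]])
      sprintf("%s\t%s\t%s", el$chrom[i], fmt_coord(pos[keep]),
              fmt_num(track$values[[i]][keep]))
    }))
  } else {
    parts <- list(el$chrom, fmt_coord(el$start))
    if (track$type %in% c("S", "VS")) parts <- c(parts, list(fmt_coord(el$end)))
    if (track$type %in% c("VP", "VS")) {
      v <- if (track$value_kind == "number") fmt_num(el$value) else el$value
      parts <- c(parts, list(v))
    }
    if (has_strand) parts <- c(parts, list(el$strand))
    do.call(paste, c(parts, sep = "\t"))
  }
  c(hdr, paste0("###", paste(cols, collapse = "\t")), body)
}

#' Tabular import specification
#'
#' Describes how to interpret an unstructured tabular file as a track:
#' which columns hold coordinates and values, how many header lines to
#' skip, the coordinate base and end convention, and the separator.
#'
#' @param chrom_col,start_col Mandatory 1-based column indices.
#' @param end_col,value_col Optional column indices; `end_col` turns the
#'   result into segments, `value_col` attaches values.
#' @param skip Header lines to skip.
#' @param base Coordinate base of the input, 0 or 1.
#' @param end_inclusive Whether the end column is inclusive.
#' @param sep Field separator.
#' @return A `tabular_spec` object for [import_tabular()].
#' @export
tabular_spec <- function(chrom_col, start_col, end_col = NULL,
                         value_col = NULL, skip = 0, base = 0,
                         end_inclusive = FALSE, sep = "\t") {
  idx <- c(chrom_col, start_col, end_col, value_col)
  if (anyDuplicated(idx)) stop_invalid_parameter("column indices must be distinct")
  if (!base %in% c(0, 1)) stop_invalid_parameter("base must be 0 or 1")
  structure(list(chrom_col = chrom_col, start_col = start_col,
                 end_col = end_col, value_col = value_col, skip = skip,
                 base = base, end_inclusive = end_inclusive, sep = sep),
            class = "tabular_spec")
}

#' Structure tabular data into a track
#'
#' @param path Path to the delimited text file.
#' @param spec A [tabular_spec()].
#' @param genome A [genome()] for bounds checking.
#' @param name Track label.
#' @return A `track`: `P`/`S` without a value column, `VP`/`VS` with one
#'   (value kind inferred from the column contents).
#' @export
import_tabular <- function(path, spec, genome, name = basename(path)) {
  if (!file.exists(path)) stop_parse("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (spec$skip > 0) lines <- lines[-seq_len(spec$skip)]
  lines <- lines[nzchar(trimws(lines))]
  rows <- strsplit(lines, spec$sep, fixed = TRUE)
  maxcol <- max(spec$chrom_col, spec$start_col, spec$end_col %||% 0,
                spec$value_col %||% 0)
  short <- which(vapply(rows, length, 1L) < maxcol)
  if (length(short)) {
    stop_parse("row %d: expected at least %d columns", short[1L], maxcol)
  }
  col <- function(j) vapply(rows, `[[`, "", j)
  chrom <- col(spec$chrom_col)
  start <- suppressWarnings(as.numeric(col(spec$start_col)))
  if (anyNA(start)) {
    stop_parse("row %d: non-numeric start coordinate", which(is.na(start))[1L])
  }
  start <- start - spec$base
  value <- if (!is.null(spec$value_col)) {
    raw <- col(spec$value_col)
    num <- suppressWarnings(as.numeric(raw))
    if (anyNA(num)) raw else num
  }
  tr <- if (is.null(spec$end_col)) {
    point_track(chrom, start, value = value, name = name)
  } else {
    end <- suppressWarnings(as.numeric(col(spec$end_col)))
    if (anyNA(end)) {
      stop_parse("row %d: non-numeric end coordinate", which(is.na(end))[1L])
    }
    end <- end - spec$base + if (spec$end_inclusive) 1 else 0
    segment_track(chrom, start, end, value = value, name = name)
  }
  check_track_bounds(tr, genome, path)
  tr
}
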