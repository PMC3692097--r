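# Batch command language -------------------------------------------------------
#
# A batch file holds one analysis command per line: a tool name followed by
# whitespace-separated fields. '#' starts a comment; double quotes protect
# fields with spaces (and suppress expansion). Two expansions give bulk
# execution:
#   a/b/c   alternatives: the command is run once per alternative; several
#           multi-valued fields expand as a cartesian product in field order
#           (or in lock-step with zip = TRUE)
#   *       in a field that contains a '*' the whole field is treated as a
#           path glob under the track root and expands to every matching
#           file, sorted lexicographically ('/' is then a path separator,
#           not an alternative separator)

tokenize_batch_line <- function(line) {
  toks <- character(0); quoted <- logical(0)
  i <- 1L; n <- nchar(line)
  while (i <= n) {
    ch <- substr(line, i, i)
    if (grepl("^[ \t]$", ch)) { i <- i + 1L; next }
    if (ch == "#") break
    if (ch == "\"") {
      j <- i + 1L
      while (j <= n && substr(line, j, j) != "\"") j <- j + 1L
      if (j > n) stop_parse("unterminated quote")
      toks <- c(toks, substr(line, i + 1L, j - 1L)); quoted <- c(quoted, TRUE)
      i <- j + 1L
    } else {
      j <- i
      while (j <= n && !grepl("^[ \t]$", substr(line, j, j))) j <- j + 1L
      toks <- c(toks, substr(line, i, j - 1L)); quoted <- c(quoted, FALSE)
      i <- j
    }
  }
  list(tokens = toks, quoted = quoted)
}

field_alternatives <- function(token, quoted, track_root) {
  if (quoted) return(token)
  if (grepl("*", token, fixed = TRUE)) {
    pat <- if (!is.null(track_root)) file.path(track_root, token) else token
    hits <- sort(Sys.glob(pat))
    hits <- hits[!dir.exists(hits)]
    if (length(hits) == 0L) {
      stop_parse("'%s' matches no track files under %s", token,
                 track_root %||% ".")
    }
    return(hits)
  }
  strsplit(token, "/", fixed = TRUE)[[1L]]
}

#' Expand a batch command text into concrete commands
#'
#' @param lines Character vector of batch lines (or a single string with
#'   embedded newlines).
#' @param track_root Directory against which `*` globs are resolved.
#' @param zip Expand multiple multi-valued fields in lock-step instead of
#'   as a cartesian product (all multi-valued fields must then have the
#'   same number of alternatives).
#' @return List of `batch_command` objects (`$tool`, `$args`); the total
#'   expansion count is `length()` of the result.
#' @export
expand_batch <- function(lines, track_root = NULL, zip = FALSE) {
  lines <- unlist(strsplit(lines, "\n", fixed = TRUE))
  out <- list()
  for (ln in seq_along(lines)) {
    tk <- tryCatch(tokenize_batch_line(lines[ln]), trackstat_error = function(e)
      stop_parse("batch line %d: %s", ln, conditionMessage(e)))
    if (length(tk$tokens) == 0L) next
    alts <- mapply(field_alternatives, tk$tokens, tk$quoted,
                   MoreArgs = list(track_root = track_root), SIMPLIFY = FALSE)
    counts <- lengths(alts)
    combos <- if (zip) {
      k <- max(counts)
      if (!all(counts %in% c(1L, k))) {
        stop_parse("batch line %d: zip expansion needs equal alternative counts",
                   ln)
      }
      lapply(seq_len(k), function(i)
        vapply(alts, function(a) a[[min(i, length(a))]], ""))
    } else {
      cb <- list(character(0))
      for (a in alts) {
        cb <- unlist(lapply(cb, function(pre)
          lapply(a, function(x) c(pre, x))), recursive = FALSE)
      }
      cb
    }
    for (fields in combos) {
      out <- c(out, list(structure(
        list(tool = fields[[1L]], args = fields[-1L], line = ln),
        class = "batch_command")))
    }
  }
  out
}

#' @export
print.batch_command <- function(x, ...) {
  cat(sprintf("<batch_command: %s %s>\n", x$tool, paste(x$args, collapse = " ")))
  invisible(x)
}

format_from_path <- function(path) {
  switch(tolower(tools::file_ext(path)),
         bed = "bed", bedgraph = "bedgraph", bg = "bedgraph", wig = "wig",
         gtrack = "gtrack",
         stop_invalid_parameter("cannot infer track format of '%s'", path))
}

split_kv_args <- function(args) {
  iskv <- grepl("^[A-Za-z_]+=", args)
  kv <- strsplit(args[iskv], "=", fixed = TRUE)
  opts <- lapply(kv, function(x) paste(x[-1L], collapse = "="))
  names(opts) <- vapply(kv, `[[`, "", 1L)
  list(pos = args[!iskv], opts = opts)
}

# Execute one concrete command; returns a list(result_lines, table,
# input_files).
exec_batch_command <- function(cmd, config) {
  a <- split_kv_args(cmd$args)
  genome <- config$genome
  bins <- config$bins %||% {
    if (!is.null(config$bin_size)) make_bins(genome, config$bin_size) else
      make_bins(genome, max(genome$chromosomes))
  }
  seed <- as.integer(a$opts$seed %||% config$seed %||% 1L)
  load_tr <- function(path) {
    read_track(path, format_from_path(path), genome)
  }
  switch(cmd$tool,
    describe = {
      stat <- a$pos[1L]
      t1 <- load_tr(a$pos[2L])
      t2 <- if (length(a$pos) >= 3L) load_tr(a$pos[3L])
      res <- switch(stat,
        count = if (track_type(t1) %in% c("P", "VP")) point_stats(t1, bins)
          else coverage_stats(t1, bins),
        coverage = coverage_stats(t1, bins),
        enrichment = overlap_and_enrichment(t1, t2, bins),
        nearest = nearest_distances(t1, t2, bins),
        inside = points_in_segments(t1, t2, bins),
        correlation = pearson_correlation(t1, t2, bins),
        stop_invalid_parameter("unknown describe statistic '%s'", stat))
      gl <- res$global[vapply(res$global, function(v)
        is.numeric(v) && length(v) == 1L, TRUE)]
      list(result_lines = c(sprintf("statistic: %s", res$statistic),
                            sprintf("global %s: %g", names(gl), unlist(gl))),
           table = res$per_bin,
           input_files = a$pos[-1L])
    },
    test = {
      question <- a$pos[1L]
      t1 <- load_tr(a$pos[2L])
      t2 <- load_tr(a$pos[3L])
      null <- if (!is.null(a$opts$null))
        null_model_spec(a$opts$null, seed = seed)
      spec <- test_spec(question, t1, t2, bins, null = null,
                        alternative = a$opts$alt %||% "more",
                        mc = mc_params(seed = seed))
      res <- run_test(spec)
      list(result_lines = report_test(res), table = res$per_bin,
           input_files = a$pos[2:3])
    },
    convert = {
      t1 <- load_tr(a$pos[1L])
      write_track(t1, a$pos[2L], format_from_path(a$pos[2L]))
      list(result_lines = sprintf("converted %s -> %s (%d elements)",
                                  a$pos[1L], a$pos[2L], n_elements(t1)),
           table = NULL, input_files = a$pos[1L])
    },
    simulate = {
      tr <- simulate_track(genome, as.integer(a$pos[1L]),
                           track_type = a$pos[2L] %||% "P", seed = seed)
      write_track(tr, a$pos[3L], format_from_path(a$pos[3L]))
      list(result_lines = sprintf("simulated %d elements -> %s",
                                  n_elements(tr), a$pos[3L]),
           table = NULL, input_files = character(0))
    },
    stop_invalid_parameter("unknown batch tool '%s'", cmd$tool))
}

#' Execute a list of batch commands with per-command reports
#'
#' Each command is run in isolation: a failure is captured into that
#' command's report and does not abort the batch (the batch status is then
#' nonzero). Every report echoes the tool, all parameters, input file MD5
#' checksums, the seed and the package version, so any result can be
#' reproduced from its report alone.
#'
#' @param commands List of `batch_command`s from [expand_batch()].
#' @param config List: `genome` (a [genome()] or chrom.sizes path),
#'   `out_dir`, optional `bin_size` (default: one bin per chromosome),
#'   `seed`.
#' @return Character vector of report paths; `attr(, "status")` is 0 iff
#'   all commands succeeded.
#' @export
run_batch <- function(commands, config) {
  if (is.character(config$genome)) {
    config$genome <- read_chrom_sizes(config$genome)
  }
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  status <- 0L
  reports <- character(0)
  for (i in seq_along(commands)) {
    cmd <- commands[[i]]
    rpath <- file.path(out_dir, sprintf("cmd_%03d_report.txt", i))
    tpath <- file.path(out_dir, sprintf("cmd_%03d_result.tsv", i))
    res <- tryCatch(exec_batch_command(cmd, config), error = function(e) e)
    hdr <- c(sprintf("command: %s %s", cmd$tool, paste(cmd$args, collapse = " ")),
             sprintf("library-of-statistics version: trackstat %s",
                     as.character(utils::packageVersion("trackstat"))),
             sprintf("genome: %s", config$genome$name),
             sprintf("seed: %s", config$seed %||% 1L))
    files <- if (!inherits(res, "error")) res$input_files else character(0)
    files <- files[file.exists(files)]
    if (length(files)) {
      hdr <- c(hdr, sprintf("input checksum: %s  %s", tools::md5sum(files),
                            files))
    }
    if (inherits(res, "error")) {
      status <- 1L
      writeLines(c(hdr, sprintf("status: FAILED"),
                   sprintf("error: %s", conditionMessage(res))), rpath)
    } else {
      writeLines(c(hdr, "status: ok", res$result_lines), rpath)
      if (!is.null(res$table)) {
        utils::write.table(res$table, tpath, sep = "\t", quote = FALSE,
                           row.names = FALSE)
      }
    }
    reports <- c(reports, rpath)
  }
  structure(reports, status = status)
}
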