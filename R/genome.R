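#' Define a genome assembly
#'
#' A genome is a named, ordered collection of chromosomes with their lengths
#' in base pairs. All tracks and analysis bins are interpreted against a
#' genome; coordinates are 0-based and half-open throughout the package.
#'
#' @param name Text label for the assembly (e.g. `"toy1"`, `"hg19"`).
#' @param chromosomes Named numeric vector of chromosome lengths in bp;
#'   names are chromosome names and must be unique, lengths must be positive.
#' @return An object of class `"genome"`.
#' @examples
#' g <- genome("toy", c(chr1 = 1000, chr2 = 500))
#' genome_length(g)
#' @export
genome <- function(name, chromosomes) {
  if (is.null(names(chromosomes)) || any(names(chromosomes) == "")) {
    stop_invalid_parameter("all chromosomes must be named")
  }
  if (anyDuplicated(names(chromosomes))) {
    stop_invalid_parameter("chromosome names must be unique")
  }
  if (any(chromosomes <= 0) || any(!is.finite(chromosomes))) {
    stop_invalid_parameter("all chromosome lengths must be positive")
  }
  structure(list(name = name, chromosomes = as.numeric(chromosomes),
                 chrom_names = names(chromosomes)),
            class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome '%s': %d chromosome(s), %s bp>\n",
              x$name, length(x$chromosomes),
              format(sum(x$chromosomes), big.mark = ",", scientific = FALSE)))
  invisible(x)
}

#' Total genome length in bp
#' @param genome A [genome()] object.
#' @return Numeric scalar.
#' @export
genome_length <- function(genome) sum(genome$chromosomes)

chrom_length <- function(genome, chrom) {
  i <- match(chrom, genome$chrom_names)
  if (anyNA(i)) {
    stop_validation("unknown chromosome(s): %s",
                    paste(unique(chrom[is.na(i)]), collapse = ", "))
  }
  genome$chromosomes[i]
}

#' Read a UCSC chrom.sizes file as a genome
#'
#' Two tab- (or whitespace-) separated columns: chromosome name and length.
#'
#' @param path Path to the chrom.sizes file.
#' @param name Assembly label; defaults to the file name.
#' @return A [genome()] object.
#' @export
read_chrom_sizes <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop_parse("chrom.sizes file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(vapply(parts, length, 1L) < 2L)
  if (length(bad)) stop_parse("chrom.sizes line %d: expected two columns", bad[1L])
  lens <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  if (anyNA(lens)) {
    stop_parse("chrom.sizes line %d: non-numeric length",
               which(is.na(lens))[1L])
  }
  names(lens) <- vapply(parts, `[[`, "", 1L)
  genome(name, lens)
}
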