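# Classed condition helpers -------------------------------------------------

ts_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "trackstat_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stop_invalid_parameter <- function(msg, ...) ts_stop("invalid_parameter_error", msg, ...)
stop_parse             <- function(msg, ...) ts_stop("parse_error", msg, ...)
stop_validation        <- function(msg, ...) ts_stop("validation_error", msg, ...)
stop_capability        <- function(msg, ...) ts_stop("capability_error", msg, ...)
stop_type              <- function(msg, ...) ts_stop("type_error", msg, ...)
stop_feasibility       <- function(msg, ...) ts_stop("feasibility_error", msg, ...)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Interval primitives --------------------------------------------------------
#
# All coordinates are 0-based half-open [start, end). Points are zero-width
# intervals (start == end). These are plain-vector routines because they sit
# inside the Monte Carlo resampling loop where per-call overhead dominates.

# Union of intervals. adjacent = TRUE merges book-ended intervals as well.
iv_merge <- function(start, end, adjacent = TRUE) {
  n <- length(start)
  if (n == 0L) return(list(start = numeric(0), end = numeric(0)))
  o <- order(start, end)
  s <- start[o]; e <- end[o]
  if (n == 1L) return(list(start = s, end = e))
  emax <- cummax(e)
  # interval i starts a new run if its start exceeds (or equals, when not
  # merging adjacency) the running max end of all previous intervals
  newrun <- if (adjacent) s > c(-Inf, emax[-n]) else s >= c(-Inf, emax[-n])
  newrun[1L] <- TRUE
  grp <- cumsum(newrun)
  list(start = s[newrun], end = as.numeric(tapply(emax, grp, max)))
}

iv_total_bp <- function(start, end) sum(end - start)

# Covered bp of the merged, sorted set (s, e) lying in [0, x), vectorized in x.
iv_covered_before <- function(x, s, e, cumcov = cumsum(e - s)) {
  i <- findInterval(x, s)
  out <- numeric(length(x))
  hit <- i > 0L
  ih <- i[hit]
  out[hit] <- cumcov[ih] - pmax(0, e[ih] - x[hit])
  out
}

# Total intersection bp between two interval sets (each unioned first).
iv_intersect_bp <- function(s1, e1, s2, e2) {
  if (length(s1) == 0L || length(s2) == 0L) return(0)
  a <- iv_merge(s1, e1); b <- iv_merge(s2, e2)
  cc <- cumsum(b$end - b$start)
  sum(iv_covered_before(a$end, b$start, b$end, cc) -
      iv_covered_before(a$start, b$start, b$end, cc))
}

# Intersect query intervals with a sorted, non-overlapping region set.
# Returns the query index alongside each clipped piece.
iv_intersect_regions <- function(qs, qe, rs, re) {
  nq <- length(qs)
  if (nq == 0L || length(rs) == 0L) {
    return(list(q = integer(0), start = numeric(0), end = numeric(0)))
  }
  i1 <- findInterval(qs, re) + 1L                      # first region with re > qs
  i2 <- findInterval(qe, rs, left.open = TRUE)         # last region with rs < qe
  nhit <- pmax(0L, i2 - i1 + 1L)
  keep <- nhit > 0L
  if (!any(keep)) {
    return(list(q = integer(0), start = numeric(0), end = numeric(0)))
  }
  qidx <- rep.int(which(keep), nhit[keep])
  ridx <- sequence(nhit[keep], from = i1[keep])
  list(q = qidx,
       start = pmax(qs[qidx], rs[ridx]),
       end   = pmin(qe[qidx], re[ridx]),
       region = ridx)
}

# For zero-width or wide queries, distance to the nearest interval of a
# sorted non-overlapping subject set: max(0, ss - qe, qs - se), minimized.
iv_nearest_dist <- function(qs, qe, ss, se) {
  nq <- length(qs)
  if (nq == 0L) return(numeric(0))
  if (length(ss) == 0L) return(rep(NA_real_, nq))
  i <- findInterval(qs, ss)
  d_lo <- ifelse(i >= 1L, pmax(0, qs - se[pmax(i, 1L)]), Inf)
  ip1 <- i + 1L
  d_hi <- ifelse(ip1 <= length(ss), pmax(0, ss[pmin(ip1, length(ss))] - qe), Inf)
  pmin(d_lo, d_hi)
}

# Nearest subject *point* index for query points (both sorted not required
# for queries; subjects must be sorted). Ties resolve to the earlier subject.
pt_nearest_idx <- function(q, p) {
  if (length(p) == 0L) return(rep(NA_integer_, length(q)))
  i <- findInterval(q, p)
  lo <- pmax(i, 1L)
  hi <- pmin(i + 1L, length(p))
  d_lo <- ifelse(i >= 1L, abs(q - p[lo]), Inf)
  d_hi <- ifelse(i + 1L <= length(p), abs(p[hi] - q), Inf)
  ifelse(d_lo <= d_hi, lo, hi)
}

# Are points contained in the merged sorted segment set? (s <= p < e)
pt_inside <- function(p, ss, se) {
  if (length(ss) == 0L) return(rep(FALSE, length(p)))
  i <- findInterval(p, ss)
  i > 0L & p < se[pmax(i, 1L)]
}

# Index of the containing segment among *sorted possibly-overlapping*
# segments; NA when uncontained. When several segments contain the point the
# one with the greatest start (innermost by start) is returned. The cummax
# bound keeps the back-walk short for realistic overlap depths.
pt_containing_seg <- function(p, ss, se) {
  if (length(ss) == 0L) return(rep(NA_integer_, length(p)))
  i <- findInterval(p, ss)
  emax <- cummax(se)
  out <- rep(NA_integer_, length(p))
  for (k in which(i > 0L)) {
    for (j in i[k]:1L) {
      if (p[k] < se[j]) { out[k] <- j; break }
      if (emax[j] <= p[k]) break     # nothing earlier can reach past p
    }
  }
  out
}

# Deterministic child seed derivation: one root stream per analysis, one
# substream per bin, independent of bin evaluation order. Kept below 2^31.
child_seed <- function(root, i) {
  as.integer((abs(as.numeric(root)) * 48271 + as.numeric(i) * 16807 + 11) %%
               2147483629)
}

# Run expr under a saved RNG state, returning list(value, state).
with_rng_state <- function(state, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  if (is.null(state$seed_vec)) set.seed(state$seed) else
    assign(".Random.seed", state$seed_vec, envir = globalenv())
  val <- force(expr)
  list(value = val,
       state = list(seed = state$seed,
                    seed_vec = get(".Random.seed", envir = globalenv())))
}

fmt_num <- function(x) sprintf("%.17g", x)
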