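# Hypothesis tests ------------------------------------------------------------
#
# Each question is a generic genomic test statistic plus a default null
# model. P-values come from Monte Carlo permutation with the MCFDR
# sequential sampling scheme (samples are added in rounds until a test is
# either FDR-significant or its p-value is precisely estimated), or from a
# closed-form asymptotic route where one is standard. Results are reported
# per analysis bin and globally, with Benjamini-Hochberg adjustment across
# bins.

#' Monte Carlo / MCFDR parameters
#'
#' @param chunk Null samples added per sequential round, per active bin.
#' @param h Exceedance stop count: a bin stops sampling once `h` null
#'   samples at least as extreme as the observed statistic have accrued
#'   (its p-value is then precisely estimated).
#' @param q FDR significance threshold: a bin stops once its BH-adjusted
#'   p-value drops to `q` or below.
#' @param max_samples Hard cap on null samples per bin.
#' @param seed Root seed; per-bin child streams are derived from it.
#' @return An `mc_params` object.
#' @export
mc_params <- function(chunk = 100, h = 20, q = 0.05, max_samples = 10000,
                      seed = 1L) {
  if (chunk < 1 || h < 1 || q <= 0 || q >= 1 || max_samples < chunk) {
    stop_invalid_parameter(
      "need chunk >= 1, h >= 1, 0 < q < 1, max_samples >= chunk")
  }
  structure(list(chunk = as.integer(chunk), h = as.integer(h), q = q,
                 max_samples = as.integer(max_samples),
                 seed = as.integer(seed)),
            class = "mc_params")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted values; monotone and never below the raw p-values.
#' A thin wrapper around [stats::p.adjust()] that tolerates empty input.
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @return Adjusted values of the same length.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  stats::p.adjust(pvalues, method = "BH")
}

# Question registry -----------------------------------------------------------
# req1/req2: geometric/value requirement codes --
#   P any points, S any segments, F function, VPnum/VSnum numeric-valued,
#   VPcc/VScc case-control, VPcat/VScat categorical, PS points-or-segments
# rand: what the default null randomizes --
#   pos1 positional randomization of track1 (uniform_independent default;
#        preserve_gaps / intensity_guided selectable),
#   val1/val2 value permutation, lab1/lab2 label permutation,
#   freq source-label permutation of the two merged point sets
# direction: +1 when larger statistic = more of the "more" effect
QUESTIONS <- list(
  frequency_difference = list(req1 = "P", req2 = "P", rand = "freq",
                              direction = +1, asymptotic = TRUE),
  nearby = list(req1 = "PS", req2 = "PS", rand = "pos1", direction = +1,
                asymptotic = FALSE),   # statistic already sign-flipped
  inside = list(req1 = "P", req2 = "S", rand = "pos1", direction = +1,
                asymptotic = FALSE),
  border = list(req1 = "P", req2 = "S", rand = "pos1", direction = -1,
                asymptotic = FALSE),
  similar_segments = list(req1 = "S", req2 = "S", rand = "pos1",
                          direction = +1, asymptotic = FALSE),
  overlap = list(req1 = "S", req2 = "S", rand = "pos1", direction = +1,
                 asymptotic = FALSE),
  correlation = list(req1 = "F", req2 = "F", rand = "val2", direction = +1,
                     asymptotic = TRUE),
  values_at_points = list(req1 = "P", req2 = "F", rand = "pos1",
                          direction = +1, asymptotic = FALSE),
  values_inside = list(req1 = "S", req2 = "F", rand = "pos1", direction = +1,
                       asymptotic = FALSE),
  value_landing = list(req1 = "P", req2 = "VSnum", rand = "val2",
                       direction = +1, asymptotic = FALSE),
  inside_vs_outside_values = list(req1 = "S", req2 = "VPnum", rand = "val2",
                                  direction = +1, asymptotic = FALSE),
  nearby_values = list(req1 = "VPnum", req2 = "VPnum", rand = "val1",
                       direction = -1, asymptotic = FALSE),
  case_landing = list(req1 = "P", req2 = "VScc", rand = "lab2",
                      direction = +1, asymptotic = FALSE),
  preferential_overlap = list(req1 = "VScc", req2 = "S", rand = "lab1",
                              direction = +1, asymptotic = FALSE),
  differential_colocation = list(req1 = "VPcat", req2 = "VScat",
                                 rand = "lab1", direction = +1,
                                 asymptotic = TRUE)
)

matches_req <- function(track, req) {
  if (is.null(track)) return(FALSE)
  switch(req,
    P = is_point_type(track),
    S = is_segment_type(track),
    PS = is_point_type(track) || is_segment_type(track),
    F = track$type == "F",
    VPnum = track$type == "VP" && track$value_kind == "number",
    VSnum = track$type == "VS" && track$value_kind == "number",
    VPcc = track$type == "VP" && track$value_kind == "case_control",
    VScc = track$type == "VS" && track$value_kind == "case_control",
    VPcat = track$type == "VP" && track$value_kind == "category",
    VScat = track$type == "VS" && track$value_kind == "category",
    FALSE)
}

# The type-driven menu: which questions are valid for the supplied tracks.
valid_questions <- function(track1, track2) {
  names(Filter(function(info) matches_req(track1, info$req1) &&
                 matches_req(track2, info$req2), QUESTIONS))
}

check_question_types <- function(question, track1, track2) {
  info <- QUESTIONS[[question]]
  if (is.null(info)) {
    stop_invalid_parameter("unknown question '%s'; available: %s", question,
                           paste(names(QUESTIONS), collapse = ", "))
  }
  if (!matches_req(track1, info$req1) || !matches_req(track2, info$req2)) {
    ok <- valid_questions(track1, track2)
    stop_type(paste0(
      "question '%s' needs track types (%s, %s); supplied (%s, %s). ",
      "Analyses valid for the supplied tracks: %s"),
      question, info$req1, info$req2,
      track1$type, if (is.null(track2)) "none" else track2$type,
      if (length(ok)) paste(ok, collapse = ", ") else "none")
  }
  info
}

#' Specify a hypothesis test
#'
#' @param question Question id; one of `names(trackstat_questions())`.
#' @param track1,track2 The tracks under test (types must match the
#'   question's requirements).
#' @param regions A [bin_set()] of analysis bins.
#' @param null A [null_model_spec()]; `NULL` selects the question's default
#'   null model.
#' @param alternative `"more"`, `"less"` or `"different"`.
#' @param mc [mc_params()] for the Monte Carlo evaluation.
#' @param evaluation `"auto"` (asymptotic where standard, otherwise Monte
#'   Carlo), `"monte_carlo"`, or `"asymptotic"`.
#' @return A `test_spec` for [run_test()].
#' @export
test_spec <- function(question, track1, track2, regions, null = NULL,
                      alternative = c("more", "less", "different"),
                      mc = mc_params(),
                      evaluation = c("auto", "monte_carlo", "asymptotic")) {
  alternative <- match.arg(alternative)
  evaluation <- match.arg(evaluation)
  info <- check_question_types(question, track1, track2)
  if (evaluation == "asymptotic" && !info$asymptotic) {
    stop_capability("question '%s' has no asymptotic route", question)
  }
  structure(list(question = question, track1 = track1, track2 = track2,
                 regions = regions, null = null, alternative = alternative,
                 mc = mc, evaluation = evaluation),
            class = "test_spec")
}

#' Available questions and their track-type requirements
#' @return Named list of question metadata.
#' @export
trackstat_questions <- function() QUESTIONS

# Per-bin context --------------------------------------------------------------

build_bin_ctx <- function(question, track1, track2, bins, null) {
  info <- QUESTIONS[[question]]
  el1 <- track1$elements
  el2 <- if (!is.null(track2)) track2$elements
  f1v <- if (track1$type == "F") f_values_on_bins(track1, bins)
  f2v <- if (!is.null(track2) && track2$type == "F")
    f_values_on_bins(track2, bins)
  lapply(seq_len(nrow(bins)), function(i) {
    b <- list(L = bins$end[i] - bins$start[i], bs = bins$start[i],
              chrom = bins$chrom[i])
    r1 <- rows_in_bin(el1, bins, i)
    if (is_point_type(track1)) {
      b$p1 <- el1$start[r1]; b$v1 <- el1$value[r1]
    } else if (is_segment_type(track1)) {
      b$s1 <- el1$start[r1]; b$e1 <- el1$end[r1]; b$v1 <- el1$value[r1]
      b$len1 <- b$e1 - b$s1
    } else b$f1 <- f1v[[i]]
    if (!is.null(track2)) {
      r2 <- rows_in_bin(el2, bins, i)
      if (is_point_type(track2)) {
        b$p2 <- el2$start[r2]; b$v2 <- el2$value[r2]
        m <- iv_merge(b$p2, b$p2)
        b$m2s <- m$start; b$m2e <- m$end
      } else if (is_segment_type(track2)) {
        b$s2 <- el2$start[r2]; b$e2 <- el2$end[r2]; b$v2 <- el2$value[r2]
        m <- iv_merge(b$s2, b$e2)
        b$m2s <- m$start; b$m2e <- m$end
        b$cum2 <- cumsum(b$m2e - b$m2s)
      } else b$f2 <- f2v[[i]]
    }
    if (info$rand == "pos1" && !is.null(null) &&
        null$model == "intensity_guided") {
      b$w <- intensity_weights(null$intensity, bins$chrom[i], bins$start[i],
                               bins$end[i])
    }
    b
  })
}

# Statistic functions: each takes a list of per-bin contexts and returns a
# single number computed over all of them (NA when undefined).

stat_fun_for <- function(question) {
  switch(question,
    overlap = function(ctxs) {
      tot <- 0
      for (b in ctxs) {
        if (length(b$s1) == 0L || length(b$m2s) == 0L) next
        m1 <- iv_merge(b$s1, b$e1)
        tot <- tot + sum(iv_covered_before(m1$end, b$m2s, b$m2e, b$cum2) -
                           iv_covered_before(m1$start, b$m2s, b$m2e, b$cum2))
      }
      tot
    },
    inside = function(ctxs) {
      tot <- 0; any1 <- FALSE
      for (b in ctxs) {
        if (length(b$p1) == 0L) next
        any1 <- TRUE
        tot <- tot + sum(pt_inside(b$p1, b$m2s, b$m2e))
      }
      if (any1) tot else NA_real_
    },
    nearby = function(ctxs) {
      s <- 0; n <- 0
      for (b in ctxs) {
        qs <- if (is.null(b$s1)) b$p1 else b$s1
        qe <- if (is.null(b$s1)) b$p1 else b$e1
        if (length(qs) == 0L || length(b$m2s) == 0L) next
        d <- iv_nearest_dist(qs, qe, b$m2s, b$m2e)
        s <- s + sum(d); n <- n + length(d)
      }
      if (n > 0) -s / n else NA_real_   # sign flipped: larger = closer
    },
    border = function(ctxs) {
      acc <- 0; n <- 0
      for (b in ctxs) {
        if (length(b$p1) == 0L || length(b$s2) == 0L) next
        ci <- pt_containing_seg(b$p1, b$s2, b$e2)
        hit <- !is.na(ci)
        if (!any(hit)) next
        r <- (b$p1[hit] - b$s2[ci[hit]]) / (b$e2[ci[hit]] - b$s2[ci[hit]])
        acc <- acc + sum(pmin(r, 1 - r)); n <- n + sum(hit)
      }
      if (n > 0) acc / n else NA_real_  # small = border-heavy
    },
    similar_segments = function(ctxs) {
      acc <- 0; n <- 0
      for (b in ctxs) {
        if (length(b$s1) == 0L) next
        for (j in seq_along(b$s1)) {
          s <- b$s1[j]; e <- b$e1[j]
          cand <- which(b$s2 < e & b$e2 > s)
          bj <- 0
          if (length(cand)) {
            inter <- pmin(e, b$e2[cand]) - pmax(s, b$s2[cand])
            uni <- pmax(e, b$e2[cand]) - pmin(s, b$s2[cand])
            bj <- max(inter / uni)
          }
          acc <- acc + bj; n <- n + 1
        }
      }
      if (n > 0) acc / n else NA_real_
    },
    correlation = function(ctxs) {
      x <- numeric(0); y <- numeric(0)
      for (b in ctxs) {
        ok <- !is.na(b$f1) & !is.na(b$f2)
        x <- c(x, b$f1[ok]); y <- c(y, b$f2[ok])
      }
      if (length(x) >= 2L && stats::sd(x) > 0 && stats::sd(y) > 0)
        stats::cor(x, y) else NA_real_
    },
    values_at_points = function(ctxs) {
      s <- 0; n <- 0
      for (b in ctxs) {
        if (length(b$p1) == 0L) next
        v <- b$f2[b$p1 - b$bs + 1]
        v <- v[!is.na(v)]
        s <- s + sum(v); n <- n + length(v)
      }
      if (n > 0) s / n else NA_real_
    },
    values_inside = function(ctxs) {
      s <- 0; n <- 0
      for (b in ctxs) {
        if (length(b$s1) == 0L) next
        m1 <- iv_merge(b$s1, b$e1)
        idx <- unlist(mapply(function(s0, e0) seq(s0, e0 - 1), m1$start,
                             m1$end, SIMPLIFY = FALSE)) - b$bs + 1
        v <- b$f2[idx]; v <- v[!is.na(v)]
        s <- s + sum(v); n <- n + length(v)
      }
      if (n > 0) s / n else NA_real_
    },
    value_landing = function(ctxs) {
      dens <- numeric(0); val <- numeric(0)
      for (b in ctxs) {
        if (length(b$s2) == 0L) next
        cnt <- vapply(seq_along(b$s2), function(j)
          sum(b$p1 >= b$s2[j] & b$p1 < b$e2[j]), 1)
        dens <- c(dens, cnt / (b$e2 - b$s2)); val <- c(val, b$v2)
      }
      if (length(dens) >= 2L && stats::sd(dens) > 0 && stats::sd(val) > 0)
        stats::cor(val, dens) else NA_real_
    },
    inside_vs_outside_values = function(ctxs) {
      si <- 0; ni <- 0; so <- 0; no <- 0
      for (b in ctxs) {
        if (length(b$p2) == 0L) next
        m1 <- iv_merge(b$s1 %||% numeric(0), b$e1 %||% numeric(0))
        ins <- pt_inside(b$p2, m1$start, m1$end)
        si <- si + sum(b$v2[ins]); ni <- ni + sum(ins)
        so <- so + sum(b$v2[!ins]); no <- no + sum(!ins)
      }
      if (ni > 0 && no > 0) si / ni - so / no else NA_real_
    },
    nearby_values = function(ctxs) {
      s <- 0; n <- 0
      for (b in ctxs) {
        if (length(b$p1) == 0L || length(b$p2) == 0L) next
        o2 <- order(b$p2)
        idx <- pt_nearest_idx(b$p1, b$p2[o2])
        s <- s + sum(abs(b$v1 - b$v2[o2][idx])); n <- n + length(idx)
      }
      if (n > 0) s / n else NA_real_    # small = values more similar
    },
    case_landing = function(ctxs) {
      nc <- 0; bc <- 0; nk <- 0; bk <- 0
      for (b in ctxs) {
        if (length(b$s2) == 0L) next
        ca <- b$v2 == "case"
        mc_ <- iv_merge(b$s2[ca], b$e2[ca])
        mk <- iv_merge(b$s2[!ca], b$e2[!ca])
        nc <- nc + sum(pt_inside(b$p1, mc_$start, mc_$end))
        nk <- nk + sum(pt_inside(b$p1, mk$start, mk$end))
        bc <- bc + iv_total_bp(mc_$start, mc_$end)
        bk <- bk + iv_total_bp(mk$start, mk$end)
      }
      if (bc > 0 && bk > 0) nc / bc - nk / bk else NA_real_
    },
    preferential_overlap = function(ctxs) {
      oc <- 0; bc <- 0; ok_ <- 0; bk <- 0
      for (b in ctxs) {
        if (length(b$s1) == 0L || length(b$m2s) == 0L) next
        ca <- b$v1 == "case"
        mc_ <- iv_merge(b$s1[ca], b$e1[ca])
        mk <- iv_merge(b$s1[!ca], b$e1[!ca])
        ovl <- function(m) if (length(m$start))
          sum(iv_covered_before(m$end, b$m2s, b$m2e, b$cum2) -
                iv_covered_before(m$start, b$m2s, b$m2e, b$cum2)) else 0
        oc <- oc + ovl(mc_); ok_ <- ok_ + ovl(mk)
        bc <- bc + iv_total_bp(mc_$start, mc_$end)
        bk <- bk + iv_total_bp(mk$start, mk$end)
      }
      if (bc > 0 && bk > 0) oc / bc - ok_ / bk else NA_real_
    },
    differential_colocation = function(ctxs) {
      tab <- NULL
      for (b in ctxs) {
        if (length(b$p1) == 0L || length(b$s2) == 0L) next
        rl <- sort(unique(b$v1)); cl <- sort(unique(b$v2))
        t0 <- matrix(0, length(rl), length(cl), dimnames = list(rl, cl))
        for (cj in cl) {
          sel <- b$v2 == cj
          m <- iv_merge(b$s2[sel], b$e2[sel])
          ins <- pt_inside(b$p1, m$start, m$end)
          for (ri in rl) t0[ri, cj] <- sum(ins & b$v1 == ri)
        }
        tab <- if (is.null(tab)) t0 else merge_tables(tab, t0)
      }
      if (is.null(tab) || sum(tab) == 0) return(NA_real_)
      chisq_stat(tab)
    },
    frequency_difference = function(ctxs) {
      n1 <- vapply(ctxs, function(b) length(b$p1), 1)
      n2 <- vapply(ctxs, function(b) length(b$p2), 1)
      k <- n1 + n2
      if (sum(k) == 0) return(NA_real_)
      pg <- sum(n1) / sum(k)
      ok <- k > 0
      sum(k[ok] * (n1[ok] / k[ok] - pg)^2)
    },
    stop_invalid_parameter("unknown question '%s'", question))
}

merge_tables <- function(a, b) {
  rl <- union(rownames(a), rownames(b)); cl <- union(colnames(a), colnames(b))
  out <- matrix(0, length(rl), length(cl), dimnames = list(rl, cl))
  out[rownames(a), colnames(a)] <- a
  out[rownames(b), colnames(b)] <- out[rownames(b), colnames(b)] + b
  out
}

chisq_stat <- function(tab) {
  exp_ <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  ok <- exp_ > 0
  sum((tab[ok] - exp_[ok])^2 / exp_[ok])
}

#' Compute a question's test statistic on one bin
#'
#' The raw (unsigned) statistic as defined for the question: intersection
#' bp for overlap, inside count for containment, mean nearest distance with
#' the sign flipped for proximity, mean `min(relpos, 1-relpos)` for border
#' accumulation, and so on. `NA` when undefined (e.g. a required track is
#' empty in the bin).
#'
#' @param question Question id.
#' @param track1,track2 Tracks matching the question's type requirements.
#' @param bin A single region (data.frame row or list with `chrom`,
#'   `start`, `end`).
#' @return A single number.
#' @export
compute_statistic <- function(question, track1, track2, bin) {
  check_question_types(question, track1, track2)
  bins <- bin_set(as.character(bin$chrom), as.numeric(bin$start),
                  as.numeric(bin$end))
  ctxs <- build_bin_ctx(question, track1, track2, bins, NULL)
  stat_fun_for(question)(ctxs)
}

# Null draws -------------------------------------------------------------------

# Return a copy of bin context b with the randomized fields replaced,
# under the question's randomization target and the null model.
draw_null_bin <- function(b, info, null) {
  model <- if (is.null(null)) "uniform_independent" else null$model
  switch(info$rand,
    pos1 = {
      if (!is.null(b$p1)) {
        n <- length(b$p1)
        if (n) b$p1 <- b$bs + switch(model,
          uniform_independent = place_points_uniform(n, b$L),
          preserve_gaps = place_preserve_gaps(rep(0, n), diff(sort(b$p1 - b$bs)),
                                              b$L, zero_width = TRUE)$start,
          intensity_guided = place_points_intensity(n, b$w),
          stop_invalid_parameter("null model %s not usable here", model))
      } else {
        n <- length(b$s1)
        if (n) {
          p <- switch(model,
            uniform_independent = place_segments_uniform(b$len1, b$L),
            preserve_gaps = {
              o <- order(b$s1)
              place_preserve_gaps(b$len1[o],
                                  (b$s1[o])[-1L] - (b$e1[o])[-n], b$L)
            },
            stop_invalid_parameter("null model %s not usable here", model))
          b$s1 <- b$bs + p$start; b$e1 <- b$s1 + p$len
        }
      }
      b
    },
    val1 = { if (length(b$v1) > 1L) b$v1 <- b$v1[sample.int(length(b$v1))]; b },
    val2 = {
      if (!is.null(b$f2)) {
        def <- which(!is.na(b$f2))
        b$f2[def] <- b$f2[def][sample.int(length(def))]
      } else if (length(b$v2) > 1L) {
        b$v2 <- b$v2[sample.int(length(b$v2))]
      }
      b
    },
    lab1 = { if (length(b$v1) > 1L) b$v1 <- b$v1[sample.int(length(b$v1))]; b },
    lab2 = { if (length(b$v2) > 1L) b$v2 <- b$v2[sample.int(length(b$v2))]; b },
    stop_invalid_parameter("no null draw for randomization kind %s", info$rand))
}

# MCFDR engine -----------------------------------------------------------------

#' Sequential Monte Carlo p-values with FDR-driven stopping (MCFDR)
#'
#' Null samples are drawn in rounds of `mc$chunk` per still-active bin.
#' After each round the add-one p-value estimate `(x+1)/(n+1)` is updated
#' and BH-adjusted across all bins; a bin stops sampling when its
#' exceedance count reaches `mc$h` (precisely estimated null), when its
#' adjusted value drops to `mc$q` or below (significant), or at
#' `mc$max_samples`. Deterministic given the per-bin sampler's seeding.
#'
#' @param observed Numeric vector of per-bin observed statistics (`NA` =
#'   undefined; such bins are excluded from the FDR family).
#' @param sampler Function `(bin_index, m)` returning `m` null statistics
#'   for that bin.
#' @param mc [mc_params()].
#' @param alternative `"more"`, `"less"` or `"different"`.
#' @param direction +1 if larger statistics mean more of the "more"-side
#'   effect, -1 if smaller do.
#' @return A data.frame with per-bin `p`, `adjusted`, `significant`,
#'   `samples`, `exceedances`, `null_mean`.
#' @export
mcfdr_engine <- function(observed, sampler, mc = mc_params(),
                         alternative = c("more", "less", "different"),
                         direction = 1) {
  alternative <- match.arg(alternative)
  nb <- length(observed)
  eff_obs <- direction * observed
  n <- integer(nb); xm <- integer(nb); xl <- integer(nb); ssum <- numeric(nb)
  defined <- !is.na(observed)
  active <- which(defined)
  p_of <- function() {
    p <- rep(NA_real_, nb)
    pm <- (xm + 1) / (n + 1); pl <- (xl + 1) / (n + 1)
    p[defined] <- switch(alternative,
      more = pm[defined], less = pl[defined],
      different = pmin(1, 2 * pmin(pm[defined], pl[defined])))
    p
  }
  while (length(active)) {
    for (i in active) {
      m <- min(mc$chunk, mc$max_samples - n[i])
      s <- direction * sampler(i, m)
      n[i] <- n[i] + m
      xm[i] <- xm[i] + sum(s >= eff_obs[i])
      xl[i] <- xl[i] + sum(s <= eff_obs[i])
      ssum[i] <- ssum[i] + sum(direction * s)
    }
    p <- p_of()
    adj <- rep(NA_real_, nb)
    adj[defined] <- bh_adjust(p[defined])
    xstop <- switch(alternative, more = xm, less = xl,
                    different = pmin(xm, xl))
    active <- which(defined & xstop < mc$h & adj > mc$q & n < mc$max_samples)
  }
  p <- p_of()
  adj <- rep(NA_real_, nb)
  adj[defined] <- bh_adjust(p[defined])
  data.frame(p = p, adjusted = adj,
             significant = !is.na(adj) & adj <= mc$q,
             samples = n,
             exceedances = switch(alternative, more = xm, less = xl,
                                  different = pmin(xm, xl)),
             null_mean = ifelse(n > 0, ssum / n, NA_real_))
}

# Asymptotic routes ------------------------------------------------------------

#' Closed-form p-values for questions with a standard asymptotic route
#'
#' * `"correlation"`: t-transform of Pearson's r (`data = list(r, n)` or
#'   `list(x, y)`).
#' * `"differential_colocation"`: chi-square statistic of the contingency
#'   table (`data` = matrix); inherently two-sided.
#' * `"case_control_2x2"`: Fisher's exact test on a 2x2 table.
#' * `"frequency_difference"`: exact binomial for one bin
#'   (`data = list(n1, n, p0)`).
#'
#' @param question One of the ids above.
#' @param data Question-specific data, see details.
#' @param alternative `"more"`, `"less"` or `"different"`.
#' @return The p-value.
#' @export
asymptotic_test <- function(question, data,
                            alternative = c("more", "less", "different")) {
  alternative <- match.arg(alternative)
  alt_std <- c(more = "greater", less = "less", different = "two.sided")
  switch(question,
    correlation = {
      if (!is.null(data$x)) {
        data <- list(r = stats::cor(data$x, data$y), n = length(data$x))
      }
      r <- data$r; n <- data$n
      if (n < 3) return(NA_real_)
      tt <- r * sqrt((n - 2) / max(1e-300, 1 - r^2))
      switch(alternative,
        more = stats::pt(tt, n - 2, lower.tail = FALSE),
        less = stats::pt(tt, n - 2),
        different = 2 * stats::pt(abs(tt), n - 2, lower.tail = FALSE))
    },
    differential_colocation = {
      tab <- as.matrix(data)
      df <- (nrow(tab) - 1) * (ncol(tab) - 1)
      stats::pchisq(chisq_stat(tab), df, lower.tail = FALSE)
    },
    case_control_2x2 = {
      stats::fisher.test(as.matrix(data),
                         alternative = alt_std[[alternative]])$p.value
    },
    frequency_difference = {
      stats::binom.test(data$n1, data$n, data$p0,
                        alternative = alt_std[[alternative]])$p.value
    },
    stop_capability("question '%s' has no asymptotic route", question))
}

# run_test ---------------------------------------------------------------------

#' Run a hypothesis test on one or two tracks
#'
#' Computes the question's statistic per analysis bin and globally, then
#' evaluates p-values by sequential Monte Carlo (MCFDR) under the selected
#' null model, or by the asymptotic route where one is standard. The global
#' statistic is tested with its own Monte Carlo stream in which every bin
#' is randomized jointly (per-bin randomization concatenated), not by
#' pooling bin p-values.
#'
#' @param spec A [test_spec()].
#' @return A `test_result`: per-bin data.frame (`observed`, `null_mean`,
#'   `p`, `adjusted`, `significant`, `samples`, `exceedances`), a `global`
#'   list with the same fields, and a full parameter echo.
#' @export
run_test <- function(spec) {
  stopifnot(inherits(spec, "test_spec"))
  question <- spec$question
  info <- QUESTIONS[[question]]
  bins <- bin_set(as.data.frame(spec$regions))
  t1 <- clip_track(spec$track1, bins)
  t2 <- if (!is.null(spec$track2)) clip_track(spec$track2, bins)
  null <- spec$null
  if (!is.null(null) && info$rand != "pos1" &&
      null$model %in% c("uniform_independent", "preserve_gaps",
                        "intensity_guided")) {
    stop_invalid_parameter(
      "question '%s' randomizes %s; positional null '%s' does not apply",
      question, info$rand, null$model)
  }
  ctxs <- build_bin_ctx(question, t1, t2, bins, null)
  stat <- stat_fun_for(question)
  obs_bin <- vapply(ctxs, function(b) stat(list(b)), 1)
  obs_global <- stat(ctxs)
  route <- spec$evaluation
  if (route == "auto") {
    route <- if (question %in% c("correlation", "frequency_difference"))
      "asymptotic" else "monte_carlo"
  }
  if (route == "asymptotic" && !info$asymptotic) {
    stop_capability("question '%s' has no asymptotic route", question)
  }
  per_bin <- bin_frame(bins)
  per_bin$observed <- obs_bin
  echo <- list(question = question, alternative = spec$alternative,
               evaluation = route,
               null_model = if (info$rand == "pos1")
                 (if (is.null(null)) "uniform_independent" else null$model)
               else c(pos1 = "positional", val1 = "permute_values",
                      val2 = "permute_values", lab1 = "permute_labels",
                      lab2 = "permute_labels", freq = "permute_labels")[[info$rand]],
               randomized = info$rand, direction = info$direction,
               mc = unclass(spec$mc), seed = spec$mc$seed,
               track1 = spec$track1$name, track2 = spec$track2$name %||% NA,
               n_bins = nrow(bins))
  if (route == "asymptotic") {
    res <- asymptotic_route(question, ctxs, obs_bin, obs_global, spec, per_bin)
  } else {
    res <- mc_route(question, info, ctxs, obs_bin, obs_global, spec, per_bin)
  }
  res$params <- echo
  class(res) <- "test_result"
  res
}

mc_route <- function(question, info, ctxs, obs_bin, obs_global, spec, per_bin) {
  stat <- stat_fun_for(question)
  mc <- spec$mc
  nb <- length(ctxs)
  if (info$rand == "freq") {
    return(freq_mc_route(ctxs, obs_bin, obs_global, spec, per_bin))
  }
  states <- lapply(seq_len(nb), function(i)
    list(seed = child_seed(mc$seed, i)))
  sampler <- function(i, m) {
    st <- with_rng_state(states[[i]], {
      vapply(seq_len(m), function(j)
        stat(list(draw_null_bin(ctxs[[i]], info, spec$null))), 1)
    })
    states[[i]] <<- st$state
    st$value
  }
  eng <- mcfdr_engine(obs_bin, sampler, mc, spec$alternative, info$direction)
  per_bin <- cbind(per_bin, eng)
  # global stream: all bins randomized jointly
  gstate <- list(seed = child_seed(mc$seed, 0L))
  gsampler <- function(i, m) {
    st <- with_rng_state(gstate, {
      vapply(seq_len(m), function(j)
        stat(lapply(ctxs, draw_null_bin, info = info, null = spec$null)), 1)
    })
    gstate <<- st$state
    st$value
  }
  geng <- mcfdr_engine(obs_global, gsampler, mc, spec$alternative,
                       info$direction)
  list(per_bin = per_bin,
       global = c(list(observed = obs_global), as.list(geng[1L, ])))
}

freq_mc_route <- function(ctxs, obs_bin, obs_global, spec, per_bin) {
  # null: source labels of the merged point set permuted globally;
  # per bin the marginal is hypergeometric in the bin's point count
  mc <- spec$mc
  n1 <- vapply(ctxs, function(b) length(b$p1), 1)
  n2 <- vapply(ctxs, function(b) length(b$p2), 1)
  k <- n1 + n2
  N1 <- sum(n1); N2 <- sum(n2)
  pg <- if (N1 + N2 > 0) N1 / (N1 + N2) else NA_real_
  obs_prop <- ifelse(k > 0, n1 / k, NA_real_)
  states <- lapply(seq_along(ctxs), function(i)
    list(seed = child_seed(mc$seed, i)))
  sampler <- function(i, m) {
    st <- with_rng_state(states[[i]], {
      stats::rhyper(m, N1, N2, k[i]) / k[i]
    })
    states[[i]] <<- st$state
    st$value
  }
  eng <- mcfdr_engine(obs_prop, sampler, mc, spec$alternative, +1)
  per_bin$observed <- obs_prop
  per_bin <- cbind(per_bin, eng)
  gstate <- list(seed = child_seed(mc$seed, 0L))
  gsampler <- function(i, m) {
    st <- with_rng_state(gstate, {
      vapply(seq_len(m), function(j) {
        lab <- sample.int(N1 + N2) <= N1
        ki <- 0L
        s <- 0
        for (bi in seq_along(k)) {
          if (k[bi] == 0) next
          x <- sum(lab[(ki + 1):(ki + k[bi])])
          s <- s + k[bi] * (x / k[bi] - pg)^2
          ki <- ki + k[bi]
        }
        s
      }, 1)
    })
    gstate <<- st$state
    st$value
  }
  # heterogeneity statistic: one-sided by construction
  geng <- mcfdr_engine(obs_global, gsampler, mc, "more", +1)
  list(per_bin = per_bin,
       global = c(list(observed = obs_global, global_proportion = pg),
                  as.list(geng[1L, ])))
}

asymptotic_route <- function(question, ctxs, obs_bin, obs_global, spec,
                             per_bin) {
  alt <- spec$alternative
  if (question == "correlation") {
    nvec <- vapply(ctxs, function(b)
      sum(!is.na(b$f1) & !is.na(b$f2)), 1)
    p <- vapply(seq_along(ctxs), function(i) {
      if (is.na(obs_bin[i])) NA_real_ else
        asymptotic_test("correlation", list(r = obs_bin[i], n = nvec[i]), alt)
    }, 1)
    ng <- sum(nvec)
    pg <- if (is.na(obs_global)) NA_real_ else
      asymptotic_test("correlation", list(r = obs_global, n = ng), alt)
  } else if (question == "frequency_difference") {
    n1 <- vapply(ctxs, function(b) length(b$p1), 1)
    n2 <- vapply(ctxs, function(b) length(b$p2), 1)
    k <- n1 + n2
    p0 <- if (sum(k) > 0) sum(n1) / sum(k) else NA_real_
    obs_bin <- ifelse(k > 0, n1 / k, NA_real_)
    per_bin$observed <- obs_bin
    p <- vapply(seq_along(ctxs), function(i) {
      if (k[i] == 0) NA_real_ else
        asymptotic_test("frequency_difference",
                        list(n1 = n1[i], n = k[i], p0 = p0), alt)
    }, 1)
    # global: chi-square homogeneity of proportions across bins
    ok <- k > 0
    pg <- if (sum(ok) >= 2L) {
      tab <- rbind(n1[ok], n2[ok])
      if (all(rowSums(tab) > 0))
        stats::pchisq(chisq_stat(tab), df = sum(ok) - 1, lower.tail = FALSE)
      else NA_real_
    } else NA_real_
  } else if (question == "differential_colocation") {
    p <- vapply(seq_along(ctxs), function(i) {
      b <- ctxs[[i]]
      if (is.na(obs_bin[i]) || length(b$p1) == 0L || length(b$s2) == 0L)
        return(NA_real_)
      df <- (length(unique(b$v1)) - 1) * (length(unique(b$v2)) - 1)
      if (df < 1) return(NA_real_)
      stats::pchisq(obs_bin[i], df, lower.tail = FALSE)
    }, 1)
    rl <- length(unique(unlist(lapply(ctxs, `[[`, "v1"))))
    cl <- length(unique(unlist(lapply(ctxs, `[[`, "v2"))))
    pg <- if (!is.na(obs_global) && rl > 1 && cl > 1)
      stats::pchisq(obs_global, (rl - 1) * (cl - 1), lower.tail = FALSE)
    else NA_real_
  } else {
    stop_capability("no asymptotic route for '%s'", question)
  }
  defined <- !is.na(p)
  adj <- rep(NA_real_, length(p))
  adj[defined] <- bh_adjust(p[defined])
  per_bin$p <- p
  per_bin$adjusted <- adj
  per_bin$significant <- !is.na(adj) & adj <= spec$mc$q
  per_bin$samples <- 0L
  list(per_bin = per_bin,
       global = list(observed = obs_global, p = pg,
                     significant = !is.na(pg) && pg <= spec$mc$q,
                     samples = 0L))
}

#' @export
print.test_result <- function(x, ...) {
  p <- x$params
  cat(sprintf("Hypothesis test: %s (alternative: %s)\n", p$question,
              p$alternative))
  cat(sprintf("  tracks: %s vs %s\n", p$track1, p$track2))
  cat(sprintf("  evaluation: %s; null model: %s; seed: %d\n", p$evaluation,
              p$null_model, p$seed))
  g <- x$global
  cat(sprintf("  global: observed = %g, p = %g%s\n", g$observed, g$p,
              if (isTRUE(g$significant)) " (significant)" else ""))
  nsig <- sum(x$per_bin$significant, na.rm = TRUE)
  cat(sprintf("  bins: %d analyzed, %d significant at q = %g\n",
              nrow(x$per_bin), nsig, p$mc$q))
  invisible(x)
}

#' One-line report of a test result with full parameter echo
#'
#' @param result A `test_result`.
#' @param file Optional path; when given the report is written there.
#' @return The report lines, invisibly.
#' @export
report_test <- function(result, file = NULL) {
  p <- result$params
  lines <- c(
    sprintf("question: %s", p$question),
    sprintf("alternative: %s", p$alternative),
    sprintf("evaluation: %s", p$evaluation),
    sprintf("null model: %s (randomizes: %s)", p$null_model, p$randomized),
    sprintf("tracks: track1=%s track2=%s", p$track1, p$track2),
    sprintf("bins: %d", p$n_bins),
    sprintf("mc: chunk=%d h=%d q=%g max_samples=%d seed=%d",
            p$mc$chunk, p$mc$h, p$mc$q, p$mc$max_samples, p$seed),
    sprintf("global observed: %g", result$global$observed),
    sprintf("global p: %g", result$global$p),
    sprintf("significant bins: %d / %d",
            sum(result$per_bin$significant, na.rm = TRUE),
            nrow(result$per_bin)))
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}
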