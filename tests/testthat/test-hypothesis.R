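test_that("compute_statistic matches the per-question definitions", {
  bin1 <- list(chrom = "chr1", start = 0, end = 40)
  expect_equal(compute_statistic("overlap", segment_track("chr1", 0, 10),
                                 segment_track("chr1", 5, 15), bin1), 5)
  expect_equal(compute_statistic("border", point_track("chr1", c(20, 29)),
                                 segment_track("chr1", 20, 30), bin1), 0.05)
  expect_equal(compute_statistic("inside", point_track("chr1", c(1, 5, 12)),
                                 segment_track("chr1", 0, 6), bin1), 2)
  # nearby: sign flipped so larger = closer
  expect_equal(compute_statistic("nearby", point_track("chr1", 10),
                                 point_track("chr1", c(0, 25)), bin1), -10)
  # chi-square statistic of a diagonal table is 10 (hand: expected 2.5/cell)
  expect_equal(trackstat:::chisq_stat(matrix(c(5, 0, 0, 5), 2)), 10)
  # empty required track -> undefined
  expect_true(is.na(compute_statistic("inside",
                                      point_track(character(0), numeric(0)),
                                      segment_track("chr1", 0, 6), bin1)))
})

test_that("type mismatches list the analyses valid for the supplied tracks", {
  err <- tryCatch(test_spec("overlap", point_track("chr1", 1),
                            point_track("chr1", 2),
                            bin_set("chr1", 0, 10)),
                  error = function(e) e)
  expect_s3_class(err, "type_error")
  expect_match(conditionMessage(err), "nearby")
  expect_match(conditionMessage(err), "frequency_difference")
})

test_that("MC p-value uses the add-one estimator and never reaches zero", {
  # observed overlap is maximal and unreachable by the null most of the
  # time; with max_samples = 99 and no exceedance p-hat = (0+1)/(99+1)
  bins <- bin_set("chr1", 0, 1000)
  t1 <- segment_track("chr1", 100, 110)
  t2 <- segment_track("chr1", 100, 110)
  res <- run_test(test_spec("overlap", t1, t2, bins,
                            mc = mc_params(chunk = 99, max_samples = 99,
                                           seed = 7)))
  expect_equal(res$global$samples, 99)
  expect_gte(res$global$p, 1 / 100)
  if (res$global$exceedances == 0) expect_equal(res$global$p, 0.01)
  expect_gt(res$global$p, 0)
})

test_that("MC p converges to the exactly enumerated null probability", {
  # genome of 6 bp, segments cover [0,3), one point: exact P(inside >= 1)
  # over the 6 uniform placements is 3/6
  bins <- bin_set("chr1", 0, 6)
  t1 <- point_track("chr1", 1)
  t2 <- segment_track("chr1", 0, 3)
  n <- 4000
  res <- run_test(test_spec("inside", t1, t2, bins,
                            mc = mc_params(chunk = n, max_samples = n,
                                           h = n, seed = 3)))
  se <- sqrt(0.5 * 0.5 / n)
  expect_lt(abs(res$global$p - 0.5), 3 * se)
})

test_that("two-sided p is the doubled smaller tail on a symmetric null", {
  bins <- bin_set("chr1", 0, 200)
  t1 <- point_track("chr1", c(10, 60, 110, 160))
  t2 <- segment_track("chr1", c(0, 100), c(50, 150))
  mk <- function(alt) run_test(test_spec("inside", t1, t2, bins,
                                         alternative = alt,
                                         mc = mc_params(chunk = 1000,
                                                        max_samples = 1000,
                                                        h = 1000, seed = 5)))
  pm <- mk("more")$global$p
  pl <- mk("less")$global$p
  pd <- mk("different")$global$p
  expect_equal(pd, min(1, 2 * min(pm, pl)), tolerance = 0.05)
})

test_that("mcfdr engine stops on exceedances, significance or the cap", {
  mc <- mc_params(chunk = 100, h = 20, q = 0.05, max_samples = 10000, seed = 1)
  # null always >= observed: stops after ceil(h/chunk) = 1 round, p ~ 1
  r1 <- mcfdr_engine(observed = 0,
                     sampler = function(i, m) rep(1, m), mc = mc)
  expect_equal(r1$samples, 100)
  expect_gt(r1$p, 0.9)
  # observed far in the tail: significant after exactly one round
  r2 <- mcfdr_engine(observed = 10,
                     sampler = function(i, m) runif(m), mc = mc)
  expect_equal(r2$samples, 100)
  expect_true(r2$significant)
  expect_equal(r2$p, 1 / 101)
  # cap: a p-value near 0.01 cannot be significant at q=0.05 under BH with
  # many tiny bins... single bin with borderline stat runs to a stop
  r3 <- mcfdr_engine(observed = 0.995,
                     sampler = function(i, m) runif(m),
                     mc = mc_params(chunk = 100, h = 3, q = 1e-6,
                                    max_samples = 400, seed = 2))
  expect_lte(r3$samples, 400)
  expect_gte(r3$exceedances, 0)
})

test_that("mcfdr engine is deterministic given seeded samplers", {
  run_once <- function() {
    states <- lapply(1:5, function(i) list(seed = i))
    sampler <- function(i, m) {
      st <- trackstat:::with_rng_state(states[[i]], stats::rnorm(m))
      states[[i]] <<- st$state
      st$value
    }
    mcfdr_engine(observed = c(0.5, 1, 2, 3, NA), sampler,
                 mc_params(chunk = 50, max_samples = 500, seed = 1))
  }
  a <- run_once(); b <- run_once()
  expect_identical(a, b)
  expect_true(is.na(a$p[5]))            # undefined bin excluded
})

test_that("asymptotic routes match their closed forms and exact oracles", {
  expect_equal(asymptotic_test("correlation", list(r = 0, n = 10),
                               "different"), 1)
  expect_equal(asymptotic_test("frequency_difference",
                               list(n1 = 5, n = 5, p0 = 0.5), "more"),
               0.5^5)
  expect_equal(asymptotic_test("differential_colocation",
                               matrix(c(5, 0, 0, 5), 2), "different"),
               stats::pchisq(10, 1, lower.tail = FALSE))
  # Fisher on [[1,0],[0,1]] vs enumeration of tables with margins (1,1)/(1,1):
  # the two permissible tables each have hypergeometric probability 1/2, so
  # the two-sided p (sum of tables as or less probable) is 1
  expect_equal(asymptotic_test("case_control_2x2", matrix(c(1, 0, 0, 1), 2),
                               "different"), 1)
  hyper_probs <- vapply(0:1, function(x) stats::dhyper(x, 1, 1, 1), 1)
  expect_equal(sum(hyper_probs[hyper_probs <= hyper_probs[2] + 1e-12]), 1)
  expect_error(asymptotic_test("overlap", list()), class = "capability_error")
})

test_that("bh_adjust follows the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(bh_adjust(rep(0.3, 4)), rep(0.3, 4))
  expect_equal(bh_adjust(0.07), 0.07)
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  p <- c(0.001, 0.2, 0.04, 0.9)
  expect_true(all(bh_adjust(p) >= p))
})

test_that("run_test is bit-deterministic given its spec", {
  g <- toy_genome(2000)
  bins <- make_bins(g, 500)
  t1 <- random_track(g, "P", 20, seed = 1)
  t2 <- random_track(g, "S", 8, seed = 2)
  spec <- test_spec("inside", t1, t2, bins, mc = mc_params(seed = 42))
  a <- run_test(spec); b <- run_test(spec)
  expect_identical(a$per_bin, b$per_bin)
  expect_identical(a$global, b$global)
})

test_that("case/control label swap mirrors the statistic and one-sided p", {
  g <- toy_genome(1000)
  bins <- bin_set("chr1", 0, 1000)
  ca <- random_track(g, "S", 6, seed = 21)
  co <- random_track(g, "S", 6, seed = 22)
  t2 <- random_track(g, "S", 10, seed = 23)
  cc <- merge_case_control(ca, co)
  swapped <- cc
  swapped$elements$value <- ifelse(cc$elements$value == "case", "control",
                                   "case")
  r1 <- run_test(test_spec("preferential_overlap", cc, t2, bins,
                           alternative = "more", mc = mc_params(seed = 5)))
  r2 <- run_test(test_spec("preferential_overlap", swapped, t2, bins,
                           alternative = "less", mc = mc_params(seed = 5)))
  expect_equal(r1$global$observed, -r2$global$observed)
  expect_equal(r1$global$p, r2$global$p)
})

test_that("each question runs end to end on matching synthetic tracks", {
  g <- toy_genome(1500)
  bins <- make_bins(g, 750)
  mc <- mc_params(chunk = 50, max_samples = 100, h = 10, seed = 9)
  mk <- function(tt, n, seed, vk = "number")
    random_track(g, tt, n, seed = seed, value_kind = vk)
  cases <- list(
    list("frequency_difference", mk("P", 20, 1), mk("P", 20, 2)),
    list("nearby", mk("P", 10, 3), mk("S", 6, 4)),
    list("inside", mk("P", 10, 5), mk("S", 6, 6)),
    list("border", mk("P", 15, 7), mk("S", 6, 8)),
    list("similar_segments", mk("S", 6, 9), mk("S", 6, 10)),
    list("overlap", mk("S", 6, 11), mk("S", 6, 12)),
    list("correlation", mk("F", 4, 13), mk("F", 4, 14)),
    list("values_at_points", mk("P", 10, 15), mk("F", 4, 16)),
    list("values_inside", mk("S", 5, 17), mk("F", 4, 18)),
    list("value_landing", mk("P", 20, 19), mk("VS", 8, 20)),
    list("inside_vs_outside_values", mk("S", 6, 21), mk("VP", 20, 22)),
    list("nearby_values", mk("VP", 10, 23), mk("VP", 10, 24)),
    list("case_landing", mk("P", 20, 25), mk("VS", 8, 26, "case_control")),
    list("preferential_overlap", mk("VS", 8, 27, "case_control"),
         mk("S", 6, 28)),
    list("differential_colocation", mk("VP", 25, 29, "category"),
         mk("VS", 8, 30, "category")))
  for (cs in cases) {
    res <- run_test(test_spec(cs[[1]], cs[[2]], cs[[3]], bins, mc = mc))
    expect_s3_class(res, "test_result")
    expect_true(is.numeric(res$global$p))
    expect_true(all(res$per_bin$p > 0, na.rm = TRUE))
    expect_true(all(res$per_bin$adjusted >= res$per_bin$p, na.rm = TRUE))
    expect_equal(res$params$question, cs[[1]])
    lines <- report_test(res)
    expect_match(lines, "null model", all = FALSE)
    expect_match(lines, "seed", all = FALSE)
  }
})

test_that("selectable positional nulls feed the MC evaluation", {
  g <- toy_genome(1000)
  bins <- bin_set("chr1", 0, 1000)
  t1 <- random_track(g, "P", 15, seed = 31)
  t2 <- random_track(g, "S", 6, seed = 32)
  mc <- mc_params(chunk = 50, max_samples = 100, h = 10, seed = 1)
  for (model in c("uniform_independent", "preserve_gaps")) {
    res <- run_test(test_spec("inside", t1, t2, bins,
                              null = null_model_spec(model, seed = 1),
                              mc = mc))
    expect_equal(res$params$null_model, model)
    expect_true(res$global$p > 0 && res$global$p <= 1)
  }
  it <- make_intensity_track(t1, list(distance_to_nearest(t2, g)), g, bins,
                             strata_per_confounder = 5)
  res <- run_test(test_spec("inside", t1, t2, bins,
                            null = null_model_spec("intensity_guided",
                                                   intensity = it, seed = 1),
                            mc = mc))
  expect_equal(res$params$null_model, "intensity_guided")
  # positional null rejected for a label-permutation question
  cc <- random_track(g, "VS", 8, seed = 33, value_kind = "case_control")
  expect_error(run_test(test_spec("preferential_overlap", cc, t2, bins,
                                  null = null_model_spec("uniform_independent"),
                                  mc = mc)),
               class = "invalid_parameter_error")
})

test_that("auto evaluation picks the asymptotic route for correlation", {
  g <- toy_genome(400)
  bins <- make_bins(g, 200)
  f1 <- random_track(g, "F", 3, seed = 41)
  f2 <- random_track(g, "F", 3, seed = 42)
  res <- run_test(test_spec("correlation", f1, f2, bins))
  expect_equal(res$params$evaluation, "asymptotic")
  expect_equal(res$global$samples, 0L)
  res2 <- run_test(test_spec("frequency_difference",
                             random_track(g, "P", 20, seed = 43),
                             random_track(g, "P", 20, seed = 44), bins))
  expect_equal(res2$params$evaluation, "asymptotic")
  expect_error(run_test(test_spec("overlap", random_track(g, "S", 5, seed = 1),
                                  random_track(g, "S", 5, seed = 2), bins,
                                  evaluation = "asymptotic")),
               class = "capability_error")
})
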