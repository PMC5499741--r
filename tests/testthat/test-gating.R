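make_events <- function(n = 1000, seed = 1, ...) {
  gen_population_events(population_spec(n_events = n,
                                        channels = c(GFP = 1000),
                                        eta_int = 0.1, seed = seed, ...))
}

test_that("time trimming removes the unstable head and tail of the acquisition", {
  set.seed(1)
  ev <- data.frame(TIME = runif(1000, 0, 10), FSC = 59000, SSC = 27000,
                   GFP = 100)
  tr <- trim_time(ev)  # defaults: 1 s head, 0.2 s tail
  expect_equal(nrow(tr) / 1000, (10 - 1.2) / 10, tolerance = 0.05)
  expect_true(min(tr$TIME) >= min(ev$TIME) + 1)
  expect_true(max(tr$TIME) <= max(ev$TIME) - 0.2)
  # identity at zero trims
  expect_identical(nrow(trim_time(ev, 0, 0)), nrow(ev))
  # span shorter than the trims is an error
  short <- ev; short$TIME <- runif(1000, 0, 1)
  expect_error(trim_time(short), "span")
})

test_that("trimming degrades to a warning no-op without a TIME channel", {
  ev <- data.frame(FSC = rep(59000, 10), SSC = 27000, GFP = 100)
  expect_warning(out <- trim_time(ev), "TIME")
  expect_identical(out, ev)
})

test_that("scatter thresholds are closed intervals", {
  ev <- data.frame(FSC = c(39999, 40000, 100000, 100001, 60000),
                   SSC = c(50000, 10000, 90000, 50000, 9999),
                   GFP = 1:5)
  g <- scatter_threshold_gate(ev)
  expect_identical(g$GFP, c(2L, 3L))
  expect_warning(scatter_threshold_gate(
    data.frame(FSC = 0, SSC = 0, GFP = 1)), "no events")
})

test_that("threshold gating removes all generator-flagged debris", {
  ev <- make_events(n = 10000, seed = 2, debris_fraction = 0.1)
  g <- scatter_threshold_gate(ev)
  expect_identical(sum(attr(g, "provenance") == "debris"), 0L)
})

test_that("density centre finds the mode of a tight cluster and honours overrides", {
  ev <- make_events(n = 10000, seed = 3, scatter_sd = c(1500, 1500))
  ctr <- density_center(ev)
  expect_lt(abs(ctr["FSC"] - 59000), 1001)
  expect_lt(abs(ctr["SSC"] - 27000), 1001)
  # the dual-reporter comparison gate uses a manual centre
  expect_equal(density_center(ev, manual = c(57000, 24500)),
               c(FSC = 57000, SSC = 24500))
  expect_error(density_center(ev[1:50, ]), "100")
})

test_that("equal-count density ties break lexicographically", {
  ev <- data.frame(FSC = rep(c(45500, 61500), each = 200),
                   SSC = rep(c(45500, 20500), each = 200),
                   GFP = 1)
  ctr <- density_center(ev)
  expect_equal(unname(ctr), c(45500, 45500))
})

test_that("radial distance follows the printed Euclidean formula", {
  ev <- data.frame(FSC = 62000, SSC = 31000)
  expect_equal(radial_distance(ev, c(59000, 27000)), 5000)  # 3-4-5 triangle
  expect_equal(radial_distance(data.frame(FSC = 59000, SSC = 27000),
                               c(59000, 27000)), 0)
  # symmetric in which axis carries which offset
  expect_equal(radial_distance(data.frame(FSC = 63000, SSC = 30000),
                               c(59000, 27000)),
               radial_distance(data.frame(FSC = 62000, SSC = 31000),
                               c(59000, 27000)))
})

test_that("CV statistic: definition, scale invariance, domain", {
  expect_equal(cv_stat(c(1, 1, 1)), 0)
  expect_equal(cv_stat(c(2, 4, 4, 4, 5, 5, 7, 9)), 42.76, tolerance = 1e-4)
  x <- rlnorm(50, 0, 0.2)
  expect_equal(cv_stat(x), cv_stat(10 * x))
  expect_error(cv_stat(c(1)), "2 values")
  expect_error(cv_stat(c(-2, 0)), "mean")
})

test_that("radial gate statistics and edge cases", {
  ev <- make_events(n = 20000, seed = 6)
  ctr <- c(59000, 27000)
  g <- radial_gate(ev, ctr, 4000)
  expect_true(g$n_in < nrow(ev))
  expect_equal(unname(g$mean["GFP"]), 1000, tolerance = 0.02)
  expect_equal(unname(g$cv_percent["GFP"]), 10, tolerance = 0.1)
  # infinite radius reproduces the ungated CV
  g_all <- radial_gate(ev, ctr, Inf)
  expect_equal(unname(g_all$cv_percent["GFP"]), cv_stat(ev$GFP))
  expect_error(radial_gate(ev, c(0, 0), radius = 10), "empty gate")
  expect_error(radial_gate(ev, ctr, radius = -1), "radius")
})

test_that("cv_vs_radius is consistent with single gates and monotone in count", {
  ev <- make_events(n = 10000, seed = 7)
  ctr <- c(59000, 27000)
  curve <- cv_vs_radius(ev, ctr, radii = c(2000, 4000, 8000, 16000))
  expect_true(all(diff(curve$n_in) >= 0))
  g <- radial_gate(ev, ctr, 4000)
  expect_equal(curve$cv_GFP[curve$radius == 4000],
               unname(g$cv_percent["GFP"]))
  expect_error(cv_vs_radius(ev, ctr, c(4000, 2000)), "increasing")
})

test_that("scatter-coupled extrinsic noise makes gated CV grow with radius", {
  ev <- gen_population_events(population_spec(
    n_events = 30000, channels = c(GFP = 1000), eta_int = 0.05,
    eta_ext = 0.1, ext_scatter_coupling = 0.1, seed = 8))
  curve <- cv_vs_radius(ev, c(59000, 27000),
                        radii = c(2000, 6000, 12000, 20000))
  expect_true(all(diff(curve$cv_GFP) > 0))
  # uncoupled control: flat within Monte-Carlo error
  ev0 <- gen_population_events(population_spec(
    n_events = 30000, channels = c(GFP = 1000), eta_int = 0.05,
    eta_ext = 0, seed = 8))
  curve0 <- cv_vs_radius(ev0, c(59000, 27000),
                         radii = c(2000, 6000, 12000, 20000))
  expect_lt(diff(range(curve0$cv_GFP)), 0.5)
})

test_that("trim and threshold steps commute on uniform-TIME populations", {
  ev <- make_events(n = 8000, seed = 9, debris_fraction = 0.1)
  a <- scatter_threshold_gate(trim_time(ev))
  b <- trim_time(scatter_threshold_gate(ev))
  expect_equal(a, b, ignore_attr = TRUE)
})

test_that("the reader validates required channels", {
  f <- tempfile(fileext = ".tsv")
  write.table(data.frame(TIME = 1, FSC = 2, GFP = 3), f, sep = "\t",
              row.names = FALSE, quote = FALSE)
  expect_error(read_events(f), "SSC")
  write.table(data.frame(TIME = 1, FSC = 2, SSC = 3), f, sep = "\t",
              row.names = FALSE, quote = FALSE)
  expect_error(read_events(f), "fluorescence")
  unlink(f)
})
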