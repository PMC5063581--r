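# network model container, bundled microcircuit fixture, perturbation and
# working-point-preserving surgery

test_that("bundled microcircuit matches its published construction", {
  m <- micro()
  expect_equal(n_pop(m), 8L)
  expect_equal(sum(m$sizes), 77169)
  expect_equal(m$labels, c("23E", "23I", "4E", "4I", "5E", "5I", "6E", "6I"))
  expect_true(all(m$neuron$tau_s == 0.5e-3))
  expect_true(all(m$d_std == 1e-3))            # stabilised delay spread
  # loader applies the indegree and external-drive reductions
  m0 <- microcircuit(modified = FALSE)
  expect_equal(m$K[3, 4], 0.85 * m0$K[3, 4])
  expect_equal(m$K_ext[3], 0.81 * m0$K_ext[3])
  expect_equal(m$K[-3, ], m0$K[-3, ])
  # excitatory/inhibitory column sign structure, doubled 4E -> 2/3E weight
  exc <- c(1, 3, 5, 7)
  expect_true(all(m$W[, exc] > 0))
  expect_true(all(m$W[, -exc] < 0))
  expect_equal(m$W[1, 3], 2 * m$W[3, 3])
  expect_equal(m$g, 4)
})

test_that("fixture file is pinned by checksum", {
  path <- system.file("extdata", "microcircuit.yaml", package = "popspectra")
  expect_equal(unname(tools::md5sum(path)), fixture_md5)
})

test_that("corrupt or missing fixture files fail loudly", {
  expect_error(microcircuit(file = tempfile()), "not found")
  bad <- tempfile(fileext = ".yaml")
  writeLines("labels: [A]\nsizes: [10]", bad)
  expect_error(microcircuit(file = bad), "missing fields")
})

test_that("perturb_indegree scales exactly one entry and keeps the original", {
  m <- micro()
  p <- perturb_indegree(m, "4I", "4I", 0.10)
  expect_equal(p$K[4, 4], 1.10 * m$K[4, 4])
  p$K[4, 4] <- m$K[4, 4]
  expect_equal(p$K, m$K)
  expect_equal(perturb_indegree(m, 2, 5, 0)$K, m$K)
  q <- perturb_indegree(m, "5I", "5E", -0.15)
  expect_equal(q$K[6, 5], 0.85 * m$K[6, 5])
  expect_error(perturb_indegree(m, 1, 1, -1.5), "negative")
})

test_that("compensation restores the mean input at the original rates", {
  m <- micro()
  st <- micro_state()
  # identical models: no adjustment
  same <- compensate_external(m, m, rates = st$rates)
  expect_equal(same$K_ext, m$K_ext)
  expect_equal(max(abs(attr(same, "sigma_residual"))), 0)
  # +10% on 4I<-4I adds inhibition onto 4I, so the excitatory external
  # drive must grow to restore the mean; restoration is exact
  p <- perturb_indegree(m, "4I", "4I", 0.10)
  comp <- compensate_external(m, p, rates = st$rates)
  expect_gt(comp$K_ext[4], m$K_ext[4])
  wp0 <- working_point(m, st$rates)
  wp1 <- working_point(comp, st$rates)
  expect_lt(max(abs(wp1$mu - wp0$mu) / pmax(abs(wp0$mu), 1)), 1e-10)
  # sigma residual reported and small relative to sigma itself
  expect_lt(max(abs(attr(comp, "sigma_residual"))) / min(wp0$sigma), 0.1)
  # two-channel mode restores the variance as well whenever the required
  # adjustment is an addition (here: removing inhibitory synapses removes
  # variance, which the noise channel can replace)
  q <- perturb_indegree(m, "4I", "4I", -0.10)
  comp2 <- compensate_external(m, q, rates = st$rates, two_channel = TRUE)
  wp2 <- working_point(comp2, st$rates)
  expect_lt(max(abs(wp2$mu - wp0$mu)), 1e-8)
  expect_lt(max(abs(wp2$sigma - wp0$sigma)), 1e-8)
})

test_that("stated modifications approximately recover the 4E working point", {
  # the bundled 19% external reduction overshoots the exact mean-channel
  # compensation (16.5%), so recovery is approximate, not exact
  m0 <- microcircuit(modified = FALSE)
  m0$d_std[] <- 1e-3
  st0 <- solve_selfconsistent(m0)
  wp0 <- working_point(m0, st0$rates)
  wp1 <- working_point(micro(), st0$rates)
  expect_lt(abs(wp1$mu[3] - wp0$mu[3]) / abs(wp0$mu[3]), 0.12)
  expect_lt(abs(wp1$sigma[3] - wp0$sigma[3]) / wp0$sigma[3], 0.09)
  # exact two-channel compensation of the same indegree change restores
  # both moments
  mx <- perturb_indegree(m0, "4E", "4I", -0.15)
  mc <- compensate_external(m0, mx, rates = st0$rates, two_channel = TRUE)
  wpc <- working_point(mc, st0$rates)
  expect_lt(abs(wpc$mu[3] - wp0$mu[3]), 1e-10)
  expect_lt(abs(wpc$sigma[3] - wp0$sigma[3]), 1e-8)
})

test_that("isolate_subcircuit preserves every working point exactly", {
  m <- micro()
  st <- micro_state()
  wp0 <- working_point(m, st$rates)
  # keep all: model unchanged
  all_mask <- matrix(TRUE, 8, 8)
  expect_equal(isolate_subcircuit(m, all_mask, st$rates)$K, m$K)
  # within-layer-2/3 only
  iso <- isolate_subcircuit(m, c("23E", "23I"), st$rates)
  expect_true(all(iso$K[-(1:2), ] == 0) && all(iso$K[, -(1:2)] == 0))
  wp1 <- working_point(iso, st$rates)
  expect_equal(wp1$mu, wp0$mu, tolerance = 1e-12)
  expect_equal(wp1$sigma, wp0$sigma, tolerance = 1e-12)
  # dropping a single connection by pair list
  mask <- m$K > 0
  mask[4, 1] <- FALSE                      # 4I <- 2/3E
  iso2 <- isolate_subcircuit(m, mask, st$rates)
  expect_equal(iso2$K[4, 1], 0)
  expect_equal(sum(iso2$K > 0), sum(m$K > 0) - 1)
  wp2 <- working_point(iso2, st$rates)
  expect_equal(wp2$mu, wp0$mu, tolerance = 1e-12)
  expect_equal(wp2$sigma, wp0$sigma, tolerance = 1e-12)
  # self-consistent rates of the isolated model equal the original rates
  st_iso <- solve_selfconsistent(iso, init = st$rates)
  expect_lt(max(abs(st_iso$rates - st$rates)), 1e-8)
})

test_that("network configs round-trip through the plain-text format", {
  m <- make_net2()
  path <- tempfile(fileext = ".yaml")
  write_network_config(m, path)
  m2 <- read_network_config(path)
  for (f in c("sizes", "K", "W", "d_mean", "d_std", "K_ext", "r_ext"))
    expect_equal(m2[[f]], m[[f]], tolerance = 1e-12)
  expect_equal(m2$neuron, m$neuron, tolerance = 1e-12)
})

test_that("invalid models are rejected", {
  m <- make_net2()
  bad <- m; bad$K[1, 2] <- -5
  expect_error(popspectra:::validate_network_model(bad), "non-negative")
  bad <- m; bad$neuron$V_th <- c(0, 0)
  expect_error(popspectra:::validate_network_model(bad), "V_th")
})
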