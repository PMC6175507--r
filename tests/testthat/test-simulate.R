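test_that("covariate generator honors the survey design and its seed", {
  cfg <- generator_config(seed = 5)
  cov <- simulate_covariates(cfg)
  expect_equal(nrow(cov$sites), 96)
  nv <- table(cov$visits$site)
  expect_true(all(nv >= 1 & nv <= 5))
  expect_true(nrow(cov$visits) >= 96 && nrow(cov$visits) <= 480)

  # determinism bit for bit
  cov2 <- simulate_covariates(cfg)
  expect_identical(cov, cov2)

  # every generated covariate column is standardized
  for (col in c("rocks", "barerock", "vegetation", "siteslope")) {
    expect_equal(mean(cov$sites[[col]]), 0, tolerance = 1e-8)
    expect_equal(sd(cov$sites[[col]]), 1, tolerance = 1e-8)
  }
  for (col in c("humidity", "temperature", "samplingeffort", "hour", "rainfall")) {
    expect_equal(mean(cov$visits[[col]]), 0, tolerance = 1e-8)
    expect_equal(sd(cov$visits[[col]]), 1, tolerance = 1e-8)
  }

  # mean visit count approaches 3 under the uniform 1..5 design
  big <- simulate_covariates(generator_config(n_sites = 5000, seed = 6))
  expect_equal(nrow(big$visits) / 5000, 3, tolerance = 0.1)
})

test_that("occupancy-state generator follows the logistic model", {
  cov <- simulate_covariates(generator_config(n_sites = 2000, seed = 10))
  # all-zero coefficients: psi = 0.5 everywhere
  occ <- simulate_occupancy_state(rep(0, 5), cov$sites, seed = 1)
  expect_true(all(occ$psi == 0.5))
  expect_equal(mean(occ$z), 0.5, tolerance = 0.05)
  # saturated intercept
  occ <- simulate_occupancy_state(c(20, 0, 0, 0, 0), cov$sites, seed = 1)
  expect_true(all(occ$z == 1))
  # a strong vegetation effect at vegetation = 1: psi = inverse-logit(3.14)
  one <- data.frame(site = "a", rocks = 0, barerock = 0, vegetation = 1,
                    siteslope = 0)
  occ <- simulate_occupancy_state(c(0, 0, 0, 3.14, 0), one, seed = 1)
  expect_equal(occ$psi, plogis(3.14), tolerance = 1e-12)
  expect_equal(occ$psi, 0.958, tolerance = 1e-3)
})

test_that("detection generator: structural zeros, saturation, generating rate", {
  n <- 500
  sites <- data.frame(site = sprintf("s%03d", 1:n), rocks = 0, barerock = 0,
                      vegetation = 0, siteslope = 0)
  visits <- do.call(rbind, lapply(1:n, function(i) {
    data.frame(site = sites$site[i], visit = 1:200, y = 0L, humidity = 0,
               temperature = 0, samplingeffort = 0, hour = 0, rainfall = 0)
  }))
  # unoccupied sites never yield detections
  det <- simulate_detections(c(20, rep(0, 9)), 0, rep(0L, n), sites, visits,
                             seed = 2)
  expect_true(all(det$y == 0))
  # p -> 1 at occupied sites
  det <- simulate_detections(c(20, rep(0, 9)), 0, rep(1L, n), sites, visits,
                             seed = 2)
  expect_true(all(det$y == 1))
  # Monte-Carlo check of the generating rate on 100,000 occupied site-visits
  det <- simulate_detections(c(qlogis(0.26), rep(0, 9)), 0, rep(1L, n),
                             sites, visits, seed = 3)
  expect_equal(length(det$y), 100000)
  expect_equal(mean(det$y), 0.26, tolerance = 0.01)
})

test_that("composed study simulation: invariants, determinism, substreams", {
  sim <- quick_sim(seed = 1)
  d <- sim$data
  expect_s3_class(d, "occu_data")
  expect_equal(n_sites(d), 96)
  expect_true(all(d$visits$y %in% c(0, 1)))
  # conservation: detected <= occupied <= n_sites, across seeds
  for (s in 1:8) {
    sm <- quick_sim(seed = s)
    n_det <- sum(observed_occupancy(sm$data))
    expect_lte(n_det, sum(sm$truth$z))
    expect_lte(sum(sm$truth$z), n_sites(sm$data))
  }
  # bit-for-bit determinism
  sim2 <- quick_sim(seed = 1)
  expect_identical(sim, sim2)
  # substreams: changing detection coefficients leaves covariates and z alone
  alt <- simulate_study(generator_config(seed = 1,
                                         detection_coefs = c(1, rep(0, 9))))
  expect_identical(alt$truth$z, sim$truth$z)
  expect_identical(alt$data$sites, sim$data$sites)
  expect_identical(alt$data$visits[, -3], sim$data$visits[, -3])

  # detection off: no observed occupancy despite occupied sites
  off <- simulate_study(generator_config(seed = 1,
                                         detection_coefs = c(-50, rep(0, 9))))
  expect_gt(sum(off$truth$z), 0)
  expect_equal(sum(observed_occupancy(off$data)), 0)
})

test_that("expected naive occupancy matches the closed form", {
  # psi = 0.8, p = 0.26, exactly 3 visits: E[naive] = 0.8 * (1 - 0.74^3)
  cfg <- generator_config(n_sites = 10000, visit_probs = c(0, 0, 1, 0, 0),
                          seed = 12)
  sim <- simulate_study(cfg)
  expected <- 0.8 * (1 - (1 - 0.26)^3)
  expect_equal(mean(observed_occupancy(sim$data)), expected, tolerance = 0.02)
})

test_that("study simulation writes valid dataset files and a truth record", {
  tmp <- withr::local_tempdir()
  sim <- simulate_study(generator_config(n_sites = 20, seed = 2),
                        out_dir = tmp)
  expect_true(file.exists(file.path(tmp, "visits.csv")))
  expect_true(file.exists(file.path(tmp, "truth.json")))
  back <- read_occu_data(file.path(tmp, "visits.csv"),
                         file.path(tmp, "sites.csv"), standardized = TRUE)
  expect_equal(back$visits$y, sim$data$visits$y)
})
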