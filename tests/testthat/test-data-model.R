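test_that("standardize matches hand calculations and rejects degenerate input", {
  expect_equal(standardize(c(1, 2, 3)), c(-1, 0, 1))
  expect_equal(standardize(c(2, 4)), c(-1, 1) / sqrt(2))
  expect_error(standardize(c(5, 5, 5), name = "rocks"),
               class = "occu_degenerate_covariate")
  expect_error(standardize(3), class = "occu_degenerate_covariate")

  # idempotence and moment contract on random vectors
  set.seed(42)
  for (i in 1:10) {
    x <- rnorm(sample(5:50, 1), mean = runif(1, -5, 5), sd = runif(1, 0.1, 9))
    s <- standardize(x)
    expect_equal(mean(s), 0, tolerance = 1e-12)
    expect_equal(sd(s), 1, tolerance = 1e-12)
    expect_equal(standardize(s), s, tolerance = 1e-10)
  }
})

test_that("visit table parsing: ragged histories, ordering, validation errors", {
  tmp <- withr::local_tempdir()
  vp <- file.path(tmp, "visits.csv")
  writeLines(c("site,visit,y,humidity,temperature,effort,hour,rain",
               "A,1,0,0.1,0.2,0.3,600,0",
               "A,2,1,0.2,0.1,0.3,700,1",
               "A,3,0,0.3,0.0,0.3,800,0"), vp)
  v <- read_visit_table(vp)
  expect_equal(nrow(v), 3)
  expect_equal(v$y, c(0, 1, 0))
  expect_named(v, c("site", "visit", "y", "humidity", "temperature",
                    "samplingeffort", "hour", "rainfall"))

  sites <- data.frame(site = "A", rocks = 1, barerock = 2, vegetation = 3,
                      siteslope = 4)
  d <- occu_data(v, sites)
  expect_equal(n_sites(d), 1)
  expect_equal(max(d$visits$y), 1)

  # non-binary detection
  v2 <- v; v2$y[2] <- 2
  expect_error(occu_data(v2, sites), class = "occu_nonbinary_detection")
  # duplicate (site, visit)
  v3 <- v; v3$visit[2] <- 1
  expect_error(occu_data(v3, sites), class = "occu_duplicate_visit")
  # missing column
  writeLines(c("site,visit,y,humidity,temperature,effort,hour",
               "A,1,0,0.1,0.2,0.3,600"), vp)
  expect_error(read_visit_table(vp), class = "occu_missing_column")
  # non-numeric covariate
  v4 <- v; v4$humidity <- c("a", "b", "c")
  expect_error(occu_data(v4, sites), class = "occu_nonnumeric_covariate")
})

test_that("write-then-read round trip reproduces a simulated dataset", {
  sim <- quick_sim(seed = 3)
  tmp <- withr::local_tempdir()
  write_occu_data(sim$data, tmp)
  back <- read_occu_data(file.path(tmp, "visits.csv"),
                         file.path(tmp, "sites.csv"), standardized = TRUE)
  expect_equal(back$sites$site, sim$data$sites$site)
  expect_equal(back$visits$y, sim$data$visits$y)
  for (col in c("rocks", "barerock", "vegetation", "siteslope"))
    expect_equal(back$sites[[col]], sim$data$sites[[col]], tolerance = 1e-12)
  for (col in c("humidity", "temperature", "samplingeffort", "hour", "rainfall"))
    expect_equal(back$visits[[col]], sim$data$visits[[col]], tolerance = 1e-12)
})

test_that("prepare_occu_data standardizes every covariate column", {
  sim <- quick_sim(seed = 4)
  raw <- sim$data
  # un-standardize by rescaling, then re-prepare
  raw$standardized <- FALSE
  raw$sites$rocks <- raw$sites$rocks * 7 + 3
  raw$visits$hour <- raw$visits$hour * 120 + 720
  prep <- prepare_occu_data(raw)
  expect_true(prep$standardized)
  for (col in c("rocks", "barerock", "vegetation", "siteslope")) {
    expect_equal(mean(prep$sites[[col]]), 0, tolerance = 1e-8)
    expect_equal(sd(prep$sites[[col]]), 1, tolerance = 1e-8)
  }
  for (col in c("humidity", "temperature", "samplingeffort", "hour", "rainfall")) {
    expect_equal(mean(prep$visits[[col]]), 0, tolerance = 1e-8)
    expect_equal(sd(prep$visits[[col]]), 1, tolerance = 1e-8)
  }
})

test_that("collinearity screen flags exact pairs and passes independent draws", {
  set.seed(7)
  x <- rnorm(100)
  tab <- data.frame(a = x, b = x, c = rnorm(100))
  fl <- check_collinearity(tab, threshold = 0.7)
  expect_equal(nrow(fl), 1)
  expect_setequal(unlist(fl[1, c("var1", "var2")]), c("a", "b"))
  expect_equal(fl$r, 1)

  fl2 <- check_collinearity(data.frame(a = x, neg = -x), threshold = 0.7)
  expect_equal(fl2$r, -1)

  set.seed(8)
  ind <- as.data.frame(matrix(rnorm(1000 * 4), ncol = 4))
  expect_equal(nrow(check_collinearity(ind, threshold = 0.7)), 0)

  # symmetry in column order and invariance to affine rescaling
  set.seed(9)
  tab <- data.frame(a = rnorm(50), b = rnorm(50))
  tab$c <- tab$a * 0.9 + rnorm(50, sd = 0.1)
  f1 <- check_collinearity(tab, 0.7)
  f2 <- check_collinearity(tab[, c(3, 1, 2)], 0.7)
  expect_equal(nrow(f1), nrow(f2))
  expect_setequal(paste(pmin(f1$var1, f1$var2), pmax(f1$var1, f1$var2)),
                  paste(pmin(f2$var1, f2$var2), pmax(f2$var1, f2$var2)))
  tab_resc <- data.frame(a = 5 * tab$a - 2, b = tab$b / 3, c = tab$c + 10)
  f3 <- check_collinearity(tab_resc, 0.7)
  expect_equal(abs(f3$r), abs(f1$r), tolerance = 1e-12)

  expect_error(check_collinearity(data.frame(a = rep(1, 10), b = rnorm(10))),
               class = "occu_degenerate_covariate")
})

test_that("temporal covariates average per site over realized visits", {
  d <- tiny_data(list(c(0, 1), 0, c(0, 0, 1)))
  d$visits$humidity <- c(-1, 1, 0.4, 0.5, 0.5, -1.0)
  d$visits$temperature <- c(2, 2, -3, 0.5, 0.5, -1.0)
  avg <- average_temporal_covariates(d)
  expect_equal(avg$humidity, c(0, 0.4, 0))
  expect_equal(avg$temperature, c(2, -3, 0))
  # single-visit site keeps its own values
  expect_equal(avg$humidity[2], d$visits$humidity[3])
})
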