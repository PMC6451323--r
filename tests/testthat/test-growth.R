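# parameter sets used across the growth tests
.growthTestParams <- list(
  log_logistic = c(A = 2, V_L = 15, alpha = 33, beta = 3),
  log_normal   = c(A = 2, V_L = 15, mu = log(26) + 0.36, sigma = 0.6),
  gompertz     = c(A = 2, V_L = 15, k = 0.15, t_i = 30),
  logistic     = c(A = 2, V_L = 15, k = 0.2, t_i = 30),
  weibull      = c(A = 2, V_L = 15, lambda = 35, k = 2.5),
  richards     = c(A = 2, V_L = 15, k = 0.2, t_i = 30, nu = 0.7))

test_that("model curves hit their half-rise anchors and asymptotes", {
  # log-logistic passes A + V_L/2 at t = alpha
  p <- .growthTestParams$log_logistic
  expect_equal(modelValue("log_logistic", p, p["alpha"]),
               unname(p["A"] + p["V_L"] / 2), ignore_attr = TRUE)
  # log-normal passes A + V_L/2 at t = e^mu
  q <- .growthTestParams$log_normal
  expect_equal(modelValue("log_normal", q, exp(q["mu"])),
               unname(q["A"] + q["V_L"] / 2), ignore_attr = TRUE)
  # all models approach A + V_L
  for (m in growthModelIds()) {
    pm <- .growthTestParams[[m]]
    expect_equal(modelValue(m, pm, 1e6), unname(pm["A"] + pm["V_L"]),
                 tolerance = 1e-6, ignore_attr = TRUE, info = m)
  }
  expect_error(modelValue("log_logistic", p, -1), "t > 0")
  expect_error(modelValue("log_normal", c(A = 1, V_L = 2, mu = 3, sigma = 0), 10),
               "positive")
})

test_that("analytic rates match finite differences and are non-negative", {
  set.seed(31)
  for (m in growthModelIds()) {
    p <- .growthTestParams[[m]]
    ts <- sort(runif(20, 18, 90))
    r <- modelRate(m, p, ts)
    expect_true(all(r >= 0), info = m)
    h <- 1e-5
    fd <- (modelValue(m, p, ts + h) - modelValue(m, p, ts - h)) / (2 * h)
    expect_equal(r, fd, tolerance = 1e-6, info = m)
  }
})

test_that("rates integrate to V_L and curves are non-decreasing", {
  for (m in growthModelIds()) {
    p <- .growthTestParams[[m]]
    pk <- peakGrowthTime(m, p, method = "numeric")$time
    # log-time and Weibull rates live on t > 0; the shifted classical
    # models have mass at negative shifted times as well
    lo <- if (m %in% c("gompertz", "logistic", "richards")) -Inf else 1e-8
    total <- integrate(function(t) modelRate(m, p, t), lo, pk,
                       rel.tol = 1e-9)$value +
      integrate(function(t) modelRate(m, p, t), pk, Inf,
                rel.tol = 1e-9)$value
    expect_equal(total, unname(p["V_L"]), tolerance = 1e-4, info = m)
    tt <- seq(1, 200, by = 0.25)
    expect_true(all(diff(modelValue(m, p, tt)) >= -1e-10), info = m)
  }
})

test_that("closed-form peak times agree with the numeric argmax", {
  # worked examples
  expect_equal(peakGrowthTime("log_logistic",
    c(A = 0, V_L = 1, alpha = 30, beta = 3))$time,
    30 * 0.5^(1 / 3), tolerance = 1e-10)
  expect_equal(peakGrowthTime("log_normal",
    c(A = 0, V_L = 1, mu = 3.3, sigma = 0.5))$time,
    exp(3.3 - 0.25), tolerance = 1e-10)
  # beta <= 1 has no interior maximum
  flat <- peakGrowthTime("log_logistic", c(A = 0, V_L = 1, alpha = 30, beta = 0.8))
  expect_true(flat$boundary)
  expect_true(is.na(flat$time))
  # 20 random parameter draws, closed form vs numeric argmax
  set.seed(17)
  for (i in 1:20) {
    m <- sample(growthModelIds(), 1)
    p <- .growthTestParams[[m]]
    p["V_L"] <- runif(1, 5, 50)
    if (m == "log_logistic") p["beta"] <- runif(1, 1.5, 6)
    if (m == "log_normal") p["sigma"] <- runif(1, 0.2, 0.8)
    if (m == "weibull") p["k"] <- runif(1, 1.5, 5)
    cf <- peakGrowthTime(m, p)$time
    nu <- peakGrowthTime(m, p, method = "numeric")$time
    expect_equal(cf, nu, tolerance = 1e-4, info = paste(m, i))
  }
})

test_that("noise-free series round-trip to the generating parameters", {
  for (m in growthModelIds()) {
    p <- .growthTestParams[[m]]
    s <- generateGrowthSeries(growthSeriesSpec(m, p, noiseSigma = 0))
    f <- fitGrowthModel(s, m)
    expect_true(f@converged, info = m)
    expect_equal(fitParams(f)[names(p)], p, tolerance = 1e-4, info = m)
  }
})

test_that("noisy series recover parameters within a few percent", {
  p <- .growthTestParams$log_logistic
  # parameter-wise relative errors pooled over 20 noise realisations
  errs <- sapply(1:20, function(s) {
    spec <- growthSeriesSpec("log_logistic", p, nPoints = 100,
                             noiseSigma = 0.02 * p[["V_L"]], seed = s)
    f <- fitGrowthModel(generateGrowthSeries(spec), "log_logistic")
    abs(fitParams(f)[names(p)] - p) / abs(p)
  })
  expect_lte(median(errs), 0.05)
})

test_that("degenerate constant series yields a flagged boundary fit", {
  s <- VolumeSeries(seq(20, 80, length.out = 30), rep(5, 30))
  f <- fitGrowthModel(s, "logistic")
  expect_true(f@boundary || fitParams(f)[["V_L"]] < 1e-3)
  expect_lt(fitRss(f), 1e-6)
})

test_that("model comparison ranks the generating model first at low noise", {
  p <- .growthTestParams$log_logistic
  wins <- sapply(1:20, function(s) {
    spec <- growthSeriesSpec("log_logistic", p, nPoints = 100,
                             noiseSigma = 0.005 * p[["V_L"]], seed = s)
    series <- generateGrowthSeries(spec)
    cmp <- compareModels(series, c("log_logistic", "gompertz"), nRestarts = 6)
    cmp$table$rss[cmp$table$model == "log_logistic"] <
      cmp$table$rss[cmp$table$model == "gompertz"]
  })
  expect_gte(mean(wins), 0.9)
})

test_that("log-time models beat all non-log-time models on log-normal data", {
  p <- .growthTestParams$log_normal
  spec <- growthSeriesSpec("log_normal", p, nPoints = 80,
                           noiseSigma = 0.005 * p[["V_L"]], seed = 3)
  cmp <- compareModels(generateGrowthSeries(spec), growthModelIds(),
                       nRestarts = 6)
  tab <- cmp$table
  logTime <- tab$rss[tab$model %in% c("log_normal", "log_logistic")]
  classical <- tab$rss[!tab$model %in% c("log_normal", "log_logistic")]
  expect_true(max(logTime) < min(classical))
})

test_that("nested models never fit worse than their special case", {
  p <- .growthTestParams$logistic
  s <- generateGrowthSeries(growthSeriesSpec("logistic", p,
    nPoints = 50, noiseSigma = 0.3, seed = 9))
  fLog <- fitGrowthModel(s, "logistic")
  fRich <- fitGrowthModel(s, "richards")
  expect_lte(fitRss(fRich), fitRss(fLog) * (1 + 1e-6) + 1e-9)
  # the same model twice gives the same rss
  cmp <- compareModels(s, c("logistic", "logistic", "gompertz"))
  expect_equal(cmp$fits[[1]]@rss, cmp$fits[[2]]@rss)
})
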