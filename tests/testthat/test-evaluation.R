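test_that("error maps are signed truth-minus-reconstruction", {
  a <- matrix(runif(16), 4, 4); b <- matrix(runif(16), 4, 4)
  expect_equal(error_map(a, a), matrix(0, 4, 4))
  expect_equal(error_map(matrix(0.75, 4, 4), matrix(1, 4, 4)),
               matrix(0.25, 4, 4))
  expect_equal(error_map(a, b), -error_map(b, a))
  expect_error(error_map(a, matrix(0, 2, 2)), "shapes")
})

test_that("MSE/RMSE match an elementwise loop oracle", {
  set.seed(5)
  a <- matrix(runif(15 * 9), 15, 9); b <- matrix(runif(15 * 9), 15, 9)
  acc <- 0
  for (i in 1:15) for (j in 1:9) acc <- acc + (a[i, j] - b[i, j])^2
  expect_equal(metric_mse(a, b), acc / (15 * 9))
  expect_equal(metric_rmse(a, b), sqrt(acc / (15 * 9)))
  d4 <- matrix(0.04, 8, 8)
  expect_equal(metric_mse(d4, matrix(0, 8, 8)), 0.0016)
  expect_equal(metric_rmse(d4, matrix(0, 8, 8)), 0.04)
  expect_equal(metric_mse(a, a), 0)
})

test_that("PSNR follows the decibel formula and handles edge cases", {
  expect_equal(metric_psnr(0.01), 20)
  expect_equal(metric_psnr(1e-4), 40)
  expect_equal(metric_psnr(1, max_i = 255), 20 * log10(255), tolerance = 1e-12)
  expect_equal(metric_psnr(1, max_i = 255), 48.1308, tolerance = 1e-4)
  expect_identical(metric_psnr(0), Inf)
  expect_error(metric_psnr(-1), "mse")
  # for unit dynamic range, PSNR = -10 log10(MSE) exactly
  for (m in c(0.5, 0.02, 3e-4)) expect_equal(metric_psnr(m), -10 * log10(m))
})

test_that("SSIM matches a brute-force sliding-window oracle", {
  set.seed(8)
  x <- matrix(runif(256), 16, 16)
  y <- pmin(pmax(x + matrix(rnorm(256, sd = 0.1), 16, 16), 0), 1)
  expect_equal(metric_ssim(x, y), ssim_bruteforce(x, y), tolerance = 1e-10)
  z <- matrix(seq(0, 1, length.out = 256), 16, 16)
  expect_equal(metric_ssim(x, z), ssim_bruteforce(x, z), tolerance = 1e-10)
})

test_that("SSIM is 1 on identical inputs, symmetric, and bounded above by 1", {
  set.seed(9)
  x <- matrix(runif(400), 20, 20)
  y <- matrix(runif(400), 20, 20)
  expect_equal(metric_ssim(x, x), 1)
  expect_equal(metric_ssim(x, y), metric_ssim(y, x))
  expect_lte(metric_ssim(x, y), 1)
  expect_lt(metric_ssim(x, y), metric_ssim(x, x))
  expect_error(metric_ssim(matrix(0, 4, 4), matrix(0, 4, 4)), "window")
})

test_that("Mann-Whitney U matches brute-force enumeration on small samples", {
  res <- mannwhitney_u(c(1, 2), c(3, 4))
  expect_equal(res$U, 0)
  cases <- list(
    list(a = c(1.2, 3.4, 0.5), b = c(2.2, 5.1, 4.4)),
    list(a = c(10, 2, 7, 1), b = c(3, 8, 12)),
    list(a = c(0.1, 0.9), b = c(0.4, 0.6, 1.3, 2.0))
  )
  for (cs in cases) {
    got <- mannwhitney_u(cs$a, cs$b)
    ref <- mw_bruteforce(cs$a, cs$b)
    expect_equal(got$U, ref$U)
    expect_equal(got$p, ref$p, tolerance = 1e-12)
  }
  expect_error(mannwhitney_u(numeric(0), 1:3), "nonempty")
})

test_that("U statistics of the two sides sum to n_a * n_b on tie-free data", {
  set.seed(12)
  for (i in 1:5) {
    a <- rnorm(6); b <- rnorm(9)
    ua <- mannwhitney_u(a, b)$U
    ub <- mannwhitney_u(b, a)$U
    expect_equal(ua + ub, length(a) * length(b))
  }
})

test_that("identical samples give a non-significant two-sided p", {
  x <- c(1, 2, 3, 4, 5)
  expect_gt(mannwhitney_u(x, x)$p, 0.9)
})

test_that("the perceptual metric is a pluggable backend", {
  set_lpips_backend(NULL)
  expect_true(is.na(metric_lpips(matrix(1, 4, 4), matrix(0, 4, 4))))
  set_lpips_backend(function(x, y) mean(abs(x - y)))
  x <- matrix(runif(64), 8, 8)
  noisy <- pmin(pmax(x + rnorm(64, sd = 0.2), 0), 1)
  expect_equal(metric_lpips(x, x), 0)
  expect_gt(metric_lpips(x, noisy), metric_lpips(x, x))
  set_lpips_backend(function(x, y) stop("boom"))
  expect_warning(v <- metric_lpips(x, x), "backend failed")
  expect_true(is.na(v))
  set_lpips_backend(NULL)
})

test_that("evaluation records have consistent metric identities", {
  ds <- toy_dataset(n_subj = 2, per_subj = 1, h = 8)
  # toy geometry: targets are 32x32, larger than the SSIM window
  rec <- evaluate_methods(ds, methods = c("nearest", "spline"))
  expect_equal(nrow(rec), 2 * length(ds))
  expect_equal(rec$rmse^2, rec$mse, tolerance = 1e-15)
  expect_true(all(rec$ssim <= 1))
  expect_true(all(rec$mse >= 0))
  expect_true(all(is.na(rec$lpips)))
  expect_error(evaluate_methods(ds, methods = "bicubic"), "unknown method")
  expect_error(evaluate_methods(ds, methods = "model"), "requires")
})

test_that("summaries report mean, sample SD, and all pairwise tests", {
  rec <- data.frame(
    method = rep(c("a", "b", "c"), each = 2),
    mse = c(1, 3, 10, 12, 20, 22),
    ssim = c(0.9, 0.8, 0.5, 0.6, 0.3, 0.2))
  rep <- summarize_evaluation(rec)
  s <- rep$summary
  expect_equal(s$mse_mean[s$method == "a"], 2)
  expect_equal(s$mse_sd[s$method == "a"], sqrt(2))
  expect_equal(nrow(rep$tests), 3 * 2)  # 3 method pairs x 2 metrics
  expect_output(print(rep), "Mann-Whitney")
})

test_that("clearly separated samples are flagged significant", {
  set.seed(30)
  rec <- data.frame(method = rep(c("good", "bad"), each = 12),
                    mse = c(runif(12, 0, 0.1), runif(12, 0.5, 1)))
  rep <- summarize_evaluation(rec)
  expect_true(all(rep$tests$significant))
  # and overlapping ones are not
  rec2 <- data.frame(method = rep(c("x", "y"), each = 12),
                     mse = c(runif(12), runif(12)))
  rep2 <- summarize_evaluation(rec2)
  expect_true(all(rep2$tests$p > 0.001))
})
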