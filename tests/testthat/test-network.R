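test_that("configuration validation enforces the architecture contract", {
  cfg <- srnet_config()
  expect_equal(cfg$upscale_factor, 4L)
  expect_equal(cfg$in_channels, 2L)
  expect_error(srnet_config(n_pairs = 0), "n_pairs")
  expect_error(srnet_config(upscale_factor = 3), "power of two")
  expect_error(srnet_config(base_channels = 0), "base_channels")
  red <- srnet_config(preset = "reduced")
  expect_equal(red$base_channels, 16L)
})

test_that("the model maps 2-channel LR inputs to 4x-upscaled single-channel maps", {
  model <- build_srnet(srnet_config(preset = "reduced", seed = 2))
  x <- array(runif(32 * 32 * 2), c(32, 32, 2))
  y <- upscale(model, x)
  expect_equal(dim(y), c(128, 128))
  expect_true(all(y >= 0 & y <= 1))  # clipped
  xb <- array(runif(32 * 32 * 2 * 3), c(32, 32, 2, 3))
  yb <- upscale(model, xb)
  expect_equal(dim(yb), c(128, 128, 1, 3))
  expect_error(upscale(model, array(0, c(32, 32, 3))), "lr_input")
})

test_that("inference is deterministic and seeded builds are reproducible", {
  model <- build_srnet(srnet_config(preset = "reduced", seed = 5))
  x <- array(runif(32 * 32 * 2), c(32, 32, 2))
  expect_identical(upscale(model, x), upscale(model, x))
  m2 <- build_srnet(srnet_config(preset = "reduced", seed = 5))
  expect_identical(mrsisr:::get_param_state(model$net),
                   mrsisr:::get_param_state(m2$net))
  m3 <- build_srnet(srnet_config(preset = "reduced", seed = 6))
  expect_false(identical(mrsisr:::get_param_state(model$net),
                         mrsisr:::get_param_state(m3$net)))
})

test_that("HFAB attention gates stay within [0,1]", {
  model <- build_srnet(srnet_config(preset = "reduced", seed = 3))
  x <- array(rnorm(32 * 32 * 2 * 2, sd = 2), c(32, 32, 2, 2))
  invisible(model$net$fw(x, train = FALSE))
  gr <- mrsisr:::hfab_gate_ranges(model)
  expect_equal(nrow(gr), model$config$n_pairs)
  expect_true(all(gr[, 1] >= 0))
  expect_true(all(gr[, 2] <= 1))
})

test_that("ERB reduces to the identity when its branch is zeroed", {
  erb <- mrsisr:::nn_erb(4, 2)
  for (p in mrsisr:::collect_params(erb))
    assign(p$val, 0 * get(p$val, envir = p$mod), envir = p$mod)
  x <- array(rnorm(6 * 6 * 4 * 2), c(6, 6, 4, 2))
  expect_equal(erb$fw(x, train = TRUE), x)
  z <- array(0, c(6, 6, 4, 1))
  expect_equal(erb$fw(z, train = TRUE), z)
})

test_that("the GDFN multiplicative gate shapes the output", {
  set.seed(4)
  gdfn <- mrsisr:::nn_gdfn(4, 2)
  # give the zero-initialized projection real weights so the branch is active
  ps <- mrsisr:::collect_params(gdfn)
  for (p in ps) {
    v <- get(p$val, envir = p$mod)
    r <- stats::rnorm(length(v), sd = 0.3)
    if (!is.null(dim(v))) dim(r) <- dim(v)
    assign(p$val, r, envir = p$mod)
  }
  x <- array(rnorm(8 * 8 * 4 * 1), c(8, 8, 4, 1))
  y_gated <- gdfn$fw(x, train = TRUE)
  expect_equal(dim(y_gated), dim(x))
  # force the gate branch to a constant 1: output must change
  gdfn$children[[3]]$fw <- function(x, train) array(1, dim(x))
  y_open <- gdfn$fw(x, train = TRUE)
  expect_gt(max(abs(y_gated - y_open)), 1e-6)
})

test_that("the sub-pixel head turns 32x32 features into 128x128 maps", {
  head <- mrsisr:::nn_head(4, 1, 4)
  x <- array(rnorm(32 * 32 * 4), c(32, 32, 4, 1))
  y <- head$fw(x, train = TRUE)
  expect_equal(dim(y), c(128, 128, 1, 1))
  # zero features, zero biases -> zero map
  z <- head$fw(array(0, c(32, 32, 4, 1)), train = TRUE)
  expect_true(all(z == 0))
  # averaging kernels propagate constants
  for (p in mrsisr:::collect_params(head)) {
    v <- get(p$val, envir = p$mod)
    if (length(dim(v)) == 4)
      assign(p$val, array(1 / (dim(v)[1] * dim(v)[2] * dim(v)[3]), dim(v)),
             envir = p$mod)
    else assign(p$val, 0 * v, envir = p$mod)
  }
  yc <- head$fw(array(0.7, c(32, 32, 4, 1)), train = TRUE)
  expect_equal(as.vector(yc[8:120, 8:120, 1, 1]), rep(0.7, 113^2),
               tolerance = 1e-12)
})

test_that("the default configuration meets the parameter budget", {
  model <- build_srnet(srnet_config())
  expect_gt(model$n_params, 0.9 * 650000)
  expect_lt(model$n_params, 1.1 * 650000)
  sm <- summary(model)
  expect_equal(sum(sm$blocks), model$n_params)
  expect_output(print(model), "params")
})

test_that("an untrained model differs from the spline baseline", {
  model <- build_srnet(srnet_config(preset = "reduced", seed = 9))
  lr <- matrix(runif(32 * 32), 32, 32)
  x <- array(c(lr, lr), c(32, 32, 2))
  expect_gt(max(abs(upscale(model, x) - spline_upscale(lr, 4))), 1e-3)
})

test_that("checkpoints round-trip weights, config and history", {
  model <- build_srnet(srnet_config(preset = "reduced", seed = 4))
  model$history <- data.frame(epoch = 1, train_loss = 0.5, val_loss = 0.6)
  path <- tempfile(fileext = ".rds")
  srnet_save(model, path)
  back <- srnet_load(path)
  expect_identical(mrsisr:::get_param_state(back$net),
                   mrsisr:::get_param_state(model$net))
  expect_equal(back$config, model$config)
  expect_equal(back$history, model$history)
  x <- array(runif(32 * 32 * 2), c(32, 32, 2))
  expect_identical(upscale(back, x), upscale(model, x))
})
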