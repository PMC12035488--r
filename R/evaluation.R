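# Fidelity metrics (MSE/RMSE/PSNR/SSIM), an optional perceptual-metric
# plug-in, per-map evaluation records and method-level summaries with
# Mann-Whitney U comparisons.

#' Pixelwise error map
#'
#' `truth - upscaled` (ground truth minus reconstruction), the convention
#' used for the difference images in the comparison figures.
#'
#' @param upscaled,truth Matrices or [metabolite_map()]s of equal shape.
#' @return A numeric matrix of signed errors.
#' @export
error_map <- function(upscaled, truth) {
  a <- as_map_values(upscaled); b <- as_map_values(truth)
  if (!identical(dim(a), dim(b))) stop_invalid("shapes differ")
  b - a
}

#' Mean squared error and root mean squared error
#'
#' @param a,b Numeric arrays of equal shape.
#' @return A scalar.
#' @export
metric_mse <- function(a, b) {
  a <- as_map_values(a); b <- as_map_values(b)
  if (!identical(dim(a), dim(b))) stop_invalid("shapes differ")
  mean((a - b)^2)
}

#' @rdname metric_mse
#' @export
metric_rmse <- function(a, b) sqrt(metric_mse(a, b))

#' Peak signal-to-noise ratio (dB)
#'
#' `20 log10(max_i) - 10 log10(mse)`; for normalized maps `max_i = 1` so
#' PSNR reduces to `-10 log10(mse)`. A zero MSE is reported as `Inf`.
#'
#' @param mse_value Mean squared error (>= 0).
#' @param max_i Maximum possible pixel value (default 1 for normalized maps).
#' @return PSNR in dB.
#' @export
metric_psnr <- function(mse_value, max_i = 1.0) {
  if (mse_value < 0) stop_invalid("mse must be >= 0")
  if (mse_value == 0) return(Inf)
  20 * log10(max_i) - 10 * log10(mse_value)
}

#' SSIM parameters
#'
#' Stabilization constants `c1 = (k1 L)^2`, `c2 = (k2 L)^2` with the
#' conventional `k1 = 0.01`, `k2 = 0.03`, dynamic range `L = 1` for
#' normalized maps, and an 11x11 Gaussian window with sigma 1.5.
#'
#' @param k1,k2 Stabilization coefficients.
#' @param L Dynamic range of the pixel values.
#' @param window_size Odd Gaussian window side length.
#' @param sigma Gaussian window standard deviation.
#' @return A list of class `ssim_params`.
#' @export
ssim_params <- function(k1 = 0.01, k2 = 0.03, L = 1.0, window_size = 11L,
                        sigma = 1.5) {
  if (k1 <= 0 || k2 <= 0 || L <= 0) stop_invalid("k1, k2, L must be > 0")
  if (window_size %% 2 != 1) stop_invalid("window_size must be odd")
  structure(list(k1 = k1, k2 = k2, L = L, window_size = as.integer(window_size),
                 sigma = sigma, c1 = (k1 * L)^2, c2 = (k2 * L)^2),
            class = "ssim_params")
}

gaussian_window <- function(size, sigma) {
  g <- stats::dnorm(seq(-(size %/% 2), size %/% 2), sd = sigma)
  w <- outer(g, g)
  w / sum(w)
}

# windowed local average over valid positions (no padding)
valid_filter <- function(m, kern) {
  k <- nrow(kern)
  x <- array(m, c(nrow(m), ncol(m), 1L, 1L))
  w <- array(kern, c(k, k, 1L, 1L))
  y <- cpp_conv2d_forward(x, w, 0, 0L, 1L)
  matrix(y, nrow(m) - k + 1L, ncol(m) - k + 1L)
}

#' Structural similarity index
#'
#' Local means, variances and covariance are computed under a Gaussian
#' window at every fully-contained (valid) window position; the per-position
#' SSIM values are averaged. Bounded above by 1, with `ssim(x, x) = 1`.
#'
#' @param x,y Matrices (or maps) of equal shape, at least as large as the
#'   window.
#' @param params An [ssim_params()].
#' @return Mean SSIM.
#' @export
metric_ssim <- function(x, y, params = ssim_params()) {
  x <- as_map_values(x); y <- as_map_values(y)
  if (!identical(dim(x), dim(y))) stop_invalid("shapes differ")
  if (nrow(x) < params$window_size || ncol(x) < params$window_size)
    stop_invalid("image smaller than the SSIM window")
  w <- gaussian_window(params$window_size, params$sigma)
  mx <- valid_filter(x, w); my <- valid_filter(y, w)
  sxx <- valid_filter(x * x, w) - mx * mx
  syy <- valid_filter(y * y, w) - my * my
  sxy <- valid_filter(x * y, w) - mx * my
  num <- (2 * mx * my + params$c1) * (2 * sxy + params$c2)
  den <- (mx^2 + my^2 + params$c1) * (sxx + syy + params$c2)
  mean(num / den)
}

# perceptual-metric plug-in registry --------------------------------------

the <- new.env(parent = emptyenv())

#' Register a perceptual (LPIPS-style) metric backend
#'
#' The perceptual distance requires a pretrained external backend and is
#' therefore pluggable: register any `function(x, y)` returning a
#' nonnegative scalar (lower = more similar). With no backend registered,
#' [metric_lpips()] returns `NA` and evaluation reports simply omit the
#' metric.
#'
#' @param backend A `function(x, y)` or `NULL` to unregister.
#' @export
set_lpips_backend <- function(backend) {
  if (!is.null(backend) && !is.function(backend))
    stop_invalid("backend must be a function(x, y) or NULL")
  the$lpips_backend <- backend
  invisible(backend)
}

has_lpips_backend <- function() !is.null(the$lpips_backend)

#' Perceptual distance between two maps
#'
#' @param x,y Matrices of equal shape.
#' @return The backend's distance, or `NA_real_` if no backend is registered
#'   or the backend fails (with a warning).
#' @export
metric_lpips <- function(x, y) {
  if (!has_lpips_backend()) return(NA_real_)
  out <- tryCatch(the$lpips_backend(as_map_values(x), as_map_values(y)),
                  error = function(e) {
                    warning("perceptual backend failed: ", conditionMessage(e))
                    NA_real_
                  })
  as.numeric(out)
}

#' Mann-Whitney U test for two metric samples
#'
#' Two-sided rank-sum comparison. Small tie-free samples (both sizes <= 8)
#' use the exact null distribution; larger or tied samples use the normal
#' approximation with tie correction.
#'
#' @param sample_a,sample_b Numeric vectors (nonempty).
#' @return A list with `U` (the U statistic of `sample_a`) and `p`.
#' @export
#' @examples
#' mannwhitney_u(c(1, 2), c(3, 4))$U  # 0
mannwhitney_u <- function(sample_a, sample_b) {
  if (length(sample_a) == 0 || length(sample_b) == 0)
    stop_invalid("samples must be nonempty")
  ties <- any(duplicated(c(sample_a, sample_b)))
  use_exact <- !ties && length(sample_a) <= 8 && length(sample_b) <= 8
  ht <- suppressWarnings(stats::wilcox.test(sample_a, sample_b,
                                            alternative = "two.sided",
                                            exact = use_exact, correct = !use_exact))
  list(U = unname(ht$statistic), p = ht$p.value)
}

#' Evaluate upscaling methods on a test dataset
#'
#' For every example the ground-truth 128x128 map is compared against each
#' method's reconstruction: the learned model consumes the 2-channel LR
#' input, the baselines the LR map channel alone. One record per (method,
#' map) with MSE, RMSE, PSNR, SSIM and (when a backend is registered) the
#' perceptual distance.
#'
#' @param dataset A test `sr_dataset`.
#' @param methods Subset of `c("model", "nearest", "spline")`.
#' @param model A trained `srnet` (required when `"model"` is included).
#' @param params An [ssim_params()].
#' @param self_ensemble Use the geometric self-ensemble for the model's
#'   predictions (see [upscale()]).
#' @return A data frame of evaluation records.
#' @export
evaluate_methods <- function(dataset, methods = c("nearest", "spline"),
                             model = NULL, params = ssim_params(),
                             self_ensemble = FALSE) {
  bad <- setdiff(methods, c("model", "nearest", "spline"))
  if (length(bad)) stop_invalid("unknown method(s) ", paste(bad, collapse = ", "),
                                "; valid: model, nearest, spline")
  if ("model" %in% methods && is.null(model))
    stop_invalid("including 'model' requires a trained model")
  recs <- list()
  # model predictions in bounded-size chunks to cap memory
  preds <- NULL
  if ("model" %in% methods) {
    n <- length(dataset$examples)
    chunks <- lapply(seq(1, n, by = 24), function(s) {
      upscale(model, dataset_lr_batch(dataset, s:min(s + 23, n)),
              self_ensemble = self_ensemble)
    })
    preds <- array(unlist(chunks, use.names = FALSE),
                   c(dim(chunks[[1]])[1:3], n))
  }
  for (i in seq_along(dataset$examples)) {
    ex <- dataset$examples[[i]]
    truth <- ex$hr[, , 1]
    f <- nrow(truth) %/% nrow(ex$lr[, , 1])
    for (m in methods) {
      up <- switch(m,
        nearest = nearest_upscale(ex$lr[, , 1], f),
        spline = spline_upscale(ex$lr[, , 1], f),
        model = preds[, , 1, i])
      mse <- metric_mse(up, truth)
      recs[[length(recs) + 1]] <- data.frame(
        method = m, subject_id = ex$meta$subject_id,
        slice_index = ex$meta$slice_index, map_type = ex$meta$map_type,
        mse = mse, rmse = sqrt(mse), psnr = metric_psnr(mse, params$L),
        ssim = metric_ssim(up, truth, params),
        lpips = metric_lpips(up, truth), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, recs)
}

#' Summarize evaluation records into a method-comparison report
#'
#' Per-method mean and sample (n-1) standard deviation of each metric, plus
#' two-sided pairwise Mann-Whitney U tests between methods for every metric,
#' flagged at the 0.05 significance threshold.
#'
#' @param records Data frame from [evaluate_methods()].
#' @param alpha Significance threshold (default 0.05).
#' @return An object of class `eval_report`.
#' @export
summarize_evaluation <- function(records, alpha = 0.05) {
  metrics <- intersect(c("mse", "rmse", "psnr", "ssim", "lpips"), names(records))
  metrics <- metrics[vapply(metrics, function(m) !all(is.na(records[[m]])), TRUE)]
  methods <- unique(records$method)
  summary <- do.call(rbind, lapply(methods, function(m) {
    sub <- records[records$method == m, ]
    row <- data.frame(method = m, n = nrow(sub), stringsAsFactors = FALSE)
    for (met in metrics) {
      row[[paste0(met, "_mean")]] <- mean(sub[[met]])
      row[[paste0(met, "_sd")]] <- stats::sd(sub[[met]])
    }
    row
  }))
  tests <- NULL
  if (length(methods) >= 2) {
    pairs <- utils::combn(methods, 2, simplify = FALSE)
    tests <- do.call(rbind, lapply(pairs, function(pr) {
      do.call(rbind, lapply(metrics, function(met) {
        res <- mannwhitney_u(records[[met]][records$method == pr[1]],
                             records[[met]][records$method == pr[2]])
        data.frame(method_a = pr[1], method_b = pr[2], metric = met,
                   U = res$U, p = res$p, significant = res$p < alpha,
                   stringsAsFactors = FALSE)
      }))
    }))
  }
  structure(list(summary = summary, tests = tests, alpha = alpha,
                 metrics = metrics), class = "eval_report")
}

#' @export
print.eval_report <- function(x, digits = 4, ...) {
  cat("Upscaling method comparison (mean (SD) per metric)\n\n")
  hdr <- sprintf("%-9s", "method")
  for (m in x$metrics) hdr <- paste0(hdr, sprintf("  %-18s", toupper(m)))
  cat(hdr, "\n")
  for (i in seq_len(nrow(x$summary))) {
    line <- sprintf("%-9s", x$summary$method[i])
    for (m in x$metrics) {
      line <- paste0(line, sprintf("  %-18s",
        sprintf("%.*f (%.*f)", digits, x$summary[[paste0(m, "_mean")]][i],
                digits, x$summary[[paste0(m, "_sd")]][i])))
    }
    cat(line, "\n")
  }
  if (!is.null(x$tests)) {
    cat(sprintf("\nPairwise Mann-Whitney U tests (two-sided, alpha = %g):\n",
                x$alpha))
    for (i in seq_len(nrow(x$tests))) {
      t <- x$tests[i, ]
      cat(sprintf("  %-7s vs %-7s  %-5s  U = %8.1f  p = %.4g%s\n",
                  t$method_a, t$method_b, t$metric, t$U, t$p,
                  if (t$significant) "  *" else ""))
    }
  }
  invisible(x)
}

#' Write evaluation outputs as CSV
#'
#' @param records Data frame from [evaluate_methods()].
#' @param report An `eval_report`.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_evaluation <- function(records, report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(records, file.path(dir, "records.csv"), row.names = FALSE)
  utils::write.csv(report$summary, file.path(dir, "summary.csv"), row.names = FALSE)
  if (!is.null(report$tests))
    utils::write.csv(report$tests, file.path(dir, "tests.csv"), row.names = FALSE)
  invisible(dir)
}
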