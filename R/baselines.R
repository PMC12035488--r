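# Classical interpolation baselines the network is compared against. Both
# accept either a plain matrix or a metabolite_map and return the same kind.

as_map_values <- function(x) if (inherits(x, "metabolite_map")) x$values else x

rewrap_map <- function(x, values) {
  if (inherits(x, "metabolite_map")) {
    x$values <- values
    x$resolution <- nrow(values)
    x
  } else values
}

#' Nearest-neighbor upscaling
#'
#' Replicates each low-resolution pixel into a `factor x factor` block; the
#' exact inverse of block-mean downsampling on images that are constant
#' within blocks.
#'
#' @param lr A matrix or [metabolite_map()].
#' @param factor Integer upscaling factor (>= 1; `1` returns the input).
#' @return The upscaled matrix or map.
#' @export
nearest_upscale <- function(lr, factor = 4L) {
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1) stop_invalid("factor must be a positive integer")
  x <- as_map_values(lr)
  rewrap_map(lr, kronecker(x, matrix(1, factor, factor)))
}

# reflect-pad a vector of samples by p on both sides (half-sample symmetric)
reflect_pad <- function(v, p) {
  n <- length(v)
  c(v[pmin(p:1, n)], v, v[pmax(n - seq_len(p) + 1, 1)])
}

interp_1d <- function(v, xout, order) {
  p <- 3L
  xs <- seq(1 - p, length(v) + p)
  vs <- reflect_pad(v, p)
  if (order == 1) {
    stats::approx(xs, vs, xout = xout, rule = 2)$y
  } else if (order == 2) {
    # local 3-point Lagrange quadratic centered on the nearest sample
    j <- pmin(pmax(round(xout), xs[2]), xs[length(xs) - 1])
    i0 <- j - xs[1] + 1  # index of center sample in vs (xs[i] = xs[1] + i - 1)
    t <- xout - j
    y0 <- vs[i0]; ym <- vs[i0 - 1]; yp <- vs[i0 + 1]
    y0 + t * (yp - ym) / 2 + t^2 * (yp - 2 * y0 + ym) / 2
  } else {
    stats::splinefun(xs, vs, method = "natural")(xout)
  }
}

#' Spline upscaling
#'
#' Separable polynomial-spline interpolation with the half-pixel center
#' convention (output pixel `i` samples the input at `(i - 0.5)/factor +
#' 0.5`), reflect boundary handling, and (for inputs within `[0, 1]`)
#' clipping of spline overshoot back to `[0, 1]`. The default `order = 3` is
#' a natural cubic spline; `order = 1` is linear and `order = 2` a local
#' quadratic.
#'
#' @param lr A matrix or [metabolite_map()].
#' @param factor Integer upscaling factor (>= 1).
#' @param order Interpolation order, one of 1, 2, 3.
#' @param clip Clip the result to `[0, 1]` (default `TRUE`; applied only when
#'   the input itself lies in `[0, 1]`).
#' @return The upscaled matrix or map.
#' @export
spline_upscale <- function(lr, factor = 4L, order = 3L, clip = TRUE) {
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1) stop_invalid("factor must be a positive integer")
  if (!order %in% 1:3) stop_invalid("order must be 1, 2 or 3")
  x <- as_map_values(lr)
  if (factor == 1) return(lr)
  n <- nrow(x); m <- ncol(x)
  xo <- (seq_len(n * factor) - 0.5) / factor + 0.5
  yo <- (seq_len(m * factor) - 0.5) / factor + 0.5
  tmp <- apply(x, 2, interp_1d, xout = xo, order = order)      # rows
  out <- t(apply(tmp, 1, interp_1d, xout = yo, order = order)) # cols
  if (clip && min(x) >= 0 && max(x) <= 1) out <- pmin(pmax(out, 0), 1)
  rewrap_map(lr, out)
}

#' Upscale with a selectable method
#'
#' Shared interface over the learned model and the two interpolation
#' baselines.
#'
#' @param lr A matrix, [metabolite_map()], or (for `"model"`) a
#'   `(32, 32, 2)` input array.
#' @param method `"model"`, `"nearest"` or `"spline"`.
#' @param model A trained `srnet`, required for `method = "model"`.
#' @param factor Upscaling factor for the baselines.
#' @return The upscaled image.
#' @export
upscale_method <- function(lr, method = c("model", "nearest", "spline"),
                           model = NULL, factor = 4L) {
  method <- match.arg(method)
  switch(method,
    nearest = nearest_upscale(lr, factor),
    spline = spline_upscale(lr, factor),
    model = {
      if (is.null(model)) stop_invalid("method = 'model' requires a trained model")
      upscale(model, lr)
    })
}
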