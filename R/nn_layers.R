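# Minimal define-by-hand neural network layers with explicit forward/backward
# passes. Tensors are base-R double arrays with dim (H, W, C, N); convolutions
# run through the compiled im2col+GEMM kernels in src/.
#
# A "module" is an environment with fields:
#   fw(x, train)  forward pass (caches what backward needs)
#   bw(dy)        backward pass; accumulates parameter gradients, returns dx
#   params()      list of parameter/gradient slot name pairs for the optimizer

conv2d_forward <- function(x, w, b, pad, groups = 1L)
  cpp_conv2d_forward(x, w, b, as.integer(pad), as.integer(groups))

# per-channel sum of an (H,W,C,N) array
channel_sum <- function(x) {
  d <- dim(x)
  m <- matrix(x, nrow = d[1] * d[2])
  cs <- .colSums(m, d[1] * d[2], d[3] * d[4])
  .rowSums(matrix(cs, d[3], d[4]), d[3], d[4])
}

# expand a per-channel vector to the full (H,W,C,N) length
channel_expand <- function(v, d) rep(rep(v, each = d[1] * d[2]), times = d[4])

nn_conv <- function(k, cin, cout, groups = 1L, gain = sqrt(2)) {
  m <- new.env(parent = emptyenv())
  m$kind <- "conv"
  m$pad <- (k - 1L) %/% 2L
  m$groups <- as.integer(groups)
  fan_in <- k * k * cin / groups
  m$W <- array(stats::rnorm(k * k * (cin %/% groups) * cout, sd = gain / sqrt(fan_in)),
               dim = c(k, k, cin %/% groups, cout))
  m$b <- numeric(cout)
  m$gW <- NULL; m$gb <- NULL
  m$fw <- function(x, train) {
    m$x <- if (train) x  # cache only when a backward pass can follow
    cpp_conv2d_forward(x, m$W, m$b, m$pad, m$groups)
  }
  m$bw <- function(dy) {
    g <- cpp_conv2d_backward(m$x, m$W, dy, m$pad, m$groups)
    m$gW <- if (is.null(m$gW)) g$dw else m$gW + g$dw
    m$gb <- if (is.null(m$gb)) g$db else m$gb + g$db
    m$x <- NULL
    g$dx
  }
  m$params <- function() list(c("W", "gW"), c("b", "gb"))
  m
}

nn_bn <- function(ch, momentum = 0.1, eps = 1e-5) {
  m <- new.env(parent = emptyenv())
  m$kind <- "bn"
  m$gamma <- rep(1, ch); m$beta <- numeric(ch)
  m$run_mean <- numeric(ch); m$run_var <- rep(1, ch)
  m$momentum <- momentum; m$eps <- eps
  m$ggamma <- NULL; m$gbeta <- NULL
  m$fw <- function(x, train) {
    d <- dim(x)
    if (train) {
      n <- d[1] * d[2] * d[4]
      mu <- channel_sum(x) / n
      xc <- x - channel_expand(mu, d)
      va <- channel_sum(xc * xc) / n
      m$run_mean <- (1 - m$momentum) * m$run_mean + m$momentum * mu
      m$run_var <- (1 - m$momentum) * m$run_var + m$momentum * va
      invstd <- 1 / sqrt(va + m$eps)
      xhat <- xc * channel_expand(invstd, d)
      m$xhat <- xhat; m$invstd <- invstd; m$n <- n
      xhat * channel_expand(m$gamma, d) + channel_expand(m$beta, d)
    } else {
      invstd <- 1 / sqrt(m$run_var + m$eps)
      (x - channel_expand(m$run_mean, d)) * channel_expand(m$gamma * invstd, d) +
        channel_expand(m$beta, d)
    }
  }
  m$bw <- function(dy) {
    d <- dim(dy)
    dxhat <- dy * channel_expand(m$gamma, d)
    dg <- channel_sum(dy * m$xhat)
    db <- channel_sum(dy)
    m$ggamma <- if (is.null(m$ggamma)) dg else m$ggamma + dg
    m$gbeta <- if (is.null(m$gbeta)) db else m$gbeta + db
    s1 <- channel_sum(dxhat) / m$n
    s2 <- channel_sum(dxhat * m$xhat) / m$n
    dx <- (dxhat - channel_expand(s1, d) - m$xhat * channel_expand(s2, d)) *
      channel_expand(m$invstd, d)
    m$xhat <- NULL
    dx
  }
  m$params <- function() list(c("gamma", "ggamma"), c("beta", "gbeta"))
  m
}

# "gelu" is the sigmoid-weighted linear unit x * sigmoid(1.702 x), the cheap
# smooth approximation of the Gaussian-error gate
nn_act <- function(type = c("relu", "gelu", "sigmoid")) {
  type <- match.arg(type)
  m <- new.env(parent = emptyenv())
  m$kind <- type
  m$fw <- switch(type,
    relu = function(x, train) { m$x <- if (train) x; x * (x > 0) },
    gelu = function(x, train) {
      s <- 1 / (1 + exp(-1.702 * x))
      if (train) { m$x <- x; m$s <- s }
      x * s
    },
    sigmoid = function(x, train) {
      y <- 1 / (1 + exp(-x))
      m$y <- if (train) y
      y
    }
  )
  m$bw <- switch(type,
    relu = function(dy) { dx <- dy * (m$x > 0); m$x <- NULL; dx },
    gelu = function(dy) {
      dx <- dy * (m$s + 1.702 * m$x * m$s * (1 - m$s))
      m$x <- NULL; m$s <- NULL
      dx
    },
    sigmoid = function(dy) { dx <- dy * m$y * (1 - m$y); m$y <- NULL; dx }
  )
  m$params <- function() list()
  m
}

# depth-to-space rearrangement: (H, W, C*r^2, N) -> (rH, rW, C, N)
nn_pixel_shuffle <- function(r = 2L) {
  m <- new.env(parent = emptyenv())
  m$kind <- "pixel_shuffle"; m$r <- as.integer(r)
  m$fw <- function(x, train) {
    stopifnot(dim(x)[3] %% (m$r * m$r) == 0)
    cpp_pixel_shuffle(x, m$r, FALSE)
  }
  m$bw <- function(dy) cpp_pixel_shuffle(dy, m$r, TRUE)
  m$params <- function() list()
  m
}

nn_seq <- function(...) {
  m <- new.env(parent = emptyenv())
  m$kind <- "seq"
  m$layers <- list(...)
  m$fw <- function(x, train) {
    for (l in m$layers) x <- l$fw(x, train)
    x
  }
  m$bw <- function(dy) {
    for (l in rev(m$layers)) dy <- l$bw(dy)
    dy
  }
  m$params <- function() list()
  m
}

# walk a module tree collecting (module, value-slot, grad-slot) triples
collect_params <- function(mod) {
  out <- list()
  rec <- function(m) {
    for (p in m$params()) out[[length(out) + 1]] <<- list(mod = m, val = p[1], grad = p[2])
    if (!is.null(m$layers)) for (l in m$layers) rec(l)
    if (!is.null(m$children)) for (l in m$children) rec(l)
  }
  rec(mod)
  out
}

zero_grads <- function(mod) {
  for (p in collect_params(mod)) assign(p$grad, NULL, envir = p$mod)
  invisible(NULL)
}

n_parameters <- function(mod) {
  sum(vapply(collect_params(mod), function(p) length(get(p$val, envir = p$mod)), 0))
}

# flat copies of parameter values, for checkpointing
get_param_state <- function(mod) {
  lapply(collect_params(mod), function(p) get(p$val, envir = p$mod))
}

set_param_state <- function(mod, state) {
  ps <- collect_params(mod)
  stopifnot(length(ps) == length(state))
  for (i in seq_along(ps)) assign(ps[[i]]$val, state[[i]], envir = ps[[i]]$mod)
  invisible(NULL)
}

# running batch-norm statistics are state too; captured alongside weights
get_bn_state <- function(mod) {
  out <- list()
  rec <- function(m) {
    if (identical(m$kind, "bn")) out[[length(out) + 1]] <<- list(m$run_mean, m$run_var)
    if (!is.null(m$layers)) for (l in m$layers) rec(l)
    if (!is.null(m$children)) for (l in m$children) rec(l)
  }
  rec(mod)
  out
}

set_bn_state <- function(mod, state) {
  i <- 0
  rec <- function(m) {
    if (identical(m$kind, "bn")) {
      i <<- i + 1
      m$run_mean <- state[[i]][[1]]; m$run_var <- state[[i]][[2]]
    }
    if (!is.null(m$layers)) for (l in m$layers) rec(l)
    if (!is.null(m$children)) for (l in m$children) rec(l)
  }
  rec(mod)
  invisible(NULL)
}
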