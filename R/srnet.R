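#' Configuration for the super-resolution network
#'
#' The network upscales 2-channel 32x32 inputs (a normalized low-resolution
#' metabolite map concatenated with a matched low-resolution FLAIR slice) to a
#' 1-channel 128x128 map. Its body stacks `n_pairs` pairs of a high-frequency
#' attention block (HFAB) followed by a gated depthwise-convolution
#' feed-forward block (GDFN), with two long skip connections from the shallow
#' features (one at the body midpoint, one at the body end), and finishes with
#' a two-stage sub-pixel convolution head.
#'
#' The default width `base_channels = 48` is chosen so that the default
#' configuration carries approximately 650,000 trainable parameters. The
#' `"reduced"` preset (`base_channels = 16`, `n_pairs = 4`) is a small model
#' for CPU-scale experiments and sanity checks.
#'
#' @param base_channels Feature width of the body.
#' @param n_pairs Number of HFAB+GDFN pairs (>= 1).
#' @param upscale_factor Spatial upscaling factor; must be a power of two
#'   (the reference pipeline uses 4).
#' @param in_channels,out_channels Input/output channel counts.
#' @param erb_expansion Channel expansion inside the enhanced residual block.
#' @param gdfn_expansion Channel expansion of the GDFN branches.
#' @param attn_reduction Channel reduction inside the HFAB attention branch.
#' @param sigmoid_head If `TRUE` the output conv is followed by a sigmoid;
#'   default is a linear head with clipping to `[0, 1]` at inference.
#' @param seed Seed for weight initialization.
#' @param preset `"default"` or `"reduced"`.
#' @return An object of class `srnet_config`.
#' @export
#' @examples
#' srnet_config(preset = "reduced")
srnet_config <- function(base_channels = 48L, n_pairs = 8L, upscale_factor = 4L,
                         in_channels = 2L, out_channels = 1L,
                         erb_expansion = 2L, gdfn_expansion = 2L,
                         attn_reduction = 2L, sigmoid_head = FALSE, seed = 1L,
                         preset = c("default", "reduced")) {
  preset <- match.arg(preset)
  if (preset == "reduced") {
    if (missing(base_channels)) base_channels <- 16L
    if (missing(n_pairs)) n_pairs <- 4L
  }
  cfg <- list(base_channels = as.integer(base_channels),
              n_pairs = as.integer(n_pairs),
              upscale_factor = as.integer(upscale_factor),
              in_channels = as.integer(in_channels),
              out_channels = as.integer(out_channels),
              erb_expansion = as.integer(erb_expansion),
              gdfn_expansion = as.integer(gdfn_expansion),
              attn_reduction = as.integer(attn_reduction),
              sigmoid_head = isTRUE(sigmoid_head),
              seed = as.integer(seed))
  if (cfg$n_pairs < 1) stop_invalid("n_pairs must be >= 1")
  if (cfg$base_channels < 1) stop_invalid("base_channels must be >= 1")
  if (cfg$upscale_factor < 2 ||
      2^round(log2(cfg$upscale_factor)) != cfg$upscale_factor)
    stop_invalid("upscale_factor must be a power of two (reference: 4)")
  if (cfg$base_channels %% cfg$attn_reduction != 0)
    stop_invalid("base_channels must be divisible by attn_reduction")
  class(cfg) <- "srnet_config"
  cfg
}

# enhanced residual block: 1x1 expand -> 3x3 conv -> 1x1 contract, + input
nn_erb <- function(ch, expansion = 2L) {
  m <- new.env(parent = emptyenv())
  m$kind <- "erb"
  e <- ch * expansion
  m$children <- list(nn_seq(nn_conv(1, ch, e), nn_act("relu"),
                            nn_conv(3, e, e), nn_act("relu"),
                            nn_conv(1, e, ch)))
  m$fw <- function(x, train) x + m$children[[1]]$fw(x, train)
  m$bw <- function(dy) dy + m$children[[1]]$bw(dy)
  m$params <- function() list()
  m
}

# high-frequency attention block: a batch-normalized convolutional branch
# (with an ERB at reduced width) produces a sigmoid gate g in [0,1];
# output = x + x * g
nn_hfab <- function(ch, reduction = 2L, erb_expansion = 2L) {
  m <- new.env(parent = emptyenv())
  m$kind <- "hfab"
  cr <- ch %/% reduction
  m$children <- list(nn_seq(nn_bn(ch),
                            nn_conv(3, ch, cr), nn_act("relu"),
                            nn_erb(cr, erb_expansion),
                            nn_conv(3, cr, ch),
                            nn_bn(ch), nn_act("sigmoid")))
  m$fw <- function(x, train) {
    g <- m$children[[1]]$fw(x, train)
    if (train) { m$x <- x; m$g <- g }
    m$gate_range <- range(g)  # instrumentation: gate boundedness
    x + x * g
  }
  m$bw <- function(dy) {
    dx <- dy * (1 + m$g) + m$children[[1]]$bw(dy * m$x)
    m$x <- NULL; m$g <- NULL
    dx
  }
  m$params <- function() list()
  m
}

# gated depthwise-conv feed-forward block: two parallel 1x1 + depthwise-3x3
# projections; the GELU of one gates the other elementwise; 1x1 back, + input
nn_gdfn <- function(ch, expansion = 2L) {
  m <- new.env(parent = emptyenv())
  m$kind <- "gdfn"
  e <- ch * expansion
  p1 <- nn_seq(nn_conv(1, ch, e), nn_conv(3, e, e, groups = e))
  p2 <- nn_seq(nn_conv(1, ch, e), nn_conv(3, e, e, groups = e))
  act <- nn_act("gelu")
  # zero-init projection makes the block an identity at initialization,
  # preventing the multiplicative gate from inflating activations through
  # the stacked body
  proj <- nn_conv(1, e, ch, gain = 0)
  m$children <- list(p1, p2, act, proj)
  m$fw <- function(x, train) {
    a <- p1$fw(x, train)
    b <- p2$fw(x, train)
    h <- act$fw(a, train)
    if (train) { m$h <- h; m$b2 <- b }
    x + proj$fw(h * b, train)
  }
  m$bw <- function(dy) {
    dm <- proj$bw(dy)
    dh <- dm * m$b2
    db <- dm * m$h
    m$h <- NULL; m$b2 <- NULL
    dy + p1$bw(act$bw(dh)) + p2$bw(db)
  }
  m$params <- function() list()
  m
}

# sub-pixel upsampling head: (3x3 conv to 4C -> depth-to-space x2) per stage,
# then 3x3 conv to out_channels; linear output by default
nn_head <- function(ch, out_ch, factor, sigmoid_head = FALSE) {
  n_stages <- as.integer(round(log2(factor)))
  layers <- list()
  for (s in seq_len(n_stages)) {
    layers[[length(layers) + 1]] <- nn_conv(3, ch, 4L * ch)
    layers[[length(layers) + 1]] <- nn_pixel_shuffle(2L)
  }
  # small output-layer init keeps initial predictions near zero so early
  # training is not spent shrinking the output scale
  layers[[length(layers) + 1]] <- nn_conv(3, ch, out_ch, gain = 0.1)
  if (sigmoid_head) layers[[length(layers) + 1]] <- nn_act("sigmoid")
  do.call(nn_seq, layers)
}

build_net_graph <- function(cfg) {
  ch <- cfg$base_channels
  net <- new.env(parent = emptyenv())
  net$kind <- "srnet_graph"
  net$shallow <- nn_conv(3, cfg$in_channels, ch)
  net$blocks <- list()
  for (i in seq_len(cfg$n_pairs)) {
    net$blocks[[2 * i - 1]] <- nn_hfab(ch, cfg$attn_reduction, cfg$erb_expansion)
    net$blocks[[2 * i]] <- nn_gdfn(ch, cfg$gdfn_expansion)
  }
  net$head <- nn_head(ch, cfg$out_channels, cfg$upscale_factor, cfg$sigmoid_head)
  net$mid <- as.integer(ceiling(cfg$n_pairs / 2))
  net$n_pairs <- cfg$n_pairs
  net$children <- c(list(net$shallow), net$blocks, list(net$head))
  net$fw <- function(x, train) {
    f0 <- net$shallow$fw(x, train)
    h <- f0
    for (i in seq_len(net$n_pairs)) {
      h <- net$blocks[[2 * i - 1]]$fw(h, train)
      h <- net$blocks[[2 * i]]$fw(h, train)
      if (i == net$mid) h <- h + f0
    }
    h <- h + f0
    net$head$fw(h, train)
  }
  net$bw <- function(dy) {
    dh <- net$head$bw(dy)
    df0 <- dh
    for (i in rev(seq_len(net$n_pairs))) {
      if (i == net$mid) df0 <- df0 + dh
      dh <- net$blocks[[2 * i]]$bw(dh)
      dh <- net$blocks[[2 * i - 1]]$bw(dh)
    }
    df0 <- df0 + dh
    net$shallow$bw(df0)
  }
  net$params <- function() list()
  net
}

#' Build an (untrained) super-resolution network
#'
#' Constructs the attention-based x4 super-resolution model with seeded weight
#' initialization. Use [srnet_fit()] to build and train in one call.
#'
#' @param config An [srnet_config()] object.
#' @return An object of class `srnet`.
#' @export
#' @examples
#' model <- build_srnet(srnet_config(base_channels = 8, n_pairs = 1))
#' model$n_params
build_srnet <- function(config = srnet_config()) {
  if (!inherits(config, "srnet_config")) stop_invalid("config must be an srnet_config")
  net <- with_seed(derive_seed(config$seed, "init"), build_net_graph(config))
  obj <- list(net = net, config = config, n_params = n_parameters(net),
              trained = FALSE, history = NULL)
  class(obj) <- "srnet"
  obj
}

# rigid transforms of (H, W, C, N) arrays acting on the spatial dims
rot90_4d <- function(a, k) {
  k <- k %% 4
  for (i in seq_len(k)) {
    a <- aperm(a[rev(seq_len(dim(a)[1])), , , , drop = FALSE], c(2, 1, 3, 4))
  }
  a
}

fliph_4d <- function(a) a[, rev(seq_len(dim(a)[2])), , , drop = FALSE]

#' Upscale low-resolution inputs with the network
#'
#' Runs the model in inference mode (batch normalization uses its stored
#' running statistics, so repeated calls are deterministic) and clips the
#' output to `[0, 1]`, the range of normalized metabolite maps.
#'
#' With `self_ensemble = TRUE` the prediction is the geometric self-ensemble:
#' the mean of the eight predictions obtained under the dihedral symmetries
#' (four 90-degree rotations, with and without a flip), each mapped back to
#' the original orientation. This averages away orientation-dependent
#' reconstruction noise at an 8x inference cost.
#'
#' @param model An `srnet` object.
#' @param lr_input A `(h, w, in_channels)` array for a single input or a
#'   `(h, w, in_channels, n)` batch.
#' @param clip Clip outputs to `[0, 1]` (default `TRUE`).
#' @param self_ensemble Average the eight dihedral-transform predictions.
#' @return A `(4h, 4w)` matrix for a single input, or a `(4h, 4w, 1, n)`
#'   array for a batch.
#' @export
upscale <- function(model, lr_input, clip = TRUE, self_ensemble = FALSE) {
  stopifnot(inherits(model, "srnet"))
  single <- length(dim(lr_input)) == 3
  if (single) dim(lr_input) <- c(dim(lr_input), 1L)
  d <- dim(lr_input)
  if (length(d) != 4 || d[3] != model$config$in_channels)
    stop_invalid("lr_input must be (h, w, ", model$config$in_channels, "[, n])")
  if (self_ensemble) {
    y <- NULL
    for (fl in c(FALSE, TRUE)) {
      for (k in 0:3) {
        xt <- rot90_4d(if (fl) fliph_4d(lr_input) else lr_input, k)
        pt <- model$net$fw(xt, train = FALSE)
        pt <- rot90_4d(pt, (4 - k) %% 4)
        if (fl) pt <- fliph_4d(pt)
        y <- if (is.null(y)) pt else y + pt
      }
    }
    y <- y / 8
  } else {
    y <- model$net$fw(lr_input, train = FALSE)
  }
  if (clip) y <- pmin(pmax(y, 0), 1)
  if (single) {
    dy <- dim(y)
    matrix(y, dy[1], dy[2])
  } else y
}

#' @export
predict.srnet <- function(object, newdata, ...) {
  if (inherits(newdata, "sr_dataset")) {
    lr <- dataset_lr_batch(newdata)
    return(upscale(object, lr))
  }
  upscale(object, newdata)
}

hfab_gate_ranges <- function(model) {
  stopifnot(inherits(model, "srnet"))
  idx <- seq(1, 2 * model$config$n_pairs, by = 2)
  t(vapply(model$net$blocks[idx], function(b) b$gate_range %||% c(NA_real_, NA_real_),
           numeric(2)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

block_param_counts <- function(model) {
  net <- model$net
  counts <- c(shallow = n_parameters(net$shallow))
  for (i in seq_len(net$n_pairs)) {
    counts[paste0("hfab_", i)] <- n_parameters(net$blocks[[2 * i - 1]])
    counts[paste0("gdfn_", i)] <- n_parameters(net$blocks[[2 * i]])
  }
  counts["head"] <- n_parameters(net$head)
  counts
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the configuration, all weights, batch-norm running
#' statistics, and the training history.
#'
#' @param model An `srnet` object.
#' @param path File path.
#' @return `srnet_load` returns the restored `srnet` object.
#' @export
srnet_save <- function(model, path) {
  stopifnot(inherits(model, "srnet"))
  saveRDS(list(config = model$config, params = get_param_state(model$net),
               bn = get_bn_state(model$net), history = model$history,
               trained = model$trained), path)
  invisible(path)
}

#' @rdname srnet_save
#' @export
srnet_load <- function(path) {
  st <- readRDS(path)
  model <- build_srnet(st$config)
  set_param_state(model$net, st$params)
  set_bn_state(model$net, st$bn)
  model$history <- st$history
  model$trained <- isTRUE(st$trained)
  model
}
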