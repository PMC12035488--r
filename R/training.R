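#' Log hyperbolic cosine loss
#'
#' `mean(log(cosh(pred - target)))`, evaluated through the numerically stable
#' identity `log(cosh(x)) = |x| + log1p(exp(-2|x|)) - log(2)`. Behaves like
#' L2/2 for small residuals and like L1 (minus `log 2`) for large ones, and
#' is smooth throughout.
#'
#' @param pred,target Numeric arrays of identical shape.
#' @return A nonnegative scalar; 0 iff `pred == target`.
#' @export
#' @examples
#' logcosh_loss(matrix(0.01, 4, 4), matrix(0, 4, 4))  # ~ 0.5 * 0.01^2
logcosh_loss <- function(pred, target) {
  if (!identical(dim(pred), dim(target)))
    stop_invalid("pred and target shapes differ")
  a <- abs(pred - target)
  mean(a + log1p(exp(-2 * a)) - log(2))
}

# gradient of logcosh_loss w.r.t. pred: tanh(pred - target) / n
logcosh_grad <- function(pred, target) {
  g <- tanh(pred - target) / length(pred)
  dim(g) <- dim(pred)
  g
}

#' Randomly rotate and flip a training example
#'
#' Applies a seeded random choice of rotation by a multiple of 90 degrees and
#' horizontal/vertical flips, identically to every input channel and the
#' target (90-degree multiples avoid any interpolation). The pixel-value
#' multiset is preserved.
#'
#' @param example A training example (list with `lr` `(h,w,c)` and `hr`
#'   `(H,W,1)` arrays).
#' @param seed Integer seed.
#' @param rot Optional fixed number of 90-degree rotations (0-3); overrides
#'   the random draw.
#' @param flip_h,flip_v Optional fixed horizontal/vertical flips.
#' @return The transformed example.
#' @export
augment_example <- function(example, seed = 1L, rot = NULL, flip_h = NULL,
                            flip_v = NULL) {
  ops <- if (!is.null(rot) || !is.null(flip_h) || !is.null(flip_v)) {
    list(k = rot %||% 0L, fh = isTRUE(flip_h), fv = isTRUE(flip_v))
  } else {
    with_seed(seed, list(k = sample(0:3, 1), fh = stats::runif(1) < 0.5,
                         fv = stats::runif(1) < 0.5))
  }
  tf <- function(a) {
    for (ch in seq_len(dim(a)[3])) {
      m <- a[, , ch]
      if (ops$k > 0) for (r in seq_len(ops$k)) m <- t(m[nrow(m):1, , drop = FALSE])
      if (ops$fh) m <- m[, ncol(m):1, drop = FALSE]
      if (ops$fv) m <- m[nrow(m):1, , drop = FALSE]
      a[, , ch] <- m
    }
    a
  }
  example$lr <- tf(example$lr)
  example$hr <- tf(example$hr)
  example
}

#' Split a dataset into training and validation sets by subject
#'
#' Subjects (not individual maps) are assigned to one side, so no subject
#' contributes slices to both; the validation side receives
#' `round(val_fraction * n_subjects)` subjects.
#'
#' @param dataset An `sr_dataset`.
#' @param val_fraction Fraction of subjects for validation (default 0.30).
#' @param seed Seed for the subject shuffle.
#' @return A list with `train` and `val` `sr_dataset`s.
#' @export
split_train_val <- function(dataset, val_fraction = 0.30, seed = 1L) {
  if (length(dataset) == 0) stop_invalid("dataset is empty")
  if (val_fraction <= 0 || val_fraction >= 1)
    stop_invalid("val_fraction must be in (0, 1)")
  subj <- unique(dataset$manifest$subject_id)
  if (length(subj) < 2) stop_invalid("need at least 2 subjects to split")
  n_val <- max(1L, round(val_fraction * length(subj)))
  val_subj <- with_seed(derive_seed(seed, "split"), sample(subj, n_val))
  take <- function(keep) {
    idx <- which(dataset$manifest$subject_id %in% keep)
    structure(list(examples = dataset$examples[idx],
                   manifest = dataset$manifest[idx, , drop = FALSE]),
              class = "sr_dataset")
  }
  list(train = take(setdiff(subj, val_subj)), val = take(val_subj))
}

#' Training control parameters
#'
#' Defaults mirror the reference protocol (batch size 24, Adam at learning
#' rate 1e-5, 100 epochs, 30% of subjects held out for validation, rotation/
#' flip augmentation). Smaller budgets are used for CPU-scale experiments.
#'
#' @param batch_size Minibatch size (>= 1).
#' @param learning_rate Adam learning rate.
#' @param epochs Number of epochs.
#' @param val_fraction Subject fraction for validation, in (0, 1).
#' @param augment Apply random rotation/flip augmentation.
#' @param seed Seed for shuffling/augmentation.
#' @param lr_decay Multiplicative learning-rate decay per epoch (1 = constant).
#' @param val_every Evaluate validation loss every `val_every` epochs (always
#'   on the final epoch); intermediate epochs record `NA`.
#' @param swa_from If set, final weights are the equal-weight average of the
#'   per-epoch weights from this epoch onward (stochastic weight averaging),
#'   instead of the best-validation checkpoint; batch-norm statistics are
#'   re-estimated afterwards either way.
#' @param stop_train_loss Optional early-stop threshold on the epoch training
#'   loss (`NULL` to disable).
#' @param verbose Print per-epoch summaries.
#' @return A list of class `train_control`.
#' @export
train_control <- function(batch_size = 24L, learning_rate = 1e-5, epochs = 100L,
                          val_fraction = 0.30, augment = TRUE, seed = 1L,
                          lr_decay = 1, val_every = 1L, swa_from = NULL,
                          stop_train_loss = NULL, verbose = FALSE) {
  if (batch_size < 1) stop_invalid("batch_size must be >= 1")
  if (val_fraction <= 0 || val_fraction >= 1)
    stop_invalid("val_fraction must be in (0, 1)")
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 val_fraction = val_fraction, augment = isTRUE(augment),
                 seed = as.integer(seed), lr_decay = lr_decay,
                 val_every = as.integer(val_every),
                 swa_from = if (!is.null(swa_from)) as.integer(swa_from),
                 stop_train_loss = stop_train_loss,
                 verbose = isTRUE(verbose)),
            class = "train_control")
}

adam_state <- function(net) {
  lapply(collect_params(net), function(p)
    list(m = 0 * get(p$val, envir = p$mod), v = 0 * get(p$val, envir = p$mod)))
}

adam_step <- function(net, state, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  ps <- collect_params(net)
  for (i in seq_along(ps)) {
    g <- get(ps[[i]]$grad, envir = ps[[i]]$mod)
    if (is.null(g)) next
    st <- state[[i]]
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g * g
    mhat <- st$m / (1 - beta1^t)
    vhat <- st$v / (1 - beta2^t)
    w <- get(ps[[i]]$val, envir = ps[[i]]$mod)
    assign(ps[[i]]$val, w - lr * mhat / (sqrt(vhat) + eps), envir = ps[[i]]$mod)
    state[[i]] <- st
  }
  state
}

eval_loss <- function(net, dataset, batch_size = 24L) {
  n <- length(dataset)
  tot <- 0
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    pred <- net$fw(dataset_lr_batch(dataset, idx), train = FALSE)
    tot <- tot + logcosh_loss(pred, dataset_hr_batch(dataset, idx)) * length(idx)
  }
  tot / n
}

#' Train a super-resolution network
#'
#' Minimizes the log-cosh reconstruction loss with Adam. The dataset is split
#' at the subject level, shuffled and augmented per epoch under seeded
#' streams; per-epoch training and validation losses are recorded and the
#' weights with the best validation loss are restored at the end.
#'
#' @param model An `srnet` from [build_srnet()].
#' @param dataset An `sr_dataset` from [build_dataset()].
#' @param control A [train_control()].
#' @return The trained `srnet`, with a `history` data frame
#'   (`epoch`, `train_loss`, `val_loss`).
#' @export
train_srnet <- function(model, dataset, control = train_control()) {
  stopifnot(inherits(model, "srnet"))
  if (length(dataset) == 0) stop_invalid("dataset is empty")
  split <- split_train_val(dataset, control$val_fraction,
                           seed = derive_seed(control$seed, "valsplit"))
  fit_srnet_on(model, split$train, split$val, control)
}

# core loop on an explicit train/val split (also used when overfitting a
# single batch, where train == val)
fit_srnet_on <- function(model, train_set, val_set, control) {
  net <- model$net
  state <- adam_state(net)
  n <- length(train_set)
  history <- data.frame(epoch = integer(), train_loss = double(),
                        val_loss = double())
  best_val <- Inf
  best <- NULL
  swa <- NULL
  n_swa <- 0
  step <- 0
  for (epoch in seq_len(control$epochs)) {
    lr_epoch <- control$learning_rate * control$lr_decay^(epoch - 1)
    ord <- with_seed(derive_seed(control$seed, paste0("shuffle_", epoch)),
                     sample.int(n))
    ep_loss <- 0
    for (start in seq(1, n, by = control$batch_size)) {
      idx <- ord[start:min(start + control$batch_size - 1, n)]
      ex <- train_set$examples[idx]
      if (control$augment) {
        aseed <- derive_seed(control$seed, paste0("aug_", epoch, "_", start))
        ex <- lapply(seq_along(ex), function(i)
          augment_example(ex[[i]], seed = aseed + i))
      }
      x <- array(unlist(lapply(ex, `[[`, "lr"), use.names = FALSE),
                 c(dim(ex[[1]]$lr), length(ex)))
      y <- array(unlist(lapply(ex, `[[`, "hr"), use.names = FALSE),
                 c(dim(ex[[1]]$hr), length(ex)))
      zero_grads(net)
      pred <- net$fw(x, train = TRUE)
      loss <- logcosh_loss(pred, y)
      if (!is.finite(loss))
        stop("training aborted: non-finite loss at epoch ", epoch,
             " (step ", step + 1, ")")
      net$bw(logcosh_grad(pred, y))
      step <- step + 1
      state <- adam_step(net, state, lr_epoch, step)
      ep_loss <- ep_loss + loss * length(idx)
    }
    ep_loss <- ep_loss / n
    stopping <- epoch == control$epochs ||
      (!is.null(control$stop_train_loss) && ep_loss < control$stop_train_loss)
    val_loss <- if (stopping || epoch %% control$val_every == 0)
      eval_loss(net, val_set, control$batch_size) else NA_real_
    history <- rbind(history, data.frame(epoch = epoch, train_loss = ep_loss,
                                         val_loss = val_loss))
    if (control$verbose)
      message(sprintf("epoch %3d  train %.6f  val %.6f", epoch, ep_loss, val_loss))
    if (!is.na(val_loss) && val_loss < best_val) {
      best_val <- val_loss
      best <- list(p = get_param_state(net), b = get_bn_state(net))
    }
    if (!is.null(control$swa_from) && epoch >= control$swa_from) {
      p <- get_param_state(net)
      n_swa <- n_swa + 1
      swa <- if (is.null(swa)) p
             else mapply(function(a, b) a + (b - a) / n_swa, swa, p,
                         SIMPLIFY = FALSE)
    }
    if (stopping) break
  }
  if (!is.null(swa)) {
    set_param_state(net, swa)
  } else if (!is.null(best)) {
    set_param_state(net, best$p)
    set_bn_state(net, best$b)
  }
  refresh_bn_stats(net, train_set, control$batch_size,
                   seed = derive_seed(control$seed, "bnrefresh"))
  model$history <- history
  model$trained <- TRUE
  model
}

# re-estimate batch-norm running statistics over (up to max_batches of) the
# training set for the final weights, so inference-mode normalization matches
# the trained behavior; setting momentum to 1/i at the i-th batch makes the
# running values the plain average of the batch moments
refresh_bn_stats <- function(net, dataset, batch_size, seed = 1L,
                             max_batches = 8L) {
  bns <- list()
  rec <- function(m) {
    if (identical(m$kind, "bn")) bns[[length(bns) + 1]] <<- m
    if (!is.null(m$layers)) for (l in m$layers) rec(l)
    if (!is.null(m$children)) for (l in m$children) rec(l)
  }
  rec(net)
  if (length(bns) == 0) return(invisible(NULL))
  n <- length(dataset)
  ord <- with_seed(seed, sample.int(n))
  starts <- seq(1, n, by = batch_size)
  starts <- starts[seq_len(min(length(starts), max_batches))]
  i <- 0
  for (start in starts) {
    i <- i + 1
    for (b in bns) b$momentum <- 1 / i
    idx <- ord[start:min(start + batch_size - 1, n)]
    invisible(net$fw(dataset_lr_batch(dataset, idx), train = TRUE))
  }
  for (b in bns) b$momentum <- 0.1
  invisible(NULL)
}

#' Fit a super-resolution model to a paired dataset
#'
#' Convenience wrapper: builds the network from `config` and trains it with
#' [train_srnet()]; the classed return value supports `print`, `summary`,
#' `predict`, `plot` and `residuals`.
#'
#' @param dataset An `sr_dataset`.
#' @param config An [srnet_config()].
#' @param control A [train_control()].
#' @return A trained `srnet` object.
#' @export
srnet_fit <- function(dataset, config = srnet_config(),
                      control = train_control()) {
  train_srnet(build_srnet(config), dataset, control)
}
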