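# Shared fixtures built in code.

# hand-built 8x8 segmentation with one pure pixel per compartment and a
# single-pixel tumor; everything else background
tiny_scene <- function(grade = "HGG") {
  z <- matrix(0, 8, 8)
  gm <- z; gm[1, 1] <- 1
  wm <- z; wm[2, 2] <- 1
  csf <- z; csf[3, 3] <- 1
  mask <- z; mask[4, 4] <- 1
  list(seg = tissue_segmentation(gm, wm, csf, "tiny", 1L),
       tumor = tumor_mask(mask, grade))
}

# fabricated slice triple with controllable FLAIR/tumor, for select_slices
fake_slice <- function(flair, mask, slice_index = 1L) {
  list(seg = tissue_segmentation(matrix(0, nrow(flair), ncol(flair)),
                                 matrix(0, nrow(flair), ncol(flair)),
                                 matrix(0, nrow(flair), ncol(flair)),
                                 "fake", slice_index),
       tumor = tumor_mask(mask, "HGG"),
       flair = flair_slice(flair, "fake", slice_index))
}

# small synthetic paired dataset with arbitrary geometry (lr h x w, hr 4h x 4w)
# across n_subj fake subjects, for exercising the training loop cheaply
toy_dataset <- function(n_subj = 4, per_subj = 2, h = 8, seed = 99) {
  examples <- list()
  manifest <- list()
  set.seed(seed)
  for (s in seq_len(n_subj)) {
    for (k in seq_len(per_subj)) {
      hr <- matrix(stats::runif((4 * h)^2), 4 * h, 4 * h)
      lr1 <- mrsisr:::block_mean(hr, 4L)
      lr <- array(c(lr1, lr1), c(h, h, 2))
      examples[[length(examples) + 1]] <- list(
        lr = lr, hr = array(hr, c(4 * h, 4 * h, 1)),
        meta = list(subject_id = paste0("s", s), slice_index = k,
                    map_type = "tCho", grade = "HGG"))
      manifest[[length(manifest) + 1]] <- data.frame(
        subject_id = paste0("s", s), slice_index = k, map_type = "tCho",
        grade = "HGG", stringsAsFactors = FALSE)
    }
  }
  structure(list(examples = examples, manifest = do.call(rbind, manifest)),
            class = "sr_dataset")
}

# brute-force SSIM with a Gaussian window over valid positions (double loop)
ssim_bruteforce <- function(x, y, params = ssim_params()) {
  k <- params$window_size
  g <- stats::dnorm(seq(-(k %/% 2), k %/% 2), sd = params$sigma)
  w <- outer(g, g); w <- w / sum(w)
  vals <- c()
  for (i in seq_len(nrow(x) - k + 1)) {
    for (j in seq_len(ncol(x) - k + 1)) {
      px <- x[i:(i + k - 1), j:(j + k - 1)]
      py <- y[i:(i + k - 1), j:(j + k - 1)]
      mx <- sum(w * px); my <- sum(w * py)
      vx <- sum(w * px^2) - mx^2; vy <- sum(w * py^2) - my^2
      cxy <- sum(w * px * py) - mx * my
      vals <- c(vals, ((2 * mx * my + params$c1) * (2 * cxy + params$c2)) /
                  ((mx^2 + my^2 + params$c1) * (vx + vy + params$c2)))
    }
  }
  mean(vals)
}

# exact two-sided Mann-Whitney p by enumeration of all group assignments
mw_bruteforce <- function(a, b) {
  u_stat <- function(aa, bb) sum(outer(aa, bb, ">")) + 0.5 * sum(outer(aa, bb, "=="))
  u_obs <- u_stat(a, b)
  pooled <- c(a, b)
  n <- length(a)
  combs <- utils::combn(length(pooled), n)
  us <- apply(combs, 2, function(ix) u_stat(pooled[ix], pooled[-ix]))
  mu <- length(a) * length(b) / 2
  p <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
  list(U = u_obs, p = min(1, p))
}
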