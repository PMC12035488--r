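# S3 methods for the fitted model and the map/dataset containers.

#' @export
print.srnet <- function(x, ...) {
  cfg <- x$config
  cat("Super-resolution network (x", cfg$upscale_factor, ")\n", sep = "")
  cat(sprintf("  input  : %d x 32 x 32 (map + FLAIR)\n", cfg$in_channels))
  cat(sprintf("  body   : %d x (HFAB -> GDFN), %d channels, 2 long skips\n",
              cfg$n_pairs, cfg$base_channels))
  cat(sprintf("  params : %s\n", format(x$n_params, big.mark = ",")))
  cat(sprintf("  trained: %s\n", if (x$trained) "yes" else "no"))
  if (!is.null(x$history)) {
    h <- x$history
    cat(sprintf("  final losses (epoch %d): train %.6f, val %.6f\n",
                h$epoch[nrow(h)], h$train_loss[nrow(h)], h$val_loss[nrow(h)]))
  }
  invisible(x)
}

#' @export
summary.srnet <- function(object, ...) {
  out <- list(config = object$config, n_params = object$n_params,
              blocks = block_param_counts(object), trained = object$trained,
              history = object$history)
  class(out) <- "summary.srnet"
  out
}

#' @export
print.summary.srnet <- function(x, ...) {
  cat("Per-block trainable parameter counts:\n")
  for (nm in names(x$blocks))
    cat(sprintf("  %-10s %8d\n", nm, x$blocks[[nm]]))
  cat(sprintf("  %-10s %8d\n", "total", x$n_params))
  invisible(x)
}

#' @export
plot.srnet <- function(x, ...) {
  if (is.null(x$history)) stop_invalid("model has no training history")
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("steelblue", "firebrick"),
                    xlab = "epoch", ylab = "log-cosh loss", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}

#' @export
residuals.srnet <- function(object, dataset, ...) {
  stopifnot(inherits(dataset, "sr_dataset"))
  pred <- upscale(object, dataset_lr_batch(dataset))
  dataset_hr_batch(dataset) - pred
}

#' @export
print.metabolite_map <- function(x, ...) {
  cat(sprintf("%s map, %dx%d (%.4g mm voxels)%s, subject %s slice %d\n",
              x$map_type, x$resolution, x$resolution, voxel_size_mm(x),
              if (x$normalized) ", normalized" else "",
              x$subject_id, x$slice_index))
  cat(sprintf("  values in [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
plot.metabolite_map <- function(x, ...) {
  graphics::image(t(x$values[nrow(x$values):1, ]), axes = FALSE, asp = 1,
                  col = grDevices::hcl.colors(64, "viridis"),
                  main = x$map_type, ...)
  invisible(x)
}

#' @export
print.sr_dataset <- function(x, ...) {
  cat(sprintf("sr_dataset: %d examples (%d subjects, %d map types)\n",
              length(x), length(unique(x$manifest$subject_id)),
              length(unique(x$manifest$map_type))))
  invisible(x)
}
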