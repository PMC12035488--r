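#' Metabolite map container
#'
#' A single-channel 2-D metabolite (or ratio) map with its geometry and
#' normalization state. With the default 220 mm field of view, the 128x128
#' high-resolution grid has a 1.71875 mm in-plane voxel edge and the 32x32
#' low-resolution grid 6.875 mm (slice thickness 10 mm).
#'
#' @param values Nonnegative numeric matrix.
#' @param map_type One of [map_types()].
#' @param normalized Logical; if `TRUE`, values must lie in `[0, 1]` with
#'   max 1 (or the map all zero).
#' @param fov_mm In-plane field of view in mm (default 220).
#' @param slice_thickness_mm Slice thickness in mm (default 10).
#' @param subject_id,slice_index,grade Provenance metadata.
#' @return An object of class `metabolite_map`.
#' @export
metabolite_map <- function(values, map_type, normalized = FALSE, fov_mm = 220,
                           slice_thickness_mm = 10, subject_id = "subj",
                           slice_index = 1L, grade = NA_character_) {
  stopifnot(is.matrix(values))
  if (!map_type %in% map_types()) stop_invalid("unknown map_type '", map_type, "'")
  if (any(!is.finite(values)) || any(values < 0))
    stop_invalid("map values must be finite and >= 0")
  if (normalized) {
    mx <- max(values)
    if (max(values) > 1 + 1e-12 || (mx != 0 && abs(mx - 1) > 1e-9))
      stop_invalid("a normalized map must have max 1 (or be all zero)")
  }
  structure(list(values = values, map_type = map_type,
                 resolution = nrow(values), normalized = isTRUE(normalized),
                 fov_mm = fov_mm, slice_thickness_mm = slice_thickness_mm,
                 subject_id = subject_id, slice_index = as.integer(slice_index),
                 grade = grade),
            class = "metabolite_map")
}

#' In-plane voxel edge length of a map (mm)
#'
#' @param m A [metabolite_map()].
#' @return `fov_mm / resolution` in mm.
#' @export
#' @examples
#' voxel_size_mm(metabolite_map(matrix(0.5, 32, 32), "tCho"))  # 6.875
voxel_size_mm <- function(m) m$fov_mm / m$resolution

#' Synthesize an unnormalized high-resolution metabolite map
#'
#' Pixel values combine compartment point estimates with the soft tissue
#' occupancies: `C_GM * gm + C_WM * wm + 0 * csf` outside the tumor; inside
#' the tumor mask, the tumor value (grade-dependent for ratio maps) replaces
#' the tissue contribution by default, since the tissue planes underneath the
#' mask would otherwise be double-counted.
#'
#' @param seg A [tissue_segmentation()].
#' @param tumor A [tumor_mask()].
#' @param table A [concentration_table()].
#' @param map_type One of [map_types()].
#' @param mode `"deterministic"` (table estimates) or `"sampled"` (seeded
#'   uniform draws within the literature ranges for the tumor value).
#' @param seed Seed used in sampled mode.
#' @param tumor_additive If `TRUE`, the tumor contribution is added on top of
#'   the tissue contribution instead of replacing it.
#' @return An unnormalized 128x128 [metabolite_map()].
#' @export
synthesize_map <- function(seg, tumor, table, map_type,
                           mode = c("deterministic", "sampled"), seed = 1L,
                           tumor_additive = FALSE) {
  mode <- match.arg(mode)
  if (!inherits(seg, "tissue_segmentation")) stop_invalid("seg must be a tissue_segmentation")
  if (!identical(dim(seg$gm), dim(tumor$mask)))
    stop_invalid("segmentation and tumor mask shapes differ")
  c_gm <- table_lookup(table, map_type, "GM")$estimate
  c_wm <- table_lookup(table, map_type, "WM")$estimate
  vals <- c_gm * seg$gm + c_wm * seg$wm  # + 0 * csf
  tv <- tumor_value(table, map_type, tumor$grade, mode, seed)
  inside <- tumor$mask > 0
  if (any(inside)) {
    if (tumor_additive) vals[inside] <- vals[inside] + tv
    else vals[inside] <- tv
  }
  metabolite_map(vals, map_type, normalized = FALSE,
                 subject_id = seg$subject_id, slice_index = seg$slice_index,
                 grade = tumor$grade)
}

#' Normalize a metabolite map to [0, 1]
#'
#' Divides by the map maximum; an all-zero map is returned unchanged (but
#' flagged normalized). Idempotent.
#'
#' @param m A [metabolite_map()] with nonnegative values.
#' @return The normalized map.
#' @export
normalize_map <- function(m) {
  stopifnot(inherits(m, "metabolite_map"))
  if (any(m$values < 0)) stop_invalid("cannot normalize a map with negative values")
  mx <- max(m$values)
  if (mx > 0) m$values <- m$values / mx
  m$normalized <- TRUE
  m
}

block_mean <- function(x, f) {
  d <- dim(x)
  y <- array(x, c(f, d[1] %/% f, f, d[2] %/% f))
  colMeans(aperm(y, c(1, 3, 2, 4)), dims = 2)
}

#' Downsample a map by block averaging
#'
#' Each low-resolution pixel is the mean of its `factor x factor` block,
#' emulating the larger-voxel signal integration of an MRSI acquisition;
#' the voxel edge in the metadata grows by `factor`.
#'
#' @param hr A [metabolite_map()] whose resolution is divisible by `factor`.
#' @param factor Integer downsampling factor (default 4).
#' @return The low-resolution [metabolite_map()].
#' @export
downsample_map <- function(hr, factor = 4L) {
  stopifnot(inherits(hr, "metabolite_map"))
  factor <- as.integer(factor)
  if (factor < 1 || hr$resolution %% factor != 0)
    stop_invalid("map resolution must be divisible by the downsampling factor")
  out <- hr
  out$values <- block_mean(hr$values, factor)
  out$resolution <- hr$resolution %/% factor
  out
}

minmax01 <- function(x) {
  r <- range(x)
  if (r[2] > r[1]) (x - r[1]) / (r[2] - r[1]) else x * 0
}

#' Build a paired low/high-resolution training dataset
#'
#' For every selected slice of every subject, five training examples are
#' produced (one per map type). Each example pairs a normalized 128x128
#' high-resolution target with a 2-channel 32x32 input: channel 1 is the
#' block-averaged low-resolution map, channel 2 the FLAIR slice block-averaged
#' to 32x32 and min-max normalized to `[0, 1]`.
#'
#' In `"sampled"` mode the tumor value is drawn once per subject and map type
#' (a lesion keeps one metabolic profile across its slices).
#'
#' @param subjects A list of `phantom_subject` objects (see
#'   [generate_cohort()]) or equivalent slice-triple lists.
#' @param table A [concentration_table()].
#' @param mode `"deterministic"` or `"sampled"`.
#' @param seed Root seed for sampled mode.
#' @param min_k,max_k Slice-selection bounds passed to [select_slices()].
#' @return An object of class `sr_dataset`: a list with `examples` (list of
#'   `lr`/`hr`/`meta` triples) and a `manifest` data frame.
#' @export
build_dataset <- function(subjects, table = concentration_table(),
                          mode = c("deterministic", "sampled"), seed = 1L,
                          min_k = 5L, max_k = 10L) {
  mode <- match.arg(mode)
  examples <- list()
  manifest <- list()
  for (subj in subjects) {
    sel <- select_slices(subj, min_k = min_k, max_k = max_k)
    sid <- attr(subj, "subject_id") %||% subj[[1]]$seg$subject_id
    idx <- vapply(subj, function(s) s$seg$slice_index, integer(1))
    for (si in sel) {
      s <- subj[[match(si, idx)]]
      flair_lr <- minmax01(block_mean(s$flair$intensity,
                                      nrow(s$flair$intensity) %/% 32L))
      for (mt in map_types()) {
        hr <- normalize_map(synthesize_map(
          s$seg, s$tumor, table, mt, mode = mode,
          seed = derive_seed(seed, paste0(sid, "_", mt))))
        lr <- downsample_map(hr, hr$resolution %/% 32L)
        lr_in <- array(c(lr$values, flair_lr), c(32L, 32L, 2L))
        hr_t <- array(hr$values, c(dim(hr$values), 1L))
        examples[[length(examples) + 1]] <- list(
          lr = lr_in, hr = hr_t,
          meta = list(subject_id = sid, slice_index = si, map_type = mt,
                      grade = s$tumor$grade))
        manifest[[length(manifest) + 1]] <- data.frame(
          subject_id = sid, slice_index = si, map_type = mt,
          grade = s$tumor$grade, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(examples) == 0) {
    warning("no eligible slices; returning an empty dataset")
    manifest <- data.frame(subject_id = character(), slice_index = integer(),
                           map_type = character(), grade = character())
  } else manifest <- do.call(rbind, manifest)
  structure(list(examples = examples, manifest = manifest), class = "sr_dataset")
}

#' @export
length.sr_dataset <- function(x) length(x$examples)

# stack example inputs/targets into (H, W, C, N) batches
dataset_lr_batch <- function(dataset, idx = seq_along(dataset$examples)) {
  arrs <- lapply(dataset$examples[idx], `[[`, "lr")
  array(unlist(arrs, use.names = FALSE), c(dim(arrs[[1]]), length(arrs)))
}

dataset_hr_batch <- function(dataset, idx = seq_along(dataset$examples)) {
  arrs <- lapply(dataset$examples[idx], `[[`, "hr")
  array(unlist(arrs, use.names = FALSE), c(dim(arrs[[1]]), length(arrs)))
}
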