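# Seeded synthetic brain-slice anatomies: soft GM/WM/CSF segmentations, a
# contiguous graded tumor mask, and a tumor-hyperintense FLAIR slice. These
# stand in for skull-stripped glioma MRI anatomies segmented into partial
# -volume tissue maps, so the rest of the pipeline is free of external data.

#' Tissue segmentation, tumor mask and FLAIR constructors
#'
#' Lightweight validated containers for per-slice phantom planes. Occupancy
#' planes are `size x size` matrices of fractions in `[0, 1]` with
#' `gm + wm + csf <= 1` at every pixel (remainder = background).
#'
#' @param gm,wm,csf Occupancy matrices.
#' @param subject_id Subject identifier.
#' @param slice_index Integer slice index.
#' @return An object of class `tissue_segmentation`.
#' @export
tissue_segmentation <- function(gm, wm, csf, subject_id = "subj", slice_index = 1L) {
  stopifnot(is.matrix(gm), identical(dim(gm), dim(wm)), identical(dim(gm), dim(csf)))
  tot <- gm + wm + csf
  if (any(gm < 0) || any(wm < 0) || any(csf < 0) || any(tot > 1 + 1e-9))
    stop_invalid("occupancy fractions must be in [0,1] with gm+wm+csf <= 1")
  structure(list(gm = gm, wm = wm, csf = csf, subject_id = subject_id,
                 slice_index = as.integer(slice_index)),
            class = "tissue_segmentation")
}

#' @param mask Binary matrix (0/1); may be empty (all zero).
#' @param grade `"LGG"` or `"HGG"`.
#' @rdname tissue_segmentation
#' @export
tumor_mask <- function(mask, grade = c("HGG", "LGG")) {
  grade <- match.arg(grade)
  stopifnot(is.matrix(mask))
  if (!all(mask %in% c(0, 1))) stop_invalid("tumor mask values must be 0/1")
  structure(list(mask = mask, grade = grade), class = "tumor_mask")
}

#' @param intensity Nonnegative intensity matrix.
#' @rdname tissue_segmentation
#' @export
flair_slice <- function(intensity, subject_id = "subj", slice_index = 1L) {
  stopifnot(is.matrix(intensity))
  if (any(!is.finite(intensity)) || any(intensity < 0))
    stop_invalid("FLAIR intensities must be finite and nonnegative")
  structure(list(intensity = intensity, subject_id = subject_id,
                 slice_index = as.integer(slice_index)),
            class = "flair_slice")
}

# isotropic Gaussian blur, separable: row/column band matrices with
# renormalized (truncated) edge weights
gauss_blur <- function(m, sigma) {
  smat <- function(n) {
    G <- stats::dnorm(outer(seq_len(n), seq_len(n), "-"), sd = sigma)
    G / rowSums(G)
  }
  smat(nrow(m)) %*% m %*% t(smat(ncol(m)))
}

# standardized smooth random field on an n x n grid
smooth_field <- function(n, sigma = 8) {
  f <- gauss_blur(matrix(stats::rnorm(n * n), n, n), sigma)
  (f - mean(f)) / stats::sd(f)
}

# largest 4-connected component of a binary matrix (flood fill)
largest_component <- function(mask) {
  n <- nrow(mask); m <- ncol(mask)
  lab <- matrix(0L, n, m)
  cur <- 0L
  best <- integer(0); best_size <- 0L
  idx <- which(mask > 0)
  for (s in idx) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    queue <- s; lab[s] <- cur; comp <- s
    while (length(queue)) {
      p <- queue[length(queue)]; queue <- queue[-length(queue)]
      i <- (p - 1L) %% n + 1L; j <- (p - 1L) %/% n + 1L
      for (q in c(if (i > 1) p - 1L, if (i < n) p + 1L,
                  if (j > 1) p - n, if (j < m) p + n)) {
        if (mask[q] > 0 && lab[q] == 0L) {
          lab[q] <- cur; queue <- c(queue, q); comp <- c(comp, q)
        }
      }
    }
    if (length(comp) > best_size) { best_size <- length(comp); best <- comp }
  }
  out <- matrix(0, n, m)
  out[best] <- 1
  out
}

#' Generate a synthetic glioma subject
#'
#' Produces `n_slices` axial brain-slice phantoms for one subject: an
#' elliptical head with a cortical gray-matter band, central white matter,
#' ventricular and peripheral CSF (soft partial-volume occupancies), a
#' contiguous tumor blob overlapping WM/GM whose extent waxes and wanes
#' smoothly across slices, and a FLAIR slice in which tumor tissue is
#' hyperintense (so the slice-selection rule can fire). Fully deterministic
#' for a given seed.
#'
#' @param seed Integer seed.
#' @param grade Tumor grade, `"HGG"` or `"LGG"`.
#' @param n_slices Number of slices (>= 1).
#' @param size Grid size (default 128).
#' @param binarize If `TRUE`, occupancies are hardened to 0/1 labels.
#' @return A list of class `phantom_subject`; each element is a list with
#'   components `seg` ([tissue_segmentation()]), `tumor` ([tumor_mask()]) and
#'   `flair` ([flair_slice()]).
#' @export
#' @examples
#' subj <- generate_subject(seed = 0, grade = "HGG", n_slices = 1)
#' range(subj[[1]]$seg$gm)
generate_subject <- function(seed, grade = c("HGG", "LGG"), n_slices = 1L,
                             size = 128L, binarize = FALSE) {
  grade <- match.arg(grade)
  n_slices <- as.integer(n_slices)
  if (is.na(n_slices) || n_slices < 1) stop_invalid("n_slices must be >= 1")
  subject_id <- sprintf("phantom_%d", as.integer(seed))

  with_seed(derive_seed(seed, "phantom"), {
    # subject-level anatomy parameters
    a <- stats::runif(1, 0.72, 0.82)        # head semi-axis (x)
    b <- stats::runif(1, 0.86, 0.94)        # head semi-axis (y)
    r_csf <- stats::runif(1, 0.90, 0.94)    # peripheral CSF rim onset
    bandw <- stats::runif(1, 0.11, 0.16)    # cortical band width
    vent_w <- stats::runif(1, 0.07, 0.10)   # ventricle semi-axes
    vent_h <- stats::runif(1, 0.18, 0.26)
    vent_x <- stats::runif(1, 0.12, 0.18)
    theta <- stats::runif(1, 0, 2 * pi)     # tumor direction from center
    rad <- stats::runif(1, 0.25, 0.5)       # tumor center eccentricity
    rt0 <- stats::runif(1, 0.16, 0.26)      # tumor radius
    phase <- stats::runif(1, 0, 2 * pi)
    eta_anat <- smooth_field(size, sigma = 10)   # anatomy irregularity
    eta_tum <- smooth_field(size, sigma = 6)     # tumor shape irregularity
    eta_bias <- smooth_field(size, sigma = 14)   # FLAIR bias field
    noise_seeds <- sample.int(.Machine$integer.max - 1L, n_slices)

    ax <- seq(-1, 1, length.out = size)
    X <- matrix(ax, size, size)
    Y <- matrix(ax, size, size, byrow = TRUE)
    cx <- rad * cos(theta) * a * 0.7
    cy <- rad * sin(theta) * b * 0.7
    mid_slice <- (n_slices + 1) / 2
    extent <- max(n_slices * 0.45, 1)

    slices <- vector("list", n_slices)
    for (t in seq_len(n_slices)) {
      # smooth through-plane modulation of the anatomy
      ht <- 0.94 + 0.06 * cos(2 * pi * (t - 1) / max(2 * n_slices, 12) + phase)
      vt <- 1 + 0.15 * sin(2 * pi * (t - 1) / max(2 * n_slices, 12) + phase)
      re <- sqrt((X / (a * ht))^2 + (Y / (b * ht))^2) * (1 + 0.05 * eta_anat)

      outer_occ <- stats::plogis((1 - re) / 0.015)
      p_rim <- stats::plogis((re - r_csf) / 0.015)
      p_gm <- stats::plogis((re - (r_csf - bandw)) / 0.02)
      csf_rim <- outer_occ * p_rim
      gm <- outer_occ * (1 - p_rim) * p_gm
      interior <- outer_occ * (1 - p_rim) * (1 - p_gm)
      v1 <- stats::plogis((1 - sqrt(((X + vent_x) / (vent_w * vt))^2 +
                                      ((Y - 0.05) / (vent_h * vt))^2)) / 0.06)
      v2 <- stats::plogis((1 - sqrt(((X - vent_x) / (vent_w * vt))^2 +
                                      ((Y - 0.05) / (vent_h * vt))^2)) / 0.06)
      vent <- pmax(v1, v2)
      csf <- csf_rim + interior * vent
      wm <- interior * (1 - vent)

      # tumor: blob present near its central slice, fading smoothly away
      shrink <- 1 - ((t - mid_slice) / extent)^2
      mask <- matrix(0, size, size)
      if (shrink > 0.1) {
        rt <- rt0 * sqrt(shrink)
        rho2 <- ((X - cx) / rt)^2 + ((Y - cy) / rt)^2
        bump <- exp(-rho2) + 0.30 * eta_tum
        cand <- (bump > 0.55) & (re < 0.88)
        if (any(cand)) mask <- largest_component(cand * 1)
      }

      if (binarize) {
        lab <- (outer_occ > 0.5) *
          max.col(cbind(as.vector(gm), as.vector(wm), as.vector(csf)))
        gm <- matrix(as.numeric(lab == 1), size, size)
        wm <- matrix(as.numeric(lab == 2), size, size)
        csf <- matrix(as.numeric(lab == 3), size, size)
      }

      # FLAIR: CSF suppressed, GM > WM, tumor hyperintense; bias field + noise
      flair <- 0.62 * gm + 0.45 * wm + 0.08 * csf
      flair <- flair * (1 + 0.08 * eta_bias)
      if (any(mask > 0)) flair[mask > 0] <- 0.9 + 0.05 * eta_tum[mask > 0]
      flair <- flair + with_seed(noise_seeds[t],
                                 matrix(stats::rnorm(size * size, sd = 0.01), size, size))
      flair <- pmax(flair, 0)

      slices[[t]] <- list(
        seg = tissue_segmentation(pmin(gm, 1), pmin(wm, 1), pmin(csf, 1),
                                  subject_id, t),
        tumor = tumor_mask(mask, grade),
        flair = flair_slice(flair, subject_id, t)
      )
    }
    structure(slices, class = "phantom_subject", subject_id = subject_id,
              grade = grade)
  })
}

#' Generate a cohort of phantom subjects
#'
#' @param n_subjects Number of subjects.
#' @param seed Root seed; per-subject seeds are derived from it.
#' @param grade_mix Fraction of subjects assigned HGG (the remainder LGG).
#' @param n_slices Slices per subject.
#' @param size Grid size.
#' @return A list of `phantom_subject` objects.
#' @export
generate_cohort <- function(n_subjects, seed = 1L, grade_mix = 0.5,
                            n_slices = 1L, size = 128L) {
  if (n_subjects < 1) stop_invalid("n_subjects must be >= 1")
  grades <- with_seed(derive_seed(seed, "grades"), {
    g <- rep(c("HGG", "LGG"),
             c(round(n_subjects * grade_mix), n_subjects - round(n_subjects * grade_mix)))
    sample(g)
  })
  lapply(seq_len(n_subjects), function(i)
    generate_subject(seed = derive_seed(seed, paste0("subject_", i)),
                     grade = grades[i], n_slices = n_slices, size = size))
}

#' Select tumor-conspicuous slices
#'
#' A slice is eligible when the mean FLAIR intensity over its tumor pixels
#' strictly exceeds the mean intensity of the entire slice; between `min_k`
#' and `max_k` eligible slices are kept per subject (all eligible ones when
#' fewer than `min_k` are available), ordered by slice index.
#'
#' @param slices A `phantom_subject` or list of slice triples
#'   (`seg`/`tumor`/`flair`).
#' @param min_k,max_k Target range for the number of selected slices.
#' @return Integer vector of selected slice indices.
#' @export
select_slices <- function(slices, min_k = 5L, max_k = 10L) {
  if (length(slices) == 0) stop_invalid("no slices supplied")
  eligible <- vapply(slices, function(s) {
    f <- s$flair$intensity
    m <- s$tumor$mask > 0
    if (!any(m)) return(FALSE)
    mean(f[m]) > mean(f)
  }, logical(1))
  idx <- vapply(slices, function(s) s$seg$slice_index, integer(1))
  sel <- sort(idx[eligible])
  if (length(sel) > max_k) sel <- sel[seq_len(max_k)]
  sel
}
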