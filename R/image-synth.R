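#' Synthetic image configuration
#'
#' Parameters of the synthetic two-channel 3D ovariole stack generator.
#' Channel 1 emulates a nuclear stain (traffic jam / groucho); channel 2
#' emulates the clone marker (GFP), whose per-nucleus intensity is drawn
#' from a high or a low distribution according to the ground-truth label.
#' Nuclei are rendered as 3D Gaussian blobs at non-overlapping centres.
#'
#' @param dim_vox Integer volume dimensions in voxels, `c(x, y, z)`; x is
#'   the anterior-posterior axis.
#' @param voxel_size_um Voxel size in micrometres, `c(x, y, z)`
#'   (anisotropic allowed; confocal z steps are typically coarser).
#' @param n_nuclei Number of nuclei to place.
#' @param nuclear_diameter_um Range from which each nucleus's diameter is
#'   drawn uniformly (somatic nuclei measure about 2-2.25 um).
#' @param labeled_fraction Ground-truth fraction of clone-labelled nuclei.
#' @param exact_count If `TRUE`, exactly `round(labeled_fraction *
#'   n_nuclei)` nuclei are labelled; otherwise each nucleus is labelled
#'   independently.
#' @param nuclear_amplitude,background,noise_sd Nuclear-channel peak blob
#'   intensity, additive background level, and Gaussian noise SD.
#' @param label_high_mean,label_high_sd Label-channel blob amplitude
#'   distribution for marker-positive nuclei.
#' @param label_low_mean,label_low_sd Same for marker-negative nuclei.
#' @param min_spacing_um Minimum distance between nucleus centres.
#' @param max_retries Rejection-sampling budget for packing.
#' @param positive_marking If `FALSE` (negative marking), clone cells are
#'   the marker-negative ones.
#' @return An object of class `image_config`.
#' @export
image_config <- function(dim_vox = c(200L, 100L, 24L),
                         voxel_size_um = c(0.2, 0.2, 0.5),
                         n_nuclei = 200L,
                         nuclear_diameter_um = c(2.0, 2.25),
                         labeled_fraction = 0.5,
                         exact_count = FALSE,
                         nuclear_amplitude = 100,
                         background = 10,
                         noise_sd = 5,
                         label_high_mean = 150,
                         label_high_sd = 15,
                         label_low_mean = 15,
                         label_low_sd = 4,
                         min_spacing_um = 2.3,
                         max_retries = 20000L,
                         positive_marking = FALSE) {
  stopifnot(length(dim_vox) == 3, all(dim_vox > 0),
            length(voxel_size_um) == 3, all(voxel_size_um > 0),
            n_nuclei >= 1,
            labeled_fraction >= 0, labeled_fraction <= 1,
            label_high_mean > label_low_mean,
            min_spacing_um > 0)
  structure(list(dim_vox = as.integer(dim_vox),
                 voxel_size_um = voxel_size_um,
                 n_nuclei = as.integer(n_nuclei),
                 nuclear_diameter_um = nuclear_diameter_um,
                 labeled_fraction = labeled_fraction,
                 exact_count = exact_count,
                 nuclear_amplitude = nuclear_amplitude,
                 background = background,
                 noise_sd = noise_sd,
                 label_high_mean = label_high_mean,
                 label_high_sd = label_high_sd,
                 label_low_mean = label_low_mean,
                 label_low_sd = label_low_sd,
                 min_spacing_um = min_spacing_um,
                 max_retries = as.integer(max_retries),
                 positive_marking = positive_marking),
            class = "image_config")
}

#' Generate a synthetic two-channel 3D stack with ground truth
#'
#' Places `n_nuclei` centres by rejection sampling at the configured
#' minimum spacing, renders each nucleus as an anisotropy-aware 3D
#' Gaussian blob (sigma = diameter/4) in both channels, draws the label
#' channel amplitude from the high or low distribution according to the
#' ground-truth label, and adds background plus Gaussian noise.
#'
#' Physical coordinates are voxel-centred: voxel `i` (1-based) spans
#' `[(i-1), i) * voxel_size` with centre `(i - 0.5) * voxel_size` um.
#' The anterior-posterior axis is +x (array dimension 1).
#'
#' @param config An [image_config()].
#' @param seed Integer seed.
#' @return An object of class `image_stack`: a list with `nuclear` and
#'   `label` 3D arrays, `voxel_size_um`, and `truth` — a tibble with one
#'   row per nucleus (`nucleus`, `x_um`, `y_um`, `z_um`, `diameter_um`,
#'   `labeled`, `label_amplitude`).
#' @export
generate_stack <- function(config, seed = 1L) {
  stopifnot(inherits(config, "image_config"))
  set.seed(seed)
  cfg <- config
  ext_um <- cfg$dim_vox * cfg$voxel_size_um
  margin <- max(cfg$nuclear_diameter_um) / 2

  if (any(ext_um <= 2 * margin)) {
    stop("volume too small for the nuclear diameter", call. = FALSE)
  }

  centres <- matrix(NA_real_, cfg$n_nuclei, 3)
  placed <- 0L
  tries <- 0L
  min_sp2 <- cfg$min_spacing_um^2
  while (placed < cfg$n_nuclei) {
    tries <- tries + 1L
    if (tries > cfg$max_retries) {
      stop("could not place ", cfg$n_nuclei, " nuclei at spacing ",
           cfg$min_spacing_um, " um within the retry budget", call. = FALSE)
    }
    cand <- stats::runif(3, min = margin, max = ext_um - margin)
    if (placed > 0L) {
      d2 <- colSums((t(centres[seq_len(placed), , drop = FALSE]) - cand)^2)
      if (min(d2) < min_sp2) next
    }
    placed <- placed + 1L
    centres[placed, ] <- cand
  }

  diam <- stats::runif(cfg$n_nuclei, cfg$nuclear_diameter_um[1],
                       cfg$nuclear_diameter_um[2])
  labeled <- if (cfg$exact_count) {
    k <- round(cfg$labeled_fraction * cfg$n_nuclei)
    sample(rep(c(TRUE, FALSE), c(k, cfg$n_nuclei - k)))
  } else {
    stats::runif(cfg$n_nuclei) < cfg$labeled_fraction
  }
  # under negative marking the clone (labeled) cells are marker-low
  marker_high <- if (cfg$positive_marking) labeled else !labeled
  amp_label <- ifelse(
    marker_high,
    stats::rnorm(cfg$n_nuclei, cfg$label_high_mean, cfg$label_high_sd),
    stats::rnorm(cfg$n_nuclei, cfg$label_low_mean, cfg$label_low_sd))
  amp_label <- pmax(amp_label, 0)

  nuc <- array(0, cfg$dim_vox)
  lab <- array(0, cfg$dim_vox)
  for (i in seq_len(cfg$n_nuclei)) {
    sigma <- diam[i] / 4
    win <- render_window(centres[i, ], sigma, cfg$dim_vox, cfg$voxel_size_um)
    if (is.null(win)) next
    blob <- win$weights
    idx <- win$index
    nuc[idx] <- nuc[idx] + cfg$nuclear_amplitude * blob
    lab[idx] <- lab[idx] + amp_label[i] * blob
  }
  nv <- prod(cfg$dim_vox)
  nuc <- pmax(nuc + cfg$background + stats::rnorm(nv, 0, cfg$noise_sd), 0)
  lab <- pmax(lab + cfg$background + stats::rnorm(nv, 0, cfg$noise_sd), 0)
  dim(nuc) <- cfg$dim_vox
  dim(lab) <- cfg$dim_vox

  structure(list(
    nuclear = nuc, label = lab,
    voxel_size_um = cfg$voxel_size_um,
    positive_marking = cfg$positive_marking,
    truth = tibble::tibble(
      nucleus = seq_len(cfg$n_nuclei),
      x_um = centres[, 1], y_um = centres[, 2], z_um = centres[, 3],
      diameter_um = diam, labeled = labeled,
      label_amplitude = amp_label)),
    class = "image_stack")
}

# Gaussian blob weights within +/- 3 sigma of a centre; returns linear
# voxel indices and weights, or NULL if the window is empty.
render_window <- function(centre_um, sigma_um, dim_vox, voxel_size_um) {
  lo <- pmax(1L, floor((centre_um - 3 * sigma_um) / voxel_size_um) + 1L)
  hi <- pmin(dim_vox, ceiling((centre_um + 3 * sigma_um) / voxel_size_um))
  if (any(lo > hi)) return(NULL)
  ax <- lapply(1:3, function(a) {
    coords <- (seq(lo[a], hi[a]) - 0.5) * voxel_size_um[a]
    exp(-(coords - centre_um[a])^2 / (2 * sigma_um^2))
  })
  w <- outer(outer(ax[[1]], ax[[2]]), ax[[3]])
  ii <- seq(lo[1], hi[1]); jj <- seq(lo[2], hi[2]); kk <- seq(lo[3], hi[3])
  grid <- expand.grid(i = ii, j = jj, k = kk)
  idx <- grid$i + (grid$j - 1L) * dim_vox[1] +
    (grid$k - 1L) * dim_vox[1] * dim_vox[2]
  list(index = idx, weights = as.vector(w))
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$nuclear)
  cat("<image_stack> ", paste(d, collapse = " x "), " voxels (",
      paste(signif(d * x$voxel_size_um, 3), collapse = " x "), " um), ",
      "2 channels", sep = "")
  if (!is.null(x$truth)) cat(", ", nrow(x$truth), " ground-truth nuclei",
                             sep = "")
  cat("\n")
  invisible(x)
}

#' Read and write image stacks as multi-page TIFF
#'
#' Stacks are stored as 32-bit float multi-page TIFF, channel-major
#' (all z planes of the nuclear channel, then all z planes of the label
#' channel). The ground-truth table, voxel size and marking polarity are
#' written to a JSON sidecar `<path>.json`.
#'
#' @param stack An `image_stack`.
#' @param path Output TIFF path.
#' @return `write_stack` returns `path` invisibly; `read_stack` returns an
#'   `image_stack` (with truth table if the sidecar is present).
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$nuclear)
  pages <- c(lapply(seq_len(d[3]), function(k) stack$nuclear[, , k] / 2^16),
             lapply(seq_len(d[3]), function(k) stack$label[, , k] / 2^16))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  sidecar <- list(dim_vox = d, voxel_size_um = stack$voxel_size_um,
                  positive_marking = isTRUE(stack$positive_marking),
                  scale = 2^16)
  if (!is.null(stack$truth)) sidecar$truth <- stack$truth
  jsonlite::write_json(sidecar, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE, dataframe = "columns")
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  d <- as.integer(meta$dim_vox)
  sc <- meta$scale
  nz <- d[3]
  stack_from <- function(off) {
    a <- array(0, d)
    for (k in seq_len(nz)) a[, , k] <- pages[[off + k]] * sc
    a
  }
  truth <- if (!is.null(meta$truth)) tibble::as_tibble(meta$truth) else NULL
  structure(list(nuclear = stack_from(0L), label = stack_from(nz),
                 voxel_size_um = meta$voxel_size_um,
                 positive_marking = isTRUE(meta$positive_marking),
                 truth = truth),
            class = "image_stack")
}
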