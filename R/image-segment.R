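#' Segment nuclei in a 3D stack
#'
#' Automated re-implementation of an interactive surface-rendering
#' workflow, with the manual inspect-and-repair loop replaced by
#' reproducible rules:
#'
#' 1. separable 3D Gaussian smoothing of the nuclear channel;
#' 2. diameter-scaled background subtraction (Gaussian high-pass: a
#'    blur at the nuclear diameter scale is subtracted);
#' 3. global Otsu thresholding of the processed channel (a bimodality
#'    guard returns an empty result, with a warning, for blank images);
#' 4. seed detection at local intensity maxima separated by at least half
#'    the nuclear diameter — the splitting rule for touching objects;
#' 5. assignment of each foreground voxel to the nearest seed within one
#'    nuclear diameter (anisotropy-aware distance);
#' 6. removal of surfaces below a volume floor (the quality threshold).
#'
#' @param stack An `image_stack` (see [generate_stack()], [read_stack()]).
#' @param smoothing_sigma_um Gaussian smoothing sigma, micrometres.
#' @param diameter_um Approximate nuclear diameter, micrometres; scales
#'   the background subtraction, the seed separation and the assignment
#'   radius.
#' @param quality_threshold Minimum surface volume in cubic micrometres.
#' @return A tibble of class `nucleus_surfaces`, one row per segmented
#'   nucleus: `nucleus`, `x_um`, `y_um`, `z_um` (intensity-weighted
#'   centroid), `n_voxels`, `volume_um3`, `mean_nuclear`, `mean_label`,
#'   and a `voxels` list-column of linear voxel indices (disjoint across
#'   surfaces). Empty (zero-row) if no foreground is found.
#' @export
segment_nuclei <- function(stack, smoothing_sigma_um = 0.4,
                           diameter_um = 2.1, quality_threshold = 1) {
  stopifnot(inherits(stack, "image_stack"), diameter_um > 0)
  vs <- stack$voxel_size_um
  img <- stack$nuclear
  d <- dim(img)

  smooth <- gaussian_blur3d(img, smoothing_sigma_um / vs)
  bg <- gaussian_blur3d(smooth, diameter_um / vs, d)
  proc <- smooth - bg
  dim(proc) <- d
  dim(smooth) <- d

  empty <- empty_surfaces()
  # blank guard: a nucleus-bearing high-passed image is strongly
  # right-skewed (sparse bright blobs); smoothed noise is symmetric
  pv <- as.vector(proc)
  skew <- mean((pv - mean(pv))^3) / stats::sd(pv)^3
  if (!is.finite(skew) || skew < 0.5) {
    warning("no foreground detected (image appears blank)", call. = FALSE)
    return(empty)
  }
  ot <- otsu_split(pv)
  fg <- proc > ot$threshold
  if (!any(fg)) {
    warning("all-background segmentation result", call. = FALSE)
    return(empty)
  }

  seeds <- find_seeds(smooth, fg, min_sep_um = diameter_um / 2, vs)
  if (nrow(seeds) == 0) {
    warning("no seeds found above threshold", call. = FALSE)
    return(empty)
  }

  assign <- assign_to_seeds(fg, seeds, radius_um = diameter_um, vs, d)
  vox_um3 <- prod(vs)
  min_vox <- max(2L, ceiling(quality_threshold / vox_um3))

  keep <- which(tabulate(assign$label, nbins = nrow(seeds)) >= min_vox)
  if (length(keep) == 0) {
    warning("all surfaces below the quality threshold", call. = FALSE)
    return(empty)
  }

  out <- purrr::map(seq_along(keep), function(si) {
    s <- keep[si]
    vox <- assign$index[assign$label == s]
    w <- stack$nuclear[vox]
    ijk <- arrayInd(vox, d)
    cen <- colSums(ijk * w) / sum(w)
    tibble::tibble(
      nucleus = si,
      x_um = (cen[1] - 0.5) * vs[1],
      y_um = (cen[2] - 0.5) * vs[2],
      z_um = (cen[3] - 0.5) * vs[3],
      n_voxels = length(vox),
      volume_um3 = length(vox) * vox_um3,
      mean_nuclear = mean(stack$nuclear[vox]),
      mean_label = mean(stack$label[vox]),
      voxels = list(vox))
  }) |>
    dplyr::bind_rows()
  class(out) <- c("nucleus_surfaces", class(out))
  out
}

empty_surfaces <- function() {
  out <- tibble::tibble(nucleus = integer(), x_um = numeric(),
                        y_um = numeric(), z_um = numeric(),
                        n_voxels = integer(), volume_um3 = numeric(),
                        mean_nuclear = numeric(), mean_label = numeric(),
                        voxels = list())
  class(out) <- c("nucleus_surfaces", class(out))
  out
}

# separable Gaussian blur; sigma_vox is per-axis sigma in voxels.
# Edge effects are corrected by normalising with the blurred unit image.
gaussian_blur3d <- function(a, sigma_vox, d = dim(a)) {
  ones <- array(1, d)
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s < 1e-6) next
    half <- max(1L, ceiling(2.5 * s))
    k <- stats::dnorm(seq(-half, half), sd = s)
    k <- k / sum(k)
    a <- conv_axis(a, k, axis, d)
    ones <- conv_axis(ones, k, axis, d)
  }
  a / ones
}

conv_axis <- function(a, k, axis, d) {
  perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  ap <- aperm(array(a, d), perm)
  m <- matrix(ap, nrow = d[axis])
  half <- (length(k) - 1L) %/% 2L
  pad <- matrix(0, half, ncol(m))
  out <- stats::filter(rbind(pad, m, pad), k, sides = 2)
  out <- out[(half + 1L):(half + d[axis]), , drop = FALSE]
  back <- array(out, d[perm])
  as.vector(aperm(back, order(perm)))
}

# exact 1-D Otsu: split minimising within-class variance
otsu_split <- function(v) {
  v <- v[is.finite(v)]
  n <- length(v)
  tot <- stats::var(v) * (n - 1) / n
  if (n < 2 || tot == 0) {
    return(list(threshold = if (n) v[1] else 0, bimodality = 0))
  }
  # histogram approximation (exact enough at 512 bins, O(n) not O(n^2))
  h <- graphics::hist(v, breaks = 512, plot = FALSE)
  w <- h$counts / n
  m <- h$mids
  cw <- cumsum(w)
  cm <- cumsum(w * m)
  mu <- cm[length(cm)]
  valid <- cw > 0 & cw < 1
  between <- (mu * cw - cm)^2 / (cw * (1 - cw))
  between[!valid] <- -Inf
  j <- which.max(between)
  list(threshold = h$breaks[j + 1], bimodality = between[j] / tot)
}

# local 26-neighbourhood maxima of `img` within `fg`, greedily thinned to
# a minimum separation (um); returns tibble(i, j, k, value)
find_seeds <- function(img, fg, min_sep_um, vs) {
  d <- dim(img)
  is_max <- fg
  for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
    if (di == 0 && dj == 0 && dk == 0) next
    shifted <- shift3d(img, c(di, dj, dk), d, fill = -Inf)
    is_max <- is_max & (img >= shifted)
  }
  idx <- which(is_max)
  if (length(idx) == 0) return(tibble::tibble(i = integer(), j = integer(),
                                              k = integer(), value = numeric()))
  ijk <- arrayInd(idx, d)
  val <- img[idx]
  ord <- order(val, decreasing = TRUE)
  ijk <- ijk[ord, , drop = FALSE]
  val <- val[ord]
  pos <- sweep(ijk - 0.5, 2, vs, "*")
  sel <- integer(0)
  min_sep2 <- min_sep_um^2
  for (i in seq_along(val)) {
    if (length(sel)) {
      d2 <- colSums((t(pos[sel, , drop = FALSE]) - pos[i, ])^2)
      if (min(d2) < min_sep2) next
    }
    sel <- c(sel, i)
  }
  tibble::tibble(i = ijk[sel, 1], j = ijk[sel, 2], k = ijk[sel, 3],
                 value = val[sel])
}

shift3d <- function(a, by, d, fill = 0) {
  out <- array(fill, d)
  src <- lapply(1:3, function(ax) {
    s <- seq_len(d[ax]) - by[ax]
    s[s >= 1 & s <= d[ax]]
  })
  dst <- lapply(1:3, function(ax) {
    s <- seq_len(d[ax])
    s[s - by[ax] >= 1 & s - by[ax] <= d[ax]]
  })
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# nearest-seed assignment of foreground voxels within a radius (um)
assign_to_seeds <- function(fg, seeds, radius_um, vs, d) {
  best <- array(Inf, d)
  label <- array(0L, d)
  rad_vox <- ceiling(radius_um / vs)
  for (s in seq_len(nrow(seeds))) {
    c_ijk <- c(seeds$i[s], seeds$j[s], seeds$k[s])
    lo <- pmax(1L, c_ijk - rad_vox)
    hi <- pmin(d, c_ijk + rad_vox)
    ii <- seq(lo[1], hi[1]); jj <- seq(lo[2], hi[2]); kk <- seq(lo[3], hi[3])
    dx2 <- ((ii - c_ijk[1]) * vs[1])^2
    dy2 <- ((jj - c_ijk[2]) * vs[2])^2
    dz2 <- ((kk - c_ijk[3]) * vs[3])^2
    d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
    sub_fg <- fg[ii, jj, kk]
    sub_best <- best[ii, jj, kk]
    upd <- sub_fg & d2 <= radius_um^2 & d2 < sub_best
    sub_best[upd] <- d2[upd]
    sub_lab <- label[ii, jj, kk]
    sub_lab[upd] <- s
    best[ii, jj, kk] <- sub_best
    label[ii, jj, kk] <- sub_lab
  }
  idx <- which(label > 0L)
  list(index = idx, label = label[idx])
}

#' Automated label/no-label intensity threshold
#'
#' Reproducible stand-in for the interactive scatterplot procedure used to
#' separate marker-negative from marker-positive cells: per-nucleus mean
#' intensities are split by exact Otsu clustering on the log scale (the
#' split minimising within-class variance), and a bimodality diagnostic
#' (between-class variance over total variance, 0-1) flags degenerate
#' unimodal inputs, for which no classes are assigned.
#'
#' @param mean_intensities Numeric vector of per-nucleus mean label-channel
#'   intensities (length >= 2).
#' @param min_bimodality Bimodality score below which the input is
#'   declared unimodal.
#' @return A list of class `label_threshold`: `threshold` (original
#'   intensity scale), `class` (factor `"low"`/`"high"` per nucleus; all
#'   `NA` when unimodal), `bimodality`, `unimodal`.
#' @export
fit_label_threshold <- function(mean_intensities, min_bimodality = 0.6) {
  v <- mean_intensities
  if (length(v) < 2) stop("need at least 2 surfaces to fit a threshold",
                          call. = FALSE)
  if (any(v < 0)) stop("intensities must be non-negative", call. = FALSE)
  lv <- log(v + 1e-6)
  n <- length(lv)
  sv <- sort(lv)
  tot <- stats::var(lv) * (n - 1) / n
  if (tot == 0) {
    return(structure(list(threshold = NA_real_,
                          class = factor(rep(NA, n),
                                         levels = c("low", "high")),
                          bimodality = 0, unimodal = TRUE),
                     class = "label_threshold"))
  }
  # exact Otsu over the n - 1 candidate splits of the sorted values
  csum <- cumsum(sv)
  k <- seq_len(n - 1)
  mu_lo <- csum[k] / k
  mu_hi <- (csum[n] - csum[k]) / (n - k)
  between <- (k / n) * (1 - k / n) * (mu_lo - mu_hi)^2
  j <- which.max(between)
  bimod <- between[j] / tot
  thr_log <- (sv[j] + sv[j + 1]) / 2
  if (bimod < min_bimodality) {
    return(structure(list(threshold = exp(thr_log),
                          class = factor(rep(NA, n),
                                         levels = c("low", "high")),
                          bimodality = bimod, unimodal = TRUE),
                     class = "label_threshold"))
  }
  structure(list(threshold = exp(thr_log),
                 class = factor(ifelse(lv > thr_log, "high", "low"),
                                levels = c("low", "high")),
                 bimodality = bimod, unimodal = FALSE),
            class = "label_threshold")
}

#' @export
print.label_threshold <- function(x, ...) {
  if (x$unimodal) {
    cat("<label_threshold> unimodal input (bimodality ",
        signif(x$bimodality, 3), "); no classes assigned\n", sep = "")
  } else {
    cat("<label_threshold> threshold ", signif(x$threshold, 4),
        " (bimodality ", signif(x$bimodality, 3), "); ",
        sum(x$class == "low"), " low / ", sum(x$class == "high"),
        " high\n", sep = "")
  }
  invisible(x)
}

#' Clone fraction from classified nuclei
#'
#' Counts marker-negative and marker-positive nuclei within a region of
#' interest along the anterior-posterior (x) axis and computes the clone
#' (labelled) fraction: negative count over total for negative-marking
#' systems, positive count over total for positive marking.
#'
#' @param surfaces A `nucleus_surfaces` tibble ([segment_nuclei()]).
#' @param threshold Intensity threshold (e.g. from
#'   [fit_label_threshold()]).
#' @param region_bounds_x Optional `c(min, max)` bounds in micrometres
#'   along x; `NULL` uses all surfaces.
#' @param positive_marking Marking polarity (see [image_config()]).
#' @return A one-row tibble: `n_total`, `n_negative`, `n_positive`,
#'   `labeled_fraction`.
#' @export
quantify_clone_fraction <- function(surfaces, threshold,
                                    region_bounds_x = NULL,
                                    positive_marking = FALSE) {
  s <- surfaces
  if (!is.null(region_bounds_x)) {
    s <- dplyr::filter(s, .data$x_um >= region_bounds_x[1],
                       .data$x_um <= region_bounds_x[2])
  }
  if (nrow(s) == 0) stop("no surfaces in the region of interest",
                         call. = FALSE)
  n_neg <- sum(s$mean_label < threshold)
  n_pos <- nrow(s) - n_neg
  tibble::tibble(
    n_total = nrow(s), n_negative = n_neg, n_positive = n_pos,
    labeled_fraction = if (positive_marking) n_pos / nrow(s)
    else n_neg / nrow(s))
}

#' Match segmented surfaces to ground-truth nuclei
#'
#' Optimal one-to-one assignment (Hungarian algorithm via
#' \pkg{clue}, with a greedy fallback) between segmented centroids and
#' ground-truth centres, gated at a maximum distance; reports precision,
#' recall and F1 of the segmentation.
#'
#' @param surfaces A `nucleus_surfaces` tibble.
#' @param truth Ground-truth tibble with `x_um`, `y_um`, `z_um` (e.g.
#'   `stack$truth`).
#' @param gate_um Maximum centroid distance for a valid match.
#' @return A list: `matches` (tibble `nucleus`, `truth`, `dist_um`),
#'   `n_matched`, `precision`, `recall`, `f1`.
#' @export
match_nuclei <- function(surfaces, truth, gate_um = 1) {
  if (nrow(surfaces) == 0 || nrow(truth) == 0) {
    return(list(matches = tibble::tibble(nucleus = integer(),
                                         truth = integer(),
                                         dist_um = numeric()),
                n_matched = 0L, precision = 0, recall = 0, f1 = 0))
  }
  a <- as.matrix(surfaces[, c("x_um", "y_um", "z_um")])
  b <- as.matrix(truth[, c("x_um", "y_um", "z_um")])
  dmat <- sqrt(outer(rowSums(a^2), rep(1, nrow(b))) +
                 outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * a %*% t(b))
  big <- 10 * gate_um
  cost <- pmin(dmat, big)
  if (requireNamespace("clue", quietly = TRUE)) {
    n <- max(nrow(cost), ncol(cost))
    sq <- matrix(big, n, n)
    sq[seq_len(nrow(cost)), seq_len(ncol(cost))] <- cost
    sol <- as.integer(clue::solve_LSAP(sq))
    pairs <- tibble::tibble(nucleus = seq_len(n), truth = sol)
    pairs <- dplyr::filter(pairs, .data$nucleus <= nrow(cost),
                           .data$truth <= ncol(cost))
  } else {
    ord <- order(dmat)
    used_a <- logical(nrow(dmat)); used_b <- logical(ncol(dmat))
    na_ <- integer(0); nb_ <- integer(0)
    for (o in ord) {
      ai <- (o - 1) %% nrow(dmat) + 1
      bi <- (o - 1) %/% nrow(dmat) + 1
      if (dmat[ai, bi] > gate_um) break
      if (used_a[ai] || used_b[bi]) next
      used_a[ai] <- TRUE; used_b[bi] <- TRUE
      na_ <- c(na_, ai); nb_ <- c(nb_, bi)
    }
    pairs <- tibble::tibble(nucleus = na_, truth = nb_)
  }
  pairs$dist_um <- dmat[cbind(pairs$nucleus, pairs$truth)]
  pairs <- dplyr::filter(pairs, .data$dist_um <= gate_um)
  tp <- nrow(pairs)
  precision <- tp / nrow(surfaces)
  recall <- tp / nrow(truth)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(matches = pairs, n_matched = tp,
       precision = precision, recall = recall, f1 = f1)
}
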