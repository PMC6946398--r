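# Shared fixtures and independent oracles used across test files.

# Sequential Polya-urn oracle: literal one-cell-at-a-time reinforcement,
# independent of the de Finetti sampler used by the package.
sequential_polya_urn <- function(k, n) {
  counts <- rep(1L, k)
  for (i in seq_len(n - k)) {
    j <- sample.int(k, 1L, prob = counts)
    counts[j] <- counts[j] + 1L
  }
  counts
}

# A minimal, fast simulator configuration for unit tests.
quick_config <- function(...) {
  sim_config(sample_dphs = 7, ...)
}

# Build one synthetic patch-record tibble row (the simulator's output
# shape) so classification rules can be tested on constructed cases.
make_patch_row <- function(ovariole = 1L, dphs = 7, patch_id = 1L,
                           phenotype = "GFP-", origin = "fsc",
                           touches_border = FALSE,
                           in_germarium_only = FALSE,
                           n_follicles_spanned = 1L,
                           germarium_fraction = 0,
                           frac_follicles = list(0.5),
                           cell_count = 50L,
                           contiguous_with = NA_integer_,
                           total_cells_scored = 300,
                           anterior_fasiii = NA,
                           anterior_contiguous = NA) {
  tibble::tibble(
    ovariole = ovariole, dphs = dphs, patch_id = patch_id,
    phenotype = phenotype, origin = origin,
    touches_border = touches_border,
    in_germarium_only = in_germarium_only,
    n_follicles_spanned = as.integer(n_follicles_spanned),
    germarium_fraction = germarium_fraction,
    frac_follicles = frac_follicles,
    mean_fraction = mean(unlist(frac_follicles)),
    cell_count = as.integer(cell_count),
    contiguous_with = contiguous_with,
    total_cells_scored = total_cells_scored,
    anterior_fasiii = anterior_fasiii,
    anterior_contiguous = anterior_contiguous)
}

# Archetypal single-ovariole records for each clone-pattern category.
make_category_record <- function(category, ovariole = 1L) {
  switch(category,
    fsc_persistent = make_patch_row(
      ovariole, touches_border = TRUE, n_follicles_spanned = 3L,
      germarium_fraction = 0.5, frac_follicles = list(c(0.5, 0.5, 0.5))),
    transient = make_patch_row(
      ovariole, frac_follicles = list(0.4), n_follicles_spanned = 1L),
    replacement = make_patch_row(
      ovariole, n_follicles_spanned = 2L,
      frac_follicles = list(c(0.6, 0.6))),
    small_germarium = make_patch_row(
      ovariole, in_germarium_only = TRUE, n_follicles_spanned = 0L,
      germarium_fraction = 0.1, frac_follicles = list(numeric(0)),
      cell_count = 4L),
    discontinuous = dplyr::bind_rows(
      make_patch_row(ovariole, patch_id = 1L, touches_border = TRUE,
                     n_follicles_spanned = 1L, germarium_fraction = 0.3,
                     frac_follicles = list(0.3)),
      make_patch_row(ovariole, patch_id = 2L, n_follicles_spanned = 1L,
                     frac_follicles = list(0.6),
                     contiguous_with = NA_integer_)),
    stop("unknown category fixture: ", category))
}

# Two-blob stack at an exact centre-to-centre spacing, for split tests.
two_blob_stack <- function(spacing_um, diameter_um = 2.1,
                           noise_sd = 2, seed = 1) {
  set.seed(seed)
  dim_vox <- c(60L, 40L, 16L)
  vs <- c(0.2, 0.2, 0.5)
  c1 <- c(4, 4, 4)
  c2 <- c1 + c(spacing_um, 0, 0)
  nuc <- array(0, dim_vox)
  lab <- array(0, dim_vox)
  for (cc in list(c1, c2)) {
    win <- fscclone:::render_window(cc, diameter_um / 4, dim_vox, vs)
    nuc[win$index] <- nuc[win$index] + 100 * win$weights
    lab[win$index] <- lab[win$index] + 120 * win$weights
  }
  nv <- prod(dim_vox)
  nuc <- pmax(nuc + 10 + stats::rnorm(nv, 0, noise_sd), 0)
  dim(nuc) <- dim_vox
  structure(list(nuclear = nuc, label = lab, voxel_size_um = vs,
                 truth = tibble::tibble(
                   nucleus = 1:2,
                   x_um = c(c1[1], c2[1]), y_um = c(c1[2], c2[2]),
                   z_um = c(c1[3], c2[3]),
                   diameter_um = diameter_um, labeled = c(TRUE, TRUE),
                   label_amplitude = 120)),
            class = "image_stack")
}
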