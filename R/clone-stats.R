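#' Classify clone patterns into the five-category scheme
#'
#' Each recombinant phenotype within an ovariole record is assigned exactly
#' one of five patterns, with the following precedence (discontinuity is
#' checked first because it is the decisive anomaly):
#'
#' 1. `discontinuous` — a border-touching patch coexists with a
#'    non-contiguous same-phenotype patch downstream;
#' 2. `fsc_persistent` — a contiguous patch touches the Region 2a/2b
#'    border and spans at least one budded follicle (a labelled stem
#'    cell's lineage);
#' 3. `replacement` — a patch spans two or more follicles without border
#'    contact (the expected remnant of a recent FSC replacement);
#' 4. `small_germarium` — all patches lie within the germarium and none
#'    touches the border;
#' 5. `transient` — a patch covers at most half of one follicle and does
#'    not touch the border (a labelled non-stem cell).
#'
#' @param cohort A tibble of ovariole patch records as produced by
#'   [simulate_cohort()] / [simulate_ovariole()].
#' @return A tibble with one row per `(ovariole, dphs, phenotype)` holding
#'   the assigned `category` (factor with the five levels above).
#'   Ovariole-days without a recombinant patch are omitted.
#' @export
classify_clone_pattern <- function(cohort) {
  cohort |>
    dplyr::filter(!is.na(.data$phenotype)) |>
    dplyr::group_by(.data$ovariole, .data$dphs, .data$phenotype) |>
    dplyr::summarise(category = classify_patch_group(
      touches_border = .data$touches_border,
      in_germarium_only = .data$in_germarium_only,
      n_follicles_spanned = .data$n_follicles_spanned,
      frac_follicles = .data$frac_follicles,
      contiguous_with = .data$contiguous_with),
      .groups = "drop") |>
    dplyr::mutate(category = factor(.data$category, levels = clone_categories()))
}

#' @rdname classify_clone_pattern
#' @export
clone_categories <- function() {
  c("fsc_persistent", "transient", "replacement",
    "small_germarium", "discontinuous")
}

classify_patch_group <- function(touches_border, in_germarium_only,
                                 n_follicles_spanned, frac_follicles,
                                 contiguous_with) {
  border <- which(touches_border)
  downstream_detached <- which(!touches_border & !in_germarium_only &
                                 is.na(contiguous_with))
  if (length(border) && length(downstream_detached)) {
    return("discontinuous")
  }
  if (any(touches_border & n_follicles_spanned >= 1)) {
    return("fsc_persistent")
  }
  if (any(!touches_border & n_follicles_spanned >= 2)) {
    return("replacement")
  }
  if (all(in_germarium_only) && !any(touches_border)) {
    return("small_germarium")
  }
  # remaining: non-border patches within at most one follicle
  "transient"
}

#' Classify an ovariole's labelling state
#'
#' An ovariole is `"none"` if it has no persistent FSC clone, `"full"` if a
#' single phenotype's persistent clone covers (essentially) the whole
#' follicle epithelium in every scored follicle and the germarium, and
#' `"mosaic"` otherwise. Clone-size analysis uses mosaic ovarioles only.
#'
#' @param cohort A patch-record tibble ([simulate_cohort()]).
#' @param tol Coverage above `1 - tol` counts as complete.
#' @return A tibble with one row per `(ovariole, dphs)`: `labeling`
#'   (factor none/mosaic/full), and for ovarioles with a persistent clone
#'   the `phenotype` and its overall labelled `fraction` of scored cells.
#' @export
classify_labeling <- function(cohort, tol = 1e-3) {
  cats <- classify_clone_pattern(cohort)
  persistent <- dplyr::filter(cats, .data$category == "fsc_persistent")

  per_record <- cohort |>
    dplyr::distinct(.data$ovariole, .data$dphs, .data$total_cells_scored)

  if (nrow(persistent) == 0) {
    return(per_record |>
             dplyr::transmute(.data$ovariole, .data$dphs,
                              labeling = factor("none", levels =
                                                  c("none", "mosaic", "full")),
                              phenotype = NA_character_,
                              fraction = NA_real_))
  }

  frac <- cohort |>
    dplyr::inner_join(persistent,
                      by = c("ovariole", "dphs", "phenotype")) |>
    dplyr::group_by(.data$ovariole, .data$dphs, .data$phenotype) |>
    dplyr::summarise(
      fraction = sum(.data$cell_count) / .data$total_cells_scored[1],
      complete = all(unlist(.data$frac_follicles) > 1 - tol) &&
        all(.data$germarium_fraction[.data$touches_border] > 1 - tol),
      .groups = "drop") |>
    # if several phenotypes have persistent clones, keep the largest
    dplyr::group_by(.data$ovariole, .data$dphs) |>
    dplyr::slice_max(.data$fraction, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()

  per_record |>
    dplyr::left_join(frac, by = c("ovariole", "dphs")) |>
    dplyr::transmute(
      .data$ovariole, .data$dphs,
      labeling = factor(dplyr::case_when(
        is.na(.data$fraction) ~ "none",
        .data$complete ~ "full",
        TRUE ~ "mosaic"), levels = c("none", "mosaic", "full")),
      phenotype = .data$phenotype,
      fraction = .data$fraction)
}

#' Count uniquely labelled lineages per ovariole
#'
#' The number of distinct marker-combination classes visible in the scored
#' region (Region 2a/2b border through the first budded follicles): the
#' distinct phenotypes of all patches, plus the unrecombined class when
#' unlabelled cells are present (for the three-colour system the
#' unrecombined tissue is itself a visibly marked class). Disjoint patches
#' sharing a phenotype count once — lineages are counted by marker
#' combination, not by patch.
#'
#' @param cohort A patch-record tibble.
#' @param system The [marking_system()] used (defaults to the one attached
#'   to the cohort).
#' @return A tibble `(ovariole, dphs, n_lineages)`.
#' @export
count_unique_lineages <- function(cohort, system = NULL) {
  if (is.null(system)) {
    cfg <- attr(cohort, "config")
    if (is.null(cfg)) stop("supply `system` (cohort carries no config)",
                           call. = FALSE)
    system <- cfg$marking_system
  }
  bg <- unrecombined_phenotype(system)
  cohort |>
    dplyr::group_by(.data$ovariole, .data$dphs) |>
    dplyr::summarise(
      n_lineages = {
        ph <- unique(stats::na.omit(.data$phenotype))
        labelled <- sum(.data$cell_count, na.rm = TRUE)
        unlabelled <- .data$total_cells_scored[1] - labelled
        length(ph) + as.integer(unlabelled > 0 && !(bg %in% ph))
      },
      .groups = "drop")
}

#' Frequency tables of clone summaries
#'
#' Tabulates a cohort by phenotype, clone-pattern category, lineage
#' diversity, or labelling class, optionally grouped (for example by
#' `dphs`), returning counts and percentages.
#'
#' @param cohort A patch-record tibble ([simulate_cohort()]).
#' @param key One of `"phenotype"`, `"category"`, `"diversity"`,
#'   `"labeling"`.
#' @param by Optional grouping column name (e.g. `"dphs"`).
#' @return A tibble with the grouping column (if any), `label`, `count`
#'   and `percent`; rows in deterministic (lexicographic) label order and
#'   percents summing to 100 within each group.
#' @export
tally_clones <- function(cohort,
                         key = c("phenotype", "category", "diversity",
                                 "labeling"),
                         by = NULL) {
  key <- match.arg(key)
  if (nrow(cohort) == 0) stop("empty cohort", call. = FALSE)
  units <- switch(key,
    phenotype = cohort |>
      dplyr::filter(!is.na(.data$phenotype)) |>
      dplyr::distinct(.data$ovariole, .data$dphs, .data$phenotype) |>
      dplyr::rename(label = "phenotype"),
    category = classify_clone_pattern(cohort) |>
      dplyr::mutate(label = as.character(.data$category)) |>
      dplyr::select("ovariole", "dphs", "label"),
    diversity = count_unique_lineages(cohort) |>
      dplyr::mutate(label = as.character(.data$n_lineages)) |>
      dplyr::select("ovariole", "dphs", "label"),
    labeling = classify_labeling(cohort) |>
      dplyr::mutate(label = as.character(.data$labeling)) |>
      dplyr::select("ovariole", "dphs", "label"))
  if (key == "diversity") units <- dplyr::semi_join(
    units, cohort, by = c("ovariole", "dphs"))
  if (nrow(units) == 0) stop("no units to tabulate for key '", key, "'",
                             call. = FALSE)
  grp <- if (!is.null(by)) {
    if (!by %in% names(units)) {
      units <- dplyr::left_join(
        units, dplyr::distinct(cohort, .data$ovariole, .data$dphs,
                               dplyr::across(dplyr::all_of(by))),
        by = c("ovariole", "dphs"))
    }
    by
  } else character(0)
  units |>
    dplyr::count(dplyr::across(dplyr::all_of(grp)), .data$label,
                 name = "count") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::mutate(percent = 100 * .data$count / sum(.data$count)) |>
    dplyr::ungroup() |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(grp, "label"))))
}

#' Mean lineage diversity over the time course
#'
#' Convenience summary of [count_unique_lineages()]: mean (and SD) number
#' of uniquely labelled lineages per ovariole at each sampled dphs.
#'
#' @param cohort A patch-record tibble.
#' @return A tibble `(dphs, n, mean_lineages, sd_lineages)`.
#' @export
diversity_timecourse <- function(cohort) {
  count_unique_lineages(cohort) |>
    dplyr::group_by(.data$dphs) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_lineages = mean(.data$n_lineages),
                     sd_lineages = stats::sd(.data$n_lineages),
                     .groups = "drop")
}

#' Goodness of fit of observed label frequencies
#'
#' Pearson chi-square test of an observed frequency table against expected
#' proportions (for example the 1:1:1:2:2:2 marker-combination prediction
#' of the equal-genotype model).
#'
#' @param observed A tibble with columns `label` (or `phenotype`) and
#'   `count`, or a named count vector.
#' @param expected A tibble with columns `phenotype` (or `label`) and
#'   `probability`, as returned by [phenotype_distribution()], or a named
#'   probability vector. Must cover every observed label with positive
#'   probability.
#' @return A one-row tibble: `statistic`, `df` (classes − 1), `p.value`,
#'   `n`.
#' @export
goodness_of_fit <- function(observed, expected) {
  if (is.data.frame(observed)) {
    lab <- if ("label" %in% names(observed)) "label" else "phenotype"
    counts <- stats::setNames(observed$count, observed[[lab]])
  } else {
    counts <- observed
  }
  if (is.data.frame(expected)) {
    lab <- if ("phenotype" %in% names(expected)) "phenotype" else "label"
    probs <- stats::setNames(expected$probability, expected[[lab]])
  } else {
    probs <- expected
  }
  if (sum(counts) < 1) stop("total observed count must be >= 1", call. = FALSE)
  missing <- setdiff(names(counts)[counts > 0], names(probs)[probs > 0])
  if (length(missing)) {
    stop("labels observed with expected probability 0: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  full <- union(names(probs), names(counts))
  x <- stats::setNames(rep(0, length(full)), full)
  x[names(counts)] <- counts
  p <- stats::setNames(rep(0, length(full)), full)
  p[names(probs)] <- probs
  ht <- suppressWarnings(stats::chisq.test(x, p = p, rescale.p = TRUE))
  tibble::tibble(statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p.value = ht$p.value,
                 n = sum(x))
}

#' Position class of the anterior-most labelled cell
#'
#' Classifies where each persistent clone begins relative to the FasIII
#' expression boundary (which coincides with the Region 2a/2b border):
#' `"border"` if the anterior-most labelled cell is FasIII-positive at the
#' boundary, `"adjacent"` if it is FasIII-negative but contiguous with the
#' clone at the boundary, and `"anterior"` if it is FasIII-negative and
#' detached from the clone (an independently labelled escort/IGS cell).
#'
#' @param cohort A patch-record tibble with `anterior_fasiii` and
#'   `anterior_contiguous` annotations (records without a persistent clone
#'   carry `NA` and are skipped).
#' @return A tibble `(ovariole, dphs, anterior_class)` with
#'   `anterior_class` a factor border/adjacent/anterior.
#' @export
anterior_cell_class <- function(cohort) {
  recs <- cohort |>
    dplyr::distinct(.data$ovariole, .data$dphs, .data$anterior_fasiii,
                    .data$anterior_contiguous) |>
    dplyr::filter(!is.na(.data$anterior_fasiii))
  if (nrow(recs) && any(is.na(recs$anterior_contiguous))) {
    stop("anterior-cell annotation incomplete (contiguity flag missing)",
         call. = FALSE)
  }
  recs |>
    dplyr::transmute(
      .data$ovariole, .data$dphs,
      anterior_class = factor(dplyr::case_when(
        .data$anterior_fasiii ~ "border",
        .data$anterior_contiguous ~ "adjacent",
        TRUE ~ "anterior"), levels = c("border", "adjacent", "anterior")))
}
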