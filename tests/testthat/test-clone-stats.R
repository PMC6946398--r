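test_that("constructed archetypes map to their clone-pattern categories", {
  for (cat in clone_categories()) {
    rec <- make_category_record(cat)
    res <- classify_clone_pattern(rec)
    expect_equal(as.character(res$category), cat, info = cat)
  }
  # border patch spanning germarium + 3 follicles -> persistent
  rec <- make_patch_row(touches_border = TRUE, n_follicles_spanned = 3L,
                        germarium_fraction = 0.4,
                        frac_follicles = list(c(0.4, 0.5, 0.6)))
  expect_equal(as.character(classify_clone_pattern(rec)$category),
               "fsc_persistent")
  # no recombinant patch -> no category rows, not an error
  empty <- make_patch_row()
  empty$phenotype <- NA_character_
  expect_equal(nrow(classify_clone_pattern(empty)), 0L)
})

test_that("discontinuity takes precedence over the persistent pattern", {
  rec <- make_category_record("discontinuous")
  expect_equal(as.character(classify_clone_pattern(rec)$category),
               "discontinuous")
  # same two patches, but downstream patch contiguous with the border
  # patch -> persistent, not discontinuous
  rec2 <- rec
  rec2$contiguous_with[2] <- 1L
  expect_equal(as.character(classify_clone_pattern(rec2)$category),
               "fsc_persistent")
})

test_that("labelling classes split none / mosaic / full", {
  none <- make_patch_row()
  none$phenotype <- NA_character_
  expect_equal(as.character(classify_labeling(none)$labeling), "none")

  mosaic <- make_category_record("fsc_persistent")
  expect_equal(as.character(classify_labeling(mosaic)$labeling), "mosaic")

  full <- make_patch_row(touches_border = TRUE, n_follicles_spanned = 3L,
                         germarium_fraction = 1,
                         frac_follicles = list(c(1, 1, 1)),
                         cell_count = 300L)
  expect_equal(as.character(classify_labeling(full)$labeling), "full")
  # a transient-only ovariole has no persistent clone -> none
  tr <- make_category_record("transient")
  expect_equal(as.character(classify_labeling(tr)$labeling), "none")
})

test_that("lineage diversity counts phenotype classes, not patches", {
  sys <- marking_system("LGR")
  as_cohort <- function(x) structure(x, config = list(marking_system = sys))
  # only unrecombined (triple-positive) tissue present
  only_bg <- make_patch_row(phenotype = "BGR", touches_border = TRUE,
                            cell_count = 300L, germarium_fraction = 1,
                            frac_follicles = list(c(1, 1, 1)))
  expect_equal(count_unique_lineages(as_cohort(only_bg))$n_lineages, 1L)
  # background + one recombinant class (two disjoint patches of it)
  two <- dplyr::bind_rows(
    make_patch_row(phenotype = "GR", patch_id = 1L, cell_count = 50L),
    make_patch_row(phenotype = "GR", patch_id = 2L, cell_count = 40L))
  expect_equal(count_unique_lineages(as_cohort(two))$n_lineages, 2L)
  # empty record: no patches, all cells unlabelled background
  empty <- make_patch_row()
  empty$phenotype <- NA_character_
  empty$cell_count <- NA_integer_
  expect_equal(count_unique_lineages(as_cohort(empty))$n_lineages, 1L)
})

test_that("frequency tables count, percent and group correctly", {
  recs <- dplyr::bind_rows(lapply(1:10, function(i) {
    make_category_record("fsc_persistent", ovariole = i)
  }))
  tab <- tally_clones(recs, "category")
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$percent, 100)
  expect_equal(tab$count, 10L)

  mixed <- dplyr::bind_rows(
    dplyr::bind_rows(lapply(1:6, function(i)
      make_category_record("fsc_persistent", ovariole = i))),
    dplyr::bind_rows(lapply(7:10, function(i)
      make_category_record("transient", ovariole = i))))
  tab2 <- tally_clones(mixed, "category")
  expect_equal(tab2$percent[tab2$label == "fsc_persistent"], 60)
  expect_equal(sum(tab2$percent), 100, tolerance = 0.1)

  grouped <- tally_clones(mixed, "category", by = "dphs")
  sums <- grouped |>
    dplyr::group_by(dphs) |>
    dplyr::summarise(s = sum(percent))
  expect_true(all(abs(sums$s - 100) < 0.1))

  expect_error(tally_clones(mixed[0, ], "category"), "empty cohort")
})

test_that("known category proportions are recovered by classification", {
  # multinomial sampling + classification round trip
  props <- c(fsc_persistent = 0.615, transient = 0.206,
             replacement = 0.036, small_germarium = 0.083,
             discontinuous = 0.060)
  set.seed(5)
  n <- 2000
  draw <- sample(names(props), n, replace = TRUE, prob = props)
  cohort <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    make_category_record(draw[i], ovariole = i)
  }))
  tab <- tally_clones(cohort, "category")
  for (cat in names(props)) {
    p <- props[[cat]]
    se <- sqrt(p * (1 - p) / n)
    got <- tab$percent[tab$label == cat] / 100
    expect_lt(abs(got - p), 3 * se)
  }
})

test_that("goodness of fit matches the hand-computed Pearson statistic", {
  expected <- phenotype_distribution(marking_system("LGR"))
  exact <- tibble::tibble(label = c("B", "G", "BG", "BR", "GR", "BGR"),
                          count = c(10, 10, 10, 20, 20, 20))
  g0 <- goodness_of_fit(exact, expected)
  expect_equal(g0$statistic, 0, tolerance = 1e-12)
  expect_equal(g0$p.value, 1, tolerance = 1e-12)
  expect_equal(g0$df, 5)

  # all 90 observations in one class: chi2 = (90-10)^2/10 + 10 + 10
  #   + 20 + 20 + 20 = 720 (hand-evaluated Pearson sum)
  lop <- tibble::tibble(label = c("B", "G", "BG", "BR", "GR", "BGR"),
                        count = c(90, 0, 0, 0, 0, 0))
  g1 <- goodness_of_fit(lop, expected)
  expect_equal(g1$statistic, 720, tolerance = 1e-9)

  expect_error(
    goodness_of_fit(tibble::tibble(label = "none", count = 5), expected),
    "probability 0")
})

test_that("anterior-most labelled cell classes follow FasIII and contiguity", {
  rec <- function(fas, contig) {
    make_patch_row(touches_border = TRUE, n_follicles_spanned = 2L,
                   frac_follicles = list(c(0.5, 0.5)),
                   anterior_fasiii = fas, anterior_contiguous = contig)
  }
  expect_equal(as.character(anterior_cell_class(rec(TRUE, TRUE))$anterior_class),
               "border")
  expect_equal(as.character(anterior_cell_class(rec(FALSE, TRUE))$anterior_class),
               "adjacent")
  expect_equal(as.character(anterior_cell_class(rec(FALSE, FALSE))$anterior_class),
               "anterior")
  bad <- rec(TRUE, NA)
  expect_error(anterior_cell_class(bad), "annotation incomplete")
})
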