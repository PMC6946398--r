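test_that("follicle composition models split cells as specified", {
  det <- sample_follicle_composition(c("A", "B"), 900, "deterministic")
  expect_equal(det$cells, c(450L, 450L))
  expect_equal(sample_follicle_composition("A", 900, "polya")$cells, 900L)
  det3 <- sample_follicle_composition(c("A", "B", "C"), 10, "deterministic")
  expect_equal(sum(det3$cells), 10L)
  expect_equal(det3$cells, c(4L, 3L, 3L))

  expect_error(sample_follicle_composition(character(), 10),
               "at least one founder")
  expect_error(sample_follicle_composition(c("A", "B"), 1),
               "at least the number of founders")
})

test_that("Polya-urn sampler matches the sequential urn's uniform limit law", {
  # For two founders with unit initial weight, the count of founder A
  # after growth to n cells is uniform on 1..(n-1); verify both the
  # literal sequential urn and the package's de Finetti sampler.
  n <- 10
  reps <- 2000
  set.seed(7)
  seq_counts <- replicate(reps, sequential_polya_urn(2, n)[1])
  pkg_counts <- replicate(reps, {
    sample_follicle_composition(c("A", "B"), n, "polya")$cells[1]
  })
  p_seq <- chisq.test(table(factor(seq_counts, levels = 1:(n - 1))))$p.value
  p_pkg <- chisq.test(table(factor(pkg_counts, levels = 1:(n - 1))))$p.value
  expect_gt(p_seq, 1e-4)
  expect_gt(p_pkg, 1e-4)

  # mean fraction of A is 1/2 within 3 SE; spread covers (0, 1)
  set.seed(8)
  fr <- replicate(3000, {
    sample_follicle_composition(c("A", "B"), 900, "polya")$cells[1] / 900
  })
  se <- sd(fr) / sqrt(length(fr))
  expect_lt(abs(mean(fr) - 0.5), 3 * se)
  expect_lt(min(fr), 0.1)
  expect_gt(max(fr), 0.9)
})

test_that("no label sources means no patches at any dphs", {
  cfg <- sim_config(induction_prob = 0, background_rate = 0,
                    silencing_rate = 0, quiescence_rate = 0,
                    sample_dphs = c(5, 14, 25))
  co <- simulate_cohort(cfg, 20, seed = 1)
  expect_true(all(is.na(co$phenotype)))
})

test_that("one forced labelled FSC under deterministic growth gives 0.5 everywhere", {
  cfg <- sim_config(forced_labeled_fsc = 1, growth_model = "deterministic",
                    background_rate = 0, quiescence_rate = 0,
                    replacement_rate = 0, sample_dphs = c(7, 14))
  co <- simulate_cohort(cfg, 5, seed = 2)
  expect_true(all(!is.na(co$phenotype)))
  expect_true(all(co$touches_border))
  expect_true(all(abs(unlist(co$frac_follicles) - 0.5) < 0.02))
  expect_true(all(abs(co$germarium_fraction - 0.5) < 1e-9))
})

test_that("cohorts are reproducible and extendable under one master seed", {
  cfg <- quick_config()
  a <- simulate_cohort(cfg, 10, seed = 99)
  b <- simulate_cohort(cfg, 10, seed = 99)
  expect_identical(dplyr::select(a, -"frac_follicles"),
                   dplyr::select(b, -"frac_follicles"))
  expect_identical(a$frac_follicles, b$frac_follicles)
  # per-ovariole substreams: the first 5 ovarioles of a longer cohort
  # match the 5-ovariole cohort
  c5 <- simulate_cohort(cfg, 5, seed = 99)
  expect_identical(dplyr::filter(a, ovariole <= 5)$cell_count, c5$cell_count)

  expect_error(simulate_cohort(cfg, 0), ">= 1")
})

test_that("labelled FSC fraction follows the complement rule", {
  cfg <- sim_config(sample_dphs = 7, background_rate = 0,
                    replacement_rate = 0, quiescence_rate = 0)
  n <- 1500
  co <- simulate_cohort(cfg, n, seed = 13)
  has_fsc <- co |>
    dplyr::group_by(ovariole) |>
    dplyr::summarise(any_fsc = any(!is.na(origin) & origin == "fsc" &
                                     touches_border))
  p_expect <- 1 - (1 - 0.187)^2
  se <- sqrt(p_expect * (1 - p_expect) / n)
  expect_lt(abs(mean(has_fsc$any_fsc) - p_expect), 3 * se)
})

test_that("expected labelled fraction is 1/l for one labelled FSC of l", {
  for (l in c(1, 2, 4)) {
    cfg <- sim_config(n_fsc = l, forced_labeled_fsc = 1,
                      background_rate = 0, quiescence_rate = 0,
                      replacement_rate = 0, sample_dphs = 7)
    co <- simulate_cohort(cfg, 200, seed = 100 + l)
    fr <- co |>
      dplyr::filter(!is.na(phenotype)) |>
      dplyr::group_by(ovariole) |>
      dplyr::summarise(f = sum(cell_count) / total_cells_scored[1])
    se <- sd(fr$f) / sqrt(nrow(fr))
    expect_lt(abs(mean(fr$f) - 1 / l), 3 * se + 0.01)
  }
})

test_that("transient patches clear the scored region; conservation holds", {
  cfg <- sim_config(sample_dphs = c(5, 25), quiescence_rate = 0,
                    background_rate = 0)
  co <- simulate_cohort(cfg, 150, seed = 21)
  late <- dplyr::filter(co, dphs == 25, !is.na(phenotype))
  expect_true(all(late$origin != "transient"))
  # cell-count conservation in every record
  per_rec <- co |>
    dplyr::group_by(ovariole, dphs) |>
    dplyr::summarise(lab = sum(cell_count, na.rm = TRUE),
                     tot = total_cells_scored[1], .groups = "drop")
  expect_true(all(per_rec$lab <= per_rec$tot))
  # diversity never exceeds the number of phenotype classes
  div <- count_unique_lineages(co)
  n_classes <- nrow(phenotype_distribution(
    attr(co, "config")$marking_system))
  expect_true(all(div$n_lineages <= n_classes))
})

test_that("marker silencing produces anomalous LGR phenotypes at a rate", {
  cfg <- sim_config(marking_system = marking_system("LGR"),
                    silencing_rate = 0.01, sample_dphs = 14)
  co <- simulate_cohort(cfg, 150, seed = 33)
  ph <- unique(na.omit(co$phenotype))
  canon <- is_canonical_phenotype(marking_system("LGR"), ph)
  # with heritable per-division silencing over ~2 weeks, at least one
  # non-canonical combination (e.g. RFP-only or triple-negative) appears
  expect_gt(sum(!canon$canonical), 0)
})
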