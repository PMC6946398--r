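#' Simulator configuration
#'
#' Parameters of the stochastic germarium/ovariole simulator. Defaults
#' reproduce the study conditions of FSC lineage tracing in Drosophila:
#' two active FSCs per germarium, a 9.6 h follicle-cell cycle, ~900
#' follicle cells per Stage 6 egg chamber, ~100 h transit from the Region
#' 2a/2b border to Stage 6, an 8-9 day clearance time for transient clones
#' to exit the scored region, and a four-heat-shock induction regimen.
#'
#' @param n_fsc Number of active FSCs (founding lineages) per germarium.
#' @param cycle_h Follicle-cell division time, hours.
#' @param follicle_cells_stage6 Cell count at which a follicle stops
#'   growing (Stage 6 exit from mitosis).
#' @param transit_h Border-to-Stage-6 transit time, hours (documentation
#'   of the timescale; the scored region is controlled by
#'   `n_scored_follicles` and `budding_interval_h`).
#' @param ovariole_clearance_d Days for a transient clone to traverse the
#'   ovariole and leave the scored region (8-9 d; default 8.5).
#' @param budding_interval_h Hours between successive follicle foundings.
#'   The interval is not directly measured; the default of 12 h is a
#'   placeholder consistent with several follicles in transit at once.
#' @param induction_prob Per-cell probability that the heat-shock protocol
#'   as a whole produces a visibly recombinant label in an FSC or transit
#'   cell (internally spread across the shocks as a per-shock hazard).
#'   The default 0.187 makes ~33.9\% of two-FSC ovarioles carry an FSC
#'   clone (`1 - (1 - p)^2`), matching the sparse labelling of the
#'   standard four-heat-shock regimen.
#' @param background_rate Per-cell-division probability of spontaneous
#'   (heat-shock-independent) recombination. Default 2e-4 keeps
#'   background clone induction below ~2\% of ovarioles per week, as
#'   observed for the GFP-negative FRT19A system.
#' @param silencing_rate Per-cell-division probability that a labelled
#'   lineage heritably silences one expressed marker (an LGR failure
#'   mode producing anomalous marker combinations). Default 0.
#' @param replacement_rate Per-day probability that an active FSC is lost
#'   and replaced by a daughter of another FSC lineage.
#' @param quiescence_rate Probability that a labelled transit cell becomes
#'   quiescent instead of differentiating, producing a small-germarium
#'   patch that may later detach into a discontinuous pattern.
#' @param quiescence_dwell_d Mean dwell time (days) of a quiescent cell
#'   before it resumes differentiation.
#' @param heat_shock_times_h Times (hours) of the heat shocks; the
#'   default is four shocks over three days. `dphs` is measured from the
#'   last heat shock.
#' @param sample_dphs Days post (last) heat shock at which each ovariole
#'   is scored.
#' @param marking_system A [marking_system()].
#' @param growth_model `"polya"` (exchangeable reinforcement; founder
#'   shares are Dirichlet-distributed) or `"deterministic"` (equal split).
#' @param n_scored_follicles Number of budded follicles, counted from the
#'   germarium, included in the scored region.
#' @param germarium_cells Somatic (prefollicle) cells scored within the
#'   germarium.
#' @param cells_at_budding Follicle-cell count when a follicle buds.
#' @param n_transit_pool Transit (prefollicle, non-stem) cells exposed to
#'   each heat shock.
#' @param p_anterior_adjacent,p_anterior_detached Probabilities that the
#'   anterior-most labelled cell of an ovariole with a persistent clone is
#'   annotated FasIII-negative-but-contiguous, or FasIII-negative and
#'   detached from the clone (independently labelled escort/IGS cell).
#' @param forced_labeled_fsc `NULL`, or an integer: label exactly this
#'   many FSCs at time 0 and disable heat-shock induction, isolating the
#'   stem-cell lineage contribution (used for clone-size calibration).
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_fsc = 2,
                       cycle_h = 9.6,
                       follicle_cells_stage6 = 900,
                       transit_h = 100,
                       ovariole_clearance_d = 8.5,
                       budding_interval_h = 12,
                       induction_prob = 0.187,
                       background_rate = 2e-4,
                       silencing_rate = 0,
                       replacement_rate = 0.005,
                       quiescence_rate = 0.05,
                       quiescence_dwell_d = 6,
                       heat_shock_times_h = c(0, 24, 48, 72),
                       sample_dphs = c(5, 7, 9, 12, 14, 20, 25),
                       marking_system = fscclone::marking_system("GFPNEG_FRT19A"),
                       growth_model = c("polya", "deterministic"),
                       n_scored_follicles = 3,
                       germarium_cells = 40,
                       cells_at_budding = 30,
                       n_transit_pool = 4,
                       p_anterior_adjacent = 0.079,
                       p_anterior_detached = 0.063,
                       forced_labeled_fsc = NULL) {
  growth_model <- match.arg(growth_model)
  cfg <- list(n_fsc = n_fsc, cycle_h = cycle_h,
              follicle_cells_stage6 = follicle_cells_stage6,
              transit_h = transit_h,
              ovariole_clearance_d = ovariole_clearance_d,
              budding_interval_h = budding_interval_h,
              induction_prob = induction_prob,
              background_rate = background_rate,
              silencing_rate = silencing_rate,
              replacement_rate = replacement_rate,
              quiescence_rate = quiescence_rate,
              quiescence_dwell_d = quiescence_dwell_d,
              heat_shock_times_h = heat_shock_times_h,
              sample_dphs = sample_dphs,
              marking_system = marking_system,
              growth_model = growth_model,
              n_scored_follicles = n_scored_follicles,
              germarium_cells = germarium_cells,
              cells_at_budding = cells_at_budding,
              n_transit_pool = n_transit_pool,
              p_anterior_adjacent = p_anterior_adjacent,
              p_anterior_detached = p_anterior_detached,
              forced_labeled_fsc = forced_labeled_fsc)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot_msg <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
  stopifnot_msg(cfg$n_fsc >= 1, "n_fsc must be >= 1")
  for (nm in c("induction_prob", "background_rate", "silencing_rate",
               "replacement_rate", "quiescence_rate")) {
    stopifnot_msg(cfg[[nm]] >= 0 && cfg[[nm]] <= 1,
                  paste0(nm, " must be in [0, 1]"))
  }
  for (nm in c("cycle_h", "transit_h", "budding_interval_h",
               "ovariole_clearance_d", "quiescence_dwell_d")) {
    stopifnot_msg(cfg[[nm]] > 0, paste0(nm, " must be positive"))
  }
  stopifnot_msg(!is.unsorted(cfg$sample_dphs),
                "sample_dphs must be sorted ascending")
  stopifnot_msg(inherits(cfg$marking_system, "marking_system"),
                "marking_system must be a marking_system object")
  stopifnot_msg(is.null(cfg$forced_labeled_fsc) ||
                  (cfg$forced_labeled_fsc >= 0 &&
                     cfg$forced_labeled_fsc <= cfg$n_fsc),
                "forced_labeled_fsc must be between 0 and n_fsc")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_fsc, " FSC(s), ", x$marking_system$name,
      ", growth = ", x$growth_model, "\n", sep = "")
  cat("  cycle ", x$cycle_h, " h; heat shocks at ",
      paste(x$heat_shock_times_h, collapse = ", "), " h; sampled at dphs ",
      paste(x$sample_dphs, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Sample the lineage composition of one follicle
#'
#' Each follicle is founded by a small set of progenitors (typically one
#' per active FSC) and grows to its final cell count. Under the Polya-urn
#' model each new cell joins a lineage with probability proportional to
#' that lineage's current size — the simplest exchangeable reinforcement
#' model, whose founder shares converge to a symmetric Dirichlet (for two
#' founders, uniform on (0,1)). The sequential urn is sampled through its
#' exact de Finetti representation (Dirichlet weights, then a multinomial
#' for the remaining cells). The deterministic model splits cells equally
#' with largest-remainder rounding.
#'
#' @param founder_labels Character vector of founder lineage labels
#'   (repeats allowed; one founder per element).
#' @param final_cells Total cell count of the grown follicle
#'   (`>= length(founder_labels)`).
#' @param growth_model `"polya"` or `"deterministic"`.
#' @return A tibble with columns `label` (one row per founder, in input
#'   order) and `cells`; `sum(cells) == final_cells`.
#' @examples
#' set.seed(1)
#' sample_follicle_composition(c("A", "B"), 900, "polya")
#' @export
sample_follicle_composition <- function(founder_labels, final_cells,
                                        growth_model = c("polya",
                                                         "deterministic")) {
  growth_model <- match.arg(growth_model)
  k <- length(founder_labels)
  if (k < 1) stop("at least one founder is required", call. = FALSE)
  if (final_cells < k) {
    stop("final_cells must be at least the number of founders", call. = FALSE)
  }
  tibble::tibble(label = founder_labels,
                 cells = founder_cell_counts(k, final_cells, growth_model))
}

# vector core of sample_follicle_composition (hot path)
founder_cell_counts <- function(k, final_cells, growth_model) {
  if (growth_model == "deterministic") {
    base <- floor(final_cells / k)
    cells <- rep(base, k)
    rem <- final_cells - base * k
    if (rem > 0) cells[seq_len(rem)] <- cells[seq_len(rem)] + 1L
  } else if (k == 1L) {
    cells <- final_cells
  } else {
    w <- stats::rgamma(k, shape = 1)        # Dirichlet(1, ..., 1)
    cells <- 1L + as.integer(stats::rmultinom(1, final_cells - k,
                                              prob = w / sum(w)))
  }
  as.integer(cells)
}

# ---- internal event machinery ----------------------------------------------

draw_recombinant_phenotype <- function(system, n = 1) {
  rp <- recombinant_phenotypes(system)
  sample(rp$phenotype, n, replace = TRUE, prob = rp$probability)
}

# geometric number of divisions until a silencing event, as a time (hours)
draw_silencing_time <- function(start, rate, cycle_h) {
  if (rate <= 0) return(Inf)
  start + cycle_h * (stats::rgeom(1, rate) + 1)
}

silenced_label <- function(system, phenotype) {
  if (length(system$markers) == 1L) {
    # silencing the single marker turns GFP+ into GFP- and vice versa is
    # not meaningful; only expression loss is modelled
    return(if (phenotype == "GFP+") "GFP-" else phenotype)
  }
  letters3 <- c(B = "LacZ", G = "GFP", R = "RFP")
  present <- names(letters3)[vapply(names(letters3), grepl, TRUE, x = phenotype)]
  if (length(present) == 0L) return(phenotype)
  drop <- sample(present, 1)
  expressed <- letters3[setdiff(present, drop)]
  phenotype_label(system, unname(expressed))
}

# Joint simulation of FSC slot label histories plus transient/quiescent
# events over [0, t_end]. Returns list(segments, transients), each a plain
# list of parallel vectors (hot path; tibbles are built only in the
# record assembly). Segment: slot, phenotype, start, end (Inf while
# active), silenced_at, silenced_to. Transient: phenotype, start, end,
# quiescent, wake (NA unless quiescent), fraction, origin.
simulate_label_history <- function(cfg, t_end) {
  sys <- cfg$marking_system
  rp <- recombinant_phenotypes(sys)
  draw_phen <- function() {
    sample(rp$phenotype, 1L, prob = rp$probability)
  }
  slot_label <- rep(NA_character_, cfg$n_fsc)
  segs <- list()
  open_seg <- rep(NA_integer_, cfg$n_fsc)   # index into segs

  open_segment <- function(slot, phen, start) {
    segs[[length(segs) + 1]] <<- list(slot = slot, phenotype = phen,
                                      start = start, end = Inf)
    open_seg[slot] <<- length(segs)
    slot_label[slot] <<- phen
  }
  close_segment <- function(slot, t) {
    if (!is.na(open_seg[slot])) {
      segs[[open_seg[slot]]]$end <<- t
      open_seg[slot] <<- NA_integer_
    }
    slot_label[slot] <<- NA_character_
  }

  # event times
  ev <- list()
  add_ev <- function(time, type, slot = NA_integer_) {
    ev[[length(ev) + 1]] <<- list(time = time, type = type, slot = slot)
  }
  # induction_prob is the per-cell labelling probability over the whole
  # heat-shock protocol; convert to a per-shock hazard so that the
  # cumulative probability across the regimen equals induction_prob
  n_shocks <- length(cfg$heat_shock_times_h)
  p_shock <- 1 - (1 - cfg$induction_prob)^(1 / max(1, n_shocks))
  if (is.null(cfg$forced_labeled_fsc)) {
    for (hs in cfg$heat_shock_times_h) add_ev(hs, "heat_shock")
  } else if (cfg$forced_labeled_fsc > 0) {
    for (s in seq_len(cfg$forced_labeled_fsc)) {
      open_segment(s, draw_phen(), 0)
    }
  }
  per_h_bg <- cfg$background_rate / cfg$cycle_h
  if (per_h_bg > 0) {
    for (s in seq_len(cfg$n_fsc)) {
      tt <- 0
      repeat {
        tt <- tt + stats::rexp(1, per_h_bg)
        if (tt > t_end) break
        add_ev(tt, "bg_label", s)
      }
    }
    # background recombination in the transit pool
    rate <- per_h_bg * cfg$n_transit_pool
    tt <- 0
    repeat {
      tt <- tt + stats::rexp(1, rate)
      if (tt > t_end) break
      add_ev(tt, "bg_transient")
    }
  }
  if (cfg$replacement_rate > 0) {
    per_h_rep <- cfg$replacement_rate / 24
    for (s in seq_len(cfg$n_fsc)) {
      tt <- 0
      repeat {
        tt <- tt + stats::rexp(1, per_h_rep)
        if (tt > t_end) break
        add_ev(tt, "replace", s)
      }
    }
  }

  transients <- list()
  add_transient <- function(phen, start, origin) {
    quiescent <- stats::runif(1) < cfg$quiescence_rate
    wake <- if (quiescent) {
      start + 24 * stats::rexp(1, 1 / cfg$quiescence_dwell_d)
    } else NA_real_
    transients[[length(transients) + 1]] <<- list(
      phenotype = phen, start = start,
      end = if (quiescent) NA_real_ else start + 24 * cfg$ovariole_clearance_d,
      quiescent = quiescent, wake = wake,
      fraction = stats::runif(1, 0.03, 0.5),
      origin = origin)
  }

  if (length(ev)) {
    ord <- order(vapply(ev, `[[`, 0, "time"))
    for (e in ev[ord]) {
      switch(e$type,
        heat_shock = {
          for (s in seq_len(cfg$n_fsc)) {
            if (is.na(slot_label[s]) &&
                stats::runif(1) < p_shock) {
              open_segment(s, draw_phen(), e$time)
            }
          }
          n_lab <- stats::rbinom(1, cfg$n_transit_pool, p_shock)
          for (i in seq_len(n_lab)) {
            add_transient(draw_phen(), e$time, "transient")
          }
        },
        bg_label = {
          if (is.na(slot_label[e$slot])) {
            open_segment(e$slot, draw_phen(), e$time)
          }
        },
        bg_transient = {
          add_transient(draw_phen(), e$time, "background")
        },
        replace = {
          if (cfg$n_fsc > 1) {
            donor <- sample(setdiff(seq_len(cfg$n_fsc), e$slot), 1)
            close_segment(e$slot, e$time)
            if (!is.na(slot_label[donor])) {
              open_segment(e$slot, slot_label[donor], e$time)
            }
          }
        })
    }
  }

  seg_tbl <- if (length(segs)) {
    tibble::tibble(
      slot = vapply(segs, `[[`, 0L, "slot"),
      phenotype = vapply(segs, `[[`, "", "phenotype"),
      start = vapply(segs, `[[`, 0, "start"),
      end = vapply(segs, `[[`, 0, "end")
    )
  } else {
    tibble::tibble(slot = integer(), phenotype = character(),
                   start = numeric(), end = numeric())
  }
  if (nrow(seg_tbl)) {
    seg_tbl$silenced_at <- vapply(seg_tbl$start, draw_silencing_time, 0,
                                  rate = cfg$silencing_rate,
                                  cycle_h = cfg$cycle_h)
    seg_tbl$silenced_to <- ifelse(
      is.finite(seg_tbl$silenced_at),
      vapply(seg_tbl$phenotype, function(p) silenced_label(sys, p), ""),
      NA_character_)
  } else {
    seg_tbl$silenced_at <- numeric()
    seg_tbl$silenced_to <- character()
  }

  tr_tbl <- if (length(transients)) {
    tibble::tibble(
      phenotype = vapply(transients, `[[`, "", "phenotype"),
      start = vapply(transients, `[[`, 0, "start"),
      end = vapply(transients, `[[`, 0, "end"),
      quiescent = vapply(transients, `[[`, TRUE, "quiescent"),
      wake = vapply(transients, `[[`, 0, "wake"),
      fraction = vapply(transients, `[[`, 0, "fraction"),
      origin = vapply(transients, `[[`, "", "origin")
    )
  } else {
    tibble::tibble(phenotype = character(), start = numeric(),
                   end = numeric(), quiescent = logical(), wake = numeric(),
                   fraction = numeric(), origin = character())
  }
  list(segments = seg_tbl, transients = tr_tbl)
}

patch_phenotype_at <- function(seg_row, t) {
  if (is.finite(seg_row$silenced_at) && t >= seg_row$silenced_at) {
    seg_row$silenced_to
  } else {
    seg_row$phenotype
  }
}

#' Simulate one ovariole through a dphs time course
#'
#' Event-driven simulation of a single ovariole: at each heat shock, each
#' unlabelled FSC (and each transit cell in the germarium) independently
#' acquires a visibly recombinant label with probability `induction_prob`;
#' spontaneous recombination and marker silencing occur at per-division
#' rates thereafter; follicles are founded at fixed intervals with one
#' founder per active FSC and grow (Polya-urn or deterministically) toward
#' the Stage 6 cell count; labelled FSC lineages form border-touching
#' contiguous patches; labelled transit cells form transient patches that
#' leave the scored region after `ovariole_clearance_d` days; FSC
#' replacement truncates a lineage's border contact; quiescent labelled
#' cells form small-germarium patches that may later detach into
#' discontinuous patterns. The ovariole is scored (germarium plus the
#' `n_scored_follicles` youngest budded follicles) at each `sample_dphs`.
#'
#' @param config A [sim_config()].
#' @param ovariole Integer id stored in the output.
#' @return A tibble (one row per patch per sampling day; ovarioles with no
#'   patch at a sampling day yield a single row with `phenotype = NA`) with
#'   columns: `ovariole`, `dphs`, `patch_id`, `phenotype`, `origin`
#'   (`"fsc"`, `"transient"`, `"quiescent"`, `"background"`),
#'   `touches_border`, `in_germarium_only`, `n_follicles_spanned`,
#'   `germarium_fraction`, `frac_follicles` (list-column of per-follicle
#'   labelled fractions), `mean_fraction`, `cell_count`, `contiguous_with`,
#'   `total_cells_scored`, `anterior_fasiii`, `anterior_contiguous`.
#' @seealso [simulate_cohort()] for replicated ovarioles with seed control.
#' @export
simulate_ovariole <- function(config, ovariole = 1L) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  last_hs <- if (is.null(cfg$forced_labeled_fsc)) {
    max(cfg$heat_shock_times_h)
  } else 0
  sample_t <- last_hs + cfg$sample_dphs * 24
  t_end <- max(sample_t)

  hist <- simulate_label_history(cfg, t_end)
  segs <- hist$segments
  trans <- hist$transients

  records <- vector("list", length(sample_t))
  for (si in seq_along(sample_t)) {
    t <- sample_t[si]
    records[[si]] <- score_ovariole_at(cfg, segs, trans, t,
                                       dphs = cfg$sample_dphs[si],
                                       ovariole = ovariole)
  }
  dplyr::bind_rows(records)
}

# Score the ovariole at absolute time t (hours).
score_ovariole_at <- function(cfg, segs, trans, t, dphs, ovariole) {
  b <- cfg$budding_interval_h
  newest <- floor(t / b) * b
  tb <- newest - b * (seq_len(cfg$n_scored_follicles) - 1) # youngest first
  n_cells_f <- as.integer(round(pmin(
    cfg$follicle_cells_stage6,
    cfg$cells_at_budding * 2^((t - tb) / cfg$cycle_h))))
  total <- cfg$germarium_cells + sum(n_cells_f)

  phen_at <- function(i, tau) {
    if (is.finite(segs$silenced_at[i]) && tau >= segs$silenced_at[i]) {
      segs$silenced_to[i]
    } else {
      segs$phenotype[i]
    }
  }

  # per-follicle founder cell counts: one founder per slot
  comp <- lapply(seq_along(tb), function(j) {
    founder_cell_counts(cfg$n_fsc, n_cells_f[j], cfg$growth_model)
  })
  germ <- founder_cell_counts(cfg$n_fsc, cfg$germarium_cells,
                              cfg$growth_model)

  patches <- list()
  add_patch <- function(...) patches[[length(patches) + 1]] <<- list(...)

  # FSC lineage segments -> patches
  if (nrow(segs)) {
    for (i in seq_len(nrow(segs))) {
      if (segs$start[i] >= t) next
      # a lineage founds every follicle budded while it is active (tb <= t
      # always holds for scored follicles)
      covered <- which(tb >= segs$start[i] & tb < segs$end[i])
      active <- segs$end[i] > t
      if (!active && length(covered) == 0) next   # fully exited the region
      fr <- numeric(0); cells <- 0L
      if (length(covered)) {
        fr <- vapply(covered, function(j) {
          comp[[j]][segs$slot[i]] / sum(comp[[j]])
        }, 0)
        cells <- sum(vapply(covered, function(j) {
          comp[[j]][segs$slot[i]]
        }, 0L))
      }
      gf <- 0
      if (active) {
        gf <- germ[segs$slot[i]] / sum(germ)
        cells <- cells + germ[segs$slot[i]]
      }
      if (cells == 0L) next
      add_patch(phenotype = phen_at(i, t),
                origin = "fsc",
                touches_border = active,
                in_germarium_only = active && length(covered) == 0,
                n_follicles_spanned = length(covered),
                germarium_fraction = gf,
                frac_follicles = fr,
                cell_count = as.integer(cells),
                follicle_slots = covered)
    }
  }

  # transient / quiescent / background patches
  if (nrow(trans)) {
    for (i in seq_len(nrow(trans))) {
      tr <- list(phenotype = trans$phenotype[i], start = trans$start[i],
                 end = trans$end[i], quiescent = trans$quiescent[i],
                 wake = trans$wake[i], fraction = trans$fraction[i],
                 origin = trans$origin[i])
      if (tr$quiescent) {
        if (tr$start <= t && t < tr$wake) {
          # dormant: small patch inside the germarium
          cells <- max(1L, as.integer(round(tr$fraction * 0.2 *
                                              cfg$germarium_cells)))
          add_patch(phenotype = tr$phenotype, origin = "quiescent",
                    touches_border = FALSE, in_germarium_only = TRUE,
                    n_follicles_spanned = 0L, germarium_fraction =
                      cells / cfg$germarium_cells,
                    frac_follicles = numeric(0),
                    cell_count = cells, follicle_slots = integer(0))
        } else if (t >= tr$wake &&
                   t < tr$wake + 24 * cfg$ovariole_clearance_d) {
          # woke up and detached downstream
          j <- min(2L, cfg$n_scored_follicles)
          cells <- max(1L, as.integer(round(tr$fraction * n_cells_f[j])))
          add_patch(phenotype = tr$phenotype, origin = "quiescent",
                    touches_border = FALSE, in_germarium_only = FALSE,
                    n_follicles_spanned = 1L, germarium_fraction = 0,
                    frac_follicles = tr$fraction,
                    cell_count = cells, follicle_slots = j)
        }
      } else if (tr$start <= t && t < tr$end) {
        j <- min(2L, cfg$n_scored_follicles)
        cells <- max(1L, as.integer(round(tr$fraction * n_cells_f[j])))
        add_patch(phenotype = tr$phenotype, origin = tr$origin,
                  touches_border = FALSE, in_germarium_only = FALSE,
                  n_follicles_spanned = 1L, germarium_fraction = 0,
                  frac_follicles = tr$fraction,
                  cell_count = cells, follicle_slots = j)
      }
    }
  }

  # contiguity between same-phenotype patches: a patch is contiguous with
  # an earlier one if their follicle spans overlap or abut (or both touch
  # the germarium/border interface)
  contiguous_with <- rep(NA_integer_, length(patches))
  if (length(patches) > 1) {
    for (i in 2:length(patches)) {
      for (j in 1:(i - 1)) {
        if (patches[[i]]$phenotype != patches[[j]]$phenotype) next
        si <- patches[[i]]$follicle_slots; sj <- patches[[j]]$follicle_slots
        both_germ <- (patches[[i]]$touches_border ||
                        patches[[i]]$in_germarium_only) &&
          (patches[[j]]$touches_border || patches[[j]]$in_germarium_only)
        overlap <- length(si) && length(sj) &&
          min(abs(outer(si, sj, "-"))) <= 1
        if (both_germ || overlap) {
          contiguous_with[i] <- j
          break
        }
      }
    }
  }

  # cap labelled cells at the scored total (overlapping transient patches
  # can oversubscribe a follicle); strict after integer rounding
  cells_vec <- vapply(patches, `[[`, 0L, "cell_count")
  tot_lab <- sum(cells_vec)
  if (tot_lab > total) {
    cells_vec <- pmax(1L, as.integer(floor(cells_vec * total / tot_lab)))
    while (sum(cells_vec) > total) {
      j <- which.max(cells_vec)
      cells_vec[j] <- cells_vec[j] - 1L
    }
  }

  # anterior-most labelled cell annotation
  has_border <- any(vapply(patches, `[[`, TRUE, "touches_border"))
  if (has_border) {
    u <- stats::runif(1)
    if (u < cfg$p_anterior_detached) {
      af <- FALSE; ac <- FALSE
    } else if (u < cfg$p_anterior_detached + cfg$p_anterior_adjacent) {
      af <- FALSE; ac <- TRUE
    } else {
      af <- TRUE; ac <- TRUE
    }
  } else {
    af <- NA; ac <- NA
  }

  if (length(patches) == 0) {
    return(tibble::new_tibble(list(
      ovariole = ovariole, dphs = dphs, patch_id = NA_integer_,
      phenotype = NA_character_, origin = NA_character_,
      touches_border = NA, in_germarium_only = NA,
      n_follicles_spanned = NA_integer_, germarium_fraction = NA_real_,
      frac_follicles = list(numeric(0)), mean_fraction = NA_real_,
      cell_count = NA_integer_, contiguous_with = NA_integer_,
      total_cells_scored = total, anterior_fasiii = af,
      anterior_contiguous = ac), nrow = 1L))
  }

  np <- length(patches)
  tibble::new_tibble(list(
    ovariole = rep(ovariole, np),
    dphs = rep(dphs, np),
    patch_id = seq_len(np),
    phenotype = vapply(patches, `[[`, "", "phenotype"),
    origin = vapply(patches, `[[`, "", "origin"),
    touches_border = vapply(patches, `[[`, TRUE, "touches_border"),
    in_germarium_only = vapply(patches, `[[`, TRUE, "in_germarium_only"),
    n_follicles_spanned = vapply(patches, `[[`, 0L, "n_follicles_spanned"),
    germarium_fraction = vapply(patches, `[[`, 0, "germarium_fraction"),
    frac_follicles = lapply(patches, `[[`, "frac_follicles"),
    mean_fraction = vapply(patches, function(p) {
      fr <- c(if (p$touches_border || p$in_germarium_only)
        p$germarium_fraction, p$frac_follicles)
      if (length(fr)) mean(fr) else 0
    }, 0),
    cell_count = cells_vec,
    contiguous_with = contiguous_with,
    total_cells_scored = rep(total, np),
    anterior_fasiii = rep(af, np),
    anterior_contiguous = rep(ac, np)), nrow = np)
}

#' Simulate a cohort of independent ovarioles
#'
#' Replicates [simulate_ovariole()] with a documented seed-derivation
#' scheme: the master seed initialises R's RNG, one sub-seed per ovariole
#' is drawn up front, and each ovariole is simulated under its own
#' sub-seed. Identical `(config, n_ovarioles, seed)` therefore give
#' identical cohorts, and ovariole `i` is unchanged by adding more
#' ovarioles after it.
#'
#' @param config A [sim_config()].
#' @param n_ovarioles Number of independent ovarioles (`>= 1`).
#' @param seed Master integer seed.
#' @return A tibble of class `fsc_cohort`: the row-bound
#'   [simulate_ovariole()] records with the configuration attached as
#'   attribute `config` and the seed as attribute `seed`.
#' @examples
#' cohort <- simulate_cohort(sim_config(sample_dphs = 7), 20, seed = 1)
#' dplyr::count(cohort, phenotype)
#' @export
simulate_cohort <- function(config, n_ovarioles, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.numeric(n_ovarioles) || n_ovarioles < 1) {
    stop("n_ovarioles must be >= 1", call. = FALSE)
  }
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, n_ovarioles)
  out <- purrr::map(seq_len(n_ovarioles), function(i) {
    set.seed(sub_seeds[i])
    simulate_ovariole(config, ovariole = i)
  }) |>
    dplyr::bind_rows()
  attr(out, "config") <- config
  attr(out, "seed") <- seed
  class(out) <- c("fsc_cohort", class(out))
  out
}
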