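#' Clonal marking systems
#'
#' Construct one of the three Flp/FRT clonal marking systems used for
#' follicle stem cell (FSC) lineage tracing:
#'
#' * `"GFPNEG_FRT19A"` — single FRT pair on the X chromosome; all cells
#'   initially express GFP and mitotic recombination produces GFP-negative
#'   clones (negative marking).
#' * `"MARCM_FRT19A"` — single FRT pair; cells carry a GAL80 repressor in
#'   trans so they are initially unlabelled, and homozygous loss of the
#'   repressor produces GFP-positive clones (positive marking).
#' * `"LGR"` — dual-FRT three-colour scheme on chromosome II: LacZ and GFP
#'   sit in trans distal to FRT40A on 2L, and RFP sits distal to the single
#'   2R site (named FRT42B or FRT42D in different sources; the model treats
#'   them as one site, since only the arm topology matters). Recombination
#'   at both sites can produce six marker combinations.
#'
#' A marking system is a list with one `arm` entry per FRT-bearing
#' chromosome arm; each arm carries the two homolog-distal alleles (the
#' null allele is `"none"`).
#'
#' @param name One of `"GFPNEG_FRT19A"`, `"MARCM_FRT19A"`, `"LGR"`.
#' @return An object of class `marking_system`.
#' @examples
#' marking_system("LGR")
#' phenotype_distribution(marking_system("GFPNEG_FRT19A"))
#' @export
marking_system <- function(name = c("GFPNEG_FRT19A", "MARCM_FRT19A", "LGR")) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% c("GFPNEG_FRT19A", "MARCM_FRT19A", "LGR")) {
    stop("unknown marking system: ", paste(name, collapse = ", "),
         " (expected one of GFPNEG_FRT19A, MARCM_FRT19A, LGR)", call. = FALSE)
  }
  sys <- switch(name,
    GFPNEG_FRT19A = list(
      name = "GFPNEG_FRT19A",
      mode = "dominant",          # marker expressed iff >= 1 copy present
      arms = list(arm_spec("X", "FRT19A", "GFP", "none")),
      markers = "GFP",
      labelled_is_negative = TRUE
    ),
    MARCM_FRT19A = list(
      name = "MARCM_FRT19A",
      mode = "marcm",             # labelled iff repressor copy number is 0
      arms = list(arm_spec("X", "FRT19A", "GAL80", "none")),
      markers = "GFP",
      labelled_is_negative = FALSE
    ),
    LGR = list(
      name = "LGR",
      mode = "dominant",
      arms = list(
        arm_spec("2L", "FRT40A", "GFP", "LacZ"),
        arm_spec("2R", "FRT42B", "RFP", "none")
      ),
      markers = c("LacZ", "GFP", "RFP"),
      labelled_is_negative = FALSE
    )
  )
  structure(sys, class = "marking_system")
}

arm_spec <- function(arm_id, frt_site, allele_hom1, allele_hom2) {
  if (identical(allele_hom1, allele_hom2) && allele_hom1 != "none") {
    stop("arm ", arm_id, ": the two homolog-distal alleles must differ",
         call. = FALSE)
  }
  list(arm_id = arm_id, frt_site = frt_site,
       allele_hom1 = allele_hom1, allele_hom2 = allele_hom2)
}

#' @export
print.marking_system <- function(x, ...) {
  cat("<marking_system> ", x$name, " (", x$mode, " labelling)\n", sep = "")
  for (a in x$arms) {
    cat("  arm ", a$arm_id, " [", a$frt_site, "]: ",
        a$allele_hom1, " / ", a$allele_hom2, "\n", sep = "")
  }
  invisible(x)
}

#' Enumerate post-recombination genotypes
#'
#' Under the equal-genotype model, recombination at every FRT site followed
#' by sister-chromatid segregation is assumed to make the three possible
#' unordered allele pairs on each arm (hom1/hom1, hom1/hom2, hom2/hom2)
#' equally likely, independently across arms. For the dual-FRT LGR system
#' this yields nine genotypes at probability 1/9 each; for a single-FRT
#' system, three genotypes at 1/3. The chromatid-level mechanics behind
#' this assumption can be audited with [chromatid_oracle()].
#'
#' @param system A [marking_system()].
#' @return A tibble with one row per genotype: one column per arm
#'   (named by `arm_id`, holding the unordered allele pair as `"a/b"`),
#'   a `genotype` list-column of per-arm allele pairs, and `probability`.
#' @examples
#' enumerate_genotypes(marking_system("LGR"))
#' @export
enumerate_genotypes <- function(system) {
  stopifnot(inherits(system, "marking_system"))
  per_arm <- lapply(system$arms, function(a) {
    list(c(a$allele_hom1, a$allele_hom1),
         c(a$allele_hom1, a$allele_hom2),
         c(a$allele_hom2, a$allele_hom2))
  })
  idx <- expand.grid(rep(list(1:3), length(per_arm)))
  genotypes <- lapply(seq_len(nrow(idx)), function(i) {
    g <- lapply(seq_along(per_arm), function(j) sort(per_arm[[j]][[idx[i, j]]]))
    names(g) <- vapply(system$arms, `[[`, "", "arm_id")
    g
  })
  out <- tibble::tibble(genotype = genotypes,
                        probability = rep(1 / nrow(idx), nrow(idx)))
  for (j in seq_along(system$arms)) {
    out[[system$arms[[j]]$arm_id]] <-
      vapply(genotypes, function(g) paste(g[[j]], collapse = "/"), "")
  }
  dplyr::relocate(out, dplyr::all_of(vapply(system$arms, `[[`, "", "arm_id")))
}

#' Map a genotype to its expressed phenotype
#'
#' For dominantly marked systems (GFP-negative and LGR) a marker is
#' expressed iff at least one copy is present anywhere in the genotype.
#' For MARCM the logic is inverted at the repressor: the cell is
#' GFP-labelled iff it carries zero copies of the GAL80 repressor
#' (homozygous repressor loss).
#'
#' @param system A [marking_system()].
#' @param genotype A named list of per-arm allele pairs, as produced by
#'   [enumerate_genotypes()] (its `genotype` list-column), or a character
#'   vector of `"a/b"` pairs named by arm.
#' @return A phenotype label (see [phenotype_label()]): for LGR, the
#'   expressed subset of \{LacZ, GFP, RFP\} written as letters `B`, `G`,
#'   `R` (e.g. `"BGR"`, `"BR"`, `"none"`); for the single-FRT systems,
#'   `"GFP+"` or `"GFP-"`.
#' @export
genotype_to_phenotype <- function(system, genotype) {
  stopifnot(inherits(system, "marking_system"))
  genotype <- as_genotype(system, genotype)
  alleles <- unlist(genotype, use.names = FALSE)
  arm_ids <- vapply(system$arms, `[[`, "", "arm_id")
  if (!setequal(names(genotype), arm_ids)) {
    stop("genotype arms (", paste(names(genotype), collapse = ", "),
         ") do not match system arms (", paste(arm_ids, collapse = ", "), ")",
         call. = FALSE)
  }
  for (a in system$arms) {
    ok <- genotype[[a$arm_id]] %in% c(a$allele_hom1, a$allele_hom2)
    if (!all(ok)) {
      stop("allele ", paste(genotype[[a$arm_id]][!ok], collapse = ", "),
           " is not valid for arm ", a$arm_id, call. = FALSE)
    }
  }
  if (system$mode == "marcm") {
    labelled <- sum(alleles == "GAL80") == 0L
    return(if (labelled) "GFP+" else "GFP-")
  }
  expressed <- intersect(system$markers, alleles)
  phenotype_label(system, expressed)
}

as_genotype <- function(system, genotype) {
  if (is.character(genotype)) {
    genotype <- lapply(strsplit(genotype, "/", fixed = TRUE), sort)
    names(genotype) <- vapply(system$arms, `[[`, "", "arm_id")[seq_along(genotype)]
  }
  genotype
}

#' Canonical phenotype label
#'
#' @param system A [marking_system()].
#' @param expressed Character vector of expressed markers (subset of the
#'   system's markers).
#' @return For LGR, letters `B` (LacZ), `G` (GFP), `R` (RFP) concatenated in
#'   that order (the unrecombined state is `"BGR"`, the empty set `"none"`);
#'   for single-marker systems `"GFP+"`/`"GFP-"`.
#' @export
phenotype_label <- function(system, expressed) {
  if (length(system$markers) == 1L) {
    return(if (system$markers %in% expressed) "GFP+" else "GFP-")
  }
  letters3 <- c(LacZ = "B", GFP = "G", RFP = "R")
  lab <- paste(letters3[system$markers[system$markers %in% expressed]],
               collapse = "")
  if (lab == "") "none" else lab
}

#' Phenotype distribution of a marking system
#'
#' Pushes [enumerate_genotypes()] through [genotype_to_phenotype()] and sums
#' probabilities of genotypes sharing a phenotype. For LGR this reproduces
#' the six detectable marker combinations at frequencies
#' B:G:BG:BR:GR:BGR = 1:1:1:2:2:2.
#'
#' @param system A [marking_system()].
#' @return A tibble with columns `phenotype` and `probability`
#'   (probabilities sum to 1), sorted by decreasing probability then label.
#' @export
phenotype_distribution <- function(system) {
  key <- paste0("pd_", system$name)
  cached <- get0(key, envir = .fsc_cache)
  if (!is.null(cached)) return(cached)
  out <- phenotype_distribution_impl(system)
  assign(key, out, envir = .fsc_cache)
  out
}

# the three named systems are immutable, so distributions are memoised
.fsc_cache <- new.env(parent = emptyenv())

phenotype_distribution_impl <- function(system) {
  enumerate_genotypes(system) |>
    dplyr::mutate(
      phenotype = vapply(.data$genotype,
                         function(g) genotype_to_phenotype(system, g), "")
    ) |>
    dplyr::count(.data$phenotype, wt = .data$probability,
                 name = "probability") |>
    dplyr::arrange(dplyr::desc(.data$probability), .data$phenotype)
}

#' Unrecombined phenotype of a system
#'
#' The marker combination displayed by cells that never underwent
#' recombination (the background tissue), and the set of visibly
#' recombinant clone phenotypes.
#' @param system A [marking_system()].
#' @return For `unrecombined_phenotype`, a single label; for
#'   `recombinant_phenotypes`, a tibble of `phenotype`, `probability`
#'   renormalised over the visibly recombinant classes.
#' @export
unrecombined_phenotype <- function(system) {
  switch(system$name,
         GFPNEG_FRT19A = "GFP+",
         MARCM_FRT19A  = "GFP-",
         LGR           = "BGR")
}

#' @rdname unrecombined_phenotype
#' @export
recombinant_phenotypes <- function(system) {
  key <- paste0("rp_", system$name)
  cached <- get0(key, envir = .fsc_cache)
  if (!is.null(cached)) return(cached)
  bg <- unrecombined_phenotype(system)
  out <- phenotype_distribution(system) |>
    dplyr::filter(.data$phenotype != bg) |>
    dplyr::mutate(probability = .data$probability / sum(.data$probability))
  assign(key, out, envir = .fsc_cache)
  out
}

#' Flag phenotypes that the marking system cannot produce
#'
#' A phenotype is canonical iff it is reachable by [enumerate_genotypes()].
#' For LGR, LacZ and GFP sit in trans on the same arm (2L), so every cell
#' must express at least one of the two; any phenotype lacking both (the
#' RFP-only and triple-negative classes) is anomalous and indicates marker
#' silencing or another failure of the system.
#'
#' @param system A [marking_system()].
#' @param phenotype Character vector of phenotype labels.
#' @return A tibble with columns `phenotype`, `canonical` (logical) and
#'   `reason` (`NA` for canonical phenotypes).
#' @examples
#' is_canonical_phenotype(marking_system("LGR"), c("R", "none", "BGR"))
#' @export
is_canonical_phenotype <- function(system, phenotype) {
  reachable <- phenotype_distribution(system)$phenotype
  reason <- function(p) {
    if (p %in% reachable) return(NA_character_)
    if (system$name == "LGR" && !grepl("B", p) && !grepl("G", p)) {
      return("2L markers (LacZ, GFP) both absent: unreachable because they sit in trans on the same arm")
    }
    "phenotype not reachable by recombination in this system"
  }
  tibble::tibble(
    phenotype = phenotype,
    canonical = phenotype %in% reachable,
    reason = vapply(phenotype, reason, "")
  )
}

# ---- chromatid-level oracle -------------------------------------------------

#' Segregation assumptions for the chromatid-level oracle
#'
#' The equal-genotype model asserts, without mechanism, that the three
#' allele pairs per arm are equally likely after recombination. This
#' object parameterises the G2 chromatid-level mechanics so the assertion
#' can be audited: each homolog is replicated into two sister chromatids;
#' an exchange at an FRT site swaps the site-distal segment between one
#' chromatid of each homolog (uniform random pairing); a daughter receives
#' one chromatid per homolog.
#'
#' @param exchange_prob Probability that an exchange occurs at each FRT
#'   site (the equal-genotype narrative assumes 1).
#' @param independent_sites If `TRUE`, the chromatid pairing is drawn
#'   independently at each FRT site; if `FALSE`, both sites use the same
#'   pairing (a single double-exchange event on one chromatid pair).
#' @param segregation `"random"` — each daughter draws one chromatid per
#'   homolog uniformly and independently; `"recombinants_apart"` — the two
#'   chromatids involved in the (first) exchange segregate to opposite
#'   daughters (X segregation); `"equal_genotype"` — bypass the chromatid
#'   mechanics and draw the per-arm allele pairs uniformly, reproducing
#'   [enumerate_genotypes()] by construction.
#' @return An object of class `segregation_assumptions`.
#' @export
segregation_assumptions <- function(exchange_prob = 1,
                                    independent_sites = TRUE,
                                    segregation = c("random",
                                                    "recombinants_apart",
                                                    "equal_genotype")) {
  stopifnot(exchange_prob >= 0, exchange_prob <= 1)
  structure(list(exchange_prob = exchange_prob,
                 independent_sites = independent_sites,
                 segregation = match.arg(segregation)),
            class = "segregation_assumptions")
}

#' Chromatid-level phenotype distribution
#'
#' Computes the daughter-cell phenotype distribution produced by G2 mitotic
#' recombination simulated (or enumerated) at the chromatid level, under
#' explicit [segregation_assumptions()]. This is an audit oracle for the
#' equal-genotype model: under plausible mechanics (uniform chromatid
#' pairing, random segregation) the distribution differs from the uniform
#' nine-genotype assumption.
#'
#' @param system A [marking_system()].
#' @param assumptions A [segregation_assumptions()].
#' @param mode `"exhaustive"` enumerates all pairing-and-segregation
#'   configurations exactly; `"monte_carlo"` samples `n` daughters.
#' @param n Number of Monte-Carlo draws (ignored in exhaustive mode).
#' @param seed Optional integer seed for Monte-Carlo mode.
#' @return A tibble of `phenotype`, `probability` (summing to 1).
#' @export
chromatid_oracle <- function(system,
                             assumptions = segregation_assumptions(),
                             mode = c("exhaustive", "monte_carlo"),
                             n = 1e5, seed = NULL) {
  stopifnot(inherits(system, "marking_system"),
            inherits(assumptions, "segregation_assumptions"))
  mode <- match.arg(mode)

  if (assumptions$segregation == "equal_genotype") {
    tab <- enumerate_genotypes(system)
    ph <- vapply(tab$genotype, function(g) genotype_to_phenotype(system, g), "")
    return(collapse_phenotypes(ph, tab$probability))
  }

  if (mode == "monte_carlo") {
    if (!is.numeric(n) || n <= 0) stop("n must be a positive count", call. = FALSE)
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
      set.seed(seed)
    }
  }

  n_arms <- length(system$arms)
  # chromatids: matrix [4, n_arms] of distal alleles; rows 1:2 = homolog 1
  # sisters, rows 3:4 = homolog 2 sisters.
  base <- matrix("", 4L, n_arms)
  for (j in seq_len(n_arms)) {
    base[1:2, j] <- system$arms[[j]]$allele_hom1
    base[3:4, j] <- system$arms[[j]]$allele_hom2
  }

  daughter_phenos <- function(occ, pair, segj) {
    # occ: logical per site; pair: matrix [n_arms, 2] chromatid indices
    # (row of homolog 1 in 1:2, row of homolog 2 in 3:4); segj: index 1:4
    # choosing (chromatid of hom1, chromatid of hom2) for the daughter.
    chrom <- base
    for (j in seq_len(n_arms)) {
      if (occ[j]) {
        i1 <- pair[j, 1]; i2 <- pair[j, 2]
        tmp <- chrom[i1, j]; chrom[i1, j] <- chrom[i2, j]; chrom[i2, j] <- tmp
      }
    }
    s1 <- c(1L, 1L, 2L, 2L)[segj]; s2 <- c(3L, 4L, 3L, 4L)[segj]
    g <- lapply(seq_len(n_arms), function(j) sort(c(chrom[s1, j], chrom[s2, j])))
    names(g) <- vapply(system$arms, `[[`, "", "arm_id")
    genotype_to_phenotype(system, g)
  }

  seg_choices <- function(occ, pair) {
    if (assumptions$segregation == "recombinants_apart" && any(occ)) {
      j0 <- which(occ)[1]
      c1 <- pair[j0, 1]; c2 <- pair[j0, 2]
      # the two exchanged chromatids go to opposite daughters: daughters are
      # (c1, sister of c2) and (sister of c1, c2); index = (s1-1)*2 + (s2-2)
      a <- (c1 - 1L) * 2L + (7L - c2 - 2L)
      b <- (3L - c1 - 1L) * 2L + (c2 - 2L)
      c(a, b)
    } else {
      1:4
    }
  }

  if (mode == "exhaustive") {
    occ_list <- expand.grid(rep(list(c(TRUE, FALSE)), n_arms))
    res <- list(); wts <- numeric(0)
    for (oi in seq_len(nrow(occ_list))) {
      occ <- as.logical(occ_list[oi, ])
      w_occ <- prod(ifelse(occ, assumptions$exchange_prob,
                           1 - assumptions$exchange_prob))
      if (w_occ == 0) next
      pairings <- if (assumptions$independent_sites) {
        expand.grid(rep(list(1:4), n_arms))
      } else {
        data.frame(matrix(rep(1:4, n_arms), 4L, n_arms))
      }
      for (pi in seq_len(nrow(pairings))) {
        pair <- matrix(0L, n_arms, 2L)
        for (j in seq_len(n_arms)) {
          pj <- pairings[pi, j]
          pair[j, ] <- c(c(1L, 1L, 2L, 2L)[pj], c(3L, 4L, 3L, 4L)[pj])
        }
        segs <- seg_choices(occ, pair)
        for (sj in segs) {
          res <- c(res, daughter_phenos(occ, pair, sj))
          wts <- c(wts, w_occ / nrow(pairings) / length(segs))
        }
      }
    }
    return(collapse_phenotypes(unlist(res), wts))
  }

  # Monte-Carlo
  ph <- character(n)
  for (i in seq_len(n)) {
    occ <- stats::runif(n_arms) < assumptions$exchange_prob
    if (assumptions$independent_sites) {
      pj <- sample.int(4L, n_arms, replace = TRUE)
    } else {
      pj <- rep(sample.int(4L, 1L), n_arms)
    }
    pair <- cbind(c(1L, 1L, 2L, 2L)[pj], c(3L, 4L, 3L, 4L)[pj])
    segs <- seg_choices(occ, pair)
    sj <- segs[sample.int(length(segs), 1L)]
    ph[i] <- daughter_phenos(occ, pair, sj)
  }
  collapse_phenotypes(ph, rep(1 / n, n))
}

collapse_phenotypes <- function(phenotype, weight) {
  tibble::tibble(phenotype = phenotype, probability = weight) |>
    dplyr::count(.data$phenotype, wt = .data$probability,
                 name = "probability") |>
    dplyr::arrange(dplyr::desc(.data$probability), .data$phenotype)
}
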