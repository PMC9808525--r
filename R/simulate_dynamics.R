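#' Configure clonal dynamics for a simulated transplantation experiment
#'
#' Encodes the qualitative behaviors seen in barcoded transplantation
#' studies: a heavy-tailed clone-size distribution (a few large plus many
#' small engrafted clones), lineage-restricted output, tissue-specific
#' clonal expansions, and clone sizes that wax and wane over serial
#' timepoints while staying recognizably stable.
#'
#' @param n_clones number of engrafted clones.
#' @param alpha symmetric Dirichlet concentration for baseline clone sizes
#'   (default 0.5; `alpha < 1` gives heavy-tailed clone sizes).
#' @param lineage_bias optional `data.frame(clone, population, mult)` of
#'   per-clone output multipliers (`mult > 0`) applied in the named
#'   population.
#' @param tissue_bias optional `data.frame` of planted tissue-biased
#'   expansions with columns `fold` (`>= 1`), `tissue`, optionally
#'   `population` (`NA` = all populations) and either `clone` (engrafted
#'   clone index) or `baseline_rank` (rank of the clone by baseline size,
#'   1 = largest).
#' @param temporal_sigma standard deviation of the per-timepoint log-normal
#'   random-walk step (`>= 0`; 0 = perfectly stable clones).
#' @return A `dynamics_config` list.
#' @export
dynamics_config <- function(n_clones, alpha = 0.5, lineage_bias = NULL,
                            tissue_bias = NULL, temporal_sigma = 0) {
  stopifnot(n_clones >= 1, alpha > 0, temporal_sigma >= 0)
  if (!is.null(lineage_bias)) {
    stopifnot(all(c("clone", "population", "mult") %in% names(lineage_bias)),
              all(lineage_bias$mult > 0))
  }
  if (!is.null(tissue_bias)) {
    stopifnot(all(c("fold", "tissue") %in% names(tissue_bias)),
              all(tissue_bias$fold >= 1))
    if (is.null(tissue_bias$population)) tissue_bias$population <- NA_character_
    if (is.null(tissue_bias$clone) && is.null(tissue_bias$baseline_rank)) {
      stop_ct("tissue_bias needs a 'clone' or 'baseline_rank' column")
    }
  }
  structure(list(n_clones = as.integer(n_clones), alpha = alpha,
                 lineage_bias = lineage_bias, tissue_bias = tissue_bias,
                 temporal_sigma = temporal_sigma),
            class = "dynamics_config")
}

#' Simulate per-sample true clonal fractions
#'
#' Engrafts `cfg$n_clones` clones drawn from the distinct barcodes of a
#' transduction, assigns baseline sizes from a symmetric Dirichlet, then for
#' every sample multiplies baseline by the clone's lineage multiplier, any
#' planted tissue-bias fold, and a per-location log-normal random walk over
#' that location's timepoints, renormalizing each sample to sum to 1.
#'
#' @param assignment a `clone_assignment` from [simulate_transduction()]
#'   with materialized barcode sequences, or a character vector of clone
#'   barcodes.
#' @param cfg a [dynamics_config()].
#' @param sheet a [sample_sheet()].
#' @param seed optional integer seed.
#' @return A `simulation_truth` object: `fractions` (clone x sample matrix,
#'   rownames barcodes, columns in sheet order; each column sums to 1),
#'   `biased` (planted biases with realized post-normalization fold),
#'   `clone_barcodes`, `baseline`, `seed`.
#' @export
simulate_clonal_dynamics <- function(assignment, cfg, sheet, seed = NULL) {
  stopifnot(inherits(cfg, "dynamics_config"))
  sheet <- validate_sample_sheet(as.data.frame(sheet))
  if (inherits(assignment, "clone_assignment")) {
    pool <- unique(assignment$cell_barcode)
  } else {
    pool <- unique(as.character(assignment))
  }
  if (is.numeric(pool)) {
    stop_ct("clonal dynamics needs materialized barcode sequences; ",
            "run simulate_transduction() on a barcode_library")
  }
  if (length(pool) < cfg$n_clones) {
    stop_ct("only ", length(pool), " distinct barcodes available for ",
            cfg$n_clones, " engrafted clones")
  }
  if (!is.null(cfg$tissue_bias)) {
    bad <- setdiff(cfg$tissue_bias$tissue, sheet$tissue)
    if (length(bad)) {
      stop_ct("tissue_bias names tissue(s) absent from the sample sheet: ",
              paste(bad, collapse = ", "))
    }
    badp <- setdiff(stats::na.omit(cfg$tissue_bias$population), sheet$population)
    if (length(badp)) {
      stop_ct("tissue_bias names population(s) absent from the sample sheet: ",
              paste(badp, collapse = ", "))
    }
  }
  n <- cfg$n_clones
  with_seed_(seed, {
    clones <- sample(pool, n)
    g <- stats::rgamma(n, shape = cfg$alpha)
    while (sum(g) == 0) g <- stats::rgamma(n, shape = cfg$alpha)
    baseline <- g / sum(g)

    # resolve planted biases to clone indices
    biased <- cfg$tissue_bias
    if (!is.null(biased)) {
      if (is.null(biased$clone)) {
        rk <- order(baseline, decreasing = TRUE)
        biased$clone <- rk[biased$baseline_rank]
      }
      stopifnot(all(biased$clone >= 1 & biased$clone <= n))
      biased$barcode <- clones[biased$clone]
    }

    # lineage multipliers, clone x population
    pops <- unique(sheet$population)
    lin <- matrix(1, n, length(pops), dimnames = list(NULL, pops))
    if (!is.null(cfg$lineage_bias)) {
      lb <- cfg$lineage_bias
      for (i in seq_len(nrow(lb))) {
        lin[lb$clone[i], as.character(lb$population[i])] <- lb$mult[i]
      }
    }

    # per-location log-normal random walk over ordered timepoints
    loc <- paste(sheet$tissue, sheet$population, sep = ":")
    walk <- vector("list", 0)
    for (l in unique(loc)) {
      tps <- sort(unique(sheet$timepoint_months[loc == l]))
      w <- matrix(1, n, length(tps), dimnames = list(NULL, as.character(tps)))
      # walk starts at the baseline state; one log-normal step per
      # timepoint transition
      prev <- rep(1, n)
      for (j in seq_along(tps)) {
        if (j > 1L) prev <- prev * exp(stats::rnorm(n, 0, cfg$temporal_sigma))
        w[, j] <- prev
      }
      walk[[l]] <- w
    }

    frac <- matrix(0, n, nrow(sheet),
                   dimnames = list(clones, sheet$sample_id))
    for (s in seq_len(nrow(sheet))) {
      wts <- baseline * lin[, sheet$population[s]]
      if (!is.null(biased)) {
        hit <- biased$tissue == sheet$tissue[s] &
          (is.na(biased$population) | biased$population == sheet$population[s])
        for (i in which(hit)) {
          wts[biased$clone[i]] <- wts[biased$clone[i]] * biased$fold[i]
        }
      }
      wts <- wts * walk[[loc[s]]][, as.character(sheet$timepoint_months[s])]
      frac[, s] <- wts / sum(wts)
    }

    if (!is.null(biased)) {
      biased$realized_fold <- vapply(seq_len(nrow(biased)), function(i) {
        pop_ok <- is.na(biased$population[i]) |
          sheet$population == biased$population[i]
        focal <- sheet$tissue == biased$tissue[i] & pop_ok
        other <- sheet$tissue != biased$tissue[i] & pop_ok
        if (!any(focal) || !any(other)) return(NA_real_)
        mean(frac[biased$clone[i], focal]) /
          max(tapply(frac[biased$clone[i], other],
                     loc[other], mean))
      }, numeric(1))
    }

    structure(list(fractions = frac,
                   biased = biased,
                   clone_barcodes = clones,
                   baseline = baseline,
                   seed = seed),
              class = "simulation_truth")
  })
}
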