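#' Simulation configuration for synthetic spectral libraries
#'
#' The defaults describe the clean validation regime: 4 skeleton groups of 8
#' members (above the minimum group size of 5 that triggers query
#' generation), 2 planted diagnostic fragments and 1 planted neutral loss
#' per group, 30 non-diagnostic noise peaks per spectrum, no signal dropout
#' and no cross-group decoy overlap. Planted signal m/z values are kept
#' pairwise separated by more than 3 effective tolerance windows so bins
#' never merge accidentally; jitter is bounded well inside the tolerance so
#' harmonization is exercised but never ambiguous.
#'
#' @param n_groups number of skeleton groups.
#' @param members_per_group spectra per group.
#' @param planted_fragments_per_group diagnostic fragments planted per group.
#' @param planted_losses_per_group diagnostic neutral losses planted per
#'   group (realized as a fragment at `precursor - loss`).
#' @param noise_peaks_per_spectrum non-diagnostic peaks per spectrum.
#' @param mz_range fragment m/z range (Th).
#' @param precursor_range precursor m/z range (Th); disjoint from and above
#'   `mz_range` so every fragment survives the precursor-region filter.
#' @param loss_range neutral-loss value range (Da).
#' @param jitter_sd m/z jitter standard deviation (Da); must be at most a
#'   third of the absolute tolerance.
#' @param dropout_rate probability that a planted signal is missing from a
#'   given group member.
#' @param decoy_overlap_rate probability that a planted signal also appears
#'   in any given out-group spectrum.
#' @param seed RNG seed.
#' @param tol the [tolerance()] the downstream analysis will use (controls
#'   the separation guards).
#' @return an object of class `SimulationConfig`.
#' @export
simulation_config <- function(n_groups = 4L, members_per_group = 8L,
                              planted_fragments_per_group = 2L,
                              planted_losses_per_group = 1L,
                              noise_peaks_per_spectrum = 30L,
                              mz_range = c(100, 450),
                              precursor_range = c(500, 900),
                              loss_range = c(60, 250),
                              jitter_sd = 0.002,
                              dropout_rate = 0,
                              decoy_overlap_rate = 0,
                              seed = 42L,
                              tol = tolerance()) {
  stopifnot(n_groups >= 1, members_per_group >= 1,
            planted_fragments_per_group >= 0, planted_losses_per_group >= 0,
            planted_fragments_per_group + planted_losses_per_group >= 1,
            noise_peaks_per_spectrum >= 0,
            mz_range[1] > 0, diff(mz_range) > 0,
            precursor_range[1] > mz_range[2],
            jitter_sd <= tol$absolute / 3,
            dropout_rate >= 0, dropout_rate <= 1,
            decoy_overlap_rate >= 0, decoy_overlap_rate <= 1)
  structure(as.list(environment()), class = "SimulationConfig")
}

# draw n values in range, pairwise separated by > sep from each other and
# from `avoid`; errors when the range cannot host them
draw_separated <- function(n, range, sep, avoid = numeric(0),
                           max_tries = 10000L) {
  vals <- numeric(0)
  tries <- 0L
  while (length(vals) < n) {
    x <- stats::runif(1, range[1], range[2])
    if (!length(c(vals, avoid)) || min(abs(c(vals, avoid) - x)) > sep) {
      vals <- c(vals, x)
    }
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("infeasible configuration: cannot place ", n,
           " separated signals in [", range[1], ", ", range[2], "]")
    }
  }
  round_half_up(vals, 4L)
}

#' Simulate a ground-truthed spectral library
#'
#' Each group member contains its group's planted fragments (m/z jittered,
#' unless dropped out) and planted losses realized as fragments at
#' `precursor - loss`; with probability `decoy_overlap_rate` a planted
#' signal also appears in an out-group spectrum. Noise peaks are uniform
#' over `mz_range` but excluded from a +/- 2.1 Da guard band around every
#' planted fragment position (protecting both the tolerance window and the
#' carbon-isotope spacings used by deisotoping) and from the loss
#' neighborhoods of every planted loss. Intensities follow an exponential
#' distribution scaled to raw units; with probability 1/2 a planted peak is
#' promoted to base peak, so intensity normalization stays nontrivial.
#'
#' @param config a [simulation_config()].
#' @return list with `library` (a [spectral_library()]) and `truth`: list
#'   with `planted` (skeleton -> data.frame `kind`, `mz`) and `presence`
#'   (data.frame `spectrum_id`, `skeleton`, `kind`, `mz`, `present`).
#' @export
simulate_library <- function(config = simulation_config()) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  cfg <- config
  sep <- 3 * max(tol_window(cfg$tol, cfg$mz_range[2]),
                 tol_window(cfg$tol, cfg$precursor_range[2]))

  nfrag <- cfg$n_groups * cfg$planted_fragments_per_group
  nloss <- cfg$n_groups * cfg$planted_losses_per_group
  frag_pool <- draw_separated(nfrag, cfg$mz_range, max(sep, 2.1))
  loss_pool <- draw_separated(nloss, cfg$loss_range, max(sep, 2.1),
                              avoid = numeric(0))
  skeletons <- sprintf("skeleton_%02d", seq_len(cfg$n_groups))
  planted <- list()
  fi <- 0L; li <- 0L
  for (g in seq_len(cfg$n_groups)) {
    fr <- if (cfg$planted_fragments_per_group > 0)
      frag_pool[fi + seq_len(cfg$planted_fragments_per_group)] else numeric(0)
    lo <- if (cfg$planted_losses_per_group > 0)
      loss_pool[li + seq_len(cfg$planted_losses_per_group)] else numeric(0)
    fi <- fi + length(fr); li <- li + length(lo)
    planted[[skeletons[g]]] <- data.frame(
      kind = c(rep("fragment", length(fr)), rep("loss", length(lo))),
      mz = c(fr, lo))
  }

  jit <- function(n) {
    pmin(pmax(stats::rnorm(n, 0, cfg$jitter_sd), -cfg$tol$absolute * 0.9),
         cfg$tol$absolute * 0.9)
  }
  all_frag_pos <- frag_pool
  spectra <- list()
  presence <- list()
  for (g in seq_len(cfg$n_groups)) {
    for (m in seq_len(cfg$members_per_group)) {
      sid <- sprintf("G%02d_S%02d", g, m)
      precursor <- draw_precursor(cfg, frag_pool, loss_pool)
      mzs <- numeric(0); is_planted <- logical(0)
      # own planted signals, subject to dropout
      own <- planted[[skeletons[g]]]
      realized <- stats::runif(nrow(own)) >= cfg$dropout_rate
      for (k in seq_len(nrow(own))) {
        if (!realized[k]) next
        pos <- if (own$kind[k] == "fragment") own$mz[k] else
          precursor - own$mz[k]
        mzs <- c(mzs, pos + jit(1)); is_planted <- c(is_planted, TRUE)
      }
      presence[[length(presence) + 1L]] <- data.frame(
        spectrum_id = sid, skeleton = skeletons[g], kind = own$kind,
        mz = own$mz, present = realized)
      # decoy overlap: other groups' signals leak in
      if (cfg$decoy_overlap_rate > 0) {
        for (h in setdiff(seq_len(cfg$n_groups), g)) {
          oth <- planted[[skeletons[h]]]
          leak <- stats::runif(nrow(oth)) < cfg$decoy_overlap_rate
          for (k in which(leak)) {
            pos <- if (oth$kind[k] == "fragment") oth$mz[k] else
              precursor - oth$mz[k]
            mzs <- c(mzs, pos + jit(1)); is_planted <- c(is_planted, FALSE)
          }
        }
      }
      # noise peaks outside all guarded neighborhoods
      guard_frag <- c(all_frag_pos, precursor - loss_pool)
      nnoise <- cfg$noise_peaks_per_spectrum
      noise <- numeric(0)
      while (length(noise) < nnoise) {
        x <- stats::runif(nnoise, cfg$mz_range[1], cfg$mz_range[2])
        ok <- vapply(x, function(v) {
          all(abs(guard_frag - v) > 2.1) &&
            all(abs(loss_pool - (precursor - v)) > 2.1)
        }, logical(1))
        noise <- c(noise, x[ok])
      }
      noise <- noise[seq_len(nnoise)]
      mzs <- c(mzs, noise)
      is_planted <- c(is_planted, rep(FALSE, length(noise)))
      ints <- stats::rexp(length(mzs), rate = 1) + 0.05
      if (any(is_planted) && stats::runif(1) < 0.5) {
        promote <- sample(which(is_planted), 1L)
        ints[promote] <- max(ints) * 1.2
      }
      spectra[[length(spectra) + 1L]] <- spectrum(
        spectrum_id = sid, precursor_mz = precursor,
        mz = round_half_up(mzs, 4L), intensity = round(ints * 1e4, 1),
        compound_name = sprintf("synthetic_compound_%s", sid),
        skeleton = skeletons[g])
    }
  }
  list(library = spectral_library(spectra),
       truth = list(planted = planted,
                    presence = do.call(rbind, presence),
                    config = cfg))
}

#' Simulate an extract-level feature dataset
#'
#' Desk-scale stand-in for a multi-extract feature table: `n_spiked_per_group`
#' features per skeleton carry the full planted signature of that skeleton
#' (all fragments plus loss-realized fragments), while background features
#' avoid every signature neighborhood. Each feature carries `SAMPLE` and
#' `GENUS` metadata for source-attribution summaries.
#'
#' @param truth the `truth` element returned by [simulate_library()].
#' @param n_background_features number of signature-free features.
#' @param n_spiked_per_group signature-bearing features per skeleton.
#' @param seed RNG seed.
#' @param genera character vector of genus names to cycle through.
#' @param plants_per_genus plants per genus (sample labels).
#' @return list with `library` (feature-level [spectral_library()], all
#'   features ungrouped) and `spiked` (skeleton -> character vector of
#'   feature ids).
#' @export
simulate_extract <- function(truth, n_background_features = 100L,
                             n_spiked_per_group = 5L, seed = 1L,
                             genera = c("Rauvolfia", "Mitragyna", "Uncaria"),
                             plants_per_genus = 2L) {
  set.seed(seed)
  cfg <- truth$config
  planted <- truth$planted
  frag_pool <- unlist(lapply(planted, function(p) p$mz[p$kind == "fragment"]))
  loss_pool <- unlist(lapply(planted, function(p) p$mz[p$kind == "loss"]))
  plants <- as.vector(outer(genera, seq_len(plants_per_genus),
                            function(g, i) sprintf("%s_plant_%d", g, i)))
  plant_genus <- rep(genera, times = plants_per_genus)
  pick_sample <- function() {
    k <- sample.int(length(plants), 1L)
    list(SAMPLE = plants[k], GENUS = plant_genus[k])
  }
  jit <- function(n) {
    pmin(pmax(stats::rnorm(n, 0, cfg$jitter_sd), -cfg$tol$absolute * 0.9),
         cfg$tol$absolute * 0.9)
  }
  spectra <- list(); spiked <- list()
  fid <- 0L
  for (skel in names(planted)) {
    ids <- character(0)
    for (r in seq_len(n_spiked_per_group)) {
      fid <- fid + 1L
      sid <- sprintf("EXT_%04d", fid)
      precursor <- draw_precursor(cfg, frag_pool, loss_pool)
      p <- planted[[skel]]
      pos <- ifelse(p$kind == "fragment", p$mz, precursor - p$mz)
      mzs <- pos + jit(length(pos))
      nn <- max(cfg$noise_peaks_per_spectrum %/% 3L, 5L)
      noise <- draw_background_mz(nn, cfg, precursor, frag_pool, loss_pool)
      mzs <- c(mzs, noise)
      ints <- stats::rexp(length(mzs)) + 0.05
      meta <- pick_sample()
      spectra[[length(spectra) + 1L]] <- spectrum(
        spectrum_id = sid, precursor_mz = precursor,
        mz = round_half_up(mzs, 4L), intensity = round(ints * 1e4, 1),
        metadata = meta)
      ids <- c(ids, sid)
    }
    spiked[[skel]] <- ids
  }
  for (r in seq_len(n_background_features)) {
    fid <- fid + 1L
    sid <- sprintf("EXT_%04d", fid)
    precursor <- round_half_up(stats::runif(1, cfg$precursor_range[1],
                                            cfg$precursor_range[2]), 4L)
    nn <- max(cfg$noise_peaks_per_spectrum %/% 2L, 8L)
    mzs <- draw_background_mz(nn, cfg, precursor, frag_pool, loss_pool)
    ints <- stats::rexp(length(mzs)) + 0.05
    meta <- pick_sample()
    spectra[[length(spectra) + 1L]] <- spectrum(
      spectrum_id = sid, precursor_mz = precursor,
      mz = round_half_up(mzs, 4L), intensity = round(ints * 1e4, 1),
      metadata = meta)
  }
  list(library = spectral_library(spectra), spiked = spiked)
}

# draw a precursor avoiding cross-channel collisions: if precursor ~ f + l
# the fragment realized for loss l would coincide with planted fragment f
# (and f would imply loss l), silently coupling two groups' signatures
draw_precursor <- function(cfg, frag_pool, loss_pool, guard = 0.05) {
  sums <- if (length(frag_pool) && length(loss_pool)) {
    as.vector(outer(frag_pool, loss_pool, `+`))
  } else numeric(0)
  repeat {
    p <- stats::runif(1, cfg$precursor_range[1], cfg$precursor_range[2])
    if (!length(sums) || min(abs(sums - p)) > guard) {
      return(round_half_up(p, 4L))
    }
  }
}

draw_background_mz <- function(n, cfg, precursor, frag_pool, loss_pool) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::runif(n, cfg$mz_range[1], cfg$mz_range[2])
    ok <- vapply(x, function(v) {
      (!length(frag_pool) || all(abs(frag_pool - v) > 2.1)) &&
        (!length(loss_pool) || all(abs(loss_pool - (precursor - v)) > 2.1))
    }, logical(1))
    out <- c(out, x[ok])
  }
  out[seq_len(n)]
}

#' Source table of an extract simulation
#'
#' Builds the feature-by-sample intensity table consumed by
#' [genus_attribution()]: each feature's total ion intensity is placed in
#' its sample-of-origin column.
#'
#' @param extract output of [simulate_extract()].
#' @return a [source_table()].
#' @export
extract_source_table <- function(extract) {
  lib <- extract$library
  ids <- names(lib$spectra)
  samples <- vapply(lib$spectra, function(s) s$metadata$SAMPLE, character(1))
  genera <- vapply(lib$spectra, function(s) s$metadata$GENUS, character(1))
  usamp <- unique(samples)
  m <- matrix(0, nrow = length(ids), ncol = length(usamp),
              dimnames = list(ids, usamp))
  for (i in seq_along(ids)) {
    m[i, samples[i]] <- sum(lib$spectra[[i]]$peaks$intensity)
  }
  source_table(m, usamp,
               vapply(usamp, function(s) genera[samples == s][1], character(1)))
}
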