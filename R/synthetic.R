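# Seeded synthetic spectral libraries, metadata tables and noisy query
# spectra, so the whole identification pipeline can be exercised at desk
# scale. Synthetic "fragments" are mass values, not chemistry: peaks are
# drawn as random fractions of the parent mass minus small neutral-loss
# offsets, with log-normal relative intensities. Annotation SMILES are
# placeholder alkane tokens.

# run expr under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (is.null(old))
      rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  expr
}

#' Specification of a synthetic spectral library
#'
#' @param n_chemicals Number of chemicals (>= 1).
#' @param mass_range Parent neutral-mass interval in Da (default 80-600,
#'   the typical small-molecule screening range).
#' @param peaks_per_energy Interval for the per-block fragment count
#'   (default 5-20).
#' @param modes Ionization modes to emit per chemical (default `"ESI+"`).
#' @param near_isobar_fraction Fraction of chemicals given a partner within
#'   5 ppm, to stress candidate ranking (default 0.1).
#' @param seed Integer seed; a fixed seed makes [generate_library()] output
#'   byte-identical across runs.
#' @return A `library_spec` list.
#' @export
library_spec <- function(n_chemicals, mass_range = c(80, 600),
                         peaks_per_energy = c(5, 20), modes = "ESI+",
                         near_isobar_fraction = 0.1, seed = 1L) {
  stopifnot(n_chemicals >= 1, length(mass_range) == 2,
            mass_range[1] > 0, mass_range[1] < mass_range[2],
            length(peaks_per_energy) == 2,
            peaks_per_energy[1] >= 1,
            peaks_per_energy[1] <= peaks_per_energy[2],
            near_isobar_fraction >= 0, near_isobar_fraction <= 1)
  modes <- vapply(modes, canon_mode, character(1), USE.NAMES = FALSE)
  structure(list(n_chemicals = as.integer(n_chemicals),
                 mass_range = as.numeric(mass_range),
                 peaks_per_energy = as.integer(peaks_per_energy),
                 modes = modes,
                 near_isobar_fraction = near_isobar_fraction,
                 seed = as.integer(seed)),
            class = "library_spec")
}

#' Specification of query-spectrum noise
#'
#' Emulates the measurement error separating an instrument spectrum from the
#' predicted spectrum it should match: Gaussian m/z jitter (ppm scale),
#' multiplicative log-normal intensity noise, Bernoulli peak dropout, and
#' Poisson spurious peaks.
#'
#' @param mz_jitter_ppm Standard deviation of per-peak m/z jitter in ppm.
#' @param intensity_cv Coefficient of variation of intensity noise.
#' @param dropout Per-peak dropout probability (must be < 1).
#' @param spurious_rate Expected number of spurious peaks per query (Poisson
#'   mean).
#' @param seed Optional seed for [make_query()].
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(mz_jitter_ppm = 0, intensity_cv = 0, dropout = 0,
                       spurious_rate = 0, seed = NULL) {
  stopifnot(mz_jitter_ppm >= 0, intensity_cv >= 0, spurious_rate >= 0,
            dropout >= 0)
  if (dropout >= 1) stop("dropout must be < 1")
  structure(list(mz_jitter_ppm = mz_jitter_ppm, intensity_cv = intensity_cv,
                 dropout = dropout, spurious_rate = spurious_rate,
                 seed = seed),
            class = "noise_spec")
}

# snap a value to exactly what the flat format prints (six decimals), so
# generated libraries are write/parse fixpoints; round() alone can differ
# from the printed decimal by one ulp
snap6 <- function(x) as.numeric(sprintf("%.6f", x))

# sample one integer from [a, b] without the scalar sample() pitfall
sample_int <- function(a, b) if (a == b) a else sample(a:b, 1)

# placeholder fragment SMILES: unbranched alkane chain per annotation id
placeholder_smiles <- function(id) {
  strrep("C", (id %% 6L) + 1L)
}

# random fragment m/z values below the parent: fractions of the parent mass
# minus a small neutral-loss offset, kept >= 40 Da and <= parent
synth_fragment_mz <- function(n, parent_mass) {
  frac <- stats::runif(n, 0.1, 0.98)
  loss <- stats::runif(n, 0.5, 18) # H2O-scale neutral losses
  mz <- pmax(40, pmin(parent_mass, frac * parent_mass - loss * frac))
  mz <- snap6(sort(mz))
  # enforce strictly increasing values (duplicates collapse match indices)
  while (any(duplicated(mz))) {
    mz[duplicated(mz)] <- mz[duplicated(mz)] + 0.001
    mz <- sort(mz)
  }
  snap6(mz)
}

synth_energy_block <- function(parent_mass, n_peaks, next_ann_id) {
  mz <- synth_fragment_mz(n_peaks, parent_mass)
  intensity <- stats::rlnorm(n_peaks, meanlog = 2, sdlog = 1.2)
  intensity <- snap6(intensity / max(intensity) * 100)
  n_ann <- 1L + stats::rbinom(n_peaks, 1L, 0.15) # 15% of peaks carry 2 annotations
  ids <- vector("list", n_peaks); ann <- vector("list", n_peaks)
  for (i in seq_len(n_peaks)) {
    ids[[i]] <- next_ann_id + seq_len(n_ann[i]) - 1L
    next_ann_id <- next_ann_id + n_ann[i]
    ann[[i]] <- if (n_ann[i] == 1L) intensity[i] else {
      w <- stats::runif(n_ann[i]); snap6(intensity[i] * w / sum(w))
    }
  }
  list(peaks = peak_table(mz, intensity, ids, ann), next_ann_id = next_ann_id)
}

#' Generate a synthetic spectral library with matching metadata
#'
#' Draws parent masses uniformly over the spec's range, optionally planting
#' near-isobaric partners (within 5 ppm) for a fraction of chemicals, builds
#' per-energy fragment blocks satisfying every flat-format invariant (sorted
#' peaks, fragments below parent + 1.01 Da, three blocks for ESI and one for
#' EI), and draws long-tailed metadata counts. Fully reproducible: the same
#' spec yields byte-identical [write_dat()] output.
#'
#' @param spec A [library_spec()].
#' @return List with `records` (list of `spectrum_record`) and `metadata`
#'   (data.frame in the [read_metadata_csv()] layout).
#' @export
generate_library <- function(spec) {
  stopifnot(inherits(spec, "library_spec"))
  with_seed(spec$seed, {
    n <- spec$n_chemicals
    masses <- stats::runif(n, spec$mass_range[1], spec$mass_range[2])
    n_iso <- floor(spec$near_isobar_fraction * n)
    if (n_iso >= 1) {
      # partner pairs: second member's mass within +/-3 ppm of the first
      partners <- seq_len(n_iso)
      targets <- n - n_iso + seq_len(n_iso)
      masses[targets] <- masses[partners] *
        (1 + stats::runif(n_iso, -3e-6, 3e-6))
    }
    masses <- snap6(masses)
    records <- vector("list", 0)
    meta <- vector("list", n)
    for (i in seq_len(n)) {
      dtxcid <- sprintf("DTXCID%07d", i)
      dtxsid <- sprintf("DTXSID%07d", i)
      # synthetic CxHyNzOw formula roughly consistent with the mass scale
      nc <- max(1L, round(masses[i] / 19))
      nh <- max(1L, round(masses[i] / 12))
      form <- sprintf("C%dH%dN2O2", nc, nh)
      smiles <- strrep("C", max(1L, nc %% 12L))
      inchikey <- paste0(substr(paste0(rep(LETTERS, 2), collapse = ""), 1, 14),
                         "-", sprintf("%010d", i), "-N")
      for (mode in spec$modes) {
        labels <- energy_labels_for_mode(mode)
        next_id <- 0L
        energies <- list(); annotations <- character()
        for (lab in labels) {
          k <- sample_int(spec$peaks_per_energy[1], spec$peaks_per_energy[2])
          blk <- synth_energy_block(masses[i], k, next_id)
          energies[[lab]] <- blk$peaks
          new_ids <- next_id:(blk$next_ann_id - 1L)
          annotations[as.character(new_ids)] <-
            vapply(new_ids, placeholder_smiles, character(1))
          next_id <- blk$next_ann_id
        }
        records[[length(records) + 1L]] <- spectrum_record(
          dtxcid = dtxcid, smiles = smiles, mass = masses[i], formula = form,
          inchikey = inchikey, mode = mode, energies = energies,
          annotations = annotations,
          datetime = "2019-01-01 00:00:00", cfm_version = "synthetic-1.0")
      }
      meta[[i]] <- data.frame(
        dtxcid = dtxcid, dtxsid = dtxsid,
        preferred_name = paste0("Synthetic compound ", i),
        casrn = sprintf("%d-%02d-%d", 100000 + i, i %% 100, i %% 10),
        ms_ready_formula = form,
        ms_ready_monoisotopic_mass = masses[i],
        ms_ready_smiles = smiles,
        # long-tailed prevalence counts, as in real chemistry databases
        data_sources = stats::rpois(1, stats::rlnorm(1, 2, 1.5)),
        pubmed_refs = stats::rpois(1, stats::rlnorm(1, 3, 2)),
        pubchem_sources = stats::rpois(1, stats::rlnorm(1, 2, 1)),
        cpdat_count = if (stats::runif(1) < 0.3) NA_integer_
                      else stats::rpois(1, stats::rlnorm(1, 1, 1.5)),
        in_susdat = stats::runif(1) < 0.5,
        in_stoffident = stats::runif(1) < 0.3,
        in_toxcast = stats::runif(1) < 0.4)
    }
    list(records = records, metadata = do.call(rbind, meta))
  })
}

#' Derive a noisy query spectrum from a library record
#'
#' Applies per-peak Gaussian m/z jitter (ppm scale), multiplicative
#' log-normal intensity noise, Bernoulli dropout, and Poisson-count spurious
#' peaks (uniform m/z over the fragment range) to one energy block. The
#' parent mass receives the same ppm-scale jitter. If every true peak drops
#' out, the dropout draw is repeated until at least one peak survives.
#'
#' @param record A `spectrum_record`.
#' @param energy_label Energy block to corrupt.
#' @param noise A [noise_spec()].
#' @return List with `query` (a `query_spectrum`) and `truth` (the source
#'   dtxcid).
#' @export
make_query <- function(record, energy_label, noise = noise_spec()) {
  lab <- canon_energy_label(energy_label)
  if (!lab %in% names(record$energies))
    stop("energy '", lab, "' absent from record")
  pk <- record$energies[[lab]]
  if (!nrow(pk)) stop("cannot build a query from an empty energy block")
  with_seed(noise$seed, {
    repeat {
      keep <- stats::runif(nrow(pk)) >= noise$dropout
      if (any(keep)) break
    }
    mz <- pk$mz[keep]
    intensity <- pk$intensity[keep]
    if (noise$mz_jitter_ppm > 0)
      mz <- mz * (1 + stats::rnorm(length(mz), 0, noise$mz_jitter_ppm * 1e-6))
    if (noise$intensity_cv > 0) {
      sdlog <- sqrt(log(1 + noise$intensity_cv^2))
      intensity <- intensity * stats::rlnorm(length(intensity),
                                             -sdlog^2 / 2, sdlog)
    }
    n_spur <- if (noise$spurious_rate > 0) stats::rpois(1, noise$spurious_rate) else 0L
    if (n_spur > 0) {
      rng <- range(pk$mz)
      mz <- c(mz, stats::runif(n_spur, rng[1], rng[2]))
      intensity <- c(intensity,
                     stats::runif(n_spur, 0, stats::quantile(pk$intensity, 0.25)))
    }
    parent <- record$header$mass
    if (noise$mz_jitter_ppm > 0)
      parent <- parent * (1 + stats::rnorm(1, 0, noise$mz_jitter_ppm * 1e-6))
    list(query = query_spectrum(data.frame(mz = mz, intensity = intensity),
                                parent_mass = parent, mode = record$mode),
         truth = record$header$dtxcid)
  })
}

#' End-to-end recovery experiment
#'
#' Generates a library, loads it into a store, draws queries from random
#' member records under the given noise model, runs the full search
#' (parent-mass retrieval, per-energy cosine scoring, sum ranking), and
#' summarizes how often the true chemical is recovered.
#'
#' @param lib_spec A [library_spec()].
#' @param noise A [noise_spec()].
#' @param n_queries Number of queries to draw.
#' @param parent_tol_ppm Parent-mass search window (default 10 ppm).
#' @param frag_tol_ppm Fragment-match window (default 10 ppm).
#' @param energy_label Energy block queries are derived from (default
#'   `"energy1"`, the middle collision energy; `"ei"` for EI libraries).
#' @param seed Seed for query sampling and noise.
#' @return List: `n_queries`, `rank1_rate`, `top5_rate`, `mean_true_score`
#'   (mean sum score of the true chemical), `top5_ci` (95% binomial
#'   confidence interval for the top-5 rate).
#' @export
recovery_experiment <- function(lib_spec, noise = noise_spec(),
                                n_queries = 100, parent_tol_ppm = 10,
                                frag_tol_ppm = 10, energy_label = NULL,
                                seed = 1L) {
  lib <- generate_library(lib_spec)
  store <- load_library(lib$records)
  if (is.null(energy_label))
    energy_label <- if (all(vapply(lib$records, `[[`, "", "mode") == "EI"))
      "ei" else "energy1"
  with_seed(seed, {
    idx <- sample(length(lib$records), n_queries, replace = TRUE)
    ranks <- integer(n_queries)
    true_scores <- numeric(n_queries)
    for (q in seq_len(n_queries)) {
      rec <- lib$records[[idx[q]]]
      qu <- make_query(rec, energy_label, noise)
      res <- search_library(store, qu$query, parent_tol_ppm = parent_tol_ppm,
                            frag_tol_ppm = frag_tol_ppm, rank_by = "sum")
      hit <- match(qu$truth, res$dtxcid)
      ranks[q] <- if (is.na(hit)) NA_integer_ else res$rank[hit]
      true_scores[q] <- if (is.na(hit)) 0 else res$sum_score[hit]
    }
    top5 <- sum(!is.na(ranks) & ranks <= 5)
    ci <- stats::binom.test(top5, n_queries)$conf.int
    list(n_queries = n_queries,
         rank1_rate = mean(!is.na(ranks) & ranks == 1),
         top5_rate = top5 / n_queries,
         mean_true_score = mean(true_scores),
         top5_ci = as.numeric(ci))
  })
}
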