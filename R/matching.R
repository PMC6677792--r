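# Identification workflow: fragment matching inside a mass-accuracy window,
# per-collision-energy cosine dot-product scoring, multi-energy aggregation,
# and candidate ranking with optional chemical-metadata fusion.

#' Construct a query spectrum
#'
#' An observed (or simulated) MS/MS peak list plus the information needed to
#' retrieve candidates: the parent neutral mass and/or molecular formula. If
#' the parent was measured as an adduct m/z, pass the adduct label and the
#' observed value; the neutral mass is recovered on ingestion.
#'
#' @param peaks Two-column data.frame or matrix (`mz`, `intensity`).
#' @param parent_mass Parent mass in Da: the neutral mass, or the observed
#'   adduct m/z when `adduct` is not `"M"`.
#' @param formula Optional molecular formula string (alternative search key).
#' @param mode Ionization mode (`"ESI+"`, `"ESI-"`, `"EI"`).
#' @param adduct Adduct under which `parent_mass` was observed (`"M"`,
#'   `"[M+H]+"`, `"[M-H]-"`).
#' @return A `query_spectrum`: list with `parent_mass` (neutral Da), `formula`,
#'   `mode`, and `peaks` sorted ascending in m/z.
#' @export
query_spectrum <- function(peaks, parent_mass = NULL, formula = NULL,
                           mode = "ESI+", adduct = "M") {
  if (is.null(parent_mass) && is.null(formula))
    stop("a query needs at least one of parent_mass or formula")
  peaks <- as.data.frame(peaks)[, 1:2]
  names(peaks) <- c("mz", "intensity")
  peaks <- peaks[order(peaks$mz), , drop = FALSE]
  rownames(peaks) <- NULL
  if (!is.null(parent_mass)) {
    shift <- adduct_mz(1, adduct) - 1 # signed adduct mass shift
    parent_mass <- parent_mass - shift
    if (parent_mass <= 0) stop("parent mass non-positive after adduct correction")
  }
  structure(list(parent_mass = parent_mass, formula = formula,
                 mode = canon_mode(mode), peaks = peaks),
            class = "query_spectrum")
}

#' Scale a peak list to relative intensities (base peak = 100)
#'
#' @param peaks data.frame/matrix with `mz` and `intensity` columns.
#' @return Same shape, intensities scaled so the maximum is exactly 100;
#'   ratios preserved. Empty or all-zero input is an error.
#' @export
normalize_relative <- function(peaks) {
  p <- as.data.frame(peaks)
  if (!nrow(p)) stop("cannot normalize an empty peak list")
  if (any(p$intensity < 0)) stop("negative intensities")
  m <- max(p$intensity)
  if (m <= 0) stop("cannot normalize an all-zero peak list")
  p$intensity <- p$intensity / m * 100
  p
}

frag_tolerance_da <- function(mz, tol_ppm = NULL, tol_da = NULL,
                              floor_da = 0.001) {
  if (!is.null(tol_da)) {
    if (tol_da < 0) stop("negative tolerance")
    return(rep(tol_da, length(mz)))
  }
  if (is.null(tol_ppm)) tol_ppm <- 10
  if (tol_ppm < 0) stop("negative tolerance")
  pmax(mz * tol_ppm * 1e-6, floor_da)
}

#' Match fragments between two peak lists
#'
#' Greedy nearest-mass one-to-one assignment: all candidate pairs within
#' tolerance are sorted by absolute mass difference (ties by lower query
#' index, then lower library index) and assigned in order, skipping indices
#' already used. Deterministic. The ppm window is evaluated against the query
#' peak's m/z with an absolute floor (`floor_da`) for tiny m/z; an absolute
#' Dalton tolerance can be given instead via `tol_da`.
#'
#' @param query_peaks,library_peaks Peak data.frames ascending in m/z.
#' @param tol_ppm Relative tolerance in ppm (default 10; ignored when
#'   `tol_da` given).
#' @param tol_da Absolute tolerance in Da (optional).
#' @param floor_da Absolute floor under the ppm window (default 0.001 Da).
#' @return A `peak_match` list: `pairs` (two-column integer matrix, query and
#'   library row indices), `unmatched_query`, `unmatched_library`, `tolerance`.
#' @export
match_fragments <- function(query_peaks, library_peaks, tol_ppm = NULL,
                            tol_da = NULL, floor_da = 0.001) {
  q <- as.data.frame(query_peaks); l <- as.data.frame(library_peaks)
  if (nrow(q) && is.unsorted(q$mz)) stop("query peaks must ascend in m/z")
  if (nrow(l) && is.unsorted(l$mz)) stop("library peaks must ascend in m/z")
  tol <- frag_tolerance_da(q$mz, tol_ppm, tol_da, floor_da)
  if (nrow(q) && nrow(l)) {
    d <- abs(outer(q$mz, l$mz, "-"))
    within <- which(d <= tol, arr.ind = TRUE) # tol recycles down columns: query-indexed
    cand <- data.frame(qi = within[, 1], li = within[, 2],
                       d = d[within])
    cand <- cand[order(cand$d, cand$qi, cand$li), , drop = FALSE]
    used_q <- logical(nrow(q)); used_l <- logical(nrow(l))
    keep <- logical(nrow(cand))
    for (r in seq_len(nrow(cand))) {
      qi <- cand$qi[r]; li <- cand$li[r]
      if (!used_q[qi] && !used_l[li]) {
        used_q[qi] <- TRUE; used_l[li] <- TRUE; keep[r] <- TRUE
      }
    }
    pairs <- as.matrix(cand[keep, c("qi", "li"), drop = FALSE])
  } else {
    pairs <- matrix(integer(), ncol = 2)
  }
  colnames(pairs) <- c("query", "library")
  structure(list(pairs = pairs,
                 unmatched_query = setdiff(seq_len(nrow(q)), pairs[, 1]),
                 unmatched_library = setdiff(seq_len(nrow(l)), pairs[, 2]),
                 tolerance = if (!is.null(tol_da)) list(da = tol_da)
                             else list(ppm = if (is.null(tol_ppm)) 10 else tol_ppm,
                                       floor_da = floor_da)),
            class = "peak_match")
}

#' Cosine dot-product similarity of two matched spectra
#'
#' `sum over matched pairs of Iq*Il / (sqrt(sum over ALL query peaks Iq^2) *
#' sqrt(sum over ALL library peaks Il^2))`. The denominators run over all
#' peaks of each spectrum, so unmatched (spurious or missing) peaks penalize
#' the score. An optional Stein-Scott style weighting `I <- mz^mz_power *
#' I^intensity_power` is applied to both spectra before scoring (defaults: no
#' weighting). The score is invariant to uniform intensity rescaling of
#' either spectrum, symmetric, and lies in [0, 1].
#'
#' @param query_peaks,library_peaks Peak data.frames (`mz`, `intensity`).
#' @param match A `peak_match` from [match_fragments()]; computed at the
#'   default tolerance when omitted.
#' @param mz_power,intensity_power Weighting exponents (defaults 0 and 1).
#' @return Score in [0, 1].
#' @export
cosine_score <- function(query_peaks, library_peaks, match = NULL,
                         mz_power = 0, intensity_power = 1) {
  q <- as.data.frame(query_peaks); l <- as.data.frame(library_peaks)
  if (!nrow(q) || !nrow(l)) stop("cannot score an empty spectrum")
  if (is.null(match)) match <- match_fragments(q, l)
  p <- match$pairs
  if (nrow(p) && (max(p[, 1]) > nrow(q) || max(p[, 2]) > nrow(l)))
    stop("match references out-of-range peak indices")
  wq <- q$mz^mz_power * q$intensity^intensity_power
  wl <- l$mz^mz_power * l$intensity^intensity_power
  den <- sqrt(sum(wq^2)) * sqrt(sum(wl^2))
  if (den == 0) return(0)
  num <- sum(wq[p[, 1]] * wl[p[, 2]])
  min(1, num / den)
}

energy_labels_for_mode <- function(mode) {
  if (canon_mode(mode) == "EI") "ei" else .energy_labels_esi
}

#' Score one candidate record against a query
#'
#' Computes one cosine score per energy block present in the record (absent
#' blocks are NA), the sum score over present energies, and matched-peak
#' counts per energy.
#'
#' @param query A `query_spectrum`.
#' @param record A `spectrum_record` (or a named list of peak tables keyed by
#'   energy label, with attribute/field `dtxcid`).
#' @param tol_ppm,tol_da,floor_da Fragment tolerance (see [match_fragments()]).
#' @param mz_power,intensity_power Cosine weighting (see [cosine_score()]).
#' @return A one-row data.frame: `dtxcid`, `score_<label>` per possible label
#'   of the mode, `sum_score`, `matched_<label>`, `matched_total`.
#' @export
score_candidate <- function(query, record, tol_ppm = 10, tol_da = NULL,
                            floor_da = 0.001, mz_power = 0,
                            intensity_power = 1) {
  if (inherits(record, "spectrum_record")) {
    if (record$mode != query$mode)
      stop("mode mismatch: query ", query$mode, " vs record ", record$mode)
    blocks <- record$energies
    dtxcid <- record$header$dtxcid
  } else {
    blocks <- record$energies
    dtxcid <- record$dtxcid
  }
  labels <- energy_labels_for_mode(query$mode)
  qn <- normalize_relative(query$peaks)
  scores <- stats::setNames(rep(NA_real_, length(labels)), labels)
  matched <- stats::setNames(rep(NA_integer_, length(labels)), labels)
  for (lab in intersect(labels, names(blocks))) {
    pk <- blocks[[lab]]
    if (!nrow(pk) || max(pk$intensity) <= 0) { scores[lab] <- 0; matched[lab] <- 0L; next }
    ln <- normalize_relative(pk[, c("mz", "intensity")])
    m <- match_fragments(qn, ln, tol_ppm = tol_ppm, tol_da = tol_da,
                         floor_da = floor_da)
    scores[lab] <- cosine_score(qn, ln, m, mz_power = mz_power,
                                intensity_power = intensity_power)
    matched[lab] <- nrow(m$pairs)
  }
  out <- data.frame(dtxcid = dtxcid)
  for (lab in labels) out[[paste0("score_", lab)]] <- scores[[lab]]
  out$sum_score <- sum(scores, na.rm = TRUE)
  for (lab in labels) out[[paste0("matched_", lab)]] <- matched[[lab]]
  out$matched_total <- sum(matched, na.rm = TRUE)
  out
}

rank_key_column <- function(scores, key) {
  key <- tolower(key)
  col <- if (key == "sum") "sum_score" else paste0("score_", key)
  if (!col %in% names(scores))
    stop("unknown ranking key '", key, "'")
  col
}

# competition ranks ("1224") over values sorted descending, with a float
# tolerance so near-equal scores are ranked as ties before tie-breaking
competition_ranks <- function(sorted_values, tol = 1e-12) {
  n <- length(sorted_values)
  if (!n) return(integer())
  r <- integer(n); r[1] <- 1L
  for (i in seq_len(n)[-1]) {
    r[i] <- if (sorted_values[i - 1] - sorted_values[i] <= tol) r[i - 1] else i
  }
  r
}

#' Rank scored candidates
#'
#' Orders candidates descending by the chosen score (the multi-energy sum by
#' default), breaking ties by higher matched-peak total, then by dtxcid.
#' Scores within 1e-12 are treated as tied and share a competition rank
#' (1, 2, 2, 4, ...); the order *within* a tie class follows the tie-break
#' rule, so the output order is deterministic.
#'
#' @param scores data.frame of [score_candidate()] rows.
#' @param key `"sum"` or an energy label (`"energy0"`, `"energy1"`,
#'   `"energy2"`, `"ei"`).
#' @return The reordered data.frame with a `rank` column prepended.
#' @export
rank_candidates <- function(scores, key = "sum") {
  if (!nrow(scores)) {
    scores$rank <- integer()
    return(scores)
  }
  col <- rank_key_column(scores, key)
  v <- scores[[col]]
  v[is.na(v)] <- -Inf
  ord <- order(-v, -scores$matched_total, scores$dtxcid)
  out <- scores[ord, , drop = FALSE]
  out <- cbind(rank = competition_ranks(v[ord]), out)
  rownames(out) <- NULL
  out
}

metadata_counts <- function(scores, metadata) {
  if (is.data.frame(metadata)) {
    counts <- stats::setNames(metadata$data_sources, metadata$dtxcid)
  } else {
    counts <- metadata
  }
  out <- counts[scores$dtxcid]
  if (anyNA(out)) {
    warning(sum(is.na(out)), " candidate(s) missing from metadata; ",
            "treated as zero data sources")
    out[is.na(out)] <- 0
  }
  as.numeric(out)
}

#' Metadata-augmented candidate ranking
#'
#' Fuses the spectral ranking with a ranking by chemical-metadata prevalence
#' (the `data_sources` count: the more sources a chemical appears in, the more
#' likely it occurs in a real sample). Strategies:
#'
#' * `"rrf"` (default): reciprocal-rank fusion,
#'   `combined = 1/(k + r_spectral) + w * 1/(k + r_metadata)` with `k = rrf_k`;
#' * `"zscore"`: `z(spectral score) + w * z(log1p(data_sources))`;
#' * `"tiebreak"`: spectral ranking, metadata used only to order tied ranks.
#'
#' With `metadata_weight = 0`, or when all metadata counts are equal, every
#' strategy reduces exactly to the spectral ranking.
#'
#' @param scores data.frame of [score_candidate()] rows (ranked or not; the
#'   spectral ranking is recomputed from `key`).
#' @param metadata data.frame from [read_metadata_csv()] (or a named numeric
#'   vector dtxcid -> data-source count). Candidates missing from the
#'   metadata are treated as zero-count with a warning.
#' @param strategy Fusion strategy (above).
#' @param rrf_k Reciprocal-rank-fusion constant (default 60).
#' @param metadata_weight Relative weight of the metadata ranking (default 1).
#' @param key Spectral ranking key (see [rank_candidates()]).
#' @return The candidates reordered by the combined criterion, with
#'   `combined_rank`, `combined_score`, `data_sources` and the spectral `rank`
#'   columns.
#' @export
combined_rank <- function(scores, metadata, strategy = c("rrf", "zscore",
                                                         "tiebreak"),
                          rrf_k = 60, metadata_weight = 1, key = "sum") {
  strategy <- match.arg(strategy)
  if (!is.numeric(rrf_k) || rrf_k < 0) stop("invalid rrf_k")
  if (!is.numeric(metadata_weight) || metadata_weight < 0)
    stop("invalid metadata_weight")
  spec <- rank_candidates(scores, key = key)
  if (!nrow(spec)) {
    spec$combined_rank <- integer(); spec$combined_score <- numeric()
    spec$data_sources <- numeric()
    return(spec)
  }
  counts <- metadata_counts(spec, metadata)
  r_meta <- competition_ranks(sort(counts, decreasing = TRUE))[
    match(-counts, sort(-counts))]
  combined <- switch(strategy,
    rrf = 1 / (rrf_k + spec$rank) + metadata_weight / (rrf_k + r_meta),
    zscore = {
      z <- function(x) {
        s <- stats::sd(x)
        if (is.na(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
      }
      kcol <- rank_key_column(spec, key)
      v <- spec[[kcol]]; v[is.na(v)] <- 0
      z(v) + metadata_weight * z(log1p(counts))
    },
    tiebreak = {
      # order within spectral tie classes by metadata count
      -(spec$rank + (if (metadata_weight > 0)
        stats::ave(-counts, spec$rank, FUN = function(x) rank(x, ties.method = "first") - 1) * 1e-9
        else 0))
    })
  ord <- order(-combined, seq_len(nrow(spec))) # stable: spectral order breaks ties
  out <- spec[ord, , drop = FALSE]
  out$data_sources <- counts[ord]
  out$combined_score <- combined[ord]
  out$combined_rank <- competition_ranks(combined[ord])
  rownames(out) <- NULL
  out
}

#' Search a spectral library with a query spectrum
#'
#' The full identification workflow: retrieve candidates by parent mass
#' (ppm window) or formula, score each candidate's stored energy blocks
#' against the query with the cosine dot product, rank, and optionally fuse
#' with chemical metadata.
#'
#' @param store A `library_store`.
#' @param query A `query_spectrum`.
#' @param parent_tol_ppm Parent-mass window in ppm (default 10).
#' @param frag_tol_ppm,frag_tol_da,floor_da Fragment-match tolerance.
#' @param rank_by Ranking key (see [rank_candidates()]).
#' @param metadata Optional metadata table for [combined_rank()].
#' @param strategy,rrf_k,metadata_weight Fusion parameters.
#' @param mz_power,intensity_power Cosine weighting exponents.
#' @param top_k Truncate the result to the first `top_k` rows.
#' @return Ranked candidate data.frame (one row per candidate) with scores,
#'   matched counts, `ppm_error`, `rank`, and combined-rank columns when
#'   metadata is supplied. Empty candidate set yields an empty data.frame.
#' @export
search_library <- function(store, query, parent_tol_ppm = 10,
                           frag_tol_ppm = 10, frag_tol_da = NULL,
                           floor_da = 0.001, rank_by = "sum",
                           metadata = NULL, strategy = "rrf", rrf_k = 60,
                           metadata_weight = 1, mz_power = 0,
                           intensity_power = 1, top_k = Inf) {
  stopifnot(inherits(query, "query_spectrum"))
  hits <- if (!is.null(query$parent_mass))
    query_by_mass(store, query$parent_mass, parent_tol_ppm, query$mode)
  else query_by_formula(store, query$formula, query$mode)
  if (!nrow(hits)) {
    out <- data.frame(rank = integer(), dtxcid = character(),
                      sum_score = numeric(), ppm_error = numeric())
    return(out)
  }
  labels <- energy_labels_for_mode(query$mode)
  rows <- lapply(hits$dtxcid, function(id) {
    blocks <- list()
    for (lab in labels) {
      pk <- tryCatch(get_spectrum(store, id, query$mode, lab),
                     error = function(e) NULL)
      if (!is.null(pk)) blocks[[lab]] <- pk
    }
    score_candidate(query, list(dtxcid = id, energies = blocks),
                    tol_ppm = frag_tol_ppm, tol_da = frag_tol_da,
                    floor_da = floor_da, mz_power = mz_power,
                    intensity_power = intensity_power)
  })
  scores <- do.call(rbind, rows)
  scores$ppm_error <- hits$ppm_error[match(scores$dtxcid, hits$dtxcid)]
  ranked <- if (is.null(metadata)) rank_candidates(scores, key = rank_by)
  else combined_rank(scores, metadata, strategy = strategy, rrf_k = rrf_k,
                     metadata_weight = metadata_weight, key = rank_by)
  utils::head(ranked, top_k)
}
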