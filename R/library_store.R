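# Embedded relational spectral store. Four normalized tables mirror the
# chemical / job / peak / fragintensity entity-relationship design used for
# server-scale deployments of predicted-spectrum libraries; here they live in
# keyed data.tables inside an environment handle, and the same schema is
# exportable as engine-neutral SQL DDL for anyone loading onto a server.

#' Create an empty spectral library store
#'
#' @return A `library_store` handle (an environment holding the `chemical`,
#'   `job`, `peak` and `fragintensity` tables plus id counters).
#' @seealso [load_library()], [query_by_mass()], [write_schema_sql()]
#' @export
library_store <- function() {
  st <- new.env(parent = emptyenv())
  st$chemical <- data.table::data.table(
    dtxcid = character(), smiles = character(), formula = character(),
    mass = numeric(), inchikey = character())
  st$job <- data.table::data.table(
    job_id = integer(), dtxcid = character(), mode = character(),
    energy_label = character(), cfm_version = character(),
    timestamp = character())
  st$peak <- data.table::data.table(
    peak_id = integer(), job_id = integer(), mz = numeric(),
    relative_intensity = numeric())
  st$fragintensity <- data.table::data.table(
    peak_id = integer(), annotation_id = integer(), intensity = numeric(),
    fragment_smiles = character())
  st$next_job_id <- 1L
  st$next_peak_id <- 1L
  st$last_report <- NULL
  class(st) <- "library_store"
  st
}

#' @export
print.library_store <- function(x, ...) {
  cat("<library_store>",
      nrow(x$chemical), "chemicals,",
      nrow(x$job), "jobs,",
      nrow(x$peak), "peaks,",
      nrow(x$fragintensity), "fragment annotations\n")
  invisible(x)
}

#' Load predicted-spectrum records into a store
#'
#' Each energy block of a record becomes one job (a chemical processed for one
#' mode at one collision-energy tier); jobs are keyed by
#' (dtxcid, mode, energy_label) and re-loading the same key *replaces* the
#' previous job, so rebuilds are idempotent. Two records with the same key and
#' different peaks inside one call is a conflict and raises an error.
#'
#' @param records List of `spectrum_record` objects.
#' @param store An existing `library_store` to extend, or NULL for a new one.
#' @return The store, with the load report (counts per table, records loaded)
#'   available via [load_report()].
#' @export
load_library <- function(records, store = NULL) {
  if (inherits(records, "spectrum_record")) records <- list(records)
  if (is.null(store)) store <- library_store()
  stopifnot(inherits(store, "library_store"))
  seen <- new.env(parent = emptyenv())
  n_loaded <- 0L
  jid <- store$next_job_id
  pid <- store$next_peak_id
  new_chem <- list(); new_job <- list(); new_peak <- list(); new_frag <- list()
  for (rec in records) {
    v <- validate_record(rec)
    if (length(v$errors))
      stop("invalid record ", rec$header$dtxcid, ": ",
           paste(v$errors, collapse = "; "))
    h <- rec$header
    new_chem[[h$dtxcid]] <- data.table::data.table(
      dtxcid = h$dtxcid, smiles = h$smiles, formula = hill_string(h$formula),
      mass = h$mass, inchikey = h$inchikey)
    for (lab in names(rec$energies)) {
      key <- paste(h$dtxcid, rec$mode, lab, sep = "|")
      if (!is.null(seen[[key]])) {
        if (!identical(seen[[key]], rec$energies[[lab]]))
          stop("conflicting duplicate job for ", h$dtxcid, " (", rec$mode,
               ", ", lab, ") with differing peaks in the same load")
        next # byte-identical duplicate: keep the first copy
      }
      seen[[key]] <- rec$energies[[lab]]
      new_job[[key]] <- data.table::data.table(
        job_id = jid, dtxcid = h$dtxcid, mode = rec$mode, energy_label = lab,
        cfm_version = h$cfm_version, timestamp = h$datetime)
      pk <- rec$energies[[lab]]
      if (nrow(pk)) {
        pids <- pid + seq_len(nrow(pk)) - 1L
        pid <- pid + nrow(pk)
        new_peak[[key]] <- data.table::data.table(
          peak_id = pids, job_id = jid, mz = pk$mz,
          relative_intensity = pk$intensity)
        nid <- lengths(pk$ids)
        if (any(nid > 0L)) {
          ids <- unlist(pk$ids)
          new_frag[[key]] <- data.table::data.table(
            peak_id = rep(pids, nid),
            annotation_id = as.integer(ids),
            intensity = unlist(pk$ann_int),
            fragment_smiles = unname(rec$annotations[as.character(ids)]))
        }
      }
      jid <- jid + 1L
    }
    n_loaded <- n_loaded + 1L
  }
  # replace semantics: drop any previously stored chemicals/jobs re-loaded now
  if (length(new_job)) {
    old_key <- paste(store$job$dtxcid, store$job$mode, store$job$energy_label,
                     sep = "|")
    drop_jobs <- store$job$job_id[old_key %in% names(new_job)]
    if (length(drop_jobs)) {
      drop_peaks <- store$peak$peak_id[store$peak$job_id %in% drop_jobs]
      store$fragintensity <- store$fragintensity[!store$fragintensity$peak_id %in% drop_peaks]
      store$peak <- store$peak[!store$peak$job_id %in% drop_jobs]
      store$job <- store$job[!store$job$job_id %in% drop_jobs]
    }
  }
  if (length(new_chem)) {
    store$chemical <- rbind(
      store$chemical[!store$chemical$dtxcid %in% names(new_chem)],
      data.table::rbindlist(new_chem))
    store$job <- rbind(store$job, data.table::rbindlist(new_job))
    store$peak <- rbind(store$peak, data.table::rbindlist(new_peak))
    if (length(new_frag))
      store$fragintensity <- rbind(store$fragintensity,
                                   data.table::rbindlist(new_frag))
  }
  store$next_job_id <- jid
  store$next_peak_id <- pid
  index_store(store)
  store$last_report <- list(
    records_loaded = n_loaded,
    chemical = nrow(store$chemical),
    job = nrow(store$job),
    peak = nrow(store$peak),
    fragintensity = nrow(store$fragintensity))
  store
}

#' Load report of the most recent [load_library()] call
#'
#' @param store A `library_store`.
#' @return List with `records_loaded` and row counts per table.
#' @export
load_report <- function(store) store$last_report

index_store <- function(store) {
  data.table::setkey(store$chemical, mass)      # B-tree analogue on mass
  data.table::setindex(store$chemical, formula) # secondary index on Hill string
  data.table::setkey(store$job, dtxcid, mode, energy_label)
  data.table::setkey(store$peak, job_id, mz)
  data.table::setkey(store$fragintensity, peak_id)
  invisible(store)
}

#' Retrieve candidates by parent neutral mass within a ppm window
#'
#' Returns every chemical whose stored mass lies within `tol_ppm` of the query
#' mass (closed interval; ppm denominator is the query mass) and that has at
#' least one job in the requested ionization mode.
#'
#' @param store A `library_store`.
#' @param neutral_mass Query neutral monoisotopic mass in Da (> 0).
#' @param tol_ppm Mass tolerance in ppm (>= 0, default 10).
#' @param mode Ionization mode (`"ESI+"`, `"ESI-"`, `"EI"`).
#' @return data.frame of candidate hits (`dtxcid`, `mass`, `formula`,
#'   `ppm_error`) sorted by absolute ppm error, ties by dtxcid.
#' @export
query_by_mass <- function(store, neutral_mass, tol_ppm = 10, mode = "ESI+") {
  mass <- dtxcid <- NULL
  if (!is.numeric(neutral_mass) || length(neutral_mass) != 1L || neutral_mass <= 0)
    stop("neutral_mass must be a single positive number")
  if (!is.numeric(tol_ppm) || tol_ppm < 0) stop("tol_ppm must be >= 0")
  qmode <- canon_mode(mode)
  half <- neutral_mass * tol_ppm * 1e-6
  hits <- store$chemical[mass >= neutral_mass - half & mass <= neutral_mass + half]
  in_mode <- unique(store$job$dtxcid[store$job$mode == qmode])
  hits <- hits[dtxcid %in% in_mode]
  finish_hits(hits, neutral_mass)
}

finish_hits <- function(hits, neutral_mass) {
  out <- data.frame(dtxcid = hits$dtxcid, mass = hits$mass,
                    formula = hits$formula,
                    ppm_error = ppm_error(hits$mass, neutral_mass))
  out <- out[order(abs(out$ppm_error), out$dtxcid), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Retrieve candidates by molecular formula
#'
#' Matches on canonical Hill strings, so `"C12 H12N4O3S"` and
#' `"C12H12N4O3S"` retrieve the same set. The reported ppm error is 0 by
#' convention for formula matches.
#'
#' @param store A `library_store`.
#' @param formula Formula string (any tokenization accepted by
#'   [parse_formula()]).
#' @param mode Ionization mode.
#' @return data.frame as in [query_by_mass()].
#' @export
query_by_formula <- function(store, formula, mode = "ESI+") {
  dtxcid <- NULL
  canon <- hill_string(parse_formula(formula))
  qmode <- canon_mode(mode)
  hits <- store$chemical[list(formula = canon), on = "formula", nomatch = NULL]
  in_mode <- unique(store$job$dtxcid[store$job$mode == qmode])
  hits <- hits[dtxcid %in% in_mode]
  out <- data.frame(dtxcid = hits$dtxcid, mass = hits$mass,
                    formula = hits$formula,
                    ppm_error = rep(0, nrow(hits)))
  out <- out[order(out$dtxcid), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fetch one stored energy spectrum
#'
#' @param store A `library_store`.
#' @param dtxcid Chemical identifier.
#' @param mode Ionization mode.
#' @param energy_label Energy block label.
#' @return A peak table (see [peak_table()]) with peaks ascending in m/z,
#'   identical to what was loaded; attribute `"fragment_smiles"` carries the
#'   annotation id -> SMILES map for the returned peaks.
#' @export
get_spectrum <- function(store, dtxcid, mode, energy_label) {
  qmode <- canon_mode(mode)
  lab <- canon_energy_label(energy_label)
  qid <- dtxcid # avoid data.table column/argument name capture in subsets
  if (!qid %in% store$chemical$dtxcid)
    stop("dtxcid '", qid, "' not in library")
  jobs <- store$job[store$job$dtxcid == qid]
  if (!qmode %in% jobs$mode)
    stop("no ", qmode, " job for ", dtxcid)
  jid <- jobs$job_id[jobs$mode == qmode & jobs$energy_label == lab]
  if (!length(jid))
    stop("no energy block '", lab, "' for ", dtxcid, " in mode ", qmode)
  pk <- store$peak[store$peak$job_id %in% jid]
  pk <- pk[order(pk$mz)]
  frag <- store$fragintensity[store$fragintensity$peak_id %in% pk$peak_id]
  by_peak <- split(frag, factor(frag$peak_id, levels = pk$peak_id))
  tab <- peak_table(mz = pk$mz, intensity = pk$relative_intensity,
                    ids = lapply(by_peak, function(d) d$annotation_id),
                    ann_int = lapply(by_peak, function(d) d$intensity))
  ann <- unique(frag[, c("annotation_id", "fragment_smiles")])
  attr(tab, "fragment_smiles") <- stats::setNames(ann$fragment_smiles,
                                                  ann$annotation_id)
  tab
}

#' Export the store schema as SQL DDL
#'
#' Writes engine-neutral `CREATE TABLE` statements for the four-table layout
#' (chemical, job, peak, fragintensity) with the same keys and referential
#' constraints the embedded store enforces, so the library can be recreated
#' on a server RDBMS.
#'
#' @param path Output path (default `"schema.sql"`).
#' @return The path, invisibly.
#' @export
write_schema_sql <- function(path = "schema.sql") {
  ddl <- c(
    "-- Spectral library schema: chemicals, prediction jobs, peaks, fragment annotations",
    "CREATE TABLE chemical (",
    "  dtxcid   VARCHAR(32) PRIMARY KEY,",
    "  smiles   TEXT NOT NULL,",
    "  formula  VARCHAR(64) NOT NULL,",
    "  mass     DOUBLE PRECISION NOT NULL CHECK (mass > 0),",
    "  inchikey CHAR(27) NOT NULL",
    ");",
    "CREATE INDEX idx_chemical_mass ON chemical (mass);",
    "CREATE INDEX idx_chemical_formula ON chemical (formula);",
    "",
    "CREATE TABLE job (",
    "  job_id       INTEGER PRIMARY KEY,",
    "  dtxcid       VARCHAR(32) NOT NULL REFERENCES chemical (dtxcid),",
    "  mode         VARCHAR(4)  NOT NULL CHECK (mode IN ('ESI+','ESI-','EI')),",
    "  energy_label VARCHAR(8)  NOT NULL,",
    "  cfm_version  VARCHAR(32),",
    "  timestamp    VARCHAR(32),",
    "  UNIQUE (dtxcid, mode, energy_label)",
    ");",
    "",
    "CREATE TABLE peak (",
    "  peak_id            INTEGER PRIMARY KEY,",
    "  job_id             INTEGER NOT NULL REFERENCES job (job_id),",
    "  mz                 DOUBLE PRECISION NOT NULL CHECK (mz > 0),",
    "  relative_intensity DOUBLE PRECISION NOT NULL CHECK (relative_intensity >= 0)",
    ");",
    "CREATE INDEX idx_peak_job ON peak (job_id, mz);",
    "",
    "CREATE TABLE fragintensity (",
    "  peak_id         INTEGER NOT NULL REFERENCES peak (peak_id),",
    "  annotation_id   INTEGER NOT NULL,",
    "  intensity       DOUBLE PRECISION NOT NULL,",
    "  fragment_smiles TEXT,",
    "  PRIMARY KEY (peak_id, annotation_id)",
    ");")
  writeLines(ddl, path)
  invisible(path)
}
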