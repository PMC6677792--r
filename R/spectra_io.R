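# I/O for the multi-energy predicted-spectrum flat format, the companion
# chemical-metadata CSV, and NIST-MSP export.
#
# Flat-file dialect (one record):
#   Date/time: <text>
#   CFM-ID version: <text>
#   DTXCID: DTXCID<digits>
#   SMILES: <text>
#   MASS: <Da>
#   FORMULA: <Hill formula>
#   INCHI_KEY: <27-char key>
#   energy0            <- block markers for ESI; EI has one unlabeled block
#   <mz> <intensity> <id1> [<id2> ...] (<a1> [<a2> ...])
#   ...
#   energy1 / energy2 blocks
#   <id> <fragment SMILES>     <- annotation table, one id per line
#   <blank line(s) between records>
# The parenthesized per-annotation intensity group appears only when a peak
# carries more than one annotation id. Numeric fields are written at up to six
# decimal places. Readers accept plain or gzip-compressed text (R connections
# decompress transparently).

.header_keys <- c("Date/time", "CFM-ID version", "DTXCID", "SMILES",
                  "MASS", "FORMULA", "INCHI_KEY")
.energy_labels_esi <- c("energy0", "energy1", "energy2")

#' Collision energies (eV) of the standard ESI energy tiers
#'
#' `energy0`, `energy1`, `energy2` correspond to 10, 20 and 40 eV; electron
#' impact (`ei`) records carry a single block with no collision-energy tier.
#'
#' @return Named numeric vector (NA for `ei`).
#' @export
collision_energies <- function() {
  c(energy0 = 10, energy1 = 20, energy2 = 40, ei = NA_real_)
}

canon_energy_label <- function(label) {
  lab <- tolower(gsub("[[:space:]]", "", label))
  ok <- c(.energy_labels_esi, "ei")
  if (!lab %in% ok)
    stop("unknown energy label '", label, "'; expected one of ",
         paste(ok, collapse = ", "))
  lab
}

canon_mode <- function(mode) {
  m <- toupper(gsub("[[:space:]]", "", mode))
  m <- c("ESI+" = "ESI+", "ESIPOS" = "ESI+", "ESI-" = "ESI-",
         "ESINEG" = "ESI-", "EI" = "EI")[m]
  if (is.na(m)) stop("unknown ionization mode '", mode,
                     "'; expected ESI+, ESI- or EI")
  unname(m)
}

#' Construct a peak table
#'
#' One row per fragment peak: m/z, relative intensity, the annotation ids
#' explaining the fragment, and the per-annotation intensities. For a peak
#' with a single annotation the annotation intensity equals the peak's
#' relative intensity.
#'
#' @param mz Numeric vector of m/z values (Da), ascending.
#' @param intensity Non-negative relative intensities.
#' @param ids List of integer vectors of annotation ids (one per peak), or
#'   NULL for unannotated peaks.
#' @param ann_int List of numeric vectors of per-annotation intensities,
#'   parallel to `ids`; defaults to the peak intensity for single-id peaks.
#' @return A data.frame with columns `mz`, `intensity`, and list columns
#'   `ids`, `ann_int`.
#' @export
peak_table <- function(mz = numeric(), intensity = numeric(),
                       ids = NULL, ann_int = NULL) {
  n <- length(mz)
  stopifnot(length(intensity) == n)
  if (is.null(ids)) ids <- rep(list(integer()), n)
  if (is.null(ann_int))
    ann_int <- lapply(seq_len(n), function(i)
      if (length(ids[[i]]) == 1L) intensity[i] else rep(intensity[i] / max(1L, length(ids[[i]])), length(ids[[i]])))
  stopifnot(length(ids) == n, length(ann_int) == n)
  df <- data.frame(mz = as.numeric(mz), intensity = as.numeric(intensity))
  df$ids <- lapply(ids, as.integer)
  df$ann_int <- lapply(ann_int, as.numeric)
  df
}

#' Construct a predicted-spectrum record
#'
#' Bundles one chemical's header metadata, ionization mode, per-energy peak
#' tables and fragment-annotation SMILES into a `spectrum_record`.
#'
#' @param dtxcid Chemical identifier, `DTXCID` followed by digits.
#' @param smiles Structure SMILES (carried opaquely).
#' @param mass Neutral monoisotopic mass in Da.
#' @param formula Molecular formula string.
#' @param inchikey Standard InChIKey.
#' @param mode Ionization mode: `"ESI+"`, `"ESI-"` or `"EI"`.
#' @param energies Named list of peak tables (see [peak_table()]); names among
#'   `energy0`, `energy1`, `energy2` for ESI, exactly `ei` for EI.
#' @param annotations Named character vector: annotation id -> fragment SMILES.
#' @param datetime,cfm_version Free-text provenance fields.
#' @return A `spectrum_record` object.
#' @export
spectrum_record <- function(dtxcid, smiles, mass, formula, inchikey,
                            mode, energies, annotations = character(),
                            datetime = "1970-01-01 00:00:00",
                            cfm_version = "2.0") {
  rec <- structure(list(
    header = list(datetime = datetime, cfm_version = cfm_version,
                  dtxcid = dtxcid, smiles = smiles, mass = as.numeric(mass),
                  formula = formula, inchikey = inchikey),
    mode = canon_mode(mode),
    energies = energies,
    annotations = annotations
  ), class = "spectrum_record")
  rec
}

#' @export
print.spectrum_record <- function(x, ...) {
  np <- vapply(x$energies, nrow, 0L)
  cat("<spectrum_record> ", x$header$dtxcid, " [", x$mode, "] ",
      x$header$formula, " mass=", x$header$mass, "\n  blocks: ",
      paste(sprintf("%s(%d peaks)", names(np), np), collapse = ", "),
      "; ", length(x$annotations), " annotations\n", sep = "")
  invisible(x)
}

#' Validate a predicted-spectrum record
#'
#' Checks the structural invariants: identifier syntax, positive mass, a
#' parseable formula, header mass consistent with the formula mass (0.001 Da,
#' warning-level beyond), peak tables ascending in m/z with parallel
#' annotation columns, no fragment above the protonated parent (+1.01 Da for
#' hydrogen transfer), correct block structure per mode, and annotation ids
#' resolvable in the annotation table (warning-level: record is incomplete,
#' not invalid).
#'
#' @param record A `spectrum_record`.
#' @return List with character vectors `errors` and `warnings` (empty when
#'   the record is fully valid).
#' @export
validate_record <- function(record) {
  errs <- character(); warns <- character()
  h <- record$header
  if (!grepl("^DTXCID[0-9]+$", h$dtxcid))
    errs <- c(errs, sprintf("bad DTXCID '%s'", h$dtxcid))
  if (!is.numeric(h$mass) || is.na(h$mass) || h$mass <= 0)
    errs <- c(errs, "MASS must be positive")
  fm <- tryCatch(monoisotopic_mass(h$formula), error = function(e) NA_real_)
  if (is.na(fm)) {
    errs <- c(errs, sprintf("FORMULA '%s' does not parse", h$formula))
  } else if (is.numeric(h$mass) && !is.na(h$mass) && abs(fm - h$mass) > 0.001) {
    warns <- c(warns, sprintf("MASS %.5f disagrees with formula mass %.5f by > 0.001 Da",
                              h$mass, fm))
  }
  labs <- names(record$energies)
  if (record$mode == "EI") {
    if (!identical(labs, "ei"))
      errs <- c(errs, "EI records carry exactly one 'ei' block")
  } else {
    if (length(labs) > 3L || !all(labs %in% .energy_labels_esi))
      errs <- c(errs, "ESI records carry up to three blocks among energy0/1/2")
  }
  referenced <- integer()
  for (lab in labs) {
    pk <- record$energies[[lab]]
    if (nrow(pk)) {
      if (is.unsorted(pk$mz))
        errs <- c(errs, sprintf("%s peaks not ascending in m/z", lab))
      if (any(pk$mz <= 0)) errs <- c(errs, sprintf("%s has non-positive m/z", lab))
      if (any(pk$intensity < 0)) errs <- c(errs, sprintf("%s has negative intensity", lab))
      if (!is.na(h$mass) && any(pk$mz > h$mass + 1.01))
        errs <- c(errs, sprintf("%s has fragment m/z above parent mass + 1.01 Da", lab))
      nid <- lengths(pk$ids); nai <- lengths(pk$ann_int)
      if (any(nid != nai))
        errs <- c(errs, sprintf("%s annotation id/intensity lengths differ", lab))
      referenced <- c(referenced, unlist(pk$ids))
    }
  }
  missing_ann <- setdiff(unique(referenced), as.integer(names(record$annotations)))
  if (length(missing_ann))
    warns <- c(warns, sprintf("incomplete: annotation id(s) %s lack SMILES entries",
                              paste(missing_ann, collapse = ",")))
  list(errors = errs, warnings = warns)
}

# fixed-point numeric formatting at <= 6 dp; round-trips exactly through
# as.numeric for values rounded to 6 decimals
num_str <- function(x) {
  s <- sprintf("%.6f", x)
  s <- sub("0+$", "", s)
  sub("\\.$", "", s)
}

peak_line <- function(mz, intensity, ids, ann_int, sep = " ") {
  base <- paste(num_str(mz), num_str(intensity))
  if (length(ids) == 0L) return(base)
  line <- paste(base, paste(ids, collapse = sep))
  if (length(ids) > 1L)
    line <- paste0(line, sep, "(", paste(num_str(ann_int), collapse = sep), ")")
  line
}

#' Write predicted-spectrum records to the flat format
#'
#' Inverse of [parse_dat()]: `parse_dat(write_dat(r))` reproduces the records
#' field-for-field and peak-for-peak (numeric fields at six-decimal
#' precision). Records failing [validate_record()] are refused.
#'
#' @param records A list of `spectrum_record` objects.
#' @param path Optional output path; `.gz` suffix writes gzip-compressed text.
#' @return Character vector of lines, invisibly when `path` is given.
#' @export
write_dat <- function(records, path = NULL) {
  if (inherits(records, "spectrum_record")) records <- list(records)
  out <- character()
  for (rec in records) {
    v <- validate_record(rec)
    if (length(v$errors))
      stop("refusing to write invalid record ", rec$header$dtxcid, ": ",
           paste(v$errors, collapse = "; "))
    h <- rec$header
    out <- c(out,
             paste0("Date/time: ", h$datetime),
             paste0("CFM-ID version: ", h$cfm_version),
             paste0("DTXCID: ", h$dtxcid),
             paste0("SMILES: ", h$smiles),
             paste0("MASS: ", num_str(h$mass)),
             paste0("FORMULA: ", h$formula),
             paste0("INCHI_KEY: ", h$inchikey))
    for (lab in names(rec$energies)) {
      if (lab != "ei") out <- c(out, lab)
      pk <- rec$energies[[lab]]
      if (nrow(pk))
        out <- c(out, vapply(seq_len(nrow(pk)), function(i)
          peak_line(pk$mz[i], pk$intensity[i], pk$ids[[i]], pk$ann_int[[i]]),
          character(1)))
    }
    if (length(rec$annotations)) {
      ord <- order(as.integer(names(rec$annotations)))
      out <- c(out, paste(names(rec$annotations)[ord],
                          unname(rec$annotations)[ord]))
    }
    out <- c(out, "")
  }
  if (!is.null(path)) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
    on.exit(close(con))
    writeLines(out, con)
    return(invisible(out))
  }
  out
}

is_number_token <- function(tok) grepl("^[0-9]+\\.?[0-9]*([eE][+-]?[0-9]+)?$", tok)

parse_peak_line <- function(tokens) {
  mz <- suppressWarnings(as.numeric(tokens[1]))
  intensity <- suppressWarnings(as.numeric(tokens[2]))
  if (is.na(mz) || is.na(intensity)) return(NULL)
  rest <- tokens[-(1:2)]
  ids <- integer(); ann <- numeric()
  if (length(rest)) {
    par_open <- grep("^\\(", rest)
    if (length(par_open)) {
      id_toks <- rest[seq_len(par_open[1] - 1L)]
      ann_toks <- rest[par_open[1]:length(rest)]
      ann_toks <- gsub("[()]", "", ann_toks)
      ann_toks <- ann_toks[nzchar(ann_toks)]
      ann <- suppressWarnings(as.numeric(ann_toks))
    } else {
      id_toks <- rest
    }
    ids <- suppressWarnings(as.integer(id_toks))
    if (anyNA(ids) || anyNA(ann)) return(NULL)
    if (length(ann) == 0L && length(ids) == 1L) ann <- intensity
    if (length(ids) != length(ann)) return(NULL)
  }
  list(mz = mz, intensity = intensity, ids = ids, ann_int = ann)
}

#' Parse a predicted-spectrum flat file
#'
#' Reads records from the multi-energy flat format (see the dialect notes in
#' this file's documentation). Malformed records are skipped and reported
#' rather than aborting the stream; peaks out of m/z order are re-sorted with
#' a warning.
#'
#' @param input Path to a plain or gzip-compressed file, or a character
#'   vector of lines.
#' @param mode Ionization mode of the file: `"ESI+"`, `"ESI-"` or `"EI"`.
#' @param strict If TRUE, any record-level problem raises an error instead of
#'   skipping the record.
#' @return List of `spectrum_record` objects; attribute `"errors"` holds a
#'   data.frame (`line`, `dtxcid`, `message`) describing skipped records.
#' @export
parse_dat <- function(input, mode, strict = FALSE) {
  mode <- canon_mode(mode)
  lines <- if (length(input) == 1L && !grepl("\n", input) && file.exists(input))
    readLines(input) else as.character(input)
  if (length(lines) == 1L && grepl("\n", lines))
    lines <- strsplit(lines, "\n", fixed = TRUE)[[1]]
  hdr_start <- grep("^Date/time:", lines)
  records <- list()
  errors <- data.frame(line = integer(), dtxcid = character(),
                       message = character())
  fail <- function(at, id, msg) {
    if (strict) stop("record at line ", at, " (", id, "): ", msg)
    errors[nrow(errors) + 1L, ] <<- list(at, id, msg)
  }
  bounds <- c(hdr_start, length(lines) + 1L)
  for (k in seq_along(hdr_start)) {
    from <- hdr_start[k]; to <- bounds[k + 1L] - 1L
    chunk <- lines[from:to]
    rec <- tryCatch(parse_record_chunk(chunk, mode, from),
                    error = function(e) e)
    if (inherits(rec, "error")) {
      id <- sub("^DTXCID: *", "", grep("^DTXCID:", chunk, value = TRUE)[1])
      fail(from, if (is.na(id)) "?" else id, conditionMessage(rec))
    } else {
      records[[length(records) + 1L]] <- rec
    }
  }
  attr(records, "errors") <- errors
  records
}

parse_record_chunk <- function(chunk, mode, offset) {
  # header: seven KEY: value lines
  hdr <- list()
  i <- 1L
  for (key in .header_keys) {
    while (i <= length(chunk) && !nzchar(trimws(chunk[i]))) i <- i + 1L
    if (i > length(chunk) || !startsWith(chunk[i], paste0(key, ":")))
      stop("missing header field '", key, "' (line ", offset + i - 1L, ")")
    hdr[[key]] <- trimws(substring(chunk[i], nchar(key) + 2L))
    i <- i + 1L
  }
  mass <- suppressWarnings(as.numeric(hdr$MASS))
  if (is.na(mass) || mass <= 0)
    stop("MASS field '", hdr$MASS, "' is not a positive number")
  energies <- list()
  cur <- if (mode == "EI") "ei" else NA_character_
  cur_peaks <- list()
  annotations <- character()
  flush_block <- function() {
    if (!is.na(cur)) {
      pk <- do.call(rbind_peaks, cur_peaks)
      if (is.unsorted(pk$mz)) {
        warning("peaks of ", hdr$DTXCID, " ", cur,
                " out of m/z order; re-sorted", call. = FALSE)
        pk <- pk[order(pk$mz), , drop = FALSE]
        rownames(pk) <- NULL
      }
      energies[[cur]] <<- pk
    }
  }
  while (i <= length(chunk)) {
    line <- trimws(chunk[i])
    if (!nzchar(line)) { i <- i + 1L; next }
    if (grepl("^energy[0-2]$", tolower(line))) {
      if (mode == "EI")
        stop("energy marker '", line, "' in an EI file (line ", offset + i - 1L, ")")
      flush_block()
      cur <- tolower(line); cur_peaks <- list()
      i <- i + 1L; next
    }
    tokens <- strsplit(line, "[ \t]+")[[1]]
    if (length(tokens) >= 2L && is_number_token(tokens[1]) &&
        is_number_token(tokens[2])) {
      if (is.na(cur))
        stop("peak line before any energy marker (line ", offset + i - 1L, ")")
      pk <- parse_peak_line(tokens)
      if (is.null(pk))
        stop("unparseable peak line '", line, "' (line ", offset + i - 1L, ")")
      cur_peaks[[length(cur_peaks) + 1L]] <- pk
    } else if (grepl("^[0-9]+$", tokens[1]) && length(tokens) >= 2L) {
      annotations[tokens[1]] <- paste(tokens[-1], collapse = " ")
    } else {
      stop("unparseable line '", line, "' (line ", offset + i - 1L, ")")
    }
    i <- i + 1L
  }
  flush_block()
  if (mode == "EI" && is.null(energies$ei)) energies$ei <- peak_table()
  spectrum_record(dtxcid = hdr$DTXCID, smiles = hdr$SMILES, mass = mass,
                  formula = hdr$FORMULA, inchikey = hdr$INCHI_KEY,
                  mode = mode, energies = energies, annotations = annotations,
                  datetime = hdr$`Date/time`, cfm_version = hdr$`CFM-ID version`)
}

rbind_peaks <- function(...) {
  pks <- list(...)
  if (!length(pks)) return(peak_table())
  peak_table(mz = vapply(pks, `[[`, 0, "mz"),
             intensity = vapply(pks, `[[`, 0, "intensity"),
             ids = lapply(pks, `[[`, "ids"),
             ann_int = lapply(pks, `[[`, "ann_int"))
}

#' Export one energy block as a NIST-MSP text block
#'
#' The precursor m/z follows the record's mode: `[M+H]+` for ESI+, `[M-H]-`
#' for ESI-, and the neutral mass for EI.
#'
#' @param record A `spectrum_record`.
#' @param energy_label Energy block to export (`energy0`/`energy1`/`energy2`/`ei`).
#' @return Character vector of MSP lines.
#' @export
export_msp <- function(record, energy_label) {
  lab <- canon_energy_label(energy_label)
  if (!lab %in% names(record$energies))
    stop("energy '", lab, "' absent; available: ",
         paste(names(record$energies), collapse = ", "))
  adduct <- switch(record$mode, "ESI+" = "[M+H]+", "ESI-" = "[M-H]-", "EI" = "M")
  pk <- record$energies[[lab]]
  ce <- collision_energies()[[lab]]
  c(paste0("Name: ", record$header$dtxcid),
    paste0("PrecursorMZ: ", num_str(adduct_mz(record$header$mass, adduct))),
    paste0("Precursor_type: ", adduct),
    paste0("Formula: ", record$header$formula),
    paste0("InChIKey: ", record$header$inchikey),
    if (!is.na(ce)) paste0("Collision_energy: ", ce) else NULL,
    paste0("Comments: mode=", record$mode, " energy=", lab),
    paste0("Num Peaks: ", nrow(pk)),
    if (nrow(pk)) paste(num_str(pk$mz), num_str(pk$intensity)) else NULL,
    "")
}

.metadata_cols <- c(DTXCID = "dtxcid", DTXSID = "dtxsid",
                    PREFERRED_NAME = "preferred_name", CASRN = "casrn",
                    MS_READY_MOLECULAR_FORMULA = "ms_ready_formula",
                    MS_READY_MONOISOTOPIC_MASS = "ms_ready_monoisotopic_mass",
                    MS_READY_SMILES = "ms_ready_smiles",
                    DATA_SOURCES = "data_sources",
                    NUMBER_OF_PUBMED_ARTICLES = "pubmed_refs",
                    PUBCHEM_DATA_SOURCES = "pubchem_sources",
                    CPDAT_COUNT = "cpdat_count",
                    SUSDAT = "in_susdat", STOFFIDENT = "in_stoffident",
                    TOXCAST = "in_toxcast")
.count_cols <- c("data_sources", "pubmed_refs", "pubchem_sources", "cpdat_count")
.flag_cols <- c("in_susdat", "in_stoffident", "in_toxcast")

#' Read a chemical-metadata CSV
#'
#' Reads the 14-column metadata table keyed by DTXCID (identifiers, formula,
#' monoisotopic mass, SMILES, data-source / literature / product-occurrence
#' counts, and suspect-list flags). Missing counts printed as dashes or blank
#' map to NA (absent), not zero; list-membership cells map to logical flags.
#' Rows with a non-numeric count cell are skipped with a warning.
#'
#' @param path CSV file path (plain or gzip).
#' @return data.frame with columns `dtxcid`, `dtxsid`, `preferred_name`,
#'   `casrn`, `ms_ready_formula`, `ms_ready_monoisotopic_mass`,
#'   `ms_ready_smiles`, `data_sources`, `pubmed_refs`, `pubchem_sources`,
#'   `cpdat_count`, `in_susdat`, `in_stoffident`, `in_toxcast`.
#' @export
read_metadata_csv <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  missing <- setdiff(names(.metadata_cols), names(raw))
  if (length(missing))
    stop("metadata CSV missing required column(s): ",
         paste(missing, collapse = ", "), "; expected header: ",
         paste(names(.metadata_cols), collapse = ","))
  raw <- raw[names(.metadata_cols)]
  names(raw) <- unname(.metadata_cols)
  absent <- function(x) !nzchar(trimws(x)) | trimws(x) %in% c("-", "—", "NA")
  bad_rows <- rep(FALSE, nrow(raw))
  for (cc in .count_cols) {
    cell <- trimws(raw[[cc]])
    val <- suppressWarnings(as.integer(cell))
    bad <- !absent(cell) & is.na(val)
    bad_rows <- bad_rows | bad
    val[absent(cell)] <- NA_integer_
    raw[[cc]] <- val
  }
  if (any(bad_rows)) {
    warning(sum(bad_rows), " metadata row(s) skipped: non-numeric count cell(s)")
    raw <- raw[!bad_rows, , drop = FALSE]
  }
  for (fc in .flag_cols) raw[[fc]] <- toupper(trimws(raw[[fc]])) == "Y"
  raw$ms_ready_monoisotopic_mass <- as.numeric(raw$ms_ready_monoisotopic_mass)
  bad_id <- !grepl("^DTXSID[0-9]+$", raw$dtxsid)
  if (any(bad_id)) {
    warning(sum(bad_id), " metadata row(s) skipped: malformed DTXSID")
    raw <- raw[!bad_id, , drop = FALSE]
  }
  rownames(raw) <- NULL
  raw
}

#' Write a chemical-metadata CSV
#'
#' Inverse of [read_metadata_csv()]: absent counts are written as `-`, flags
#' as `Y` / `-`.
#'
#' @param metadata data.frame in the layout returned by [read_metadata_csv()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_metadata_csv <- function(metadata, path) {
  out <- metadata
  for (cc in .count_cols) {
    v <- as.character(out[[cc]]); v[is.na(v)] <- "-"
    out[[cc]] <- v
  }
  for (fc in .flag_cols) out[[fc]] <- ifelse(out[[fc]], "Y", "-")
  out$ms_ready_monoisotopic_mass <- num_str(out$ms_ready_monoisotopic_mass)
  names(out) <- names(.metadata_cols)[match(names(out), unname(.metadata_cols))]
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
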