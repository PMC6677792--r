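# Shared fixture builders: everything is generated in code, no stored data.

# minimal hand-built ESI+ record with known peaks
fixture_record <- function(dtxcid = "DTXCID0000001",
                           mass = 194.08038, formula = "C8H10N4O2",
                           mode = "ESI+",
                           energies = NULL) {
  if (is.null(energies)) {
    energies <- list(
      energy0 = peak_table(mz = c(56.049, 83.060, 110.071),
                           intensity = c(20, 100, 55),
                           ids = list(0L, 1L, c(2L, 3L)),
                           ann_int = list(20, 100, c(40, 15))),
      energy1 = peak_table(mz = c(42.034, 83.060),
                           intensity = c(100, 30),
                           ids = list(4L, 1L),
                           ann_int = list(100, 30)),
      energy2 = peak_table(mz = c(42.034), intensity = c(100),
                           ids = list(4L), ann_int = list(100)))
  }
  spectrum_record(
    dtxcid = dtxcid, smiles = "CN1C=NC2=C1C(=O)N(C)C(=O)N2C",
    mass = mass, formula = formula,
    inchikey = "RYYVLZVUVIJVGH-UHFFFAOYSA-N", mode = mode,
    energies = energies,
    annotations = c("0" = "CN", "1" = "CNC", "2" = "CC", "3" = "C",
                    "4" = "CNCC"),
    datetime = "2019-01-01 12:00:00", cfm_version = "2.0-test")
}

# strip S3 class tags so identical() compares structure only
record_essence <- function(records) lapply(records, unclass)

# brute-force reference for query_by_mass over a mass table
brute_force_mass_query <- function(masses, dtxcids, neutral_mass, tol_ppm) {
  ppm <- abs(masses - neutral_mass) / neutral_mass * 1e6
  keep <- which(ppm <= tol_ppm)
  keep[order(ppm[keep], dtxcids[keep])]
}

# brute-force optimal check of the one-to-one matching contract on tiny inputs:
# enumerates every one-to-one assignment of within-tolerance pairs and verifies
# the greedy result is a maximal valid assignment built nearest-first
all_within_pairs <- function(qmz, lmz, tol_da) {
  pairs <- expand.grid(qi = seq_along(qmz), li = seq_along(lmz))
  pairs$d <- abs(qmz[pairs$qi] - lmz[pairs$li])
  pairs[pairs$d <= tol_da, , drop = FALSE]
}
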