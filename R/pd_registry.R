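#' Build a permitted-dose registry
#'
#' A permitted dose (PD) is the chronic daily oral dose of a chemical below
#' which non-carcinogenic effects are not expected — a reference dose (RfD),
#' population adjusted dose (PAD), minimal risk level (MRL), tolerable daily
#' intake (TDI), acceptable daily intake (ADI), a value backed out of a
#' maximum contaminant level (MCL), or a dose derived from an inhalation
#' reference concentration. The registry pairs one PD per chemical with a
#' metabolite-to-parent map: a metabolite with no PD of its own is assumed to
#' carry the toxicity of its parent compound, so lookups fall back to the
#' parent's record.
#'
#' @param records Data frame with columns `chemical`, `pd` (mg/kg/day),
#'   `source_code` (integer provenance key) and `basis` (one of RfD, PAD,
#'   MRL, MCL, TDI, ADI, derived).
#' @param parent_map Optional data frame with columns `metabolite` and
#'   `parent`; every parent must resolve to a record.
#' @param pd_warn_ceiling Plausibility ceiling in mg/kg/day; records with a
#'   larger PD are kept verbatim but reported through a warning so that
#'   transcription anomalies in published dose tables surface instead of
#'   being silently corrected. Use `Inf` to disable.
#' @return An object of class `pd_registry`.
#' @seealso [default_pd_registry()], [read_pd_table()], [lookup_pd()]
#' @examples
#' reg <- pd_registry(
#'   tibble::tibble(
#'     chemical = c("Arsenic", "Atrazine"),
#'     pd = c(3e-4, 1.9e-3), source_code = c(1L, 2L), basis = "RfD"
#'   ),
#'   parent_map = tibble::tibble(metabolite = "Deethylatrazine", parent = "Atrazine")
#' )
#' lookup_pd(reg, c("arsenic", "Deethylatrazine", "Calcium"))
#' @export
pd_registry <- function(records, parent_map = NULL, pd_warn_ceiling = 10) {
  records <- as_tibble(records)
  required <- c("chemical", "pd", "source_code", "basis")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    abort_format(paste0(
      "PD table is missing column(s): ", paste(missing_cols, collapse = ", ")
    ))
  }
  records <- records[required]
  records$chemical <- as.character(records$chemical)
  if (!is.numeric(records$pd) || anyNA(records$pd)) {
    abort_validation("All permitted doses must be numeric and non-missing.")
  }
  if (any(records$pd <= 0)) {
    bad <- records$chemical[records$pd <= 0]
    abort_validation(paste0(
      "Permitted doses must be strictly positive; offending chemical(s): ",
      paste(bad, collapse = ", ")
    ))
  }
  allowed_basis <- c("RfD", "PAD", "MRL", "MCL", "TDI", "ADI", "derived")
  if (!all(records$basis %in% allowed_basis)) {
    abort_validation(paste0(
      "`basis` must be one of ", paste(allowed_basis, collapse = ", "), "."
    ))
  }
  key <- normalize_chemical(records$chemical)
  if (anyDuplicated(key)) {
    dups <- unique(records$chemical[duplicated(key) | duplicated(key, fromLast = TRUE)])
    abort_validation(paste0(
      "Duplicate chemical name(s) in PD table: ", paste(dups, collapse = ", ")
    ))
  }
  records$key <- key

  if (is.null(parent_map)) {
    parent_map <- tibble(metabolite = character(), parent = character())
  }
  parent_map <- as_tibble(parent_map)
  if (!all(c("metabolite", "parent") %in% names(parent_map))) {
    abort_format("Parent map must have columns `metabolite` and `parent`.")
  }
  parent_map <- parent_map[c("metabolite", "parent")]
  parent_map$metabolite_key <- normalize_chemical(parent_map$metabolite)
  parent_map$parent_key <- normalize_chemical(parent_map$parent)
  unresolved <- setdiff(parent_map$parent_key, records$key)
  if (length(unresolved) > 0) {
    bad <- unique(parent_map$parent[parent_map$parent_key %in% unresolved])
    abort_validation(paste0(
      "Parent map targets without a PD record: ", paste(bad, collapse = ", ")
    ))
  }

  flagged <- records[records$pd > pd_warn_ceiling, c("chemical", "pd")]
  if (nrow(flagged) > 0) {
    warn(
      paste0(
        "PD value(s) above the plausibility ceiling of ", pd_warn_ceiling,
        " mg/kg/day (kept as supplied): ",
        paste(sprintf("%s = %g", flagged$chemical, flagged$pd), collapse = ", ")
      ),
      class = "mcrscreen_pd_plausibility"
    )
  }

  structure(
    list(records = records, parent_map = parent_map, flagged = flagged),
    class = "pd_registry"
  )
}

#' Read a permitted-dose table from CSV
#'
#' Expects a UTF-8 CSV with header
#' `chemical,pd_mg_per_kg_day,source_code,basis`; the optional parent map is
#' a CSV with header `metabolite,parent`.
#'
#' @param path Path to the PD table CSV.
#' @param parent_map_path Optional path to a metabolite-to-parent CSV.
#' @inheritParams pd_registry
#' @return A `pd_registry`.
#' @export
read_pd_table <- function(path, parent_map_path = NULL, pd_warn_ceiling = 10) {
  if (!file.exists(path)) {
    abort_format(paste0("PD table not found: ", path))
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  if (!"pd_mg_per_kg_day" %in% names(raw)) {
    abort_format("PD table must have a `pd_mg_per_kg_day` column.")
  }
  pd_num <- suppressWarnings(as.numeric(raw$pd_mg_per_kg_day))
  if (nrow(raw) > 0 && anyNA(pd_num)) {
    abort_validation("Non-numeric permitted dose(s) in PD table.")
  }
  records <- tibble(
    chemical = raw$chemical %||% character(),
    pd = pd_num,
    source_code = suppressWarnings(as.integer(raw$source_code)),
    basis = raw$basis
  )
  parent_map <- NULL
  if (!is.null(parent_map_path)) {
    if (!file.exists(parent_map_path)) {
      abort_format(paste0("Parent map not found: ", parent_map_path))
    }
    parent_map <- readr::read_csv(
      parent_map_path,
      col_types = readr::cols(.default = readr::col_character())
    )
  }
  pd_registry(records, parent_map = parent_map, pd_warn_ceiling = pd_warn_ceiling)
}

#' Write a permitted-dose registry back to CSV
#'
#' Inverse of [read_pd_table()]: writing and re-reading reproduces the
#' registry records exactly.
#'
#' @param registry A `pd_registry`.
#' @param path Output CSV path for the records.
#' @param parent_map_path Optional output path for the parent map.
#' @return `path`, invisibly.
#' @export
write_pd_table <- function(registry, path, parent_map_path = NULL) {
  stopifnot(inherits(registry, "pd_registry"))
  out <- registry$records
  readr::write_csv(
    tibble(
      chemical = out$chemical,
      pd_mg_per_kg_day = out$pd,
      source_code = out$source_code,
      basis = out$basis
    ),
    path
  )
  if (!is.null(parent_map_path)) {
    readr::write_csv(registry$parent_map[c("metabolite", "parent")], parent_map_path)
  }
  invisible(path)
}

#' Packaged ground-water permitted-dose registry
#'
#' Loads the permitted-dose table shipped with the package (115 chemicals:
#' major ions, trace elements, pesticides and their degradates, and volatile
#' organics, each with its provenance source code and basis) together with
#' the packaged metabolite-to-parent map. Two entries (fluoride at 60 and
#' natural uranium at 30 mg/kg/day) exceed the default plausibility ceiling
#' and are reported through a warning; they are reproduced as published, not
#' corrected.
#'
#' @inheritParams pd_registry
#' @param quiet If `TRUE`, suppress the plausibility warning.
#' @return A `pd_registry`.
#' @export
default_pd_registry <- function(pd_warn_ceiling = 10, quiet = FALSE) {
  load <- function() {
    read_pd_table(
      system.file("extdata", "pd_table.csv", package = "mcrscreen", mustWork = TRUE),
      parent_map_path = system.file(
        "extdata", "parent_map.csv",
        package = "mcrscreen", mustWork = TRUE
      ),
      pd_warn_ceiling = pd_warn_ceiling
    )
  }
  if (quiet) suppressWarnings(load()) else load()
}

#' Look up permitted doses, falling back to parent compounds
#'
#' Resolution order: a chemical's own record first; failing that, the record
#' of its parent compound if the registry's metabolite map names one
#' (metabolites are assumed to carry the parent's toxicity); otherwise a
#' "no PD" outcome — a row with `pd = NA` and `match = "none"`. Absence of a
#' PD is a modelled outcome, not an error: such chemicals simply contribute
#' nothing to a hazard index.
#'
#' @param registry A `pd_registry`.
#' @param chemical Character vector of chemical names (matching is
#'   normalisation-insensitive, see [normalize_chemical()]).
#' @return A tibble with one row per requested name: `chemical`, `pd`,
#'   `source_code`, `basis`, `match` (`"direct"`, `"parent"` or `"none"`)
#'   and `matched_record` (the record's chemical name, `NA` for none).
#' @export
lookup_pd <- function(registry, chemical) {
  stopifnot(inherits(registry, "pd_registry"))
  key <- normalize_chemical(chemical)
  rec <- registry$records
  idx <- match(key, rec$key)
  match_type <- ifelse(is.na(idx), "none", "direct")
  pm <- registry$parent_map
  via_parent <- is.na(idx) & key %in% pm$metabolite_key
  if (any(via_parent)) {
    parent_key <- pm$parent_key[match(key[via_parent], pm$metabolite_key)]
    idx[via_parent] <- match(parent_key, rec$key)
    match_type[via_parent] <- "parent"
  }
  tibble(
    chemical = as.character(chemical),
    pd = rec$pd[idx],
    source_code = rec$source_code[idx],
    basis = rec$basis[idx],
    match = match_type,
    matched_record = rec$chemical[idx]
  )
}

#' Convert an inhalation reference concentration to an oral permitted dose
#'
#' Screening-level route extrapolation for a chemical with an inhalation
#' reference concentration (RfC) but no oral reference dose: the inhaled air
#' volume times the fraction cleared through the lung, scaled by body
#' weight,
#' \deqn{PD = RfC \times BR \times f_{clear} / BW.}
#' The default assumptions (20 m3/day breathed, 40% lung clearance, 60 kg
#' body weight) give `0.09 * 20 * 0.4 / 60 = 0.012` mg/kg/day for an RfC of
#' 0.09 mg/m3. The value is returned unrounded; rounding for presentation in
#' a dose table is the caller's choice.
#'
#' @param rfc Inhalation reference concentration, mg/m3.
#' @param breathing_rate Air volume breathed, m3/day.
#' @param clearance_fraction Fraction of the inhaled chemical cleared through
#'   the lung, in `[0, 1]`.
#' @param body_weight Body weight, kg (must be positive).
#' @return Oral-equivalent permitted dose, mg/kg/day.
#' @examples
#' rfc_to_oral_pd(0.09) # 0.012
#' @export
rfc_to_oral_pd <- function(rfc, breathing_rate = 20, clearance_fraction = 0.4,
                           body_weight = 60) {
  check_number(rfc, "rfc", lower = 0)
  check_number(breathing_rate, "breathing_rate", lower = 0)
  check_number(clearance_fraction, "clearance_fraction", lower = 0)
  if (any(clearance_fraction > 1)) {
    abort_domain("`clearance_fraction` must lie in [0, 1].")
  }
  check_number(body_weight, "body_weight", lower = 0, allow_zero = FALSE)
  rfc * breathing_rate * clearance_fraction / body_weight
}

#' @export
print.pd_registry <- function(x, ...) {
  cat(
    "<pd_registry> ", nrow(x$records), " chemicals, ",
    nrow(x$parent_map), " metabolite-parent mappings\n",
    sep = ""
  )
  if (nrow(x$flagged) > 0) {
    cat(
      "  flagged (above plausibility ceiling): ",
      paste(x$flagged$chemical, collapse = ", "), "\n",
      sep = ""
    )
  }
  invisible(x)
}

#' @describeIn pd_registry Tidy the registry records into a tibble.
#' @param x A `pd_registry`.
#' @param ... Unused.
#' @export
tidy.pd_registry <- function(x, ...) {
  x$records[c("chemical", "pd", "source_code", "basis")]
}
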