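# JSON sensor-parameter database: load, validate, save; a reconstructed
# database of published sensors ships with the package.

.record_fields <- c("name", "kind", "R_A", "R_B", "delta2")

.sensor_from_record <- function(rec, where = "record") {
  for (f in .record_fields)
    if (is.null(rec[[f]]))
      stop(sprintf("%s: missing required field '%s'", where, f), call. = FALSE)
  kind <- rec$kind
  if (!kind %in% c("redox", "pH", "ligand"))
    stop(sprintf("%s: field 'kind' must be redox|pH|ligand, got '%s'", where, kind),
         call. = FALSE)
  const_field <- switch(kind, redox = "e0_mv", pH = "pKa", ligand = "pKd")
  if (is.null(rec[[const_field]]))
    stop(sprintf("%s: a '%s' sensor requires field '%s'", where, kind, const_field),
         call. = FALSE)
  tryCatch(
    switch(kind,
      redox = biosensor(rec$name, "redox",
                        R_A = rec$R_A, R_B = rec$R_B, delta2 = rec$delta2,
                        e0 = rec$e0_mv,
                        z = if (is.null(rec$z)) 2L else rec$z,
                        temperature = if (is.null(rec$temperature_K)) 298.15 else rec$temperature_K),
      pH = biosensor(rec$name, "pH",
                     R_A = rec$R_A, R_B = rec$R_B, delta2 = rec$delta2, pKa = rec$pKa),
      ligand = biosensor(rec$name, "ligand",
                         R_A = rec$R_A, R_B = rec$R_B, delta2 = rec$delta2, pKd = rec$pKd)),
    error = function(e) stop(sprintf("%s: %s", where, conditionMessage(e)), call. = FALSE))
}

#' Load a sensor database from JSON
#'
#' The file holds a JSON array of records with fields `name`, `kind`
#' (`redox|pH|ligand`), `R_A`, `R_B`, `delta2`, the kind's chemistry constant
#' (`e0_mv`, `pKa` or `pKd`), optional `z` and `temperature_K` (redox), and an
#' optional free-text `note` documenting provenance. Every record is
#' validated through [biosensor()]; duplicate names are rejected.
#'
#' @param path Path to the JSON file.
#' @return Named list of [biosensor()]s (names = sensor names). Each sensor
#'   carries its `note` as the attribute `"note"`.
#' @export
load_sensor_db <- function(path) {
  recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.list(recs)) stop("sensor database must be a JSON array of records", call. = FALSE)
  sensors <- lapply(seq_along(recs), function(i) {
    rec <- recs[[i]]
    nm <- if (is.null(rec$name)) sprintf("#%d", i) else rec$name
    s <- .sensor_from_record(rec, where = sprintf("record %d ('%s')", i, nm))
    attr(s, "note") <- if (is.null(rec$note)) NA_character_ else rec$note
    s
  })
  nms <- vapply(sensors, function(s) s$name, character(1))
  dup <- nms[duplicated(nms)]
  if (length(dup)) stop("duplicate sensor names in database: ",
                        paste(unique(dup), collapse = ", "), call. = FALSE)
  stats::setNames(sensors, nms)
}

#' Save a sensor database to JSON
#'
#' Inverse of [load_sensor_db()]; a save/load round trip reproduces every
#' sensor exactly.
#'
#' @param sensors List of [biosensor()]s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_sensor_db <- function(sensors, path) {
  if (inherits(sensors, "biosensor")) sensors <- list(sensors)
  recs <- lapply(sensors, function(s) {
    stopifnot(inherits(s, "biosensor"))
    rec <- list(name = s$name, kind = s$kind,
                R_A = s$factors$R_A, R_B = s$factors$R_B, delta2 = s$factors$delta2)
    rec <- switch(s$kind,
      redox = c(rec, list(e0_mv = s$chemistry$e0, z = s$chemistry$z,
                          temperature_K = s$chemistry$temperature)),
      pH = c(rec, list(pKa = s$chemistry$pKa)),
      ligand = c(rec, list(pKd = s$chemistry$pKd)))
    note <- attr(s, "note")
    if (!is.null(note) && !is.na(note)) rec$note <- note
    rec
  })
  jsonlite::write_json(unname(recs), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Bundled sensor database
#'
#' Loads the database shipped with the package
#' (`extdata/sensor_db_synthetic.json`): eleven glutathione-redox (roGFP
#' family) sensors plus pH and ligand (NADH, NADPH, histidine) sensors. The
#' midpoint potentials, pKa and Kd values come from the primary biosensor
#' literature; the ratio endpoints and second-band dynamic ranges are
#' reconstructed representative values (hence the `synthetic` label), since
#' microscope-specific conversion factors are instrument dependent. Each
#' record carries a provenance note. Treat the database as a worked example
#' and starting point, not as a calibration of any particular microscope.
#'
#' @param kind Optional filter: `"redox"`, `"pH"` or `"ligand"`.
#' @return Named list of [biosensor()]s.
#' @export
sensor_db <- function(kind = NULL) {
  path <- system.file("extdata", "sensor_db_synthetic.json", package = "sensorspan")
  sensors <- load_sensor_db(path)
  if (!is.null(kind)) sensors <- Filter(function(s) identical(s$kind, kind), sensors)
  sensors
}
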