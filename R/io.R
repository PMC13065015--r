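# Register bundle I/O: one CSV per register plus a JSON sidecar with the
# generating configuration, so user-supplied registers with the same
# schemas can enter the pipeline.

REGISTER_TABLES <- c("persons", "addresses", "diagnoses", "dispensations",
                     "vitals", "parent_diagnoses", "parent_dispensations",
                     "latent", "biomarkers")

#' Write a register bundle to a directory of CSV files
#'
#' @param bundle a `register_bundle`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_registers <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tb in REGISTER_TABLES) {
    if (is.null(bundle[[tb]])) next
    utils::write.csv(bundle[[tb]], file.path(dir, paste0(tb, ".csv")),
                     row.names = FALSE)
  }
  cfg <- bundle$config
  cfg$admin_end <- as.character(cfg$admin_end)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a register bundle from a directory of CSV files
#'
#' @param dir directory written by [write_registers()] (or user-supplied
#'   CSVs with the same column schemas)
#' @return a `register_bundle`
#' @export
read_registers <- function(dir) {
  cfgfile <- file.path(dir, "config.json")
  cfg <- if (file.exists(cfgfile)) {
    raw <- jsonlite::fromJSON(cfgfile)
    keep <- intersect(names(raw), names(formals(sim_config)))
    do.call(sim_config, raw[keep])
  } else sim_config()
  b <- empty_bundle(cfg)
  datecols <- c(persons = "birth_date", diagnoses = "event_date",
                dispensations = "dispense_date", vitals = "event_date",
                parent_diagnoses = "event_date",
                parent_dispensations = "dispense_date")
  for (tb in REGISTER_TABLES) {
    f <- file.path(dir, paste0(tb, ".csv"))
    if (!file.exists(f)) next
    df <- utils::read.csv(f, stringsAsFactors = FALSE)
    if (tb %in% names(datecols) && nrow(df))
      df[[datecols[tb]]] <- as.Date(df[[datecols[tb]]])
    b[[tb]] <- df
  }
  b
}
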