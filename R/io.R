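# Delimited-text schemas shared by the generator, the readers and the
# pipeline outputs. One row per measurement, keyed by station/depth/vessel.

fjordfe_schemas <- list(
  dissolution = c("station", "depth_top", "thickness", "extraction", "vessel",
                  "is_control", "time_s", "conc_uM", "dry_mass_g", "volume_l"),
  hcl = c("station", "depth_top", "step", "fe2", "fe_total"),
  tracer = c("station", "depth_top", "thickness", "sulfate_mM", "porosity",
             "a_tris", "a_so4", "t_days"),
  stations = c("station", "distance_km")
)

check_schema <- function(df, kind, file = "<in-memory>") {
  need <- fjordfe_schemas[[kind]]
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop(sprintf("schema error in %s (%s table): missing column(s) %s",
                 file, kind, paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  num_cols <- setdiff(need, c("station", "extraction", "vessel", "step",
                              "is_control"))
  for (cl in num_cols) {
    if (!is.numeric(df[[cl]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[cl]]))) &
                     !is.na(df[[cl]]))
      stop(sprintf("schema error in %s: column '%s' is not numeric (row %s)",
                   file, cl, if (length(bad)) bad[1] else "?"), call. = FALSE)
    }
  }
  invisible(df)
}

read_table_checked <- function(path, kind) {
  if (!file.exists(path)) {
    stop("schema error: input file not found: ", path, call. = FALSE)
  }
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_schema(df, kind, file = path)
  df
}

#' Read pipeline input tables
#'
#' Tab-separated readers for the four input schemas. Column sets are
#' validated up front; a missing or non-numeric column raises a schema error
#' naming the file and column.
#'
#' @param path Path to a tab-separated file.
#' @return A tibble.
#' @name readers
NULL

#' @rdname readers
#' @export
read_dissolution_table <- function(path) read_table_checked(path, "dissolution")

#' @rdname readers
#' @export
read_hcl_table <- function(path) read_table_checked(path, "hcl")

#' @rdname readers
#' @export
read_tracer_table <- function(path) read_table_checked(path, "tracer")

#' @rdname readers
#' @export
read_station_table <- function(path) read_table_checked(path, "stations")

#' Write a simulated bundle as pipeline input files
#'
#' Writes the four input tables of a [simulate_transect] bundle (and the
#' truth ledger, for reference) as tab-separated files into `dir`.
#'
#' @param bundle A `fjordfe_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "fjordfe_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(bundle$dissolution, file.path(dir, "dissolution.tsv"))
  readr::write_tsv(bundle$hcl, file.path(dir, "hcl.tsv"))
  readr::write_tsv(bundle$tracer, file.path(dir, "tracer.tsv"))
  readr::write_tsv(bundle$stations, file.path(dir, "stations.tsv"))
  readr::write_tsv(bundle$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

read_bundle_dir <- function(dir) {
  list(
    stations = read_station_table(file.path(dir, "stations.tsv")),
    dissolution = read_dissolution_table(file.path(dir, "dissolution.tsv")),
    hcl = read_hcl_table(file.path(dir, "hcl.tsv")),
    tracer = read_tracer_table(file.path(dir, "tracer.tsv"))
  )
}
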