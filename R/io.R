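# CSV schemas. Column names carry their units as suffixes; readers
# validate names and types and refuse silently-mismatched files.

.schemas <- list(
  animal_days = c(cow_id = "character", block = "integer",
                  sequence = "character", period = "integer",
                  treatment = "character", day = "integer",
                  dmi_kg_d = "numeric", milk_kg_d = "numeric",
                  fat_pct = "numeric", protein_pct = "numeric",
                  lactose_pct = "numeric", bw_kg = "numeric",
                  water_l_d = "numeric"),
  excreta = c(cow_id = "character", period = "integer",
              treatment = "character", day = "integer",
              feces_fresh_kg = "numeric", feces_dm_fraction = "numeric",
              feces_n_g_per_kg_dm = "numeric",
              feces_ge_j_per_g_dm = "numeric",
              feces_ash_g_per_kg_dm = "numeric",
              urine_kg_d = "numeric", urine_n_g_per_kg = "numeric"),
  chamber_trace = c(time_h = "numeric", gas = "character",
                    inlet_fraction = "numeric",
                    outlet_fraction = "numeric",
                    airflow_m3_h = "numeric", chamber_id = "character")
)

#' Read and validate a pipeline CSV
#'
#' Reads a UTF-8, dot-decimal CSV and validates it against one of the
#' pipeline schemas (or a user-supplied one): missing columns, unexpected
#' columns and untypeable values are reported by name.
#'
#' @param path File path.
#' @param schema Either the name of a built-in schema (`"animal_days"`,
#'   `"excreta"`, `"chamber_trace"`) or a named character vector of
#'   column -> type (`"character"`, `"integer"`, `"numeric"`).
#' @return A validated data frame.
#' @export
read_table <- function(path, schema) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.character(schema) && length(schema) == 1L) {
    schema <- .schemas[[schema]]
    if (is.null(schema)) stop("unknown schema name", call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  if (nrow(df) == 0L) stop("no records in ", path, call. = FALSE)
  missing <- setdiff(names(schema), names(df))
  extra <- setdiff(names(df), names(schema))
  if (length(missing) || length(extra)) {
    stop("schema mismatch in ", path,
         if (length(missing)) paste0("; missing: ",
                                     paste(missing, collapse = ", ")),
         if (length(extra)) paste0("; unexpected: ",
                                   paste(extra, collapse = ", ")),
         call. = FALSE)
  }
  bad <- character(0)
  for (nm in names(schema)) {
    suppressWarnings(conv <- switch(schema[[nm]],
                                    character = as.character(df[[nm]]),
                                    integer = as.integer(df[[nm]]),
                                    numeric = as.numeric(df[[nm]])))
    if (anyNA(conv) && !anyNA(df[[nm]])) bad <- c(bad, nm)
    df[[nm]] <- conv
  }
  if (length(bad)) {
    stop("unparseable values in column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  df[names(schema)]
}

#' Write a pipeline CSV
#'
#' UTF-8, dot-decimal, no row names; the inverse of [read_table()]
#' (round-trip content-identical up to numeric printing).
#'
#' @param df Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a chamber trace in long CSV form
#'
#' @param trace A [chamber_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chamber_trace <- function(trace, path) {
  stopifnot(inherits(trace, "chamber_trace"))
  long <- do.call(rbind, lapply(c("o2", "co2", "ch4"), function(g) {
    data.frame(time_h = trace$time_h, gas = g,
               inlet_fraction = trace[[paste0(g, "_in")]],
               outlet_fraction = trace[[paste0(g, "_out")]],
               airflow_m3_h = trace$airflow_m3_h,
               chamber_id = trace$chamber_id,
               stringsAsFactors = FALSE)
  }))
  write_table(long, path)
}

#' Read a chamber trace from long CSV form
#'
#' @param path File path (schema `chamber_trace`).
#' @param recovery Chamber recovery rate to attach (default 0.997).
#' @return A [chamber_trace()].
#' @export
read_chamber_trace <- function(path, recovery = 0.997) {
  long <- read_table(path, "chamber_trace")
  gases <- split(long, long$gas)
  if (!all(c("o2", "co2", "ch4") %in% names(gases))) {
    stop("trace must contain gases o2, co2, ch4", call. = FALSE)
  }
  tt <- sort(unique(long$time_h))
  pick <- function(g, col) {
    gg <- gases[[g]][order(gases[[g]]$time_h), ]
    if (!identical(gg$time_h, tt)) {
      stop("gases sampled on different time grids", call. = FALSE)
    }
    gg[[col]]
  }
  chamber_trace(tt,
                o2_in = pick("o2", "inlet_fraction"),
                o2_out = pick("o2", "outlet_fraction"),
                co2_in = pick("co2", "inlet_fraction"),
                co2_out = pick("co2", "outlet_fraction"),
                ch4_in = pick("ch4", "inlet_fraction"),
                ch4_out = pick("ch4", "outlet_fraction"),
                airflow_m3_h = long$airflow_m3_h[1],
                recovery = recovery,
                chamber_id = long$chamber_id[1])
}
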