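#' Read and validate a per-cell mRNA count table
#'
#' CSV dialect: comma-separated, header row, UTF-8, '.' decimal. Required
#' columns: `clone_id`, `condition`, `cell_id`, `mrna_count`. Rows with
#' missing, negative or non-integer counts are rejected with their line
#' numbers.
#'
#' @param path path to a CSV file.
#' @return A validated data.frame (a CellCountTable).
#' @export
read_count_table <- function(path) {
  tbl <- .read_csv_checked(path, c("clone_id", "condition", "cell_id",
                                   "mrna_count"))
  cnt <- suppressWarnings(as.numeric(tbl$mrna_count))
  bad <- which(is.na(cnt) | cnt < 0 | cnt != floor(cnt))
  if (length(bad))
    stop("invalid mrna_count (missing, negative or non-integer) at line(s): ",
         paste(bad + 1L, collapse = ", "), call. = FALSE)
  tbl$mrna_count <- as.integer(cnt)
  tbl
}

#' Read and validate a flow-cytometry event table
#'
#' Required columns: `clone_id`, `condition`, `event_id`, `fsc`, `ssc`,
#' `mesf`; all three measurement channels must be non-negative numbers.
#'
#' @param path path to a CSV file.
#' @return A validated data.frame (a FlowEventTable).
#' @export
read_flow_table <- function(path) {
  tbl <- .read_csv_checked(path, c("clone_id", "condition", "event_id",
                                   "fsc", "ssc", "mesf"))
  for (col in c("fsc", "ssc", "mesf")) {
    v <- suppressWarnings(as.numeric(tbl[[col]]))
    bad <- which(is.na(v) | v < 0)
    if (length(bad))
      stop("invalid ", col, " at line(s): ",
           paste(bad + 1L, collapse = ", "), call. = FALSE)
    tbl[[col]] <- v
  }
  tbl
}

.read_csv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  if (nrow(tbl) == 0)
    stop("empty table: ", path, call. = FALSE)
  missing <- setdiff(required, names(tbl))
  if (length(missing))
    stop("missing column(s) in ", path, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  tbl
}

#' Write interchange CSV tables
#'
#' Writers for the package's tables (counts, flow events, population
#' summaries, burst estimates, manifold curves). Fixed dialect: comma,
#' header row, UTF-8, '.' decimal, no row names; floating-point values are
#' written with 9 significant digits for reproducible diffs. The flow
#' writer keeps only the schema columns (`clone_id`, `condition`,
#' `event_id`, `fsc`, `ssc`, `mesf`), dropping any generator ground-truth
#' columns.
#'
#' @param tbl the table to write.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_count_table <- function(tbl, path) {
  .write_csv(tbl[, c("clone_id", "condition", "cell_id", "mrna_count")], path)
}

#' @rdname write_count_table
#' @export
write_flow_table <- function(tbl, path) {
  .write_csv(tbl[, c("clone_id", "condition", "event_id",
                     "fsc", "ssc", "mesf")], path)
}

#' @rdname write_count_table
#' @export
write_table_csv <- function(tbl, path) .write_csv(tbl, path)

.write_csv <- function(tbl, path) {
  num <- vapply(tbl, is.double, logical(1))
  tbl[num] <- lapply(tbl[num], function(x) signif(x, 9))
  utils::write.csv(tbl, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a run configuration (YAML or JSON)
#'
#' Accepts a YAML or JSON file with optional blocks `panel` (arguments of
#' [clone_panel_config()]), `perturbation` ([perturbation_config()]),
#' and scalar options `seed`, `gate_n`, `grid_max`, `units`.
#'
#' @param path configuration file; format chosen by extension
#'   (`.json` vs `.yaml`/`.yml`).
#' @return A list with elements `panel`, `perturbation`, `seed`, `gate_n`,
#'   `grid_max`, `units`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path) else yaml::read_yaml(path)
  panel_args <- as.list(raw$panel %||% list())
  if (!is.null(raw$seed) && is.null(panel_args$seed))
    panel_args$seed <- raw$seed
  pert_args <- as.list(raw$perturbation %||% list())
  list(panel = do.call(clone_panel_config, panel_args),
       perturbation = do.call(perturbation_config, pert_args),
       seed = as.integer(raw$seed %||% panel_args$seed %||% 1L),
       gate_n = raw$gate_n %||% 3000,
       grid_max = raw$grid_max %||% 12,
       units = raw$units %||% "fish")
}

# Rolling polynomial hash of a serialized object; used only to stamp run
# logs so a report can be matched to the configuration that produced it.
.config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483629
  sprintf("%08x", as.integer(h))
}
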