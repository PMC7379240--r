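## Table schemas for the TSV interchange format. Every stage reads and
## writes tab-separated tables with a one-line header and '#' provenance
## comments, so stages stay decoupled from one another.

socialfly_schemas <- list(
  detections = c("frame_index", "centroid_x", "centroid_y", "major_axis",
                 "minor_axis", "orientation", "area_px", "on_food",
                 "near_food", "paint", "merged_flag"),
  aggregation = c("time_min", "n_on", "n_near", "total_in_chamber",
                  "replicate_id"),
  scene_truth = c("frame_index", "time_min", "id", "x", "y", "body_major",
                  "body_minor", "orientation", "paint", "on_food"),
  aggression = c("fly_label", "condition", "lunges_150s",
                 "density_at_arrival"),
  ortholog_map = c("reference_gene_id", "species", "species_gene_id"),
  de_records = c("gene_id", "log2fc", "padj"),
  expression = "gene_id",
  sweep = c("density", "condition", "mean_t40", "sd_t40", "n_defined",
            "n_runs")
)

#' Read a pipeline TSV table with schema validation
#'
#' Reads a tab-separated table (skipping `#` provenance comments) and, when
#' a schema name is given, validates that every required column is present,
#' raising a schema error that names the missing columns. An empty file
#' with a valid header is an empty table, not an error.
#'
#' @param path Path to a TSV file.
#' @param schema Optional schema name, one of
#'   `r paste(names(socialfly_schemas), collapse = ", ")`.
#' @return A tibble.
#' @export
read_table <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tbl <- utils::read.delim(path, comment.char = "#", sep = "\t",
                           stringsAsFactors = FALSE)
  tbl <- tibble::as_tibble(tbl)
  if (!is.null(schema)) {
    schema <- match.arg(schema, names(socialfly_schemas))
    required <- socialfly_schemas[[schema]]
    missing <- setdiff(required, names(tbl))
    if (length(missing)) {
      stop(structure(
        class = c("socialfly_schema_error", "error", "condition"),
        list(message = sprintf("table '%s' does not match schema '%s': missing column(s) %s",
                               path, schema, paste(missing, collapse = ", ")),
             call = NULL)))
    }
  }
  ## logical columns survive the round trip as "TRUE"/"FALSE" strings when
  ## the table was empty or mixed; normalize
  for (cn in names(tbl)) {
    if (is.character(tbl[[cn]]) && length(tbl[[cn]]) > 0 &&
        all(tbl[[cn]] %in% c("TRUE", "FALSE", "NA"))) {
      tbl[[cn]] <- as.logical(tbl[[cn]])
    }
  }
  tbl
}

#' Write a pipeline TSV table with a provenance header
#'
#' Writes tab-separated values preceded by `#` comment lines recording the
#' tool version and a hash of the run configuration, so any output table
#' can be traced to the configuration that produced it. No timestamps are
#' written: two runs from the same configuration produce byte-identical
#' files. Floating-point columns are serialized with 6 significant digits
#' by default; pass `digits = NA` for full precision.
#'
#' @param table A data frame or tibble.
#' @param path Output path (parent directory must exist).
#' @param config Optional configuration list hashed into the header.
#' @param digits Significant digits for numeric columns (default 6; `NA`
#'   keeps full precision).
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path, config = NULL, digits = 6) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("parent directory does not exist: ", dir,
                             call. = FALSE)
  tbl <- as.data.frame(table)
  for (cn in names(tbl)) {
    if (is.numeric(tbl[[cn]]) && !is.integer(tbl[[cn]])) {
      tbl[[cn]] <- if (is.na(digits)) {
        formatC(tbl[[cn]], digits = 17, format = "g")
      } else {
        formatC(signif(tbl[[cn]], digits), digits = digits, format = "g")
      }
      tbl[[cn]][tbl[[cn]] %in% c("NA", " NA")] <- "NA"
    }
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    sprintf("# socialfly %s", as.character(utils::packageVersion("socialfly"))),
    sprintf("# config_hash %s", config_hash(config))
  ), con)
  utils::write.table(tbl, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Hash a run configuration
#'
#' MD5 digest of the canonical YAML serialization of a configuration list;
#' `"none"` for a `NULL` configuration. Used in provenance headers.
#'
#' @param config A list (or `NULL`).
#' @return A character scalar.
#' @export
config_hash <- function(config) {
  if (is.null(config)) return("none")
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(config), tmp)
  unname(tools::md5sum(tmp))
}

#' Read a run configuration file
#'
#' Accepts YAML or JSON (YAML being a superset, both parse through the
#' same reader). Returns a plain nested list.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` configuration file.
#' @return A list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  yaml::read_yaml(path)
}
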