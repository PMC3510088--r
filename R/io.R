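# Shared format readers/writers and run configuration.

#' Read a FASTA file
#'
#' Thin wrapper over `Biostrings::readDNAStringSet` that upper-cases
#' sequences and rejects duplicate record ids.
#'
#' @param path FASTA file path.
#' @return a `Biostrings::DNAStringSet`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  x <- tryCatch(Biostrings::readDNAStringSet(path),
                error = function(e)
                  stop("malformed FASTA '", path, "': ", conditionMessage(e),
                       call. = FALSE))
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x)))
    stop("duplicate FASTA ids: ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "),
         call. = FALSE)
  Biostrings::DNAStringSet(toupper(x))
}

#' Write sequences to FASTA
#' @param x a `Biostrings::DNAStringSet` or named character vector.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(x, path) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

# column types: "character", "numeric", "integer"
check_schema <- function(d, schema, path) {
  missing_cols <- setdiff(names(schema), names(d))
  if (length(missing_cols))
    stop("'", path, "' lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (col in names(schema)) {
    v <- d[[col]]
    if (schema[[col]] %in% c("numeric", "integer")) {
      if (is.character(v)) {
        v[v %in% c("NA", "")] <- NA
        conv <- suppressWarnings(as.numeric(v))
        bad <- which(is.na(conv) & !is.na(v))
        if (length(bad))
          stop(sprintf("'%s': non-numeric value '%s' in column '%s', row %d",
                       path, v[bad[1]], col, bad[1]), call. = FALSE)
        v <- conv
      }
      if (schema[[col]] == "integer") v <- as.integer(v)
      d[[col]] <- v
    } else {
      d[[col]] <- as.character(v)
    }
  }
  d
}

#' Read a TSV table against a named schema
#'
#' @param path TSV path (header required, `NA` as missing token).
#' @param schema named character vector mapping required column names to
#'   types (`"character"`, `"numeric"`, `"integer"`). Extra columns are
#'   kept as read.
#' @return validated data.frame.
#' @export
read_table <- function(path, schema) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  d <- utils::read.delim(path, sep = "\t", header = TRUE,
                         colClasses = "character",
                         na.strings = "NA", check.names = FALSE,
                         stringsAsFactors = FALSE)
  check_schema(d, as.list(schema), path)
}

#' Write a TSV table
#' @param d data.frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_table <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

# schemas of the tabular dialects
SCHEMA_PLATE <- c(sample_id = "character", condition = "character",
                  target = "character", replicate = "integer",
                  ct = "numeric")
SCHEMA_STANDARDS <- c(target = "character", copies = "numeric",
                      ct = "numeric")
SCHEMA_SPOTS <- c(slide_id = "character", subarray = "integer",
                  capture_id = "character", spot_replicate = "integer",
                  channel = "character", signal = "numeric",
                  background = "numeric")
SCHEMA_LAYOUT <- c(subarray = "integer", row = "integer", col = "integer",
                   capture_id = "character")
SCHEMA_SAMPLES <- c(slide_id = "character", subarray = "integer",
                    channel = "character", sample_id = "character",
                    condition = "character")
SCHEMA_CATALOGUE <- c(tfbs_name = "character", tfbs_sequence = "character")

#' Readers for the package's tabular dialects
#'
#' `read_plate` reads qPCR Ct records (an optional `experiment` column is
#' typed when present), `read_standards` dilution series,
#' `read_spots`/`read_layout`/`read_samples` the microarray inputs, and
#' `read_catalogue` a TFBS catalogue.
#'
#' @param path TSV path.
#' @return validated data.frame.
#' @export
read_plate <- function(path) {
  d <- read_table(path, SCHEMA_PLATE)
  if ("experiment" %in% names(d))
    d <- check_schema(d, list(experiment = "integer"), path)
  d
}

#' @rdname read_plate
#' @export
read_standards <- function(path) read_table(path, SCHEMA_STANDARDS)

#' @rdname read_plate
#' @export
read_spots <- function(path) read_table(path, SCHEMA_SPOTS)

#' @rdname read_plate
#' @export
read_layout <- function(path) read_table(path, SCHEMA_LAYOUT)

#' @rdname read_plate
#' @export
read_samples <- function(path) read_table(path, SCHEMA_SAMPLES)

#' @rdname read_plate
#' @export
read_catalogue <- function(path) read_table(path, SCHEMA_CATALOGUE)

RUN_CONFIG_KEYS <- c("seed", "constraints", "model", "noise", "paths",
                     "log_level", "alpha", "basal_band", "efficiency_bounds")

#' Read and validate a YAML run configuration
#'
#' Accepted top-level keys: `seed`, `constraints` (passed to
#' [design_constraints()]), `model` (passed to [model_spec()]), `noise`
#' (passed to [synthetic_design()]), `paths`, `log_level`, `alpha`,
#' `basal_band`, `efficiency_bounds`. Unknown keys are rejected so typos
#' fail loudly before any stage runs.
#'
#' @param path YAML file path.
#' @return named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  unknown <- setdiff(names(cfg), RUN_CONFIG_KEYS)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg
}
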