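# Readers and writers for the plain-text interchange formats: counts TSV,
# sample-metadata CSV, GMT gene sets, apical-POD CSV.

#' Read a counts matrix from TSV
#'
#' Expects genes in rows and a header of sample ids; the first column holds
#' gene ids.
#'
#' @param path TSV file path.
#' @return Integer matrix with gene row names and sample column names.
#' @export
read_counts <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(df) < 2) abort("counts TSV needs a gene-id column plus samples")
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    abort(paste0("duplicate gene ids in counts: ",
                 paste(head(dup, 5), collapse = ", ")))
  }
  m <- as.matrix(df[, -1])
  if (anyNA(m)) abort("missing values in counts matrix")
  storage.mode(m) <- "integer"
  rownames(m) <- genes
  m
}

#' Write a counts matrix (or experiment) to TSV
#' @param x A [dr_experiment()] or a counts matrix with dimnames.
#' @param path Output TSV path.
#' @export
write_counts <- function(x, path) {
  counts <- if (inherits(x, "dr_experiment")) x$counts else x
  df <- tibble::as_tibble(counts, rownames = "gene_id")
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read per-sample metadata from CSV
#'
#' Requires columns `sample_id` and `dose`; an optional `batch` column carries
#' blocking labels.
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_sample_metadata <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("sample_id", "dose") %in% names(df))) {
    abort("sample metadata must contain columns `sample_id` and `dose`")
  }
  df$sample_id <- as.character(df$sample_id)
  df
}

#' Read a counts TSV and metadata CSV into an experiment
#'
#' @param counts_path,metadata_path File paths.
#' @param dose_units Unit label for the dose axis.
#' @return A [dr_experiment()]. Errors name any sample present in one file but
#'   not the other.
#' @export
read_experiment <- function(counts_path, metadata_path,
                            dose_units = "mg/Kg-bw/day") {
  counts <- read_counts(counts_path)
  samples <- read_sample_metadata(metadata_path)
  dr_experiment(counts, samples, dose_units)
}

#' Read gene sets from a GMT file
#'
#' Standard 3+-column tab-separated format: set id, description, then member
#' gene ids. Trailing tabs are tolerated; a duplicated gene within a set is
#' dropped with a warning naming the set and line.
#'
#' @param path GMT file path.
#' @return Named list of character vectors of member gene ids, with the
#'   descriptions in attribute `"descriptions"`.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  descs <- character()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    # strip trailing tabs only; an empty description field stays in place
    while (length(parts) > 0 && !nzchar(parts[length(parts)])) {
      parts <- parts[-length(parts)]
    }
    if (length(parts) < 3) {
      abort(paste0("GMT line ", i, ": need set id, description and at least ",
                   "one gene"))
    }
    id <- parts[1]
    genes <- parts[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warn(paste0("GMT line ", i, " (", id, "): duplicate gene ids ",
                  "deduplicated"))
      genes <- unique(genes)
    }
    if (id %in% names(sets)) {
      abort(paste0("GMT line ", i, ": duplicate set id ", id))
    }
    sets[[id]] <- genes
    descs[id] <- parts[2]
  }
  attr(sets, "descriptions") <- descs
  sets
}

#' Write gene sets to a GMT file
#' @param gene_sets Named list of member gene-id vectors.
#' @param path Output path.
#' @param descriptions Optional named descriptions (default `"na"`).
#' @export
write_gmt <- function(gene_sets, path, descriptions = NULL) {
  if (is.null(names(gene_sets))) abort("gene_sets must be a named list")
  descs <- descriptions %||% attr(gene_sets, "descriptions") %||%
    setNames(rep("na", length(gene_sets)), names(gene_sets))
  lines <- vapply(names(gene_sets), function(id) {
    paste(c(id, descs[[id]] %||% "na", gene_sets[[id]]), collapse = "\t")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read an apical point-of-departure table from CSV
#'
#' Expected columns: `chemical`, `species`, `endpoint_type` (one of NOAEL,
#' LOAEL, NOEC, LOEC), `value` (positive), `units`, and optionally
#' `study_duration` and `qualifier` (`"exact"` or `"less_than"` for values
#' printed as "< x"; default `"exact"`).
#'
#' @param path CSV file path.
#' @return A validated tibble of `ApodRecord` rows.
#' @export
read_apod <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("chemical", "species", "endpoint_type", "value", "units")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(paste0("APOD CSV missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  bad_type <- setdiff(unique(df$endpoint_type),
                      c("NOAEL", "LOAEL", "NOEC", "LOEC"))
  if (length(bad_type) > 0) {
    abort(paste0("unknown endpoint_type: ", paste(bad_type, collapse = ", ")))
  }
  if (any(df$value <= 0 | is.na(df$value))) {
    abort("APOD values must be positive")
  }
  if (!"qualifier" %in% names(df)) df$qualifier <- "exact"
  df$qualifier[is.na(df$qualifier)] <- "exact"
  bad_q <- setdiff(unique(df$qualifier), c("exact", "less_than"))
  if (length(bad_q) > 0) {
    abort(paste0("unknown qualifier: ", paste(bad_q, collapse = ", ")))
  }
  if (!"study_duration" %in% names(df)) df$study_duration <- NA_character_
  as_tibble(df)
}
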