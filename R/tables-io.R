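#' Read and validate a per-cell measurement table
#'
#' Reads a CSV of per-cell image-cytometry measurements (one row per measured
#' cell) and enforces the measurement conventions of intestine image
#' cytometry: rings are integers 1-9, intensities are non-negative numbers,
#' each cell is identified uniquely by (experiment, animal, ring, cell) and a
#' binucleate cell stores the average of its two nuclei (`nucleus_count` is 1
#' or 2). Rows violating row-level rules are rejected and listed, with their
#' file line numbers, in the parse report; structural problems (a missing
#' mandatory column, a duplicated cell key) are errors.
#'
#' @param path path to a CSV file with a header row.
#' @param config optional list mapping file columns to roles:
#'   `config$columns` is a named character vector renaming file columns to
#'   the canonical roles `experiment_id`, `animal_id`, `ring`, `cell_id`,
#'   `nucleus_count`; `config$channels` is a named character vector mapping
#'   canonical channel names to file columns. With `config = NULL` canonical
#'   names are assumed and every column starting with `ch_` is a channel.
#' @return data.frame of validated cells with canonical column names plus a
#'   logical `binucleate` flag; the parse report (`rows_read`, `rows_kept`,
#'   `rows_rejected`, `reasons` data.frame with `line` and `reason`) is
#'   attached as attribute `"parse_report"` and retrievable with
#'   [parse_report()].
#' @seealso [write_cells()], [summarize_per_animal()]
#' @examples
#' path <- system.file("extdata", "example_cells.csv",
#'                     package = "dualreporter")
#' cells <- read_cells(path)
#' parse_report(cells)$rows_kept
#' @export
read_cells <- function(path, config = NULL) {
  raw <- utils::read.csv(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  colmap <- c(experiment_id = "experiment_id", animal_id = "animal_id",
              ring = "ring", cell_id = "cell_id",
              nucleus_count = "nucleus_count")
  if (!is.null(config$columns)) {
    colmap[names(config$columns)] <- unlist(config$columns)
  }
  if (!is.null(config$channels)) {
    chanmap <- unlist(config$channels)
  } else {
    src <- grep("^ch_", names(raw), value = TRUE)
    chanmap <- stats::setNames(src, src)
  }
  if (length(chanmap) == 0L)
    stop("no intensity channel columns found")
  for (role in names(colmap)) {
    if (!colmap[[role]] %in% names(raw))
      stop("missing column: ", role)
  }
  missing_ch <- chanmap[!chanmap %in% names(raw)]
  if (length(missing_ch))
    stop("missing column: ", names(missing_ch)[1])

  n <- nrow(raw)
  cells <- data.frame(
    experiment_id = as.character(raw[[colmap["experiment_id"]]]),
    animal_id = as.character(raw[[colmap["animal_id"]]]),
    ring = suppressWarnings(as.integer(raw[[colmap["ring"]]])),
    cell_id = as.character(raw[[colmap["cell_id"]]]),
    nucleus_count = suppressWarnings(as.integer(raw[[colmap["nucleus_count"]]])),
    stringsAsFactors = FALSE
  )
  for (ch in names(chanmap)) {
    cells[[ch]] <- suppressWarnings(as.numeric(raw[[chanmap[[ch]]]]))
  }

  reason <- rep(NA_character_, n)
  flag <- function(bad, why) {
    bad <- bad & is.na(reason)
    reason[bad] <<- why
  }
  flag(is.na(cells$ring) | cells$ring < 1L | cells$ring > 9L,
       "ring must be an integer in 1..9")
  flag(is.na(cells$nucleus_count) | !cells$nucleus_count %in% c(1L, 2L),
       "nucleus_count must be 1 or 2")
  for (ch in names(chanmap)) {
    flag(is.na(cells[[ch]]), paste0("non-numeric intensity in ", ch))
    flag(!is.na(cells[[ch]]) & cells[[ch]] < 0,
         paste0("negative intensity in ", ch))
  }
  keep <- is.na(reason)
  # +1 for the header row: report file line numbers
  reasons <- data.frame(line = which(!keep) + 1L,
                        reason = reason[!keep],
                        stringsAsFactors = FALSE)
  cells <- cells[keep, , drop = FALSE]
  rownames(cells) <- NULL

  key <- paste(cells$experiment_id, cells$animal_id, cells$ring,
               cells$cell_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- cells[duplicated(key), c("experiment_id", "animal_id", "ring",
                                  "cell_id")][1, ]
    stop("duplicate cell key: ", paste(unlist(d), collapse = " / "))
  }
  cells$binucleate <- cells$nucleus_count == 2L
  attr(cells, "channels") <- names(chanmap)
  attr(cells, "parse_report") <- list(
    rows_read = n, rows_kept = nrow(cells),
    rows_rejected = n - nrow(cells), reasons = reasons
  )
  cells
}

#' Retrieve the parse report of a table read with [read_cells()]
#' @param cells a table returned by [read_cells()].
#' @return the parse report list, or `NULL` if none is attached.
#' @export
parse_report <- function(cells) attr(cells, "parse_report")

#' Write a per-cell table as CSV
#'
#' Writes the canonical cells CSV dialect (header row, UTF-8, no row names).
#' Reading the result back with [read_cells()] reproduces the table exactly.
#'
#' @param cells data.frame of cells.
#' @param path output path.
#' @param keep_truth keep `true_*` latent columns if present (default
#'   `FALSE`, producing a blind fixture).
#' @return `path`, invisibly.
#' @export
write_cells <- function(cells, path, keep_truth = FALSE) {
  df <- as.data.frame(cells)
  df$binucleate <- NULL
  if (!keep_truth) df <- df[, !grepl("^true_", names(df)), drop = FALSE]
  # full-precision intensities so that read(write(T)) == T exactly
  for (col in names(df))
    if (is.double(df[[col]])) df[[col]] <- sprintf("%.17g", df[[col]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Channel columns of a cells table
#'
#' @param cells a cells data.frame.
#' @return character vector of intensity column names, from the table's
#'   `"channels"` attribute when present, otherwise all columns starting
#'   with `ch_`.
#' @export
cell_channels <- function(cells) {
  ch <- attr(cells, "channels")
  if (is.null(ch)) ch <- grep("^ch_", names(cells), value = TRUE)
  ch
}

#' Summarize a per-cell table to one row per animal
#'
#' Per animal and channel, the unweighted mean intensity over that animal's
#' measured cells, with the number of cells recorded. Animal-level summaries
#' feed the whole-animal correlation analyses (brighter animals have
#' brighter cells across distinctly regulated reporters).
#'
#' @param cells a cells data.frame (validated or simulated).
#' @param channels intensity columns to summarize; default
#'   [cell_channels()].
#' @return data.frame with `experiment_id`, `animal_id`, `n_cells` and one
#'   mean-intensity column per channel. Empty input yields an empty table
#'   with a warning.
#' @export
summarize_per_animal <- function(cells, channels = cell_channels(cells)) {
  empty <- data.frame(experiment_id = character(), animal_id = character(),
                      n_cells = integer(), stringsAsFactors = FALSE)
  for (ch in channels) empty[[ch]] <- numeric()
  if (nrow(cells) == 0L) {
    warning("no cells to summarize; returning an empty table")
    return(empty)
  }
  key <- interaction(cells$experiment_id, cells$animal_id, drop = TRUE,
                     lex.order = TRUE)
  first <- !duplicated(key)
  out <- data.frame(experiment_id = cells$experiment_id[first],
                    animal_id = cells$animal_id[first],
                    n_cells = as.integer(table(key)[as.character(key[first])]),
                    stringsAsFactors = FALSE)
  for (ch in channels) {
    means <- tapply(cells[[ch]], key, mean)
    out[[ch]] <- as.numeric(means[as.character(key[first])])
  }
  out <- out[order(out$experiment_id, out$animal_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a pipeline run configuration from YAML
#'
#' @param path YAML file path.
#' @return the configuration list (see [run_pipeline()] for the schema).
#' @export
read_run_config <- function(path) yaml::read_yaml(path)
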