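#' Read an expression matrix from delimited text
#'
#' Reads a tab- or comma-delimited table of log-scale expression values
#' (already preprocessed, e.g. MAS5/RMA output; no normalisation is applied)
#' into a tidy samples-by-probes tibble. The delimiter is auto-detected from
#' the header line; the first column holds row IDs. Columns named
#' `preservation` or `specimen_source` are kept as per-sample metadata
#' (only meaningful with `orientation = "samples_in_rows"`).
#'
#' @param path Path to a delimited text file with one header row and one ID
#'   column.
#' @param orientation `"samples_in_rows"` (default) if rows are samples and
#'   columns probes, `"probes_in_rows"` for the transpose. The result is
#'   always samples x probes.
#' @return A tibble with columns `sample_id`, one numeric column per probe
#'   (in file order), and any metadata columns present.
#' @export
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("id\tP1\tP2", "s1\t1.5\t2.5", "s2\t0.5\t3.5"), f)
#' read_expression_matrix(f)
read_expression_matrix <- function(path,
                                   orientation = c("samples_in_rows",
                                                   "probes_in_rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) {
    stop_input(sprintf("File not found: %s", path), "noderisk_io_error")
  }
  raw <- read_delim_auto(path)
  if (nrow(raw) == 0 || ncol(raw) < 2) {
    stop_input(sprintf("Empty expression matrix in '%s'.", path),
               "noderisk_format_error")
  }
  names(raw)[1] <- "sample_id"
  dup <- unique(names(raw)[-1][duplicated(names(raw)[-1])])
  if (length(dup) > 0) {
    stop_input(sprintf("Duplicate column ID(s) in '%s': %s", path,
                       toString(dup)), "noderisk_format_error")
  }
  if (orientation == "probes_in_rows") {
    raw <- transpose_expression(raw, path)
  }
  meta_here <- intersect(.meta_cols, names(raw))
  for (p in setdiff(names(raw), c("sample_id", meta_here))) {
    v <- raw[[p]]
    # base strtod parsing: correctly rounded, so %.17g output round-trips
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & !is.na(v))
    if (length(bad) > 0) {
      stop_input(sprintf(
        "Non-numeric value '%s' at row '%s', column '%s' of '%s'.",
        v[bad[1]], raw$sample_id[bad[1]], p, path), "noderisk_parse_error")
    }
    if (anyNA(num)) {
      stop_input(sprintf(
        "Missing value at row '%s', column '%s' of '%s' (missing values are rejected).",
        raw$sample_id[which(is.na(num))[1]], p, path), "noderisk_parse_error")
    }
    raw[[p]] <- num
  }
  validate_expression(raw, path)
}

# Read a delimited file as all-character columns, auto-detecting tab vs comma
# from the header line.
read_delim_auto <- function(path) {
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE,
    name_repair = "minimal")
}

transpose_expression <- function(raw, path) {
  probe_ids <- raw$sample_id
  dup <- unique(probe_ids[duplicated(probe_ids)])
  if (length(dup) > 0) {
    stop_input(sprintf("Duplicate row ID(s) in '%s': %s", path, toString(dup)),
               "noderisk_format_error")
  }
  sample_ids <- names(raw)[-1]
  m <- t(as.matrix(raw[, -1, drop = FALSE]))
  out <- as_tibble(m, .name_repair = "minimal")
  names(out) <- probe_ids
  dplyr::bind_cols(tibble(sample_id = sample_ids), out)
}

#' Write an expression matrix to tab-delimited text
#'
#' Values are formatted with 17 significant digits so that a write/read
#' round trip reproduces doubles bit-identically.
#'
#' @param x Expression tibble (as returned by [read_expression_matrix()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  x <- validate_expression(x)
  out <- x
  for (p in probe_cols(x)) {
    out[[p]] <- sprintf("%.17g", x[[p]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene panel (probe to gene-symbol map)
#'
#' The panel defines the signature: an ordered two-column table mapping probe
#' IDs to gene symbols. The published instance has 21 probes covering 20
#' genes, but any non-empty panel is accepted (probe identities are supplied
#' by the user, not bundled).
#'
#' @param path Two-column delimited file with header `probe_id, gene_symbol`.
#' @return A tibble with columns `probe_id` and `gene_symbol`, file order
#'   preserved, of class `gene_panel`.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) {
    stop_input(sprintf("File not found: %s", path), "noderisk_io_error")
  }
  raw <- read_delim_auto(path)
  if (nrow(raw) == 0) {
    stop_input(sprintf("Empty panel file '%s'.", path),
               "noderisk_format_error")
  }
  if (ncol(raw) != 2) {
    stop_input(sprintf("Panel file '%s' must have exactly 2 columns, found %d.",
                       path, ncol(raw)), "noderisk_format_error")
  }
  names(raw) <- c("probe_id", "gene_symbol")
  new_panel(raw)
}

new_panel <- function(x) {
  x <- as_tibble(x)
  x$probe_id <- as.character(x$probe_id)
  x$gene_symbol <- as.character(x$gene_symbol)
  dup <- unique(x$probe_id[duplicated(x$probe_id)])
  if (length(dup) > 0) {
    stop_input(sprintf("Duplicate probe ID(s) in panel: %s", toString(dup)),
               "noderisk_format_error")
  }
  if (anyNA(x$probe_id) || anyNA(x$gene_symbol)) {
    stop_input("Panel contains missing probe IDs or gene symbols.",
               "noderisk_format_error")
  }
  class(x) <- c("gene_panel", class(x))
  x
}

#' @export
print.gene_panel <- function(x, ...) {
  cat(sprintf("<gene_panel: %d probes / %d genes>\n",
              nrow(x), dplyr::n_distinct(x$gene_symbol)))
  NextMethod()
}

#' Read binary nodal-status labels
#'
#' @param path Two-column delimited file with header `sample_id, node_status`
#'   and status coded 0 (node-negative) / 1 (node-positive).
#' @return A tibble with columns `sample_id` (character) and `node_status`
#'   (integer 0/1).
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) {
    stop_input(sprintf("File not found: %s", path), "noderisk_io_error")
  }
  raw <- read_delim_auto(path)
  if (nrow(raw) == 0 || ncol(raw) != 2) {
    stop_input(sprintf("Labels file '%s' must be a non-empty 2-column table.",
                       path), "noderisk_format_error")
  }
  names(raw) <- c("sample_id", "node_status")
  dup <- unique(raw$sample_id[duplicated(raw$sample_id)])
  if (length(dup) > 0) {
    stop_input(sprintf("Duplicate sample ID(s) in labels: %s", toString(dup)),
               "noderisk_format_error")
  }
  status <- suppressWarnings(as.integer(raw$node_status))
  if (anyNA(status) || !all(status %in% c(0L, 1L))) {
    stop_input("node_status must be coded 0 (node-negative) or 1 (node-positive).",
               "noderisk_parse_error")
  }
  tibble(sample_id = as.character(raw$sample_id), node_status = status)
}

#' Restrict an expression matrix to a gene panel
#'
#' Keeps only the panel's probes, reordered to panel order. In strict mode a
#' missing probe is an error listing every absent ID; in lenient mode missing
#' probes are dropped with a warning and recorded in the `dropped_probes`
#' attribute of the result.
#'
#' @param x Expression tibble.
#' @param panel A `gene_panel` (or anything with a `probe_id` column) or a
#'   character vector of probe IDs.
#' @param strict If `TRUE` (default) any panel probe absent from `x` is an
#'   error.
#' @return The subsetted expression tibble; metadata columns are kept.
#' @export
subset_to_panel <- function(x, panel, strict = TRUE) {
  x <- validate_expression(x)
  probes <- if (is.character(panel)) panel else panel$probe_id
  if (length(probes) == 0) {
    stop_input("Panel has no probes.", "noderisk_format_error")
  }
  missing <- setdiff(probes, probe_cols(x))
  if (length(missing) > 0) {
    if (strict) {
      stop_input(sprintf("Panel probe(s) missing from matrix: %s",
                         toString(missing)), "noderisk_missing_probe_error")
    }
    warn(sprintf("Dropping %d panel probe(s) missing from matrix: %s",
                 length(missing), toString(missing)))
    probes <- setdiff(probes, missing)
    if (length(probes) == 0) {
      stop_input("No panel probes present in matrix.",
                 "noderisk_missing_probe_error")
    }
  }
  keep <- c("sample_id", intersect(.meta_cols, names(x)), probes)
  out <- x[, keep]
  if (length(missing) > 0) attr(out, "dropped_probes") <- missing
  out
}
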