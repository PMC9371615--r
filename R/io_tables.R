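#' Read a MaxQuant-style phosphosite table
#'
#' Parses a tab-delimited site table in the "Phospho (STY)Sites" dialect
#' subset: columns `Protein`, `Position`, `Amino acid`, `Multiplicity`,
#' optionally `Reverse` and `Potential contaminant` (flagged with `"+"`),
#' and one `Intensity <sample_id>` column per sample. Rows flagged as
#' reverse decoys or potential contaminants are dropped. Intensity `0` and
#' empty cells both mean "not detected" and are stored as missing.
#'
#' @param path path to the tab-delimited table (UTF-8, `.` decimal point).
#' @param sample_map data.frame with columns `sample_id`, `group`,
#'   optionally `included`; every `sample_id` must match an
#'   `Intensity <sample_id>` column.
#' @return a [site_matrix()] on the raw intensity scale; row order is input
#'   order (after decoy/contaminant removal).
#' @export
read_site_table <- function(path, sample_map) {
  if (!file.exists(path)) stop("site table not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           quote = "", na.strings = c("", "NA"),
                           fileEncoding = "UTF-8")
  sample_map <- as.data.frame(sample_map)
  needed <- c("Protein", "Position", "Amino acid", "Multiplicity")
  miss <- setdiff(needed, names(tab))
  if (length(miss) > 0L) {
    stop("site table is missing column(s): ", paste(miss, collapse = ", "))
  }
  int_cols <- paste("Intensity", sample_map$sample_id)
  absent <- int_cols[!int_cols %in% names(tab)]
  if (length(absent) > 0L) {
    stop("configuration error: no intensity column for sample(s): ",
         paste(sub("^Intensity ", "", absent), collapse = ", "))
  }
  # absent flag columns are treated as all-false (minimal fixtures)
  flagged <- rep(FALSE, nrow(tab))
  for (fc in c("Reverse", "Potential contaminant")) {
    if (fc %in% names(tab)) {
      flagged <- flagged | (!is.na(tab[[fc]]) & tab[[fc]] == "+")
    }
  }
  tab <- tab[!flagged, , drop = FALSE]
  intensity <- as.matrix(tab[, int_cols, drop = FALSE])
  storage.mode(intensity) <- "double"
  if (any(intensity < 0, na.rm = TRUE)) {
    stop("input error: negative intensity value(s) in ", path)
  }
  sites <- data.frame(
    protein = as.character(tab$Protein),
    position = as.integer(tab$Position),
    residue = as.character(tab$`Amino acid`),
    multiplicity = as.integer(tab$Multiplicity),
    stringsAsFactors = FALSE
  )
  site_matrix(sites, sample_map, intensity, scale = "raw")
}

#' Write a phosphosite matrix in the same dialect [read_site_table()] reads
#'
#' Missing cells are written as `0`, matching the MaxQuant convention of
#' `0` for unquantified sites; a write/read round trip therefore preserves
#' keys, values and the missing pattern exactly.
#'
#' @param m a `site_matrix` on the raw scale.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(m, path) {
  stopifnot(inherits(m, "site_matrix"))
  if (m$scale != "raw") stop("write_site_table expects raw-scale intensities")
  out <- data.frame(
    Protein = m$sites$protein,
    Position = m$sites$position,
    `Amino acid` = m$sites$residue,
    Multiplicity = m$sites$multiplicity,
    Reverse = "",
    `Potential contaminant` = "",
    check.names = FALSE, stringsAsFactors = FALSE
  )
  grid <- m$intensity
  grid[is.na(grid)] <- 0
  colnames(grid) <- paste("Intensity", m$samples$sample_id)
  out <- cbind(out, as.data.frame(grid, check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a protein-to-term annotation table
#'
#' Accepts a two-column tab-delimited file `protein<TAB>term` (one pair per
#' line, optional third column with a human-readable term name) or the
#' list form `protein<TAB>term1;term2;...`. Duplicated pairs are collapsed.
#'
#' @param path path to the annotation table. A header line is detected when
#'   the first line's first field is `protein` (case-insensitive).
#' @return an `annotation_map`: a named list mapping each protein accession
#'   to a character vector of term ids, with a `term_names` attribute
#'   (named character vector) when names were provided.
#' @export
read_annotation_table <- function(path) {
  if (!file.exists(path)) stop("annotation table not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) > 0L) {
    first <- tolower(strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]][1L])
    if (identical(first, "protein")) lines <- lines[-1L]
  }
  pairs_protein <- character(0)
  pairs_term <- character(0)
  term_names <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 2L || !nzchar(fields[[1L]])) {
      stop("input error: malformed annotation line ", i, ": ", lines[[i]])
    }
    terms <- strsplit(fields[[2L]], ";", fixed = TRUE)[[1L]]
    terms <- trimws(terms)
    terms <- terms[nzchar(terms)]
    pairs_protein <- c(pairs_protein, rep(fields[[1L]], length(terms)))
    pairs_term <- c(pairs_term, terms)
    if (length(fields) >= 3L && length(terms) == 1L && nzchar(fields[[3L]])) {
      term_names[terms] <- fields[[3L]]
    }
  }
  map <- lapply(split(pairs_term, pairs_protein), function(v) sort(unique(v)))
  # drop the grouping-induced reordering: keep it; lookup is by name
  structure(map, term_names = term_names, class = "annotation_map")
}

#' Write all stage result tables and a run manifest
#'
#' Writes one tab-delimited file per available stage result (quality
#' control, dropped sites, differential testing, presence classification,
#' protein sets, term enrichment, imputation mask) plus a plain-text
#' `manifest.txt` echoing parameters, seeds and per-stage row counts.
#' Identical inputs and seeds produce byte-identical result files;
#' the manifest timestamp is the only run-varying field.
#'
#' @param results named list; recognised elements: `qc` (data.frame),
#'   `dropped_sites` (data.frame), `differential` (a `perm_fdr` object or
#'   its table), `classification` (a `presence_classification` or its
#'   table), `protein_sets` (data.frame), `enrichment` (data.frame),
#'   `imputation_mask` (data.frame), and `params` (named list echoed into
#'   the manifest).
#' @param out_dir output directory; created if needed.
#' @return data.frame manifest of written files (file, rows), invisibly
#'   returned after writing.
#' @export
write_results <- function(results, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, mode = 2L) != 0L) {
    stop("output directory is not writable: ", out_dir)
  }
  as_table <- function(x) {
    if (inherits(x, "perm_fdr")) return(x$table)
    if (inherits(x, "presence_classification")) return(x$table)
    as.data.frame(x)
  }
  stage_files <- c(qc = "qc.tsv", dropped_sites = "dropped_sites.tsv",
                   differential = "differential.tsv",
                   classification = "classification.tsv",
                   protein_sets = "protein_sets.tsv",
                   enrichment = "enrichment.tsv",
                   imputation_mask = "imputation_mask.tsv")
  written <- character(0)
  rows <- integer(0)
  for (stage in names(stage_files)) {
    if (is.null(results[[stage]])) next
    tab <- as_table(results[[stage]])
    f <- file.path(out_dir, stage_files[[stage]])
    utils::write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
    written <- c(written, stage_files[[stage]])
    rows <- c(rows, nrow(tab))
  }
  manifest <- data.frame(file = written, rows = rows,
                         stringsAsFactors = FALSE)
  man_lines <- c(
    paste0("timestamp: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    paste0("phosphopipe_version: ",
           as.character(utils::packageVersion("phosphopipe"))),
    "parameters:",
    manifest_params_lines(results$params),
    "files:",
    sprintf("  %s: %d rows", manifest$file, manifest$rows)
  )
  writeLines(man_lines, file.path(out_dir, "manifest.txt"))
  invisible(manifest)
}

manifest_params_lines <- function(params, indent = "  ") {
  if (is.null(params) || length(params) == 0L) return(paste0(indent, "(none)"))
  unlist(lapply(names(params), function(nm) {
    v <- params[[nm]]
    if (is.list(v)) {
      c(paste0(indent, nm, ":"), manifest_params_lines(v, paste0(indent, "  ")))
    } else {
      paste0(indent, nm, ": ", paste(format(v, trim = TRUE), collapse = ", "))
    }
  }))
}
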