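#' Classify sites as group-enriched by detection pattern
#'
#' A site is enriched with a group when it is detected in nearly all of
#' that group's samples and almost none of the other's — the rule the
#' two-group neutrophil design applies literally as "detected in 3-4 of 4
#' DMSO and 0-1 of 5 neratinib samples" (and symmetrically 4-5 of 5 vs
#' 0-1 of 4). Defaults generalise those thresholds to
#' `min_in = group size - 1` and `max_out = 1`. Classification depends only
#' on the detection pattern, never on intensity magnitudes, and runs on the
#' pre-imputation detection matrix.
#'
#' @param det a [detection_matrix()] over exactly two groups.
#' @param min_in named integer vector (one per group) or single integer:
#'   minimum detections in the enriched ("in") group; default
#'   `group size - 1` per group.
#' @param max_out maximum detections tolerated in the other ("out") group;
#'   default 1.
#' @return a `presence_classification`: list with `table` (site key,
#'   per-group counts, `label` in `{<groupA>_enriched, <groupB>_enriched,
#'   neither}`), `enriched_sites` (named list of site keys per group),
#'   `proteins` (named list of collapsed distinct protein accessions per
#'   group) and `params`.
#' @export
classify_sites <- function(det, min_in = NULL, max_out = 1L) {
  stopifnot(inherits(det, "detection_matrix"))
  groups <- colnames(det$counts)
  if (length(groups) != 2L) stop("exactly two groups required")
  sizes <- det$group_sizes[groups]
  if (is.null(min_in)) {
    min_in <- stats::setNames(pmax(1L, sizes - 1L), groups)
  }
  if (length(min_in) == 1L && is.null(names(min_in))) {
    min_in <- stats::setNames(rep(as.integer(min_in), 2L), groups)
  }
  min_in <- min_in[groups]
  if (any(min_in < 1L) || any(min_in > sizes)) {
    stop("configuration error: min_in must satisfy 1 <= min_in <= group size")
  }
  if (max_out < 0L || any(max_out >= sizes)) {
    stop("configuration error: max_out must satisfy 0 <= max_out < ",
         "other group's size")
  }
  # the bounds above make the two enrichment conditions mutually exclusive:
  # min_in > max_out in both directions
  if (any(min_in <= max_out)) {
    stop("configuration error: min_in must exceed max_out, otherwise a ",
         "site could satisfy both directions")
  }
  a <- groups[1L]; b <- groups[2L]
  ca <- det$counts[, a]; cb <- det$counts[, b]
  lab_a <- ca >= min_in[[a]] & cb <= max_out
  lab_b <- cb >= min_in[[b]] & ca <= max_out
  label <- rep("neither", length(ca))
  label[lab_a] <- paste0(a, "_enriched")
  label[lab_b] <- paste0(b, "_enriched")
  keys <- rownames(det$counts)
  tab <- data.frame(site = keys, det$counts, label = label,
                    check.names = FALSE, stringsAsFactors = FALSE,
                    row.names = NULL)
  enriched <- stats::setNames(list(keys[lab_a], keys[lab_b]), groups)
  proteins <- stats::setNames(
    list(sort(unique(det$sites$protein[lab_a])),
         sort(unique(det$sites$protein[lab_b]))), groups)
  structure(
    list(table = tab, enriched_sites = enriched, proteins = proteins,
         params = list(min_in = min_in, max_out = max_out,
                       group_sizes = sizes)),
    class = "presence_classification"
  )
}

#' @export
print.presence_classification <- function(x, ...) {
  g <- names(x$enriched_sites)
  cat("presence/absence classification:\n")
  for (gg in g) {
    cat(sprintf("  %s-enriched: %d sites -> %d proteins\n", gg,
                length(x$enriched_sites[[gg]]), length(x$proteins[[gg]])))
  }
  cat(sprintf("  neither: %d sites\n", sum(x$table$label == "neither")))
  invisible(x)
}

#' Collapse a set of enriched sites to distinct proteins
#'
#' @param x a `presence_classification` (collapses each group's enriched
#'   sites) or a character vector of site keys as produced by [site_key()].
#' @return named list of distinct protein accessions per group, or a
#'   character vector of distinct accessions for a plain site-key vector.
#' @export
collapse_to_proteins <- function(x) {
  if (inherits(x, "presence_classification")) return(x$proteins)
  sort(unique(sub("_[0-9]+_[STY]_[123]$", "", as.character(x))))
}
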