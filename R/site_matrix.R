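#' Construct a phosphosite intensity matrix
#'
#' The pipeline's entry object: a site-by-sample grid of mass-spectrometry
#' intensities with explicit missingness (`NA`), keyed by phosphosite
#' (protein accession, residue position, residue, multiplicity) and carrying
#' per-sample group metadata.
#'
#' @param sites data.frame with columns `protein`, `position`, `residue`,
#'   `multiplicity`; one row per site x multiplicity state.
#' @param samples data.frame with columns `sample_id`, `group` and optionally
#'   `included` (logical, default all `TRUE`).
#' @param intensity numeric matrix, `nrow(sites)` x `nrow(samples)`;
#'   missing (not detected) entries are `NA`. Raw intensities must be
#'   non-negative; zeros are converted to `NA` (MaxQuant writes 0 for
#'   unquantified sites).
#' @param scale `"raw"` for intensities, `"log2"` for log2-transformed values.
#'
#' @return An object of class `site_matrix`: a list with elements `sites`,
#'   `samples`, `intensity` and `scale`.
#' @export
site_matrix <- function(sites, samples, intensity, scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  sites <- as.data.frame(sites)
  samples <- as.data.frame(samples)
  required <- c("protein", "position", "residue", "multiplicity")
  missing_cols <- setdiff(required, names(sites))
  if (length(missing_cols) > 0L) {
    stop("sites is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!all(c("sample_id", "group") %in% names(samples))) {
    stop("samples must have columns 'sample_id' and 'group'")
  }
  if (is.null(samples$included)) samples$included <- TRUE
  samples$sample_id <- as.character(samples$sample_id)
  samples$group <- as.character(samples$group)
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicate sample_id: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
               collapse = ", "))
  }
  intensity <- as.matrix(intensity)
  storage.mode(intensity) <- "double"
  if (nrow(intensity) != nrow(sites) || ncol(intensity) != nrow(samples)) {
    stop("intensity must be ", nrow(sites), " x ", nrow(samples),
         ", got ", nrow(intensity), " x ", ncol(intensity))
  }
  bad_res <- !sites$residue %in% c("S", "T", "Y")
  if (any(bad_res)) {
    stop("residue must be one of S, T, Y; offending rows: ",
         paste(utils::head(which(bad_res), 5L), collapse = ", "))
  }
  if (!all(sites$multiplicity %in% 1:3)) {
    stop("multiplicity must be in {1, 2, 3}")
  }
  if (any(sites$position < 1 | sites$position != round(sites$position))) {
    stop("position must be a positive integer")
  }
  key <- site_key(sites)
  if (anyDuplicated(key)) {
    stop("duplicate site keys: ",
         paste(utils::head(unique(key[duplicated(key)]), 5L), collapse = "; "))
  }
  if (scale == "raw") {
    if (any(intensity < 0, na.rm = TRUE)) {
      stop("negative intensity values are not permitted")
    }
    intensity[!is.na(intensity) & intensity == 0] <- NA_real_
  } else {
    if (any(!is.finite(intensity[!is.na(intensity)]))) {
      stop("log2 values must be finite")
    }
  }
  dimnames(intensity) <- list(key, samples$sample_id)
  structure(
    list(sites = sites, samples = samples, intensity = intensity,
         scale = scale),
    class = "site_matrix"
  )
}

#' Canonical site key strings
#'
#' @param sites a `site_matrix` or its `sites` data.frame.
#' @return character vector `protein_position_residue_multiplicity`
#'   (e.g. `"P12345_17_S_1"`), unique within a matrix.
#' @export
site_key <- function(sites) {
  if (inherits(sites, "site_matrix")) sites <- sites$sites
  paste(sites$protein, sites$position, sites$residue, sites$multiplicity,
        sep = "_")
}

#' @export
print.site_matrix <- function(x, ...) {
  n_missing <- sum(is.na(x$intensity))
  cat(sprintf("site_matrix (%s scale): %d sites x %d samples\n",
              x$scale, nrow(x$sites), nrow(x$samples)))
  cat(sprintf("  groups: %s\n",
              paste(sprintf("%s (n=%d)", names(table(x$samples$group)),
                            as.integer(table(x$samples$group))),
                    collapse = ", ")))
  cat(sprintf("  missing cells: %d of %d (%.1f%%)\n", n_missing,
              length(x$intensity), 100 * n_missing / length(x$intensity)))
  invisible(x)
}

#' @export
dim.site_matrix <- function(x) dim(x$intensity)

# samples retained for computation: included == TRUE
included_samples <- function(m) {
  m$samples[m$samples$included, , drop = FALSE]
}

# split included sample column indices by group, in group-name order
group_columns <- function(m) {
  inc <- which(m$samples$included)
  split(inc, m$samples$group[inc])
}

#' Exclude samples from all downstream computation
#'
#' Marks samples as excluded (e.g. after a poor quality-control correlation).
#' Exclusion is an explicit action: [sample_qc()] only flags.
#'
#' @param m a `site_matrix`.
#' @param sample_ids character vector of sample ids to exclude.
#' @return the matrix with those samples marked `included = FALSE` and
#'   their columns removed from the intensity grid.
#' @export
exclude_samples <- function(m, sample_ids) {
  stopifnot(inherits(m, "site_matrix"))
  unknown <- setdiff(sample_ids, m$samples$sample_id)
  if (length(unknown) > 0L) {
    stop("unknown sample id(s): ", paste(unknown, collapse = ", "))
  }
  keep <- !(m$samples$sample_id %in% sample_ids)
  m$samples <- m$samples[keep, , drop = FALSE]
  rownames(m$samples) <- NULL
  m$intensity <- m$intensity[, keep, drop = FALSE]
  m
}
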