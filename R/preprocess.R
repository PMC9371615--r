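#' Log2-transform a raw intensity matrix
#'
#' @param m a raw-scale `site_matrix`; all present values must be positive
#'   (zeros are already mapped to missing on read).
#' @return the matrix with each present value `v` replaced by `log2(v)`;
#'   the missing pattern is unchanged.
#' @export
log2_transform <- function(m) {
  stopifnot(inherits(m, "site_matrix"))
  if (m$scale != "raw") stop("matrix is already on the log2 scale")
  if (any(m$intensity <= 0, na.rm = TRUE)) {
    stop("input error: present intensity <= 0 cannot be log-transformed")
  }
  m$intensity <- log2(m$intensity)
  m$scale <- "log2"
  m
}

#' Median-normalize each sample column
#'
#' Subtracts from every present value in a column the median of that
#' column's present values, so that each column's present-value median is 0
#' afterwards. Missing cells are untouched: under intensity-dependent
#' (MNAR) missingness the centering must use observed values only.
#'
#' @param m a log2-scale `site_matrix`; every included sample needs at
#'   least one present value.
#' @return the normalized matrix; idempotent.
#' @export
median_normalize <- function(m) {
  stopifnot(inherits(m, "site_matrix"))
  if (m$scale != "log2") stop("median normalization expects log2 values")
  inc <- which(m$samples$included)
  for (j in inc) {
    col <- m$intensity[, j]
    if (all(is.na(col))) {
      stop("input error: sample '", m$samples$sample_id[j],
           "' has no present values")
    }
    m$intensity[, j] <- col - stats::median(col, na.rm = TRUE)
  }
  m
}

#' Detection matrix and per-group detection counts
#'
#' @param m a `site_matrix` (any scale); a cell is detected iff present.
#' @return a `detection_matrix`: list with `detected` (site x sample logical
#'   matrix over included samples), `counts` (site x group integer matrix of
#'   detections per group), and `group_sizes` (named integer vector).
#' @export
detection_matrix <- function(m) {
  stopifnot(inherits(m, "site_matrix"))
  cols <- group_columns(m)
  inc <- which(m$samples$included)
  detected <- !is.na(m$intensity[, inc, drop = FALSE])
  counts <- vapply(cols, function(j) {
    rowSums(!is.na(m$intensity[, j, drop = FALSE]))
  }, numeric(nrow(m$sites)))
  counts <- matrix(as.integer(counts), nrow = nrow(m$sites),
                   dimnames = list(site_key(m), names(cols)))
  structure(
    list(detected = detected, counts = counts,
         group_sizes = vapply(cols, length, integer(1)),
         sites = m$sites),
    class = "detection_matrix"
  )
}

#' @export
print.detection_matrix <- function(x, ...) {
  cat(sprintf("detection_matrix: %d sites, groups %s\n", nrow(x$counts),
              paste(sprintf("%s (n=%d)", names(x$group_sizes),
                            x$group_sizes), collapse = ", ")))
  invisible(x)
}

#' Filter sites on a minimum number of valid values per group
#'
#' A site is retained iff at least one group has at least `min_valid`
#' present values among its included samples.
#'
#' @param m a `site_matrix`.
#' @param min_valid positive integer, default 3.
#' @return list with `matrix` (retained rows, input order preserved) and
#'   `dropped` (data.frame of dropped site keys with per-group counts).
#' @export
filter_min_valid <- function(m, min_valid = 3L) {
  stopifnot(inherits(m, "site_matrix"))
  if (min_valid < 1L) stop("configuration error: min_valid must be >= 1")
  det <- detection_matrix(m)
  if (min_valid > max(det$group_sizes)) {
    stop("configuration error: min_valid (", min_valid,
         ") exceeds every group size")
  }
  keep <- apply(det$counts >= min_valid, 1L, any)
  dropped <- data.frame(site = site_key(m)[!keep],
                        det$counts[!keep, , drop = FALSE],
                        check.names = FALSE, row.names = NULL)
  out <- m
  out$sites <- m$sites[keep, , drop = FALSE]
  rownames(out$sites) <- NULL
  out$intensity <- m$intensity[keep, , drop = FALSE]
  list(matrix = out, dropped = dropped)
}

#' Sample quality control by mean pairwise correlation
#'
#' For each included sample, computes the mean of its pairwise
#' product-moment correlations with every other included sample, each
#' correlation using pairwise-complete present values. Pairs sharing fewer
#' than 3 present values are incomputable: they contribute nothing to the
#' mean and are listed in the report. Samples whose mean correlation falls
#' below `threshold` are flagged; flagging only reports — removal is the
#' explicit [exclude_samples()] action.
#'
#' @param m a log2-scale `site_matrix` with at least 3 included samples.
#' @param threshold absolute flagging threshold on the mean correlation,
#'   default 0.7.
#' @return a `qc_report`: list with `table` (sample_id, mean_correlation,
#'   n_pairs, flagged), `pairwise` (full symmetric correlation matrix) and
#'   `incomputable_pairs` (data.frame, possibly empty).
#' @export
sample_qc <- function(m, threshold = 0.7) {
  stopifnot(inherits(m, "site_matrix"))
  inc <- which(m$samples$included)
  if (length(inc) < 3L) stop("sample QC needs at least 3 included samples")
  ids <- m$samples$sample_id[inc]
  k <- length(inc)
  cmat <- matrix(NA_real_, k, k, dimnames = list(ids, ids))
  diag(cmat) <- 1
  bad_a <- character(0); bad_b <- character(0)
  for (a in seq_len(k - 1L)) {
    for (b in seq.int(a + 1L, k)) {
      x <- m$intensity[, inc[a]]
      y <- m$intensity[, inc[b]]
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < 3L) {
        bad_a <- c(bad_a, ids[a]); bad_b <- c(bad_b, ids[b])
        next
      }
      cmat[a, b] <- cmat[b, a] <- stats::cor(x[ok], y[ok])
    }
  }
  mean_cor <- vapply(seq_len(k), function(i) {
    v <- cmat[i, -i]
    mean(v[!is.na(v)])
  }, numeric(1))
  n_pairs <- vapply(seq_len(k), function(i) sum(!is.na(cmat[i, -i])),
                    integer(1))
  tab <- data.frame(sample_id = ids, mean_correlation = mean_cor,
                    n_pairs = n_pairs,
                    flagged = !is.nan(mean_cor) & mean_cor < threshold,
                    stringsAsFactors = FALSE)
  structure(
    list(table = tab, pairwise = cmat,
         incomputable_pairs = data.frame(sample_a = bad_a, sample_b = bad_b,
                                         stringsAsFactors = FALSE),
         threshold = threshold),
    class = "qc_report"
  )
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("sample QC (flag threshold %.2f):\n", x$threshold))
  print(x$table, row.names = FALSE)
  if (nrow(x$incomputable_pairs) > 0L) {
    cat(nrow(x$incomputable_pairs),
        "pair(s) had <3 shared present values\n")
  }
  invisible(x)
}
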