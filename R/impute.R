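#' Downshifted-Gaussian imputation of missing log2 values
#'
#' Replaces each missing cell with an independent draw from a Gaussian
#' shifted below the observed values, emulating the standard Perseus-style
#' treatment of left-censored (missing-not-at-random) proteomics data: in
#' column `j`, missing cells receive draws from
#' `Normal(mean_j - downshift * sd_j, (width * sd_j)^2)` where `mean_j` and
#' `sd_j` are the mean and standard deviation of the column's present
#' values (`per_sample` mode) or of all present values in the matrix
#' (`global` mode).
#'
#' Draws for each column come from a stream derived deterministically from
#' `(seed, sample_id)`, so results are invariant to column processing order
#' and identical seeds give identical output. Columns with a missing cell
#' but fewer than 2 present values fall back to global statistics, recorded
#' in the returned log.
#'
#' @param m a log2-scale `site_matrix`.
#' @param width width of the imputation distribution as a fraction of the
#'   observed SD; default 0.3.
#' @param downshift downshift of its mean, in observed SDs; default 1.8.
#' @param mode `"per_sample"` (column statistics, the default) or
#'   `"global"` (whole-matrix statistics).
#' @param seed integer seed; mandatory.
#' @return list with `matrix` (complete `site_matrix`; present cells
#'   bit-identical to the input), `mask` (logical matrix marking exactly
#'   the imputed cells) and `log` (character vector of per-column notes,
#'   e.g. global fallbacks).
#' @export
impute_downshift <- function(m, width = 0.3, downshift = 1.8,
                             mode = c("per_sample", "global"), seed) {
  stopifnot(inherits(m, "site_matrix"))
  mode <- match.arg(mode)
  if (m$scale != "log2") stop("imputation expects log2 values")
  if (missing(seed) || is.null(seed)) {
    stop("a seed is mandatory for imputation")
  }
  if (!is.finite(width) || width <= 0) stop("width must be > 0")
  if (!is.finite(downshift) || downshift < 0) stop("downshift must be >= 0")
  grid <- m$intensity
  mask <- is.na(grid)
  notes <- character(0)
  obs_all <- grid[!mask]
  if (any(mask) && length(obs_all) < 2L) {
    stop("fewer than 2 present values in the whole matrix; cannot impute")
  }
  global_mean <- mean(obs_all)
  global_sd <- stats::sd(obs_all)
  inc <- which(m$samples$included)
  for (j in inc) {
    nmiss <- sum(mask[, j])
    if (nmiss == 0L) next
    obs <- grid[!mask[, j], j]
    if (mode == "per_sample" && length(obs) >= 2L) {
      mu <- mean(obs); s <- stats::sd(obs)
    } else {
      mu <- global_mean; s <- global_sd
      if (mode == "per_sample") {
        notes <- c(notes, paste0(
          "sample '", m$samples$sample_id[j],
          "' has <2 present values; used global statistics"))
      }
    }
    rng <- column_rng_seed(seed, m$samples$sample_id[j])
    grid[mask[, j], j] <- with_seed(
      rng, stats::rnorm(nmiss, mean = mu - downshift * s, sd = width * s))
  }
  m$intensity <- grid
  list(matrix = m, mask = mask, log = notes)
}

# deterministic 31-bit stream seed from (master seed, sample id);
# polynomial string hash so streams are independent of column order
column_rng_seed <- function(seed, sample_id) {
  h <- as.double(seed %% 2147483647L)
  for (code in utf8ToInt(sample_id)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}
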