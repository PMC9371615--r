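#' Two-sample pooled-variance t statistic with optional fudge factor
#'
#' Computes the Student statistic `t = diff / (se + s0)` with
#' `diff = mean(x) - mean(y)` and the pooled-variance standard error
#' `se = s_pooled * sqrt(1/nx + 1/ny)`. The two-sided reference p-value is
#' always evaluated at the unmodified (`s0 = 0`) statistic on
#' `nx + ny - 2` degrees of freedom; the `s0`-modified statistic is what
#' permutation ranking uses. With zero pooled variance the statistic is 0
#' when `diff = 0` and signed infinity when `diff != 0` and `s0 = 0`.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @param s0 non-negative fudge factor added to the standard error
#'   (SAM-style regularisation of near-zero variances); default 0.
#' @return list with `t` (s0-modified statistic), `t0` (unmodified), `p`
#'   (two-sided reference p), `diff` and `df`.
#' @export
two_sample_t <- function(x, y, s0 = 0) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L) {
    stop("both samples need at least 2 values")
  }
  if (s0 < 0) stop("s0 must be non-negative")
  nx <- length(x); ny <- length(y)
  d <- mean(x) - mean(y)
  df <- nx + ny - 2L
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / df
  se <- sqrt(sp2 * (1 / nx + 1 / ny))
  t0 <- if (se == 0) {
    if (d == 0) 0 else sign(d) * Inf
  } else d / se
  tmod <- if (se + s0 == 0) t0 else d / (se + s0)
  p <- if (is.infinite(t0)) 0 else 2 * stats::pt(-abs(t0), df)
  list(t = tmod, t0 = t0, p = p, diff = d, df = df)
}

# row-wise s0-modified |t| plus components, for a complete matrix and a
# column split; vectorised over sites
row_t_stats <- function(grid, idx_a, idx_b, s0) {
  na <- length(idx_a); nb <- length(idx_b)
  ma <- rowMeans(grid[, idx_a, drop = FALSE])
  mb <- rowMeans(grid[, idx_b, drop = FALSE])
  ssa <- rowSums((grid[, idx_a, drop = FALSE] - ma)^2)
  ssb <- rowSums((grid[, idx_b, drop = FALSE] - mb)^2)
  df <- na + nb - 2L
  se <- sqrt((ssa + ssb) / df * (1 / na + 1 / nb))
  d <- ma - mb
  t0 <- ifelse(se == 0, ifelse(d == 0, 0, sign(d) * Inf), d / se)
  tmod <- if (s0 == 0) t0 else {
    ifelse(se + s0 == 0, t0, d / (se + s0))
  }
  list(t = tmod, t0 = t0, diff = d, se = se, df = df)
}

#' Permutation-based FDR two-sample test over all sites
#'
#' For every site of a complete (post-imputation) log2 matrix, computes the
#' two-sample statistic between the two groups, then estimates the false
#' discovery rate at each observed |t| threshold from group-label
#' permutations: all distinct labelings are enumerated when their count is
#' at most `exhaustive_below`, otherwise `n_perm` labelings are drawn
#' uniformly at random (identity excluded). At the threshold set at each
#' site's |t| (sites ranked by decreasing |t|, ties kept in site order),
#'
#' `FDR = mean over permutations of #(permuted |t| >= threshold) /
#'        #(observed |t| >= threshold)`
#'
#' clipped to \[0, 1\] and made monotone non-decreasing down the ranking by
#' a cumulative minimum over the tail, so that significant sites
#' (`FDR <= q`) form a prefix of the ranking.
#'
#' @param m a complete log2-scale `site_matrix` with exactly two groups of
#'   included samples, each of size >= 2.
#' @param q target false discovery rate, default 0.05.
#' @param s0 fudge factor passed to the statistic, default 0 (p-values are
#'   always reported for the unmodified statistic).
#' @param n_perm number of random label permutations when not exhaustive;
#'   default 250, minimum 10.
#' @param exhaustive_below enumerate all distinct labelings when their
#'   count is at most this; default 1000.
#' @param seed integer seed for random permutation draws (unused in
#'   exhaustive mode but accepted for a uniform call surface).
#' @return a `perm_fdr` object: list with `table` (per-site results:
#'   key columns, `diff` = mean(first group) - mean(second group), groups
#'   taken in alphabetical order, `t`,
#'   `p`, `fdr`, `significant`, `direction`), `groups`, `higher_in` (named
#'   list of significant site keys by group), `n_labelings`, `mode`,
#'   `params` and `log`.
#' @export
perm_fdr <- function(m, q = 0.05, s0 = 0, n_perm = 250L,
                     exhaustive_below = 1000L, seed = NULL) {
  stopifnot(inherits(m, "site_matrix"))
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)")
  if (n_perm < 10L) stop("n_perm must be at least 10")
  if (anyNA(m$intensity[, m$samples$included, drop = FALSE])) {
    stop("matrix must be complete (impute before testing)")
  }
  cols <- group_columns(m)   # split() orders groups alphabetically
  if (length(cols) != 2L) {
    stop("exactly two groups required, got: ",
         paste(names(cols), collapse = ", "))
  }
  if (any(lengths(cols) < 2L)) {
    stop("each group needs at least 2 included samples")
  }
  grid <- m$intensity
  idx_a <- cols[[1L]]; idx_b <- cols[[2L]]
  all_idx <- c(idx_a, idx_b)
  k <- length(all_idx); na <- length(idx_a)
  n_distinct <- choose(k, na)
  log_notes <- character(0)

  obs <- row_t_stats(grid, idx_a, idx_b, s0)
  p <- ifelse(is.infinite(obs$t0), 0, 2 * stats::pt(-abs(obs$t0), obs$df))

  mode <- if (n_distinct <= exhaustive_below) "exhaustive" else "random"
  if (mode == "random" && n_perm >= n_distinct - 1) {
    mode <- "exhaustive"
    log_notes <- c(log_notes,
                   "n_perm >= available distinct labelings; enumerating all")
  }
  if (mode == "exhaustive") {
    labelings <- utils::combn(k, na, simplify = FALSE)
  } else {
    if (is.null(seed)) stop("a seed is mandatory for random permutations")
    labelings <- draw_labelings(k, na, n_perm, seed)
  }
  n_sites <- nrow(grid)
  null_abs <- numeric(n_sites * length(labelings))
  for (i in seq_along(labelings)) {
    sel <- all_idx[labelings[[i]]]
    perm <- row_t_stats(grid, sel, setdiff(all_idx, sel), s0)
    null_abs[seq_len(n_sites) + (i - 1L) * n_sites] <- abs(perm$t)
  }

  abs_t <- abs(obs$t)
  # rank by decreasing |t|; order() is stable so ties keep site order
  rank_idx <- order(-abs_t)
  thr <- abs_t[rank_idx]
  obs_sorted <- sort(abs_t)
  null_sorted <- sort(null_abs)
  # #(v >= thr) via binary search on the ascending sort; left.open counts
  # the elements strictly below thr
  n_ge <- function(sorted, thr_vec) {
    length(sorted) - findInterval(thr_vec, sorted, left.open = TRUE)
  }
  obs_count <- n_ge(obs_sorted, thr)
  null_mean <- n_ge(null_sorted, thr) / length(labelings)
  fdr_raw <- pmin(1, pmax(0, null_mean / obs_count))
  fdr_mono <- rev(cummin(rev(fdr_raw)))
  fdr <- numeric(n_sites)
  fdr[rank_idx] <- fdr_mono
  significant <- fdr <= q

  keys <- site_key(m)
  direction <- rep(NA_character_, n_sites)
  direction[significant & obs$diff > 0] <- names(cols)[1L]
  direction[significant & obs$diff < 0] <- names(cols)[2L]
  tab <- data.frame(
    site = keys, m$sites,
    n_a = length(idx_a), n_b = length(idx_b),
    diff = obs$diff, t = obs$t, p = p, fdr = fdr,
    significant = significant, direction = direction,
    stringsAsFactors = FALSE, row.names = NULL
  )
  higher_in <- list(
    keys[significant & obs$diff > 0],
    keys[significant & obs$diff < 0]
  )
  names(higher_in) <- names(cols)
  structure(
    list(table = tab, groups = names(cols), higher_in = higher_in,
         n_labelings = length(labelings), mode = mode,
         params = list(q = q, s0 = s0, n_perm = n_perm,
                       exhaustive_below = exhaustive_below, seed = seed),
         log = log_notes),
    class = "perm_fdr"
  )
}

# uniform random labelings (choices of the first group's columns) with the
# identity labeling 1..na excluded
draw_labelings <- function(k, na, n_perm, seed) {
  identity_key <- paste(seq_len(na), collapse = ",")
  with_seed(seed, {
    out <- vector("list", n_perm)
    i <- 1L
    while (i <= n_perm) {
      lab <- sort(sample.int(k, na))
      if (paste(lab, collapse = ",") == identity_key) next
      out[[i]] <- lab
      i <- i + 1L
    }
    out
  })
}

#' @export
print.perm_fdr <- function(x, ...) {
  n_sig <- sum(x$table$significant)
  cat(sprintf(
    "permutation-FDR two-sample test: %d sites, groups %s vs %s\n",
    nrow(x$table), x$groups[1L], x$groups[2L]))
  cat(sprintf("  %s mode, %d labelings; q = %g, s0 = %g\n",
              x$mode, x$n_labelings, x$params$q, x$params$s0))
  cat(sprintf("  significant: %d (%d higher in %s, %d higher in %s)\n",
              n_sig, length(x$higher_in[[1L]]), x$groups[1L],
              length(x$higher_in[[2L]]), x$groups[2L]))
  invisible(x)
}

#' @export
summary.perm_fdr <- function(object, ...) {
  tab <- object$table
  tab <- tab[order(tab$fdr, -abs(tab$t)), ]
  print(object)
  cat("top sites:\n")
  print(utils::head(tab[, c("site", "diff", "t", "p", "fdr", "significant")],
                    10L), row.names = FALSE)
  invisible(object)
}
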