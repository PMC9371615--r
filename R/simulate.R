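#' Simulate a two-group phosphosite intensity dataset with known truth
#'
#' Emulates the mass-spectrometry output the pipeline consumes: a site x
#' sample grid of log-normal intensities with intensity-dependent
#' (left-censored, MNAR) missingness, a fraction of group-shifted sites, a
#' fraction of group-exclusive ("presence/absence") sites, and an optional
#' protein-term annotation model with truly enriched terms. Defaults mirror
#' the study design after quality-control exclusion: 4 vs 5 samples.
#'
#' Per site `i` and sample `j` the latent log2 value is
#' `baseline_i + effect_i * [j in second group] + noise_ij`; a cell is
#' detected with probability `1 / (1 + exp(-(x - m)/s))` (logistic in
#' abundance) and its raw intensity is then `2^x`, otherwise it is missing.
#' Presence/absence sites have their "off"-group abundance fixed 8 detection
#' scales below the midpoint, i.e. effectively undetectable.
#'
#' @param n_sites number of site rows.
#' @param group_sizes named integer vector of included samples per group;
#'   default `c(DMSO = 4, neratinib = 5)`.
#' @param baseline_mean,baseline_sd site-level log2 abundance distribution;
#'   defaults 23 and 2 (typical label-free MS intensity scale).
#' @param residual_sd per-measurement noise SD in log2 units; default 0.5.
#' @param effect_fraction fraction of sites carrying a group shift;
#'   default 0.1.
#' @param effect_size shift magnitude in log2 units (default 1, i.e. 2
#'   residual SDs); sign random per site.
#' @param effect_model `"fixed"` magnitude or `"half_normal"` with scale
#'   `effect_size`.
#' @param presence_absence_fraction fraction of group-exclusive sites;
#'   default 0.05.
#' @param detection_midpoint,detection_scale logistic detection model
#'   parameters `m` and `s`; defaults 20.5 and 0.5 give roughly 10%
#'   missingness under the default abundance distribution.
#' @param n_proteins number of proteins sites are assigned to; default
#'   `ceiling(n_sites / 3)`.
#' @param n_terms,term_coverage,n_enriched_terms annotation model: number
#'   of terms, per-protein annotation probability, and number of terms whose
#'   annotated proteins preferentially receive the non-null sites. Set
#'   `n_terms = 0` to skip annotations.
#' @param seed integer seed; identical parameters and seed give identical
#'   output.
#' @return a `phospho_sim`: list with `matrix` (a raw-scale
#'   [site_matrix()]), `truth` (data.frame: `site`, `protein`, `class` in
#'   `{null, shifted, presence_absence}`, signed `effect` in log2 units —
#'   exactly 0 for null sites), `annotations` (an `annotation_map` or
#'   `NULL`), `term_truth` (data.frame `term`, `enriched`), `latent` (the
#'   noiseless-censoring log2 abundance grid underlying detection, for
#'   calibration checks) and `params`.
#' @export
simulate_phospho_dataset <- function(n_sites = 1000L,
                                     group_sizes = c(DMSO = 4L,
                                                     neratinib = 5L),
                                     baseline_mean = 23,
                                     baseline_sd = 2,
                                     residual_sd = 0.5,
                                     effect_fraction = 0.1,
                                     effect_size = 1,
                                     effect_model = c("fixed",
                                                      "half_normal"),
                                     presence_absence_fraction = 0.05,
                                     detection_midpoint = 20.5,
                                     detection_scale = 0.5,
                                     n_proteins = NULL,
                                     n_terms = 0L,
                                     term_coverage = 0.1,
                                     n_enriched_terms = 2L,
                                     seed) {
  effect_model <- match.arg(effect_model)
  if (missing(seed)) stop("a seed is mandatory for simulation")
  if (is.null(names(group_sizes)) || length(group_sizes) != 2L) {
    stop("configuration error: group_sizes must be a named vector of two")
  }
  if (any(group_sizes < 2L)) {
    stop("configuration error: group sizes must be >= 2")
  }
  if (effect_fraction < 0 || effect_fraction > 1 ||
      presence_absence_fraction < 0 || presence_absence_fraction > 1 ||
      effect_fraction + presence_absence_fraction > 1) {
    stop("configuration error: class fractions must lie in [0, 1] and sum",
         " to at most 1")
  }
  if (detection_scale <= 0) {
    stop("configuration error: detection_scale must be > 0")
  }
  if (is.null(n_proteins)) n_proteins <- ceiling(n_sites / 3)
  with_seed(seed, {
    groups <- names(group_sizes)
    samples <- data.frame(
      sample_id = unlist(lapply(groups, function(g) {
        paste0(g, "_", seq_len(group_sizes[[g]]))
      })),
      group = rep(groups, group_sizes),
      included = TRUE, stringsAsFactors = FALSE
    )
    k <- nrow(samples)
    in_b <- samples$group == groups[2L]

    proteins <- sprintf("P%05d", seq_len(n_proteins))
    site_protein <- sample(proteins, n_sites, replace = TRUE)

    annotations <- NULL
    term_truth <- data.frame(term = character(0), enriched = logical(0),
                             stringsAsFactors = FALSE)
    enriched_prot <- character(0)
    if (n_terms > 0L) {
      terms <- sprintf("T%03d", seq_len(n_terms))
      ann_mat <- matrix(stats::runif(n_proteins * n_terms) < term_coverage,
                        n_proteins, n_terms,
                        dimnames = list(proteins, terms))
      map <- apply(ann_mat, 1L, function(r) terms[r], simplify = FALSE)
      annotations <- structure(map, term_names = NULL,
                               class = "annotation_map")
      enr <- terms[seq_len(min(n_enriched_terms, n_terms))]
      term_truth <- data.frame(term = terms, enriched = terms %in% enr,
                               stringsAsFactors = FALSE)
      enriched_prot <- proteins[rowSums(
        ann_mat[, enr, drop = FALSE]) > 0L]
    }

    n_pa <- round(presence_absence_fraction * n_sites)
    n_shift <- round(effect_fraction * n_sites)
    # non-null sites land preferentially on proteins carrying an enriched
    # term so that term-level recovery is testable
    pref <- which(site_protein %in% enriched_prot)
    pool <- c(sample(pref), sample(setdiff(seq_len(n_sites), pref)))
    idx_pa <- pool[seq_len(n_pa)]
    idx_shift <- pool[n_pa + seq_len(n_shift)]
    class <- rep("null", n_sites)
    class[idx_pa] <- "presence_absence"
    class[idx_shift] <- "shifted"

    baseline <- stats::rnorm(n_sites, baseline_mean, baseline_sd)
    effect <- numeric(n_sites)
    sgn <- sample(c(-1, 1), n_sites, replace = TRUE)
    if (effect_model == "fixed") {
      effect[idx_shift] <- sgn[idx_shift] * effect_size
    } else {
      effect[idx_shift] <- sgn[idx_shift] *
        abs(stats::rnorm(n_shift, 0, effect_size))
    }

    latent <- baseline + outer(effect, as.numeric(in_b)) +
      matrix(stats::rnorm(n_sites * k, 0, residual_sd), n_sites, k)
    # group-exclusive sites: the off group sits far below the detection
    # midpoint, the on group at its baseline
    off_level <- detection_midpoint - 8 * detection_scale
    for (i in idx_pa) {
      off_in_b <- sgn[i] < 0      # negative sign: off in the second group
      off_cols <- if (off_in_b) in_b else !in_b
      latent[i, off_cols] <- off_level +
        stats::rnorm(sum(off_cols), 0, residual_sd)
      on_mean <- mean(latent[i, !off_cols])
      effect[i] <- if (off_in_b) off_level - on_mean else on_mean - off_level
    }

    p_detect <- 1 / (1 + exp(-(latent - detection_midpoint) /
                               detection_scale))
    detected <- matrix(stats::runif(n_sites * k), n_sites, k) < p_detect
    intensity <- ifelse(detected, 2^latent, NA_real_)

    sites <- data.frame(
      protein = site_protein,
      position = seq_len(n_sites),
      residue = sample(c("S", "T", "Y"), n_sites, replace = TRUE,
                       prob = c(0.85, 0.13, 0.02)),
      multiplicity = sample(1:3, n_sites, replace = TRUE,
                            prob = c(0.7, 0.25, 0.05)),
      stringsAsFactors = FALSE
    )
    m <- site_matrix(sites, samples, intensity, scale = "raw")
    truth <- data.frame(site = site_key(m), protein = site_protein,
                        class = class, effect = effect,
                        stringsAsFactors = FALSE)
    dimnames(latent) <- dimnames(m$intensity)
    structure(
      list(matrix = m, truth = truth, annotations = annotations,
           term_truth = term_truth, latent = latent,
           params = list(n_sites = n_sites, group_sizes = group_sizes,
                         baseline_mean = baseline_mean,
                         baseline_sd = baseline_sd,
                         residual_sd = residual_sd,
                         effect_fraction = effect_fraction,
                         effect_size = effect_size,
                         effect_model = effect_model,
                         presence_absence_fraction =
                           presence_absence_fraction,
                         detection_midpoint = detection_midpoint,
                         detection_scale = detection_scale,
                         n_proteins = n_proteins, n_terms = n_terms,
                         term_coverage = term_coverage,
                         n_enriched_terms = n_enriched_terms,
                         seed = seed)),
      class = "phospho_sim"
    )
  })
}

#' @export
print.phospho_sim <- function(x, ...) {
  cat("simulated phosphosite dataset\n")
  print(x$matrix)
  cat(sprintf("  truth: %s\n",
              paste(sprintf("%s=%d", names(table(x$truth$class)),
                            as.integer(table(x$truth$class))),
                    collapse = ", ")))
  invisible(x)
}

#' Score pipeline calls against simulated ground truth
#'
#' @param diff a `perm_fdr` result, or `NULL` to skip differential metrics.
#' @param classification a `presence_classification`, or `NULL` to skip
#'   detection-pattern metrics.
#' @param truth the `truth` data.frame of a [simulate_phospho_dataset()]
#'   run (or the `phospho_sim` itself).
#' @param enrichment optional `term_enrichment` result scored against the
#'   simulation's `term_truth` (pass the `phospho_sim` as `truth` to supply
#'   it).
#' @return list of recovery metrics, all in \[0, 1\]: `power` (shifted
#'   sites called significant), `fdp` (called sites whose truth class is
#'   null; 0 when nothing is called), `n_called`, and when a classification
#'   is given `pa_sensitivity` (presence/absence sites labeled enriched in
#'   their true direction) and `pa_specificity` (other sites labeled
#'   neither); with `enrichment`, `term_sensitivity` and `term_specificity`.
#' @export
evaluate_calls <- function(diff = NULL, classification = NULL, truth,
                           enrichment = NULL) {
  term_truth <- NULL
  if (inherits(truth, "phospho_sim")) {
    term_truth <- truth$term_truth
    truth <- truth$truth
  }
  out <- list()
  if (!is.null(diff)) {
    tab <- diff$table
    if (!setequal(tab$site, truth$site)) {
      idx <- match(tab$site, truth$site)
      if (anyNA(idx)) stop("site keys of calls and truth do not align")
      truth_d <- truth[idx, , drop = FALSE]
    } else {
      truth_d <- truth[match(tab$site, truth$site), , drop = FALSE]
    }
    called <- tab$significant
    shifted <- truth_d$class == "shifted"
    out$power <- if (any(shifted)) mean(called[shifted]) else NA_real_
    out$fdp <- if (any(called)) {
      mean(truth_d$class[called] == "null")
    } else 0
    out$n_called <- sum(called)
  }
  if (!is.null(classification)) {
    tab <- classification$table
    idx <- match(tab$site, truth$site)
    if (anyNA(idx)) stop("site keys of classification and truth do not align")
    truth_c <- truth[idx, , drop = FALSE]
    groups <- names(classification$enriched_sites)
    # positive effect means higher in the second group
    true_label <- ifelse(
      truth_c$class == "presence_absence",
      paste0(ifelse(truth_c$effect > 0, groups[2L], groups[1L]),
             "_enriched"),
      "neither")
    is_pa <- truth_c$class == "presence_absence"
    out$pa_sensitivity <- if (any(is_pa)) {
      mean(tab$label[is_pa] == true_label[is_pa])
    } else NA_real_
    out$pa_specificity <- if (any(!is_pa)) {
      mean(tab$label[!is_pa] == "neither")
    } else NA_real_
  }
  if (!is.null(enrichment) && !is.null(term_truth) &&
      nrow(term_truth) > 0L) {
    idx <- match(term_truth$term, enrichment$term)
    called <- !is.na(idx) & enrichment$enriched[idx]
    enr <- term_truth$enriched
    out$term_sensitivity <- if (any(enr)) mean(called[enr]) else NA_real_
    out$term_specificity <- if (any(!enr)) mean(!called[!enr]) else NA_real_
  }
  out
}
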