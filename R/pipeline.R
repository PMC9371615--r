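#' Assemble a pipeline configuration
#'
#' All stage parameters in one validated object. Defaults reproduce the
#' published statistical treatment: log2 transform, per-sample median
#' normalization, minimum of 3 valid values in at least one group,
#' downshifted-Gaussian imputation (width 0.3, downshift 1.8), two-sided
#' two-sample tests with permutation FDR at q = 0.05, and detection-pattern
#' classification at min_in = group size - 1, max_out = 1.
#'
#' @param site_table path to the phosphosite table, or a `site_matrix`.
#' @param sample_map data.frame (`sample_id`, `group`, optional `included`);
#'   required when `site_table` is a path.
#' @param annotations path to an annotation table, an `annotation_map`, or
#'   `NULL` to skip term enrichment.
#' @param out_dir output directory for result tables, or `NULL` to skip
#'   writing.
#' @param exclude character vector of sample ids excluded from every
#'   computation (the explicit QC-exclusion action).
#' @param min_valid,qc_threshold,width,downshift,impute_mode,q,s0,n_perm,
#'   exhaustive_below,min_in,max_out,enrichment_alpha stage parameters; see
#'   the stage functions.
#' @param seed master seed (mandatory); imputation and permutation streams
#'   are derived from it deterministically.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(site_table, sample_map = NULL,
                            annotations = NULL, out_dir = NULL,
                            exclude = character(0),
                            min_valid = 3L, qc_threshold = 0.7,
                            width = 0.3, downshift = 1.8,
                            impute_mode = "per_sample",
                            q = 0.05, s0 = 0, n_perm = 250L,
                            exhaustive_below = 1000L,
                            min_in = NULL, max_out = 1L,
                            enrichment_alpha = 0.05, seed) {
  if (missing(seed) || is.null(seed)) stop("a master seed is mandatory")
  structure(
    list(site_table = site_table, sample_map = sample_map,
         annotations = annotations, out_dir = out_dir, exclude = exclude,
         min_valid = min_valid, qc_threshold = qc_threshold,
         width = width, downshift = downshift, impute_mode = impute_mode,
         q = q, s0 = s0, n_perm = n_perm,
         exhaustive_below = exhaustive_below,
         min_in = min_in, max_out = max_out,
         enrichment_alpha = enrichment_alpha, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Plain-text key-value format mirroring the [pipeline_config()] arguments;
#' `sample_map` is a list of `{sample_id, group, included}` entries and
#' relative paths are resolved against the YAML file's directory.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (!grepl("^(/|[A-Za-z]:)", p)) file.path(base, p) else p
  }
  sm <- NULL
  if (!is.null(raw$sample_map)) {
    sm <- do.call(rbind, lapply(raw$sample_map, function(e) {
      data.frame(sample_id = e$sample_id, group = e$group,
                 included = if (is.null(e$included)) TRUE else e$included,
                 stringsAsFactors = FALSE)
    }))
  }
  args <- raw[setdiff(names(raw), c("site_table", "sample_map",
                                    "annotations", "out_dir"))]
  do.call(pipeline_config, c(
    list(site_table = resolve(raw$site_table), sample_map = sm,
         annotations = resolve(raw$annotations),
         out_dir = resolve(raw$out_dir)),
    args))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full differential phosphoproteomics pipeline
#'
#' Fixed stage order: read, log2 transform, sample QC (flag only), explicit
#' exclusions, median normalization, detection-pattern classification (on
#' the pre-imputation detection matrix), minimum-valid-value filter,
#' downshifted-Gaussian imputation, permutation-FDR two-sample test,
#' protein collapsing, hypergeometric term enrichment, and result writing.
#' Identical config and seed give identical outputs (the manifest timestamp
#' aside).
#'
#' @param config a `pipeline_config` (or YAML path).
#' @return a `pipeline_run`: list with `manifest` (parameters, derived
#'   seeds, excluded samples, per-stage row counts, written files) and
#'   `results` (`qc`, `classification`, `differential`, `enrichment`,
#'   `dropped_sites`, `background`, `recovery`-ready tables).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- list(impute = column_rng_seed(config$seed, "impute"),
                perm = column_rng_seed(config$seed, "permutation"))

  m <- run_stage("read", {
    if (inherits(config$site_table, "site_matrix")) config$site_table
    else read_site_table(config$site_table, config$sample_map)
  })
  n_input <- nrow(m$sites)

  logm <- run_stage("log2_transform", log2_transform(m))
  qc <- run_stage("sample_qc", sample_qc(logm, config$qc_threshold))
  if (length(config$exclude) > 0L) {
    logm <- run_stage("exclude_samples",
                      exclude_samples(logm, config$exclude))
  }
  logm <- run_stage("median_normalize", median_normalize(logm))

  det <- run_stage("detection_matrix", detection_matrix(logm))
  classification <- run_stage("classify_sites", {
    classify_sites(det, min_in = config$min_in, max_out = config$max_out)
  })

  filt <- run_stage("filter_min_valid",
                    filter_min_valid(logm, config$min_valid))
  imp <- run_stage("impute_downshift", {
    impute_downshift(filt$matrix, width = config$width,
                     downshift = config$downshift,
                     mode = config$impute_mode, seed = seeds$impute)
  })
  diff <- run_stage("perm_fdr", {
    perm_fdr(imp$matrix, q = config$q, s0 = config$s0,
             n_perm = config$n_perm,
             exhaustive_below = config$exhaustive_below,
             seed = seeds$perm)
  })

  background <- sort(unique(filt$matrix$sites$protein))
  diff_proteins <- lapply(diff$higher_in, function(keys) {
    sort(unique(filt$matrix$sites$protein[
      match(keys, site_key(filt$matrix))]))
  })

  annotations <- config$annotations
  if (is.character(annotations)) {
    annotations <- run_stage("read_annotation_table",
                             read_annotation_table(annotations))
  }
  enrichment <- NULL
  if (!is.null(annotations)) {
    enrichment <- run_stage("enrich_terms", {
      sets <- c(
        stats::setNames(diff_proteins,
                        paste0("higher_in_", names(diff_proteins))),
        stats::setNames(
          lapply(classification$proteins, intersect, x = background),
          paste0("presence_", names(classification$proteins)))
      )
      res <- lapply(names(sets), function(nm) {
        r <- enrich_terms(intersect(sets[[nm]], background), background,
                          annotations, alpha = config$enrichment_alpha)
        if (nrow(r) > 0L) cbind(set = nm, r) else NULL
      })
      do.call(rbind, res)
    })
  }

  mask_tab <- data.frame(site = rep(rownames(imp$mask), ncol(imp$mask)),
                         sample = rep(colnames(imp$mask),
                                      each = nrow(imp$mask)),
                         imputed = as.vector(imp$mask),
                         stringsAsFactors = FALSE)
  mask_tab <- mask_tab[mask_tab$imputed, c("site", "sample"), drop = FALSE]

  protein_sets <- do.call(rbind, lapply(names(classification$proteins),
    function(g) {
      p <- classification$proteins[[g]]
      if (length(p) == 0L) return(NULL)
      data.frame(group = g, protein = p, stringsAsFactors = FALSE)
    }))
  if (is.null(protein_sets)) {
    protein_sets <- data.frame(group = character(0), protein = character(0))
  }

  results <- list(qc = qc$table, dropped_sites = filt$dropped,
                  differential = diff, classification = classification,
                  protein_sets = protein_sets, enrichment = enrichment,
                  imputation_mask = mask_tab,
                  params = config[setdiff(names(config),
                                          c("site_table", "sample_map",
                                            "annotations"))])
  files <- NULL
  if (!is.null(config$out_dir)) {
    files <- run_stage("write_results",
                       write_results(results, config$out_dir))
  }
  manifest <- list(
    seed = config$seed, derived_seeds = seeds,
    excluded_samples = config$exclude,
    qc_flagged = qc$table$sample_id[qc$table$flagged],
    counts = c(input_sites = n_input,
               classified_sites = nrow(classification$table),
               filtered_sites = nrow(filt$matrix$sites),
               dropped_sites = nrow(filt$dropped),
               imputed_cells = sum(imp$mask),
               significant_sites = sum(diff$table$significant),
               enrichment_rows = if (is.null(enrichment)) 0L
                                 else nrow(enrichment)),
    files = files
  )
  structure(list(manifest = manifest, results = results,
                 filtered = filt$matrix, imputed = imp$matrix,
                 background = background, diff_proteins = diff_proteins),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("phosphopipe run\n")
  cnt <- x$manifest$counts
  for (nm in names(cnt)) cat(sprintf("  %s: %d\n", nm, cnt[[nm]]))
  if (length(x$manifest$qc_flagged) > 0L) {
    cat("  QC-flagged samples:",
        paste(x$manifest$qc_flagged, collapse = ", "), "\n")
  }
  invisible(x)
}
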