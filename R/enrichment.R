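#' Upper-tail hypergeometric p-value
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N population, K annotated, n drawn)`:
#' the probability of seeing at least `k` annotated proteins in a selection
#' of `n` from a background of `N` containing `K` annotated, i.e. the
#' classic over-representation test.
#'
#' @param k observed overlap (selected and annotated).
#' @param K annotated proteins in the background.
#' @param n selection size.
#' @param N background size.
#' @return the upper-tail probability, in (0, 1].
#' @export
hypergeom_pvalue <- function(k, K, n, N) {
  ok <- k >= 0 & K >= 0 & n >= 0 & K <= N & n <= N & k <= pmin(K, n)
  if (!all(ok)) {
    stop("input error: need 0 <= k <= min(K, n), K <= N, n <= N")
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Hypergeometric over-representation of annotation terms
#'
#' Tests every term with at least one annotated background protein for
#' over-representation in the selected protein set, with
#' Benjamini-Hochberg adjustment over all tested terms. One-sided
#' (over-representation) only.
#'
#' @param selected character vector of selected protein accessions; must be
#'   a subset of `background`.
#' @param background character vector of background accessions (by default
#'   the caller passes all proteins with a quantified site passing the
#'   validity filter).
#' @param annotations an `annotation_map` from [read_annotation_table()],
#'   or a named list mapping protein accession to a character vector of
#'   term ids.
#' @param alpha significance level on the adjusted value; default 0.05.
#' @return data.frame of class `term_enrichment`, one row per term:
#'   `term`, `name`, `k`, `K`, `n`, `N`, `p`, `q`, `enriched`, sorted by
#'   `p` then term id.
#' @export
enrich_terms <- function(selected, background, annotations, alpha = 0.05) {
  selected <- unique(as.character(selected))
  background <- unique(as.character(background))
  offenders <- setdiff(selected, background)
  if (length(offenders) > 0L) {
    stop("input error: selected proteins not in background: ",
         paste(utils::head(offenders, 5L), collapse = ", "))
  }
  term_names <- attr(annotations, "term_names")
  ann <- annotations[names(annotations) %in% background]
  term_to_bg <- split(rep(names(ann), lengths(ann)), unlist(ann))
  if (length(term_to_bg) == 0L) {
    out <- data.frame(term = character(0), name = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), p = numeric(0), q = numeric(0),
                      enriched = logical(0), stringsAsFactors = FALSE)
    class(out) <- c("term_enrichment", "data.frame")
    return(out)
  }
  n <- length(selected); N <- length(background)
  K <- vapply(term_to_bg, function(p) length(unique(p)), integer(1))
  k <- vapply(term_to_bg,
              function(p) length(intersect(unique(p), selected)), integer(1))
  p <- hypergeom_pvalue(k, K, n, N)
  q <- stats::p.adjust(p, method = "BH")
  terms <- names(term_to_bg)
  nm <- if (is.null(term_names)) rep(NA_character_, length(terms)) else {
    unname(term_names[terms])
  }
  out <- data.frame(term = terms, name = nm, k = k, K = K, n = n, N = N,
                    p = p, q = q, enriched = q <= alpha,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("term_enrichment", "data.frame")
  out
}
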