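# in-code fixtures shared across test files

# a minimal two-group matrix from an explicit grid (NA = missing)
tiny_matrix <- function(grid, groups = NULL, scale = "raw") {
  grid <- as.matrix(grid)
  k <- ncol(grid)
  if (is.null(groups)) groups <- rep(c("A", "B"), length.out = k)
  sites <- data.frame(protein = paste0("P", seq_len(nrow(grid))),
                      position = seq_len(nrow(grid)),
                      residue = "S", multiplicity = 1L)
  samples <- data.frame(sample_id = paste0("s", seq_len(k)), group = groups,
                        included = TRUE)
  site_matrix(sites, samples, grid, scale = scale)
}

# write a MaxQuant-dialect site table; rows = list of lists
write_fixture_table <- function(rows, sample_ids, path,
                                reverse = NULL, contaminant = NULL) {
  header <- c("Protein", "Position", "Amino acid", "Multiplicity",
              "Reverse", "Potential contaminant",
              paste("Intensity", sample_ids))
  lines <- vapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    paste(c(r$protein, r$position, r$residue, r$multiplicity,
            if (!is.null(reverse) && i %in% reverse) "+" else "",
            if (!is.null(contaminant) && i %in% contaminant) "+" else "",
            r$intensity), collapse = "\t")
  }, character(1))
  writeLines(c(paste(header, collapse = "\t"), lines), path)
  path
}

fixture_sample_map <- function(sample_ids, groups) {
  data.frame(sample_id = sample_ids, group = groups, included = TRUE,
             stringsAsFactors = FALSE)
}

# detection_matrix stand-in built directly from per-group counts, for
# classification tests that only need the counts
counts_detection <- function(counts_a, counts_b, size_a, size_b,
                             proteins = NULL,
                             groups = c("A", "B")) {
  n <- length(counts_a)
  if (is.null(proteins)) proteins <- paste0("P", seq_len(n))
  counts <- cbind(as.integer(counts_a), as.integer(counts_b))
  dimnames(counts) <- list(paste0(proteins, "_", seq_len(n), "_S_1"), groups)
  structure(
    list(detected = NULL, counts = counts,
         group_sizes = stats::setNames(c(size_a, size_b), groups),
         sites = data.frame(protein = proteins, position = seq_len(n),
                            residue = "S", multiplicity = 1L)),
    class = "detection_matrix"
  )
}
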