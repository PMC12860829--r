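#' Extract the cohort radiomics feature table
#'
#' One row per subject, one column per `<region>_<family>_<feature>`.
#' Regions are iterated in atlas label order and the feature order within a
#' region is fixed, so the column order is deterministic. With the 20-region
#' atlas and all families enabled this yields 2,140 columns. Features are
#' computed on SUVR-normalized volumes (whole-brain reference).
#'
#' @param cohort A [simulate_cohort()] result (or any list with `subjects`).
#' @param atlas Matching [build_parcellation()] atlas.
#' @param families Enabled feature families.
#' @param bin_width Discretization bin width on the SUVR scale.
#' @param suvr If `TRUE` (default) volumes are SUVR-normalized before
#'   extraction.
#' @return Object of class `pf_feature_table`: `values` (numeric matrix),
#'   `subjects`, `diagnosis`, `meta` (bin width, families, cohort id).
#' @export
extract_table <- function(cohort, atlas, families = radiomics_families(),
                          bin_width = 0.05, suvr = TRUE) {
  subs <- cohort$subjects
  rows <- vector("list", length(subs))
  for (k in seq_along(subs)) {
    vol <- subs[[k]]$volume
    if (!identical(dim(vol$data), dim(atlas$labels)))
      stop("subject ", subs[[k]]$id, " grid mismatches atlas shape")
    if (suvr) vol <- to_suvr(vol)
    feats <- lapply(seq_along(atlas$registry), function(i) {
      roi <- atlas$labels == i
      v <- compute_features(vol, roi, families, bin_width)
      names(v) <- paste0(atlas$registry[[i]], "_", names(v))
      v
    })
    rows[[k]] <- unlist(feats)
  }
  values <- do.call(rbind, rows)
  rownames(values) <- vapply(subs, `[[`, "", "id")
  structure(list(values = values,
                 subjects = rownames(values),
                 diagnosis = vapply(subs, `[[`, "", "diagnosis"),
                 meta = list(bin_width = bin_width, families = families,
                             cohort_id = cohort$cohort_id %||% "cohort",
                             normalized = FALSE)),
            class = "pf_feature_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pf_feature_table <- function(x, ...) {
  cat(sprintf("<pf_feature_table> %d subjects x %d features (%s)%s\n",
              nrow(x$values), ncol(x$values), x$meta$cohort_id %||% "?",
              if (isTRUE(x$meta$normalized)) ", normalized" else ""))
  invisible(x)
}

#' Build a feature table from a plain matrix
#'
#' Convenience constructor used for latent-feature blocks and synthetic
#' benchmark tables.
#'
#' @param values Numeric matrix with row (subject) and column names.
#' @param diagnosis Character vector of class labels per row.
#' @param cohort_id Cohort identifier.
#' @return A `pf_feature_table`.
#' @export
feature_table <- function(values, diagnosis, cohort_id = "cohort") {
  stopifnot(is.matrix(values), nrow(values) == length(diagnosis))
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("s%03d", seq_len(nrow(values)))
  structure(list(values = values, subjects = rownames(values),
                 diagnosis = diagnosis,
                 meta = list(cohort_id = cohort_id, normalized = FALSE)),
            class = "pf_feature_table")
}

#' Z-score a feature table against reference-cohort statistics
#'
#' Per column: `(x - mu_ref) / sd_ref` with the mean and standard deviation
#' taken from the reference (training) table. Columns whose reference
#' standard deviation is zero carry no information under this normalization
#' and are flagged and dropped.
#'
#' @param table Table to normalize.
#' @param reference_table Reference (training) table with the same columns;
#'   defaults to `table` itself.
#' @return Normalized `pf_feature_table` with `meta$norm` recording the
#'   reference statistics and `meta$dropped` the zero-variance columns.
#' @export
normalize_table <- function(table, reference_table = table) {
  if (!identical(colnames(table$values), colnames(reference_table$values)))
    stop("column mismatch between table and reference")
  mu <- colMeans(reference_table$values)
  sdv <- apply(reference_table$values, 2, sd)
  drop <- !is.finite(sdv) | sdv == 0 | !is.finite(mu)
  keep <- which(!drop)
  vals <- sweep(sweep(table$values[, keep, drop = FALSE], 2, mu[keep]),
                2, sdv[keep], `/`)
  out <- table
  out$values <- vals
  out$meta$normalized <- TRUE
  out$meta$norm <- list(mu = mu[keep], sd = sdv[keep],
                        reference = reference_table$meta$cohort_id %||% "ref")
  out$meta$dropped <- colnames(table$values)[drop]
  out
}

#' Write a feature table as TSV
#'
#' A `#`-prefixed header block records the extraction metadata (bin width,
#' families) before the tab-separated matrix.
#'
#' @param table A `pf_feature_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# cohort=%s bin_width=%s families=%s",
                     table$meta$cohort_id %||% "?",
                     table$meta$bin_width %||% "NA",
                     paste(table$meta$families %||% "NA", collapse = ",")),
             con)
  df <- data.frame(subject = table$subjects, diagnosis = table$diagnosis,
                   table$values, check.names = FALSE)
  write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
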