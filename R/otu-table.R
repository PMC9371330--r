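#' OTU count table with sample and taxon metadata
#'
#' Central data object of the pipeline: a nonnegative integer count matrix
#' (samples in rows, OTUs in columns), per-sample metadata and optional
#' per-OTU annotations (taxonomic Class, functional guild).
#'
#' @param counts numeric matrix of nonnegative counts, samples x OTUs, with
#'   unique row and column names.
#' @param sample_meta data.frame keyed by `sample_id`; recognised columns are
#'   `genotype`, `subpopulation`, `site`, `timepoint`, `doy`, `infected`,
#'   `is_control`.
#' @param otu_meta optional data.frame keyed by `otu_id` with e.g. `class`
#'   and `guild` columns.
#' @return an object of class `otu_table`.
#' @export
otu_table <- function(counts, sample_meta, otu_meta = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || (ncol(counts) > 0 && is.null(colnames(counts))))
    stop_input("counts must have sample row names and OTU column names")
  if (ncol(counts) == 0) colnames(counts) <- character()
  if (anyDuplicated(rownames(counts)))
    stop_input("duplicate sample ids: %s",
               paste(unique(rownames(counts)[duplicated(rownames(counts))]),
                     collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop_input("duplicate OTU ids: %s",
               paste(unique(colnames(counts)[duplicated(colnames(counts))]),
                     collapse = ", "))
  if (any(counts < 0) || any(!is.finite(counts)))
    stop_input("counts must be finite and nonnegative (%d offending entries)",
               sum(counts < 0 | !is.finite(counts)))
  sample_meta <- as.data.frame(sample_meta)
  if (is.null(sample_meta$sample_id))
    stop_input("sample_meta must have a sample_id column")
  missing_meta <- setdiff(rownames(counts), sample_meta$sample_id)
  if (length(missing_meta))
    stop_input("samples absent from metadata: %s",
               paste(missing_meta, collapse = ", "))
  extra_meta <- setdiff(sample_meta$sample_id, rownames(counts))
  if (length(extra_meta))
    stop_input("metadata rows without counts: %s",
               paste(extra_meta, collapse = ", "))
  sample_meta <- sample_meta[match(rownames(counts), sample_meta$sample_id), ,
                             drop = FALSE]
  rownames(sample_meta) <- sample_meta$sample_id
  if (is.null(sample_meta$is_control)) sample_meta$is_control <- FALSE
  if (!is.null(otu_meta)) {
    otu_meta <- as.data.frame(otu_meta)
    if (is.null(otu_meta$otu_id))
      stop_input("otu_meta must have an otu_id column")
    otu_meta <- otu_meta[match(colnames(counts), otu_meta$otu_id), ,
                         drop = FALSE]
    otu_meta$otu_id <- colnames(counts)
    rownames(otu_meta) <- otu_meta$otu_id
  }
  structure(list(counts = counts, sample_meta = sample_meta,
                 otu_meta = otu_meta),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d samples x %d OTUs (%d control samples)\n",
              nrow(x$counts), ncol(x$counts), sum(x$sample_meta$is_control)))
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$counts)

#' Subset an OTU table by samples and/or OTUs
#'
#' @param x an [otu_table()].
#' @param samples,otus character ids or logical/integer indices; `NULL`
#'   keeps everything.
#' @return a new `otu_table`.
#' @export
subset_table <- function(x, samples = NULL, otus = NULL) {
  stopifnot(inherits(x, "otu_table"))
  counts <- x$counts
  if (!is.null(samples)) counts <- counts[samples, , drop = FALSE]
  if (!is.null(otus)) counts <- counts[, otus, drop = FALSE]
  om <- x$otu_meta
  if (!is.null(om)) om <- om[match(colnames(counts), om$otu_id), , drop = FALSE]
  otu_table(counts,
            x$sample_meta[match(rownames(counts), x$sample_meta$sample_id), ,
                          drop = FALSE],
            om)
}

#' Read an OTU table from TSV (or BIOM-JSON) files
#'
#' The count file is either a TSV with samples in rows and OTU ids in the
#' header, or a BIOM v1 (JSON) file. Metadata is a TSV with a `sample_id`
#' column; an optional OTU annotation TSV has an `otu_id` column.
#'
#' @param counts_path path to counts TSV or `.biom` JSON.
#' @param metadata_path path to sample metadata TSV.
#' @param otu_meta_path optional path to OTU annotation TSV.
#' @return an [otu_table()].
#' @export
load_table <- function(counts_path, metadata_path, otu_meta_path = NULL) {
  if (!file.exists(counts_path)) stop_input("no such file: %s", counts_path)
  if (!file.exists(metadata_path)) stop_input("no such file: %s", metadata_path)
  counts <- if (grepl("\\.biom$", counts_path)) read_biom_json(counts_path)
            else {
              df <- read.delim(counts_path, row.names = 1, check.names = FALSE)
              as.matrix(df)
            }
  meta <- read.delim(metadata_path, check.names = FALSE)
  for (col in c("infected", "is_control"))
    if (!is.null(meta[[col]])) meta[[col]] <- as.logical(meta[[col]])
  om <- NULL
  if (!is.null(otu_meta_path)) {
    if (!file.exists(otu_meta_path)) stop_input("no such file: %s", otu_meta_path)
    om <- read.delim(otu_meta_path, check.names = FALSE)
  }
  otu_table(counts, meta, om)
}

#' Write an OTU table to TSV files
#'
#' @param x an [otu_table()].
#' @param counts_path,metadata_path,otu_meta_path output paths; `NULL`
#'   elements are skipped.
#' @return invisibly, the paths written.
#' @export
write_table <- function(x, counts_path, metadata_path = NULL,
                        otu_meta_path = NULL) {
  stopifnot(inherits(x, "otu_table"))
  df <- data.frame(sample_id = rownames(x$counts), x$counts,
                   check.names = FALSE)
  write.table(df, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(metadata_path))
    write.table(x$sample_meta, metadata_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(otu_meta_path) && !is.null(x$otu_meta))
    write.table(x$otu_meta, otu_meta_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(c(counts_path, metadata_path, otu_meta_path))
}

# BIOM v1 (JSON, dense or sparse) -> samples x OTUs count matrix.
# BIOM stores observations (OTUs) in rows; we transpose on the way in/out.
read_biom_json <- function(path) {
  b <- jsonlite::read_json(path, simplifyVector = TRUE)
  otu_ids <- if (is.data.frame(b$rows)) b$rows$id else
    vapply(b$rows, `[[`, "", "id")
  sample_ids <- if (is.data.frame(b$columns)) b$columns$id else
    vapply(b$columns, `[[`, "", "id")
  m <- matrix(0, length(otu_ids), length(sample_ids))
  if (identical(b$matrix_type, "sparse")) {
    trip <- if (is.list(b$data) && !is.matrix(b$data))
      do.call(rbind, b$data) else b$data
    m[cbind(trip[, 1] + 1, trip[, 2] + 1)] <- trip[, 3]
  } else {
    dat <- if (is.list(b$data) && !is.matrix(b$data))
      do.call(rbind, b$data) else b$data
    m[] <- dat
  }
  dimnames(m) <- list(otu_ids, sample_ids)
  t(m)
}

#' Write counts as a BIOM v1 (JSON) file
#'
#' @param x an [otu_table()] or counts matrix (samples x OTUs).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_biom_json <- function(x, path) {
  counts <- if (inherits(x, "otu_table")) x$counts else as.matrix(x)
  m <- t(counts)  # BIOM rows are observations
  nz <- which(m != 0, arr.ind = TRUE)
  obj <- list(
    id = "mycodyn", format = "Biological Observation Matrix 1.0.0",
    format_url = "http://biom-format.org",
    type = "OTU table", generated_by = "mycodyn",
    date = "1970-01-01T00:00:00",
    rows = lapply(rownames(m), function(i) list(id = i, metadata = NULL)),
    columns = lapply(colnames(m), function(i) list(id = i, metadata = NULL)),
    matrix_type = "sparse", matrix_element_type = "int",
    shape = dim(m),
    data = lapply(seq_len(nrow(nz)), function(k)
      list(nz[k, 1] - 1L, nz[k, 2] - 1L, m[nz[k, 1], nz[k, 2]]))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}

#' Flag likely contaminant OTUs from negative-control samples
#'
#' For every OTU a 2x2 presence/absence table (controls vs true samples) is
#' scored with a one-sided Fisher exact test for over-representation in
#' controls. An OTU is flagged when the score falls below `threshold` and its
#' control prevalence exceeds its sample prevalence.
#'
#' @param table an [otu_table()] whose metadata has an `is_control` flag with
#'   at least one control and one true sample.
#' @param threshold score (p-value) cutoff, default 0.1.
#' @return a `contaminant_report`: data.frame with per-OTU prevalences,
#'   `score` and `flagged`, plus the pruned table in attribute `"pruned"`.
#' @export
flag_contaminants <- function(table, threshold = 0.1) {
  stopifnot(inherits(table, "otu_table"))
  ctrl <- table$sample_meta$is_control
  if (!any(ctrl) || all(ctrl))
    stop_input("need at least one control and one non-control sample")
  pres <- table$counts > 0
  n_c <- sum(ctrl); n_s <- sum(!ctrl)
  k_c <- colSums(pres[ctrl, , drop = FALSE])
  k_s <- colSums(pres[!ctrl, , drop = FALSE])
  score <- vapply(seq_along(k_c), function(j) {
    fisher.test(matrix(c(k_c[j], n_c - k_c[j], k_s[j], n_s - k_s[j]), 2),
                alternative = "greater")$p.value
  }, 0)
  prev_c <- k_c / n_c
  prev_s <- k_s / n_s
  flagged <- score < threshold & prev_c > prev_s
  rep <- data.frame(otu_id = colnames(table$counts),
                    control_prevalence = prev_c, sample_prevalence = prev_s,
                    score = score, flagged = flagged, row.names = NULL)
  pruned <- subset_table(table, otus = !flagged)
  structure(rep, class = c("contaminant_report", "data.frame"),
            pruned = pruned, threshold = threshold)
}

#' Remove flagged contaminants and control samples
#'
#' Convenience wrapper: applies [flag_contaminants()] and returns the table
#' restricted to non-control samples and unflagged OTUs.
#'
#' @inheritParams flag_contaminants
#' @return a decontaminated [otu_table()].
#' @export
decontaminate <- function(table, threshold = 0.1) {
  rep <- flag_contaminants(table, threshold)
  pruned <- attr(rep, "pruned")
  subset_table(pruned, samples = !pruned$sample_meta$is_control)
}
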