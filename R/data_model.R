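# Domain types: count tables, sample metadata, regression design.

#' Construct a validated samples x taxa count table
#'
#' The canonical container for microbiome read counts: a samples x taxa
#' matrix of non-negative integers with unique sample and taxon
#' identifiers. Library size (per-sample total read count) is derived, not
#' stored independently, so it can never drift out of sync with the counts.
#'
#' @param counts numeric matrix of non-negative integers, samples in rows,
#'   taxa in columns. Dimnames are used as identifiers when `sample_ids` /
#'   `taxon_ids` are not given.
#' @param sample_ids,taxon_ids optional character vectors of unique IDs.
#' @return An object of class `count_table` with elements `counts`
#'   (integer matrix with dimnames), `sample_ids`, `taxon_ids`, `libsize`.
#' @export
count_table <- function(counts, sample_ids = NULL, taxon_ids = NULL) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) stop("counts must be numeric")
  if (anyNA(counts)) stop("counts contain missing values")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be integers (read counts)")
  sample_ids <- sample_ids %||% rownames(counts) %||%
    paste0("sample", seq_len(nrow(counts)))
  taxon_ids <- taxon_ids %||% colnames(counts) %||%
    paste0("taxon", seq_len(ncol(counts)))
  sample_ids <- as.character(sample_ids)
  taxon_ids <- as.character(taxon_ids)
  if (anyDuplicated(sample_ids)) stop("duplicate sample IDs")
  if (anyDuplicated(taxon_ids)) stop("duplicate taxon IDs")
  if (length(sample_ids) != nrow(counts) ||
      length(taxon_ids) != ncol(counts))
    stop("ID lengths do not match table dimensions")
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(sample_ids, taxon_ids)
  structure(
    list(counts = counts, sample_ids = sample_ids, taxon_ids = taxon_ids,
         libsize = rowSums(counts)),
    class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("count_table:", nrow(x$counts), "samples x", ncol(x$counts), "taxa\n")
  cat("  library size: median", round(stats::median(x$libsize)),
      " zero fraction:", round(mean(x$counts == 0), 3), "\n")
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

#' Read a taxa count table from delimited text or BIOM 2.1
#'
#' Delimited files must carry one header row and identifiers in the first
#' column; the separator is inferred from the extension (`.csv` = comma,
#' anything else = tab). `.biom` files are read through the biomformat
#' package when it is installed. Tables stored taxa-by-samples are
#' transposed into the canonical samples x taxa orientation.
#'
#' @param path file path.
#' @param orientation `"samples_by_taxa"` (default) or `"taxa_by_samples"`.
#' @return A [count_table()].
#' @export
read_count_table <- function(path,
                             orientation = c("samples_by_taxa",
                                             "taxa_by_samples")) {
  orientation <- match.arg(orientation)
  if (grepl("\\.biom$", path, ignore.case = TRUE)) {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("reading BIOM files requires the 'biomformat' package")
    m <- as.matrix(biomformat::biom_data(biomformat::read_biom(path)))
    # BIOM stores observations (taxa) x samples
    m <- t(m)
  } else {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    df <- read.table(path, header = TRUE, sep = sep, row.names = NULL,
                     check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(df[[1L]])
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(m)) stop("non-numeric cell in count table")
    rownames(m) <- ids
    if (orientation == "taxa_by_samples") m <- t(m)
  }
  count_table(m)
}

#' Write a count table as tab-delimited text
#'
#' Inverse of [read_count_table()]: one header row of taxon IDs and a first
#' column of sample IDs. Reading the file back reproduces the counts
#' bit-exactly.
#'
#' @param table a [count_table()].
#' @param path output path.
#' @export
write_count_table <- function(table, path) {
  stopifnot(inherits(table, "count_table"))
  df <- data.frame(sample_id = table$sample_ids, table$counts,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct sample metadata for batch correction
#'
#' Restricts a metadata frame to the named batch, key and covariate
#' columns, drops incomplete rows (strict complete-case policy on the used
#' columns only) and validates that at least two batches remain.
#'
#' @param df data.frame; sample identifiers taken from `id_col` when
#'   present, otherwise from row names.
#' @param batch_col name of the batch identifier column.
#' @param key_cols character vector of key variable column names; key
#'   variables are the exposures whose effects correction must preserve.
#' @param covariate_cols optional further adjustment columns.
#' @param id_col optional sample-ID column name.
#' @return An object of class `sample_metadata`: data frame `data` with the
#'   named columns, `sample_ids`, `batch` (factor), column-role fields and
#'   `n_dropped`, the number of incomplete rows removed.
#' @export
sample_metadata <- function(df, batch_col, key_cols,
                            covariate_cols = character(), id_col = NULL) {
  df <- as.data.frame(df)
  cols <- c(batch_col, key_cols, covariate_cols)
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols))
    stop("metadata columns not found: ", paste(missing_cols, collapse = ", "))
  ids <- if (!is.null(id_col)) as.character(df[[id_col]]) else
    rownames(df) %||% as.character(seq_len(nrow(df)))
  keep <- complete.cases(df[, cols, drop = FALSE])
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message("sample_metadata: dropped ", n_dropped,
            " incomplete row(s): ", paste(head(ids[!keep], 5), collapse = ", "))
  df <- df[keep, cols, drop = FALSE]
  ids <- ids[keep]
  if (anyDuplicated(ids)) stop("duplicate sample IDs in metadata")
  batch <- factor(df[[batch_col]])
  if (nlevels(batch) < 2)
    stop("batch column must have at least two levels after filtering")
  if (any(table(batch) < 1L)) stop("every batch level needs >= 1 sample")
  rownames(df) <- ids
  structure(
    list(data = df, sample_ids = ids, batch = batch, batch_col = batch_col,
         key_cols = key_cols, covariate_cols = covariate_cols,
         n_dropped = n_dropped),
    class = "sample_metadata")
}

#' Read sample metadata from delimited text
#'
#' @inheritParams sample_metadata
#' @param path file path (`.csv` = comma separated, otherwise tab).
#' @export
read_metadata <- function(path, batch_col, key_cols,
                          covariate_cols = character(), id_col = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (is.null(id_col) && !"sample_id" %in% c(batch_col, key_cols) &&
      "sample_id" %in% names(df))
    id_col <- "sample_id"
  sample_metadata(df, batch_col, key_cols, covariate_cols, id_col = id_col)
}

#' Align a count table and metadata on shared sample IDs
#'
#' @param table a [count_table()].
#' @param meta a [sample_metadata()].
#' @return list with the two objects restricted to common samples, in
#'   matching order.
#' @export
align_samples <- function(table, meta) {
  common <- intersect(table$sample_ids, meta$sample_ids)
  if (!length(common)) stop("no shared sample IDs between counts and metadata")
  tab <- count_table(table$counts[common, , drop = FALSE])
  keep <- match(common, meta$sample_ids)
  df <- meta$data[keep, , drop = FALSE]
  m <- sample_metadata(df, meta$batch_col, meta$key_cols,
                       meta$covariate_cols)
  m$sample_ids <- common
  rownames(m$data) <- common
  list(table = tab, meta = m)
}

#' Build the regression design for the two-part model
#'
#' Assembles `X = [Z | B]`: `Z` holds the intercept, key variables and
#' covariates (categorical columns dummy-expanded against their first level
#' in sorted order) and `B` holds the batch dummies with the reference
#' batch excluded, so a reference-batch sample has an all-zero `B` row.
#' Construction fails when `X` is rank deficient or when batch completely
#' confounds a key variable (the key variable is then indistinguishable
#' from the batch effect and correction would erase it).
#'
#' @param meta a [sample_metadata()].
#' @param ref_batch reference batch level (defaults to the first level).
#' @param with_libsize logical; attach a standardized library size column
#'   (z-score over the analyzed samples) for the library-size preserving
#'   model variant.
#' @param libsize numeric per-sample library sizes, required when
#'   `with_libsize = TRUE`.
#' @return An object of class `design_matrix`: `X`, index vectors `z_idx`
#'   and `b_idx` into its columns, `key_idx` (columns in Z derived from key
#'   variables), `ref_batch`, `batch`, and optionally `libsize`,
#'   `libsize_s`.
#' @export
build_design <- function(meta, ref_batch = NULL, with_libsize = FALSE,
                         libsize = NULL) {
  stopifnot(inherits(meta, "sample_metadata"))
  batch <- meta$batch
  ref_batch <- as.character(ref_batch %||% levels(batch)[1L])
  if (!ref_batch %in% levels(batch))
    stop("ref_batch '", ref_batch, "' is not a batch level")
  bfac <- stats::relevel(batch, ref = ref_batch)
  B <- model.matrix(~bfac)[, -1L, drop = FALSE]
  colnames(B) <- paste0("batch", setdiff(levels(bfac), ref_batch))

  zdf <- meta$data[, c(meta$key_cols, meta$covariate_cols), drop = FALSE]
  for (nm in names(zdf))
    if (is.character(zdf[[nm]]) || is.logical(zdf[[nm]]))
      zdf[[nm]] <- factor(zdf[[nm]])
  Z <- model.matrix(~., data = zdf)
  key_idx <- which(attr(Z, "assign") %in%
                     match(meta$key_cols, names(zdf)))

  X <- cbind(Z, B)
  # A key variable fully explained by batch membership cannot be separated
  # from the batch effect; check this before the generic rank test so the
  # failure mode is named.
  PB <- cbind(1, B)
  for (j in setdiff(key_idx, 1L)) {
    fit <- lm.fit(PB, Z[, j])
    if (max(abs(fit$residuals)) < 1e-8)
      stop("batch completely confounds key variable '",
           colnames(Z)[j], "'; correction cannot proceed")
  }
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient; drop collinear covariates")
  out <- list(X = X, z_idx = seq_len(ncol(Z)),
              b_idx = ncol(Z) + seq_len(ncol(B)), key_idx = key_idx,
              ref_batch = ref_batch, batch = bfac,
              sample_ids = meta$sample_ids)
  if (with_libsize) {
    if (is.null(libsize)) stop("with_libsize = TRUE requires libsize")
    if (length(libsize) != nrow(X))
      stop("libsize length does not match the design")
    out$libsize <- as.numeric(libsize)
    out$libsize_s <- as.numeric(scale(libsize))
  }
  structure(out, class = "design_matrix")
}
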