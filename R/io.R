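#' Read a count matrix
#'
#' Reads genes-by-samples count data from a delimited table (first column =
#' gene symbol, header = sample ids) or from a MatrixMarket triplet directory
#' (`matrix.mtx` plus `features.tsv`/`barcodes.tsv` sidecars, 1-based indices,
#' feature-file order defining gene order). Lines starting with `#` are
#' treated as provenance comments and skipped. Gene symbols are uppercased and
#' duplicate symbols collapsed by summation.
#'
#' @param path path to a TSV/CSV file, to a `.mtx` file, or to a directory
#'   containing `matrix.mtx`, `features.tsv` and `barcodes.tsv`.
#' @param format one of `"tsv"`, `"csv"`, `"mtx-triplet"`. Guessed from the
#'   path when omitted.
#' @return a [as_count_matrix()] validated `count_matrix`.
#' @export
read_counts <- function(path, format = c("guess", "tsv", "csv", "mtx-triplet")) {
  format <- match.arg(format)
  if (format == "guess") {
    format <- if (dir.exists(path) || grepl("\\.mtx$", path)) {
      "mtx-triplet"
    } else if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  }
  if (format == "mtx-triplet") {
    return(read_counts_mtx(path))
  }
  if (!file.exists(path)) stop(sprintf("count file not found: %s", path))
  sep <- if (format == "csv") "," else "\t"
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                      check.names = FALSE, stringsAsFactors = FALSE,
                      quote = "\""),
    error = function(e) stop(sprintf("malformed count table '%s': %s", path,
                                     conditionMessage(e)))
  )
  if (ncol(df) < 2L) {
    stop(sprintf("malformed header in '%s': need a gene column plus >=1 sample column", path))
  }
  if (!is.character(df[[1L]]) || anyNA(df[[1L]])) {
    stop(sprintf("malformed count table '%s': first column must hold gene symbols", path))
  }
  num <- df[, -1L, drop = FALSE]
  for (j in seq_along(num)) {
    if (!is.numeric(num[[j]])) {
      stop(sprintf("non-numeric count entry in column '%s'", names(num)[j]))
    }
  }
  m <- as.matrix(num)
  rownames(m) <- df[[1L]]
  as_count_matrix(m)
}

read_counts_mtx <- function(path) {
  if (dir.exists(path)) {
    mtx <- file.path(path, "matrix.mtx")
    feat <- file.path(path, "features.tsv")
    bc <- file.path(path, "barcodes.tsv")
  } else {
    mtx <- path
    feat <- file.path(dirname(path), "features.tsv")
    bc <- file.path(dirname(path), "barcodes.tsv")
  }
  if (!file.exists(mtx)) stop(sprintf("matrix file not found: %s", mtx))
  if (!file.exists(feat)) stop(sprintf("features sidecar not found: %s", feat))
  if (!file.exists(bc)) stop(sprintf("barcodes sidecar not found: %s", bc))
  sp <- Matrix::readMM(mtx)
  features <- utils::read.table(feat, sep = "\t", stringsAsFactors = FALSE)[[1L]]
  barcodes <- utils::read.table(bc, sep = "\t", stringsAsFactors = FALSE)[[1L]]
  if (length(features) != nrow(sp)) {
    stop("features sidecar length does not match matrix row count")
  }
  if (length(barcodes) != ncol(sp)) {
    stop("barcodes sidecar length does not match matrix column count")
  }
  m <- as.matrix(sp)
  dimnames(m) <- list(features, barcodes)
  as_count_matrix(m)
}

#' Write a count matrix
#'
#' TSV/CSV output carries a one-line `#` provenance comment; MatrixMarket
#' output writes `matrix.mtx` with `features.tsv`/`barcodes.tsv` sidecars into
#' a directory. `read_counts()` round-trips either representation exactly.
#'
#' @param x count matrix (coerced through [as_count_matrix()]).
#' @param path output file (TSV/CSV) or directory (mtx-triplet).
#' @param format one of `"tsv"`, `"csv"`, `"mtx-triplet"`.
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path, format = c("tsv", "csv", "mtx-triplet")) {
  x <- ensure_counts(x)
  format <- match.arg(format)
  if (format == "mtx-triplet") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    sp <- methods::as(methods::as(unclass(x), "dMatrix"), "sparseMatrix")
    Matrix::writeMM(sp, file.path(path, "matrix.mtx"))
    writeLines(rownames(x), file.path(path, "features.tsv"))
    writeLines(colnames(x), file.path(path, "barcodes.tsv"))
    return(invisible(path))
  }
  sep <- if (format == "csv") "," else "\t"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dtcsig count matrix: %d genes x %d samples", nrow(x), ncol(x)), con)
  df <- data.frame(gene = rownames(x), unclass(x), check.names = FALSE)
  utils::write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' A sample sheet maps each sample id to its model (dataset) and condition
#' (for example `control` vs `DTC`). Expected columns: `sample_id`,
#' `model_id`, `condition`.
#'
#' @param path TSV file path.
#' @return data.frame with columns sample_id, model_id, condition.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "model_id", "condition")
  if (!all(need %in% names(df))) {
    stop(sprintf("sample sheet must have columns: %s", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in sample sheet")
  df[need]
}

#' @rdname read_sample_sheet
#' @param sheet sample sheet data.frame.
#' @export
write_sample_sheet <- function(sheet, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# dtcsig sample sheet", con)
  utils::write.table(sheet, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard MSigDB interchange format: one tab-separated line per set with
#' fields name, description, members... . Descriptions are discarded; member
#' symbols are uppercased and de-duplicated preserving order.
#'
#' @param path GMT file path.
#' @return named list of character vectors (class `gene_set_collection`).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop(sprintf("GMT file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop(sprintf("GMT parse error at line %d: fewer than 3 tab-separated fields", i))
    }
    name <- fields[[1L]]
    if (name %in% names(sets)) {
      stop(sprintf("GMT parse error at line %d: duplicate set name '%s'", i, name))
    }
    members <- unique(toupper(fields[-(1:2)]))
    members <- members[nzchar(members)]
    if (length(members) == 0L) {
      stop(sprintf("GMT parse error at line %d: set '%s' has no members", i, name))
    }
    sets[[name]] <- members
  }
  structure(sets, class = "gene_set_collection")
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param descriptions optional character vector of per-set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop("gene sets must have unique names")
  }
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], toupper(sets[[i]])), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read FUCCI reporter tracks
#'
#' Long-format CSV with header `cell_id,time_h,red,green,divided,dead`: one
#' row per tracked cell per imaging timepoint, with red (G1 reporter) and
#' green (S/G2 reporter) intensities and 0/1 division and death flags. Rows
#' are canonicalized to (cell_id, time_h) order; times must be strictly
#' increasing within a cell, intensities non-negative, and death absorbing.
#'
#' @param path CSV file path.
#' @return data.frame of class `track_table`.
#' @export
read_tracks <- function(path) {
  if (!file.exists(path)) stop(sprintf("tracks file not found: %s", path))
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  as_track_table(df)
}

#' @rdname read_tracks
#' @param tracks a track table.
#' @export
write_tracks <- function(tracks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# dtcsig FUCCI tracks", con)
  utils::write.table(tracks, con, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a FUCCI track table
#'
#' @param df data.frame with columns cell_id, time_h, red, green, divided, dead.
#' @return the canonicalized (sorted, validated) data.frame, class `track_table`.
#' @export
as_track_table <- function(df) {
  need <- c("cell_id", "time_h", "red", "green", "divided", "dead")
  if (!all(need %in% names(df))) {
    stop(sprintf("track table must have columns: %s", paste(need, collapse = ",")))
  }
  df <- df[need]
  df$cell_id <- as.character(df$cell_id)
  for (col in c("time_h", "red", "green", "divided", "dead")) {
    if (!is.numeric(df[[col]])) stop(sprintf("track column '%s' must be numeric", col))
  }
  if (any(df$red < 0) || any(df$green < 0)) {
    stop("track intensities must be non-negative")
  }
  if (!all(df$divided %in% c(0, 1)) || !all(df$dead %in% c(0, 1))) {
    stop("'divided' and 'dead' must be 0/1 flags")
  }
  df <- df[order(df$cell_id, df$time_h), , drop = FALSE]
  rownames(df) <- NULL
  for (cid in unique(df$cell_id)) {
    sub <- df[df$cell_id == cid, ]
    if (any(diff(sub$time_h) <= 0)) {
      stop(sprintf("times not strictly increasing within cell '%s'", cid))
    }
    if (any(diff(sub$dead) < 0)) {
      stop(sprintf("death is absorbing but cell '%s' has a dead->alive transition", cid))
    }
  }
  class(df) <- c("track_table", "data.frame")
  df
}
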