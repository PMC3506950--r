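#' Construct and validate a feature table
#'
#' A feature table is a tibble with a `sample_id` character column followed by
#' one numeric column per feature (samples x features).  Values are
#' non-negative relative abundances; `NA` marks a value flagged as missing
#' (for example by [remove_outliers()]).  The feature kind ("taxon", "gene"
#' or "gene_set") travels as an attribute.
#'
#' @param x A data frame with a `sample_id` column and numeric feature
#'   columns.
#' @param kind One of `"taxon"`, `"gene"`, `"gene_set"`.
#' @param relative Logical; when `TRUE` (default) per-sample sums must not
#'   exceed 1 beyond a `1e-6` tolerance.
#'
#' @return A validated tibble with attributes `feature_kind` and `relative`.
#' @export
#' @examples
#' ft <- feature_table(
#'   tibble::tibble(sample_id = c("s1", "s2"), a = c(0.6, 0.5), b = c(0.4, 0.5))
#' )
#' feature_kind(ft)
feature_table <- function(x, kind = c("taxon", "gene", "gene_set"),
                          relative = TRUE) {
  kind <- match.arg(kind)
  x <- tibble::as_tibble(x)
  if (!"sample_id" %in% names(x)) {
    abort("A feature table needs a `sample_id` column.")
  }
  x <- dplyr::relocate(x, "sample_id")
  x$sample_id <- as.character(x$sample_id)
  if (anyDuplicated(x$sample_id)) {
    dup <- unique(x$sample_id[duplicated(x$sample_id)])
    abort(paste0("Duplicate sample IDs: ", toString(utils::head(dup, 5))))
  }
  feats <- setdiff(names(x), "sample_id")
  if (length(feats) == 0L) abort("Feature table has no feature columns.")
  if (anyDuplicated(feats)) abort("Duplicate feature IDs.")
  for (f in feats) {
    v <- x[[f]]
    if (!is.numeric(v)) {
      abort(sprintf("Feature column '%s' is not numeric.", f))
    }
    bad <- which(!is.na(v) & v < 0)
    if (length(bad)) {
      abort(sprintf("Negative abundance at sample '%s', feature '%s': %g",
                    x$sample_id[bad[1]], f, v[bad[1]]))
    }
  }
  if (relative) {
    sums <- rowSums(as.matrix(x[feats]), na.rm = TRUE)
    over <- which(sums > 1 + 1e-6)
    if (length(over)) {
      abort(sprintf(
        "Per-sample abundance sum exceeds 1 for sample '%s' (sum = %g).",
        x$sample_id[over[1]], sums[over[1]]))
    }
  }
  attr(x, "feature_kind") <- kind
  attr(x, "relative") <- relative
  x
}

#' @rdname feature_table
#' @export
feature_kind <- function(x) attr(x, "feature_kind") %||% "taxon"

#' Feature table as a numeric matrix
#'
#' @param x A feature table.
#' @return A samples x features numeric matrix with sample IDs as row names.
#' @export
feature_matrix <- function(x) {
  m <- as.matrix(x[setdiff(names(x), "sample_id")])
  rownames(m) <- x$sample_id
  storage.mode(m) <- "double"
  m
}

# Inverse of feature_matrix(): rebuild the tibble, preserving kind.
matrix_to_feature_table <- function(m, kind = "taxon", relative = TRUE) {
  out <- tibble::as_tibble(as.data.frame(m, check.names = FALSE))
  out <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(m)), out)
  feature_table(out, kind = kind, relative = relative)
}

#' Read a feature table from TSV
#'
#' Reads a tab-delimited abundance table in either orientation and returns
#' the canonical samples x features layout.  The field uses both conventions;
#' PCL-style files put features as rows.
#'
#' @param path Path to a TSV file with an ID header row and ID first column.
#' @param orientation `"samples_as_rows"` (default) or `"features_as_rows"`.
#' @inheritParams feature_table
#' @return A feature table tibble (see [feature_table()]).
#' @export
read_feature_table <- function(path,
                               orientation = c("samples_as_rows",
                                               "features_as_rows"),
                               kind = c("taxon", "gene", "gene_set"),
                               relative = TRUE) {
  orientation <- match.arg(orientation)
  kind <- match.arg(kind)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = c("", "NA"), progress = FALSE)
  if (ncol(raw) < 2L) abort(sprintf("'%s': expected an ID column plus data.", path))
  ids <- raw[[1]]
  body <- raw[-1]
  num <- purrr::imap(body, function(col, nm) {
    out <- suppressWarnings(as.numeric(col))
    bad <- which(!is.na(col) & is.na(out))
    if (length(bad)) {
      abort(sprintf("'%s': non-numeric cell '%s' in column '%s', row %d.",
                    path, col[bad[1]], nm, bad[1]))
    }
    out
  })
  m <- do.call(cbind, num)
  rownames(m) <- ids
  if (orientation == "features_as_rows") m <- t(m)
  matrix_to_feature_table(m, kind = kind, relative = relative)
}

#' Write a feature table to TSV
#'
#' Missing values are written as `NA`.  Orientation is samples as rows, the
#' package's canonical layout; [read_feature_table()] round-trips it.
#'
#' @param x A feature table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path) {
  readr::write_tsv(x, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read a sample metadata table from TSV
#'
#' Samples are rows.  The empty string and the literal `NA` both mark a
#' missing cell; missingness is kept explicit (as `NA`), never dropped.
#'
#' @param path Path to a TSV with a `sample_id` column.
#' @param type_spec Named character vector mapping metadata names to
#'   `"continuous"` or `"categorical"`.  Columns not named are guessed
#'   (numeric-parseable -> continuous).
#' @return A tibble with `sample_id` plus typed columns: `numeric` for
#'   continuous metadata, `factor` for categorical.
#' @export
read_metadata <- function(path, type_spec = NULL) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = c("", "NA"), progress = FALSE)
  if (!"sample_id" %in% names(raw)) names(raw)[1] <- "sample_id"
  raw$sample_id <- as.character(raw$sample_id)
  if (anyDuplicated(raw$sample_id)) abort(sprintf("'%s': duplicate sample IDs.", path))
  for (nm in setdiff(names(raw), "sample_id")) {
    declared <- if (!is.null(type_spec) && nm %in% names(type_spec)) {
      type_spec[[nm]]
    } else if (all(!is.na(suppressWarnings(as.numeric(raw[[nm]])) ) |
                   is.na(raw[[nm]]))) "continuous" else "categorical"
    if (declared == "continuous") {
      parsed <- suppressWarnings(as.numeric(raw[[nm]]))
      bad <- which(!is.na(raw[[nm]]) & is.na(parsed))
      if (length(bad)) {
        abort(sprintf(
          "'%s': column '%s' declared continuous but cell '%s' (row %d) is not numeric.",
          path, nm, raw[[nm]][bad[1]], bad[1]))
      }
      raw[[nm]] <- parsed
    } else if (declared == "categorical") {
      raw[[nm]] <- factor(raw[[nm]])
    } else {
      abort(sprintf("Unknown metadata type '%s' for column '%s'.", declared, nm))
    }
  }
  raw
}

#' Write a metadata table to TSV
#' @param meta Metadata tibble as returned by [read_metadata()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  readr::write_tsv(meta, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Metadata column types
#'
#' @param meta A metadata tibble.
#' @return A tibble with columns `metadatum` and `type`
#'   (`continuous`/`categorical`).
#' @export
metadata_types <- function(meta) {
  cols <- setdiff(names(meta), "sample_id")
  tibble::tibble(
    metadatum = cols,
    type = purrr::map_chr(cols, function(nm) {
      if (is.numeric(meta[[nm]])) "continuous" else "categorical"
    })
  )
}

# Check a (features, metadata) pair is row-aligned on sample_id.
align_samples <- function(features, meta) {
  missing <- setdiff(features$sample_id, meta$sample_id)
  if (length(missing)) {
    abort(paste0("Samples absent from metadata: ",
                 toString(utils::head(missing, 5))))
  }
  meta[match(features$sample_id, meta$sample_id), , drop = FALSE]
}

#' Read a gene-set membership map
#'
#' @param path TSV with two columns: `gene_set_id`, `ko_id`.
#' @return A tibble with those two character columns.
#' @export
read_gene_set_map <- function(path) {
  m <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
  names(m)[1:2] <- c("gene_set_id", "ko_id")
  m
}
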