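# Dataset manifests, label merging, and feature-view I/O.

# Canonical category tokens and accepted synonyms (matched case-insensitively,
# with "-", " " and "." treated as "_"). Anything else is an error: a manifest
# row must never be silently dropped or guessed.
.categories <- c("leukoplakia_with_dysplasia", "leukoplakia_without_dysplasia", "oscc")

.category_synonyms <- list(
  leukoplakia_with_dysplasia = c(
    "leukoplakia_with_dysplasia", "leuko_dysplasia", "leukoplakia_dysplasia",
    "with_dysplasia"
  ),
  leukoplakia_without_dysplasia = c(
    "leukoplakia_without_dysplasia", "leuko_no_dysplasia", "no_dysplasia",
    "without_dysplasia"
  ),
  oscc = c("oscc", "carcinoma", "oral_squamous_cell_carcinoma")
)

normalize_category <- function(x) {
  key <- gsub("[-. ]", "_", tolower(trimws(x)))
  out <- rep(NA_character_, length(key))
  for (canon in names(.category_synonyms)) {
    out[key %in% .category_synonyms[[canon]]] <- canon
  }
  out
}

#' Category levels recognized in a dataset manifest
#'
#' Three histopathological categories: leukoplakia with epithelial dysplasia,
#' leukoplakia without dysplasia, and oral squamous cell carcinoma (OSCC).
#'
#' @return Character vector of the canonical category tokens.
#' @export
manifest_categories <- function() .categories

#' Load a dataset manifest from CSV
#'
#' Reads a manifest with header columns `sample_id`, `category`, and
#' optionally `image_path`. Category strings are matched case-insensitively
#' against a fixed vocabulary with documented synonyms (see
#' [manifest_categories()]); unknown strings are an error naming the row.
#' Binary labels are left unset; call [merge_labels()] to derive them.
#'
#' @param path Path to a UTF-8 CSV file.
#' @return A `data.frame` with columns `sample_id`, `image_path` (NA when
#'   absent), `category`, and `label` (all `NA` until merged), preserving
#'   file row order.
#' @seealso [merge_labels()], [summarize_manifest()]
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop_input("manifest file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("sample_id", "category") %in% names(df))) {
    stop_input("manifest must have header columns 'sample_id' and 'category'; got: ",
               paste(names(df), collapse = ", "))
  }
  as_manifest(
    sample_id = df$sample_id,
    category = df$category,
    image_path = if ("image_path" %in% names(df)) df$image_path else NA_character_
  )
}

#' Build a manifest from vectors
#'
#' @param sample_id Unique, non-empty sample identifiers.
#' @param category Category strings (canonical tokens or synonyms).
#' @param image_path Optional image paths; the pipeline is feature-first and
#'   only extraction backends require images.
#' @return Manifest `data.frame` (see [load_manifest()]).
#' @export
as_manifest <- function(sample_id, category, image_path = NA_character_) {
  sample_id <- as.character(sample_id)
  if (length(sample_id) == 0) {
    return(data.frame(sample_id = character(), image_path = character(),
                      category = character(), label = character(),
                      stringsAsFactors = FALSE))
  }
  if (anyNA(sample_id) || any(!nzchar(sample_id))) {
    stop_input("sample_id must be non-empty for every row (rows ",
               paste(which(is.na(sample_id) | !nzchar(sample_id)), collapse = ", "), ")")
  }
  dup <- unique(sample_id[duplicated(sample_id)])
  if (length(dup) > 0) {
    stop_input("duplicated sample_id: ", paste(dup, collapse = ", "))
  }
  canon <- normalize_category(category)
  if (anyNA(canon)) {
    bad <- which(is.na(canon))[1]
    stop_input("unknown category '", category[bad], "' in row ", bad,
               " (sample_id '", sample_id[bad], "'); expected one of: ",
               paste(.categories, collapse = ", "))
  }
  data.frame(
    sample_id = sample_id,
    image_path = rep_len(as.character(image_path), length(sample_id)),
    category = canon,
    label = NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Write a manifest to CSV
#'
#' @param manifest Manifest `data.frame`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest[, c("sample_id", "image_path", "category")],
                   path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Merge the three categories into binary presence/absence labels
#'
#' Presence of dysplasia (`"P"`) covers leukoplakia with dysplasia and OSCC;
#' absence (`"A"`) is leukoplakia without dysplasia. OSCC is included in the
#' presence class by the labeling convention of the source dataset even
#' though not every carcinoma necessarily exhibits dysplasia; the rule is a
#' labeling convention, not a pathological claim. The operation is total over
#' the three categories and idempotent.
#'
#' @param manifest Manifest `data.frame` with all categories set.
#' @return The manifest with `label` set for every sample.
#' @export
merge_labels <- function(manifest) {
  manifest$label <- ifelse(manifest$category == "leukoplakia_without_dysplasia", "A", "P")
  manifest
}

#' Summarize class composition of a labeled manifest
#'
#' Counts are exact integers; percentages are stored unrounded (rounding to
#' integer percent happens only in the print method). The imbalance ratio is
#' `n_P / n_A`, flagged undefined when there are no absence samples.
#'
#' @param manifest Manifest with labels set (see [merge_labels()]).
#' @return An object of class `manifest_summary`: a list with `n_total`,
#'   `n_P`, `n_A`, `pct_P`, `pct_A`, `imbalance_ratio`, and
#'   `ratio_defined`.
#' @export
summarize_manifest <- function(manifest) {
  if (nrow(manifest) > 0 && anyNA(manifest$label)) {
    stop_input("labels unset; call merge_labels() first")
  }
  n_P <- sum(manifest$label == "P")
  n_A <- sum(manifest$label == "A")
  n <- n_P + n_A
  structure(list(
    n_total = n,
    n_P = n_P,
    n_A = n_A,
    pct_P = if (n > 0) 100 * n_P / n else NA_real_,
    pct_A = if (n > 0) 100 * n_A / n else NA_real_,
    imbalance_ratio = if (n_A > 0) n_P / n_A else NA_real_,
    ratio_defined = n_A > 0
  ), class = "manifest_summary")
}

#' @export
print.manifest_summary <- function(x, ...) {
  cat(sprintf("Samples: %d total, %d presence (P), %d absence (A)\n",
              x$n_total, x$n_P, x$n_A))
  if (x$n_total > 0) {
    cat(sprintf("Class share: ~%d%% P vs ~%d%% A\n",
                round(x$pct_P), round(x$pct_A)))
  }
  if (x$ratio_defined) {
    cat(sprintf("Imbalance ratio (P:A): %.2f (~%d:1)\n",
                x$imbalance_ratio, round(x$imbalance_ratio)))
  } else {
    cat("Imbalance ratio: undefined (no absence samples)\n")
  }
  invisible(x)
}

#' Construct a feature view
#'
#' A feature view is an n-samples x d-features numeric matrix tagged with a
#' view name and aligned sample ids. Entries must be finite.
#'
#' @param view_name Name of the view (e.g. `"view1"`).
#' @param sample_ids Character vector of sample ids, one per row.
#' @param matrix Numeric matrix, rows aligned with `sample_ids`.
#' @return An object of class `feature_view`.
#' @export
feature_view <- function(view_name, sample_ids, matrix) {
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"
  sample_ids <- as.character(sample_ids)
  if (nrow(matrix) != length(sample_ids)) {
    stop_input("feature matrix has ", nrow(matrix), " rows but ",
               length(sample_ids), " sample ids")
  }
  if (ncol(matrix) < 1) stop_input("feature view must have at least one feature")
  if (any(!is.finite(matrix))) {
    bad <- which(!is.finite(matrix), arr.ind = TRUE)[1, ]
    stop_input("non-finite feature value at row ", bad[1], ", column ", bad[2])
  }
  if (anyDuplicated(sample_ids)) stop_input("duplicated sample ids in feature view")
  rownames(matrix) <- sample_ids
  structure(list(view_name = as.character(view_name),
                 sample_ids = sample_ids,
                 matrix = matrix),
            class = "feature_view")
}

#' @export
print.feature_view <- function(x, ...) {
  cat(sprintf("Feature view '%s': %d samples x %d features\n",
              x$view_name, nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' @export
dim.feature_view <- function(x) dim(x$matrix)

#' Read a feature view from delimited text
#'
#' Expects a header line `sample_id,f0,f1,...` (comma or tab separated; the
#' separator is auto-detected from the header). All non-id cells must be
#' numeric; ragged rows or non-numeric cells are errors naming the row.
#'
#' @param path Path to the file.
#' @param view_name View name to tag the result with; defaults to the file
#'   name without extension.
#' @return A [feature_view()].
#' @export
read_feature_view <- function(path, view_name = NULL) {
  if (!file.exists(path)) stop_input("feature view file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, colClasses = "character",
                          check.names = FALSE, fill = FALSE)
  if (names(df)[1] != "sample_id") {
    stop_input("first column of a feature view file must be 'sample_id', got '",
               names(df)[1], "'")
  }
  if (ncol(df) < 2) stop_input("feature view file has no feature columns")
  mat <- matrix(NA_real_, nrow = nrow(df), ncol = ncol(df) - 1L)
  for (j in 2:ncol(df)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop_input("non-numeric cell in data row ", bad, ", column '",
                 names(df)[j], "': '", df[[j]][bad], "'")
    }
    mat[, j - 1L] <- v
  }
  colnames(mat) <- names(df)[-1]
  if (is.null(view_name)) view_name <- sub("\\.[^.]*$", "", basename(path))
  feature_view(view_name, df$sample_id, mat)
}

#' Write a feature view to delimited text
#'
#' Values are written with 17 significant digits so that a write/read
#' round-trip reproduces the matrix bit-exactly.
#'
#' @param view A [feature_view()].
#' @param path Output file path.
#' @param sep Field separator, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_feature_view <- function(view, path, sep = ",") {
  stopifnot(inherits(view, "feature_view"))
  cn <- colnames(view$matrix)
  if (is.null(cn)) cn <- paste0("f", seq_len(ncol(view$matrix)) - 1L)
  header <- paste(c("sample_id", cn), collapse = sep)
  body <- vapply(seq_len(nrow(view$matrix)), function(i) {
    paste(c(view$sample_ids[i], sprintf("%.17g", view$matrix[i, ])), collapse = sep)
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
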