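#' Construct a person-by-measure score matrix
#'
#' The basic container for the package: a numeric matrix with one row per
#' person and one column per performance measure, oriented so that (after any
#' reversal) higher values mean better performance.
#'
#' @param values numeric matrix (or data frame of numerics), n persons by
#'   p measures, p >= 3. `NA` marks missing scores.
#' @param person_ids character or integer vector of unique person
#'   identifiers; defaults to existing rownames or `1:n`.
#' @param measure_names optional column labels; defaults to existing
#'   colnames or `m01, m02, ...`.
#' @param standardized logical; set by [standardize()], do not set by hand
#'   unless the columns really are z-scores.
#' @return an object of class `score_matrix` (a numeric matrix with
#'   attributes `person_ids` and `standardized`).
#' @seealso [read_scores()], [standardize()], [wim_wisd()]
#' @export
score_matrix <- function(values, person_ids = NULL, measure_names = NULL,
                         standardized = FALSE) {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  n <- nrow(values); p <- ncol(values)
  if (p < 3L) stop("a score matrix needs at least 3 measures, got ", p)
  if (is.null(person_ids)) {
    person_ids <- if (!is.null(rownames(values))) rownames(values)
                  else as.character(seq_len(n))
  }
  person_ids <- as.character(person_ids)
  if (length(person_ids) != n)
    stop("length(person_ids) != nrow(values)")
  dup <- person_ids[duplicated(person_ids)]
  if (length(dup))
    stop("duplicate person_id(s): ", paste(unique(dup), collapse = ", "))
  if (is.null(measure_names)) {
    measure_names <- if (!is.null(colnames(values))) colnames(values)
                     else sprintf("m%02d", seq_len(p))
  }
  dimnames(values) <- list(person_ids, measure_names)
  structure(values,
            standardized = isTRUE(standardized),
            class = c("score_matrix", "matrix", "array"))
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("score_matrix: %d persons x %d measures%s, %d missing cells\n",
              nrow(x), ncol(x),
              if (is_standardized(x)) " (standardized)" else "",
              sum(is.na(x))))
  invisible(x)
}

#' Test whether a score matrix has been standardized
#' @param m a `score_matrix`
#' @return logical flag set by [standardize()]
#' @export
is_standardized <- function(m) isTRUE(attr(m, "standardized"))

person_ids <- function(m) rownames(m)

# rebuild the object after a transformation, preserving/overriding attrs
restamp <- function(values, template, standardized = NULL) {
  out <- score_matrix(values,
                      person_ids = rownames(values),
                      measure_names = colnames(values),
                      standardized = if (is.null(standardized))
                        is_standardized(template) else standardized)
  out
}

#' Read a score table from CSV
#'
#' Expects a header row, one row per person, one identifier column and at
#' least three numeric score columns. Blank cells and `NA` become missing
#' values; any other non-numeric score cell is an error naming the row and
#' column.
#'
#' @param path CSV file path.
#' @param id_column name of the identifier column (default `"person_id"`).
#' @return a [score_matrix()].
#' @export
read_scores <- function(path, id_column = "person_id") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "character", na.strings = c("", "NA"))
  if (!id_column %in% names(df))
    stop("id column '", id_column, "' not found in ", path)
  ids <- df[[id_column]]
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate person_id(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  sc <- df[setdiff(names(df), id_column)]
  if (ncol(sc) < 3L)
    stop("need at least 3 score columns, found ", ncol(sc))
  vals <- matrix(NA_real_, nrow(sc), ncol(sc),
                 dimnames = list(ids, names(sc)))
  for (j in seq_len(ncol(sc))) {
    raw <- sc[[j]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(num))
    if (length(bad))
      stop("non-numeric value '", raw[bad[1]], "' in column '",
           names(sc)[j], "', row ", bad[1])
    vals[, j] <- num
  }
  score_matrix(vals, person_ids = ids)
}

#' Write a score matrix to CSV
#'
#' Inverse of [read_scores()]: the identifier column is written first,
#' missing cells as empty fields.
#'
#' @param m a `score_matrix`.
#' @param path output file path.
#' @param id_column name for the identifier column.
#' @return `path`, invisibly.
#' @export
write_scores <- function(m, path, id_column = "person_id") {
  df <- data.frame(person_ids(m), as.data.frame(unclass(m)[, , drop = FALSE]),
                   check.names = FALSE)
  names(df)[1] <- id_column
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
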