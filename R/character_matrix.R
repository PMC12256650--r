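#' Binary presence/absence character matrix
#'
#' Taxa in rows, characters in columns; cells are 1 (present), 0 (absent) or
#' `NA` (unknown, the `?` of the TSV dialect). Unknowns are carried as a
#' third state and never coerced: an unassessable morphological character
#' must not generate loss events.
#'
#' @param mat integer (or logical) matrix with unique row and column names;
#'   values in \{0, 1, NA\}
#' @return an object of class `character_matrix`
#' @export
character_matrix <- function(mat) {
  if (!is.matrix(mat)) stop("`mat` must be a matrix", call. = FALSE)
  if (nrow(mat) < 1L || ncol(mat) < 1L) {
    stop("matrix needs at least one taxon and one character", call. = FALSE)
  }
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop("matrix must have taxon row names and character column names", call. = FALSE)
  }
  if (anyDuplicated(rownames(mat))) {
    stop("duplicate taxon label(s): ",
         paste(unique(rownames(mat)[duplicated(rownames(mat))]), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(colnames(mat))) {
    stop("duplicate character label(s): ",
         paste(unique(colnames(mat)[duplicated(colnames(mat))]), collapse = ", "), call. = FALSE)
  }
  storage.mode(mat) <- "integer"
  bad <- !(mat %in% c(0L, 1L, NA_integer_))
  if (any(bad)) {
    idx <- which(matrix(bad, nrow(mat)), arr.ind = TRUE)[1L, ]
    stop(sprintf("invalid cell value at taxon '%s', character '%s'",
                 rownames(mat)[idx[1L]], colnames(mat)[idx[2L]]), call. = FALSE)
  }
  structure(mat, class = c("character_matrix", "matrix", "array"))
}

#' @export
print.character_matrix <- function(x, ...) {
  cat("character_matrix:", nrow(x), "taxa x", ncol(x), "characters;",
      sum(is.na(x)), "unknown cells\n")
  invisible(x)
}

#' Taxon labels of a character matrix
#' @param x a `character_matrix`
#' @return character vector
#' @export
matrix_taxa <- function(x) rownames(x)

#' Character labels of a character matrix
#' @param x a `character_matrix`
#' @return character vector
#' @export
matrix_characters <- function(x) colnames(x)
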