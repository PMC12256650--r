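#' Read a presence/absence matrix from TSV
#'
#' Dialect: tab-separated, header row of character labels, first column taxon
#' labels, cells in `0`, `1`, `?`. A `?` cell is read as unknown (`NA`) and
#' the total unknown count is logged.
#'
#' @param path TSV file path
#' @return a [character_matrix()]
#' @export
read_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", quote = "")
  if (ncol(df) < 2L) stop("matrix file needs a taxon column and >=1 character column", call. = FALSE)
  taxa <- df[[1L]]
  if (anyDuplicated(taxa)) {
    stop("duplicate taxon label(s): ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "), call. = FALSE)
  }
  chars <- colnames(df)[-1L]
  cells <- as.matrix(df[, -1L, drop = FALSE])
  bad <- !(cells %in% c("0", "1", "?"))
  if (any(bad)) {
    idx <- which(matrix(bad, nrow(cells)), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-{0,1,?} cell '%s' at taxon '%s', character '%s'",
                 cells[idx[1L], idx[2L]], taxa[idx[1L]], chars[idx[2L]]), call. = FALSE)
  }
  n_unknown <- sum(cells == "?")
  mat <- matrix(NA_integer_, nrow(cells), ncol(cells),
                dimnames = list(taxa, chars))
  mat[cells == "0"] <- 0L
  mat[cells == "1"] <- 1L
  if (n_unknown > 0L) {
    warning(sprintf("%d unknown ('?') cell(s) read as third state", n_unknown), call. = FALSE)
  }
  log_msg("read matrix: ", nrow(mat), " taxa x ", ncol(mat), " characters, ",
          n_unknown, " unknown cells")
  character_matrix(mat)
}

#' Write a character matrix in the TSV dialect [read_matrix()] reads
#'
#' @param x a `character_matrix`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_matrix <- function(x, path) {
  stopifnot(inherits(x, "character_matrix"))
  cells <- matrix(as.character(unclass(x)), nrow(x), dimnames = dimnames(x))
  cells[is.na(cells)] <- "?"
  df <- data.frame(taxon = rownames(x), cells, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted tree from Newick
#'
#' Internal node labels are kept; unlabeled internal nodes are auto-named
#' `N1, N2, ...` in preorder so reports are reproducible. Unbalanced
#' parentheses are reported with their character position.
#'
#' @param path path to a Newick file (ignored when `text` is given)
#' @param text optional Newick string
#' @return a [as_phylo_tree()] `phylo_tree`
#' @export
read_newick <- function(path = NULL, text = NULL) {
  if (is.null(text)) text <- paste(readLines(path, warn = FALSE), collapse = "")
  depth <- 0L
  for (i in seq_len(nchar(text))) {
    ch <- substr(text, i, i)
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("Newick parse error: unmatched ')' at position ", i, call. = FALSE)
    }
  }
  if (depth != 0L) {
    stop("Newick parse error: ", depth, " unclosed '(' at end of input (position ",
         nchar(text), ")", call. = FALSE)
  }
  phy <- ape::read.tree(text = text)
  if (is.null(phy)) stop("Newick parse error: could not parse tree", call. = FALSE)
  as_phylo_tree(phy)
}

#' Mapped-read intervals (BED6)
#'
#' Coordinates are 0-based half-open throughout: a read on `[start, end)` has
#' length `end - start`, its 5' end is `start` on the plus strand and
#' `end - 1` on the minus strand.
#'
#' @param contig,start,end,name,score,strand equal-length vectors
#' @return a data.frame of class `read_set` with a computed `length` column
#' @export
read_set <- function(contig, start, end, name = NULL, score = NULL, strand) {
  n <- length(contig)
  name <- name %||% if (n) paste0("r", seq_len(n)) else character(0)
  score <- score %||% rep(0L, n)
  start <- as.integer(start); end <- as.integer(end)
  if (any(start < 0L)) stop("negative start coordinate", call. = FALSE)
  if (any(end <= start)) {
    stop("end <= start at record ", which(end <= start)[1L], call. = FALSE)
  }
  if (!all(strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-' (record ",
         which(!(strand %in% c("+", "-")))[1L], ")", call. = FALSE)
  }
  structure(data.frame(contig = as.character(contig), start = start, end = end,
                       name = as.character(name), score = score,
                       strand = as.character(strand),
                       length = end - start, stringsAsFactors = FALSE),
            class = c("read_set", "data.frame"))
}

#' Read mapped small-RNA reads from a BED6 file
#'
#' @param path BED6 file (contig, start, end, name, score, strand); 0-based
#'   half-open
#' @return a [read_set()] preserving input order
#' @export
read_bed <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) {
    warning("empty BED file: ", path, call. = FALSE)
    return(read_set(character(0), integer(0), integer(0), strand = character(0)))
  }
  df <- utils::read.delim(path, header = FALSE, sep = "\t", quote = "",
                          colClasses = "character")
  if (ncol(df) < 6L) stop("BED6 required: missing strand column in ", path, call. = FALSE)
  read_set(contig = df[[1L]], start = as.integer(df[[2L]]), end = as.integer(df[[3L]]),
           name = df[[4L]], score = df[[5L]], strand = df[[6L]])
}

#' Write a read set as BED6
#' @param x a `read_set`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_bed <- function(x, path) {
  stopifnot(inherits(x, "read_set"))
  utils::write.table(x[, c("contig", "start", "end", "name", "score", "strand")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read contig lengths from a two-column TSV (contig, length)
#' @param path TSV path, no header
#' @return named integer vector of contig lengths
#' @export
read_genome_lengths <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t", quote = "")
  if (ncol(df) < 2L) stop("genome lengths file needs two columns", call. = FALSE)
  len <- as.integer(df[[2L]])
  if (any(is.na(len)) || any(len <= 0L)) stop("contig lengths must be positive integers", call. = FALSE)
  stats::setNames(len, as.character(df[[1L]]))
}

#' Read a per-species summary table (TSV with header)
#'
#' Expected columns include `taxon` plus any of `mirna_losses`,
#' `busco_losses`, `gene_count`, `n50`, `morph_losses`.
#'
#' @param path TSV path
#' @return data.frame
#' @export
read_species_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE, quote = "")
  if (!"taxon" %in% colnames(df)) stop("species table needs a 'taxon' column", call. = FALSE)
  num <- setdiff(colnames(df), "taxon")
  cnt <- intersect(c("mirna_losses", "busco_losses", "gene_count", "morph_losses"), num)
  if (length(cnt) && any(df[cnt] < 0, na.rm = TRUE)) {
    stop("counts must be >= 0", call. = FALSE)
  }
  if ("n50" %in% num && any(df$n50 <= 0, na.rm = TRUE)) stop("n50 must be > 0", call. = FALSE)
  df
}

#' Serialise a pipeline result to a plain list for JSON reporting
#' @param x a result object
#' @param ... unused
#' @return list
#' @export
as_report_payload <- function(x, ...) UseMethod("as_report_payload")

#' @export
as_report_payload.default <- function(x, ...) x

#' @export
as_report_payload.data.frame <- function(x, ...) {
  as.list(x[order(names(x) == "", seq_along(x))])  # keep column order, emit as columns
}

#' Write a machine-readable JSON report
#'
#' Keys are sorted recursively so two writes of the same payload are
#' byte-identical; run metadata (package version, seed, parameters) is
#' embedded under `metadata`.
#'
#' @param results a result object or named list of result objects
#' @param path output path
#' @param seed seed used for the run (or `NULL`)
#' @param parameters named list of run parameters
#' @return `path`, invisibly
#' @export
write_report <- function(results, path, seed = NULL, parameters = list()) {
  payload <- if (is.list(results) && !is.data.frame(results) && is.null(attr(results, "class"))) {
    lapply(results, as_report_payload)
  } else {
    as_report_payload(results)
  }
  doc <- list(
    metadata = list(
      package = "dolloscan",
      version = as.character(utils::packageVersion("dolloscan")),
      seed = seed,
      parameters = parameters
    ),
    results = payload
  )
  doc <- sort_keys(doc)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  invisible(path)
}

## recursive key sort for deterministic JSON output
sort_keys <- function(x) {
  if (is.list(x) && !is.null(names(x)) && all(nzchar(names(x)))) {
    x <- x[order(names(x), method = "radix")]
    lapply(x, sort_keys)
  } else if (is.list(x)) {
    lapply(x, sort_keys)
  } else x
}
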