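#' Family-to-origin-node assignment
#'
#' Maps each conserved microRNA family to the phylogenetic node where it
#' arose (e.g. Eumetazoa, Bilateria, Protostomia, Syndermata). The expected
#' complement of a taxon is then the number of families whose origin lies on
#' its root-to-tip path: for a protostome, 1 eumetazoan + 31 bilaterian + 12
#' protostome families = 44.
#'
#' @param family character vector of family labels
#' @param node character vector of origin-node labels (same length)
#' @return data.frame of class `node_assignment`
#' @export
node_assignment <- function(family, node) {
  if (length(family) != length(node)) stop("family and node must have equal length", call. = FALSE)
  if (anyDuplicated(family)) {
    stop("each family must have exactly one origin node; duplicated: ",
         paste(unique(family[duplicated(family)]), collapse = ", "), call. = FALSE)
  }
  structure(data.frame(family = as.character(family), node = as.character(node),
                       stringsAsFactors = FALSE),
            class = c("node_assignment", "data.frame"))
}

#' Read a family -> origin-node assignment from a two-column TSV
#' @param path TSV path (columns: family, origin node; no header required,
#'   a `family<TAB>node` header line is tolerated)
#' @return a [node_assignment()]
#' @export
read_node_assignment <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t", quote = "",
                          colClasses = "character")
  if (ncol(df) < 2L) stop("node assignment needs two columns", call. = FALSE)
  if (identical(tolower(df[1L, 1L]), "family")) df <- df[-1L, , drop = FALSE]
  node_assignment(df[[1L]], df[[2L]])
}

#' Expected family complement for a taxon position
#'
#' @param assignment a [node_assignment()]
#' @param path_nodes node labels on the taxon's root-to-tip path
#' @return integer count of families whose origin node lies on the path
#' @export
expected_families <- function(assignment, path_nodes) {
  stopifnot(inherits(assignment, "node_assignment"))
  unknown <- setdiff(path_nodes, assignment$node)
  if (length(unknown)) {
    stop("unknown node label(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  sum(assignment$node %in% path_nodes)
}

#' Loss percentage with full precision and a display rounding
#'
#' @param losses number of lost characters (0 <= losses <= expected)
#' @param expected expected complement size (> 0)
#' @return list with `percent` (full precision) and `display` (rounded to
#'   whole percent); the printed figures of the source literature are
#'   display-level roundings
#' @export
loss_fraction <- function(losses, expected) {
  if (expected <= 0) stop("expected must be > 0", call. = FALSE)
  if (losses < 0 || losses > expected) stop("need 0 <= losses <= expected", call. = FALSE)
  pct <- 100 * losses / expected
  list(percent = pct, display = round(pct))
}

#' Precursor hairpin annotations
#'
#' Hairpin length is defined as the annotated precursor span width; no
#' folding or structure prediction is performed.
#'
#' @param species species label per precursor
#' @param contig,start,end,strand span fields (0-based half-open, like BED)
#' @return data.frame of class `precursor_annotation` with a `length` column
#' @export
precursor_annotation <- function(species, contig, start, end, strand = "+") {
  start <- as.integer(start); end <- as.integer(end)
  if (any(end <= start)) stop("precursor end must exceed start", call. = FALSE)
  structure(data.frame(species = as.character(species), contig = as.character(contig),
                       start = start, end = end, strand = strand,
                       length = end - start, stringsAsFactors = FALSE),
            class = c("precursor_annotation", "data.frame"))
}

#' Read precursor annotations from GFF3
#'
#' @param path GFF3 file of precursor spans (1-based inclusive, per the GFF
#'   standard; converted to 0-based half-open internally)
#' @param species species label to attach (default: the GFF `source` column)
#' @return a [precursor_annotation()]
#' @export
read_precursor_gff <- function(path, species = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  precursor_annotation(
    species = species %||% as.character(S4Vectors::metadata(gr)$source %||%
                                          gr$source %||% "unknown"),
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)))
}

#' Per-species hairpin length summary
#'
#' @param annotations a [precursor_annotation()] (>= 1 row)
#' @return data.frame with per-species `n`, `mean` (1 decimal), `min`, `max`
#' @export
precursor_length_stats <- function(annotations) {
  stopifnot(inherits(annotations, "precursor_annotation"))
  if (nrow(annotations) == 0L) stop("no precursor annotations", call. = FALSE)
  sp <- split(annotations$length, annotations$species)
  data.frame(species = names(sp),
             n = vapply(sp, length, integer(1)),
             mean = vapply(sp, function(l) round(mean(l), 1), numeric(1)),
             min = vapply(sp, min, numeric(1)),
             max = vapply(sp, max, numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}
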