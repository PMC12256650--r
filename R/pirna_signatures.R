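#' Partition reads into putative piRNAs and other reads
#'
#' Putative piRNAs are reads of 27 to 32 nt inclusive — the typical piRNA
#' length class; the partition preserves input order.
#'
#' @param reads a [read_set()]
#' @param min_len,max_len inclusive length bounds (defaults 27 and 32)
#' @return list with elements `pirna` and `other`, both `read_set`s
#' @export
classify_length <- function(reads, min_len = 27L, max_len = 32L) {
  stopifnot(inherits(reads, "read_set"))
  keep <- reads$length >= min_len & reads$length <= max_len
  list(pirna = reads[keep, , drop = FALSE], other = reads[!keep, , drop = FALSE])
}

#' @export
`[.read_set` <- function(x, i, j, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(c("contig", "start", "end", "strand") %in% names(out))) {
    class(out) <- c("read_set", "data.frame")
  }
  out
}

#' Exact read-length histogram
#'
#' @param reads a [read_set()]
#' @param pirna_range inclusive bounds flagged as the piRNA class
#' @return data.frame with columns `length`, `count`, `is_pirna`
#' @export
length_histogram <- function(reads, pirna_range = c(27L, 32L)) {
  stopifnot(inherits(reads, "read_set"))
  if (nrow(reads) == 0L) {
    return(data.frame(length = integer(0), count = integer(0), is_pirna = logical(0)))
  }
  tab <- table(reads$length)
  len <- as.integer(names(tab))
  data.frame(length = len, count = as.integer(tab),
             is_pirna = len >= pirna_range[1L] & len <= pirna_range[2L])
}

#' Ping-pong 5'-overlap profile
#'
#' For every plus/minus read pair on the same contig whose spans intersect,
#' the 5' overlap is (minus-read 5') - (plus-read 5') + 1, with the minus
#' 5' at `end - 1` under 0-based half-open coordinates. Overlaps in
#' `[1, max_overlap]` are tabulated; a modal value of 10 nt is the
#' diagnostic ping-pong signature. Inputs should already be length-filtered
#' with [classify_length()].
#'
#' @param reads a [read_set()] of putative piRNAs
#' @param max_overlap largest overlap tabulated (default 25)
#' @return object of class `pingpong_profile`: list with `counts` (named
#'   vector over 1..max_overlap), `modal_overlap` (NA when no pairs) and
#'   `total_pairs`
#' @export
pingpong_profile <- function(reads, max_overlap = 25L) {
  stopifnot(inherits(reads, "read_set"))
  counts <- stats::setNames(integer(max_overlap), seq_len(max_overlap))
  if (nrow(reads)) {
    for (ctg in unique(reads$contig)) {
      sub <- reads[reads$contig == ctg, , drop = FALSE]
      plus <- sub[sub$strand == "+", , drop = FALSE]
      minus <- sub[sub$strand == "-", , drop = FALSE]
      if (nrow(plus) == 0L || nrow(minus) == 0L) next
      hits <- IRanges::findOverlaps(
        IRanges::IRanges(start = plus$start + 1L, end = plus$end),
        IRanges::IRanges(start = minus$start + 1L, end = minus$end))
      if (length(hits) == 0L) next
      ov <- (minus$end[S4Vectors::subjectHits(hits)] - 1L) -
        plus$start[S4Vectors::queryHits(hits)] + 1L
      ov <- ov[ov >= 1L & ov <= max_overlap]
      if (length(ov)) {
        tab <- tabulate(ov, nbins = max_overlap)
        counts <- counts + tab
      }
    }
  }
  total <- sum(counts)
  modal <- if (total > 0L) as.integer(names(counts)[which.max(counts)]) else NA_integer_
  structure(list(counts = counts, modal_overlap = modal, total_pairs = total),
            class = "pingpong_profile")
}

#' @export
print.pingpong_profile <- function(x, ...) {
  cat("ping-pong profile:", x$total_pairs, "pairs; modal overlap",
      x$modal_overlap, "nt\n")
  invisible(x)
}

#' @export
as_report_payload.pingpong_profile <- function(x, ...) {
  list(counts = as.list(x$counts), modal_overlap = x$modal_overlap,
       total_pairs = x$total_pairs)
}

#' Putative-piRNA counts in non-overlapping genomic windows
#'
#' Windows tile each contig from coordinate 0 without overlap; the final
#' partial window is included. Each read is assigned to the window
#' containing its start coordinate.
#'
#' @param reads a [read_set()] of putative piRNAs
#' @param contig_lengths named vector covering every read contig
#' @param window window size in bp (default 2000)
#' @return object of class `window_counts`: data.frame with `contig`,
#'   `window` (0-based index), `count`; attributes `window`, `total`,
#'   `contig_lengths`
#' @export
window_counts <- function(reads, contig_lengths, window = 2000L) {
  stopifnot(inherits(reads, "read_set"))
  unknown <- setdiff(reads$contig, names(contig_lengths))
  if (length(unknown)) stop("contig length missing for: ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  beyond <- reads$end > contig_lengths[reads$contig]
  if (any(beyond)) {
    stop("read beyond contig length: ", reads$name[which(beyond)[1L]], call. = FALSE)
  }
  nwin <- ceiling(contig_lengths / window)
  grid <- data.frame(
    contig = rep(names(contig_lengths), nwin),
    window = unlist(lapply(nwin, function(k) seq_len(k) - 1L), use.names = FALSE),
    stringsAsFactors = FALSE)
  key <- paste(grid$contig, grid$window)
  idx <- match(paste(reads$contig, reads$start %/% window), key)
  grid$count <- tabulate(idx, nbins = nrow(grid))
  structure(grid, window = as.integer(window), total = nrow(reads),
            contig_lengths = contig_lengths,
            class = c("window_counts", "data.frame"))
}

#' Windows holding at least a minimum piRNA count
#'
#' The high-density report (windows with >= 1000 putative piRNAs by
#' default).
#'
#' @param counts a `window_counts`
#' @param min_count threshold (default 1000)
#' @return the qualifying rows, sorted by decreasing count
#' @export
high_density_windows <- function(counts, min_count = 1000L) {
  stopifnot(inherits(counts, "window_counts"))
  out <- counts[counts$count >= min_count, , drop = FALSE]
  out[order(-out$count, out$contig, out$window), , drop = FALSE]
}

#' Number of top windows covering a fraction of all piRNAs
#'
#' Windows are sorted by decreasing count (ties broken by contig then window
#' index, for determinism); returns the smallest number of top windows whose
#' cumulative count reaches `fraction` of the total.
#'
#' @param counts a `window_counts` with positive total
#' @param fraction target coverage fraction in (0, 1] (default 0.9)
#' @return integer window count
#' @export
windows_to_cover <- function(counts, fraction = 0.9) {
  stopifnot(inherits(counts, "window_counts"))
  total <- attr(counts, "total")
  if (total == 0L) stop("no piRNAs: coverage target undefined", call. = FALSE)
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]", call. = FALSE)
  ord <- order(-counts$count, counts$contig, counts$window)
  cum <- cumsum(counts$count[ord])
  which(cum >= fraction * total)[1L]
}

#' Cumulative coverage curve over density-ranked windows
#'
#' The curve behind the clustering diagnostic: fraction of all piRNAs
#' contained in the top-k densest windows, as k grows. Strong clustering
#' gives a curve that plateaus quickly; uniform placement gives a near-
#' linear rise.
#'
#' @param counts a `window_counts`
#' @return data.frame with `n_windows` and `cum_fraction`
#' @export
cumulative_coverage_curve <- function(counts) {
  stopifnot(inherits(counts, "window_counts"))
  total <- attr(counts, "total")
  if (total == 0L) stop("no piRNAs", call. = FALSE)
  ord <- order(-counts$count, counts$contig, counts$window)
  data.frame(n_windows = seq_along(ord),
             cum_fraction = cumsum(counts$count[ord]) / total)
}

#' Permutation clustering-ratio statistic
#'
#' The observed number of windows needed to hold `fraction` (default 90%)
#' of the putative piRNAs is compared with the same quantity after
#' randomising read positions: each read is redrawn uniformly on its own
#' contig, preserving length, strand and per-contig read counts. The
#' clustering ratio is (mean shuffled windows) / (real windows); values
#' well above 1 indicate genomic clustering into piRNA-cluster-like loci.
#'
#' @param reads a [read_set()] of putative piRNAs (>= 1 read)
#' @param contig_lengths named vector covering every read contig
#' @param window window size in bp (default 2000)
#' @param fraction coverage fraction (default 0.9)
#' @param n_shuffles number of randomisations (default 10)
#' @param seed integer seed
#' @return object of class `clustering_result`: list with `windows_real_90`,
#'   `windows_shuffled_90` (mean), `per_shuffle`, `n_shuffles`, `seed`,
#'   `window`, `fraction`, `clustering_ratio`
#' @export
clustering_ratio <- function(reads, contig_lengths, window = 2000L,
                             fraction = 0.9, n_shuffles = 10L, seed) {
  stopifnot(inherits(reads, "read_set"))
  if (nrow(reads) == 0L) stop("no putative piRNAs", call. = FALSE)
  real <- windows_to_cover(window_counts(reads, contig_lengths, window), fraction)
  shuffled <- with_seed(seed, {
    vapply(seq_len(n_shuffles), function(s) {
      sh <- reads
      span <- contig_lengths[sh$contig] - sh$length
      sh$start <- as.integer(floor(stats::runif(nrow(sh)) * (span + 1)))
      sh$end <- sh$start + sh$length
      windows_to_cover(window_counts(sh, contig_lengths, window), fraction)
    }, numeric(1))
  })
  structure(list(windows_real_90 = real,
                 windows_shuffled_90 = mean(shuffled),
                 per_shuffle = shuffled,
                 n_shuffles = as.integer(n_shuffles),
                 seed = seed, window = as.integer(window), fraction = fraction,
                 clustering_ratio = mean(shuffled) / real),
            class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("clustering ratio = %.3f (real %d windows, shuffled mean %.1f over %d shuffles)\n",
              x$clustering_ratio, x$windows_real_90, x$windows_shuffled_90, x$n_shuffles))
  invisible(x)
}

#' @export
as_report_payload.clustering_result <- function(x, ...) unclass(x)
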