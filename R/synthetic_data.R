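#' Specification of planted per-branch loss/gain events
#'
#' Describes a synthetic presence/absence matrix by where on the tree its
#' absences were planted. Branches are identified by the child node's label.
#' Two admissible forms:
#' \itemize{
#'   \item `losses`/`gains` as named counts (branch label -> count): each
#'     character carries at most one event, so the event total must not
#'     exceed `n_characters`;
#'   \item an explicit `assignment`: a named list (character label -> list
#'     with elements `losses` and/or `gain`), which may plant one character's
#'     losses on several path-disjoint branches. The assignment is checked
#'     for Dollo-stability so the reconstruction recovers the planted counts
#'     exactly (a strict round-trip oracle).
#' }
#'
#' @param tree a `phylo_tree`
#' @param n_characters total number of characters
#' @param losses named integer vector of planted loss counts per branch
#' @param gains named integer vector of planted gain counts per branch
#' @param assignment optional explicit character -> branch-set mapping
#' @param character_labels optional character labels (default `char_001`...)
#' @return an object of class `branch_event_spec`
#' @export
branch_event_spec <- function(tree, n_characters, losses = integer(0),
                              gains = integer(0), assignment = NULL,
                              character_labels = NULL) {
  stopifnot(inherits(tree, "phylo_tree"))
  if (n_characters < 1L) stop("n_characters must be >= 1", call. = FALSE)
  branch_labels <- tree_branches(tree)$branch
  chk_branches <- function(x, what) {
    bad <- setdiff(names(x), branch_labels)
    if (length(bad)) stop("unknown ", what, " branch(es): ", paste(bad, collapse = ", "), call. = FALSE)
    if (any(x < 0)) stop(what, " counts must be >= 0", call. = FALSE)
  }

  character_labels <- character_labels %||%
    sprintf("char_%03d", seq_len(n_characters))
  if (length(character_labels) != n_characters || anyDuplicated(character_labels)) {
    stop("character_labels must be ", n_characters, " unique labels", call. = FALSE)
  }

  if (is.null(assignment)) {
    chk_branches(losses, "loss"); chk_branches(gains, "gain")
    if (sum(losses) + sum(gains) > n_characters) {
      stop("over-subscribed character budget: ", sum(losses) + sum(gains),
           " planted events > ", n_characters, " characters", call. = FALSE)
    }
  } else {
    bad <- setdiff(names(assignment), character_labels)
    if (length(bad)) stop("assignment names not in character labels: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    validate_assignment(tree, assignment)
    losses <- assignment_totals(assignment, "losses", branch_labels)
    gains <- assignment_totals(assignment, "gain", branch_labels)
  }

  structure(list(tree = tree, n_characters = n_characters,
                 losses = losses, gains = gains, assignment = assignment,
                 character_labels = character_labels),
            class = "branch_event_spec")
}

assignment_totals <- function(assignment, field, branch_labels) {
  all_b <- unlist(lapply(assignment, `[[`, field))
  tab <- table(factor(all_b, levels = branch_labels))
  out <- as.integer(tab)[tab > 0]
  stats::setNames(out, names(tab)[tab > 0])
}

## Dollo-stability check: planted loss branches of one character must be
## pairwise tip-disjoint, and every planted branch's parent must keep at
## least one present tip, so the reconstruction cannot merge or move events.
validate_assignment <- function(tree, assignment) {
  tips <- tree_tips(tree)
  for (ch in names(assignment)) {
    a <- assignment[[ch]]
    lb <- a$losses %||% character(0)
    gb <- a$gain %||% character(0)
    if (length(gb) > 1L) stop("character '", ch, "': at most one gain branch", call. = FALSE)
    if (length(gb) && length(lb)) {
      stop("character '", ch, "': gain and loss on the same character is not supported", call. = FALSE)
    }
    if (length(lb)) {
      below <- lapply(lb, function(b) tips_below(tree, b))
      if (length(lb) > 1L) {
        for (i in seq_len(length(lb) - 1L)) for (k in (i + 1L):length(lb)) {
          if (length(intersect(below[[i]], below[[k]]))) {
            stop("character '", ch, "': planted loss branches '", lb[i], "' and '",
                 lb[k], "' are nested or overlapping", call. = FALSE)
          }
        }
      }
      absent <- unique(unlist(below))
      for (b in lb) {
        p <- tree_branches(tree)
        parent <- p$parent_label[p$branch == b]
        if (!length(setdiff(tips_below(tree, parent), absent))) {
          stop("character '", ch, "': loss on '", b,
               "' is not Dollo-stable (no present tip under its parent)", call. = FALSE)
        }
      }
    }
  }
  invisible(TRUE)
}

#' Generate a matrix with planted branch losses and gains
#'
#' A character planted as lost on branch b is absent in exactly the tips
#' below b and present elsewhere; a planted gain is present only below its
#' branch; remaining characters are present in all taxa. With a random
#' (counts-only) spec, the character-to-branch draw is determined by `seed`.
#'
#' @param spec a [branch_event_spec()]
#' @param seed integer seed (unused but still required when the spec carries
#'   an explicit assignment)
#' @return a [character_matrix()] with attributes `planted_spec`,
#'   `assignment` (the realised character -> branch mapping) and
#'   `planted_polarity` (named vector, `absent` for gain characters), suited
#'   to round-trip checks against [dollo_events()]
#' @export
gen_matrix_from_branch_events <- function(spec, seed) {
  stopifnot(inherits(spec, "branch_event_spec"))
  tree <- spec$tree
  chars <- spec$character_labels

  assignment <- spec$assignment
  if (is.null(assignment)) {
    assignment <- with_seed(seed, {
      pool <- sample(chars)
      out <- list()
      for (b in names(spec$losses)) for (i in seq_len(spec$losses[[b]])) {
        ch <- pool[[1L]]; pool <- pool[-1L]
        out[[ch]] <- list(losses = b)
      }
      for (b in names(spec$gains)) for (i in seq_len(spec$gains[[b]])) {
        ch <- pool[[1L]]; pool <- pool[-1L]
        out[[ch]] <- list(gain = b)
      }
      out
    })
  }

  tips <- tree_tips(tree)
  mat <- matrix(1L, length(tips), length(chars), dimnames = list(tips, chars))
  polarity <- stats::setNames(rep("present", length(chars)), chars)
  for (ch in names(assignment)) {
    a <- assignment[[ch]]
    if (!is.null(a$gain)) {
      mat[, ch] <- 0L
      mat[tips_below(tree, a$gain), ch] <- 1L
      polarity[ch] <- "absent"
    } else if (length(a$losses)) {
      for (b in a$losses) mat[tips_below(tree, b), ch] <- 0L
    }
  }

  out <- character_matrix(mat)
  attr(out, "planted_spec") <- spec
  attr(out, "assignment") <- assignment
  attr(out, "planted_polarity") <- polarity
  out
}

#' Polarity spec matching a generated matrix
#'
#' Convenience for round-trips: gain characters get `absent` polarity,
#' everything else `present`.
#'
#' @param matrix a matrix from [gen_matrix_from_branch_events()]
#' @return a [polarity_spec()]
#' @export
planted_polarity <- function(matrix) {
  pol <- attr(matrix, "planted_polarity")
  if (is.null(pol)) stop("matrix carries no planted polarity", call. = FALSE)
  polarity_spec(default = "present", characters = pol[pol != "present"])
}

#' Preset fixtures encoding the printed syndermatan loss structure
#'
#' `paper_busco`: 954 metazoan core genes with stem losses 54 (Syndermata),
#' 61 (Hemirotifera), 165 (Pararotatoria) plus terminal losses 76
#' (Seisonidea) and 148 (Acanthocephala); the two Pararotatoria tips then
#' collectively lack 54+61+165 = 280 genes.
#'
#' `paper_mirna`: 44 conserved microRNA families with the shared-loss
#' decomposition 9 (Syndermata), 2 (Hemirotifera), 16 (Pararotatoria) and
#' terminal residuals chosen so the per-group cumulative totals are 14
#' (Monogononta), 30 (Seisonidea) and 37 (Acanthocephala). That requires 45
#' loss events over 44 families, so three families share a Seisonidea +
#' Monogononta loss and two share an Acanthocephala + Monogononta loss
#' (path-disjoint, hence Dollo-stable). The bdelloid cumulative total under
#' this decomposition is 11, not the reported group total of 10; the two are
#' not reconcilable and no bdelloid residual is planted.
#'
#' @param name `"paper_busco"` or `"paper_mirna"`
#' @param tree tree to plant on (default [syndermatan_tree()])
#' @return a [branch_event_spec()]
#' @export
preset_branch_event_spec <- function(name = c("paper_busco", "paper_mirna"),
                                     tree = syndermatan_tree()) {
  name <- match.arg(name)
  if (name == "paper_busco") {
    return(branch_event_spec(
      tree, n_characters = 954L,
      losses = c(Syndermata = 54L, Hemirotifera = 61L, Pararotatoria = 165L,
                 Seisonidea = 76L, Acanthocephala = 148L),
      character_labels = sprintf("BUSCO%04d", seq_len(954L))))
  }
  labels <- sprintf("Fam%02d", seq_len(44L))
  assignment <- c(
    stats::setNames(rep(list(list(losses = "Syndermata")), 9), labels[1:9]),
    stats::setNames(rep(list(list(losses = "Hemirotifera")), 2), labels[10:11]),
    stats::setNames(rep(list(list(losses = "Pararotatoria")), 16), labels[12:27]),
    stats::setNames(rep(list(list(losses = c("Seisonidea", "Monogononta"))), 3), labels[28:30]),
    stats::setNames(rep(list(list(losses = c("Acanthocephala", "Monogononta"))), 2), labels[31:32]),
    stats::setNames(rep(list(list(losses = "Acanthocephala")), 8), labels[33:40])
  )
  branch_event_spec(tree, n_characters = 44L, assignment = assignment,
                    character_labels = labels)
}

#' Specification for a synthetic mapped small-RNA read set
#'
#' @param contig_lengths named integer vector of contig lengths (bp)
#' @param n_reads number of reads
#' @param cluster_fraction fraction of reads falling into dense windows
#' @param n_clusters number of 2-kb cluster windows (>=1 when
#'   `cluster_fraction > 0`)
#' @param pingpong_fraction fraction of piRNA-length reads emitted as
#'   opposite-strand partners with exactly 10-nt 5' overlap
#' @param length_probs named probability vector, read length (nt) -> weight.
#'   Default: a 22-nt miRNA-like class (0.4) and a uniform 27-32 nt
#'   piRNA-like class (0.6 total)
#' @param cluster_window cluster window width in bp (default 2000)
#' @param seed default seed used by [gen_read_set()]
#' @return an object of class `read_sim_spec`
#' @export
read_sim_spec <- function(contig_lengths, n_reads,
                          cluster_fraction = 0, n_clusters = 1L,
                          pingpong_fraction = 0,
                          length_probs = NULL, cluster_window = 2000L,
                          seed = NULL) {
  if (is.null(names(contig_lengths)) || any(contig_lengths < 1)) {
    stop("contig_lengths must be a named vector of positive lengths", call. = FALSE)
  }
  if (cluster_fraction < 0 || cluster_fraction > 1 ||
      pingpong_fraction < 0 || pingpong_fraction > 1) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  if (cluster_fraction > 0 && n_clusters < 1L) {
    stop("n_clusters must be >= 1 when cluster_fraction > 0", call. = FALSE)
  }
  length_probs <- length_probs %||%
    c("22" = 0.4, stats::setNames(rep(0.1, 6), 27:32))
  if (any(length_probs < 0) || sum(length_probs) <= 0) {
    stop("length_probs must be nonnegative with positive sum", call. = FALSE)
  }
  if (cluster_fraction > 0 && max(contig_lengths) < cluster_window) {
    stop("cluster window does not fit any contig", call. = FALSE)
  }
  if (min(contig_lengths) < max(as.integer(names(length_probs)))) {
    stop("every contig must be at least as long as the longest read", call. = FALSE)
  }
  structure(list(contig_lengths = contig_lengths, n_reads = as.integer(n_reads),
                 cluster_fraction = cluster_fraction, n_clusters = as.integer(n_clusters),
                 pingpong_fraction = pingpong_fraction,
                 length_probs = length_probs / sum(length_probs),
                 cluster_window = as.integer(cluster_window), seed = seed),
            class = "read_sim_spec")
}

#' Generate a synthetic mapped small-RNA read set
#'
#' Reads are placed uniformly (contig chosen proportional to length) except
#' a `cluster_fraction` of them, which fall into `n_clusters` windows of 2
#' kb. A `pingpong_fraction` of the piRNA-length (27-32 nt) reads are
#' converted into opposite-strand partner pairs by explicit coordinate
#' arithmetic — the minus partner's 5' end sits at (plus 5') + 9 — so the
#' planted overlap mode is exactly 10 nt. Fully determined by the seed.
#'
#' @param spec a [read_sim_spec()]
#' @param seed integer seed (defaults to `spec$seed`)
#' @return a [read_set()], with attributes `planted_spec` and
#'   `cluster_windows` (data.frame of the planted windows)
#' @export
gen_read_set <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "read_sim_spec"))
  if (is.null(seed)) stop("an explicit seed is required", call. = FALSE)
  cl <- spec$contig_lengths
  n <- spec$n_reads
  lens_choices <- as.integer(names(spec$length_probs))

  with_seed(seed, {
    lens <- lens_choices[sample.int(length(lens_choices), n, replace = TRUE,
                                    prob = spec$length_probs)]
    contig <- sample(names(cl), n, replace = TRUE, prob = cl)
    start <- floor(stats::runif(n) * (cl[contig] - lens + 1))

    cluster_windows <- NULL
    if (spec$cluster_fraction > 0) {
      eligible <- names(cl)[cl >= spec$cluster_window]
      wc <- sample(eligible, spec$n_clusters, replace = TRUE, prob = cl[eligible])
      ws <- floor(stats::runif(spec$n_clusters) * (cl[wc] - spec$cluster_window + 1))
      cluster_windows <- data.frame(contig = wc, start = as.integer(ws),
                                    end = as.integer(ws + spec$cluster_window),
                                    stringsAsFactors = FALSE)
      in_cluster <- stats::runif(n) < spec$cluster_fraction
      k <- sum(in_cluster)
      if (k > 0L) {
        which_cl <- sample.int(spec$n_clusters, k, replace = TRUE)
        contig[in_cluster] <- wc[which_cl]
        start[in_cluster] <- ws[which_cl] +
          floor(stats::runif(k) * (spec$cluster_window - lens[in_cluster] + 1))
      }
    }

    strand <- sample(c("+", "-"), n, replace = TRUE)

    if (spec$pingpong_fraction > 0) {
      pi_idx <- which(lens >= 27L & lens <= 32L)
      sel <- pi_idx[stats::runif(length(pi_idx)) < spec$pingpong_fraction]
      if (length(sel) >= 2L) {
        npair <- length(sel) %/% 2L
        for (p in seq_len(npair)) {
          i <- sel[2L * p - 1L]; j <- sel[2L * p]
          ## anchor read i on the plus strand, read j as its ping-pong partner
          deficit <- max(0L, (lens[j] - 10L) - start[i])
          start[i] <- start[i] + deficit
          strand[i] <- "+"
          contig[j] <- contig[i]
          strand[j] <- "-"
          start[j] <- start[i] + 10L - lens[j]     # partner end = plus 5' + 10
        }
      }
    }

    out <- read_set(contig = contig, start = start, end = start + lens,
                    strand = strand)
    attr(out, "planted_spec") <- spec
    attr(out, "cluster_windows") <- cluster_windows
    out
  })
}

#' Generate a per-species summary table with a planted linear relation
#'
#' MicroRNA losses (the predictor) are spread evenly over `x_range`, which
#' defaults to 0-37 — the span of the six regression species (two outgroups
#' at 0, bdelloid 10, monogonont 14, seisonid 30, acanthocephalans 37). The
#' response is `slope * x + intercept + N(0, noise_sd)`, reported both raw
#' and rounded to a nonnegative integer; N50 is drawn independently so it is
#' uncorrelated with losses.
#'
#' @param n_taxa number of species (>= 3)
#' @param slope,intercept planted linear coefficients
#' @param noise_sd Gaussian noise standard deviation (>= 0)
#' @param seed integer seed
#' @param x_range range of microRNA-loss values
#' @param response name of the response column (default `busco_losses`)
#' @return data.frame of class `species_summary` with columns `taxon`,
#'   `mirna_losses`, the response (rounded), `<response>_raw`, `n50`
#' @export
gen_species_summary <- function(n_taxa, slope, intercept = 0, noise_sd = 0,
                                seed, x_range = c(0, 37),
                                response = "busco_losses") {
  if (n_taxa < 3L) stop("n_taxa must be >= 3", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  with_seed(seed, {
    x <- round(seq(x_range[1L], x_range[2L], length.out = n_taxa))
    raw <- slope * x + intercept + stats::rnorm(n_taxa, 0, noise_sd)
    n50 <- round(10^stats::runif(n_taxa, 5, 7.5))
    df <- data.frame(taxon = sprintf("sp%02d", seq_len(n_taxa)),
                     mirna_losses = as.integer(x),
                     stringsAsFactors = FALSE)
    df[[response]] <- pmax(0, round(raw))
    df[[paste0(response, "_raw")]] <- raw
    df$n50 <- n50
    class(df) <- c("species_summary", "data.frame")
    df
  })
}
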