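#' Polarity specification for ancestral states
#'
#' Under Dollo irreversibility every character needs a polarity: ancestrally
#' `present` at the root (conserved microRNA families and metazoan core genes
#' are expected from deeper nodes), ancestrally `absent` (novel characters,
#' gained once at the MRCA of the possessing tips), or `outgroup` (infer the
#' ancestral state from the outgroup taxa; if the outgroups disagree or are
#' all unknown the character is excluded from counting and logged — the
#' conservative tie rule).
#'
#' @param default polarity applied to every character without an override:
#'   one of `"present"`, `"absent"`, `"outgroup"`
#' @param outgroups character vector of outgroup taxon labels (required when
#'   any character uses `"outgroup"` polarity)
#' @param characters optional named character vector of per-character
#'   overrides, values in `present`/`absent`/`outgroup`
#' @return an object of class `polarity_spec`
#' @export
polarity_spec <- function(default = c("present", "absent", "outgroup"),
                          outgroups = character(0), characters = character(0)) {
  default <- match.arg(default)
  if (length(characters) &&
      (is.null(names(characters)) || !all(characters %in% c("present", "absent", "outgroup")))) {
    stop("`characters` must be a named vector with values present/absent/outgroup", call. = FALSE)
  }
  if ((default == "outgroup" || any(characters == "outgroup")) && length(outgroups) == 0L) {
    stop("outgroup polarity requires at least one outgroup taxon", call. = FALSE)
  }
  structure(list(default = default, outgroups = outgroups, characters = characters),
            class = "polarity_spec")
}

polarity_for <- function(polarity, character) {
  p <- polarity$characters[character]
  if (length(p) == 0L || is.na(p)) polarity$default else unname(p)
}

#' Reconstruct node states under Dollo irreversibility
#'
#' For a character ancestrally present, an internal node is scored present
#' iff at least one descendant tip is definitely present (unknown tips never
#' rescue presence), and the root is forced present. For a character
#' ancestrally absent, a single gain is placed at the most recent common
#' ancestor of the possessing tips, with Dollo losses below. This yields the
#' minimal number of loss events consistent with the tip states and
#' single-gain irreversibility.
#'
#' @param matrix a [character_matrix()]; taxa must be a subset of the tree
#'   tips (tree tips missing from the matrix are treated as unknown)
#' @param tree a `phylo_tree`
#' @param polarity a [polarity_spec()]
#' @return an object of class `node_states`: list with `states` (nodes x
#'   characters; 1/0/NA, rownames = node labels), `ancestral` (resolved
#'   polarity per character: present/absent/excluded), `excluded`
#'   (characters dropped by the outgroup tie rule), `tree`, `matrix`
#' @export
reconstruct_states <- function(matrix, tree, polarity = polarity_spec()) {
  stopifnot(inherits(matrix, "character_matrix"), inherits(tree, "phylo_tree"),
            inherits(polarity, "polarity_spec"))
  tips <- tree_tips(tree)
  missing_taxa <- setdiff(rownames(matrix), tips)
  if (length(missing_taxa)) {
    stop("matrix taxa absent from tree: ", paste(missing_taxa, collapse = ", "), call. = FALSE)
  }
  bad_out <- setdiff(polarity$outgroups, tips)
  if (length(bad_out)) {
    stop("outgroup taxa absent from tree: ", paste(bad_out, collapse = ", "), call. = FALSE)
  }

  n_all <- tree$n_tip + tree$n_node
  chars <- colnames(matrix)
  ## tip states aligned to tree tip order; tips without data -> unknown
  tip_states <- matrix(NA_integer_, tree$n_tip, length(chars),
                       dimnames = list(tips, chars))
  tip_states[rownames(matrix), ] <- unclass(matrix)

  postorder <- rev(tree$preorder)
  states <- matrix(NA_integer_, n_all, length(chars),
                   dimnames = list(tree$labels, chars))
  ancestral <- stats::setNames(character(length(chars)), chars)

  for (j in seq_along(chars)) {
    pol <- polarity_for(polarity, chars[j])
    if (pol == "outgroup") {
      og <- tip_states[polarity$outgroups, j]
      og <- og[!is.na(og)]
      if (length(og) == 0L || length(unique(og)) > 1L) {
        ancestral[j] <- "excluded"
        log_msg("character '", chars[j], "' excluded: outgroup states ",
                if (length(og)) "disagree" else "all unknown")
        next
      }
      pol <- if (og[1L] == 1L) "present" else "absent"
    }
    ancestral[j] <- pol

    ## definite presence, bottom-up
    def <- logical(n_all)
    for (v in postorder) {
      def[v] <- if (v <= tree$n_tip) {
        !is.na(tip_states[v, j]) && tip_states[v, j] == 1L
      } else {
        any(def[tree$children[[v]]])
      }
    }

    st <- integer(n_all)
    if (pol == "present") {
      st[] <- as.integer(def)
      st[tree$root] <- 1L                     # root forced present
    } else {
      poss <- which(def[seq_len(tree$n_tip)])
      if (length(poss) == 0L) {
        warning("character '", chars[j],
                "' is ancestrally absent with zero possessing tips: no events", call. = FALSE)
        st[] <- 0L
      } else {
        m <- mrca_id(tree, poss)
        inside <- c(m, if (m > tree$n_tip) unlist(descendants_ids(tree, m)))
        st[] <- 0L
        st[inside] <- as.integer(def[inside])
        st[m] <- 1L                           # gain node forced present
      }
    }
    ## tips report their raw (possibly unknown) observation
    st[seq_len(tree$n_tip)] <- tip_states[, j]
    states[, j] <- st
  }
  states[, ancestral == "excluded"] <- NA_integer_

  structure(list(states = states, ancestral = ancestral,
                 excluded = chars[ancestral == "excluded"],
                 tree = tree, matrix = matrix),
            class = "node_states")
}

## all descendant node ids (tips and internals) below an internal node
descendants_ids <- function(tree, id) {
  out <- integer(0)
  stack <- tree$children[[id]]
  while (length(stack)) {
    v <- stack[[1L]]; stack <- stack[-1L]
    out <- c(out, v)
    if (v > tree$n_tip) stack <- c(stack, tree$children[[v]])
  }
  out
}

#' Count loss and gain events per branch
#'
#' A loss sits on branch (parent to child) iff the parent is present and the
#' child absent; a gain iff the parent is absent and the child present.
#' Unknown tip states generate no events. Branches are reported in
#' deterministic preorder, identified by the child node's label.
#'
#' @param states a `node_states` from [reconstruct_states()]
#' @return an object of class `branch_event_table`: data.frame with columns
#'   `branch`, `parent_label`, `is_terminal`, `losses`, `gains`; attributes
#'   `loss_events`/`gain_events` (per-branch character lists), `root_gains`
#'   (characters gained at the root itself, carried separately since the
#'   root has no incoming branch) and `tree`
#' @export
count_branch_events <- function(states) {
  stopifnot(inherits(states, "node_states"))
  tree <- states$tree
  br <- tree_branches(tree)
  st <- states$states
  chars <- colnames(st)

  loss_events <- vector("list", nrow(br))
  gain_events <- vector("list", nrow(br))
  for (i in seq_len(nrow(br))) {
    sp <- st[br$parent_id[i], ]
    sc <- st[br$child_id[i], ]
    loss_events[[i]] <- chars[!is.na(sp) & !is.na(sc) & sp == 1L & sc == 0L]
    gain_events[[i]] <- chars[!is.na(sp) & !is.na(sc) & sp == 0L & sc == 1L]
  }
  root_gains <- chars[states$ancestral == "absent" &
                        !is.na(st[tree$root, ]) & st[tree$root, ] == 1L]

  out <- data.frame(branch = br$branch, parent_label = br$parent_label,
                    is_terminal = br$is_terminal,
                    losses = vapply(loss_events, length, integer(1)),
                    gains = vapply(gain_events, length, integer(1)),
                    stringsAsFactors = FALSE)
  names(loss_events) <- names(gain_events) <- br$branch
  structure(out, loss_events = loss_events, gain_events = gain_events,
            root_gains = root_gains, tree = tree,
            class = c("branch_event_table", "data.frame"))
}

#' Dollo loss/gain mapping in one call
#'
#' @inheritParams reconstruct_states
#' @return a `branch_event_table`
#' @export
dollo_events <- function(matrix, tree, polarity = polarity_spec()) {
  count_branch_events(reconstruct_states(matrix, tree, polarity))
}

#' @export
as_report_payload.branch_event_table <- function(x, ...) {
  list(branches = x$branch, parent = x$parent_label,
       losses = x$losses, gains = x$gains,
       root_gains = attr(x, "root_gains"),
       tip_cumulative_losses = stats::setNames(
         lapply(tree_tips(attr(x, "tree")), function(t) cumulative_tip_losses(x, t)),
         tree_tips(attr(x, "tree"))))
}

#' Cumulative losses along the root-to-tip path
#'
#' @param table a `branch_event_table`
#' @param tip tip label
#' @return integer count: the sum of losses on every branch from the root to
#'   the tip
#' @export
cumulative_tip_losses <- function(table, tip) {
  stopifnot(inherits(table, "branch_event_table"))
  tree <- attr(table, "tree")
  if (!tip %in% tree_tips(tree)) stop("unknown tip: ", tip, call. = FALSE)
  path <- root_path_ids(tree, node_id(tree, tip))
  path <- path[path != tree$root]
  sum(table$losses[match(tree$labels[path], table$branch)])
}

#' Characters absent in every taxon of a set
#'
#' The collective-absence query behind shared-loss Venn arithmetic, e.g. the
#' core genes missing from both Pararotatoria tips. Unknown cells do not
#' count as absent.
#'
#' @param matrix a `character_matrix`
#' @param taxa nonempty character vector of taxon labels in the matrix
#' @return list with `count` and `characters` (the shared-missing set, for
#'   downstream enrichment)
#' @export
shared_missing <- function(matrix, taxa) {
  stopifnot(inherits(matrix, "character_matrix"))
  if (length(taxa) == 0L) stop("`taxa` must be nonempty", call. = FALSE)
  missing <- setdiff(taxa, rownames(matrix))
  if (length(missing)) stop("taxa not in matrix: ", paste(missing, collapse = ", "), call. = FALSE)
  sub <- unclass(matrix)[taxa, , drop = FALSE]
  shared <- colnames(matrix)[colSums(sub == 0L, na.rm = TRUE) == length(taxa) &
                               colSums(is.na(sub)) == 0L]
  list(count = length(shared), characters = shared)
}
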