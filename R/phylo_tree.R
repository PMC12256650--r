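#' Rooted tree with named internal nodes
#'
#' A thin wrapper around an [ape::read.tree()] `phylo` object that adds the
#' bookkeeping the loss-mapping code needs: a parent pointer per node, a
#' deterministic preorder, and a complete label vector in which unlabeled
#' internal nodes have been auto-named `N1, N2, ...` in preorder. Internal
#' node labels are the clade vocabulary of the analysis (e.g. `Syndermata`,
#' `Hemirotifera`, `Pararotatoria`), so they must be unique.
#'
#' @param phy an object of class `phylo` (rooted)
#' @return an object of class `phylo_tree`: a list with elements `phy`,
#'   `n_tip`, `n_node`, `root` (node id), `parent` (integer vector, `NA` at
#'   the root), `children` (list of integer vectors), `preorder` (node ids,
#'   root first), and `labels` (one label per node id; tips first, ape
#'   numbering)
#' @export
as_phylo_tree <- function(phy) {
  if (!inherits(phy, "phylo")) stop("`phy` must be an ape 'phylo' object", call. = FALSE)
  if (!ape::is.rooted(phy)) stop("tree must be rooted", call. = FALSE)
  phy <- ape::reorder.phylo(phy, "cladewise")

  n_tip <- length(phy$tip.label)
  n_node <- phy$Nnode
  n_all <- n_tip + n_node
  root <- n_tip + 1L

  parent <- rep(NA_integer_, n_all)
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  children <- split(phy$edge[, 2L], factor(phy$edge[, 1L], levels = seq_len(n_all)))
  children <- lapply(children, as.integer)

  ## cladewise edges visit every parent before its children
  preorder <- c(root, phy$edge[, 2L])

  int_labels <- phy$node.label %||% rep("", n_node)
  int_labels[is.na(int_labels)] <- ""
  ## auto-name unlabeled internals by preorder rank among internal nodes
  int_pre <- preorder[preorder > n_tip]
  for (k in seq_along(int_pre)) {
    idx <- int_pre[k] - n_tip
    if (!nzchar(int_labels[idx])) int_labels[idx] <- paste0("N", k)
  }
  labels <- c(phy$tip.label, int_labels)

  if (anyDuplicated(phy$tip.label)) {
    stop("duplicate tip labels: ", paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(labels)) {
    stop("duplicate node labels: ", paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  }

  structure(list(phy = phy, n_tip = n_tip, n_node = n_node, root = root,
                 parent = parent, children = children, preorder = preorder,
                 labels = labels),
            class = "phylo_tree")
}

#' @export
print.phylo_tree <- function(x, ...) {
  cat("phylo_tree:", x$n_tip, "tips,", x$n_node, "internal nodes\n")
  cat("  tips:", paste(tree_tips(x), collapse = ", "), "\n")
  cat("  clades:", paste(x$labels[(x$n_tip + 1L):length(x$labels)], collapse = ", "), "\n")
  invisible(x)
}

#' Tip labels of a tree
#' @param tree a `phylo_tree`
#' @return character vector of tip labels
#' @export
tree_tips <- function(tree) tree$phy$tip.label

#' Node id for a node label
#' @param tree a `phylo_tree`
#' @param label node label (tip or internal)
#' @return integer node id
#' @keywords internal
node_id <- function(tree, label) {
  id <- match(label, tree$labels)
  if (anyNA(id)) {
    stop("unknown node label(s): ", paste(label[is.na(id)], collapse = ", "), call. = FALSE)
  }
  id
}

## tip ids below a node (the node itself if a tip)
tips_below_id <- function(tree, id) {
  if (id <= tree$n_tip) return(id)
  out <- integer(0)
  stack <- id
  while (length(stack)) {
    v <- stack[[1L]]; stack <- stack[-1L]
    kids <- tree$children[[v]]
    out <- c(out, kids[kids <= tree$n_tip])
    stack <- c(stack, kids[kids > tree$n_tip])
  }
  sort(out)
}

#' Tip labels in the clade below a node
#' @param tree a `phylo_tree`
#' @param label node label
#' @return character vector of tip labels
#' @export
tips_below <- function(tree, label) tree$labels[tips_below_id(tree, node_id(tree, label))]

## node ids on the root-to-node path, root first, node last
root_path_ids <- function(tree, id) {
  path <- id
  while (!is.na(tree$parent[id])) {
    id <- tree$parent[id]
    path <- c(id, path)
  }
  path
}

## most recent common ancestor (node id) of a set of tip ids
mrca_id <- function(tree, tip_ids) {
  if (length(tip_ids) == 1L) return(tip_ids)
  paths <- lapply(tip_ids, function(t) root_path_ids(tree, t))
  common <- Reduce(intersect, paths)
  common[length(common)]
}

#' Per-branch table in deterministic preorder
#'
#' Each branch is identified by its child node's label. The root has no
#' incoming branch and is excluded.
#'
#' @param tree a `phylo_tree`
#' @return data.frame with columns `branch`, `parent_label`, `child_id`,
#'   `parent_id`, `is_terminal`
#' @export
tree_branches <- function(tree) {
  ids <- tree$preorder[tree$preorder != tree$root]
  data.frame(branch = tree$labels[ids],
             parent_label = tree$labels[tree$parent[ids]],
             child_id = ids,
             parent_id = tree$parent[ids],
             is_terminal = ids <= tree$n_tip,
             stringsAsFactors = FALSE)
}

#' The fixed syndermatan reference tree
#'
#' Five tips (an outgroup plus the four syndermatan groups) with the three
#' named ingroup clades used throughout: Syndermata (all four groups),
#' Hemirotifera (Bdelloidea + Pararotatoria) and Pararotatoria
#' (Seisonidea + Acanthocephala).
#'
#' @return a `phylo_tree`
#' @export
syndermatan_tree <- function() {
  read_newick(text = paste0(
    "(Outgroup,(Monogononta,(Bdelloidea,(Seisonidea,Acanthocephala)",
    "Pararotatoria)Hemirotifera)Syndermata)Root;"))
}
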