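#' Read a rooted phylogeny with uncertainty flags
#'
#' Reads a Newick tree (polytomies and internal node labels allowed) via
#' \pkg{ape}. Branches whose child node carries a `[&uncertain]` comment
#' block immediately after its label are recorded in the `"uncertain"`
#' attribute of the returned tree as a vector of node labels; comments are
#' stripped before parsing.
#'
#' @param path Path to a Newick file (or a Newick string via `text`).
#' @param text Optional Newick string, used instead of `path`.
#' @return An [ape::read.tree()] `phylo` object with an `"uncertain"`
#'   character attribute (possibly empty).
#' @export
read_karyo_tree <- function(path = NULL, text = NULL) {
  if (is.null(text)) {
    if (is.null(path) || !file.exists(path)) {
      stop("tree file not found: ", if (is.null(path)) "<missing>" else path,
           call. = FALSE)
    }
    text <- paste(readLines(path, warn = FALSE), collapse = "")
  }
  flagged <- regmatches(
    text,
    gregexpr("[A-Za-z0-9_.'-]+(?=\\[&uncertain\\])", text, perl = TRUE)
  )[[1]]
  clean <- gsub("\\[[^]]*\\]", "", text)
  tree <- ape::read.tree(text = clean)
  if (is.null(tree)) stop("could not parse Newick tree", call. = FALSE)
  attr(tree, "uncertain") <- gsub("'", "", flagged)
  tree
}

node_children <- function(tree) {
  split(tree$edge[, 2], factor(tree$edge[, 1],
                               levels = seq_len(ape::Nnode(tree)) +
                                 ape::Ntip(tree)))
}

node_label <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  fallback <- paste0("node", seq_len(tree$Nnode) + ntip)
  nl <- tree$node.label
  if (is.null(nl)) nl <- fallback
  nl[is.na(nl) | !nzchar(nl)] <- fallback[is.na(nl) | !nzchar(nl)]
  labs <- character(length(node))
  tip <- node <= ntip
  labs[tip] <- tree$tip.label[node[tip]]
  labs[!tip] <- nl[node[!tip] - ntip]
  labs
}

#' Collapse uncertain branches into polytomies
#'
#' Sensitivity helper: every internal node flagged `[&uncertain]` (see
#' [read_karyo_tree()]) is dissolved, its children re-attached to its parent.
#' Flags on tips are ignored (a terminal branch cannot be collapsed).
#'
#' @param tree A `phylo` with an `"uncertain"` attribute.
#' @return A `phylo` with the flagged internal edges collapsed.
#' @export
collapse_uncertain <- function(tree) {
  flagged <- attr(tree, "uncertain")
  if (is.null(flagged) || !length(flagged)) return(tree)
  ntip <- ape::Ntip(tree)
  labels <- c(tree$tip.label,
              if (!is.null(tree$node.label)) tree$node.label
              else rep("", tree$Nnode))
  drop_nodes <- setdiff(which(labels %in% flagged), seq_len(ntip))
  root <- ntip + 1L
  drop_nodes <- setdiff(drop_nodes, root)
  if (!length(drop_nodes)) {
    attr(tree, "uncertain") <- character()
    return(tree)
  }
  kids <- node_children(tree)
  expand_children <- function(node) {
    parts <- character()
    for (c in kids[[as.character(node)]]) {
      parts <- c(parts,
                 if (c %in% drop_nodes) expand_children(c) else build(c))
    }
    parts
  }
  build <- function(node) {
    ch <- kids[[as.character(node)]]
    if (is.null(ch) || !length(ch)) return(labels[node])
    paste0("(", paste(expand_children(node), collapse = ","), ")",
           labels[node])
  }
  out <- ape::read.tree(text = paste0(build(root), ";"))
  attr(out, "uncertain") <- character()
  out
}
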