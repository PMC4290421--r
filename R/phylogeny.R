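#' Parse and validate a phylogeny
#'
#' Reads a rooted phylogeny with branch lengths from newick text and
#' checks the invariants every downstream computation relies on: at
#' least two uniquely labelled tips, a branch length on every edge, and
#' no negative lengths. Polytomies are preserved as-is; internal node
#' labels (e.g. posterior supports) are ignored.
#'
#' @param newick_text a newick string.
#' @return an `ape::phylo` tree.
#' @examples
#' tr <- parse_tree("((A:1,B:1):1,C:2);")
#' total_pd(tr)  # 5
#' @export
parse_tree <- function(newick_text) {
  tr <- tryCatch(ape::read.tree(text = newick_text),
                 error = function(e) NULL, warning = function(w) NULL)
  stop_if(is.null(tr) || !inherits(tr, "phylo"), "malformed newick")
  validate_tree(tr)
}

#' @rdname parse_tree
#' @param path file holding either bare newick or a NEXUS trees block
#'   (detected from the leading `#NEXUS`); the first tree is used.
#' @export
read_phylogeny <- function(path) {
  stop_if(!file.exists(path), "cannot read tree file: ", path)
  first <- toupper(trimws(readLines(path, n = 1L)))
  if (startsWith(first, "#NEXUS")) {
    tr <- ape::read.nexus(path)
    if (inherits(tr, "multiPhylo")) tr <- tr[[1]]
    validate_tree(tr)
  } else {
    parse_tree(paste(readLines(path), collapse = "\n"))
  }
}

validate_tree <- function(tr) {
  stop_if(ape::Ntip(tr) < 2, "tree must have at least 2 tips")
  stop_if(anyDuplicated(tr$tip.label) > 0, "duplicate tip labels")
  stop_if(any(!nzchar(tr$tip.label)), "empty tip label")
  stop_if(is.null(tr$edge.length) || anyNA(tr$edge.length) ||
            any(!is.finite(tr$edge.length)),
          "every branch needs a finite length")
  stop_if(any(tr$edge.length < 0), "negative branch length")
  # exactly one root node (a node that is never a child)
  parents <- unique(tr$edge[, 1])
  roots <- setdiff(parents, tr$edge[, 2])
  stop_if(length(roots) != 1L, "tree must have a single root")
  ape::reorder.phylo(tr, "cladewise")
}

#' Total phylogenetic diversity of a tree
#'
#' Faith's PD of the whole tree: the sum of all branch lengths. This is
#' the denominator of every PD-retention statistic in the package.
#'
#' @param x an `ape::phylo` tree or a [branch_table].
#' @return a single nonnegative number.
#' @export
total_pd <- function(x) {
  if (inherits(x, "phylo")) sum(x$edge.length)
  else if (inherits(x, "branch_table")) sum(x$length)
  else stop("total_pd needs a phylo or branch_table", call. = FALSE)
}

#' Graft taxa without molecular data onto a tree
#'
#' Attaches each new tip at the stem node of a designated sibling taxon,
#' i.e. as a new child of the sibling's parent node (creating or
#' extending a polytomy there). With the default branch length of zero
#' the grafted tip adds no branch length, so total PD is unchanged while
#' the tip still contributes its occurrence probabilities to every
#' ancestral branch. Instructions are applied sequentially, so a grafted
#' tip can serve as the sibling of a later instruction.
#'
#' @param tree an `ape::phylo` tree.
#' @param instructions data frame with columns `new_tip`, `sibling` and
#'   optionally `length` (default 0), e.g. from [read_graft_table()].
#' @return the augmented tree.
#' @examples
#' tr <- parse_tree("((A:1,B:1):1,C:2);")
#' tr2 <- graft_taxa(tr, data.frame(new_tip = "D", sibling = "A"))
#' total_pd(tr2)  # still 5
#' @export
graft_taxa <- function(tree, instructions) {
  stopifnot(inherits(tree, "phylo"), is.data.frame(instructions))
  stop_if(!all(c("new_tip", "sibling") %in% names(instructions)),
          "instructions need columns new_tip, sibling")
  if (is.null(instructions$length)) instructions$length <- 0
  stop_if(anyNA(instructions$length) || any(instructions$length < 0),
          "graft branch lengths must be nonnegative")
  for (k in seq_len(nrow(instructions))) {
    lab <- as.character(instructions$new_tip[k])
    sib <- as.character(instructions$sibling[k])
    stop_if(lab %in% tree$tip.label, "tip already in tree: ", lab)
    stop_if(!nzchar(lab), "empty new tip label")
    sib_idx <- match(sib, tree$tip.label)
    stop_if(is.na(sib_idx), "unknown sibling taxon: ", sib)
    stem <- tree$edge[match(sib_idx, tree$edge[, 2]), 1]
    tree <- suppressWarnings(
      phytools::bind.tip(tree, lab, edge.length = instructions$length[k],
                         where = stem, position = 0))
  }
  validate_tree(tree)
}

#' @rdname graft_taxa
#' @param path CSV with columns `new_tip,sibling,length`.
#' @export
read_graft_table <- function(path) {
  g <- utils::read.csv(path, stringsAsFactors = FALSE)
  stop_if(!all(c("new_tip", "sibling") %in% names(g)),
          "graft table needs columns new_tip,sibling[,length]")
  g
}

#' Enumerate the branches of a tree as conservation features
#'
#' Every branch of the tree -- terminal and internal -- becomes one
#' conservation feature, identified by a stable integer `branch_id`
#' assigned in preorder (cladewise) traversal with children in newick
#' file order, so repeated calls on the same tree give identical ids.
#' The root itself has no subtending edge and is not a row. For a fully
#' bifurcating tree of n tips this yields 2n - 2 branches.
#'
#' @param tree an `ape::phylo` tree.
#' @return a `branch_table` data frame with columns `branch_id`,
#'   `length`, `is_tip`, `label` (tip label or `NA`), `node` (ape node
#'   number of the branch's child end), `n_tips`, and a list-column
#'   `tips` holding each branch's descendant tip labels.
#' @examples
#' bt <- enumerate_branches(parse_tree("((A:1,B:1):1,C:2);"))
#' nrow(bt)          # 4 branches
#' sum(bt$length)    # equals total_pd of the tree
#' @export
enumerate_branches <- function(tree) {
  tree <- validate_tree(tree)
  child <- tree$edge[, 2]
  ntip <- ape::Ntip(tree)
  is_tip <- child <= ntip
  desc <- phangorn::Descendants(tree, child, type = "tips")
  tips <- lapply(desc, function(i) tree$tip.label[i])
  out <- data.frame(branch_id = seq_along(child),
                    length = tree$edge.length,
                    is_tip = is_tip,
                    label = ifelse(is_tip, tree$tip.label[child], NA),
                    node = child,
                    n_tips = lengths(tips))
  out$tips <- tips
  class(out) <- c("branch_table", "data.frame")
  out
}

#' @rdname enumerate_branches
#' @param table a `branch_table`.
#' @param path output CSV path; descendant tips are semicolon-joined.
#' @export
write_branch_table <- function(table, path) {
  flat <- table
  flat$tips <- vapply(table$tips, paste, character(1), collapse = ";")
  utils::write.csv(flat, path, row.names = FALSE)
  invisible(path)
}
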