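## Tree ingestion and clade enumeration for the recursive design
## descent, plus a distance/NJ convenience for users without a tree.
## Trees are ape "phylo" objects throughout.

#' Parse a newick tree
#'
#' @param text newick string (or a file path when `file = TRUE`).
#' @param file logical; treat `text` as a path.
#' @return an [ape::phylo] tree with unique leaf labels.
#' @examples
#' tr <- parseNewick("((A:1,B:1):1,C:2);")
#' @export
parseNewick <- function(text, file = FALSE) {
  tr <- tryCatch(
    if (file) ape::read.tree(text) else ape::read.tree(text = text),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo")) {
    stop("malformed newick input")
  }
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate leaf labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]),
               collapse = ", "))
  }
  tr
}

#' Serialize a tree to newick
#'
#' @param tree an [ape::phylo] tree.
#' @return newick string (with trailing semicolon).
#' @export
writeNewick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree)
}

#' Uncorrected p-distance matrix from an alignment
#'
#' Pairwise proportion of mismatching columns among columns where
#' neither sequence has a gap (pairwise deletion), computed via
#' [ape::dist.dna()] with `model = "raw"`.
#'
#' @param msa named character vector of equal-length aligned sequences
#'   (gaps as `-`).
#' @return symmetric numeric matrix with zero diagonal.
#' @export
pDistanceMatrix <- function(msa) {
  if (length(unique(nchar(msa))) != 1L) {
    stop("aligned sequences must have equal length")
  }
  if (is.null(names(msa))) names(msa) <- paste0("seq", seq_along(msa))
  bin <- ape::as.DNAbin(strsplit(tolower(msa), "", fixed = TRUE))
  d <- ape::dist.dna(bin, model = "raw", pairwise.deletion = TRUE)
  as.matrix(d)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining via [ape::nj()]. Because the design
#' descent needs a rooted tree and NJ output is unrooted, the result is
#' midpoint-rooted by default ([phangorn::midpoint()]).
#'
#' @param d symmetric distance matrix, >= 3 taxa.
#' @param root `"midpoint"` (default) or `"none"` to keep the unrooted
#'   NJ tree.
#' @return an [ape::phylo] tree.
#' @export
njTree <- function(d, root = c("midpoint", "none")) {
  root <- match.arg(root)
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("neighbor joining needs at least 3 taxa")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  tr <- ape::nj(stats::as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  if (root == "midpoint") tr <- phangorn::midpoint(tr)
  tr
}

# children of an internal node (ape numbering)
.treeChildren <- function(tree, node) {
  tree$edge[tree$edge[, 1] == node, 2]
}

# tip labels under a node
.leavesUnder <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  out <- character(0)
  stack <- node
  while (length(stack)) {
    n <- stack[[1]]; stack <- stack[-1]
    if (n <= ntip) out <- c(out, tree$tip.label[n])
    else stack <- c(stack, .treeChildren(tree, n))
  }
  out
}

#' Enumerate clades from the root down
#'
#' Breadth-first list of every internal node's leaf set (root first),
#' followed by each leaf as a singleton -- the candidate clusters the
#' recursive primer-design descent visits.
#'
#' @param tree a rooted [ape::phylo] tree (or a single-leaf tree).
#' @return list of character vectors of leaf labels.
#' @examples
#' cladesRootdown(parseNewick("((A,B),(C,D));"))
#' @export
cladesRootdown <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  if (ntip == 1L) return(list(tree$tip.label))
  root <- ntip + 1L
  queue <- root
  internal <- list()
  while (length(queue)) {
    n <- queue[[1]]; queue <- queue[-1]
    internal[[length(internal) + 1L]] <- .leavesUnder(tree, n)
    kids <- .treeChildren(tree, n)
    queue <- c(queue, kids[kids > ntip])
  }
  c(internal, as.list(tree$tip.label))
}
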