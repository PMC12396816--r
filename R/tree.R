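#' Extract parent-child pairs from a clonal-family tree
#'
#' Converts the edges of a rooted clonal-family phylogeny with ancestral
#' (internal-node) sequences into a [PcpSet-class]: each edge becomes one
#' pair with the rootward node's sequence as parent. The edge incident to
#' the node named `naiveId` (the unmutated germline outgroup used to root
#' the tree) is omitted, since that edge mixes rearrangement with somatic
#' hypermutation. Branch lengths are initialized from the normalized
#' mutation count of each retained pair.
#'
#' @param tree an `ape::phylo` object, a newick string, or a path to a
#'   newick file. Every node (tips and internals) must be labelled.
#' @param nodeSequences a named character vector, named `DNAStringSet`, or
#'   path to a FASTA file mapping node labels to sequences.
#' @param naiveId label of the naive (germline outgroup) node.
#' @param sampleId,familyId identifiers stored on the resulting pairs.
#' @return a [PcpSet-class] with one pair per non-naive edge.
#' @export
extractPcpsFromTree <- function(tree, nodeSequences, naiveId,
                                sampleId = "sample1", familyId = "family1") {
  if (is.character(tree)) {
    tree <- if (file.exists(tree)) ape::read.tree(tree) else ape::read.tree(text = tree)
  }
  if (!inherits(tree, "phylo")) stop("tree must be a phylo object or newick text")
  if (is.character(nodeSequences) && length(nodeSequences) == 1L &&
      file.exists(nodeSequences)) {
    ss <- Biostrings::readDNAStringSet(nodeSequences)
    nodeSequences <- stats::setNames(as.character(ss), names(ss))
  } else if (methods::is(nodeSequences, "DNAStringSet")) {
    nodeSequences <- stats::setNames(as.character(nodeSequences),
                                     names(nodeSequences))
  }
  labels <- c(tree$tip.label, tree$node.label)
  nNode <- ape::Ntip(tree) + tree$Nnode
  if (length(labels) != nNode || any(is.na(labels)) || any(labels == ""))
    stop("every tree node (tips and internals) must be labelled")
  if (!naiveId %in% labels)
    stop("naive node '", naiveId, "' not found in the tree")
  miss <- setdiff(labels, names(nodeSequences))
  if (length(miss))
    stop("no sequence provided for tree node(s): ", paste(miss, collapse = ", "))
  edges <- tree$edge
  keep <- labels[edges[, 1]] != naiveId & labels[edges[, 2]] != naiveId
  parent <- unname(nodeSequences[labels[edges[keep, 1]]])
  child <- unname(nodeSequences[labels[edges[keep, 2]]])
  PcpSet(parent, child, sampleId = sampleId, familyId = familyId,
         provenance = list(naiveId = naiveId))
}
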