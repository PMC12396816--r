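#' Construct a PcpSet of aligned parent-child pairs
#'
#' Builds a [PcpSet-class] from parallel vectors of aligned parent and child
#' sequences. Sequences must be gap-free strings over A, C, G, T, N;
#' gap characters are rejected at load time because insertions/deletions
#' make site positions ambiguous. The default loss mask marks a site
#' informative when both parent and child carry an unambiguous base. Branch
#' lengths default to the normalized mutation count of each pair (mutated
#' informative sites / informative sites).
#'
#' @param parent,child character vectors of aligned sequences.
#' @param sampleId,familyId identifiers, recycled to the number of pairs.
#' @param branchLength optional numeric branch lengths; computed from the
#'   normalized mutation count when NULL.
#' @param lossMask optional list of logical per-site masks; sites where
#'   either sequence is N are forced to FALSE.
#' @param provenance free-text metadata list.
#' @return a [PcpSet-class].
#' @examples
#' pcps <- PcpSet(parent = "ACGTACGT", child = "ACGTACTT")
#' branchLengths(pcps)
#' @export
PcpSet <- function(parent, child, sampleId = "sample1", familyId = "family1",
                   branchLength = NULL, lossMask = NULL,
                   provenance = list()) {
  if (length(parent) != length(child))
    stop("parent and child vectors must have equal length")
  n <- length(parent)
  for (i in seq_len(n)) {
    if (grepl("-", parent[i], fixed = TRUE) || grepl("-", child[i], fixed = TRUE))
      stop(sprintf("pair %d contains a gap character; gapped sequences are rejected", i))
    .checkSeq(parent[i], sprintf("parent %d", i))
    .checkSeq(child[i], sprintf("child %d", i))
    if (nchar(parent[i]) != nchar(child[i]))
      stop(sprintf("pair %d: parent and child lengths differ (%d vs %d)",
                   i, nchar(parent[i]), nchar(child[i])))
  }
  informative <- lapply(seq_len(n), function(i) {
    .charMat(parent[i]) %in% .NUC & .charMat(child[i]) %in% .NUC
  })
  if (is.null(lossMask)) {
    lossMask <- informative
  } else {
    if (length(lossMask) != n) stop("lossMask must have one entry per pair")
    lossMask <- lapply(seq_len(n), function(i) lossMask[[i]] & informative[[i]])
  }
  obj <- new("PcpSet",
    parent = as.character(parent), child = as.character(child),
    branchLength = rep(0, n),
    sampleId = rep_len(as.character(sampleId), n),
    familyId = rep_len(as.character(familyId), n),
    lossMask = lossMask, provenance = provenance
  )
  if (is.null(branchLength)) {
    obj@branchLength <- normalizedMutationCount(obj)
  } else {
    if (any(branchLength < 0)) stop("branch lengths must be nonnegative")
    obj@branchLength <- rep_len(as.numeric(branchLength), n)
  }
  validObject(obj)
  obj
}

#' @describeIn PcpSet number of pairs.
#' @param x a PcpSet.
#' @export
setMethod("length", "PcpSet", function(x) length(x@parent))

#' @describeIn PcpSet subset pairs, preserving order.
#' @param i index vector.
#' @export
setMethod("[", "PcpSet", function(x, i) {
  new("PcpSet",
    parent = x@parent[i], child = x@child[i],
    branchLength = x@branchLength[i],
    sampleId = x@sampleId[i], familyId = x@familyId[i],
    lossMask = x@lossMask[i], provenance = x@provenance
  )
})

setMethod("show", "PcpSet", function(object) {
  n <- length(object)
  cat(sprintf("PcpSet with %d parent-child pair%s\n", n, if (n == 1) "" else "s"))
  if (n > 0) {
    cat(sprintf("  sequence lengths: %s\n",
                paste(range(nchar(object@parent)), collapse = "-")))
    cat(sprintf("  samples: %d, families: %d\n",
                length(unique(object@sampleId)), length(unique(object@familyId))))
    cat(sprintf("  median mutations per pair: %g\n",
                stats::median(mutationCounts(object))))
  }
})

#' Accessors for PcpSet slots
#'
#' @param x a [PcpSet-class].
#' @return the corresponding per-pair vector or list.
#' @name pcp-accessors
#' @export
parentSeqs <- function(x) x@parent

#' @rdname pcp-accessors
#' @export
childSeqs <- function(x) x@child

#' @rdname pcp-accessors
#' @export
branchLengths <- function(x) x@branchLength

#' @rdname pcp-accessors
#' @export
lossMasks <- function(x) x@lossMask

#' @rdname pcp-accessors
#' @export
sampleIds <- function(x) x@sampleId

#' @rdname pcp-accessors
#' @export
familyIds <- function(x) x@familyId

#' Per-site mutation indicators
#'
#' For each pair, a logical vector m with m_i TRUE iff parent and child
#' differ at site i and both carry an unambiguous base. The informative
#' mask accompanying these indicators is the pair's loss mask.
#'
#' @param x a [PcpSet-class].
#' @return list of logical vectors, one per pair.
#' @export
mutationIndicators <- function(x) {
  lapply(seq_len(length(x)), function(i) {
    p <- .charMat(x@parent[i])
    c <- .charMat(x@child[i])
    p != c & p %in% .NUC & c %in% .NUC
  })
}

#' Observed mutation counts per pair
#'
#' Counts mutated sites among each pair's informative (loss-masked TRUE)
#' sites only; substitutions at masked sites do not count.
#'
#' @param x a [PcpSet-class].
#' @return integer vector.
#' @export
mutationCounts <- function(x) {
  m <- mutationIndicators(x)
  vapply(seq_len(length(x)),
         function(i) sum(m[[i]] & x@lossMask[[i]]), integer(1))
}

#' Normalized mutation count (branch length offset)
#'
#' The standard branch-length proxy t for a parent-child pair: mutated
#' informative sites divided by informative sites. Masked sites are excluded
#' from both numerator and denominator, making t a per-informative-site
#' quantity. Pairs with zero substitutions get t = 0; they are excluded from
#' training (zero gradient) but retained for evaluation.
#'
#' @param x a [PcpSet-class].
#' @return numeric vector of branch lengths.
#' @export
normalizedMutationCount <- function(x) {
  m <- mutationIndicators(x)
  vapply(seq_len(length(x)), function(i) {
    inf <- x@lossMask[[i]]
    if (!any(inf))
      stop(sprintf("pair %d has zero informative sites; t undefined", i))
    sum(m[[i]] & inf) / sum(inf)
  }, numeric(1))
}

#' Flag pairs with zero observed substitutions
#'
#' @param x a [PcpSet-class].
#' @return logical vector, TRUE for pairs with no informative mutation.
#' @export
zeroSubstitutionPairs <- function(x) mutationCounts(x) == 0L

#' Filter pairs by observed mutation count
#'
#' Retains exactly the pairs with fewer than `maxExclusive` substitutions
#' among informative sites, preserving order. The default threshold of 10
#' removes suspiciously long edges (often improper alignments) from
#' clonal-family phylogenies.
#'
#' @param x a [PcpSet-class].
#' @param maxExclusive exclusive upper bound on the substitution count.
#' @return the filtered [PcpSet-class] (possibly empty).
#' @export
filterByMutationCount <- function(x, maxExclusive = 10L) {
  x[which(mutationCounts(x) < maxExclusive)]
}

# third-position fourfold-degenerate codon prefixes, derived from the
# standard genetic code: prefixes whose four completions encode one amino acid
.fourfoldPrefixes <- function() {
  gc <- Biostrings::GENETIC_CODE
  pre <- unique(substr(names(gc), 1L, 2L))
  keep <- vapply(pre, function(p) {
    length(unique(gc[paste0(p, .NUC)])) == 1L
  }, logical(1))
  pre[keep]
}

#' Restrict the loss mask to fourfold-degenerate synonymous sites
#'
#' For in-frame (productive) sequences, mutations can only be assumed
#' selectively neutral at fourfold-degenerate sites: third codon positions
#' whose codon family encodes a single amino acid regardless of the third
#' base. This masks every site except those third positions, classified
#' from the parent codon. Codons containing N are wholly masked (degeneracy
#' undefined), as is any trailing partial codon. The result's mask never
#' exceeds the existing mask (ambiguity masking is preserved), and the
#' operation is idempotent.
#'
#' @param x a [PcpSet-class] of in-frame sequences.
#' @param frameOffset nonnegative 0-based offset of the first complete codon.
#' @return a [PcpSet-class] with restricted loss masks.
#' @export
fourfoldDegenerateMask <- function(x, frameOffset = 0L) {
  .checkScalar(frameOffset, "frameOffset", function(v) v >= 0, "must be nonnegative")
  pre4 <- .fourfoldPrefixes()
  masks <- lapply(seq_len(length(x)), function(i) {
    ch <- .charMat(x@parent[i])
    L <- length(ch)
    keep <- rep(FALSE, L)
    s <- frameOffset + 1L
    while (s + 2L <= L) {
      codon <- ch[s:(s + 2L)]
      if (!any(codon == "N") && paste0(codon[1:2], collapse = "") %in% pre4)
        keep[s + 2L] <- TRUE
      s <- s + 3L
    }
    keep & x@lossMask[[i]]
  })
  out <- x
  out@lossMask <- masks
  validObject(out)
  out
}

#' Read / write PCP tables
#'
#' PCP tables are UTF-8 tab-separated text with a header and columns
#' `parent`, `child`, `sample_id`, `family_id`, and optionally
#' `branch_length` (computed from normalized mutation counts when absent)
#' and `loss_mask` (a string of 0/1 per site). Numeric fields are written
#' with 17 significant digits so a write/read round trip is bit-exact.
#'
#' @param path file path.
#' @return `readPcpTable` returns a [PcpSet-class]; `writePcpTable`
#'   invisibly returns `path`.
#' @export
readPcpTable <- function(path) {
  if (!file.exists(path)) stop("PCP table not found: ", path)
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE,
                          fileEncoding = "UTF-8")
  need <- c("parent", "child", "sample_id", "family_id")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("PCP table missing required column(s): ", paste(miss, collapse = ", "))
  masks <- NULL
  if ("loss_mask" %in% names(df)) {
    masks <- lapply(df$loss_mask, function(s) .charMat(s) == "1")
  }
  bl <- if ("branch_length" %in% names(df)) as.numeric(df$branch_length) else NULL
  PcpSet(df$parent, df$child,
         sampleId = df$sample_id, familyId = df$family_id,
         branchLength = bl, lossMask = masks,
         provenance = list(source = path))
}

#' @rdname readPcpTable
#' @param x a [PcpSet-class] to write.
#' @export
writePcpTable <- function(x, path) {
  df <- data.frame(
    parent = x@parent, child = x@child,
    sample_id = x@sampleId, family_id = x@familyId,
    branch_length = .fmtNum(x@branchLength),
    loss_mask = vapply(x@lossMask,
                       function(m) paste0(as.integer(m), collapse = ""),
                       character(1)),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
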