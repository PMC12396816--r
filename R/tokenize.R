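#' Tokenize a sequence into centered 3-mer tokens
#'
#' Maps each site of a nucleotide sequence to an integer token for its
#' centered 3-mer (the site together with its immediate neighbours). An
#' unambiguous 3-mer b1 b2 b3 gets token 16 v(b1) + 4 v(b2) + v(b3) with
#' v(A,C,G,T) = (0,1,2,3); any 3-mer containing N, or truncated by a
#' sequence boundary, gets the ambiguity token 64. Tokens index the
#' trainable 65-row embedding table of a thrifty model.
#'
#' @param seq a single sequence string over A, C, G, T, N.
#' @return integer vector of tokens in 0..64, one per site.
#' @examples
#' tokenize3mers("ACGT")  # 64 6 27 64
#' @export
tokenize3mers <- function(seq) {
  ch <- .checkSeq(seq)
  L <- length(ch)
  v <- .baseIdx0(ch)
  left <- c(NA_integer_, v[-L])
  right <- c(v[-1L], NA_integer_)
  tok <- 16L * left + 4L * v + right
  tok[is.na(tok)] <- 64L
  tok
}

#' Centered k-mer context at a site
#'
#' Returns the k-mer window centered on 0-based site `i`, padded with N
#' beyond the sequence boundaries. Windows containing N route k-mer table
#' models to their ambiguity token.
#'
#' @param seq a sequence string over A, C, G, T, N.
#' @param i 0-based site index.
#' @param k odd window width.
#' @return the k-character context string.
#' @examples
#' kmerContext("ACGTA", 0, 5)  # "NNACG"
#' @export
kmerContext <- function(seq, i, k) {
  ch <- .checkSeq(seq)
  .checkScalar(k, "k", function(v) v >= 1 && v %% 2 == 1, "must be a positive odd integer")
  .checkScalar(i, "i", function(v) v >= 0 && v < length(ch), "out of range (0-based)")
  h <- (k - 1L) / 2
  pos <- (i - h):(i + h) + 1L # 1-based
  out <- rep("N", k)
  ok <- pos >= 1L & pos <= length(ch)
  out[ok] <- ch[pos[ok]]
  paste0(out, collapse = "")
}

# 1-based index into a 4^k + 1 table; ambiguous/boundary windows -> 4^k + 1
.kmerIdx1 <- function(seq, k) {
  ch <- .charMat(seq)
  L <- length(ch)
  v <- .baseIdx0(ch)
  h <- (k - 1L) / 2
  idx <- rep(0L, L)
  amb <- rep(FALSE, L)
  for (d in -h:h) {
    pos <- seq_len(L) + d
    vv <- ifelse(pos >= 1L & pos <= L, v[pmax(pmin(pos, L), 1L)], NA_integer_)
    amb <- amb | is.na(vv)
    vv[is.na(vv)] <- 0L
    idx <- idx * 4L + vv
  }
  idx <- idx + 1L
  idx[amb] <- 4L^k + 1L
  idx
}
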