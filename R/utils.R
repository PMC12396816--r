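# split a sequence string into a character vector of single bases
.charMat <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# validate one sequence over {A,C,G,T,N}; errors name position and symbol
.checkSeq <- function(s, what = "sequence") {
  if (length(s) != 1L || is.na(s) || nchar(s) < 1L)
    stop(what, " must be a single non-empty string")
  ch <- .charMat(s)
  bad <- which(!ch %in% .NUC_N)
  if (length(bad)) {
    stop(sprintf(
      "illegal symbol '%s' at position %d of %s (alphabet is A,C,G,T,N)",
      ch[bad[1]], bad[1] - 1L, what
    ))
  }
  invisible(ch)
}

# base -> 0..3 (A,C,G,T), NA for N
.baseIdx0 <- function(ch) {
  i <- match(ch, .NUC)
  i - 1L
}

.relu <- function(x) {
  x[x < 0] <- 0
  x
}

# full-precision numeric formatting for text round trips
.fmtNum <- function(x) sprintf("%.17g", x)

.allKmers <- function(k) {
  g <- do.call(expand.grid, rep(list(.NUC), k))
  # leftmost base is the most significant digit
  apply(g[, rev(seq_len(k)), drop = FALSE], 1L, paste0, collapse = "")
}

# stop unless x is a single finite number satisfying pred
.checkScalar <- function(x, what, pred = function(v) TRUE, msg = "invalid") {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || !pred(x))
    stop(what, " ", msg)
  invisible(x)
}
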