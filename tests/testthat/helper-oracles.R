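## Independent oracles used to check the package's statistics. These stay
## deliberately naive: sort-based BH step-up, subset enumeration for the
## hypergeometric tail, per-template cor() loops for the argmax.

## Naive Benjamini-Hochberg step-up rejection set.
bhRejectOracle <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  ok <- ps <= alpha * seq_len(m) / m
  rej <- logical(m)
  if (any(ok)) rej[o[seq_len(max(which(ok)))]] <- TRUE
  rej
}

## P(X >= k) when drawing n items from N of which K are carriers, by
## exhaustive enumeration of all n-subsets (feasible for N <= 12).
hyperEnumOracle <- function(N, K, n, k) {
  if (n == 0L) return(as.numeric(k <= 0))
  subsets <- combn(N, n)
  mean(colSums(subsets <= K) >= k)
}

## Best template by a per-template cor() loop (double-loop scan).  The
## top-two gap is reported so callers can skip argmax comparisons on
## float-level ties, which the two computation routes may break
## differently.
bruteArgmaxOracle <- function(log2profile, lib) {
  rs <- apply(templates(lib), 1L, function(tp) cor(log2profile, tp))
  top2 <- sort(rs, decreasing = TRUE)[1:2]
  list(idx = which.max(rs), R = max(rs), gap = top2[1] - top2[2])
}

## Signed circular shift as the argmin over the three unwrapped candidates.
signedShiftOracle <- function(pRef, pTarget) {
  cand <- pTarget - pRef + c(-24, 0, 24)
  cand[which.min(abs(cand))]
}

## Naive per-promoter substring presence count for one kmer.
kmerPresenceOracle <- function(seqs, kmer) {
  sum(vapply(seqs, function(s) grepl(kmer, s, fixed = TRUE), TRUE))
}
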