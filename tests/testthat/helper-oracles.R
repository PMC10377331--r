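# Independent brute-force oracles used to cross-check the implementation.

# reflect (no edge duplication) index into 1..n
reflect_idx <- function(i, n) {
  ifelse(i < 1, 2 - i, ifelse(i > n, 2 * n - i, i))
}

# naive 2-D correlation with reflective boundary, triple loop
filter2_oracle <- function(x, K) {
  H <- nrow(x); W <- ncol(x)
  k <- nrow(K); p <- (k - 1) %/% 2
  out <- matrix(0, H, W)
  for (r in seq_len(H)) for (c in seq_len(W)) {
    acc <- 0
    for (i in seq_len(k)) for (j in seq_len(k)) {
      rr <- reflect_idx(r + i - p - 1, H)
      cc <- reflect_idx(c + j - p - 1, W)
      acc <- acc + K[i, j] * x[rr, cc]
    }
    out[r, c] <- acc
  }
  out
}

dice_oracle <- function(a, b) {
  ia <- which(a); ib <- which(b)
  2 * length(intersect(ia, ib)) / (length(ia) + length(ib))
}

hausdorff_oracle <- function(a, b, spacing = c(1, 1)) {
  A <- which(a, arr.ind = TRUE); B <- which(b, arr.ind = TRUE)
  dmin <- function(P, Q) {
    sapply(seq_len(nrow(P)), function(i) {
      min(sqrt(((P[i, 1] - Q[, 1]) * spacing[1])^2 +
                 ((P[i, 2] - Q[, 2]) * spacing[2])^2))
    })
  }
  max(max(dmin(A, B)), max(dmin(B, A)))
}

# random non-empty binary mask
random_mask <- function(n, p = 0.1) {
  repeat {
    m <- matrix(runif(n * n) < p, n, n)
    if (any(m)) return(m)
  }
}

count_components <- function(mask) {
  # EBImage's connected-component labelling as an independent oracle
  max(EBImage::bwlabel(mask))
}
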