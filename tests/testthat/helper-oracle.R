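# Independent oracles, kept deliberately naive and separate from the
# package's implementation paths.

# Quadratic-space brute-force Smith-Waterman with affine gaps; a gap of
# length L costs open + L * ext.
oracle_sw <- function(a, b, mat, open = 11, ext = 1) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)   # gap in b (vertical)
  Iy <- matrix(NEG, n + 1, m + 1)   # gap in a (horizontal)
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    Ix[i, j] <- max(M[i - 1, j] - open - ext, Ix[i - 1, j] - ext)
    Iy[i, j] <- max(M[i, j - 1] - open - ext, Iy[i, j - 1] - ext)
    s <- mat[a[i - 1], b[j - 1]]
    M[i, j] <- max(0, s + max(M[i - 1, j - 1], Ix[i - 1, j - 1],
                              Iy[i - 1, j - 1]))
    best <- max(best, M[i, j], Ix[i, j], Iy[i, j])
  }
  best
}

# Brute-force connected components by boolean transitive closure.
oracle_components <- function(ids, edges) {
  n <- length(ids)
  A <- diag(TRUE, n)
  dimnames(A) <- list(ids, ids)
  for (k in seq_len(nrow(edges))) {
    A[edges$bgc1[k], edges$bgc2[k]] <- TRUE
    A[edges$bgc2[k], edges$bgc1[k]] <- TRUE
  }
  repeat {
    A2 <- (A %*% A) > 0
    if (identical(A2, A)) break
    A <- A2
  }
  # canonical partition label: smallest member id of each row's component
  apply(A, 1, function(r) min(ids[r]))
}

random_peptide <- function(len) {
  paste(sample(bgcfam:::AA20, len, replace = TRUE), collapse = "")
}
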