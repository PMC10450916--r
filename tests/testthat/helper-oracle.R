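# Brute-force GLCM oracle: enumerates every pixel pair with explicit loops.
# Kept deliberately independent of compute_glcm's vectorized tabulation.
glcm_oracle <- function(px, levels, distance, angle,
                        symmetric = TRUE, normalized = TRUE) {
  off <- switch(as.character(angle),
                "0" = c(0L, distance), "45" = c(-distance, distance),
                "90" = c(-distance, 0L), "135" = c(-distance, -distance))
  m <- matrix(0, levels, levels)
  h <- nrow(px); w <- ncol(px)
  for (r in seq_len(h)) {
    for (cc in seq_len(w)) {
      r2 <- r + off[1]; c2 <- cc + off[2]
      if (r2 >= 1L && r2 <= h && c2 >= 1L && c2 <= w) {
        i <- px[r, cc] + 1L; j <- px[r2, c2] + 1L
        m[i, j] <- m[i, j] + 1
        if (symmetric) m[j, i] <- m[j, i] + 1
      }
    }
  }
  if (normalized) m <- m / sum(m)
  m
}

random_gray_matrix <- function(h, w, levels) {
  matrix(sample.int(levels, h * w, replace = TRUE) - 1L, h, w)
}

# random normalized GLCM-like probability matrix (optionally symmetric)
random_glcm <- function(levels, symmetric = TRUE) {
  p <- matrix(stats::rexp(levels * levels), levels, levels)
  if (symmetric) p <- p + t(p)
  p <- p / sum(p)
  params <- glcm_params(distance = 1, levels = levels,
                        symmetric = symmetric, normalized = TRUE)
  structure(list(p = p, params = params, n_pairs = NA_integer_),
            class = "glcm")
}
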