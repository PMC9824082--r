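# Shared fixtures and independent oracles used across the test files.
# Oracles deliberately avoid the code paths they check: the Fourier oracle
# multiplies explicit complex basis matrices instead of calling fft, the
# DCT oracle sums cosine basis functions, the GLCM oracle counts pixel
# pairs exhaustively.

# memoised fixtures (built once per test run)
.fixtures <- new.env()
fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures, inherits = FALSE))
    assign(name, force(expr), envir = .fixtures)
  get(name, envir = .fixtures, inherits = FALSE)
}

random_stream <- function(n, seed = 1, sensor_id = "S1") {
  set.seed(seed)
  frame_stream(matrix(runif(n * 64, 15, 30), n, 64),
               timestamps = (0:(n - 1)) / 10, sensor_id = sensor_id)
}

# Small clean 8-class large-layout dataset (72 records, sensor S1).
small8 <- function() fixture("small8", {
  recs <- build_coventry_like(scene_config(), seed = 3, layouts = "large",
                              include_double = FALSE, sensors = "S1", repeats = 3)
  build_dataset(recs, "S1")
})

# 15-class toy tensor (the combined single+double vocabulary size) with
# weak class-mean offsets; cheap stand-in where only label structure matters.
small15_maps <- function() fixture("small15_maps", {
  set.seed(99)
  labels <- rep(c(paste0("AL", 1:8), paste0("B", 1:7)), each = 3)
  maps <- array(rnorm(45 * 40 * 64, 20, 1), c(45, 40, 64))
  for (i in seq_along(labels))
    maps[i, , ] <- maps[i, , ] + match(labels[i], unique(labels)) * 0.5
  dataset_tensor(maps, labels)
})

# Brute-force centered 2D DFT via explicit basis matrices (no fft call):
# F0[u,v] = sum_m sum_n X[m,n] exp(-2i*pi*(u*m/M + v*n/N)), then the
# half-swap that puts DC at (21, 33) for a 40x64 input.
brute_dft_shifted <- function(X) {
  M <- nrow(X); N <- ncol(X)
  EM <- exp(-2i * pi * outer(0:(M - 1), 0:(M - 1)) / M)
  EN <- exp(-2i * pi * outer(0:(N - 1), 0:(N - 1)) / N)
  F0 <- EM %*% X %*% t(EN)
  F0[c((M / 2 + 1):M, 1:(M / 2)), c((N / 2 + 1):N, 1:(N / 2))]
}

# Brute-force inverse from a shifted spectrum.
brute_idft <- function(Fs) {
  M <- nrow(Fs); N <- ncol(Fs)
  F0 <- Fs[c((M / 2 + 1):M, 1:(M / 2)), c((N / 2 + 1):N, 1:(N / 2))]
  EM <- exp(2i * pi * outer(0:(M - 1), 0:(M - 1)) / M)
  EN <- exp(2i * pi * outer(0:(N - 1), 0:(N - 1)) / N)
  (EM %*% F0 %*% t(EN)) / (M * N)
}

# Brute-force orthonormal type-II 2D DCT coefficient (k1, k2 zero-based).
brute_dct_coef <- function(patch, k1, k2) {
  n <- nrow(patch)
  a <- function(k) if (k == 0) sqrt(1 / n) else sqrt(2 / n)
  s <- 0
  for (m in 0:(n - 1)) for (p in 0:(n - 1))
    s <- s + patch[m + 1, p + 1] *
      cos(pi * (2 * m + 1) * k1 / (2 * n)) *
      cos(pi * (2 * p + 1) * k2 / (2 * n))
  a(k1) * a(k2) * s
}

# Exhaustive symmetric normalized co-occurrence counting at offset (dr, dc).
brute_glcm <- function(q, dr, dc, levels) {
  G <- matrix(0, levels, levels)
  for (r in seq_len(nrow(q))) for (c in seq_len(ncol(q))) {
    rr <- r + dr; cc <- c + dc
    if (rr >= 1 && rr <= nrow(q) && cc >= 1 && cc <= ncol(q)) {
      G[q[r, c], q[rr, cc]] <- G[q[r, c], q[rr, cc]] + 1
      G[q[rr, cc], q[r, c]] <- G[q[rr, cc], q[r, c]] + 1
    }
  }
  G / sum(G)
}

brute_glcm_stats <- function(P) {
  L <- nrow(P)
  ctr <- 0; dis <- 0; mu_i <- 0; mu_j <- 0
  for (i in 1:L) for (j in 1:L) {
    ctr <- ctr + P[i, j] * (i - j)^2
    dis <- dis + P[i, j] * abs(i - j)
    mu_i <- mu_i + i * P[i, j]; mu_j <- mu_j + j * P[i, j]
  }
  s_i <- 0; s_j <- 0; cov <- 0
  for (i in 1:L) for (j in 1:L) {
    s_i <- s_i + (i - mu_i)^2 * P[i, j]
    s_j <- s_j + (j - mu_j)^2 * P[i, j]
    cov <- cov + (i - mu_i) * (j - mu_j) * P[i, j]
  }
  c(correlation = if (s_i * s_j == 0) 0 else cov / sqrt(s_i * s_j),
    contrast = ctr, dissimilarity = dis, energy = sqrt(sum(P^2)))
}

# A flat 40x64 background map for spectral tests.
flat_map <- function(value = 20, seed = NULL) {
  if (is.null(seed)) return(matrix(value, 40, 64))
  set.seed(seed)
  matrix(value + rnorm(40 * 64, sd = 0.05), 40, 64)
}
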