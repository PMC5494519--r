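# Independent brute-force oracles. These deliberately use naive algorithms
# (per-pixel sorting, exhaustive threshold scans, recursive alignment
# enumeration) so they share no code with the implementation they check.

# 3x3 median with edge replication, per pixel, via sort()
median3x3_brute <- function(img) {
  H <- nrow(img); W <- ncol(img)
  out <- img
  for (r in seq_len(H)) for (c in seq_len(W)) {
    v <- numeric(9); k <- 0
    for (dr in -1:1) for (dc in -1:1) {
      rr <- min(max(r + dr, 1), H)
      cc <- min(max(c + dc, 1), W)
      k <- k + 1; v[k] <- img[rr, cc]
    }
    out[r, c] <- sort(v)[5]
  }
  storage.mode(out) <- storage.mode(img)
  out
}

# exhaustive Otsu: naive per-threshold class statistics via mean()/length()
otsu_brute <- function(v, bit_depth) {
  L <- 2^bit_depth
  best <- -Inf; best_t <- NA
  for (t in 1:(L - 1)) {
    lo <- v[v < t]; hi <- v[v >= t]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(v); w1 <- 1 - w0
    sb <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (sb > best + 1e-12) { best <- sb; best_t <- t }
  }
  best_t
}

# smallest threshold with suprathreshold fraction <= max_frac, by linear scan
noise_thr_brute <- function(v, max_frac = 0.001) {
  for (t in 0:(max(v) + 1)) {
    if (mean(v >= t) <= max_frac) return(t)
  }
  stop("unreachable")
}

# brute-force local alignment: recursive enumeration of every gapped local
# alignment path from every start cell (gap of length L costs open + L*ext)
sw_brute <- function(a, b, S, open, ext) {
  m <- length(a); n <- length(b)
  if (m == 0 || n == 0) return(0)
  best <- 0
  rec <- function(i, j, state, score) {
    if (score > best) best <<- score
    if (i <= m && j <= n) rec(i + 1, j + 1, 1L, score + S[a[i], b[j]])
    if (j <= n) rec(i, j + 1, 2L,
                    score - if (state == 2L) ext else open + ext)
    if (i <= m) rec(i + 1, j, 3L,
                    score - if (state == 3L) ext else open + ext)
  }
  for (i in seq_len(m)) for (j in seq_len(n)) rec(i, j, 0L, 0)
  best
}

# naive double-loop recount of suprathreshold pixels in summed/difference
# series (8-bit scale, strict ">")
motility_counts_brute <- function(series, threshold = 32) {
  idx <- (series$t_act + 1L):dim(series$pixels)[1]
  H <- dim(series$pixels)[3]; W <- dim(series$pixels)[4]
  summed <- lapply(idx, function(i) {
    pmin(series$pixels[i, 1, , ] + series$pixels[i, 2, , ], 255)
  })
  sum_counts <- numeric(length(summed))
  for (k in seq_along(summed)) {
    cnt <- 0
    for (r in seq_len(H)) for (c in seq_len(W)) {
      if (summed[[k]][r, c] > threshold) cnt <- cnt + 1
    }
    sum_counts[k] <- cnt
  }
  diff_counts <- numeric(length(summed) - 1L)
  for (k in seq_len(length(summed) - 1L)) {
    cnt <- 0
    for (r in seq_len(H)) for (c in seq_len(W)) {
      if (abs(summed[[k + 1L]][r, c] - summed[[k]][r, c]) > threshold)
        cnt <- cnt + 1
    }
    diff_counts[k] <- cnt
  }
  list(sum_counts = sum_counts, diff_counts = diff_counts)
}
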