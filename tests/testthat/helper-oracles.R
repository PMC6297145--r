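# Independent brute-force oracles used to check the vectorised implementations.
# All are straightforward loops, kept deliberately naive.

oracle_band_reduce <- function(arr, start, bw, bands) {
  d <- dim(arr)
  out <- array(NA_real_, c(d[1], d[2], length(bands)))
  for (b in seq_along(bands)) {
    ch <- integer(0)
    for (i in seq_len(d[3])) {
      lo <- start + (i - 1) * bw; hi <- lo + bw
      if (lo >= bands[[b]][1] && hi <= bands[[b]][2]) ch <- c(ch, i)
    }
    for (y in seq_len(d[1])) for (x in seq_len(d[2]))
      out[y, x, b] <- mean(arr[y, x, ch])
  }
  out
}

oracle_mip <- function(slices) {
  d <- dim(slices[[1]])
  out <- array(NA_real_, d)
  for (y in seq_len(d[1])) for (x in seq_len(d[2])) for (c in seq_len(d[3]))
    out[y, x, c] <- max(vapply(slices, function(s) s[y, x, c], numeric(1)))
  out
}

oracle_disk_mean <- function(arr, y, x, r) {
  d <- dim(arr)
  acc <- numeric(d[3]); cnt <- 0
  for (dy in -r:r) for (dx in -r:r) {
    if (dy^2 + dx^2 > r^2 + 1e-9) next
    yy <- y + dy; xx <- x + dx
    if (yy < 1 || yy > d[1] || xx < 1 || xx > d[2]) next
    acc <- acc + arr[yy, xx, ]; cnt <- cnt + 1
  }
  acc / cnt
}

oracle_nearest <- function(X, centers) {
  out <- integer(nrow(X))
  for (i in seq_len(nrow(X))) {
    d <- apply(centers, 1, function(cc) sum((X[i, ] - cc)^2))
    out[i] <- which(d == min(d))[1]
  }
  out
}

# stack-based flood fill
oracle_components <- function(mask, connectivity = 8) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w); cur <- 0L
  nb <- if (connectivity == 4) rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
        else as.matrix(expand.grid(dy = -1:1, dx = -1:1))[-5, ]
  for (sy in seq_len(h)) for (sx in seq_len(w)) {
    if (!mask[sy, sx] || lab[sy, sx] > 0) next
    cur <- cur + 1L
    stack <- list(c(sy, sx)); lab[sy, sx] <- cur
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (j in seq_len(nrow(nb))) {
        y <- p[1] + nb[j, 1]; x <- p[2] + nb[j, 2]
        if (y < 1 || y > h || x < 1 || x > w) next
        if (mask[y, x] && lab[y, x] == 0L) {
          lab[y, x] <- cur
          stack[[length(stack) + 1]] <- c(y, x)
        }
      }
    }
  }
  list(labels = lab, n = cur,
       sizes = if (cur > 0) tabulate(lab[lab > 0], cur) else integer(0))
}

oracle_nnd <- function(pts) {
  n <- nrow(pts)
  mins <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    for (j in seq_len(n)) if (j != i)
      best <- min(best, sqrt(sum((pts[i, ] - pts[j, ])^2)))
    mins[i] <- best
  }
  mean(mins)
}

oracle_ks_stat <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  gap <- 0
  for (t in pts)
    gap <- max(gap, abs(mean(a <= t) - mean(b <= t)))
  gap
}

oracle_patch_hist <- function(patch, k) {
  cnt <- numeric(k); tot <- 0
  for (v in as.vector(patch)) if (v > 0) { cnt[v] <- cnt[v] + 1; tot <- tot + 1 }
  if (tot == 0) rep(NA_real_, k) else cnt / tot
}

# full unsuppressed FAST segment test at every interior pixel
oracle_fast <- function(img, threshold, arc = 9) {
  circ <- cbind(c(-3, -3, -2, -1, 0, 1, 2, 3, 3, 3, 2, 1, 0, -1, -2, -3),
                c(0, 1, 2, 3, 3, 3, 2, 1, 0, -1, -2, -3, -3, -3, -2, -1))
  h <- nrow(img); w <- ncol(img)
  out <- NULL
  for (y in 4:(h - 3)) for (x in 4:(w - 3)) {
    v <- img[y, x]
    s <- vapply(1:16, function(j) img[y + circ[j, 1], x + circ[j, 2]],
                numeric(1))
    br <- c(s > v + threshold, s > v + threshold)
    dk <- c(s < v - threshold, s < v - threshold)
    hit <- FALSE
    for (st in 1:16) {
      if (all(br[st:(st + arc - 1)]) || all(dk[st:(st + arc - 1)])) {
        hit <- TRUE; break
      }
    }
    if (hit) out <- rbind(out, c(y, x))
  }
  out
}

# exhaustive 2-means: best bipartition by within-cluster sum of squares
oracle_two_means <- function(X) {
  n <- nrow(X)
  best <- NULL; best_ss <- Inf
  for (code in 1:(2^(n - 1) - 1)) {
    grp <- c(0L, as.integer(intToBits(code))[seq_len(n - 1)])
    if (length(unique(grp)) < 2) next
    ss <- 0
    for (g in 0:1) {
      Xi <- X[grp == g, , drop = FALSE]
      ctr <- colMeans(Xi)
      ss <- ss + sum(sweep(Xi, 2, ctr)^2)
    }
    if (ss < best_ss) { best_ss <- ss; best <- grp }
  }
  list(assignment = best, ss = best_ss)
}
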