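# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use naive elementwise loops and closed forms, not the
# package's own code paths.

# per-pixel moment oracle: explicit double loop over the full raster
oracle_mask_moments <- function(mask, h) {
  n <- 0; sx <- 0; sy <- 0
  for (r in seq_len(nrow(mask))) {
    for (c in seq_len(ncol(mask))) {
      if (mask[r, c]) {
        n <- n + 1
        sx <- sx + (c - 0.5)
        sy <- sy + (r - 0.5)
      }
    }
  }
  cx <- sx / n; cy <- sy / n
  sxx <- 0; syy <- 0; sxy <- 0
  for (r in seq_len(nrow(mask))) {
    for (c in seq_len(ncol(mask))) {
      if (mask[r, c]) {
        dx <- (c - 0.5) - cx; dy <- (r - 0.5) - cy
        sxx <- sxx + dx * dx; syy <- syy + dy * dy; sxy <- sxy + dx * dy
      }
    }
  }
  cov <- matrix(c(sxx / n + 1 / 12, sxy / n, sxy / n, syy / n + 1 / 12), 2)
  ev <- eigen(cov, symmetric = TRUE)$values
  list(area_mm2 = n * h^2,
       centroid_mm = c(cx * h, cy * h),
       major_mm = 4 * sqrt(ev[1]) * h,
       minor_mm = 4 * sqrt(ev[2]) * h)
}

# rank oracle: ranks by sorting, ties get the mean of their sorted positions
oracle_rank <- function(x) {
  ord <- order(x)
  r <- numeric(length(x))
  pos <- seq_along(x)
  i <- 1
  while (i <= length(x)) {
    j <- i
    while (j < length(x) && x[ord[j + 1]] == x[ord[i]]) j <- j + 1
    r[ord[i:j]] <- mean(pos[i:j])
    i <- j + 1
  }
  r
}

oracle_spearman <- function(x, y) {
  rx <- oracle_rank(x); ry <- oracle_rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# least-squares oracle: solve the 2x2 normal equations directly
oracle_ls <- function(x, y) {
  n <- length(x)
  A <- matrix(c(sum(x^2), sum(x), sum(x), n), 2)
  ab <- solve(A, c(sum(x * y), sum(y)))
  pred <- ab[1] * x + ab[2]
  r2 <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  list(a = ab[1], b = ab[2], r2 = r2)
}

# hole-filling oracle: flood fill the background from the border; any
# background pixel not reached is a hole
oracle_fill_holes <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  outside <- matrix(FALSE, H, W)
  queue <- which(!mask & (row(mask) %in% c(1, H) | col(mask) %in% c(1, W)))
  outside[queue] <- TRUE
  while (length(queue) > 0) {
    p <- queue[1]; queue <- queue[-1]
    r <- (p - 1) %% H + 1; c <- (p - 1) %/% H + 1
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      rr <- r + d[1]; cc <- c + d[2]
      if (rr >= 1 && rr <= H && cc >= 1 && cc <= W) {
        q <- (cc - 1) * H + rr
        if (!mask[q] && !outside[q]) {
          outside[q] <- TRUE
          queue <- c(queue, q)
        }
      }
    }
  }
  mask | !outside
}

# analytic egg-curve membership test for direct rasterization checks
oracle_inside_egg <- function(x, y, a, b, ovality = 0) {
  bb <- b * (1 + ovality * y / (2 * a))
  ifelse(bb > 0, (y / a)^2 + (x / bb)^2 <= 1, FALSE)
}

# draw a random single-component blob mask (union of overlapping disks)
random_blob_mask <- function(H, W, n_disks = 3) {
  cx <- runif(1, W * 0.35, W * 0.65)
  cy <- runif(1, H * 0.35, H * 0.65)
  mask <- matrix(FALSE, H, W)
  xs <- matrix(seq_len(W) - 0.5, H, W, byrow = TRUE)
  ys <- matrix(seq_len(H) - 0.5, H, W)
  px <- cx; py <- cy
  for (k in seq_len(n_disks)) {
    r <- runif(1, min(H, W) * 0.08, min(H, W) * 0.2)
    mask <- mask | ((xs - px)^2 + (ys - py)^2 <= r^2)
    step <- runif(2, -r / 2, r / 2)  # keeps successive disks overlapping
    px <- min(max(px + step[1], W * 0.25), W * 0.75)
    py <- min(max(py + step[2], H * 0.25), H * 0.75)
  }
  mask
}
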