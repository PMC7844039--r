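# Brute-force oracle implementations of every ISO parameter: naive loops,
# direct sorting and integration, independent of the package's engine code.
# Used on small grids where O(n^2) cost is irrelevant.

oracle_height <- function(surf) {
  z <- surf$heights
  n <- length(z)
  s2 <- 0; s1 <- 0; s3 <- 0; s4 <- 0; mx <- -Inf; mn <- Inf
  for (v in z) {
    s1 <- s1 + abs(v); s2 <- s2 + v^2; s3 <- s3 + v^3; s4 <- s4 + v^4
    if (v > mx) mx <- v
    if (v < mn) mn <- v
  }
  Sq <- sqrt(s2 / n)
  list(Sq = Sq, Sa = s1 / n, Ssk = (s3 / n) / Sq^3, Sku = (s4 / n) / Sq^4,
       Sp = mx, Sv = -mn, Sz = mx - mn)
}

# Abbott curve by explicit linear interpolation between descending order
# statistics mapped onto [0, 100]
oracle_curve <- function(surf, n = 1001L) {
  zs <- sort(as.vector(surf$heights), decreasing = TRUE)
  N <- length(zs)
  pg <- seq(0, 100, length.out = n)
  cg <- numeric(n)
  for (i in seq_len(n)) {
    pos <- pg[i] / 100 * (N - 1) + 1
    lo <- floor(pos); hi <- ceiling(pos)
    w <- pos - lo
    cg[i] <- (1 - w) * zs[lo] + w * zs[hi]
  }
  list(p = pg, c = cg)
}

oracle_trapz <- function(x, y) {
  s <- 0
  for (i in seq_len(length(x) - 1)) s <- s + (x[i + 1] - x[i]) *
      (y[i] + y[i + 1]) / 2
  s
}

oracle_volumes <- function(surf, p = 10, q = 80) {
  cv <- oracle_curve(surf)
  cr <- function(r) approx(cv$p, cv$c, xout = r)$y
  vm <- function(r) {
    keep <- cv$p <= r
    xs <- c(cv$p[keep], r); ys <- c(cv$c[keep], cr(r))
    (oracle_trapz(xs, ys) - r * cr(r)) / 100
  }
  vv <- function(r) {
    keep <- cv$p >= r
    xs <- c(r, cv$p[keep]); ys <- c(cr(r), cv$c[keep])
    (cr(r) * (100 - r) - oracle_trapz(xs, ys)) / 100
  }
  list(Vmp = max(0, vm(p)), Vmc = max(0, vm(q) - vm(p)),
       Vvc = max(0, vv(p) - vv(q)), Vvv = max(0, vv(q)))
}

oracle_core <- function(surf) {
  cv <- oracle_curve(surf)
  pg <- cv$p; cg <- cv$c
  n <- length(pg)
  step <- pg[2] - pg[1]
  w <- round(40 / step)
  best <- -Inf; besti <- NA
  for (i in seq_len(n - w)) {
    sl <- (cg[i + w] - cg[i]) / 40
    if (sl > best + 1e-15) { best <- sl; besti <- i }
  }
  win <- besti:(besti + w)
  # explicit least-squares line
  px <- pg[win]; py <- cg[win]
  b <- sum((px - mean(px)) * (py - mean(py))) / sum((px - mean(px))^2)
  a <- mean(py) - b * mean(px)
  y0 <- a; y100 <- a + 100 * b
  j1 <- which(cg <= y0)[1]
  Smr1 <- if (is.na(j1)) 100 else if (j1 == 1) 0 else
    pg[j1 - 1] + (cg[j1 - 1] - y0) / (cg[j1 - 1] - cg[j1]) * step
  ab <- which(cg >= y100)
  Smr2 <- if (!length(ab)) 0 else if (ab[length(ab)] == n) 100 else {
    j <- ab[length(ab)]
    pg[j] + (cg[j] - y100) / (cg[j] - cg[j + 1]) * step
  }
  Spk <- if (Smr1 <= step / 2) 0 else {
    keep <- pg <= Smr1
    xs <- c(pg[keep], Smr1)
    ys <- c(cg[keep], approx(pg, cg, xout = Smr1)$y)
    A1 <- (oracle_trapz(xs, ys) - Smr1 * y0) / 100
    max(0, 200 * A1 / Smr1)
  }
  Svk <- if (Smr2 >= 100 - step / 2) 0 else {
    keep <- pg >= Smr2
    xs <- c(Smr2, pg[keep])
    ys <- c(approx(pg, cg, xout = Smr2)$y, cg[keep])
    A2 <- (y100 * (100 - Smr2) - oracle_trapz(xs, ys)) / 100
    max(0, 200 * A2 / (100 - Smr2))
  }
  list(Sk = y0 - y100, Spk = Spk, Svk = Svk, Smr1 = Smr1, Smr2 = Smr2)
}

# circular autocorrelation by direct double loops over lags, then the same
# documented ray search as the engine (checks the FFT path of the ACF)
oracle_spatial <- function(surf, s = 0.2, n_theta = 360L) {
  z <- surf$heights - mean(surf$heights)
  nr <- nrow(z); nc <- ncol(z)
  R <- matrix(0, nr, nc)
  for (li in 0:(nr - 1)) for (lj in 0:(nc - 1)) {
    acc <- 0
    for (i in 1:nr) for (j in 1:nc) {
      ii <- (i - 1 + li) %% nr + 1
      jj <- (j - 1 + lj) %% nc + 1
      acc <- acc + z[i, j] * z[ii, jj]
    }
    R[li + 1, lj + 1] <- acc
  }
  R <- R / R[1, 1]
  iy <- c((floor(nr / 2) + 1):nr, 1:floor(nr / 2))
  ix <- c((floor(nc / 2) + 1):nc, 1:floor(nc / 2))
  ac <- list(R = R[iy, ix],
             tx = (seq_len(nc) - (ceiling(nc / 2) + 1)) * surf$dx,
             ty = (seq_len(nr) - (ceiling(nr / 2) + 1)) * surf$dy)
  dmta:::sal_str_from_acf(ac, s = s, n_theta = n_theta, dx = surf$dx,
                          dy = surf$dy)
}

oracle_hybrid <- function(surf) {
  z <- surf$heights
  nr <- nrow(z); nc <- ncol(z)
  sdq2 <- 0; sdr <- 0
  for (i in 1:nr) for (j in 1:nc) {
    jm <- max(1, j - 1); jp <- min(nc, j + 1)
    im <- max(1, i - 1); ip <- min(nr, i + 1)
    zx <- (z[i, jp] - z[i, jm]) / ((jp - jm) * surf$dx)
    zy <- (z[ip, j] - z[im, j]) / ((ip - im) * surf$dy)
    sdq2 <- sdq2 + zx^2 + zy^2
    sdr <- sdr + sqrt(1 + zx^2 + zy^2) - 1
  }
  list(Sdq = sqrt(sdq2 / (nr * nc)), Sdr = 100 * sdr / (nr * nc))
}

# prominence of one pixel by descending-threshold BFS connectivity
oracle_prominence_one <- function(z, pi, pj) {
  nr <- nrow(z); nc <- ncol(z)
  levels <- sort(unique(as.vector(z)), decreasing = TRUE)
  hp <- z[pi, pj]
  for (t in levels[levels <= hp]) {
    # connected component of {z >= t} containing (pi, pj), 8-connectivity
    inset <- z >= t
    seen <- matrix(FALSE, nr, nc)
    queue <- list(c(pi, pj))
    seen[pi, pj] <- TRUE
    found_higher <- FALSE
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      if (z[cur[1], cur[2]] > hp) { found_higher <- TRUE; break }
      for (di in -1:1) for (dj in -1:1) {
        ii <- cur[1] + di; jj <- cur[2] + dj
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
            !seen[ii, jj] && inset[ii, jj]) {
          seen[ii, jj] <- TRUE
          queue <- c(queue, list(c(ii, jj)))
        }
      }
    }
    if (found_higher) return(hp - t)
  }
  hp - min(z)  # global maximum: full relief
}

oracle_features <- function(surf, pruning = 5) {
  z <- surf$heights
  nr <- nrow(z); nc <- ncol(z)
  Sz <- max(z) - min(z)
  thr <- pruning / 100 * Sz
  area <- nr * surf$dy * nc * surf$dx
  find_kept <- function(zz) {
    kept <- list()
    for (i in 2:(nr - 1)) for (j in 2:(nc - 1)) {
      v <- zz[i, j]
      ismax <- TRUE
      for (di in -1:1) for (dj in -1:1)
        if ((di || dj) && zz[i + di, j + dj] >= v) ismax <- FALSE
      if (ismax && oracle_prominence_one(zz, i, j) >= thr)
        kept[[length(kept) + 1]] <- c(i, j, v)
    }
    kept
  }
  ks <- find_kept(z)
  kd <- find_kept(-z)
  Ssc <- if (length(ks)) mean(vapply(ks, function(s) {
    i <- s[1]; j <- s[2]
    zxx <- (z[i, j + 1] - 2 * z[i, j] + z[i, j - 1]) / surf$dx^2
    zyy <- (z[i + 1, j] - 2 * z[i, j] + z[i - 1, j]) / surf$dy^2
    -(zxx + zyy) / 2
  }, numeric(1))) else NaN
  tops <- sort(vapply(ks, `[`, numeric(1), 3), decreasing = TRUE)
  bots <- sort(vapply(kd, `[`, numeric(1), 3), decreasing = TRUE)
  top <- if (length(tops)) mean(tops[seq_len(min(5, length(tops)))]) else 0
  bot <- if (length(bots)) mean(bots[seq_len(min(5, length(bots)))]) else 0
  list(Sds = length(ks) / area, Ssc = Ssc, S5z = top + bot)
}

# relative comparison helper
rel_equal <- function(a, b, tol) {
  expect_true(all(abs(unlist(a) - unlist(b)) <=
                    tol * pmax(1, abs(unlist(b))), na.rm = TRUE),
              label = paste("relative agreement within", tol))
}
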