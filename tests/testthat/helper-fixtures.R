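# Fixture builders and independent oracles shared across the suite.
# All fixtures are built in code; nothing is read from disk.

make_rect_mask <- function(h, w, canvas = c(h + 4L, w + 4L), at = c(3L, 3L)) {
  m <- matrix(FALSE, canvas[1], canvas[2])
  m[at[1]:(at[1] + h - 1L), at[2]:(at[2] + w - 1L)] <- TRUE
  m
}

make_disc_mask <- function(radius, pad = 3L) {
  n <- 2L * radius + 1L + 2L * pad
  ctr <- radius + 1L + pad
  rr <- matrix(seq_len(n), n, n)
  cc <- t(rr)
  (rr - ctr)^2 + (cc - ctr)^2 <= radius^2
}

# 5-armed plus sign inside a 9x9 canvas (arms width 1)
make_plus_mask <- function() {
  m <- matrix(FALSE, 9, 9)
  m[5, 2:8] <- TRUE
  m[2:8, 5] <- TRUE
  m
}

make_L_mask <- function() {
  m <- matrix(FALSE, 12, 12)
  m[3:10, 3:4] <- TRUE
  m[9:10, 3:9] <- TRUE
  m
}

random_mask <- function(h, w, p = 0.25) {
  m <- matrix(stats::runif(h * w) < p, h, w)
  if (!any(m)) m[sample(h * w, 1L)] <- TRUE
  m
}

# Uniform color image fixture: H x W x 3 array of one RGB color.
uniform_rgb <- function(col, h = 8L, w = 8L) {
  arr <- array(0, dim = c(h, w, 3))
  arr[, , 1] <- col[1]; arr[, , 2] <- col[2]; arr[, , 3] <- col[3]
  arr
}

# --- Independent oracles ------------------------------------------------

# Brute-force convex hull area over the pixel-corner points: O(n^3) edge
# test (an ordered pair (i, j) is a hull edge iff every other point lies on
# its left), vectorized over the inner two loops. Entirely independent of
# the monotone-chain implementation.
brute_hull_area <- function(mask) {
  rc <- which(mask, arr.ind = TRUE)
  r <- rc[, 1]; cc <- rc[, 2]
  pts <- unique(cbind(
    x = c(cc - 0.5, cc + 0.5, cc - 0.5, cc + 0.5),
    y = c(r - 0.5, r - 0.5, r + 0.5, r + 0.5)
  ))
  n <- nrow(pts)
  if (n < 3L) return(0)
  x <- pts[, 1]; y <- pts[, 2]
  eps <- 1e-12
  on_hull <- rep(FALSE, n)
  for (i in seq_len(n)) {
    dx <- x - x[i]; dy <- y - y[i]
    # cross[j, k] = cross product of (i->j) x (i->k)
    cross <- outer(dx, dy) - outer(dy, dx)
    ok <- rowSums(cross < -eps) == 0L # every k on the left of (i -> j)
    ok[i] <- FALSE
    if (any(ok)) {
      on_hull[i] <- TRUE
      on_hull[ok] <- TRUE
    }
  }
  hp <- pts[on_hull, , drop = FALSE]
  ctr <- colMeans(hp)
  ord <- order(atan2(hp[, 2] - ctr[2], hp[, 1] - ctr[1]))
  hp <- hp[ord, , drop = FALSE]
  xx <- hp[, 1]; yy <- hp[, 2]
  abs(sum(xx * c(yy[-1], yy[1]) - c(xx[-1], xx[1]) * yy)) / 2
}

# Full-scan bounding-box oracle.
scan_extent <- function(mask) {
  rmin <- Inf; rmax <- -Inf; cmin <- Inf; cmax <- -Inf
  for (i in seq_len(nrow(mask))) {
    for (j in seq_len(ncol(mask))) {
      if (mask[i, j]) {
        rmin <- min(rmin, i); rmax <- max(rmax, i)
        cmin <- min(cmin, j); cmax <- max(cmax, j)
      }
    }
  }
  c(x_px = cmax - cmin + 1, y_px = rmax - rmin + 1)
}

# Textbook direct-sum Pearson correlation.
direct_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# Shared small cohort used by the end-to-end tests: generated once per
# test run, reused across files via the test environment.
cohort_dir_cached <- local({
  dir <- NULL
  function() {
    if (is.null(dir) || !file.exists(file.path(dir, "manifest.csv"))) {
      dir <<- file.path(tempdir(), "ricepheno_e2e_cohort")
      unlink(dir, recursive = TRUE)
      generate_cohort(3, 3, days = 8, rng_seed = 42, out_dir = dir)
    }
    dir
  }
})
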