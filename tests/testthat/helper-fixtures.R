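# Shared fixtures, built in code.

# A small, hand-checkable set of rumen proximate records.
toy_records <- function() {
  data.frame(
    sample_id = c("A", "B", "C"),
    ash = c(5, 6, 4),
    total_n = c(3.2, 2.0, 1.0),
    adf_n = c(0, 0.4, 1.0),
    ndf = c(50, 46, 60),
    adf = c(30, 30, 40),
    lignin = c(10, 12, 15),
    purine_marker = c(0.5, 1.0, 0),
    stringsAsFactors = FALSE)
}

# Closed-form OLS, independent of lm(): the oracle for regression wrappers.
ols_by_hand <- function(y, x) {
  n <- length(x)
  xc <- x - mean(x); yc <- y - mean(y)
  slope <- sum(xc * yc) / sum(xc^2)
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  se <- sqrt(sum(resid^2) / (n - 2) / sum(xc^2))
  list(slope = slope, intercept = intercept, se = se,
       r_squared = 1 - sum(resid^2) / sum(yc^2))
}

# O(n^3) hull-area oracle: finds hull points by exhaustive edge testing
# (an edge is on the hull iff every other point lies on one side), then
# applies the shoelace formula after an angular sort.
hull_area_brute <- function(x, y) {
  n <- length(x)
  pts <- unique(data.frame(x = x, y = y))
  n <- nrow(pts)
  if (n < 3) return(0)
  on_hull <- rep(FALSE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      cr <- (pts$x[j] - pts$x[i]) * (pts$y - pts$y[i]) -
        (pts$y[j] - pts$y[i]) * (pts$x - pts$x[i])
      if (all(cr <= 1e-12)) { on_hull[i] <- on_hull[j] <- TRUE }
    }
  }
  h <- pts[on_hull, ]
  if (nrow(h) < 3) return(0)
  cx <- mean(h$x); cy <- mean(h$y)
  h <- h[order(atan2(h$y - cy, h$x - cx)), ]
  k <- nrow(h); j <- c(2:k, 1)
  abs(sum(h$x * h$y[j] - h$x[j] * h$y)) / 2
}

# Independent PCA variance-fraction oracle: eigenvalues of the correlation
# matrix (prcomp-free route).
run_pca_reference <- function(df) {
  ev <- eigen(cor(as.matrix(df)), symmetric = TRUE)$values
  ev / sum(ev)
}

expect_closure <- function(profiles, tol = 1e-9) {
  s <- profiles$ap + profiles$cellulose + profiles$hemicellulose +
    profiles$lignin + profiles$ash + profiles$tnc2_lipids
  expect_true(all(abs(s - 100) < tol))
}
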