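# Shared fixtures and independent oracles for the test suite.

round_half_up <- seminomiR:::round_half_up

# small reference reused across read-processing tests
tiny_reference <- function() generate_reference(20, 5, seed = 301)

# hand-built reference with fully controlled sequences (annotation tests)
manual_reference <- function(ids, classes, seqs) {
  data.frame(feature_id = ids, class = classes, sequence = seqs,
             stringsAsFactors = FALSE)
}

# --- independent brute-force oracle for strict 2-D linear separability ----
# A strictly separating line, if one exists, can be chosen parallel to a
# line through two points of the merged set; enumerating those directions
# (perturbed both ways to break ties) and testing strict projection
# separation decides every instance.
brute_force_separable <- function(points, labels) {
  pts <- as.matrix(points)
  lv <- unique(labels)
  A <- pts[labels == lv[1], , drop = FALSE]
  B <- pts[labels == lv[2], , drop = FALSE]
  n <- nrow(pts)
  prs <- utils::combn(n, 2)
  d <- t(pts[prs[2, ], , drop = FALSE] - pts[prs[1, ], , drop = FALSE])
  keep <- colSums(d != 0) > 0
  normals <- rbind(-d[2, keep], d[1, keep])
  normals <- cbind(normals, c(1, 0), c(0, 1))
  for (eps in c(-1e-7, 0, 1e-7)) {
    rot <- matrix(c(cos(eps), sin(eps), -sin(eps), cos(eps)), 2, 2)
    w <- rot %*% normals
    pa <- A %*% w
    pb <- B %*% w
    sep <- (apply(pa, 2, max) < apply(pb, 2, min)) |
           (apply(pb, 2, max) < apply(pa, 2, min))
    if (any(sep)) return(TRUE)
  }
  FALSE
}

# random labeled 15-point instances, mixing separable and non-separable
# geometries (cluster shift of random magnitude)
random_instance <- function(seed) {
  set.seed(seed)
  n1 <- sample(3:12, 1)
  n2 <- 15 - n1
  shift <- runif(1, 0, 4)
  ang <- runif(1, 0, 2 * pi)
  pts <- rbind(matrix(rnorm(2 * n1), ncol = 2),
               matrix(rnorm(2 * n2), ncol = 2) +
                 rep(shift * c(cos(ang), sin(ang)), each = n2))
  list(points = pts, labels = rep(0:1, c(n1, n2)))
}

# --- independent penalized log-likelihood (Firth) for the grid oracle ----
# written from the definition, separately from the package's fitting code
oracle_penalized_loglik <- function(b0, b1, x, y) {
  eta <- b0 + b1 * x
  p <- 1 / (1 + exp(-eta))
  w <- p * (1 - p)
  X <- cbind(1, x)
  info <- t(X) %*% (X * w)
  dt <- det(info)
  if (dt <= 0) return(-Inf)
  sum(y * log(p) + (1 - y) * log(1 - p)) + 0.5 * log(dt)
}

# three-stage dense grid maximization of the penalized log-likelihood
oracle_grid_fit <- function(x, y) {
  b0r <- c(-15, 5); b1r <- c(-1, 5)
  for (step in c(0.1, 0.005, 0.00025)) {
    b0s <- seq(b0r[1], b0r[2], by = step)
    b1s <- seq(b1r[1], b1r[2], by = step)
    best <- c(-Inf, NA, NA)
    for (b1 in b1s) {
      pls <- vapply(b0s, oracle_penalized_loglik, numeric(1), b1 = b1,
                    x = x, y = y)
      i <- which.max(pls)
      if (pls[i] > best[1]) best <- c(pls[i], b0s[i], b1)
    }
    b0r <- best[2] + c(-2, 2) * step
    b1r <- best[3] + c(-2, 2) * step
  }
  list(pl = best[1], b0 = best[2], b1 = best[3])
}
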