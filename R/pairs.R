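#' Exact 2-D linear separability of two labeled point sets
#'
#' Decides, by convex-hull geometry rather than by an iterative classifier,
#' whether a straight line separates the two classes in the plane.  With
#' `strict = TRUE` (the default, and the notion of "complete separation"
#' used throughout the package) the line may touch no point: the classes
#' are strictly separable iff their convex hulls are disjoint, i.e. the
#' hull-to-hull distance is positive and neither hull contains the other.
#' With `strict = FALSE` points may lie on the separating line, which is
#' decided by enumerating candidate directions normal to lines through
#' point pairs.
#'
#' @param points Two-column numeric matrix of coordinates.
#' @param labels Binary labels (two levels), one per point; both classes
#'   must be non-empty.
#' @param strict Require strict separation (no point on the line)?
#' @return Logical scalar.  When strictly separable, the attribute
#'   `"margin"` carries the distance between the two convex hulls (the
#'   widest empty band between the classes).
#' @export
#' @examples
#' xor <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
#' separable_exact_2d(xor, c(0, 0, 1, 1))  # FALSE
separable_exact_2d <- function(points, labels, strict = TRUE) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2, nrow(points) == length(labels))
  lv <- unique(labels)
  if (length(lv) != 2) stopf("need exactly two classes, both non-empty")
  A <- points[labels == lv[1], , drop = FALSE]
  B <- points[labels == lv[2], , drop = FALSE]

  if (!strict) return(weakly_separable_2d(A, B))

  ha <- convex_hull(A)
  hb <- convex_hull(B)
  d <- hull_distance(ha, hb)
  if (d <= 0) return(FALSE)
  # positive boundary distance still allows full containment
  if (point_in_hull(ha[1, ], hb) || point_in_hull(hb[1, ], ha))
    return(FALSE)
  structure(TRUE, margin = d)
}

# Andrew's monotone chain; returns hull vertices in CCW order (1 or 2 rows
# for degenerate inputs)
convex_hull <- function(pts) {
  pts <- unique(pts[order(pts[, 1], pts[, 2]), , drop = FALSE])
  n <- nrow(pts)
  if (n <= 2) return(pts)
  cross <- function(o, a, b)
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  build <- function(idx) {
    h <- integer(0)
    for (i in idx) {
      while (length(h) >= 2 &&
             cross(pts[h[length(h) - 1], ], pts[h[length(h)], ],
                   pts[i, ]) <= 0)
        h <- h[-length(h)]
      h <- c(h, i)
    }
    h
  }
  lower <- build(1:n)
  upper <- build(n:1)
  pts[c(lower[-length(lower)], upper[-length(upper)]), , drop = FALSE]
}

# TRUE iff p lies inside or on the boundary of convex hull h (CCW)
point_in_hull <- function(p, h) {
  n <- nrow(h)
  if (n == 1) return(all(p == h[1, ]))
  if (n == 2) {
    d <- h[2, ] - h[1, ]
    cr <- d[1] * (p[2] - h[1, 2]) - d[2] * (p[1] - h[1, 1])
    if (cr != 0) return(FALSE)
    t <- if (abs(d[1]) >= abs(d[2])) (p[1] - h[1, 1]) / d[1]
         else (p[2] - h[1, 2]) / d[2]
    return(t >= 0 && t <= 1)
  }
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    d <- h[j, ] - h[i, ]
    if (d[1] * (p[2] - h[i, 2]) - d[2] * (p[1] - h[i, 1]) < 0) return(FALSE)
  }
  TRUE
}

hull_edges <- function(h) {
  n <- nrow(h)
  if (n == 1) return(list(list(h[1, ], h[1, ])))
  lapply(seq_len(n), function(i) {
    j <- if (i == n) 1L else i + 1L
    list(h[i, ], h[j, ])
  })
}

# minimum distance between two segments (standard clamped projection)
segment_distance <- function(p1, p2, q1, q2) {
  pt_seg <- function(p, a, b) {
    d <- b - a
    L2 <- sum(d^2)
    t <- if (L2 == 0) 0 else max(0, min(1, sum((p - a) * d) / L2))
    sqrt(sum((p - (a + t * d))^2))
  }
  if (segments_intersect(p1, p2, q1, q2)) return(0)
  min(pt_seg(p1, q1, q2), pt_seg(p2, q1, q2),
      pt_seg(q1, p1, p2), pt_seg(q2, p1, p2))
}

segments_intersect <- function(p1, p2, q1, q2) {
  o <- function(a, b, c)
    sign((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
  on_seg <- function(a, b, c)  # c collinear with a-b: is c within the box?
    min(a[1], b[1]) <= c[1] && c[1] <= max(a[1], b[1]) &&
    min(a[2], b[2]) <= c[2] && c[2] <= max(a[2], b[2])
  o1 <- o(p1, p2, q1); o2 <- o(p1, p2, q2)
  o3 <- o(q1, q2, p1); o4 <- o(q1, q2, p2)
  if (o1 != o2 && o3 != o4) return(TRUE)
  (o1 == 0 && on_seg(p1, p2, q1)) || (o2 == 0 && on_seg(p1, p2, q2)) ||
  (o3 == 0 && on_seg(q1, q2, p1)) || (o4 == 0 && on_seg(q1, q2, p2))
}

hull_distance <- function(ha, hb) {
  ea <- hull_edges(ha)
  eb <- hull_edges(hb)
  min(vapply(ea, function(sa)
    min(vapply(eb, function(sb)
      segment_distance(sa[[1]], sa[[2]], sb[[1]], sb[[2]]), numeric(1))),
    numeric(1)))
}

# non-strict separation: some direction puts max proj(A) <= min proj(B) or
# vice versa; it suffices to test normals of lines through point pairs
# (plus axis directions for degenerate cases)
weakly_separable_2d <- function(A, B) {
  pts <- rbind(A, B)
  n <- nrow(pts)
  dirs <- list(c(1, 0), c(0, 1))
  if (n >= 2) {
    prs <- combn(n, 2)
    for (k in seq_len(ncol(prs))) {
      d <- pts[prs[2, k], ] - pts[prs[1, k], ]
      if (any(d != 0)) dirs[[length(dirs) + 1]] <- c(-d[2], d[1])
    }
  }
  for (w in dirs) {
    pa <- A %*% w; pb <- B %*% w
    if (max(pa) <= min(pb) || max(pb) <= min(pa)) return(TRUE)
  }
  FALSE
}

#' Linear SVM check for complete training-set separation
#'
#' Fits a soft-margin linear support vector machine with a large cost
#' penalty on standardized coordinates and reports whether the training
#' accuracy is 100%.  This is the classifier-based route to the
#' "complete separation" criterion and serves as a cross-check of
#' [separable_exact_2d()]; at large cost the soft margin approximates the
#' hard-margin SVM, which classifies all training points correctly iff the
#' classes are linearly separable.  Emulating a hard margin requires a
#' penalty on the order of the inverse squared margin, so when the fit at
#' `cost` leaves training errors the check escalates the penalty (up to
#' `cost` times 10^6) before declaring the classes non-separable; this
#' rescues near-degenerate instances whose margin is tiny on the
#' standardized scale.
#'
#' @inheritParams separable_exact_2d
#' @param cost Initial SVM cost penalty (default 1e6).
#' @param escalate Escalate the cost when training errors remain?
#'   (default `TRUE`).
#' @return Logical scalar.
#' @export
separable_svm <- function(points, labels, cost = 1e6, escalate = TRUE) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2, nrow(points) == length(labels))
  if (length(unique(labels)) != 2)
    stopf("need exactly two classes, both non-empty")
  # standardize by hand so zero-variance coordinates don't error
  for (j in 1:2) {
    s <- sd(points[, j])
    points[, j] <- if (s > 0) (points[, j] - mean(points[, j])) / s
                   else points[, j] - mean(points[, j])
  }
  y <- factor(labels)
  costs <- if (escalate) cost * c(1, 1e6) else cost
  for (cc in costs) {
    fit <- tryCatch(
      e1071::svm(points, y, type = "C-classification", kernel = "linear",
                 cost = cc, scale = FALSE),
      error = function(e) NULL)
    if (is.null(fit)) return(FALSE)
    if (all(stats::predict(fit, points) == y)) return(TRUE)
  }
  FALSE
}

#' Exhaustively evaluate candidate pairs for complete separation
#'
#' Evaluates every unordered pair of candidate small RNAs once: the two
#' features' `log2(CPM + 1)` values over the comparison's samples form a
#' 2-D point set labeled reference vs target, and the pair is flagged
#' separable iff a line strictly separates the classes.  The decision is
#' made by the exact geometric test ([separable_exact_2d()]); the linear
#' SVM ([separable_svm()]) is run alongside as a cross-check and any
#' disagreement is recorded.
#'
#' @param cpm CPM-normalized expression matrix (features x samples), as
#'   from [normalize_cpm()].
#' @param candidates Character vector of feature ids to pair (>= 2).
#' @param metadata Data.frame with `sample_id` and `group`.
#' @param target `"lymphogen"`, `"occult"` or `"combined"`.
#' @param svm_check Also run the SVM cross-check on every pair?
#' @param cost SVM cost for the cross-check.
#' @return Data.frame of class `"srna_pairs"` with one row per pair:
#'   `small_rna_1`, `small_rna_2` (lexicographically ordered within and
#'   across rows), `separable`, `margin` (`NA` unless separable) and, if
#'   `svm_check`, `svm_separable`.  Attributes: `comparison`,
#'   `n_separating`, `svm_disagreements`.
#' @export
enumerate_separating_pairs <- function(cpm, candidates, metadata, target,
                                       svm_check = TRUE, cost = 1e6) {
  cpm <- as.matrix(cpm)
  candidates <- sort(unique(as.character(candidates)), method = "radix")
  if (length(candidates) < 2) stopf("need at least 2 candidate ids")
  miss <- setdiff(candidates, rownames(cpm))
  if (length(miss))
    stopf("candidate id(s) absent from matrix: %s", paste(miss, collapse = ", "))
  cs <- comparison_samples(metadata, target)
  sel <- c(cs$ref, cs$target)
  y <- rep(c(0, 1), c(length(cs$ref), length(cs$target)))
  X <- log2(cpm[candidates, sel, drop = FALSE] + 1)

  prs <- combn(length(candidates), 2)
  n_pairs <- ncol(prs)
  sep <- logical(n_pairs)
  svm_sep <- rep(NA, n_pairs)
  margin <- rep(NA_real_, n_pairs)
  for (k in seq_len(n_pairs)) {
    pts <- t(X[c(prs[1, k], prs[2, k]), , drop = FALSE])
    res <- separable_exact_2d(pts, y, strict = TRUE)
    sep[k] <- as.logical(res)
    if (sep[k]) margin[k] <- attr(res, "margin")
    if (svm_check) svm_sep[k] <- separable_svm(pts, y, cost = cost)
  }
  out <- data.frame(small_rna_1 = candidates[prs[1, ]],
                    small_rna_2 = candidates[prs[2, ]],
                    separable = sep, margin = margin,
                    stringsAsFactors = FALSE)
  if (svm_check) out$svm_separable <- svm_sep
  structure(out, class = c("srna_pairs", "data.frame"),
            comparison = target, n_separating = sum(sep),
            svm_disagreements = if (svm_check) sum(sep != svm_sep) else NA_integer_)
}
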