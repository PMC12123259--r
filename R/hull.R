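#' Exact convex-hull volume in arbitrary dimension
#'
#' Computes the volume of the convex hull of a point cloud: the range
#' `max - min` in one dimension, and the exact hull (hyper)volume from an
#' incremental (beneath-beyond) facet construction in two or more
#' dimensions. Point sets that are affinely dependent (fewer than m + 1
#' points, or all points on a lower-dimensional flat) have volume 0 and are
#' flagged degenerate.
#'
#' @param points Numeric matrix, one row per point, one column per axis.
#' @return Non-negative volume with a logical attribute `"degenerate"`.
#' @export
#' @examples
#' sq <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
#' hull_volume(sq) # 1
hull_volume <- function(points) {
  P <- as.matrix(points)
  storage.mode(P) <- "double"
  n <- nrow(P)
  d <- ncol(P)
  if (n == 0 || d == 0 || n < 2) {
    return(structure(0, degenerate = TRUE))
  }
  if (d == 1) {
    v <- diff(range(P[, 1]))
    return(structure(v, degenerate = v <= 0))
  }
  centered <- sweep(P, 2, colMeans(P))
  sv <- svd(centered, nu = 0, nv = 0)$d
  rank_tol <- max(n, d) * .Machine$double.eps * max(sv, 0)
  if (n < d + 1 || sum(sv > rank_tol) < d) {
    return(structure(0, degenerate = TRUE))
  }
  structure(.hull_volume_dD(P), degenerate = FALSE)
}

# Incremental (beneath-beyond) hull. Facets are d-vertex simplices with an
# outward normal; a point outside the current hull replaces its visible
# facets with the cone from the horizon ridges. The hull volume is the sum
# of simplex volumes from an interior point to each facet.
.hull_volume_dD <- function(P) {
  n <- nrow(P)
  d <- ncol(P)
  tol <- 1e-9 * max(1, max(abs(P)))

  idx <- .initial_simplex(P)
  interior <- colMeans(P[idx, , drop = FALSE])

  new_facet <- function(v) {
    V <- P[v, , drop = FALSE]
    M <- sweep(V[-1, , drop = FALSE], 2, V[1, ])
    a <- svd(M, nu = 0, nv = d)$v[, d]
    b <- sum(a * V[1, ])
    if (sum(a * interior) > b) {
      a <- -a
      b <- -b
    }
    list(v = sort(v), a = a, b = b)
  }

  facets <- apply(utils::combn(idx, d), 2, new_facet, simplify = FALSE)

  for (p in setdiff(seq_len(n), idx)) {
    x <- P[p, ]
    vis <- which(vapply(facets, function(f) sum(f$a * x) > f$b + tol,
                        logical(1)))
    if (length(vis) == 0) next
    # a ridge (facet minus one vertex) lies in exactly two hull facets;
    # ridges seen once among the visible facets are the horizon
    ridges <- unlist(lapply(vis, function(i) {
      v <- facets[[i]]$v
      vapply(seq_len(d), function(k) paste(v[-k], collapse = "_"),
             character(1))
    }))
    horizon <- names(which(table(ridges) == 1L))
    facets <- facets[-vis]
    for (r in horizon) {
      rv <- as.integer(strsplit(r, "_", fixed = TRUE)[[1]])
      facets[[length(facets) + 1L]] <- new_facet(c(rv, p))
    }
  }

  vol <- 0
  for (f in facets) {
    S <- sweep(P[f$v, , drop = FALSE], 2, interior)
    vol <- vol + abs(det(S))
  }
  vol / factorial(d)
}

# d + 1 affinely independent rows chosen greedily: start from an extreme
# point, repeatedly add the point farthest from the affine span so far.
.initial_simplex <- function(P) {
  n <- nrow(P)
  d <- ncol(P)
  idx <- which.min(P[, 1])
  for (k in seq_len(d)) {
    base <- P[idx[1], ]
    V <- sweep(P, 2, base)
    if (length(idx) == 1) {
      dists <- sqrt(rowSums(V^2))
    } else {
      span <- sweep(P[idx[-1], , drop = FALSE], 2, base)
      Q <- qr.Q(qr(t(span)))
      proj <- V %*% Q %*% t(Q)
      dists <- sqrt(rowSums((V - proj)^2))
    }
    dists[idx] <- -1
    idx <- c(idx, which.max(dists))
  }
  idx
}
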