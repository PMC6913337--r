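# Incremental 3D convex hull, used for the Solidity shape feature and the
# maximum-diameter computation. Input sizes here are surface-voxel corner
# clouds (hundreds to a few thousand points), for which the O(n * faces)
# incremental construction is comfortably fast in R.

hull3d <- function(pts) {
  pts <- unique(as.matrix(pts))
  n <- nrow(pts)
  if (n < 4) return(NULL)
  scale <- max(apply(pts, 2, function(v) diff(range(v))), 1e-12)
  eps <- 1e-9 * scale^2
  # initial simplex: extreme point, farthest point, farthest from the line,
  # farthest from the plane
  i1 <- which.min(pts[, 1] * 1e6 + pts[, 2] * 1e3 + pts[, 3])
  d1 <- rowSums(sweep(pts, 2, pts[i1, ])^2)
  i2 <- which.max(d1)
  if (d1[i2] < eps) return(NULL)
  v12 <- pts[i2, ] - pts[i1, ]
  rel <- sweep(pts, 2, pts[i1, ])
  cr <- cbind(rel[, 2] * v12[3] - rel[, 3] * v12[2],
              rel[, 3] * v12[1] - rel[, 1] * v12[3],
              rel[, 1] * v12[2] - rel[, 2] * v12[1])
  d2 <- rowSums(cr^2)
  i3 <- which.max(d2)
  if (d2[i3] < eps^2) return(NULL)
  nrm <- c(v12[2] * (pts[i3, 3] - pts[i1, 3]) - v12[3] * (pts[i3, 2] - pts[i1, 2]),
           v12[3] * (pts[i3, 1] - pts[i1, 1]) - v12[1] * (pts[i3, 3] - pts[i1, 3]),
           v12[1] * (pts[i3, 2] - pts[i1, 2]) - v12[2] * (pts[i3, 1] - pts[i1, 1]))
  d3 <- abs(rel %*% nrm)
  i4 <- which.max(d3)
  if (d3[i4] < eps * scale) return(NULL) # coplanar cloud: degenerate hull
  interior <- colMeans(pts[c(i1, i2, i3, i4), ])
  faces <- rbind(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  orient <- function(f) {
    a <- pts[f[1], ]; b <- pts[f[2], ]; cc <- pts[f[3], ]
    nn <- c((b[2] - a[2]) * (cc[3] - a[3]) - (b[3] - a[3]) * (cc[2] - a[2]),
            (b[3] - a[3]) * (cc[1] - a[1]) - (b[1] - a[1]) * (cc[3] - a[3]),
            (b[1] - a[1]) * (cc[2] - a[2]) - (b[2] - a[2]) * (cc[1] - a[1]))
    if (sum(nn * (interior - a)) > 0) f[c(1, 3, 2)] else f
  }
  faces <- t(apply(faces, 1, orient))
  face_normal <- function(f) {
    a <- pts[f[1], ]; b <- pts[f[2], ]; cc <- pts[f[3], ]
    c((b[2] - a[2]) * (cc[3] - a[3]) - (b[3] - a[3]) * (cc[2] - a[2]),
      (b[3] - a[3]) * (cc[1] - a[1]) - (b[1] - a[1]) * (cc[3] - a[3]),
      (b[1] - a[1]) * (cc[2] - a[2]) - (b[2] - a[2]) * (cc[1] - a[1]))
  }
  normals <- t(apply(faces, 1, face_normal))
  offsets <- rowSums(normals * pts[faces[, 1], , drop = FALSE])
  rest <- setdiff(seq_len(n), c(i1, i2, i3, i4))
  for (p in rest) {
    vis <- (normals %*% pts[p, ] - offsets) > eps * scale
    if (!any(vis)) next
    visf <- faces[vis, , drop = FALSE]
    edges <- rbind(visf[, 1:2], visf[, 2:3], visf[, c(3, 1)])
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    horizon <- edges[key %in% names(which(table(key) == 1)), , drop = FALSE]
    faces <- faces[!vis, , drop = FALSE]
    normals <- normals[!vis, , drop = FALSE]
    offsets <- offsets[!vis]
    if (nrow(horizon) > 0) {
      newf <- cbind(horizon, p)
      newf <- t(apply(newf, 1, orient))
      newn <- t(apply(newf, 1, face_normal))
      faces <- rbind(faces, newf)
      normals <- rbind(normals, newn)
      offsets <- c(offsets, rowSums(newn * pts[newf[, 1], , drop = FALSE]))
    }
  }
  list(points = pts, faces = faces)
}

# Volume enclosed by a (consistently outward-oriented) triangulated hull.
hull3d_volume <- function(hull) {
  if (is.null(hull)) return(0)
  pts <- hull$points
  f <- hull$faces
  v <- 0
  for (r in seq_len(nrow(f))) {
    a <- pts[f[r, 1], ]; b <- pts[f[r, 2], ]; cc <- pts[f[r, 3], ]
    v <- v + (a[1] * (b[2] * cc[3] - b[3] * cc[2]) -
              a[2] * (b[1] * cc[3] - b[3] * cc[1]) +
              a[3] * (b[1] * cc[2] - b[2] * cc[1])) / 6
  }
  abs(v)
}
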