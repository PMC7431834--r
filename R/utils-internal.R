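# Internal voxel-grid utilities shared by segmentation, tracking and the
# simulator. All take plain base-R arrays; dimension order is (x, y, z).

# Half-neighbourhood offsets for a given connectivity. Only "forward"
# (lexicographically positive) offsets are returned, so each undirected
# voxel adjacency is enumerated once.
half_offsets <- function(connectivity, ndim) {
  if (ndim == 2L) {
    if (!connectivity %in% c(4L, 8L))
      stop("2D connectivity must be 4 or 8", call. = FALSE)
    full <- as.matrix(expand.grid(dx = -1:1, dy = -1:1))
    full <- cbind(full, dz = 0L)
    ord <- if (connectivity == 4L) 1L else 2L
  } else {
    if (!connectivity %in% c(6L, 18L, 26L))
      stop("3D connectivity must be 6, 18 or 26", call. = FALSE)
    full <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
    ord <- switch(as.character(connectivity), "6" = 1L, "18" = 2L, "26" = 3L)
  }
  l1 <- rowSums(abs(full))
  keep <- l1 > 0 & l1 <= ord
  # forward = first nonzero coordinate positive
  fwd <- apply(full, 1L, function(o) {
    nz <- which(o != 0L)[1L]
    !is.na(nz) && o[nz] > 0L
  })
  full[keep & fwd, , drop = FALSE]
}

# Edge list (pairs of linear indices) between foreground voxels under the
# given connectivity. `mask` is a logical array (2D or 3D).
mask_edges <- function(mask, connectivity) {
  d <- dim(mask)
  ndim <- length(d)
  if (ndim == 2L) {
    d3 <- c(d, 1L)
    dim(mask) <- d3
  } else d3 <- d
  offs <- half_offsets(connectivity, ndim)
  lin <- array(seq_len(prod(d3)), dim = d3)
  from <- integer(0); to <- integer(0)
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    sx <- seq_len(d3[1] - abs(o[1])); sy <- seq_len(d3[2] - abs(o[2]))
    sz <- seq_len(d3[3] - abs(o[3]))
    src <- lin[sx + max(0L, -o[1]), sy + max(0L, -o[2]), sz + max(0L, -o[3]),
               drop = FALSE]
    dst <- lin[sx + max(0L, o[1]), sy + max(0L, o[2]), sz + max(0L, o[3]),
               drop = FALSE]
    both <- mask[src] & mask[dst]
    from <- c(from, src[both])
    to <- c(to, dst[both])
  }
  cbind(from, to)
}

# Connected-component labeling of a logical array. Returns an integer array
# with labels 1..K (0 = background), components numbered in raster order of
# their first voxel.
label_components <- function(mask, connectivity = if (length(dim(mask)) == 2L) 8L else 26L) {
  storage.mode(mask) <- "logical"
  fg <- which(mask)
  lab <- array(0L, dim = dim(mask))
  if (length(fg) == 0L) return(lab)
  ed <- mask_edges(mask, connectivity)
  vid <- integer(length(mask))
  vid[fg] <- seq_along(fg)
  g <- igraph::make_graph(t(cbind(vid[ed[, 1]], vid[ed[, 2]])),
                          n = length(fg), directed = FALSE)
  comp <- igraph::components(g)$membership
  # relabel so that component ids follow raster order of first occurrence
  first <- match(unique(comp), comp)
  relab <- integer(max(comp))
  relab[comp[sort(first)]] <- seq_along(first)
  lab[fg] <- relab[comp]
  lab
}

# Separable Gaussian blur with a truncated (3 sigma) kernel; rows are
# renormalized so a flat field is preserved near the boundary.
gaussian_blur <- function(x, sigma_um, voxel_size) {
  d <- dim(x)
  for (ax in seq_along(d)) {
    s <- sigma_um / voxel_size[ax]
    if (s <= 0) next
    n <- d[ax]
    rad <- max(1L, ceiling(3 * s))
    idx <- outer(seq_len(n), seq_len(n), "-")
    K <- exp(-(idx^2) / (2 * s^2))
    K[abs(idx) > rad] <- 0
    K <- K / rowSums(K)
    perm <- c(ax, setdiff(seq_along(d), ax))
    xp <- aperm(x, perm)
    dp <- dim(xp)
    xp <- K %*% matrix(xp, nrow = n)
    dim(xp) <- dp
    x <- aperm(xp, order(perm))
  }
  x
}

# Global Otsu threshold of an intensity array, on the original scale.
otsu_threshold <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  xn <- matrix((as.numeric(x) - rng[1]) / diff(rng), ncol = 1L)
  rng[1] + EBImage::otsu(xn, range = c(0, 1)) * diff(rng)
}

# --- 2D point-set geometry (pixel centres) ------------------------------

# Convex hull points (closed = FALSE), as an n x 2 matrix.
hull_points <- function(pts) {
  if (nrow(pts) == 1L) return(pts)
  h <- grDevices::chull(pts)
  pts[h, , drop = FALSE]
}

# Maximum Feret diameter (max pairwise distance over hull points).
max_feret <- function(pts) {
  h <- hull_points(pts)
  if (nrow(h) == 1L) return(0)
  max(stats::dist(h))
}

# Minimum Feret diameter: smallest projection width over hull edge normals.
min_feret <- function(pts) {
  h <- hull_points(pts)
  n <- nrow(h)
  if (n <= 1L) return(0)
  if (n == 2L) return(0)
  e <- h[c(2:n, 1L), ] - h
  len <- sqrt(rowSums(e^2))
  keep <- len > 0
  e <- e[keep, , drop = FALSE] / len[keep]
  widths <- vapply(seq_len(nrow(e)), function(i) {
    nrm <- c(-e[i, 2], e[i, 1])
    p <- h %*% nrm
    max(p) - min(p)
  }, numeric(1))
  min(widths)
}

# Minimum-area rotated bounding rectangle; returns sorted side lengths
# (long, short). Degenerate (collinear) sets return a zero short side.
min_area_rect <- function(pts) {
  h <- hull_points(pts)
  n <- nrow(h)
  if (n == 1L) return(c(0, 0))
  if (n == 2L) return(c(sqrt(sum((h[2, ] - h[1, ])^2)), 0))
  e <- h[c(2:n, 1L), ] - h
  len <- sqrt(rowSums(e^2))
  keep <- len > 0
  e <- e[keep, , drop = FALSE] / len[keep]
  best <- c(Inf, Inf); best_area <- Inf
  for (i in seq_len(nrow(e))) {
    u <- e[i, ]; v <- c(-u[2], u[1])
    pu <- h %*% u; pv <- h %*% v
    w <- max(pu) - min(pu); ht <- max(pv) - min(pv)
    if (w * ht < best_area) {
      best_area <- w * ht
      best <- sort(c(w, ht), decreasing = TRUE)
    }
  }
  best
}
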