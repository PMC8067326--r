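# Simplicial discretizations of the model domains: 2D disk/ellipse and 3D
# sphere/ellipsoid, with calcium-phosphate granules meshed as interior holes.
# Meshes are built on a background grid: simplices fully inside the shape (and
# outside every granule) are kept, boundary nodes are snapped onto the analytic
# surface (with an element-inversion guard), and interior nodes are relaxed by
# Laplacian smoothing.

#' Specify a calcium phosphate granule
#'
#' A granule is modelled as a volume-excluded ball whose surface pins the
#' order parameter to a constant value while the chemical potential keeps a
#' zero-flux condition there.
#'
#' @param center Numeric vector (length 2 or 3): granule center.
#' @param radius Positive granule radius.
#' @param value Pinned order-parameter value \code{C} on the granule surface,
#'   in \code{[-1, 1]}. \code{+1} marks the granule surface as fluid matrix.
#' @return An object of class \code{ch_granule}.
#' @examples
#' granule(c(2.5, 2.5), radius = 1, value = 1)
#' @export
granule <- function(center, radius, value = 1) {
  center <- as.numeric(center)
  if (!length(center) %in% c(2L, 3L)) stop("granule center must have 2 or 3 coordinates")
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0) {
    stop("granule radius must be a positive scalar")
  }
  if (abs(value) > 1) stop("granule pinned value must lie in [-1, 1]")
  structure(list(center = center, radius = as.numeric(radius), value = as.numeric(value)),
            class = "ch_granule")
}

#' @exportS3Method base::print
print.ch_granule <- function(x, ...) {
  cat(sprintf("<granule> center (%s), radius %g, pinned value %g\n",
              paste(format(x$center), collapse = ", "), x$radius, x$value))
  invisible(x)
}

# --- shape helpers ----------------------------------------------------------

# Semi-axes from the size parameters. Axis convention: ellipse/ellipsoid sizes
# are FULL axis lengths (an "axis of 10" means semi-axis 5), so the ellipse
# with axes 10 and 8 is comparable to the radius-5 disk.
shape_semiaxes <- function(shape, size_params) {
  size_params <- as.numeric(size_params)
  switch(shape,
    disk = {
      if (length(size_params) != 1L) stop("disk takes a single radius")
      rep(size_params, 2L)
    },
    sphere = {
      if (length(size_params) != 1L) stop("sphere takes a single radius")
      rep(size_params, 3L)
    },
    ellipse = {
      if (length(size_params) != 2L) stop("ellipse takes two full axis lengths")
      size_params / 2
    },
    ellipsoid = {
      if (length(size_params) != 3L) stop("ellipsoid takes three full axis lengths")
      size_params / 2
    },
    stop("unknown shape: ", shape)
  )
}

shape_dim <- function(shape) if (shape %in% c("disk", "ellipse")) 2L else 3L

# Level function: negative inside, ~signed distance near the surface.
# For ellipses this is the exact distance along the ray from the center,
# which is what the radial snap uses.
outer_level <- function(pts, semi) {
  scaled <- sweep(pts, 2L, semi, "/")
  rho <- sqrt(rowSums(scaled^2))    # 1 on the surface
  r <- sqrt(rowSums(pts^2))
  # distance along the ray from the center: negative inside
  lev <- r * (1 - 1 / pmax(rho, 1e-300))
  lev[rho < 1e-12] <- -min(semi)
  lev
}

granule_level <- function(pts, g) {
  sqrt(rowSums(sweep(pts, 2L, g$center, "-")^2)) - g$radius
}

# negative strictly inside the meshed region (inside shape, outside granules)
domain_level <- function(pts, semi, granules) {
  lev <- outer_level(pts, semi)
  for (g in granules) lev <- pmax(lev, -granule_level(pts, g))
  lev
}

# Radial projection onto the outer surface or a granule sphere.
project_outer <- function(pts, semi) {
  scaled <- sweep(pts, 2L, semi, "/")
  rho <- sqrt(rowSums(scaled^2))
  pts / rho
}
project_granule <- function(pts, g) {
  v <- sweep(pts, 2L, g$center, "-")
  r <- sqrt(rowSums(v^2))
  sweep(v * (g$radius / r), 2L, g$center, "+")
}

# --- granule validation -----------------------------------------------------

#' Validate granule placement inside a domain shape
#'
#' Pure report: checks that each granule ball lies strictly inside the outer
#' shape with clearance at least \code{h_target}, and that granules are
#' pairwise disjoint with the same clearance. Nothing is mutated and no error
#' is thrown; \code{\link{build_domain}} raises errors from this report.
#'
#' @param shape One of \code{"disk"}, \code{"ellipse"}, \code{"sphere"},
#'   \code{"ellipsoid"}.
#' @param size_params Disk/sphere: radius. Ellipse/ellipsoid: full axis lengths.
#' @param granules List of \code{\link{granule}} objects.
#' @param h_target Target mesh edge length used as the required clearance.
#' @return A list with a per-granule data frame (\code{inside_ok},
#'   \code{outer_clearance}) , a pairwise data frame (\code{clearance},
#'   \code{ok}) and a scalar \code{ok}.
#' @export
validate_granules <- function(shape, size_params, granules, h_target = 0.15) {
  shape <- match.arg(shape, c("disk", "ellipse", "sphere", "ellipsoid"))
  semi <- shape_semiaxes(shape, size_params)
  d <- shape_dim(shape)
  ng <- length(granules)
  per <- data.frame(granule = integer(0), outer_clearance = numeric(0),
                    inside_ok = logical(0))
  if (ng) {
    oc <- vapply(granules, function(g) {
      if (length(g$center) != d) return(NA_real_)
      # distance from granule surface to outer surface along the worst direction:
      # sample the granule sphere and take min of -outer_level minus 0
      theta <- seq(0, 2 * pi, length.out = 181L)[-181L]
      if (d == 2L) {
        pts <- cbind(g$center[1] + g$radius * cos(theta),
                     g$center[2] + g$radius * sin(theta))
      } else {
        phi <- seq(0, pi, length.out = 61L)
        grid <- expand.grid(t = theta[seq(1, 180L, by = 4L)], p = phi)
        pts <- cbind(g$center[1] + g$radius * sin(grid$p) * cos(grid$t),
                     g$center[2] + g$radius * sin(grid$p) * sin(grid$t),
                     g$center[3] + g$radius * cos(grid$p))
      }
      min(-outer_level(pts, semi))
    }, numeric(1))
    per <- data.frame(granule = seq_len(ng), outer_clearance = oc,
                      inside_ok = !is.na(oc) & oc >= h_target)
  }
  pair <- data.frame(i = integer(0), j = integer(0), clearance = numeric(0),
                     ok = logical(0))
  if (ng >= 2L) {
    idx <- utils::combn(ng, 2L)
    cl <- apply(idx, 2L, function(ij) {
      gi <- granules[[ij[1]]]; gj <- granules[[ij[2]]]
      sqrt(sum((gi$center - gj$center)^2)) - gi$radius - gj$radius
    })
    pair <- data.frame(i = idx[1, ], j = idx[2, ], clearance = cl,
                       ok = cl >= h_target)
  }
  list(per_granule = per, pairwise = pair,
       ok = all(per$inside_ok) && all(pair$ok))
}

# --- mesh construction ------------------------------------------------------

# 2D: grid squares split into two triangles with alternating diagonals.
grid_triangles <- function(nx, ny) {
  # node index of grid point (i, j), i in 0..nx, j in 0..ny (column-major in i)
  id <- function(i, j) i + 1L + (nx + 1L) * j
  i <- rep(0:(nx - 1L), times = ny)
  j <- rep(0:(ny - 1L), each = nx)
  a <- id(i, j); b <- id(i + 1L, j); c <- id(i + 1L, j + 1L); d <- id(i, j + 1L)
  alt <- (i + j) %% 2L == 0L
  t1 <- cbind(ifelse(alt, a, a), ifelse(alt, b, b), ifelse(alt, c, d))
  t2 <- cbind(ifelse(alt, a, b), ifelse(alt, c, c), ifelse(alt, d, d))
  rbind(t1, t2)
}

# 3D: Kuhn split of each cube into 6 positively oriented tetrahedra.
grid_tets <- function(nx, ny, nz) {
  id <- function(i, j, k) i + 1L + (nx + 1L) * (j + (ny + 1L) * k)
  i <- rep(0:(nx - 1L), times = ny * nz)
  j <- rep(rep(0:(ny - 1L), each = nx), times = nz)
  k <- rep(0:(nz - 1L), each = nx * ny)
  v000 <- id(i, j, k);     v100 <- id(i + 1L, j, k)
  v010 <- id(i, j + 1L, k); v110 <- id(i + 1L, j + 1L, k)
  v001 <- id(i, j, k + 1L); v101 <- id(i + 1L, j, k + 1L)
  v011 <- id(i, j + 1L, k + 1L); v111 <- id(i + 1L, j + 1L, k + 1L)
  # 6 tets around the main diagonal v000 -> v111
  rbind(cbind(v000, v100, v110, v111),
        cbind(v000, v110, v010, v111),
        cbind(v000, v010, v011, v111),
        cbind(v000, v011, v001, v111),
        cbind(v000, v001, v101, v111),
        cbind(v000, v101, v100, v111))
}

simplex_measures <- function(nodes, elements) {
  d <- ncol(nodes)
  if (d == 1L) {
    abs(nodes[elements[, 2L], 1L] - nodes[elements[, 1L], 1L])
  } else if (d == 2L) {
    x1 <- nodes[elements[, 1L], ]; x2 <- nodes[elements[, 2L], ]; x3 <- nodes[elements[, 3L], ]
    0.5 * ((x2[, 1] - x1[, 1]) * (x3[, 2] - x1[, 2]) -
           (x3[, 1] - x1[, 1]) * (x2[, 2] - x1[, 2]))
  } else {
    x1 <- nodes[elements[, 1L], ]; x2 <- nodes[elements[, 2L], ]
    x3 <- nodes[elements[, 3L], ]; x4 <- nodes[elements[, 4L], ]
    a <- x2 - x1; b <- x3 - x1; c <- x4 - x1
    (a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
     a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
     a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
  }
}

# facets of each element as an (n_elem * n_facet) x d index matrix
element_facets <- function(elements, d) {
  if (d == 1L) {
    rbind(elements[, 1L, drop = FALSE], elements[, 2L, drop = FALSE])
  } else if (d == 2L) {
    rbind(elements[, c(1L, 2L)], elements[, c(2L, 3L)], elements[, c(3L, 1L)])
  } else {
    rbind(elements[, c(2L, 3L, 4L)], elements[, c(1L, 3L, 4L)],
          elements[, c(1L, 2L, 4L)], elements[, c(1L, 2L, 3L)])
  }
}

facet_keys <- function(facets) {
  sorted <- t(apply(facets, 1L, sort))
  if (ncol(sorted) == 1L) as.character(sorted[, 1L])
  else if (ncol(sorted) == 2L) paste(sorted[, 1L], sorted[, 2L])
  else paste(sorted[, 1L], sorted[, 2L], sorted[, 3L])
}

# boundary facets (appearing in exactly one element) with owning element
boundary_facets <- function(elements, d) {
  m <- nrow(elements)
  fac <- element_facets(elements, d)
  owner <- rep(seq_len(m), times = nrow(fac) / m)
  key <- facet_keys(fac)
  tab <- table(key)
  onb <- key %in% names(tab)[tab == 1L]
  list(facets = fac[onb, , drop = FALSE], owner = owner[onb])
}

largest_component_elements <- function(elements, d) {
  m <- nrow(elements)
  fac <- element_facets(elements, d)
  owner <- rep(seq_len(m), times = nrow(fac) / m)
  key <- facet_keys(fac)
  sp <- split(owner, key)
  pairs <- sp[lengths(sp) == 2L]
  if (!length(pairs)) return(seq_len(m))
  e1 <- vapply(pairs, `[`, integer(1), 1L)
  e2 <- vapply(pairs, `[`, integer(1), 2L)
  comp <- union_find(m, cbind(e1, e2))
  keep <- comp == names(sort(table(comp), decreasing = TRUE))[1L]
  which(keep)
}

# simple union-find over n items given an edge matrix; returns component labels
union_find <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (nrow(edges)) {
    for (r in seq_len(nrow(edges))) {
      a <- find(edges[r, 1L]); b <- find(edges[r, 2L])
      if (a != b) parent[a] <- b
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Build a simplicial mesh of a model domain
#'
#' Discretizes a disk, ellipse, sphere or ellipsoid with optional granule
#' holes. Boundary facets are tagged as outer boundary or by granule index;
#' granule interiors are excluded from the element set. Boundary nodes lie on
#' the analytic surfaces, so the discretized measure converges to the analytic
#' area/volume as \code{h_target} decreases (within 2\% at the default).
#'
#' @param shape \code{"disk"}, \code{"ellipse"}, \code{"sphere"} or
#'   \code{"ellipsoid"}.
#' @param size_params Disk/sphere: radius. Ellipse/ellipsoid: full axis
#'   lengths (an axis of 10 means semi-axis 5).
#' @param granules List of \code{\link{granule}} objects (may be empty).
#' @param h_target Target edge length. The default 0.15 resolves the
#'   equilibrium interface width \code{sqrt(2 * gamma)} (about 1.41 at
#'   \code{gamma = 1}) with roughly nine elements.
#' @param smooth_iters Laplacian smoothing sweeps for interior nodes.
#' @return An object of class \code{ch_domain} with fields \code{dim},
#'   \code{nodes}, \code{elements}, \code{facets}, \code{facet_tag} (0 =
#'   outer, g = granule index), \code{node_tag} (NA interior), \code{granules},
#'   \code{h_target}, \code{shape}, \code{size_params}.
#' @examples
#' d <- build_domain("disk", 4, h_target = 0.4)
#' domain_measure(d)  # close to 16 * pi
#' @export
build_domain <- function(shape, size_params, granules = list(),
                         h_target = 0.15, smooth_iters = 8L) {
  shape <- match.arg(shape, c("disk", "ellipse", "sphere", "ellipsoid"))
  if (inherits(granules, "ch_granule")) granules <- list(granules)
  semi <- shape_semiaxes(shape, size_params)
  d <- shape_dim(shape)
  if (length(granules)) {
    bad <- vapply(granules, function(g) length(g$center) != d, logical(1))
    if (any(bad)) stop("granule center dimension does not match shape dimension")
    if (h_target > min(vapply(granules, function(g) g$radius, numeric(1)))) {
      stop("resolution error: h_target exceeds the smallest granule radius")
    }
    rep_ <- validate_granules(shape, size_params, granules, h_target)
    if (!rep_$ok) {
      bad_in <- rep_$per_granule$granule[!rep_$per_granule$inside_ok]
      bad_pr <- rep_$pairwise[!rep_$pairwise$ok, , drop = FALSE]
      msg <- "granule validation failed:"
      if (length(bad_in)) msg <- paste0(msg, " granules out of bounds or too close to the outer boundary: ",
                                        paste(bad_in, collapse = ", "), ".")
      if (nrow(bad_pr)) msg <- paste0(msg, " overlapping/too-close pairs: ",
                                      paste(sprintf("(%d,%d)", bad_pr$i, bad_pr$j), collapse = ", "), ".")
      stop(msg)
    }
  }
  h <- h_target
  lo <- -semi - 2 * h
  hi <- semi + 2 * h
  n_cells <- pmax(2L, as.integer(ceiling((hi - lo) / h)))
  if (d == 2L) {
    xs <- seq(lo[1], lo[1] + n_cells[1] * h, by = h)
    ys <- seq(lo[2], lo[2] + n_cells[2] * h, by = h)
    nodes <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
    elements <- grid_triangles(length(xs) - 1L, length(ys) - 1L)
  } else {
    xs <- seq(lo[1], lo[1] + n_cells[1] * h, by = h)
    ys <- seq(lo[2], lo[2] + n_cells[2] * h, by = h)
    zs <- seq(lo[3], lo[3] + n_cells[3] * h, by = h)
    nodes <- cbind(rep(xs, times = length(ys) * length(zs)),
                   rep(rep(ys, each = length(xs)), times = length(zs)),
                   rep(zs, each = length(xs) * length(ys)))
    elements <- grid_tets(length(xs) - 1L, length(ys) - 1L, length(zs) - 1L)
  }
  # keep simplices whose centroid lies inside the domain; their outside
  # vertices are snapped back onto the surface below, so cut cells contribute
  # their full measure instead of being discarded
  cent <- facet_midpoints(nodes, elements)
  elements <- elements[domain_level(cent, semi, granules) < 0, , drop = FALSE]
  if (!nrow(elements)) stop("empty mesh: h_target too large for this shape")
  elements <- elements[largest_component_elements(elements, d), , drop = FALSE]
  # compact node numbering
  used <- sort(unique(as.vector(elements)))
  remap <- integer(nrow(nodes)); remap[used] <- seq_along(used)
  nodes <- nodes[used, , drop = FALSE]
  elements <- matrix(remap[elements], nrow = nrow(elements))

  bf <- boundary_facets(elements, d)
  # tag each boundary facet by the nearest surface at its midpoint
  mids <- facet_midpoints(nodes, bf$facets)
  dist_out <- abs(outer_level(mids, semi))
  tag <- rep(0L, nrow(mids))
  if (length(granules)) {
    dmat <- cbind(dist_out, vapply(granules, function(g) abs(granule_level(mids, g)),
                                   numeric(nrow(mids))))
    tag <- max.col(-dmat, ties.method = "first") - 1L
  }
  # tag boundary nodes by nearest surface
  bnode <- sort(unique(as.vector(bf$facets)))
  node_tag <- rep(NA_integer_, nrow(nodes))
  bpts <- nodes[bnode, , drop = FALSE]
  ndist <- abs(outer_level(bpts, semi))
  ntag <- rep(0L, length(bnode))
  if (length(granules)) {
    dmat <- cbind(ndist, vapply(granules, function(g) abs(granule_level(bpts, g)),
                                numeric(length(bnode))))
    ntag <- max.col(-dmat, ties.method = "first") - 1L
  }
  node_tag[bnode] <- ntag

  # snap boundary nodes to their surface, guarding against element inversion
  nodes <- snap_boundary(nodes, elements, bnode, ntag, semi, granules)
  # Laplacian smoothing of interior nodes (boundary fixed)
  nodes <- smooth_interior(nodes, elements, is.na(node_tag), iters = smooth_iters)

  dom <- structure(list(
    dim = d, nodes = nodes, elements = elements,
    facets = bf$facets, facet_tag = tag, facet_owner = bf$owner,
    node_tag = node_tag, granules = granules,
    h_target = h_target, shape = shape, size_params = as.numeric(size_params),
    periodic = FALSE, cache = new.env(parent = emptyenv())
  ), class = "ch_domain")
  dom
}

facet_midpoints <- function(nodes, facets) {
  mids <- nodes[facets[, 1L], , drop = FALSE]
  for (jj in seq_len(ncol(facets))[-1L]) mids <- mids + nodes[facets[, jj], , drop = FALSE]
  mids / ncol(facets)
}

snap_boundary <- function(nodes, elements, bnode, ntag, semi, granules) {
  orig <- nodes[bnode, , drop = FALSE]
  target <- project_outer(orig, semi)
  if (length(granules)) {
    for (gi in seq_along(granules)) {
      sel <- ntag == gi
      if (any(sel)) target[sel, ] <- project_granule(orig[sel, , drop = FALSE], granules[[gi]])
    }
  }
  ref_sign <- sign(simplex_measures(nodes, elements))
  med <- stats::median(abs(simplex_measures(nodes, elements)))
  # per-node damped projection: move each boundary node as far towards its
  # surface target as its incident elements allow without inverting
  alpha <- rep(1, length(bnode))
  node_of <- integer(nrow(nodes))
  node_of[bnode] <- seq_along(bnode)
  for (pass in 1:8) {
    trial <- nodes
    trial[bnode, ] <- orig + alpha * (target - orig)
    meas <- simplex_measures(trial, elements)
    bad <- which(sign(meas) != ref_sign | abs(meas) < 1e-4 * med)
    if (!length(bad)) {
      nodes <- trial
      break
    }
    bad_b <- node_of[intersect(unique(as.vector(elements[bad, , drop = FALSE])),
                               bnode)]
    alpha[bad_b] <- alpha[bad_b] * 0.5
    if (pass == 8L) {
      alpha[bad_b] <- 0
      trial[bnode, ] <- orig + alpha * (target - orig)
      nodes <- trial
    }
  }
  nodes
}

smooth_interior <- function(nodes, elements, interior, iters = 8L, relax = 0.5) {
  if (!iters) return(nodes)
  d <- ncol(nodes)
  edges <- if (d == 1L) elements else if (d == 2L) {
    rbind(elements[, 1:2], elements[, 2:3], elements[, c(3L, 1L)])
  } else {
    rbind(elements[, 1:2], elements[, c(1L, 3L)], elements[, c(1L, 4L)],
          elements[, 2:3], elements[, c(2L, 4L)], elements[, 3:4])
  }
  edges <- rbind(edges, edges[, 2:1])
  ref_sign <- sign(simplex_measures(nodes, elements))
  prev <- nodes
  for (it in seq_len(iters)) {
    sx <- vector("list", d)
    cnt <- tabulate(edges[, 1L], nbins = nrow(nodes))
    for (jj in seq_len(d)) {
      sx[[jj]] <- unname(rowsum(nodes[edges[, 2L], jj], edges[, 1L],
                                reorder = TRUE))
    }
    present <- sort(unique(edges[, 1L]))
    for (jj in seq_len(d)) {
      avg <- nodes[, jj]
      avg[present] <- sx[[jj]] / cnt[present]
      nodes[interior, jj] <- (1 - relax) * nodes[interior, jj] + relax * avg[interior]
    }
  }
  meas <- simplex_measures(nodes, elements)
  if (any(sign(meas) != ref_sign | abs(meas) < 1e-14)) prev else nodes
}

#' Total discretized measure (area or volume) of a domain
#'
#' @param d A \code{ch_domain}.
#' @return Sum of element measures (strictly positive).
#' @export
domain_measure <- function(d) {
  stopifnot(inherits(d, "ch_domain"))
  if (!nrow(d$elements)) stop("domain has no elements")
  sum(abs(element_measures(d)))
}

#' @exportS3Method base::print
print.ch_domain <- function(x, ...) {
  cat(sprintf("<ch_domain> %s (%s), dim %d: %d nodes, %d elements, %d boundary facets, %d granule(s), h_target %g\n",
              x$shape, paste(format(x$size_params), collapse = " x "), x$dim,
              nrow(x$nodes), nrow(x$elements),
              if (is.null(x$facets)) 0L else nrow(x$facets),
              length(x$granules), x$h_target))
  invisible(x)
}

# --- simple structured domains used by fixtures, 1D analyses and tests ------

#' Structured rectangle mesh (fixture/testing helper)
#'
#' @param width,height Side lengths; the rectangle is
#'   \code{[-width/2, width/2] x [-height/2, height/2]}.
#' @param h_target Target edge length.
#' @return A \code{ch_domain} with all boundary facets tagged outer.
#' @export
rect_domain <- function(width, height, h_target = 0.15) {
  nx <- max(2L, as.integer(round(width / h_target)))
  ny <- max(2L, as.integer(round(height / h_target)))
  xs <- seq(-width / 2, width / 2, length.out = nx + 1L)
  ys <- seq(-height / 2, height / 2, length.out = ny + 1L)
  nodes <- cbind(rep(xs, times = ny + 1L), rep(ys, each = nx + 1L))
  elements <- grid_triangles(nx, ny)
  bf <- boundary_facets(elements, 2L)
  node_tag <- rep(NA_integer_, nrow(nodes))
  node_tag[unique(as.vector(bf$facets))] <- 0L
  structure(list(dim = 2L, nodes = nodes, elements = elements,
                 facets = bf$facets, facet_tag = rep(0L, nrow(bf$facets)),
                 facet_owner = bf$owner, node_tag = node_tag,
                 granules = list(), h_target = h_target, shape = "rectangle",
                 size_params = c(width, height), periodic = FALSE,
                 cache = new.env(parent = emptyenv())),
            class = "ch_domain")
}

#' 1D interval mesh with zero-flux ends
#'
#' @param from,to Interval end points.
#' @param n Number of nodes.
#' @return A \code{ch_domain} of dimension 1.
#' @export
line_domain <- function(from, to, n) {
  stopifnot(to > from, n >= 3L)
  xs <- seq(from, to, length.out = n)
  nodes <- matrix(xs, ncol = 1L)
  elements <- cbind(seq_len(n - 1L), 2:n)
  structure(list(dim = 1L, nodes = nodes, elements = elements,
                 facets = matrix(c(1L, n), ncol = 1L), facet_tag = c(0L, 0L),
                 facet_owner = c(1L, n - 1L),
                 node_tag = c(0L, rep(NA_integer_, n - 2L), 0L),
                 granules = list(), h_target = (to - from) / (n - 1L),
                 shape = "line", size_params = c(from, to), periodic = FALSE,
                 cache = new.env(parent = emptyenv())),
            class = "ch_domain")
}

#' Periodic 1D interval mesh
#'
#' Used for linear-regime validation of the solver against the dispersion
#' relation: single Fourier modes are exact eigenfunctions of the periodic
#' problem.
#'
#' @param length Period length.
#' @param n Number of nodes (and elements).
#' @return A \code{ch_domain} of dimension 1 with \code{periodic = TRUE}.
#' @export
periodic_interval_domain <- function(length, n) {
  stopifnot(length > 0, n >= 8L)
  h <- length / n
  nodes <- matrix(h * (0:(n - 1L)), ncol = 1L)
  elements <- cbind(seq_len(n), c(2:n, 1L))
  structure(list(dim = 1L, nodes = nodes, elements = elements,
                 facets = matrix(integer(0), ncol = 1L), facet_tag = integer(0),
                 facet_owner = integer(0), node_tag = rep(NA_integer_, n),
                 granules = list(), h_target = h, shape = "periodic_interval",
                 size_params = length, periodic = TRUE, elem_len = rep(h, n),
                 cache = new.env(parent = emptyenv())),
            class = "ch_domain")
}
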