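# Morphometric analysis of simulated ultrastructure: phase fractions by exact
# element splitting, interface measure of the psi = 0 level set (marching
# segments/triangles), connected components of the membrane phase over facet
# adjacency, spectral characteristic length on a resampled grid, and granule
# halo composition.
#
# Convention: psi = 0 (the midpoint of the double well) is the phase boundary;
# nodes exactly at the threshold belong to neither phase.

# de-duplicate exactly tied nodal values inside an element so the simplex
# fraction identity below has no zero denominators; the perturbation is
# measure-zero for the reported fractions
untie <- function(w, scale) {
  nv <- ncol(w)
  eps <- 1e-9 * max(scale, 1e-12)
  for (pass in 1:3) {
    dup <- matrix(FALSE, nrow(w), nv)
    for (i in seq_len(nv - 1L)) {
      for (j in (i + 1L):nv) {
        same <- w[, i] == w[, j]
        dup[same, j] <- TRUE
      }
    }
    if (!any(dup)) break
    w <- w + dup * eps * matrix(seq_len(nv), nrow(w), nv, byrow = TRUE)
  }
  w
}

# fraction of each simplex where the linear interpolant of w is positive:
#   frac = sum_{i: w_i > 0} w_i^d / prod_{j != i} (w_i - w_j)
simplex_positive_fraction <- function(w, d) {
  nv <- d + 1L
  frac <- numeric(nrow(w))
  allpos <- rowSums(w > 0) == nv
  allneg <- rowSums(w < 0) == nv
  frac[allpos] <- 1
  mixed <- which(!allpos & !allneg)
  if (length(mixed)) {
    wm <- untie(w[mixed, , drop = FALSE], max(abs(w)))
    acc <- numeric(length(mixed))
    for (i in seq_len(nv)) {
      term <- wm[, i]^d
      for (j in seq_len(nv)[-i]) term <- term / (wm[, i] - wm[, j])
      acc <- acc + ifelse(wm[, i] > 0, term, 0)
    }
    frac[mixed] <- pmin(pmax(acc, 0), 1)
  }
  frac
}

#' Phase fractions of a phase field
#'
#' Measure fractions of the fluid matrix (\code{psi > threshold}) and inner
#' membrane (\code{psi < threshold}) phases, with elements straddling the
#' threshold split exactly by linear interpolation.
#'
#' @param d A \code{ch_domain}.
#' @param psi Nodal order parameter.
#' @param threshold Phase boundary level (default 0).
#' @return Named vector \code{c(matrix_fraction, membrane_fraction)}.
#' @export
phase_fractions <- function(d, psi, threshold = 0) {
  stopifnot(inherits(d, "ch_domain"))
  check_field(d, psi, "psi")
  w <- element_values(d, psi) - threshold
  meas <- element_measures(d)
  tot <- sum(meas)
  pos <- simplex_positive_fraction(w, d$dim)
  neg <- simplex_positive_fraction(-w, d$dim)
  c(matrix_fraction = sum(meas * pos) / tot,
    membrane_fraction = sum(meas * neg) / tot)
}

#' Measure of the psi = 0 level set
#'
#' Length (2D) or area (3D) of the zero level set extracted by linear
#' interpolation on each simplex (marching segments / marching tetrahedra).
#' In 1D, the number of zero crossings is returned.
#'
#' @inheritParams phase_fractions
#' @param level Level-set value (default 0).
#' @return Nonnegative scalar; 0 for a uniform field.
#' @export
interface_measure <- function(d, psi, level = 0) {
  stopifnot(inherits(d, "ch_domain"))
  check_field(d, psi, "psi")
  w <- element_values(d, psi) - level
  nv <- d$dim + 1L
  scale <- max(abs(w))
  if (scale == 0) return(0)
  # nodes exactly on the level set would otherwise hide crossings along
  # node-aligned interfaces; nudge them consistently to one side
  w[w == 0] <- 1e-9 * scale
  mixed <- which(rowSums(w > 0) > 0 & rowSums(w < 0) > 0)
  if (!length(mixed)) return(0)
  wm <- untie(w[mixed, , drop = FALSE], max(abs(w)))
  if (d$dim == 1L) return(length(mixed))
  total <- 0
  for (e in seq_along(mixed)) {
    el <- d$elements[mixed[e], ]
    vals <- wm[e, ]
    pts <- list()
    for (i in seq_len(nv - 1L)) {
      for (j in (i + 1L):nv) {
        if (vals[i] * vals[j] < 0) {
          t <- vals[i] / (vals[i] - vals[j])
          pts[[length(pts) + 1L]] <-
            d$nodes[el[i], ] + t * (d$nodes[el[j], ] - d$nodes[el[i], ])
        }
      }
    }
    P <- do.call(rbind, pts)
    if (d$dim == 2L) {
      if (nrow(P) >= 2L) total <- total + sqrt(sum((P[2L, ] - P[1L, ])^2))
    } else {
      if (nrow(P) == 3L) {
        total <- total + tri_area3(P[1L, ], P[2L, ], P[3L, ])
      } else if (nrow(P) == 4L) {
        # 2-2 sign split: order the quad around the positive-vertex edge
        posv <- which(vals > 0)
        crossings <- list()
        for (i in seq_len(nv - 1L)) for (j in (i + 1L):nv) {
          if (vals[i] * vals[j] < 0) {
            crossings[[length(crossings) + 1L]] <- c(i, j)
          }
        }
        # cyclic quad order (a,c1), (a,c2), (b,c2), (b,c1) with positives a, b
        # and negatives c1, c2
        a <- posv[1L]; b <- posv[2L]
        negv <- setdiff(seq_len(4L), posv)
        key <- vapply(crossings, function(cr) paste(sort(cr), collapse = "-"),
                      character(1))
        idx_of <- function(p, q) which(key == paste(sort(c(p, q)), collapse = "-"))
        quad <- rbind(P[idx_of(a, negv[1L]), ], P[idx_of(a, negv[2L]), ],
                      P[idx_of(b, negv[2L]), ], P[idx_of(b, negv[1L]), ])
        total <- total + tri_area3(quad[1L, ], quad[2L, ], quad[3L, ]) +
          tri_area3(quad[1L, ], quad[3L, ], quad[4L, ])
      }
    }
  }
  total
}

tri_area3 <- function(p1, p2, p3) {
  u <- p2 - p1; v <- p3 - p1
  cr <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  0.5 * sqrt(sum(cr^2))
}

#' Count connected components of a phase
#'
#' Components of the element adjacency graph (facet adjacency: edge-sharing in
#' 2D, face-sharing in 3D, so vertex-touching regions do not bridge)
#' restricted to elements whose centroid value lies on the requested side of
#' zero.
#'
#' @inheritParams phase_fractions
#' @param phase \code{"membrane"} (centroid \code{psi < 0}) or
#'   \code{"matrix"} (centroid \code{psi > 0}).
#' @return Nonnegative integer.
#' @export
count_phase_components <- function(d, psi, phase = c("membrane", "matrix")) {
  stopifnot(inherits(d, "ch_domain"))
  check_field(d, psi, "psi")
  phase <- match.arg(phase)
  cv <- rowMeans(element_values(d, psi))
  sel <- if (phase == "membrane") cv < 0 else cv > 0
  if (!any(sel)) return(0L)
  elems <- which(sel)
  sub <- d$elements[elems, , drop = FALSE]
  m <- nrow(sub)
  fac <- element_facets(sub, d$dim)
  owner <- rep(seq_len(m), times = nrow(fac) / m)
  key <- facet_keys(fac)
  sp <- split(owner, key)
  pairs <- sp[lengths(sp) == 2L]
  edges <- if (length(pairs)) {
    cbind(vapply(pairs, `[`, integer(1), 1L), vapply(pairs, `[`, integer(1), 2L))
  } else matrix(integer(0), ncol = 2L)
  comp <- union_find(m, edges)
  length(unique(comp))
}

#' Resample a mesh field on a uniform grid
#'
#' Barycentric interpolation of the nodal field onto a regular grid over the
#' domain's bounding box (128^2 in 2D, 64^3 in 3D by default); points outside
#' the mesh are masked. Input for \code{\link{characteristic_length}}.
#'
#' @inheritParams phase_fractions
#' @param n Grid points per axis.
#' @return List of class \code{ch_grid_field}: \code{values} (array with NA
#'   outside), \code{mask}, \code{spacing}, \code{n}, \code{dim}.
#' @export
resample_to_grid <- function(d, psi, n = if (d$dim == 2L) 128L else 64L) {
  stopifnot(inherits(d, "ch_domain"), d$dim >= 2L)
  check_field(d, psi, "psi")
  lo <- apply(d$nodes, 2L, min)
  hi <- apply(d$nodes, 2L, max)
  spacing <- (hi - lo) / n
  axes <- lapply(seq_len(d$dim), function(j) lo[j] + spacing[j] * ((1:n) - 0.5))
  vals <- array(NA_real_, dim = rep(n, d$dim))
  ve <- element_values(d, psi)
  if (d$dim == 2L) {
    p1 <- d$nodes[d$elements[, 1L], , drop = FALSE]
    p2 <- d$nodes[d$elements[, 2L], , drop = FALSE]
    p3 <- d$nodes[d$elements[, 3L], , drop = FALSE]
    det2 <- (p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
            (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2])
    for (e in seq_len(nrow(d$elements))) {
      xr <- range(p1[e, 1], p2[e, 1], p3[e, 1])
      yr <- range(p1[e, 2], p2[e, 2], p3[e, 2])
      ix <- which(axes[[1]] >= xr[1] - 1e-12 & axes[[1]] <= xr[2] + 1e-12)
      iy <- which(axes[[2]] >= yr[1] - 1e-12 & axes[[2]] <= yr[2] + 1e-12)
      if (!length(ix) || !length(iy)) next
      gx <- rep(axes[[1]][ix], times = length(iy))
      gy <- rep(axes[[2]][iy], each = length(ix))
      l2 <- ((gx - p1[e, 1]) * (p3[e, 2] - p1[e, 2]) -
             (gy - p1[e, 2]) * (p3[e, 1] - p1[e, 1])) / det2[e]
      l3 <- ((gy - p1[e, 2]) * (p2[e, 1] - p1[e, 1]) -
             (gx - p1[e, 1]) * (p2[e, 2] - p1[e, 2])) / det2[e]
      l1 <- 1 - l2 - l3
      inside <- l1 >= -1e-9 & l2 >= -1e-9 & l3 >= -1e-9
      if (any(inside)) {
        v <- l1 * ve[e, 1L] + l2 * ve[e, 2L] + l3 * ve[e, 3L]
        ij <- cbind(rep(ix, times = length(iy)), rep(iy, each = length(ix)))
        vals[ij[inside, , drop = FALSE]] <- v[inside]
      }
    }
  } else {
    pl <- element_coord_list(d)
    for (e in seq_len(nrow(d$elements))) {
      P <- rbind(pl[[1]][e, ], pl[[2]][e, ], pl[[3]][e, ], pl[[4]][e, ])
      rng <- apply(P, 2L, range)
      idx <- lapply(seq_len(3L), function(j) {
        which(axes[[j]] >= rng[1, j] - 1e-12 & axes[[j]] <= rng[2, j] + 1e-12)
      })
      if (!all(lengths(idx) > 0)) next
      g <- as.matrix(expand.grid(axes[[1]][idx[[1]]], axes[[2]][idx[[2]]],
                                 axes[[3]][idx[[3]]]))
      Tm <- t(P[2:4, ]) - P[1, ]          # 3x3 with edge columns
      Ti <- solve(Tm)
      lam <- t(Ti %*% (t(g) - P[1, ]))    # lambda_2..4 per point
      l1 <- 1 - rowSums(lam)
      inside <- l1 >= -1e-9 & lam[, 1] >= -1e-9 & lam[, 2] >= -1e-9 &
        lam[, 3] >= -1e-9
      if (any(inside)) {
        v <- l1 * ve[e, 1L] + lam[, 1] * ve[e, 2L] + lam[, 2] * ve[e, 3L] +
          lam[, 3] * ve[e, 4L]
        ij <- as.matrix(expand.grid(idx[[1]], idx[[2]], idx[[3]]))
        vals[ij[inside, , drop = FALSE]] <- v[inside]
      }
    }
  }
  structure(list(values = vals, mask = !is.na(vals), spacing = spacing,
                 n = n, dim = d$dim),
            class = "ch_grid_field")
}

#' Spectral characteristic pattern length
#'
#' \code{2 pi / <k>} with \code{<k>} the first moment of the radially
#' averaged power spectrum of the mean-subtracted field. Points outside the
#' mesh are set to the field mean before the FFT so the mask does not leak
#' into the spectrum. Grows under coarsening; a single-mode sinusoid of
#' wavenumber \code{k} gives \code{2 pi / k}.
#'
#' @param grid_field A \code{ch_grid_field} from \code{\link{resample_to_grid}}.
#' @return Positive scalar; errors on a spectrally flat (uniform) field.
#' @export
characteristic_length <- function(grid_field) {
  stopifnot(inherits(grid_field, "ch_grid_field"))
  v <- grid_field$values
  mean_in <- mean(v[grid_field$mask])
  v[!grid_field$mask] <- mean_in
  a <- v - mean_in
  if (stats::sd(as.vector(a)) < 1e-14) {
    stop("spectrally flat field: characteristic length undefined")
  }
  n <- grid_field$n
  P <- Mod(stats::fft(a))^2
  freq <- c(0:(n %/% 2), -((n - n %/% 2 - 1L):1)) / n   # cycles per sample
  kaxes <- lapply(seq_len(grid_field$dim), function(j) {
    2 * pi * freq / (grid_field$spacing[j])
  })
  if (grid_field$dim == 2L) {
    kmag <- sqrt(outer(kaxes[[1]]^2, kaxes[[2]]^2, `+`))
  } else {
    kmag <- sqrt(outer(outer(kaxes[[1]]^2, kaxes[[2]]^2, `+`), kaxes[[3]]^2, `+`))
  }
  dk <- 2 * pi / (n * max(grid_field$spacing))
  bin <- as.integer(round(kmag / dk))
  keep <- bin > 0L
  pb <- tapply(P[keep], bin[keep], mean)
  kb <- as.numeric(names(pb)) * dk
  if (sum(pb) <= 0) stop("spectrally flat field: characteristic length undefined")
  kmean <- sum(pb * kb) / sum(pb)
  2 * pi / kmean
}

#' Mean order parameter in a shell around a granule
#'
#' Measure-weighted mean of \code{psi} over elements whose centroids lie
#' within \code{shell_width} of the granule surface. The simulated
#' counterpart of the matrix halo that forms around calcium phosphate
#' granules.
#'
#' @inheritParams phase_fractions
#' @param granule Granule index in \code{d$granules}.
#' @param shell_width Radial extent of the shell beyond the granule radius.
#' @return Mean of \code{psi} over the shell.
#' @export
granule_halo_mean <- function(d, psi, granule = 1L, shell_width = 0.5) {
  granule_halo_report(d, psi, granule, shell_width)$mean
}

#' Halo composition report around a granule
#'
#' @inheritParams granule_halo_mean
#' @return List with \code{mean} (measure-weighted mean psi in the shell),
#'   \code{membrane_fraction} and \code{matrix_fraction} of the shell, and
#'   the shell \code{measure}.
#' @export
granule_halo_report <- function(d, psi, granule = 1L, shell_width = 0.5) {
  stopifnot(inherits(d, "ch_domain"))
  check_field(d, psi, "psi")
  if (granule < 1L || granule > length(d$granules)) {
    stop("domain has no granule with index ", granule)
  }
  g <- d$granules[[granule]]
  cent <- facet_midpoints(d$nodes, d$elements)  # element centroids
  dist <- sqrt(rowSums(sweep(cent, 2L, g$center, "-")^2)) - g$radius
  sel <- dist >= 0 & dist <= shell_width
  if (!any(sel)) stop("empty halo shell: shell_width smaller than the mesh size")
  meas <- element_measures(d)[sel]
  ve <- element_values(d, psi)[sel, , drop = FALSE]
  w <- rowMeans(ve)
  pos <- simplex_positive_fraction(ve, d$dim)
  neg <- simplex_positive_fraction(-ve, d$dim)
  list(mean = sum(meas * w) / sum(meas),
       matrix_fraction = sum(meas * pos) / sum(meas),
       membrane_fraction = sum(meas * neg) / sum(meas),
       measure = sum(meas))
}

#' Full morphometry report
#'
#' Convenience wrapper returning every morphometric of a state in one list.
#'
#' @inheritParams phase_fractions
#' @param shell_width Halo shell width used when granules are present.
#' @param spectral Also compute the spectral characteristic length.
#' @return List of class \code{ch_morphometry}.
#' @export
morphometry_report <- function(d, psi, shell_width = 0.5,
                               spectral = (d$dim == 2L)) {
  pf <- phase_fractions(d, psi)
  cl <- NA_real_
  if (spectral && d$dim >= 2L) {
    cl <- tryCatch(characteristic_length(resample_to_grid(d, psi)),
                   error = function(e) NA_real_)
  }
  halo <- NULL
  if (length(d$granules)) {
    halo <- lapply(seq_along(d$granules), function(g) {
      granule_halo_report(d, psi, g, shell_width)
    })
  }
  structure(list(matrix_fraction = pf[["matrix_fraction"]],
                 membrane_fraction = pf[["membrane_fraction"]],
                 interface_measure = interface_measure(d, psi),
                 n_membrane_components = count_phase_components(d, psi, "membrane"),
                 characteristic_length = cl, granule_halos = halo),
            class = "ch_morphometry")
}

#' @exportS3Method base::print
print.ch_morphometry <- function(x, ...) {
  cat(sprintf("<ch_morphometry> matrix %.4f / membrane %.4f, interface %.4g, %d membrane component(s), char. length %s\n",
              x$matrix_fraction, x$membrane_fraction, x$interface_measure,
              x$n_membrane_components,
              if (is.na(x$characteristic_length)) "NA" else
                sprintf("%.4g", x$characteristic_length)))
  invisible(x)
}
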