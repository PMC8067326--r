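# P1 finite-element operators on ch_domain meshes: consistent mass matrix M,
# stiffness matrix K (the bilinear form a(u,v) = (grad u, grad v)), element
# measures and quadrature rules. Assembled once per domain and cached.

element_coord_list <- function(d) {
  nv <- d$dim + 1L
  lapply(seq_len(nv), function(i) d$nodes[d$elements[, i], , drop = FALSE])
}

element_measures <- function(d) {
  if (!is.null(d$cache$meas)) return(d$cache$meas)
  meas <- if (isTRUE(d$periodic) && d$dim == 1L) d$elem_len
          else abs(simplex_measures(d$nodes, d$elements))
  d$cache$meas <- meas
  meas
}

# Assemble (M, K); cached in the domain environment.
fem_matrices <- function(d) {
  if (!is.null(d$cache$fem)) return(d$cache$fem)
  n <- nrow(d$nodes)
  el <- d$elements
  m <- nrow(el)
  dim <- d$dim
  nv <- dim + 1L
  meas <- element_measures(d)

  if (dim == 1L) {
    len <- meas
    grads <- cbind(-1 / len, 1 / len)  # d(basis)/dx per element
  } else if (dim == 2L) {
    p <- element_coord_list(d)
    x1 <- p[[1]][, 1]; y1 <- p[[1]][, 2]
    x2 <- p[[2]][, 1]; y2 <- p[[2]][, 2]
    x3 <- p[[3]][, 1]; y3 <- p[[3]][, 2]
    det2 <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
    bx <- cbind(y2 - y3, y3 - y1, y1 - y2) / det2
    by <- cbind(x3 - x2, x1 - x3, x2 - x1) / det2
    grads <- list(bx, by)
  } else {
    p <- element_coord_list(d)
    a <- p[[2]] - p[[1]]; b <- p[[3]] - p[[1]]; cc <- p[[4]] - p[[1]]
    det3 <- a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
            a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
            a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
    # rows of inverse of [a; b; c] via cofactors: grad lambda_{2,3,4}
    g2 <- cbind(b[, 2] * cc[, 3] - b[, 3] * cc[, 2],
                b[, 3] * cc[, 1] - b[, 1] * cc[, 3],
                b[, 1] * cc[, 2] - b[, 2] * cc[, 1]) / det3
    g3 <- cbind(cc[, 2] * a[, 3] - cc[, 3] * a[, 2],
                cc[, 3] * a[, 1] - cc[, 1] * a[, 3],
                cc[, 1] * a[, 2] - cc[, 2] * a[, 1]) / det3
    g4 <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                a[, 3] * b[, 1] - a[, 1] * b[, 3],
                a[, 1] * b[, 2] - a[, 2] * b[, 1]) / det3
    g1 <- -(g2 + g3 + g4)
    grads <- list(gx = cbind(g1[, 1], g2[, 1], g3[, 1], g4[, 1]),
                  gy = cbind(g1[, 2], g2[, 2], g3[, 2], g4[, 2]),
                  gz = cbind(g1[, 3], g2[, 3], g3[, 3], g4[, 3]))
  }

  idx_i <- integer(0); idx_j <- integer(0)
  kx <- numeric(0); mx <- numeric(0)
  for (i in seq_len(nv)) {
    for (j in seq_len(nv)) {
      if (dim == 1L) {
        kij <- meas * grads[, i] * grads[, j]
      } else if (dim == 2L) {
        kij <- meas * (grads[[1]][, i] * grads[[1]][, j] +
                       grads[[2]][, i] * grads[[2]][, j])
      } else {
        kij <- meas * (grads[[1]][, i] * grads[[1]][, j] +
                       grads[[2]][, i] * grads[[2]][, j] +
                       grads[[3]][, i] * grads[[3]][, j])
      }
      mij <- meas * (1 + (i == j)) / ((nv) * (nv + 1L))
      idx_i <- c(idx_i, el[, i]); idx_j <- c(idx_j, el[, j])
      kx <- c(kx, kij); mx <- c(mx, mij)
    }
  }
  K <- Matrix::sparseMatrix(i = idx_i, j = idx_j, x = kx, dims = c(n, n))
  M <- Matrix::sparseMatrix(i = idx_i, j = idx_j, x = mx, dims = c(n, n))
  # triplet form of M, used for fast Jacobian updates in the solver
  Mt <- methods::as(M, "TsparseMatrix")
  out <- list(M = M, K = K,
              M_i = Mt@i + 1L, M_j = Mt@j + 1L, M_x = Mt@x, n = n)
  d$cache$fem <- out
  out
}

# quadrature rules in barycentric coordinates; exact gradient term is handled
# through K, these rules integrate the nonlinear bulk density
quad_rule <- function(dim) {
  if (dim == 1L) {
    # 3-point Gauss (degree 5): exact for the quartic double well on P1 fields
    s <- sqrt(3 / 5) / 2
    list(bary = rbind(c(0.5 + s, 0.5 - s), c(0.5, 0.5), c(0.5 - s, 0.5 + s)),
         w = c(5, 8, 5) / 18)
  } else if (dim == 2L) {
    # edge-midpoint rule (degree 2)
    list(bary = rbind(c(0.5, 0.5, 0), c(0, 0.5, 0.5), c(0.5, 0, 0.5)),
         w = rep(1 / 3, 3))
  } else {
    a <- (5 + 3 * sqrt(5)) / 20
    b <- (5 - sqrt(5)) / 20
    list(bary = rbind(c(a, b, b, b), c(b, a, b, b), c(b, b, a, b), c(b, b, b, a)),
         w = rep(1 / 4, 4))
  }
}

# nodal values per element (n_elem x n_vert)
element_values <- function(d, v) {
  matrix(v[d$elements], nrow = nrow(d$elements))
}

# integral over the domain of fun(field) using the bulk quadrature rule
quad_integral <- function(d, v, fun) {
  qr <- quad_rule(d$dim)
  ve <- element_values(d, v)
  meas <- element_measures(d)
  acc <- 0
  for (q in seq_along(qr$w)) {
    vals <- as.vector(ve %*% qr$bary[q, ])
    acc <- acc + qr$w[q] * sum(meas * fun(vals))
  }
  acc
}

check_field <- function(d, v, what = "field") {
  if (!is.numeric(v)) stop(what, " must be numeric")
  if (length(v) != nrow(d$nodes)) {
    stop(sprintf("%s has %d values but the domain has %d nodes",
                 what, length(v), nrow(d$nodes)))
  }
  invisible(TRUE)
}
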