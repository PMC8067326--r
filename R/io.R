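# Reproducibility shell: YAML run configuration with validation and default
# provenance, ParaView-readable VTU snapshots, exact checkpoint round trips,
# deterministic time-series CSV output, and the analytic test fixtures.

config_defaults <- list(
  domain = list(shape = "disk", size_params = 4, h_target = 0.15),
  solver = list(gamma = 1, dt = 1e-3, theta = 0.5, mobility = 0.5,
                n_steps = 1000L, newton_abs_tol = 1e-10, newton_rel_tol = 1e-8,
                newton_max_iter = 25L, seed = 1L, init_mean = 0,
                init_amplitude = 0.05),
  output = list(directory = ".", record_every = 250L, snapshot_every = 0L,
                write_snapshots = FALSE)
)

#' Load and validate a run configuration
#'
#' Reads a YAML file with sections \code{domain}, \code{granules},
#' \code{solver} and \code{output}. Unknown keys raise an error naming them;
#' missing keys are filled from documented defaults and the defaulted field
#' paths are recorded in the \code{"defaulted"} attribute. The parse ->
#' \code{\link{write_config}} -> parse round trip is the identity.
#'
#' @param path Path to a YAML configuration file.
#' @return A validated list of class \code{ch_config}.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  validate_config(raw, source = path)
}

#' @rdname load_config
#' @param config A configuration list (as parsed from YAML).
#' @param source Label used in error messages.
#' @export
validate_config <- function(config, source = "config") {
  known_sections <- c("domain", "granules", "solver", "output")
  extra <- setdiff(names(config), known_sections)
  if (length(extra)) stop("unknown config section(s): ", paste(extra, collapse = ", "))
  defaulted <- character(0)
  out <- list()
  for (sec in c("domain", "solver", "output")) {
    given <- config[[sec]]
    if (is.null(given)) given <- list()
    extra <- setdiff(names(given), names(config_defaults[[sec]]))
    if (length(extra)) {
      stop(sprintf("unknown key(s) in [%s]: %s", sec, paste(extra, collapse = ", ")))
    }
    merged <- config_defaults[[sec]]
    for (k in names(given)) merged[[k]] <- given[[k]]
    miss <- setdiff(names(merged), names(given))
    defaulted <- c(defaulted, if (length(miss)) paste(sec, miss, sep = "."))
    out[[sec]] <- merged
  }
  grans <- config$granules
  out$granules <- list()
  if (!is.null(grans) && length(grans)) {
    out$granules <- lapply(seq_along(grans), function(i) {
      g <- grans[[i]]
      extra <- setdiff(names(g), c("center", "radius", "value"))
      if (length(extra)) {
        stop(sprintf("unknown key(s) in [granules][%d]: %s", i,
                     paste(extra, collapse = ", ")))
      }
      if (is.null(g$center) || is.null(g$radius)) {
        stop(sprintf("granule %d needs center and radius", i))
      }
      if (is.null(g$value)) g$value <- 1
      list(center = as.numeric(unlist(g$center)), radius = as.numeric(g$radius),
           value = as.numeric(g$value))
    })
  }
  out$domain$shape <- match.arg(out$domain$shape,
                                c("disk", "ellipse", "sphere", "ellipsoid"))
  s <- out$solver
  if (s$theta < 0 || s$theta > 1) {
    stop("config error at solver.theta: must lie in [0, 1], got ", s$theta)
  }
  for (f in c("gamma", "dt", "mobility", "newton_abs_tol", "newton_rel_tol")) {
    if (s[[f]] <= 0) stop("config error at solver.", f, ": must be positive")
  }
  if (abs(s$init_mean) + s$init_amplitude > 1) {
    stop("config error at solver.init_mean/init_amplitude: |mean| + amplitude must be <= 1")
  }
  if (out$domain$h_target <= 0) stop("config error at domain.h_target: must be positive")
  structure(out, defaulted = sort(defaulted), class = "ch_config")
}

#' Write a configuration echo
#'
#' @param config A \code{ch_config}.
#' @param path Output YAML path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "ch_config"))
  x <- unclass(config)
  attr(x, "defaulted") <- NULL
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' @exportS3Method base::print
print.ch_config <- function(x, ...) {
  cat(sprintf("<ch_config> %s (%s), %d granule(s), %d steps at dt %g, seed %d\n",
              x$domain$shape, paste(format(x$domain$size_params), collapse = " x "),
              length(x$granules), x$solver$n_steps, x$solver$dt, x$solver$seed))
  d <- attr(x, "defaulted")
  if (length(d)) cat("  defaulted:", paste(d, collapse = ", "), "\n")
  invisible(x)
}

config_domain <- function(config) {
  grans <- lapply(config$granules, function(g) granule(g$center, g$radius, g$value))
  build_domain(config$domain$shape, config$domain$size_params, grans,
               h_target = config$domain$h_target)
}

config_solver <- function(config, seed = NULL) {
  s <- config$solver
  solver_config(gamma = s$gamma, dt = s$dt, theta = s$theta,
                mobility = s$mobility, newton_abs_tol = s$newton_abs_tol,
                newton_rel_tol = s$newton_rel_tol,
                newton_max_iter = s$newton_max_iter,
                seed = if (is.null(seed)) s$seed else seed,
                record_every = config$output$record_every,
                init_mean = s$init_mean, init_amplitude = s$init_amplitude)
}

#' Run a simulation described by a configuration
#'
#' Builds the domain, draws the seeded random initial field, runs the
#' theta-method solver, and writes the echoed config, the time-series CSV
#' and (optionally) VTU snapshots into the output directory. Two runs with
#' the same config and seed produce byte-identical CSVs.
#'
#' @param config A \code{ch_config} (see \code{\link{load_config}}).
#' @param seed Optional seed overriding \code{solver.seed}.
#' @param n_steps Optional step-count override (e.g. smoke tests).
#' @param output_dir Optional override of \code{output.directory}.
#' @param verbose Log a line per record step.
#' @return The \code{ch_run}, invisibly.
#' @export
simulate_config <- function(config, seed = NULL, n_steps = NULL,
                            output_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "ch_config"))
  dir <- if (is.null(output_dir)) config$output$directory else output_dir
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- config_domain(config)
  cfg <- config_solver(config, seed)
  steps <- if (is.null(n_steps)) config$solver$n_steps else n_steps
  psi0 <- initialize_random(d, config$solver$init_mean,
                            config$solver$init_amplitude, cfg$seed)
  sinks <- NULL
  if (isTRUE(config$output$write_snapshots) || config$output$snapshot_every > 0) {
    every <- max(1L, config$output$snapshot_every)
    sinks <- list(function(st, dom) {
      if (st$step %% every == 0L || st$step == steps) {
        write_snapshot(dom, st, file.path(dir, sprintf("snapshot_%06d.vtu", st$step)),
                       gamma = cfg$gamma)
      }
    })
  }
  run <- run_simulation(d, psi0, cfg, steps, sinks = sinks, verbose = verbose)
  write_config(config, file.path(dir, "config_echo.yaml"))
  utils::write.csv(format_records(run$records), file.path(dir, "timeseries.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(run)
}

# fixed-format record table so CSV output is byte-stable across platforms
format_records <- function(records) {
  out <- records
  for (nm in names(out)) {
    if (is.double(out[[nm]])) out[[nm]] <- sprintf("%.12e", out[[nm]])
  }
  out
}

# --- VTU snapshots ----------------------------------------------------------

vtk_cell_type <- function(dim) c(`1` = 3L, `2` = 5L, `3` = 10L)[[as.character(dim)]]
vtk_facet_type <- function(dim) c(`1` = 1L, `2` = 3L, `3` = 5L)[[as.character(dim)]]

#' Write a ParaView-readable VTU snapshot
#'
#' Serializes the mesh with point-data arrays \code{psi} and \code{mu},
#' boundary facets appended as extra cells carrying a \code{boundary_tag}
#' cell array (-1 interior element, 0 outer boundary, granule index
#' otherwise), and field data \code{step}, \code{time}, \code{gamma}.
#' Coordinates and fields are written with 17 significant digits, so a read
#' back reproduces them exactly.
#'
#' @param d A \code{ch_domain}.
#' @param state A \code{\link{ch_state}} (or a list with \code{psi},
#'   \code{mu}, \code{step}, \code{time}).
#' @param path Output file path.
#' @param gamma Value recorded in the field data.
#' @return \code{path}, invisibly.
#' @export
write_snapshot <- function(d, state, path, gamma = 1) {
  stopifnot(inherits(d, "ch_domain"))
  check_field(d, state$psi, "psi")
  mu <- if (is.null(state$mu)) rep(0, nrow(d$nodes)) else state$mu
  n <- nrow(d$nodes)
  pts <- d$nodes
  if (ncol(pts) < 3L) pts <- cbind(pts, matrix(0, n, 3L - ncol(pts)))
  cells <- lapply(seq_len(nrow(d$elements)), function(e) d$elements[e, ])
  types <- rep(vtk_cell_type(d$dim), nrow(d$elements))
  tags <- rep(-1L, nrow(d$elements))
  if (!is.null(d$facets) && nrow(d$facets)) {
    cells <- c(cells, lapply(seq_len(nrow(d$facets)), function(f) d$facets[f, ]))
    types <- c(types, rep(vtk_facet_type(d$dim), nrow(d$facets)))
    tags <- c(tags, d$facet_tag)
  }
  conn <- unlist(cells) - 1L
  offs <- cumsum(lengths(cells))
  num <- function(x) paste(sprintf("%.17g", x), collapse = " ")
  con <- file(path, open = "wt")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('  <UnstructuredGrid>')
  w('    <FieldData>')
  w('      <DataArray type="Int32" Name="step" NumberOfTuples="1" format="ascii">%d</DataArray>',
    as.integer(state$step))
  w('      <DataArray type="Float64" Name="time" NumberOfTuples="1" format="ascii">%.17g</DataArray>',
    as.numeric(state$time))
  w('      <DataArray type="Float64" Name="gamma" NumberOfTuples="1" format="ascii">%.17g</DataArray>',
    gamma)
  w('    </FieldData>')
  w('    <Piece NumberOfPoints="%d" NumberOfCells="%d">', n, length(cells))
  w('      <Points>')
  w('        <DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  writeLines(apply(pts, 1L, num), con)
  w('        </DataArray>')
  w('      </Points>')
  w('      <Cells>')
  w('        <DataArray type="Int32" Name="connectivity" format="ascii">')
  writeLines(paste(conn, collapse = " "), con)
  w('        </DataArray>')
  w('        <DataArray type="Int32" Name="offsets" format="ascii">')
  writeLines(paste(offs, collapse = " "), con)
  w('        </DataArray>')
  w('        <DataArray type="UInt8" Name="types" format="ascii">')
  writeLines(paste(types, collapse = " "), con)
  w('        </DataArray>')
  w('      </Cells>')
  w('      <PointData Scalars="psi">')
  w('        <DataArray type="Float64" Name="psi" format="ascii">')
  writeLines(num(state$psi), con)
  w('        </DataArray>')
  w('        <DataArray type="Float64" Name="mu" format="ascii">')
  writeLines(num(mu), con)
  w('        </DataArray>')
  w('      </PointData>')
  w('      <CellData Scalars="boundary_tag">')
  w('        <DataArray type="Int32" Name="boundary_tag" format="ascii">')
  writeLines(paste(tags, collapse = " "), con)
  w('        </DataArray>')
  w('      </CellData>')
  w('    </Piece>')
  w('  </UnstructuredGrid>')
  w('</VTKFile>')
  invisible(path)
}

#' Read back a VTU snapshot
#'
#' Minimal reader for files produced by \code{\link{write_snapshot}}.
#'
#' @param path VTU file path.
#' @return List with \code{nodes}, \code{cells}, \code{cell_types},
#'   \code{boundary_tag}, \code{psi}, \code{mu}, \code{step}, \code{time},
#'   \code{gamma}.
#' @export
read_snapshot <- function(path) {
  doc <- xml2::read_xml(path)
  getnum <- function(xp) {
    scan(text = xml2::xml_text(xml2::xml_find_first(doc, xp)), quiet = TRUE)
  }
  pts <- matrix(getnum(".//Points/DataArray"), ncol = 3L, byrow = TRUE)
  conn <- as.integer(getnum(".//Cells/DataArray[@Name='connectivity']")) + 1L
  offs <- as.integer(getnum(".//Cells/DataArray[@Name='offsets']"))
  types <- as.integer(getnum(".//Cells/DataArray[@Name='types']"))
  starts <- c(1L, utils::head(offs, -1L) + 1L)
  cells <- mapply(function(s, e) conn[s:e], starts, offs, SIMPLIFY = FALSE)
  list(nodes = pts, cells = cells, cell_types = types,
       boundary_tag = as.integer(getnum(".//CellData/DataArray[@Name='boundary_tag']")),
       psi = getnum(".//PointData/DataArray[@Name='psi']"),
       mu = getnum(".//PointData/DataArray[@Name='mu']"),
       step = as.integer(getnum(".//FieldData/DataArray[@Name='step']")),
       time = getnum(".//FieldData/DataArray[@Name='time']"),
       gamma = getnum(".//FieldData/DataArray[@Name='gamma']"))
}

# --- checkpoints ------------------------------------------------------------

CHECKPOINT_VERSION <- 1L

#' Write a simulation checkpoint
#'
#' Stores mesh, both fields, step, time and the config echo. Resuming from a
#' checkpoint reproduces the continued trajectory bit-compatibly with an
#' uninterrupted run (the solver is deterministic after initialization).
#'
#' @param path Checkpoint file path.
#' @param d A \code{ch_domain}.
#' @param state A \code{\link{ch_state}}.
#' @param config Optional \code{ch_config} echo to store.
#' @return \code{path}, invisibly.
#' @export
write_checkpoint <- function(path, d, state, config = NULL) {
  stopifnot(inherits(d, "ch_domain"), inherits(state, "ch_state"))
  dd <- unclass(d)
  dd$cache <- NULL   # operators are rebuilt on load
  saveRDS(list(version = CHECKPOINT_VERSION, domain = dd, state = state,
               config = config), path)
  invisible(path)
}

#' Read a simulation checkpoint
#'
#' @param path Checkpoint file path.
#' @return List with \code{domain}, \code{state}, \code{config}.
#' @export
read_checkpoint <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop("corrupt or unreadable checkpoint: ", conditionMessage(e))
  })
  if (!is.list(obj) || is.null(obj$version)) stop("corrupt checkpoint: missing version")
  if (obj$version != CHECKPOINT_VERSION) {
    stop(sprintf("checkpoint version mismatch: file has %s, reader supports %d",
                 obj$version, CHECKPOINT_VERSION))
  }
  dom <- obj$domain
  dom$cache <- new.env(parent = emptyenv())
  class(dom) <- "ch_domain"
  list(domain = dom, state = obj$state, config = obj$config)
}

# --- fixtures ---------------------------------------------------------------

#' Analytic test fixtures
#'
#' Deterministic analytic fields sampled on meshes, shared across the test
#' suite: \code{tanh_strip} (equilibrium interface profile on a strip),
#' \code{circular_interface} (radial interface at radius \code{r0} inside a
#' disk), \code{two_blobs} (two disjoint membrane blobs in a matrix
#' background), \code{sinusoid_mode} (single-mode sinusoid on a square).
#'
#' @param name Fixture name.
#' @param params Named list of parameters overriding the fixture defaults
#'   (\code{gamma}, \code{h}, \code{length}, \code{r0}, \code{radius},
#'   \code{k}, \code{n_periods} as applicable).
#' @return List with \code{domain} and \code{psi}.
#' @export
make_fixture <- function(name = c("tanh_strip", "circular_interface",
                                  "two_blobs", "sinusoid_mode"),
                         params = list()) {
  name <- match.arg(name)
  p <- function(key, default) if (!is.null(params[[key]])) params[[key]] else default
  if (name == "tanh_strip") {
    gamma <- p("gamma", 1); len <- p("length", 16); h <- p("h", 0.1)
    d <- rect_domain(len, 1, h_target = h)
    psi <- equilibrium_profile(d$nodes[, 1L], gamma)
  } else if (name == "circular_interface") {
    R <- p("radius", 3); r0 <- p("r0", 1.5); h <- p("h", 0.1)
    gamma <- p("gamma", 1)
    d <- build_domain("disk", R, h_target = h)
    r <- sqrt(rowSums(d$nodes^2))
    psi <- equilibrium_profile(r0 - r, gamma)
  } else if (name == "two_blobs") {
    h <- p("h", 0.1)
    d <- rect_domain(4, 2, h_target = h)
    x <- d$nodes[, 1L]; y <- d$nodes[, 2L]
    psi <- 0.8 - 1.6 * exp(-((x + 1)^2 + y^2) / 0.09) -
      1.6 * exp(-((x - 1)^2 + y^2) / 0.09)
  } else {
    k <- p("k", 2); n_per <- p("n_periods", 4L); h <- p("h", 0.1)
    L <- n_per * 2 * pi / k
    d <- rect_domain(L, L, h_target = h)
    psi <- 0.5 * sin(k * (d$nodes[, 1L] + L / 2))
  }
  list(domain = d, psi = psi)
}
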