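#' Regular cubic scalar grid
#'
#' A `scalar_grid` is a regular lattice with isotropic spacing carrying one
#' scalar per node: electrostatic potential (kT/e), permittivity
#' (dimensionless) or modified screening \eqn{\bar\kappa^2} (1/Angstrom^2),
#' depending on context.
#'
#' @param origin length-3 vector, position of node (1,1,1) in Angstrom.
#' @param spacing isotropic node spacing in Angstrom (> 0).
#' @param dims integer length-3 vector of node counts (each >= 3).
#' @param values numeric array of dimension `dims`, or a single value to
#'   fill with (default 0).
#' @return object of class `scalar_grid`.
#' @export
scalar_grid <- function(origin, spacing, dims, values = 0) {
  stopifnot(length(origin) == 3, all(is.finite(origin)),
            length(spacing) == 1, spacing > 0,
            length(dims) == 3, all(dims >= 3))
  dims <- as.integer(dims)
  if (length(values) == 1) values <- array(values, dim = dims)
  stopifnot(identical(dim(values), dims))
  if (any(!is.finite(values))) stop("grid values must be finite")
  structure(list(origin = as.numeric(origin), spacing = as.numeric(spacing),
                 dims = dims, values = values),
            class = "scalar_grid")
}

#' @export
print.scalar_grid <- function(x, ...) {
  cat(sprintf("scalar_grid: %dx%dx%d nodes, spacing %.4g A, origin (%.3g, %.3g, %.3g)\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing,
              x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  values: [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' Node coordinates along one grid axis
#' @param g a `scalar_grid`.
#' @param axis 1, 2 or 3.
#' @return numeric vector of node positions (Angstrom).
#' @export
grid_axis <- function(g, axis) {
  stopifnot(inherits(g, "scalar_grid"), axis %in% 1:3)
  g$origin[axis] + (seq_len(g$dims[axis]) - 1) * g$spacing
}

#' Trilinear interpolation of grid values at arbitrary points
#'
#' @param g a `scalar_grid`.
#' @param pts n x 3 matrix of positions (Angstrom); all points must lie
#'   inside the grid.
#' @return numeric vector of interpolated values.
#' @export
trilinear_interp <- function(g, pts) {
  stopifnot(inherits(g, "scalar_grid"))
  pts <- matrix(as.numeric(pts), ncol = 3)
  t <- sweep(pts, 2, g$origin) / g$spacing
  eps <- 1e-9
  if (any(t < -eps) || any(sweep(t, 2, g$dims - 1) > eps))
    stop("point outside grid in trilinear interpolation")
  t <- pmin(pmax(t, 0), matrix(rep(g$dims - 1, each = nrow(t)), ncol = 3))
  i0 <- pmin(floor(t), matrix(rep(g$dims - 2, each = nrow(t)), ncol = 3))
  f <- t - i0
  nx <- g$dims[1]; ny <- g$dims[2]
  lin <- function(dx, dy, dz)
    1 + (i0[, 1] + dx) + nx * ((i0[, 2] + dy) + ny * (i0[, 3] + dz))
  w <- function(dx, dy, dz)
    (if (dx == 1) f[, 1] else 1 - f[, 1]) *
    (if (dy == 1) f[, 2] else 1 - f[, 2]) *
    (if (dz == 1) f[, 3] else 1 - f[, 3])
  v <- as.vector(g$values)
  out <- numeric(nrow(pts))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1)
    out <- out + w(dx, dy, dz) * v[lin(dx, dy, dz)]
  out
}

#' Build the calculation grid for a structure
#'
#' Cubic grid centered on the bounding-box center of the atom spheres
#' (coordinates +/- radius, treating unset radii as 0). The box edge is the
#' largest structure extent divided by `fill_percent/100` (e.g. extent 35 A
#' at 70% fill gives a 50 A box), floored at `min_edge`. Node count per axis
#' is the largest odd value <= `settings$max_dims` unless `spacing` is given,
#' in which case dims are chosen to honour it (capped at `max_dims`).
#'
#' @param x a [struct3d()].
#' @param settings a [solver_settings()] (uses `fill_percent`, `max_dims`).
#' @param spacing optional target node spacing (Angstrom).
#' @param dims optional explicit node count per axis (scalar, made odd).
#' @param min_edge minimum box edge in Angstrom (default 20).
#' @return a `scalar_grid` with zero values (geometry carrier).
#' @export
build_grid <- function(x, settings = solver_settings(), spacing = NULL,
                       dims = NULL, min_edge = 20) {
  stopifnot(inherits(x, "struct3d"))
  fill <- settings$fill_percent
  if (!is.numeric(fill) || fill <= 0 || fill >= 100)
    stop("fill_percent must lie strictly between 0 and 100")
  xyz <- coords(x)
  r <- ifelse(is.na(x$atoms$radius), 0, x$atoms$radius)
  lo <- apply(xyz - r, 2, min); hi <- apply(xyz + r, 2, max)
  extent <- max(hi - lo)
  edge <- max(extent / (fill / 100), min_edge)
  center <- (lo + hi) / 2
  maxd <- settings$max_dims
  odd <- function(n) { n <- as.integer(n); if (n %% 2 == 0) n + 1L else n }
  if (!is.null(dims)) {
    nd <- odd(dims)
  } else if (!is.null(spacing)) {
    nd <- min(odd(ceiling(edge / spacing) + 1), odd(maxd))
  } else {
    nd <- odd(maxd)
  }
  if (nd < 3) stop("grid must have at least 3 nodes per axis")
  h <- edge / (nd - 1)
  scalar_grid(center - edge / 2, h, c(nd, nd, nd))
}

#' Write a scalar grid in OpenDX format
#'
#' The plain-text OpenDX dialect consumed by common molecular viewers
#' (regular positions/connections, rank-0 double data, 3 values per line,
#' z-index varying fastest).
#'
#' @param g a `scalar_grid`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dx <- function(g, path) {
  stopifnot(inherits(g, "scalar_grid"))
  d <- g$dims
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# OpenDX scalar grid written by ifacelec",
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.6e %.6e %.6e", g$origin[1], g$origin[2], g$origin[3]),
    sprintf("delta %.6e 0.000000e+00 0.000000e+00", g$spacing),
    sprintf("delta 0.000000e+00 %.6e 0.000000e+00", g$spacing),
    sprintf("delta 0.000000e+00 0.000000e+00 %.6e", g$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))), con)
  v <- as.vector(aperm(g$values, c(3, 2, 1)))  # z fastest in memory -> x slowest on disk
  n <- length(v)
  pad <- (3 - n %% 3) %% 3
  vv <- c(v, rep(NA_real_, pad))
  m <- matrix(sprintf("%.6e", vv), ncol = 3, byrow = TRUE)
  lines <- apply(m, 1, function(r) paste(r[!grepl("NA", r)], collapse = " "))
  writeLines(lines, con)
  writeLines(c('attribute "dep" string "positions"',
               'object "regular positions regular connections" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
  invisible(path)
}

#' Read a scalar grid from an OpenDX file
#'
#' Only isotropic, axis-aligned grids (as written by [write_dx()]) are
#' supported; anisotropic or rotated deltas raise an error.
#'
#' @param path OpenDX file path.
#' @return a `scalar_grid`.
#' @export
read_dx <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines)]
  gp <- grep("class gridpositions counts", lines, value = TRUE)
  if (length(gp) != 1) stop("malformed DX header: gridpositions line missing")
  dims <- as.integer(strsplit(trimws(sub(".*counts", "", gp)), "[[:space:]]+")[[1]])
  if (length(dims) != 3 || anyNA(dims)) stop("malformed DX header: bad counts")
  org_line <- grep("^origin", lines, value = TRUE)
  if (length(org_line) != 1) stop("malformed DX header: origin line missing")
  origin <- as.numeric(strsplit(trimws(sub("^origin", "", org_line)), "[[:space:]]+")[[1]])
  deltas <- lapply(grep("^delta", lines, value = TRUE), function(l)
    as.numeric(strsplit(trimws(sub("^delta", "", l)), "[[:space:]]+")[[1]]))
  if (length(deltas) != 3) stop("malformed DX header: expected 3 delta lines")
  dmat <- do.call(rbind, deltas)
  if (any(abs(dmat - diag(diag(dmat))) > 1e-12))
    stop("unsupported DX grid: deltas are not axis-aligned")
  sp <- diag(dmat)
  if (max(abs(sp - sp[1])) > 1e-9 * sp[1])
    stop("unsupported DX grid: non-uniform spacing (only isotropic grids supported)")
  istart <- grep("data follows", lines)
  if (length(istart) != 1) stop("malformed DX header: data section missing")
  n <- prod(dims)
  vals <- numeric(0)
  i <- istart + 1
  while (length(vals) < n && i <= length(lines)) {
    if (grepl("^(attribute|object|component)", lines[i])) break
    vals <- c(vals, as.numeric(strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]))
    i <- i + 1
  }
  if (length(vals) != n || anyNA(vals))
    stop(sprintf("malformed DX data: expected %d values, got %d", n, length(vals)))
  arr <- aperm(array(vals, dim = rev(dims)), c(3, 2, 1))
  scalar_grid(origin, sp[1], dims, arr)
}
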