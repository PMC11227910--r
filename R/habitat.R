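#' Quadrat elevation from corner elevations
#'
#' Mean of the four corner elevations; invariant to corner ordering.
#' @param corners numeric length-4 (meters), no missing values.
#' @return numeric, meters.
#' @export
quadrat_elevation <- function(corners) {
  if (length(corners) != 4 || anyNA(corners))
    stop("need 4 non-missing corner elevations")
  mean(corners)
}

#' Convexity of each cell of an elevation grid
#'
#' Interior cells: cell elevation minus the mean elevation of the eight
#' neighboring cells (positive on ridges, negative in valleys). Edge cells
#' lack some neighbors; their convexity is the cell elevation minus the
#' mean of the available neighbors together with the cell's own four corner
#' elevations when those are supplied (otherwise available neighbors only).
#' Translation-invariant: adding a constant to all elevations changes
#' nothing.
#'
#' @param elev_grid numeric matrix of cell (subplot) elevations, rows =
#'   subplot_row, cols = subplot_col.
#' @param corner_grid optional array `dim = c(nrow, ncol, 4)` of per-cell
#'   corner elevations used in the edge rule.
#' @return matrix of convexities, same shape; attribute `edge` flags cells
#'   computed with the edge rule.
#' @export
convexity_grid <- function(elev_grid, corner_grid = NULL) {
  nr <- nrow(elev_grid); nc <- ncol(elev_grid)
  out <- matrix(NA_real_, nr, nc)
  edge <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    rr <- max(1, r - 1):min(nr, r + 1)
    cc <- max(1, c - 1):min(nc, c + 1)
    nb <- elev_grid[rr, cc]
    nb <- nb[-(which(rr == r) + (which(cc == c) - 1) * length(rr))]
    interior <- length(nb) == 8L
    ref <- if (interior || is.null(corner_grid)) mean(nb)
           else mean(c(nb, corner_grid[r, c, ]))
    out[r, c] <- elev_grid[r, c] - ref
    edge[r, c] <- !interior
  }
  attr(out, "edge") <- edge
  out
}

#' Slope of a square cell from its corner elevations
#'
#' Mean angular deviation from horizontal of the four triangular planes
#' obtained by dropping each corner in turn. Corners are given in
#' perimeter order SW, SE, NE, NW for a square of side `side_m`.
#'
#' @param corners numeric length-4 corner elevations, meters.
#' @param side_m cell side length, meters.
#' @return slope in degrees.
#' @export
slope_from_corners <- function(corners, side_m = 2) {
  if (length(corners) != 4 || anyNA(corners))
    stop("need 4 non-missing corner elevations")
  s <- side_m
  pts <- rbind(c(0, 0, corners[1]), c(s, 0, corners[2]),
               c(s, s, corners[3]), c(0, s, corners[4]))
  ang <- vapply(1:4, function(drop_i) {
    tri <- pts[-drop_i, , drop = FALSE]
    n <- .cross3(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])
    acos(abs(n[3]) / sqrt(sum(n^2))) * 180 / pi
  }, numeric(1))
  mean(ang)
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Attach topographic variables to the habitat table
#'
#' Computes per-quadrat elevation (mean of the quadrat's four corner
#' elevations), slope (mean triangular-plane deviation over the quadrat
#' square) and convexity (quadrat elevation minus the mean of the eight
#' neighboring quadrats on the subplot grid, edge rule as in
#' [convexity_grid()]), and merges them into `plot$habitat` as columns
#' `elevation`, `convexity`, `slope`.
#'
#' @param plot a [plot_dataset()] whose quadrats carry `elev_c1..elev_c4`.
#' @param quadrat_m quadrat side for the slope computation, meters.
#' @return the plot with an augmented `habitat` table.
#' @export
add_topography <- function(plot, quadrat_m = 2) {
  qd <- plot$quadrats
  corners <- as.matrix(qd[, paste0("elev_c", 1:4)])
  elev <- rowMeans(corners)
  slope <- apply(corners, 1, slope_from_corners, side_m = quadrat_m)

  nr <- max(qd$subplot_row) + 1L; nc <- max(qd$subplot_col) + 1L
  grid <- matrix(NA_real_, nr, nc)
  grid[cbind(qd$subplot_row + 1L, qd$subplot_col + 1L)] <- elev
  cg <- array(NA_real_, c(nr, nc, 4))
  for (k in 1:4)
    cg[cbind(qd$subplot_row + 1L, qd$subplot_col + 1L, k)] <- corners[, k]
  cvx <- convexity_grid(grid, cg)
  convexity <- cvx[cbind(qd$subplot_row + 1L, qd$subplot_col + 1L)]

  topo <- data.frame(quadrat_id = qd$quadrat_id, elevation = elev,
                     convexity = convexity, slope = slope)
  hab <- plot$habitat
  plot$habitat <- if (is.null(hab)) topo else {
    hab <- hab[, setdiff(names(hab), c("elevation", "convexity", "slope")),
               drop = FALSE]
    merge(topo, hab, by = "quadrat_id", sort = FALSE)
  }
  plot
}

#' Soil variable columns expected in the habitat table
#' @export
SOIL_VARS <- c("ph", "ec", "c", "ap", "ak", "tn", "tp", "tk",
               "soil_temp", "soil_moist")

#' PCA of the 13 habitat variables
#'
#' Correlation-matrix PCA (each variable z-standardized) of the 3
#' topographic plus 10 soil variables; canopy openness (`gli`) is kept out
#' of the PCA and enters survival models directly. Each component's sign is
#' fixed so that its largest-magnitude loading is positive, making scores
#' deterministic across eigen-solvers. Scores are computed once on the full
#' habitat table and subset — not recomputed — at smaller spatial scales.
#'
#' @param habitat habitat table with columns `quadrat_id`, `elevation`,
#'   `convexity`, `slope` and the ten [SOIL_VARS].
#' @param n_keep number of leading components to expose as scores.
#' @return list: `scores` (data.frame quadrat_id, pca1..pca<n_keep>),
#'   `loadings` (13 x 13), `variance_fraction` (length 13, sums to 1).
#' @export
habitat_pca <- function(habitat, n_keep = 3) {
  vars <- c("elevation", "convexity", "slope", SOIL_VARS)
  .check_columns(habitat, c("quadrat_id", vars), "habitat")
  X <- as.matrix(habitat[, vars])
  if (anyNA(X)) stop("habitat table contains missing values")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance habitat variable: ",
         paste(vars[sds == 0], collapse = ", "))
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  pc$rotation <- sweep(pc$rotation, 2, flip, `*`)
  pc$x <- sweep(pc$x, 2, flip, `*`)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- data.frame(quadrat_id = habitat$quadrat_id,
                       pc$x[, seq_len(n_keep), drop = FALSE])
  names(scores) <- c("quadrat_id", paste0("pca", seq_len(n_keep)))
  list(scores = scores, loadings = pc$rotation, variance_fraction = vf)
}
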