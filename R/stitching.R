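#' Globally consistent tile positions from pairwise offsets
#'
#' Places every tile on the mosaic canvas by weighted least squares: tile 1
#' (grid origin) is anchored at (0, 0) and the remaining positions minimize
#' the squared disagreement with the confident pairwise offset estimates;
#' low-confidence (fallback) edges are down-weighted. The redundancy of a
#' grid's row and column edges lets a single corrupted estimate be voted
#' down by its neighbours.
#'
#' @param offsets List of edges; each element has `a`, `b` (tile indices),
#'   `dx`, `dy` (offset of b relative to a, px) and `confidence` (e.g. a
#'   [pairwise_offset()] result plus the pair indices).
#' @param n_tiles Number of tiles.
#' @return `n_tiles` x 2 matrix of tile origins (columns x_px, y_px),
#'   tile 1 at the origin.
#' @export
global_positions <- function(offsets, n_tiles) {
  if (n_tiles == 1) return(matrix(0, 1, 2, dimnames = list(NULL, c("x_px", "y_px"))))
  ed <- do.call(rbind, lapply(offsets, function(o)
    data.frame(a = o$a, b = o$b, dx = o$dx, dy = o$dy,
               confidence = o$confidence %||% 1)))
  # connectivity check over the undirected edge graph
  comp <- seq_len(n_tiles)
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(ed))) {
      ca <- comp[ed$a[k]]; cb <- comp[ed$b[k]]
      if (ca != cb) { comp[comp == max(ca, cb)] <- min(ca, cb); changed <- TRUE }
    }
    if (!changed) break
  }
  if (length(unique(comp)) > 1) {
    groups <- split(seq_len(n_tiles), comp)
    stop(sprintf("pairwise offset graph is disconnected; components: %s",
                 paste(vapply(groups, function(g)
                   paste0("{", paste(g, collapse = ","), "}"), ""),
                   collapse = " ")))
  }
  w0 <- pmax(ed$confidence, 1e-3)^2
  # design: row k has -1 at tile a, +1 at tile b; tile 1 fixed at 0
  A <- matrix(0, nrow(ed), n_tiles - 1)
  for (k in seq_len(nrow(ed))) {
    if (ed$a[k] > 1) A[k, ed$a[k] - 1] <- -1
    if (ed$b[k] > 1) A[k, ed$b[k] - 1] <- 1
  }
  solve_wls <- function(o, w) {
    AtW <- t(A * w)
    sol <- solve(AtW %*% A + diag(1e-9, ncol(A)), AtW %*% o)
    c(0, sol)
  }
  # robust refit: edges disagreeing with the redundant consensus by more
  # than a few pixels are outliers (decorrelated or featureless overlaps)
  # and are down-weighted so row/column redundancy votes them out. The
  # Cauchy scale is annealed from loose to tight (graduated non-convexity)
  # so good edges are not discarded before a consensus has formed.
  residuals_of <- function(px, py) {
    sqrt((ed$dx - (px[ed$b] - px[ed$a]))^2 +
           (ed$dy - (py[ed$b] - py[ed$a]))^2)
  }
  robust_cost <- function(px, py) {
    sum(w0 * log(1 + (residuals_of(px, py) / 3)^2))
  }
  irls <- function(w) {
    for (it in 1:6) {
      px <- solve_wls(ed$dx, w); py <- solve_wls(ed$dy, w)
      resid <- residuals_of(px, py)
      scale <- max(3, 4 * stats::median(resid))
      w <- w0 / (1 + (resid / scale)^2)
    }
    list(px = solve_wls(ed$dx, w), py = solve_wls(ed$dy, w))
  }
  best <- irls(w0)
  best_cost <- robust_cost(best$px, best$py)
  # a single corrupted edge can drag the squared-error optimum into a
  # basin the reweighting cannot leave (the gauge is only fixed through
  # the anchor tile); leave-out trials on the worst few edges, scored by
  # the robust cost, escape it
  resid <- residuals_of(best$px, best$py)
  for (k in utils::head(order(resid, decreasing = TRUE), 3)) {
    if (resid[k] < 3) next
    w_try <- w0; w_try[k] <- w0[k] * 1e-6
    cand <- irls(w_try)
    cc <- robust_cost(cand$px, cand$py)
    if (cc < best_cost) { best <- cand; best_cost <- cc }
  }
  cbind(x_px = best$px, y_px = best$py)
}

#' Compose tiles into a mosaic
#'
#' Places each tile at its (rounded) pixel position on a canvas sized to
#' the bounding box and blends overlaps with linear feathering: a tile's
#' weight ramps linearly from 0 at its border to 1 at `blend_width_px`
#' pixels inside, and overlapping contributions are weight-averaged. With
#' `blend_width_px = 0` the mosaic is hard-edged and the last tile written
#' wins in overlaps.
#'
#' @param tiles List of tile images (matrices).
#' @param positions Tile origins, `n x 2` (x_px, y_px), as from
#'   [global_positions()].
#' @param blend_width_px Feather width, pixels (default 16).
#' @return Composite matrix.
#' @export
compose <- function(tiles, positions, blend_width_px = 16) {
  positions <- matrix(as.numeric(positions), ncol = 2)
  if (any(!is.finite(positions))) stop("tile positions must be finite")
  n <- length(tiles)
  px <- round(positions[, 1]); py <- round(positions[, 2])
  heights <- vapply(tiles, nrow, 0L); widths <- vapply(tiles, ncol, 0L)
  x0 <- min(px); y0 <- min(py)
  W <- max(px + widths) - x0; H <- max(py + heights) - y0
  acc <- matrix(0, H, W); wacc <- matrix(0, H, W)
  for (k in seq_len(n)) {
    tr <- (py[k] - y0) + seq_len(heights[k])
    tc <- (px[k] - x0) + seq_len(widths[k])
    if (blend_width_px <= 0) {
      acc[tr, tc] <- tiles[[k]]
      wacc[tr, tc] <- 1
    } else {
      er <- pmin(seq_len(heights[k]), rev(seq_len(heights[k])))
      ec <- pmin(seq_len(widths[k]), rev(seq_len(widths[k])))
      wt <- outer(pmin(er / blend_width_px, 1), pmin(ec / blend_width_px, 1))
      acc[tr, tc] <- acc[tr, tc] + tiles[[k]] * wt
      wacc[tr, tc] <- wacc[tr, tc] + wt
    }
  }
  out <- acc
  nz <- wacc > 0
  if (blend_width_px > 0) out[nz] <- acc[nz] / wacc[nz]
  out
}

#' Stitch a scan result into a composite image
#'
#' End-to-end mosaic assembly: pairwise offsets between grid neighbours are
#' estimated by phase correlation seeded with the plan's nominal offsets,
#' refined into globally consistent positions, and feather-blended into one
#' composite. This is how a full serpentine scan's 50 MIP tiles become a
#' single nerve-net image despite the piezo stage's per-move XY error — the
#' 25%/30% overlap leaves enough shared content for registration to absorb
#' the inconsistency.
#'
#' @param scan A `scan_result` from [run_scan()] (MIPs + manifest), or a
#'   list of tiles plus `plan`.
#' @param plan The [plan_serpentine()] plan used for the scan.
#' @param pixel_um Pixel size, µm (to convert nominal offsets to px).
#' @param search_radius_px Registration search radius around nominal;
#'   `NULL` (default) sizes it automatically to 25% of the larger tile
#'   pitch plus a margin, covering a piezo stage's worst-case per-move
#'   error.
#' @param min_confidence Below this, an edge falls back to its nominal
#'   offset and is down-weighted.
#' @param blend_width_px Feather width for composition.
#' @return List: `composite` (matrix), `positions` (tile origins, px),
#'   `offsets` (edge list), `nominal_positions` (px).
#' @export
stitch_scan <- function(scan, plan, pixel_um,
                        search_radius_px = NULL, min_confidence = 0.15,
                        blend_width_px = 16) {
  tiles <- if (inherits(scan, "scan_result")) scan$mips else scan
  tl <- plan$tiles
  if (is.null(search_radius_px))
    search_radius_px <- ceiling(0.3 * max(plan$pitch_x, plan$pitch_y) /
                                  pixel_um) + 8
  n <- nrow(tl)
  stopifnot(length(tiles) == n)
  nominal <- cbind(x_px = tl$x_um / pixel_um, y_px = tl$y_um / pixel_um)
  nominal[, 1] <- nominal[, 1] - min(nominal[, 1])
  nominal[, 2] <- nominal[, 2] - min(nominal[, 2])
  # neighbour edges on the grid (right and up neighbours)
  edges <- list()
  idx <- function(i, j) which(tl$i == i & tl$j == j)
  for (t in seq_len(n)) {
    for (nb in list(c(tl$i[t] + 1L, tl$j[t]), c(tl$i[t], tl$j[t] + 1L))) {
      u <- idx(nb[1], nb[2])
      if (length(u) != 1) next
      nom <- nominal[u, ] - nominal[t, ]
      est <- pairwise_offset(tiles[[t]], tiles[[u]], nom,
                             search_radius_px = search_radius_px,
                             min_confidence = min_confidence)
      edges[[length(edges) + 1]] <- list(a = t, b = u, dx = est$dx,
                                         dy = est$dy,
                                         confidence = est$confidence,
                                         fallback = est$fallback)
    }
  }
  pos <- global_positions(edges, n)
  list(composite = compose(tiles, pos, blend_width_px),
       positions = pos, offsets = edges, nominal_positions = nominal)
}
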