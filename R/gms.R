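# Grid-based motion statistics (GMS) match filtering. The idea: under
# smooth motion, a true correspondence is surrounded by other true
# correspondences that map the same grid-cell neighbourhood in A onto the
# same neighbourhood in B, while a false match lands in a cell pair with
# little such support. A match is kept when the support count in its 3x3
# cell-neighbourhood pair exceeds alpha * sqrt(mean matches per cell).

#' GMS grid configuration
#'
#' @param grid_divisions cells per side G (default 20).
#' @param alpha threshold multiplier on `sqrt(n)` (default 6).
#' @param with_offsets also evaluate the four half-cell-shifted grids and
#'   accept a match passing under any of them (default TRUE); the shifts
#'   remove the arbitrariness of cell boundaries.
#' @param with_rotation reserved flag for rotated-grid variants; not applied
#'   (serial cephalograms are near-upright).
#' @return A list of class `gms_config`.
#' @export
gms_config <- function(grid_divisions = 20, alpha = 6,
                       with_offsets = TRUE, with_rotation = FALSE) {
  if (grid_divisions < 4) stop("`grid_divisions` must be >= 4", call. = FALSE)
  if (alpha <= 0) stop("`alpha` must be positive", call. = FALSE)
  structure(list(grid_divisions = as.integer(grid_divisions), alpha = alpha,
                 with_offsets = isTRUE(with_offsets),
                 with_rotation = isTRUE(with_rotation)),
            class = c("gms_config", "list"))
}

#' Assign keypoints to grid cells
#'
#' Cell index is `floor(G x / w) + G floor(G y / h)` with an optional
#' half-cell shift added before flooring; indices past the last cell clamp
#' to it. Offset index 0..3 selects shift `(0, 0)`, `(1/2, 0)`, `(0, 1/2)`,
#' `(1/2, 1/2)` in cell units.
#'
#' @param x,y keypoint coordinates (0-based pixels).
#' @param width,height image size in pixels.
#' @param grid_divisions cells per side G.
#' @param offset_index integer 0..3.
#' @return Integer cell indices in `0 .. G^2 - 1`.
#' @export
assign_cells <- function(x, y, width, height, grid_divisions, offset_index = 0) {
  g <- grid_divisions
  shift_x <- if (offset_index %in% c(1, 3)) 0.5 else 0
  shift_y <- if (offset_index %in% c(2, 3)) 0.5 else 0
  gx <- floor(g * x / width + shift_x)
  gy <- floor(g * y / height + shift_y)
  gx <- pmin(pmax(gx, 0), g - 1)
  gy <- pmin(pmax(gy, 0), g - 1)
  as.integer(gx + g * gy)
}

#' Filter matches by grid-based motion statistics
#'
#' For every populated cell pair (i in A, j in B) the support is the number
#' of other matches that send the 3x3 cell-neighbourhood of i onto the
#' corresponding 3x3 neighbourhood of j (same relative offsets; cells
#' falling off the grid contribute nothing). Every match in (i, j) is
#' accepted when `support > alpha * sqrt(n_i)` with `n_i` the mean number
#' of matches per in-grid A-cell over the neighbourhood of i. With
#' `with_offsets = TRUE` a match is an inlier if it is accepted under any
#' of the four half-cell-shifted grids.
#'
#' @param matches data frame `ia`, `ib`, `distance` from
#'   [match_bruteforce].
#' @param kps_a,kps_b keypoint data frames (`x`, `y`) for the two films.
#' @param size_a,size_b `(width, height)` of the two (sub-)images the
#'   keypoint coordinates live in.
#' @param config a [gms_config].
#' @return Logical inlier mask, one flag per match.
#' @export
gms_filter <- function(matches, kps_a, kps_b, size_a, size_b,
                       config = gms_config()) {
  n <- nrow(matches)
  if (n == 0) return(logical(0))
  if (n < 10) {
    warning("fewer than 10 matches; motion statistics undefined, all rejected")
    return(rep(FALSE, n))
  }
  g <- config$grid_divisions
  offsets <- if (config$with_offsets) 0:3 else 0
  inlier <- rep(FALSE, n)
  xa <- kps_a$x[matches$ia]; ya <- kps_a$y[matches$ia]
  xb <- kps_b$x[matches$ib]; yb <- kps_b$y[matches$ib]
  for (off in offsets) {
    ca <- assign_cells(xa, ya, size_a[1], size_a[2], g, off)
    cb <- assign_cells(xb, yb, size_b[1], size_b[2], g, off)
    inlier <- inlier | gms_accept_one_grid(ca, cb, g, config$alpha)
  }
  inlier
}

# Acceptance decision for one grid assignment: the support of cell pair
# (i, j) is the sum over the 9 neighbourhood offsets (dx, dy) of the match
# count from cell i+(dx,dy) to cell j+(dx,dy), evaluated once per populated
# cell pair from a dense count matrix.
gms_accept_one_grid <- function(ca, cb, g, alpha) {
  nc <- g * g
  idx <- cbind(ca + 1L, cb + 1L)
  tab <- table(factor(ca, levels = 0:(nc - 1)), factor(cb, levels = 0:(nc - 1)))
  cnt <- matrix(as.integer(tab), nc, nc)
  # matches per A-cell
  rowcnt <- rowSums(cnt)

  pairs <- unique(idx)
  support <- numeric(nrow(pairs))
  nmean <- numeric(nrow(pairs))
  gx <- function(cell) (cell - 1L) %% g
  gy <- function(cell) (cell - 1L) %/% g
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    ix <- gx(i); iy <- gy(i); jx <- gx(j); jy <- gy(j)
    s <- 0L
    tot_a <- 0L
    valid_a <- 0L
    for (dy in -1:1) {
      for (dx in -1:1) {
        aix <- ix + dx; aiy <- iy + dy
        bjx <- jx + dx; bjy <- jy + dy
        a_in <- aix >= 0 && aix < g && aiy >= 0 && aiy < g
        b_in <- bjx >= 0 && bjx < g && bjy >= 0 && bjy < g
        if (a_in) {
          acell <- aix + g * aiy + 1L
          valid_a <- valid_a + 1L
          tot_a <- tot_a + rowcnt[acell]
          if (b_in) {
            bcell <- bjx + g * bjy + 1L
            s <- s + cnt[acell, bcell]
          }
        }
      }
    }
    support[p] <- s - 1L          # exclude the candidate itself
    nmean[p] <- tot_a / valid_a
  }
  accept_pair <- support > alpha * sqrt(nmean)
  key <- paste(pairs[, 1], pairs[, 2])
  accepted <- setNames(accept_pair, key)
  accepted[paste(idx[, 1], idx[, 2])]
}
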