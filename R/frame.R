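#' Construct a coordinate frame
#'
#' A frame holds bead positions (nm) in an orthorhombic periodic box together
#' with per-bead metadata. Positions may lie outside the primary box; all
#' distance machinery applies the minimum-image convention, and [wrap_frame()]
#' folds coordinates back when a canonical image is wanted.
#'
#' @param positions N x 3 numeric matrix, nm
#' @param box length-3 numeric, orthorhombic box edge lengths in nm
#' @param beads per-bead metadata: a [bead_table()] augmented with columns
#'   `molecule_id` (integer) and `molecule_kind` (one of `AD`, `siRNA`,
#'   `water`, `Na`, `Cl`)
#' @return object of class `cg_frame`
#' @export
cg_frame <- function(positions, box, beads) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3) stop("positions must be an N x 3 matrix")
  if (length(box) != 3 || any(box <= 0)) stop("box must be 3 positive lengths")
  if (nrow(positions) != nrow(beads))
    stop("bead table length must equal the number of positions")
  need <- c("molecule_id", "molecule_kind")
  if (!all(need %in% names(beads)))
    stop("frame bead table needs molecule_id and molecule_kind columns")
  bad <- setdiff(unique(beads$molecule_kind), c("AD", "siRNA", "water", "Na", "Cl"))
  if (length(bad)) stop("unknown molecule kind(s): ", paste(bad, collapse = ", "))
  structure(list(positions = positions, box = as.numeric(box), beads = beads),
            class = "cg_frame")
}

#' @export
print.cg_frame <- function(x, ...) {
  cat(sprintf("CG frame: %d beads in a %.2f x %.2f x %.2f nm box\n",
              nrow(x$positions), x$box[1], x$box[2], x$box[3]))
  tb <- table(x$beads$molecule_kind)
  cat("  ", paste(sprintf("%s=%d", names(tb), as.integer(tb)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Wrap frame coordinates into the primary box
#'
#' @param frame a [cg_frame()]
#' @return the frame with all coordinates folded into `[0, box)`
#' @export
wrap_frame <- function(frame) {
  b <- matrix(frame$box, nrow(frame$positions), 3, byrow = TRUE)
  frame$positions <- frame$positions - floor(frame$positions / b) * b
  frame
}

# Minimum-image displacement of a matrix of vectors for an orthorhombic box.
.min_image <- function(d, box) {
  b <- matrix(box, nrow(d), 3, byrow = TRUE)
  d - round(d / b) * b
}

#' Minimum-image distances between two position sets
#'
#' @param x,y matrices of positions (nm); `y = NULL` gives the full symmetric
#'   self set
#' @param box orthorhombic box lengths, nm
#' @return |x| x |y| matrix of minimum-image distances
#' @export
pdist_pbc <- function(x, y = NULL, box) {
  x <- rbind(x)
  y <- if (is.null(y)) x else rbind(y)
  nx <- nrow(x); ny <- nrow(y)
  out <- matrix(0, nx, ny)
  # loop over the smaller side; each step is a vectorised min-image row
  for (i in seq_len(nx)) {
    d <- y - matrix(x[i, ], ny, 3, byrow = TRUE)
    d <- .min_image(d, box)
    out[i, ] <- sqrt(rowSums(d * d))
  }
  out
}

#' Pairs of beads within a cutoff under the minimum-image convention
#'
#' @param x,y position matrices; distances are taken x-against-y
#' @param box box lengths nm
#' @param cutoff nm, inclusive
#' @return two-column integer matrix of (row in x, row in y) pairs
#' @export
pairs_within <- function(x, y, box, cutoff) {
  d <- pdist_pbc(x, y, box)
  which(d <= cutoff, arr.ind = TRUE)
}

# mass-weighted centroid of an unwrapped coordinate block
.centroid <- function(coords, mass) {
  w <- mass / sum(mass)
  colSums(coords * w)
}

# Make one molecule whole: shift every bead to its minimum image relative to
# the molecule's first bead. Valid while molecular extent < box/2, which
# holds for every molecule built here (dendrimers ~3 nm, siRNA ~6 nm in
# >=13 nm boxes).
.make_whole <- function(coords, box) {
  ref <- coords[1, ]
  d <- coords - matrix(ref, nrow(coords), 3, byrow = TRUE)
  matrix(ref, nrow(coords), 3, byrow = TRUE) + .min_image(d, box)
}

#' Construct a trajectory
#'
#' @param frames list of [cg_frame()] objects with a constant bead count
#' @param times strictly increasing frame times, ns
#' @return object of class `cg_trajectory`
#' @export
cg_trajectory <- function(frames, times) {
  if (length(frames) != length(times))
    stop("one time per frame required")
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  counts <- vapply(frames, function(f) nrow(f$positions), integer(1))
  if (length(unique(counts)) > 1)
    stop("bead count must be constant across frames")
  structure(list(frames = frames, times = as.numeric(times)),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat(sprintf("CG trajectory: %d frames, %.1f-%.1f ns, %d beads\n",
              length(x$frames), min(x$times), max(x$times),
              nrow(x$frames[[1]]$positions)))
  invisible(x)
}

#' Subset a trajectory by time window
#'
#' @param trajectory a [cg_trajectory()]
#' @param from,to window bounds in ns (inclusive)
#' @return the windowed [cg_trajectory()]
#' @export
window_trajectory <- function(trajectory, from = -Inf, to = Inf) {
  keep <- trajectory$times >= from & trajectory$times <= to
  if (!any(keep)) stop("empty trajectory window")
  cg_trajectory(trajectory$frames[keep], trajectory$times[keep])
}
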