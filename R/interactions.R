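# siRNA-micelle interaction quantification: surface areas, contacts,
# solvation shells, density maps and binding statistics.

# deterministic quasi-uniform points on the unit sphere (Fibonacci spiral)
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  th <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  cbind(r * cos(th), r * sin(th), z)
}

#' Shrake-Rupley solvent-accessible surface area (coordinate interface)
#'
#' Each selected bead is given a sphere of radius (bead radius + probe)
#' sampled at `n_sphere_points` quasi-uniform points; points falling inside
#' the probe-inflated sphere of any other context bead are buried, and the
#' accessible fraction scales the analytic sphere area. Coordinates are
#' treated as an isolated (non-periodic) object.
#'
#' @param coords N x 3 coordinate matrix, nm
#' @param selection row indices whose area is wanted
#' @param context row indices that can bury surface (default: the
#'   selection itself; pass all beads to measure a part within a whole)
#' @param probe_radius probe radius, nm (default 0.26, half a CG
#'   water-bead diameter)
#' @param n_sphere_points sampling density per bead
#' @param radii per-bead radii, nm (default 0.26 for every bead)
#' @return per-selected-bead areas, nm^2 (sum for the total)
#' @export
sasa_coords <- function(coords, selection, context = selection,
                        probe_radius = 0.26, n_sphere_points = 480,
                        radii = rep(0.26, nrow(coords))) {
  coords <- as.matrix(coords)
  if (!length(selection)) stop("empty selection")
  if (any(radii[selection] <= 0) || probe_radius < 0)
    stop("bead radii must be positive")
  pts <- .sphere_points(n_sphere_points)
  context <- union(context, selection)
  out <- numeric(length(selection))
  for (s in seq_along(selection)) {
    i <- selection[s]
    Ri <- radii[i] + probe_radius
    # only context beads close enough can bury points of bead i
    d2 <- rowSums((coords[context, , drop = FALSE] -
                     matrix(coords[i, ], length(context), 3,
                            byrow = TRUE))^2)
    Rj <- radii[context] + probe_radius
    nb <- context[d2 < (Ri + Rj)^2 & context != i]
    p <- pts * Ri + matrix(coords[i, ], n_sphere_points, 3, byrow = TRUE)
    if (length(nb)) {
      acc <- rep(TRUE, n_sphere_points)
      eps <- 1e-9
      for (j in nb) {
        rj2 <- (radii[j] + probe_radius)^2
        dj2 <- rowSums((p - matrix(coords[j, ], n_sphere_points, 3,
                                   byrow = TRUE))^2)
        # strictly interior points are buried; points exactly on the other
        # sphere (coincident beads) are kept by the lower-indexed bead only
        buried <- dj2 < rj2 - eps | (abs(dj2 - rj2) <= eps & j < i)
        acc <- acc & !buried
        if (!any(acc)) break
      }
      frac <- mean(acc)
    } else {
      frac <- 1
    }
    out[s] <- 4 * pi * Ri^2 * frac
  }
  out
}

#' Shrake-Rupley SASA of a frame selection
#'
#' @param frame a [cg_frame()]
#' @param selection bead row indices (1-based) to measure
#' @param context bead row indices providing burial context (default the
#'   selection); solvent beads are normally excluded by the caller
#' @param ... passed to [sasa_coords()]
#' @return total area, nm^2
#' @export
sasa <- function(frame, selection, context = selection, ...) {
  sum(sasa_coords(frame$positions, selection, context, ...))
}

#' Count contact pairs between two selections
#'
#' Number of (a, b) bead pairs with minimum-image distance at or below the
#' cutoff (pair counting; see [amine_binding_stats()] for unique-bead
#' semantics).
#'
#' @param frame a [cg_frame()]
#' @param selection_a,selection_b disjoint bead row indices
#' @param cutoff nm, inclusive (default 0.75, the contact convention)
#' @return integer pair count
#' @export
count_contacts <- function(frame, selection_a, selection_b, cutoff = 0.75) {
  if (length(intersect(selection_a, selection_b)))
    stop("selections must be disjoint")
  if (!length(selection_a) || !length(selection_b)) return(0L)
  d <- pdist_pbc(frame$positions[selection_a, , drop = FALSE],
                 frame$positions[selection_b, , drop = FALSE], frame$box)
  sum(d <= cutoff)
}

#' Solvation-shell composition around a target
#'
#' Per-frame count of beads of one species within the cutoff of any target
#' bead, averaged over a trajectory window. The 0.65 nm default is the
#' first CG solvation shell.
#'
#' @param trajectory a [cg_trajectory()] (already windowed if desired)
#' @param target_fn function(frame) returning target bead row indices
#'   (defaults to all siRNA beads)
#' @param species molecule kind to count (`water`, `Na`, `Cl`)
#' @param cutoff nm
#' @return list with `mean`, `per_frame` counts, `species`, `cutoff`
#' @export
solvation_counts <- function(trajectory,
                             target_fn = function(fr)
                               which(fr$beads$molecule_kind == "siRNA"),
                             species = "water", cutoff = 0.65) {
  nf <- length(trajectory$frames)
  if (!nf) stop("empty trajectory window")
  counts <- integer(nf)
  warned <- FALSE
  for (f in seq_len(nf)) {
    fr <- trajectory$frames[[f]]
    tgt <- target_fn(fr)
    if (!length(tgt)) stop("empty target selection in frame ", f)
    sp <- which(fr$beads$molecule_kind == species)
    if (!length(sp)) {
      if (!warned) {
        warning("species '", species, "' absent; counts are zero")
        warned <- TRUE
      }
      counts[f] <- 0L
      next
    }
    d <- pdist_pbc(fr$positions[sp, , drop = FALSE],
                   fr$positions[tgt, , drop = FALSE], fr$box)
    counts[f] <- sum(apply(d, 1, min) <= cutoff)
  }
  list(mean = mean(counts), per_frame = counts, species = species,
       cutoff = cutoff)
}

#' Per-base-pair radial distribution function map
#'
#' For each siRNA base pair, g(r) of a species around the mass-weighted COM
#' of the two paired nucleotides: shell counts normalized by shell volume
#' and the bulk number density of the species in the box, averaged over the
#' window.
#'
#' @param trajectory a [cg_trajectory()] containing one siRNA molecule with
#'   base-pair metadata (`basepair` column)
#' @param species molecule kind whose density is mapped
#' @param bin_width radial bin width, nm
#' @param r_max outer radius, nm; must not exceed half the smallest box edge
#' @return matrix (base pairs x bins) of g(r); attributes `r` (bin centres),
#'   `bulk_density` (beads nm^-3)
#' @export
rdf_per_basepair <- function(trajectory, species = "water", bin_width = 0.1,
                             r_max = 3) {
  nf <- length(trajectory$frames)
  if (!nf) stop("empty trajectory window")
  box <- trajectory$frames[[1]]$box
  if (r_max > min(box) / 2)
    stop("r_max exceeds half the smallest box edge")
  edges <- seq(0, r_max, by = bin_width)
  nb <- length(edges) - 1L
  b1 <- trajectory$frames[[1]]$beads
  bps <- sort(unique(b1$basepair[!is.na(b1$basepair)]))
  if (!length(bps)) stop("no base-pair metadata in frame")
  counts <- matrix(0, length(bps), nb)
  dens_sum <- 0
  empty <- TRUE
  for (f in seq_len(nf)) {
    fr <- trajectory$frames[[f]]
    b <- fr$beads
    sp <- which(b$molecule_kind == species)
    if (length(sp)) empty <- FALSE
    dens_sum <- dens_sum + length(sp) / prod(fr$box)
    if (!length(sp)) next
    xs <- fr$positions[sp, , drop = FALSE]
    for (k in seq_along(bps)) {
      sel <- which(!is.na(b$basepair) & b$basepair == bps[k])
      com <- .centroid(.make_whole(fr$positions[sel, , drop = FALSE],
                                   fr$box), b$mass[sel])
      d <- pdist_pbc(rbind(com), xs, fr$box)[1, ]
      h <- graphics::hist(d[d < r_max], breaks = edges, plot = FALSE)$counts
      counts[k, ] <- counts[k, ] + h
    }
  }
  rho <- dens_sum / nf
  if (empty) {
    warning("species '", species, "' absent from window; map is zero")
    g <- counts
  } else {
    shell_vol <- (4 / 3) * pi * diff(edges^3)
    g <- counts / (nf * matrix(shell_vol, length(bps), nb, byrow = TRUE) * rho)
  }
  rownames(g) <- paste0("bp", bps)
  attr(g, "r") <- (edges[-1] + edges[-length(edges)]) / 2
  attr(g, "bulk_density") <- rho
  g
}

#' Centre-of-mass distance series between two bead groups
#'
#' Per frame: each group is made whole across the periodic boundary, its
#' mass-weighted centroid taken, and the minimum-image distance between the
#' two centroids reported.
#'
#' @param trajectory a [cg_trajectory()]
#' @param group_a,group_b functions(frame) -> bead row indices, or fixed
#'   index vectors
#' @return data.frame with `time_ns` and `com_distance`
#' @export
com_distance_series <- function(trajectory, group_a, group_b) {
  resolve <- function(g, fr) if (is.function(g)) g(fr) else g
  nf <- length(trajectory$frames)
  out <- numeric(nf)
  for (f in seq_len(nf)) {
    fr <- trajectory$frames[[f]]
    ia <- resolve(group_a, fr); ib <- resolve(group_b, fr)
    if (!length(ia) || !length(ib)) stop("empty group in frame ", f)
    ca <- .centroid(.make_whole(fr$positions[ia, , drop = FALSE], fr$box),
                    fr$beads$mass[ia])
    cb <- .centroid(.make_whole(fr$positions[ib, , drop = FALSE], fr$box),
                    fr$beads$mass[ib])
    out[f] <- pdist_pbc(rbind(ca), rbind(cb), fr$box)[1, 1]
  }
  data.frame(time_ns = trajectory$times, com_distance = out)
}

#' Find plateaus in a time series
#'
#' Sliding-window slope test: a frame belongs to a plateau when the
#' least-squares slope of the surrounding window stays below the tolerance.
#' Consecutive plateau frames of at least `min_len` form one plateau.
#'
#' @param times ns
#' @param values series values
#' @param slope_tol absolute slope threshold, units of value per ns
#' @param min_len minimum frames per plateau
#' @return data.frame with `start`, `end` (frame indices), `level` (mean
#'   value over the plateau)
#' @export
find_plateaus <- function(times, values, slope_tol = 0.01, min_len = 10) {
  n <- length(values)
  if (n < min_len) return(data.frame(start = integer(0), end = integer(0),
                                     level = numeric(0)))
  flat <- logical(n)
  for (s in seq_len(n - min_len + 1L)) {
    w <- s:(s + min_len - 1L)
    sl <- stats::coef(stats::lm(values[w] ~ times[w]))[2]
    if (abs(sl) < slope_tol) flat[w] <- TRUE
  }
  r <- rle(flat)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  data.frame(start = starts[keep], end = ends[keep],
             level = mapply(function(s, e) mean(values[s:e]),
                            starts[keep], ends[keep]))
}

#' Per-micelle amine-siRNA binding statistics
#'
#' For each micelle (a set of AD molecule ids): per frame, the number of
#' *unique* terminal-amine beads within the contact cutoff of any siRNA
#' bead; a micelle counts as bound when its COM-to-siRNA distance is at
#' most `bound_cutoff`. Means and standard errors are taken over
#' decorrelated frames (every `stride`-th frame of the window).
#'
#' @param trajectory a [cg_trajectory()] (window of interest)
#' @param micelles list of molecule-id vectors, one per micelle
#' @param cutoff contact cutoff, nm
#' @param bound_cutoff COM-distance threshold for the bound set, nm
#' @param stride frame decorrelation stride for the standard error
#' @return data.frame: one row per micelle with `n_ads`, `bound`,
#'   `mean_com_distance`, `mean_amines`, `sem_amines`
#' @export
amine_binding_stats <- function(trajectory, micelles, cutoff = 0.75,
                                bound_cutoff = 5.0, stride = 1L) {
  nf <- length(trajectory$frames)
  if (!nf) stop("empty trajectory window")
  frames <- seq(1L, nf, by = stride)
  res <- lapply(seq_along(micelles), function(mi) {
    mem <- micelles[[mi]]
    counts <- numeric(length(frames))
    dists <- numeric(length(frames))
    for (k in seq_along(frames)) {
      fr <- trajectory$frames[[frames[k]]]
      b <- fr$beads
      rna <- which(b$molecule_kind == "siRNA")
      if (!length(rna)) stop("no siRNA in frame ", frames[k])
      am <- which(b$molecule_id %in% mem & b$role == "terminal-amine")
      mic <- which(b$molecule_id %in% mem)
      cm <- .centroid(.make_whole(fr$positions[mic, , drop = FALSE], fr$box),
                      b$mass[mic])
      cr <- .centroid(.make_whole(fr$positions[rna, , drop = FALSE], fr$box),
                      b$mass[rna])
      dists[k] <- pdist_pbc(rbind(cm), rbind(cr), fr$box)[1, 1]
      d <- pdist_pbc(fr$positions[am, , drop = FALSE],
                     fr$positions[rna, , drop = FALSE], fr$box)
      counts[k] <- sum(apply(d, 1, min) <= cutoff)
    }
    data.frame(
      micelle = mi, n_ads = length(mem),
      bound = mean(dists) <= bound_cutoff,
      mean_com_distance = mean(dists),
      mean_amines = mean(counts),
      sem_amines = if (length(counts) > 1)
        stats::sd(counts) / sqrt(length(counts)) else 0)
  })
  do.call(rbind, res)
}

#' Amine-binding summary report
#'
#' Table-style per-micelle report: aggregation number, total amines,
#' mean +/- sem amines bound to the siRNA, and surface area per amine from
#' the micelle geometry.
#'
#' @param trajectory a [cg_trajectory()] window
#' @param micelles list of molecule-id vectors
#' @param spec the [ad_spec()] of the ADs
#' @param geometries optional list of [micelle_geometry()] results matched
#'   to `micelles` (for the area-per-amine column)
#' @param ... passed to [amine_binding_stats()]
#' @return data.frame
#' @export
amine_report <- function(trajectory, micelles, spec, geometries = NULL, ...) {
  st <- amine_binding_stats(trajectory, micelles, ...)
  st$total_amines <- st$n_ads * spec$n_terminal
  st$area_per_amine <- NA_real_
  if (!is.null(geometries)) {
    for (i in seq_along(geometries)) {
      g <- geometries[[i]]
      if (!isTRUE(g$degenerate))
        st$area_per_amine[i] <- g$surface_area / (g$N * spec$n_terminal)
    }
  }
  st[, c("micelle", "n_ads", "total_amines", "bound", "mean_com_distance",
         "mean_amines", "sem_amines", "area_per_amine")]
}
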