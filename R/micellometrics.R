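# Micelle descriptors: the geometric layer behind the packing-parameter
# analysis. Conventions:
#   P  = v0 / (a * l0)              (packing parameter)
#   V  = (4/3) pi R^3,  A = 4 pi R^2   (spherical core volume / area)
#   R  = 3 V / A = 3 v0 / a            (core radius from V and A)
#   I_d = l0 / R                        (interdigitation index)
#   sigma_m = e N / S_m                 (surface charge density)

#' Spherical core volume (nm^3) for a core radius R (nm)
#' @param R core radius, nm
#' @export
sphere_core_volume <- function(R) (4 / 3) * pi * R^3

#' Spherical core surface area (nm^2) for a core radius R (nm)
#' @param R core radius, nm
#' @export
sphere_core_area <- function(R) 4 * pi * R^2

#' Core radius from per-molecule volume and area (R = 3 v0 / a)
#' @param v0 hydrophobic volume per molecule, nm^3
#' @param a core area per molecule, nm^2
#' @export
core_radius_from_va <- function(v0, a) 3 * v0 / a

#' Packing parameter and shape class
#'
#' The Israelachvili packing parameter P = v0 / (a l0) predicts aggregate
#' shape from per-molecule quantities: P <= 0.33 a spherical micelle,
#' 0.33 < P <= 0.50 a cylinder, larger values a bilayer.
#'
#' @param v0 hydrophobic chain volume per molecule, nm^3
#' @param a core surface area per molecule, nm^2
#' @param l0 critical tail length, nm
#' @return list with `P` and `shape_class`
#' @export
packing_and_shape <- function(v0, a, l0) {
  if (any(c(v0, a, l0) <= 0)) stop("v0, a and l0 must all be positive")
  P <- v0 / (a * l0)
  shape <- if (P <= 0.33) "sphere" else if (P <= 0.50) "cylinder" else "bilayer"
  list(P = P, shape_class = shape)
}

#' Packing parameter of a spherical core from its radius and tail length
#'
#' For a spherical core of radius R made of N molecules, v0 = V/N and
#' a = A/N with V and A the spherical core volume and area, so P reduces to
#' R / (3 l0) independent of N. This is the arithmetic used to recompute
#' the published per-micelle packing parameters from their printed core
#' radii and tail lengths.
#'
#' @param R core radius, nm
#' @param l0 tail length, nm
#' @return list with `P` and `shape_class` (as [packing_and_shape()])
#' @export
packing_parameter_spherical <- function(R, l0) {
  if (R <= 0 || l0 <= 0) stop("R and l0 must be positive")
  V <- sphere_core_volume(R)
  A <- sphere_core_area(R)
  packing_and_shape(V, A, l0)   # v0/a with N cancelling
}

# gyration tensor quantities for mass-weighted coordinates
.gyration <- function(coords, mass) {
  com <- .centroid(coords, mass)
  d <- coords - matrix(com, nrow(coords), 3, byrow = TRUE)
  w <- mass / sum(mass)
  S <- crossprod(d * sqrt(w))       # 3x3 gyration tensor
  ev <- sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ev[ev < 0] <- 0
  rg2 <- sum(ev)
  kappa2 <- if (rg2 > 0)
    1 - 3 * (ev[1] * ev[2] + ev[2] * ev[3] + ev[3] * ev[1]) / rg2^2 else 0
  list(rg = sqrt(rg2), eigenvalues = ev, kappa2 = kappa2, com = com,
       centred = d)
}

#' Micelle geometry from an aggregate
#'
#' Radii are obtained via mass-weighted radii of gyration with the uniform
#' solid-sphere convention R = sqrt(5/3) Rg: the micelle radius from all
#' aggregate beads, the core radius from the hydrophobic (tail + ring)
#' beads. Core volume and area follow the spherical-core relations; the
#' tail length l0 is the mean ring-to-terminal-tail-bead distance over
#' member molecules. Aggregates with relative shape anisotropy
#' kappa^2 > `rod_kappa2` are flagged as rods and additionally report
#' min/max cylinder radii from axial thirds of the core.
#'
#' @param frame a [cg_frame()]
#' @param aggregate one element of [detect_aggregates()] output
#' @param spec the [ad_spec()] of the member molecules
#' @param radius_factor proportionality between Rg and radius (default
#'   sqrt(5/3), uniform solid sphere)
#' @param rod_kappa2 anisotropy threshold flagging rod-like aggregates
#' @return object of class `micelle_geometry`: a list with fields `N`,
#'   `Rg`, `micelle_radius`, `core_radius`, `tail_length`, `core_volume`,
#'   `core_area`, `surface_area`, `headgroup_volume`, `v0`, `a`, `P`,
#'   `shape_class`, `kappa2`, `is_rod`, `cyl_radius_min`, `cyl_radius_max`,
#'   `degenerate`
#' @export
micelle_geometry <- function(frame, aggregate, spec,
                             radius_factor = sqrt(5 / 3),
                             rod_kappa2 = 0.2) {
  stopifnot(inherits(spec, "ad_spec"))
  b <- frame$beads
  coords <- unwrap_aggregate(frame, aggregate)
  rows <- attr(coords, "rows")
  mass <- b$mass[rows]
  if (aggregate$n_agg < 2) {
    out <- list(N = aggregate$n_agg, degenerate = TRUE)
    class(out) <- "micelle_geometry"
    return(out)
  }
  gy_all <- .gyration(coords, mass)
  R_m <- radius_factor * gy_all$rg

  hyd <- b$hydrophobic[rows]
  gy_core <- .gyration(coords[hyd, , drop = FALSE], mass[hyd])
  R <- radius_factor * gy_core$rg
  V <- sphere_core_volume(R)
  A <- sphere_core_area(R)
  N <- aggregate$n_agg

  # tail length: ring bead to last tail bead, per molecule
  l0s <- vapply(aggregate$members, function(m) {
    mr <- which(b$molecule_id[rows] == m)
    ring <- mr[b$role[rows][mr] == "ring"]
    tails <- mr[b$role[rows][mr] == "tail"]
    tip <- tails[length(tails)]
    sqrt(sum((coords[ring, ] - coords[tip, ])^2))
  }, numeric(1))
  l0 <- mean(l0s)

  v0 <- V / N
  a <- A / N
  ps <- packing_and_shape(v0, a, l0)
  S_m <- 4 * pi * R_m^2
  head_vol <- (4 / 3) * pi * R_m^3 - V

  is_rod <- gy_all$kappa2 > rod_kappa2
  cyl_min <- cyl_max <- NA_real_
  if (is_rod) {
    # cross-section radii from axial thirds of the core, uniform-disc
    # estimator R_cyl = sqrt(2 <r_perp^2>)
    axis <- eigen(crossprod(gy_core$centred * sqrt(mass[hyd] / sum(mass[hyd]))),
                  symmetric = TRUE)$vectors[, 1]
    t_ax <- gy_core$centred %*% axis
    r_perp2 <- rowSums(gy_core$centred^2) - as.numeric(t_ax)^2
    cuts <- stats::quantile(t_ax, c(0, 1 / 3, 2 / 3, 1))
    rads <- vapply(1:3, function(s) {
      inb <- t_ax >= cuts[s] & t_ax <= cuts[s + 1]
      sqrt(2 * mean(r_perp2[inb]))
    }, numeric(1))
    cyl_min <- min(rads); cyl_max <- max(rads)
  }

  out <- list(N = N, Rg = gy_all$rg, micelle_radius = R_m, core_radius = R,
              tail_length = l0, core_volume = V, core_area = A,
              surface_area = S_m, headgroup_volume = head_vol,
              v0 = v0, a = a, P = ps$P, shape_class = ps$shape_class,
              kappa2 = gy_all$kappa2, is_rod = is_rod,
              cyl_radius_min = cyl_min, cyl_radius_max = cyl_max,
              degenerate = FALSE)
  class(out) <- "micelle_geometry"
  out
}

#' @export
print.micelle_geometry <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("degenerate aggregate (N =", x$N, ")\n")
    return(invisible(x))
  }
  cat(sprintf(
    "micelle N=%d: R_m=%.2f nm, R_core=%.2f nm, l0=%.2f nm, P=%.2f (%s)%s\n",
    x$N, x$micelle_radius, x$core_radius, x$tail_length, x$P, x$shape_class,
    if (x$is_rod) sprintf(" [rod, kappa2=%.2f]", x$kappa2) else ""))
  invisible(x)
}

#' Derived micelle/complex indices
#'
#' Computes the interdigitation index I_d = l0/R, the micelle surface
#' charge density sigma_m = e N / S_m (e the per-molecule head charge,
#' 2^(g+1)), the surface area available per amine S_m / (N e), and -- when
#' the aggregation numbers of the siRNA-bound micelles are given -- the N/P
#' ratio computed as the total number of ADs in bound micelles divided by
#' the number of core phosphates (the published convention).
#'
#' @param geometry a [micelle_geometry()] result, or any list providing
#'   `tail_length`, `core_radius`, `N` and `surface_area`
#' @param spec the [ad_spec()] of the member molecules
#' @param duplex optional [sirna_duplex_spec()] for the N/P denominator
#' @param bound_n_aggs optional vector of aggregation numbers of the
#'   micelles bound to the siRNA
#' @return list with `I_d`, `sigma_m` (e nm^-2), `area_per_amine` (nm^2)
#'   and, when computable, `np_ratio`
#' @export
derived_indices <- function(geometry, spec, duplex = NULL,
                            bound_n_aggs = NULL) {
  stopifnot(inherits(spec, "ad_spec"))
  I_d <- geometry$tail_length / geometry$core_radius
  sigma_m <- area_per_amine <- NA_real_
  if (!is.null(geometry$surface_area) && !is.null(geometry$N)) {
    if (geometry$surface_area <= 0) stop("zero micelle surface area")
    e <- spec$n_terminal
    sigma_m <- e * geometry$N / geometry$surface_area
    area_per_amine <- geometry$surface_area / (geometry$N * e)
  }
  out <- list(I_d = I_d, sigma_m = sigma_m, area_per_amine = area_per_amine)
  if (!is.null(bound_n_aggs) && !is.null(duplex))
    out$np_ratio <- sum(bound_n_aggs) / duplex$n_phosphates_core
  out
}

#' Fraction of aggregate surface area on hydrophobic beads
#'
#' Shrake-Rupley SASA of the hydrophobic (tail + ring) beads, evaluated in
#' the context of the whole isolated aggregate, divided by the SASA of all
#' aggregate beads. For a well-formed micelle the head corona buries the
#' core and the fraction is small; a lone AD exposes its full tail.
#'
#' @param frame a [cg_frame()]
#' @param aggregate one element of [detect_aggregates()] output
#' @param ... passed to [sasa()] (probe radius, sampling density)
#' @return scalar fraction in [0, 1]
#' @export
hydrophobic_sasa_fraction <- function(frame, aggregate, ...) {
  coords <- unwrap_aggregate(frame, aggregate)
  rows <- attr(coords, "rows")
  hyd <- which(frame$beads$hydrophobic[rows])
  all_idx <- seq_len(nrow(coords))
  s_all <- sasa_coords(coords, all_idx, context = all_idx, ...)
  s_hyd <- sasa_coords(coords, hyd, context = all_idx, ...)
  sum(s_hyd) / sum(s_all)
}

#' Micelle summary report for a frame
#'
#' One row per detected aggregate with the full geometric descriptor set
#' (aggregation number, radii, volumes, areas, packing parameter, shape,
#' interdigitation, surface charge density, area per amine), plus an
#' appended mean row over non-degenerate micelles.
#'
#' @param frame a [cg_frame()]
#' @param spec the [ad_spec()] of the AD molecules
#' @param cutoff aggregate linkage cutoff, nm
#' @param min_n drop aggregates smaller than this from the report
#' @return data.frame
#' @export
micelle_report <- function(frame, spec, cutoff = 0.6, min_n = 2) {
  aggs <- detect_aggregates(frame, cutoff)
  rows <- list()
  for (a in aggs) {
    if (a$n_agg < min_n) next
    g <- micelle_geometry(frame, a, spec)
    di <- derived_indices(g, spec)
    rows[[length(rows) + 1L]] <- data.frame(
      n_ads = g$N, micelle_radius = g$micelle_radius,
      core_radius = g$core_radius, tail_length = g$tail_length,
      surface_area = g$surface_area, core_volume = g$core_volume,
      headgroup_volume = g$headgroup_volume, packing_parameter = g$P,
      shape = g$shape_class, is_rod = g$is_rod, interdigitation = di$I_d,
      sigma_m = di$sigma_m, area_per_amine = di$area_per_amine)
  }
  if (!length(rows)) return(data.frame())
  tab <- do.call(rbind, rows)
  mean_row <- tab[1, ]
  num <- vapply(tab, is.numeric, logical(1))
  mean_row[num] <- lapply(tab[num], mean)
  mean_row$shape <- "(mean)"
  mean_row$is_rod <- NA
  rbind(tab, mean_row)
}
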