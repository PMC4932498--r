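# Seeded synthetic configuration generators. These emulate the *structure*
# the analysis layer assumes (micelles with hydrophobic cores and cationic
# coronas, dendriplexes, solvent and 150 mM NaCl ion beads, scripted fusion
# events) without any dynamics: trajectories are scripted fixtures.

.golden <- pi * (3 - sqrt(5))   # golden angle, rad

# n roughly equidistant unit vectors (Fibonacci sphere); deterministic
.fib_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  th <- .golden * (seq_len(n) - 1)
  cbind(r * cos(th), r * sin(th), z)
}

.unit <- function(v) v / sqrt(sum(v^2))

# orthonormal tangents to a unit vector
.tangents <- function(u) {
  e <- diag(3)[, which.min(abs(u))]
  t1 <- .unit(c(u[2] * e[3] - u[3] * e[2],
                u[3] * e[1] - u[1] * e[3],
                u[1] * e[2] - u[2] * e[1]))
  t2 <- c(u[2] * t1[3] - u[3] * t1[2],
          u[3] * t1[1] - u[1] * t1[3],
          u[1] * t1[2] - u[2] * t1[1])
  list(t1 = t1, t2 = t2)
}

# ---------------------------------------------------------------------------
# single-molecule conformations

# One AD laid out along an axis: tail along -z from the ring at the origin,
# head tree fanning out along +z. Used for lone-molecule fixtures and as the
# bead-order template for micelle placement.
.ad_layout <- function(topo, spec) {
  g <- spec$generation
  n_nodes <- 2L^(g + 1L) - 1L
  n_term <- spec$n_terminal
  n_tail <- spec$n_tail_beads
  coords <- matrix(0, nrow(topo$beads), 3)
  u <- c(0, 0, 1)
  tg <- .tangents(u)
  depth_of_node <- floor(log2(seq_len(n_nodes)))
  head_depth <- c(depth_of_node + 1L, rep(g + 2L, n_term))  # ring at depth 0
  for (h in seq_len(n_nodes + n_term)) {
    d <- head_depth[h]
    a <- .golden * h
    s <- 0.12 + 0.22 * (d - 1L)
    dir <- .unit(u + s * (cos(a) * tg$t1 + sin(a) * tg$t2))
    coords[h, ] <- dir * (0.30 * d)
  }
  ring <- n_nodes + n_term + 1L
  coords[ring, ] <- c(0, 0, 0)
  for (j in seq_len(n_tail))
    coords[ring + j, ] <- c(0, 0, -.martini$bond_r0 * j)
  coords
}

#' Build a frame holding one free amphiphilic dendrimer
#'
#' @param spec an [ad_spec()]
#' @param box box lengths, nm
#' @return a [cg_frame()] centred in the box
#' @export
single_ad_frame <- function(spec, box = c(10, 10, 10)) {
  topo <- build_ad_topology(spec)
  coords <- .ad_layout(topo, spec)
  coords <- coords + matrix(box / 2, nrow(coords), 3, byrow = TRUE)
  b <- topo$beads
  b$molecule_id <- 1L
  b$molecule_kind <- "AD"
  cg_frame(coords, box, b)
}

# union-of-columns rbind for bead tables from different molecule families
.bind_beads <- function(lst) {
  cols <- unique(unlist(lapply(lst, names)))
  lst <- lapply(lst, function(d) {
    for (cn in setdiff(cols, names(d))) d[[cn]] <- NA
    d[, cols]
  })
  out <- do.call(rbind, lst)
  rownames(out) <- NULL
  out$index <- seq_len(nrow(out)) - 1L
  out
}

# ---------------------------------------------------------------------------
# micelle generator

# Place one AD so its hydrophobic chain curves through the core. Radial bead
# distances follow the volume-uniform quantiles of the core shape (ball:
# r ~ R q^(1/3); disc cross-section: r ~ R sqrt(q)), so the pooled
# hydrophobic beads reproduce the second moment of a filled core and the
# sqrt(5/3)*Rg estimator recovers the target radius. The chain bends in its
# tangent plane just enough to give the requested ring-to-terminal tail
# length, clamped to what the core geometry admits.
.place_ad_chain <- function(u, tg_dir, origin, R_core, n_tail, d_tail,
                            radial_quantile) {
  r_ring <- 0.95 * R_core
  q <- (n_tail - seq_len(n_tail) + 0.5) / n_tail
  r_j <- R_core * radial_quantile(q)
  r_last <- r_j[n_tail]
  l0 <- min(n_tail * d_tail, r_ring + r_last - 0.05)
  l0 <- max(l0, abs(r_ring - r_last) + 0.05)
  cphi <- (r_ring^2 + r_last^2 - l0^2) / (2 * r_ring * r_last)
  phi <- acos(pmin(1, pmax(-1, cphi)))
  phi_j <- phi * seq_len(n_tail) / n_tail
  tail <- matrix(origin, n_tail, 3, byrow = TRUE) +
    r_j * (cos(phi_j) %o% u) + r_j * (sin(phi_j) %o% tg_dir)
  list(ring = origin + r_ring * u, tail = tail, l0 = l0)
}

.place_ad_heads <- function(u, tg, origin, r_ring, spec, psi) {
  g <- spec$generation
  n_nodes <- 2L^(g + 1L) - 1L
  n_term <- spec$n_terminal
  depth <- c(floor(log2(seq_len(n_nodes))) + 1L, rep(g + 2L, n_term))
  out <- matrix(0, n_nodes + n_term, 3)
  for (h in seq_len(n_nodes + n_term)) {
    a <- .golden * h + psi
    s <- 0.12 + 0.22 * (depth[h] - 1L)
    dir <- .unit(u + s * (cos(a) * tg$t1 + sin(a) * tg$t2))
    out[h, ] <- origin + dir * (r_ring + 0.30 * depth[h])
  }
  out
}

#' Generate a synthetic micelle frame
#'
#' Spherical micelles anchor one AD per Fibonacci-sphere direction with the
#' ring bead at the core-shell interface, the alkyl tail curving through the
#' core interior and the dendron head fanned outward. `rod` builds a
#' spherocylinder: a straight section of half-length `rod_half_length`
#' capped by hemispheres, chains pointing at the axis. The construction is
#' deterministic for a given seed; positional jitter of `noise` nm is added.
#'
#' @param spec an [ad_spec()]
#' @param n_ads aggregation number (>= 2)
#' @param shape `sphere` or `rod`
#' @param core_radius_target hydrophobic core radius, nm (as measured by the
#'   sqrt(5/3)*Rg estimator)
#' @param seed integer seed
#' @param rod_half_length straight-section half-length for rods, nm
#'   (default 2 x core radius)
#' @param d_tail tail bead spacing, nm; together with `core_radius_target`
#'   this sets the interdigitation regime (l0 ~ n_tail * d_tail)
#' @param orientation `inward` (normal micelle) or `outward` (tails exposed;
#'   a control construction for surface-area tests)
#' @param box box lengths (default: generous fit around the micelle)
#' @param noise Gaussian positional jitter sigma, nm
#' @param first_molecule_id starting molecule id
#' @return a [cg_frame()]; attribute `micelle` records the construction
#'   intent (`n_ads`, `core_radius`, `l0`, `shape`, `members`)
#' @export
generate_micelle <- function(spec, n_ads, shape = c("sphere", "rod"),
                             core_radius_target, seed = 1,
                             rod_half_length = 2 * core_radius_target,
                             d_tail = 0.35,
                             orientation = c("inward", "outward"),
                             box = NULL, noise = 0.02,
                             first_molecule_id = 1L) {
  shape <- match.arg(shape)
  orientation <- match.arg(orientation)
  stopifnot(inherits(spec, "ad_spec"))
  if (n_ads < 2) stop("a micelle needs at least 2 ADs")
  if (core_radius_target <= 0) stop("core radius must be positive")
  R <- core_radius_target
  surf <- if (shape == "sphere") 4 * pi * (0.95 * R)^2 else
    4 * pi * (0.95 * R)^2 + 2 * pi * 0.95 * R * 2 * rod_half_length
  if (surf / n_ads < 0.22)
    stop("infeasible packing: core radius ", R, " nm too small for ",
         n_ads, " ADs")
  set.seed(seed)
  topo <- build_ad_topology(spec)
  n_tail <- spec$n_tail_beads
  head_extent <- 0.95 * R + 0.30 * (spec$generation + 2L)

  # anchors: unit direction u, local origin o, per-core radial quantile map
  if (shape == "sphere") {
    us <- .fib_sphere(n_ads)
    os <- matrix(0, n_ads, 3)
    qmap <- rep(list(function(q) q^(1 / 3)), n_ads)
  } else {
    h <- rod_half_length
    a_cyl <- 2 * pi * 0.95 * R * 2 * h
    a_cap <- 4 * pi * (0.95 * R)^2
    n_cyl <- round(n_ads * a_cyl / (a_cyl + a_cap))
    n_cap <- n_ads - n_cyl
    us <- matrix(0, n_ads, 3); os <- matrix(0, n_ads, 3)
    qmap <- vector("list", n_ads)
    if (n_cyl > 0) {
      z <- seq(-h, h, length.out = n_cyl + 2)[2:(n_cyl + 1)]
      th <- .golden * seq_len(n_cyl) / (2 * pi) * (2 * pi)  # golden spiral
      us[seq_len(n_cyl), ] <- cbind(cos(th), sin(th), 0)
      os[seq_len(n_cyl), 3] <- z
      qmap[seq_len(n_cyl)] <- rep(list(function(q) sqrt(q)), n_cyl)
    }
    if (n_cap > 0) {
      caps <- .fib_sphere(n_cap)
      sgn <- ifelse(seq_len(n_cap) %% 2 == 0, 1, -1)
      caps[, 3] <- abs(caps[, 3]) * sgn
      ii <- n_cyl + seq_len(n_cap)
      us[ii, ] <- caps
      os[ii, 3] <- sgn * h
      qmap[ii] <- rep(list(function(q) q^(1 / 3)), n_cap)
    }
  }

  blocks <- vector("list", n_ads)
  btabs <- vector("list", n_ads)
  l0_real <- numeric(n_ads)
  for (m in seq_len(n_ads)) {
    u <- us[m, ]; o <- os[m, ]
    tg <- .tangents(u)
    psi <- .golden * m * 7
    tg_dir <- cos(psi) * tg$t1 + sin(psi) * tg$t2
    heads <- .place_ad_heads(u, tg, o, 0.95 * R, spec, psi)
    if (orientation == "inward") {
      ch <- .place_ad_chain(u, tg_dir, o, R, n_tail, d_tail, qmap[[m]])
      ring <- ch$ring; tail <- ch$tail; l0_real[m] <- ch$l0
    } else {
      ring <- o + 0.95 * R * u
      tail <- matrix(o, n_tail, 3, byrow = TRUE) +
        (0.95 * R + 0.30 * seq_len(n_tail)) %o% u
      l0_real[m] <- 0.30 * n_tail
    }
    blocks[[m]] <- rbind(heads, ring, tail)
    bt <- topo$beads
    bt$molecule_id <- first_molecule_id + m - 1L
    bt$molecule_kind <- "AD"
    btabs[[m]] <- bt
  }
  coords <- do.call(rbind, blocks)
  if (noise > 0)
    coords <- coords + matrix(stats::rnorm(length(coords), 0, noise),
                              nrow(coords), 3)
  if (is.null(box)) {
    ext <- head_extent + (if (shape == "rod") rod_half_length else 0)
    box <- rep(2 * ext + 6, 3)
  }
  coords <- coords + matrix(box / 2, nrow(coords), 3, byrow = TRUE)
  fr <- cg_frame(coords, box, .bind_beads(btabs))
  attr(fr, "micelle") <- list(
    spec = spec, n_ads = n_ads, shape = shape, core_radius = R,
    l0 = mean(l0_real),
    members = first_molecule_id + seq_len(n_ads) - 1L)
  fr
}

# ---------------------------------------------------------------------------
# siRNA-micelle complexes

#' Generate a synthetic siRNA-micelle complex
#'
#' The duplex sits at the box centre (helix axis along z); micelles are
#' placed around its waist at the requested centre-of-mass distances. Bead
#' clashes closer than 0.3 nm are relaxed by small COM-preserving
#' displacements; a request that cannot be realized raises an error.
#'
#' @param micelle_specs list of micelle descriptions, each a list with
#'   fields `spec` ([ad_spec()]), `n_ads`, `core_radius` and optionally
#'   `shape`, `d_tail`
#' @param duplex a [sirna_duplex_spec()]
#' @param com_distances requested micelle-to-siRNA COM distances, nm (one
#'   per micelle)
#' @param seed integer seed
#' @param box box lengths (default: sized to hold everything)
#' @return a [cg_frame()]; attribute `complex` records the siRNA molecule id
#'   and per-micelle member molecule ids
#' @export
generate_complex <- function(micelle_specs, duplex = sirna_duplex_spec(),
                             com_distances = numeric(), seed = 1,
                             box = NULL) {
  if (length(micelle_specs) != length(com_distances))
    stop("one COM distance per micelle required")
  set.seed(seed)
  nmic <- length(micelle_specs)
  mic_frames <- vector("list", nmic)
  next_id <- 2L
  for (i in seq_len(nmic)) {
    ms <- micelle_specs[[i]]
    mic_frames[[i]] <- generate_micelle(
      ms$spec, ms$n_ads,
      shape = if (is.null(ms$shape)) "sphere" else ms$shape,
      core_radius_target = ms$core_radius,
      d_tail = if (is.null(ms$d_tail)) 0.35 else ms$d_tail,
      seed = seed + i, noise = 0.02,
      first_molecule_id = next_id)
    next_id <- next_id + ms$n_ads
    reach <- ms$core_radius + 0.3
    if (com_distances[i] < reach)
      stop("geometric infeasibility: COM distance ", com_distances[i],
           " nm overlaps micelle ", i, " (needs >= ", round(reach, 2), " nm)")
  }
  ext <- if (nmic) max(com_distances) +
    max(vapply(mic_frames, function(f) f$box[1] / 2, numeric(1))) else 4
  if (is.null(box)) box <- rep(2 * ext + 6, 3)

  rna <- build_sirna_topology(duplex, box = box)
  rna_tab <- rna$frame$beads
  rna_xyz <- rna$frame$positions
  rna_com <- .centroid(rna_xyz, rna_tab$mass)
  shift <- box / 2 - rna_com
  rna_xyz <- rna_xyz + matrix(shift, nrow(rna_xyz), 3, byrow = TRUE)

  placed_xyz <- rna_xyz
  tabs <- list(rna_tab)
  blocks <- list(rna_xyz)
  members <- list()
  th0 <- stats::runif(1, 0, 2 * pi)
  for (i in seq_len(nmic)) {
    th <- th0 + 2 * pi * (i - 1) / max(1, nmic)
    zjit <- 0.6 * sin(2.4 * i)
    dir <- .unit(c(cos(th), sin(th), zjit / max(com_distances[i], 1)))
    target <- box / 2 + dir * com_distances[i]
    mf <- mic_frames[[i]]
    xyz <- mf$positions
    mcom <- .centroid(xyz, mf$beads$mass)
    xyz <- xyz + matrix(target - mcom, nrow(xyz), 3, byrow = TRUE)
    xyz <- .relax_clashes(xyz, mf$beads$mass, placed_xyz, box,
                          min_sep = 0.3,
                          label = sprintf("micelle %d at %.2f nm", i,
                                          com_distances[i]))
    blocks[[i + 1L]] <- xyz
    tabs[[i + 1L]] <- mf$beads
    placed_xyz <- rbind(placed_xyz, xyz)
    members[[i]] <- attr(mf, "micelle")$members
  }
  fr <- cg_frame(do.call(rbind, blocks), box, .bind_beads(tabs))
  attr(fr, "complex") <- list(sirna_molecule = 1L, micelle_members = members)
  fr
}

# push clashing beads apart with COM-preserving corrections
.relax_clashes <- function(xyz, mass, other, box, min_sep = 0.3,
                           max_iter = 60, label = "component") {
  for (it in seq_len(max_iter)) {
    d <- pdist_pbc(xyz, other, box)
    bad <- which(d < min_sep, arr.ind = TRUE)
    if (!nrow(bad)) return(xyz)
    disp <- matrix(0, nrow(xyz), 3)
    for (r in seq_len(nrow(bad))) {
      i <- bad[r, 1]; j <- bad[r, 2]
      v <- .min_image(rbind(xyz[i, ] - other[j, ]), box)[1, ]
      nv <- sqrt(sum(v^2))
      dir <- if (nv < 1e-9) c(1, 0, 0) else v / nv
      disp[i, ] <- disp[i, ] + dir * (min_sep - nv + 0.02)
    }
    xyz <- xyz + disp
    w <- mass / sum(mass)
    corr <- colSums(disp * w)
    xyz <- xyz - matrix(corr, nrow(xyz), 3, byrow = TRUE)
  }
  stop("geometric infeasibility: could not place ", label,
       " without bead overlap")
}

# ---------------------------------------------------------------------------
# solvation

#' Solvate a frame and neutralize its charge
#'
#' Fills the box with 4:1-mapped water beads on a jittered cubic lattice
#' (default spacing reproduces bulk CG water density, 8.34 beads/nm^3),
#' excluding sites near solute beads, then converts randomly chosen water
#' sites into Na/Cl ion beads: `nacl_mM` of salt pairs plus exactly enough
#' counterions to bring the total system charge to zero.
#'
#' @param frame a [cg_frame()]
#' @param nacl_mM added salt concentration, mmol/L (default 150)
#' @param seed integer seed
#' @param spacing water lattice spacing, nm
#' @param exclusion solute exclusion radius, nm
#' @param jitter lattice jitter sigma, nm
#' @return the solvated [cg_frame()]
#' @export
solvate_and_neutralize <- function(frame, nacl_mM = 150, seed = 1,
                                   spacing = 0.4925, exclusion = 0.4,
                                   jitter = 0.05) {
  if (is.null(frame$box)) stop("frame has no box")
  set.seed(seed)
  box <- frame$box
  vol <- prod(box)
  grid <- lapply(box, function(L) {
    k <- max(1L, floor(L / spacing))
    (seq_len(k) - 0.5) * (L / k)
  })
  pts <- as.matrix(expand.grid(grid))
  colnames(pts) <- NULL
  pts <- pts + matrix(stats::rnorm(length(pts), 0, jitter), nrow(pts), 3)
  pts <- pts - floor(pts / matrix(box, nrow(pts), 3, byrow = TRUE)) *
    matrix(box, nrow(pts), 3, byrow = TRUE)
  if (nrow(frame$positions)) {
    # chunked exclusion test to bound memory
    keep <- rep(TRUE, nrow(pts))
    chunk <- 20000L
    for (s in seq(1L, nrow(pts), by = chunk)) {
      e <- min(nrow(pts), s + chunk - 1L)
      d <- pdist_pbc(pts[s:e, , drop = FALSE], frame$positions, box)
      keep[s:e] <- apply(d, 1, min) > exclusion
    }
    pts <- pts[keep, , drop = FALSE]
  }
  n_sites <- nrow(pts)
  n_pairs <- round(nacl_mM * 6.02214076e-4 * vol)
  q <- sum(frame$beads$charge)
  n_cl <- n_pairs + max(q, 0L)
  n_na <- n_pairs + max(-q, 0L)
  if (n_na + n_cl > n_sites)
    stop("box too crowded to hold the requested ions")
  ord <- sample.int(n_sites)
  na_idx <- ord[seq_len(n_na)]
  cl_idx <- ord[n_na + seq_len(n_cl)]
  kind <- rep("water", n_sites)
  kind[na_idx] <- "Na"; kind[cl_idx] <- "Cl"
  name <- c(water = "W", Na = "NA+", Cl = "CL-")[kind]
  type <- c(water = "P4", Na = "Qd", Cl = "Qa")[kind]
  charge <- c(water = 0L, Na = 1L, Cl = -1L)[kind]
  role <- c(water = "water", Na = "ion-Na", Cl = "ion-Cl")[kind]
  solv <- bead_table(name, type, charge, role)
  solv$molecule_id <- max(0L, frame$beads$molecule_id) + seq_len(n_sites)
  solv$molecule_kind <- kind
  cg_frame(rbind(frame$positions, pts), box,
           .bind_beads(list(frame$beads, solv)))
}

#' An empty frame (box only)
#'
#' @param box box lengths, nm
#' @return a [cg_frame()] with no beads
#' @export
empty_frame <- function(box) {
  tab <- bead_table(character(0), character(0), integer(0), character(0))
  tab$molecule_id <- integer(0)
  tab$molecule_kind <- character(0)
  cg_frame(matrix(numeric(0), 0, 3), box, tab)
}

# ---------------------------------------------------------------------------
# scripted fusion trajectory

#' Generate a scripted two-micelle fusion trajectory
#'
#' Reproduces the canonical fusion phase structure: the micelles start at a
#' COM separation of ~9 nm, plateau near 6 nm while counterion bridges form,
#' approach, plateau near 2 nm, and merge. Each micelle carries a condensed
#' shell of chloride counterions that co-moves with it; a sparse static
#' water/ion background (down-scaled solvent lattice, 150 mM ion pairs)
#' fills the box. Per-frame Gaussian noise exercises the estimators without
#' breaking cluster identity.
#'
#' @param micelle_a,micelle_b unsolvated micelle frames from
#'   [generate_micelle()]
#' @param n_frames number of frames (>= 5)
#' @param seed integer seed
#' @param d_start,d_plateau1,d_plateau2,d_end COM-distance schedule, nm
#' @param total_ns trajectory span, ns
#' @param noise per-frame positional noise sigma, nm
#' @param water_spacing background solvent lattice spacing, nm (sparse by
#'   default to keep fixtures small)
#' @return a [cg_trajectory()]; attribute `fusion` records the member
#'   molecule ids of both micelles and the scheduled distances
#' @export
generate_fusion_trajectory <- function(micelle_a, micelle_b, n_frames = 60,
                                       seed = 1, d_start = 9,
                                       d_plateau1 = 6, d_plateau2 = 2,
                                       d_end = 0.8, total_ns = 100,
                                       noise = 0.05, water_spacing = 1.0) {
  if (n_frames < 5) stop("a fusion trajectory needs at least 5 frames")
  set.seed(seed)
  ia <- attr(micelle_a, "micelle"); ib <- attr(micelle_b, "micelle")
  if (is.null(ia) || is.null(ib))
    stop("inputs must be micelle frames from generate_micelle()")
  ext <- max(micelle_a$box[1], micelle_b$box[1]) / 2
  box <- c(d_start + 2 * ext + 2, 2 * ext + 2, 2 * ext + 2)

  # centre each micelle's beads on its COM
  centre_block <- function(fr) {
    xyz <- fr$positions
    com <- .centroid(xyz, fr$beads$mass)
    xyz - matrix(com, nrow(xyz), 3, byrow = TRUE)
  }
  xa <- centre_block(micelle_a); xb <- centre_block(micelle_b)

  # condensed chloride shell per micelle, one Cl per unit of head charge
  shell <- function(fr, local) {
    qm <- sum(fr$beads$charge)
    if (qm <= 0) return(matrix(0, 0, 3))
    rmax <- max(sqrt(rowSums(local^2)))
    .fib_sphere(qm) * (rmax + 0.4)
  }
  sa <- shell(micelle_a, xa); sb <- shell(micelle_b, xb)

  # member ids: keep A's, offset B's
  tab_a <- micelle_a$beads
  tab_b <- micelle_b$beads
  off <- max(tab_a$molecule_id)
  tab_b$molecule_id <- tab_b$molecule_id + off
  members_a <- ia$members
  members_b <- ib$members + off

  ion_tab <- function(n, kind, first_id) {
    if (!n) return(NULL)
    t <- bead_table(rep(if (kind == "Cl") "CL-" else "NA+", n),
                    rep(if (kind == "Cl") "Qa" else "Qd", n),
                    rep(if (kind == "Cl") -1L else 1L, n),
                    rep(if (kind == "Cl") "ion-Cl" else "ion-Na", n))
    t$molecule_id <- first_id + seq_len(n) - 1L
    t$molecule_kind <- kind
    t
  }
  next_id <- max(tab_b$molecule_id) + 1L
  shell_tab_a <- ion_tab(nrow(sa), "Cl", next_id)
  if (!is.null(shell_tab_a)) next_id <- next_id + nrow(sa)
  shell_tab_b <- ion_tab(nrow(sb), "Cl", next_id)
  if (!is.null(shell_tab_b)) next_id <- next_id + nrow(sb)

  # static sparse background: waters + 150 mM pairs + Na to balance shells
  centre_a0 <- c(box[1] / 2 - d_start / 2, box[2] / 2, box[3] / 2)
  centre_b0 <- c(box[1] / 2 + d_start / 2, box[2] / 2, box[3] / 2)
  seed_frame <- cg_frame(
    rbind(xa + matrix(centre_a0, nrow(xa), 3, byrow = TRUE),
          xb + matrix(centre_b0, nrow(xb), 3, byrow = TRUE)),
    box, .bind_beads(list(tab_a, tab_b)))
  n_shell_cl <- nrow(sa) + nrow(sb)
  bg <- solvate_and_neutralize(empty_frame(box), nacl_mM = 150,
                               seed = seed + 1, spacing = water_spacing)
  # balance: shells carry n_shell_cl negative charges; solute carries the
  # micelle charge; add bare Na beads for any residual negative excess
  resid <- -(sum(seed_frame$beads$charge) - n_shell_cl)  # charge to cancel
  extra_na <- max(0L, resid)
  bg_tab <- bg$beads
  bg_xyz <- bg$positions
  bg_tab$molecule_id <- bg_tab$molecule_id + next_id
  if (extra_na > 0) {
    # convert extra_na water beads into Na
    wi <- which(bg_tab$molecule_kind == "water")[seq_len(extra_na)]
    bg_tab$molecule_kind[wi] <- "Na"
    bg_tab$name[wi] <- "NA+"; bg_tab$martini_type[wi] <- "Qd"
    bg_tab$charge[wi] <- 1L; bg_tab$role[wi] <- "ion-Na"
  }

  fracs <- seq(0, 1, length.out = n_frames)
  sched <- function(f) {
    if (f < 0.20) d_start + (d_plateau1 - d_start) * f / 0.20
    else if (f < 0.45) d_plateau1
    else if (f < 0.60) d_plateau1 + (d_plateau2 - d_plateau1) * (f - 0.45) / 0.15
    else if (f < 0.85) d_plateau2
    else d_plateau2 + (d_end - d_plateau2) * (f - 0.85) / 0.15
  }
  dists <- vapply(fracs, sched, numeric(1))

  all_tab <- .bind_beads(Filter(Negate(is.null),
                                list(tab_a, tab_b, shell_tab_a, shell_tab_b,
                                     bg_tab)))
  frames <- vector("list", n_frames)
  for (k in seq_len(n_frames)) {
    d <- dists[k]
    ca <- c(box[1] / 2 - d / 2, box[2] / 2, box[3] / 2)
    cb <- c(box[1] / 2 + d / 2, box[2] / 2, box[3] / 2)
    xyz <- rbind(
      xa + matrix(ca, nrow(xa), 3, byrow = TRUE),
      xb + matrix(cb, nrow(xb), 3, byrow = TRUE),
      if (nrow(sa)) sa + matrix(ca, nrow(sa), 3, byrow = TRUE),
      if (nrow(sb)) sb + matrix(cb, nrow(sb), 3, byrow = TRUE),
      bg_xyz)
    xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, noise), nrow(xyz), 3)
    frames[[k]] <- cg_frame(xyz, box, all_tab)
  }
  tr <- cg_trajectory(frames, fracs * total_ns)
  attr(tr, "fusion") <- list(members_a = members_a, members_b = members_b,
                             scheduled = dists)
  tr
}
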