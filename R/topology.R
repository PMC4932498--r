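#' Amphiphilic dendrimer specification
#'
#' An amphiphilic dendrimer (AD) couples a hydrophilic PAMAM dendron head of
#' generation g (carrying 2^(g+1) protonated terminal amines) to a single
#' hydrophobic alkyl tail of 13, 15 or 18 carbons through an aromatic ring.
#' Under the 4:1 MARTINI mapping the tails become 3, 4 or 5 C1 beads and the
#' ring one hydrophobic bead.
#'
#' @param generation dendron generation, one of 0, 1, 2
#' @param tail_carbons alkyl tail length, one of 13, 15, 18
#' @return object of class `ad_spec` with fields `generation`, `tail_carbons`,
#'   `n_terminal` (= 2^(g+1)), `n_tail_beads`, `charge` (= `n_terminal`, the
#'   per-molecule charge e used by the surface-charge density)
#' @export
ad_spec <- function(generation, tail_carbons) {
  if (!length(generation) == 1 || !generation %in% c(0, 1, 2))
    stop("unsupported dendron generation: ", generation,
         " (supported: 0, 1, 2)")
  tail_map <- c(`13` = 3L, `15` = 4L, `18` = 5L)
  if (!length(tail_carbons) == 1 ||
      !as.character(tail_carbons) %in% names(tail_map))
    stop("unsupported tail length: ", tail_carbons,
         " carbons (supported: 13, 15, 18)")
  n_term <- 2L^(as.integer(generation) + 1L)
  structure(
    list(generation = as.integer(generation),
         tail_carbons = as.integer(tail_carbons),
         n_terminal = n_term,
         n_tail_beads = tail_map[[as.character(tail_carbons)]],
         charge = n_term),
    class = "ad_spec"
  )
}

#' @export
print.ad_spec <- function(x, ...) {
  cat(sprintf("G%d-%dC amphiphilic dendrimer: %d terminal amines (+%d e), %d tail beads\n",
              x$generation, x$tail_carbons, x$n_terminal, x$charge,
              x$n_tail_beads))
  invisible(x)
}

#' Build the CG topology of one amphiphilic dendrimer
#'
#' The dendron head is mapped as a binary tree: one neutral amide node bead
#' (Nda) per branch point and one charged Qd bead per protonated terminal
#' amine, bonded along the dendritic connectivity. The focal node attaches to
#' a single hydrophobic ring bead, which anchors the linear C1 alkyl tail.
#' Bead order: head nodes in breadth-first order, then terminal amines, then
#' the ring, then tail beads from the ring outward.
#'
#' @param spec an [ad_spec()]
#' @return a [cg_topology()] with net charge +2^(g+1)
#' @export
build_ad_topology <- function(spec) {
  stopifnot(inherits(spec, "ad_spec"))
  g <- spec$generation
  n_nodes <- 2L^(g + 1L) - 1L          # complete binary tree of branch points
  n_term <- spec$n_terminal
  n_tail <- spec$n_tail_beads

  name <- c(sprintf("N%d", seq_len(n_nodes)),
            sprintf("NH%d", seq_len(n_term)),
            "RNG",
            sprintf("C%d", seq_len(n_tail)))
  type <- c(rep("Nda", n_nodes), rep("Qd", n_term), "C1", rep("C1", n_tail))
  charge <- c(rep(0L, n_nodes), rep(1L, n_term), 0L, rep(0L, n_tail))
  role <- c(rep("head-node", n_nodes), rep("terminal-amine", n_term),
            "ring", rep("tail", n_tail))
  beads <- bead_table(name, type, charge, role)

  ring <- n_nodes + n_term            # 0-based index of the ring bead
  # tree bonds: node i (1-based heap order) has children 2i and 2i+1; heap
  # slots beyond n_nodes are terminal amines
  bi <- integer(0); bj <- integer(0); r0 <- numeric(0)
  for (p in seq_len(n_nodes)) {
    for (c_ in c(2L * p, 2L * p + 1L)) {
      child0 <- if (c_ <= n_nodes) c_ - 1L else n_nodes + (c_ - n_nodes - 1L)
      bi <- c(bi, p - 1L); bj <- c(bj, child0)
      r0 <- c(r0, .martini$branch_r0)
    }
  }
  # focal node - ring, ring - tail, tail chain
  bi <- c(bi, 0L, ring); bj <- c(bj, ring, ring + 1L)
  r0 <- c(r0, .martini$branch_r0, .martini$bond_r0)
  if (n_tail > 1) {
    bi <- c(bi, ring + seq_len(n_tail - 1L))
    bj <- c(bj, ring + seq_len(n_tail - 1L) + 1L)
    r0 <- c(r0, rep(.martini$bond_r0, n_tail - 1L))
  }
  bonds <- bonded_table("bond", bi, bj, NA_integer_, r0,
                        rep(.martini$bond_k, length(bi)))
  # gentle 180-degree angles keep the alkyl chain extended, as in the CG
  # lipid parameter set
  if (n_tail >= 2) {
    ai <- ring + 0:(n_tail - 2L)
    angles <- bonded_table("angle", ai, ai + 1L, ai + 2L,
                           rep(180, length(ai)), rep(25, length(ai)))
    bonds <- rbind(bonds, angles)
  }
  cg_topology(sprintf("G%d-%dC", g, spec$tail_carbons), beads, bonds)
}

# ---------------------------------------------------------------------------
# siRNA duplex

# base bead complements (Table-style mapping): purines 3 beads, pyrimidines 2;
# dT overhangs take the uridine complement
.base_beads <- list(
  A = c("Na", "Na", "Nda"),
  G = c("Nda", "Nda", "Na"),
  C = c("Na", "Nd"),
  U = c("Na", "Na"),
  T = c("Na", "Na")
)

.parse_strand <- function(seq) {
  seq <- gsub("[ '5'3′-]", "", seq)
  seq <- gsub("dT", "T", seq)
  toupper(strsplit(seq, "")[[1]])
}

.rna_complement <- c(A = "U", U = "A", G = "C", C = "G")

#' siRNA duplex specification
#'
#' @param sense,antisense core RNA strands written 5'->3' (A/C/G/U; `dT`
#'   tokens allowed for deoxy overhang residues). Defaults are the 20
#'   base-pair duplex targeting heat shock protein 27.
#' @param overhang 3' overhang appended to both strands when
#'   `include_overhangs` is TRUE (default the dTdT pair)
#' @param include_overhangs logical
#' @return object of class `sirna_spec` with the per-strand residue vectors,
#'   `n_basepairs` and `n_phosphates_core` (= 2 x n_basepairs; overhang
#'   phosphates are excluded from N/P accounting)
#' @export
sirna_duplex_spec <- function(sense = "GCUGCAAAAUCCGAUGAGAC",
                              antisense = "GUCUCAUCGGAUUUUGCAGC",
                              overhang = "dTdT",
                              include_overhangs = TRUE) {
  s <- .parse_strand(sense)
  a <- .parse_strand(antisense)
  strip_oh <- function(x) {
    while (length(x) && x[length(x)] == "T") x <- x[-length(x)]
    x
  }
  s <- strip_oh(s); a <- strip_oh(a)
  if (any(!s %in% c("A", "C", "G", "U")) || any(!a %in% c("A", "C", "G", "U")))
    stop("core strands must be RNA (A/C/G/U); dT is only valid as 3' overhang")
  if (length(s) != length(a))
    stop("core strands differ in length")
  if (!all(.rna_complement[s] == rev(a)))
    stop("core strands are not reverse-complementary")
  oh <- if (include_overhangs) .parse_strand(overhang) else character(0)
  if (any(oh != "T")) stop("only dT overhangs are supported")
  structure(
    list(sense = s, antisense = a, overhang = oh,
         include_overhangs = include_overhangs,
         n_basepairs = length(s),
         n_phosphates_core = 2L * length(s)),
    class = "sirna_spec"
  )
}

#' @export
print.sirna_spec <- function(x, ...) {
  cat(sprintf("siRNA duplex: %d core base pairs (%d core phosphates)%s\n",
              x$n_basepairs, x$n_phosphates_core,
              if (length(x$overhang))
                sprintf(", %d-nt dT overhangs", length(x$overhang)) else ""))
  invisible(x)
}

# per-strand residue table: base letter, strand id, residue index, overhang
# flag and the core base-pair index (residue i of strand 1 pairs with residue
# n-i+1 of strand 2; overhang residues carry NA)
.duplex_residues <- function(spec) {
  n <- spec$n_basepairs
  oh <- length(spec$overhang)
  res <- rbind(
    data.frame(base = c(spec$sense, spec$overhang), strand = 1L,
               resno = seq_len(n + oh),
               overhang = c(rep(FALSE, n), rep(TRUE, oh)),
               basepair = c(seq_len(n), rep(NA_integer_, oh))),
    data.frame(base = c(spec$antisense, spec$overhang), strand = 2L,
               resno = seq_len(n + oh),
               overhang = c(rep(FALSE, n), rep(TRUE, oh)),
               basepair = c(rev(seq_len(n)), rep(NA_integer_, oh)))
  )
  res
}

#' Build the CG topology (and coordinates) of the siRNA duplex
#'
#' Each nucleotide maps to one Qa phosphate (-1 e), one P1 ribose bead and
#' 2-3 neutral base beads (purines 3, pyrimidines 2; dT overhangs take the
#' uridine complement). Every residue, including the 5' terminal one,
#' carries a phosphate bead, so the 20-bp core holds exactly 40 phosphates.
#' When no coordinates are supplied an idealized A-form helix is generated;
#' alternatively an atomistic structure can be reduced by centre-of-mass
#' mapping via [map_atomistic_duplex()].
#'
#' @param spec a [sirna_duplex_spec()]
#' @param coords optional N_beads x 3 coordinate matrix (nm) to attach
#' @param box box lengths for the returned frame (default fits the helix)
#' @return list with `topology` (a [cg_topology()]) and `frame` (a
#'   [cg_frame()]); the topology bead table carries `strand`, `resno`,
#'   `basepair` and `overhang` metadata columns
#' @export
build_sirna_topology <- function(spec, coords = NULL, box = NULL) {
  stopifnot(inherits(spec, "sirna_spec"))
  res <- .duplex_residues(spec)
  rows <- list()
  for (r in seq_len(nrow(res))) {
    b <- res$base[r]
    bb <- .base_beads[[b]]
    if (is.null(bb)) stop("unknown residue: ", b)
    nb <- 2L + length(bb)
    rows[[r]] <- data.frame(
      name = c("PO4", "RIB", sprintf("B%d", seq_along(bb))),
      martini_type = c("Qa", "P1", bb),
      charge = c(-1L, rep(0L, nb - 1L)),
      role = c("phosphate", "sugar", rep("base", length(bb))),
      base = b, strand = res$strand[r], resno = res$resno[r],
      basepair = res$basepair[r], overhang = res$overhang[r],
      stringsAsFactors = FALSE
    )
  }
  tab <- do.call(rbind, rows)
  beads <- bead_table(tab$name, tab$martini_type, tab$charge, tab$role)
  beads$base <- tab$base
  beads$strand <- tab$strand
  beads$resno <- tab$resno
  beads$basepair <- tab$basepair
  beads$overhang <- tab$overhang

  # covalent skeleton: P-sugar, sugar-base1, base chain, sugar(i)-P(i+1)
  bi <- integer(0); bj <- integer(0); r0 <- numeric(0)
  first_of <- tapply(beads$index, list(beads$strand, beads$resno), min)
  for (st in 1:2) {
    resnos <- sort(unique(beads$resno[beads$strand == st]))
    for (rn in resnos) {
      i0 <- first_of[[as.character(st), as.character(rn)]]
      nb <- sum(beads$strand == st & beads$resno == rn)
      bi <- c(bi, i0, i0 + 1L); bj <- c(bj, i0 + 1L, i0 + 2L)
      r0 <- c(r0, 0.35, 0.35)
      if (nb == 5L) { bi <- c(bi, i0 + 2L); bj <- c(bj, i0 + 3L); r0 <- c(r0, 0.3) }
      if (nb >= 4L) { bi <- c(bi, i0 + nb - 2L); bj <- c(bj, i0 + nb - 1L); r0 <- c(r0, 0.3) }
      if (rn > resnos[1]) {
        prev <- first_of[[as.character(st), as.character(rn - 1L)]]
        bi <- c(bi, prev + 1L); bj <- c(bj, i0); r0 <- c(r0, 0.35)
      }
    }
  }
  keep <- !duplicated(paste(pmin(bi, bj), pmax(bi, bj)))
  bonds <- bonded_table("bond", bi[keep], bj[keep], NA_integer_, r0[keep],
                        rep(.martini$bond_k, sum(keep)))
  topo <- cg_topology("siRNA", beads, bonds)

  if (is.null(coords)) coords <- .aform_coords(beads, spec)
  coords <- as.matrix(coords)
  if (nrow(coords) != nrow(beads))
    stop("coordinate set has ", nrow(coords), " rows for ", nrow(beads), " beads")
  if (is.null(box)) {
    span <- apply(coords, 2, function(v) diff(range(v)))
    box <- rep(max(span) + 6, 3)
  }
  centre <- box / 2 - (apply(coords, 2, min) + apply(coords, 2, max)) / 2
  coords <- coords + matrix(centre, nrow(coords), 3, byrow = TRUE)
  fb <- beads
  fb$molecule_id <- 1L
  fb$molecule_kind <- "siRNA"
  list(topology = topo, frame = cg_frame(coords, box, fb))
}

# Idealized A-form duplex at CG resolution: rise 0.28 nm/bp, twist 32.7
# deg/bp, phosphate backbone radius 0.9 nm, base beads stepping towards the
# helical axis. Any helical geometry with realistic elastic-network contact
# statistics is acceptable here; this one keeps intra-residue bead spacings
# at 0.2-0.35 nm.
.aform_coords <- function(beads, spec) {
  rise <- 0.28; twist <- 32.7 * pi / 180
  strand_phase <- c(0, 165 * pi / 180)   # inter-strand angular offset
  n_core <- spec$n_basepairs
  coords <- matrix(0, nrow(beads), 3)
  for (r in which(!duplicated(paste(beads$strand, beads$resno)))) {
    st <- beads$strand[r]; rn <- beads$resno[r]
    # axial position: strand 1 runs +z with residue number, strand 2 is
    # antiparallel; overhang residues extend beyond the core
    level <- if (st == 1L) rn else (n_core + 1L - rn)
    z <- level * rise
    th <- level * twist * (if (st == 1L) 1 else 1) + strand_phase[st]
    sel <- which(beads$strand == st & beads$resno == rn)
    radii <- c(0.92, 0.70, 0.48, 0.30, 0.16)[seq_along(sel)]
    dth <- (seq_along(sel) - 1) * 0.12   # small azimuthal stagger
    dz <- (seq_along(sel) - 1) * 0.04
    coords[sel, ] <- cbind(radii * cos(th + dth),
                           radii * sin(th + dth),
                           z + dz)
  }
  coords
}

# ---------------------------------------------------------------------------
# atomistic -> CG reduction

# heavy-atom groups per bead, matched against PDB atom names (primes as ')
.atom_groups <- function(base, nbeads) {
  phosphate <- c("P", "OP1", "OP2", "O1P", "O2P", "O5'")
  sugar <- c("C5'", "C4'", "O4'", "C3'", "O3'", "C2'", "O2'", "C1'")
  base_groups <- switch(base,
    A = list(c("N9", "C8", "N7"), c("C5", "C6", "N6", "N1"),
             c("C2", "N3", "C4")),
    G = list(c("N9", "C8", "N7"), c("C5", "C6", "O6", "N1"),
             c("C2", "N2", "N3", "C4")),
    C = list(c("N1", "C2", "O2", "N3"), c("C4", "N4", "C5", "C6")),
    U = list(c("N1", "C2", "O2", "N3"), c("C4", "O4", "C5", "C6")),
    T = list(c("N1", "C2", "O2", "N3"), c("C4", "O4", "C5", "C6", "C7")),
    stop("no atom mapping for base ", base))
  c(list(phosphate, sugar), base_groups)[seq_len(nbeads)]
}

.atomic_masses <- c(C = 12.011, N = 14.007, O = 15.999, P = 30.974)

#' Map an atomistic duplex onto the CG bead positions
#'
#' Each CG bead is placed at the mass-weighted centre of its mapped
#' heavy-atom group (standard MARTINI practice). Atom records must carry PDB
#' atom names, residue numbers per strand and chain identifiers; hydrogens
#' are ignored.
#'
#' @param spec a [sirna_duplex_spec()]
#' @param atoms data.frame with columns `elety` (atom name), `resno`,
#'   `chain` (two values, sense strand first), `x`, `y`, `z` in nm
#' @return coordinate matrix suitable for [build_sirna_topology()]'s `coords`
#' @export
map_atomistic_duplex <- function(spec, atoms) {
  built <- build_sirna_topology(spec)   # bead ordering authority
  beads <- built$topology$beads
  chains <- unique(atoms$chain)
  if (length(chains) != 2) stop("expected exactly two chains")
  coords <- matrix(NA_real_, nrow(beads), 3)
  for (r in which(!duplicated(paste(beads$strand, beads$resno)))) {
    st <- beads$strand[r]; rn <- beads$resno[r]
    sel <- which(beads$strand == st & beads$resno == rn)
    groups <- .atom_groups(beads$base[r], length(sel))
    at <- atoms[atoms$chain == chains[st] & atoms$resno == rn, , drop = FALSE]
    if (!nrow(at)) stop("no atoms for strand ", st, " residue ", rn)
    for (gi in seq_along(groups)) {
      g <- at[at$elety %in% groups[[gi]], , drop = FALSE]
      if (!nrow(g))
        stop("no atoms found for bead group ", gi, " of residue ", rn)
      el <- substr(g$elety, 1, 1)
      m <- .atomic_masses[el]
      m[is.na(m)] <- 12
      coords[sel[gi], ] <- .centroid(cbind(g$x, g$y, g$z), m)
    }
  }
  coords
}

# ---------------------------------------------------------------------------
# elastic network

#' Overlay an elastic network on a topology
#'
#' Every bead pair (i < j) that is not covalently bonded and sits within the
#' cutoff in the supplied conformation is restrained by a harmonic term whose
#' equilibrium is the observed distance; pairs beyond the cutoff interact
#' only through non-bonded terms. Defaults follow the nucleic-acid
#' elastic-network convention: 0.7 nm cutoff, 1500 kJ mol-1 nm-2.
#'
#' @param topology a [cg_topology()]
#' @param frame a [cg_frame()] (or bare coordinate matrix) with one position
#'   per bead; distances are taken without periodicity (single molecule)
#' @param cutoff nm
#' @param k force constant, kJ mol-1 nm-2
#' @return the topology with `elastic` terms appended
#' @export
apply_elastic_network <- function(topology, frame, cutoff = 0.7, k = 1500) {
  stopifnot(inherits(topology, "cg_topology"))
  coords <- if (inherits(frame, "cg_frame")) frame$positions else as.matrix(frame)
  if (is.null(coords) || nrow(coords) != nrow(topology$beads))
    stop("elastic network needs one coordinate per bead")
  if (cutoff <= 0 || k <= 0) stop("cutoff and k must be positive")
  d <- as.matrix(stats::dist(coords))
  n <- nrow(coords)
  bonded_key <- paste(pmin(topology$bonded$i, topology$bonded$j),
                      pmax(topology$bonded$i, topology$bonded$j))
  bonded_key <- bonded_key[topology$bonded$kind != "angle"]
  idx <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  if (nrow(idx)) {
    i0 <- idx[, 1] - 1L; j0 <- idx[, 2] - 1L
    keep <- !(paste(pmin(i0, j0), pmax(i0, j0)) %in% bonded_key)
    idx <- idx[keep, , drop = FALSE]
  }
  if (nrow(idx)) {
    terms <- bonded_table("elastic", idx[, 1] - 1L, idx[, 2] - 1L,
                          NA_integer_, d[idx], rep(k, nrow(idx)))
    topology$bonded <- rbind(topology$bonded, terms)
  }
  cg_topology(topology$name, topology$beads, topology$bonded)
}
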