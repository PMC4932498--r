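# Fixture builders and independent brute-force oracles shared across tests.
# Oracles are deliberately naive O(n^2) double loops, kept separate from the
# package's vectorised implementations.

# minimum-image distance between two points, scalar arithmetic
brute_min_image_dist <- function(p, q, box) {
  d <- p - q
  d <- d - round(d / box) * box
  sqrt(sum(d^2))
}

# brute-force pair count at a cutoff
brute_count_contacts <- function(xa, xb, box, cutoff) {
  n <- 0L
  for (i in seq_len(nrow(xa)))
    for (j in seq_len(nrow(xb)))
      if (brute_min_image_dist(xa[i, ], xb[j, ], box) <= cutoff)
        n <- n + 1L
  n
}

# brute-force single-linkage partition of AD molecules on hydrophobic beads
brute_partition <- function(frame, cutoff) {
  b <- frame$beads
  mols <- sort(unique(b$molecule_id[b$molecule_kind == "AD"]))
  nm <- length(mols)
  parent <- seq_len(nm)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (a in seq_len(nm - 1)) {
    ia <- which(b$molecule_id == mols[a] & b$hydrophobic)
    for (c_ in (a + 1):nm) {
      ic <- which(b$molecule_id == mols[c_] & b$hydrophobic)
      linked <- FALSE
      for (i in ia) {
        for (j in ic) {
          if (brute_min_image_dist(frame$positions[i, ],
                                   frame$positions[j, ],
                                   frame$box) <= cutoff) {
            linked <- TRUE
            break
          }
        }
        if (linked) break
      }
      if (linked) {
        ra <- find(a); rc <- find(c_)
        if (ra != rc) parent[rc] <- ra
      }
    }
  }
  roots <- vapply(seq_len(nm), find, integer(1))
  unname(lapply(split(mols, roots), sort))
}

# canonical form of a partition for comparison
canon_partition <- function(sets) {
  sets <- lapply(sets, sort)
  sets[order(vapply(sets, `[`, integer(1), 1))]
}

# brute-force elastic-network enumeration over all bead pairs
brute_elastic <- function(coords, bonded, cutoff) {
  n <- nrow(coords)
  keys <- paste(pmin(bonded$i, bonded$j), pmax(bonded$i, bonded$j))
  out <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      if (d <= cutoff && !(paste(i - 1, j - 1) %in% keys))
        out[[length(out) + 1L]] <- c(i - 1, j - 1, d)
    }
  }
  if (!length(out)) return(matrix(numeric(0), 0, 3))
  do.call(rbind, out)
}

# random dispersion of single ADs in a box (no aggregation intended)
make_dispersion <- function(spec, n_ads, box = c(20, 20, 20), seed = 1) {
  set.seed(seed)
  topo <- build_ad_topology(spec)
  single <- single_ad_frame(spec, box = c(6, 6, 6))
  base <- single$positions -
    matrix(colMeans(single$positions), nrow(single$positions), 3, byrow = TRUE)
  tabs <- list(); blocks <- list()
  for (m in seq_len(n_ads)) {
    centre <- runif(3, 0, 1) * box
    blocks[[m]] <- base + matrix(centre, nrow(base), 3, byrow = TRUE)
    bt <- topo$beads
    bt$molecule_id <- m
    bt$molecule_kind <- "AD"
    tabs[[m]] <- bt
  }
  cg_frame(do.call(rbind, blocks), box, dendrimicelle:::.bind_beads(tabs))
}

# append free beads of a given kind to a frame
add_beads <- function(frame, xyz, kind = "water") {
  xyz <- rbind(xyz)
  n <- nrow(xyz)
  name <- c(water = "W", Na = "NA+", Cl = "CL-")[kind]
  type <- c(water = "P4", Na = "Qd", Cl = "Qa")[kind]
  charge <- c(water = 0L, Na = 1L, Cl = -1L)[kind]
  role <- c(water = "water", Na = "ion-Na", Cl = "ion-Cl")[kind]
  tab <- bead_table(rep(name, n), rep(type, n), rep(charge, n), rep(role, n))
  tab$molecule_id <- max(0L, frame$beads$molecule_id) + seq_len(n)
  tab$molecule_kind <- kind
  cg_frame(rbind(frame$positions, xyz), frame$box,
           dendrimicelle:::.bind_beads(list(frame$beads, tab)))
}
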