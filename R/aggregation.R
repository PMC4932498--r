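# Aggregate detection and tracking under periodic boundaries.

#' Detect AD aggregates in a frame
#'
#' Single-linkage clustering of AD molecules: two molecules are linked when
#' any pair of their hydrophobic beads (tail + ring) lies within the cutoff
#' under the minimum-image convention; aggregates are the connected
#' components, singletons included. The default cutoff of 0.6 nm is the
#' first CG neighbour shell.
#'
#' @param frame a [cg_frame()] containing AD molecules
#' @param cutoff linkage cutoff, nm
#' @return list of aggregates, each a list with `members` (molecule ids),
#'   `n_agg`, `centroid` (unwrapped mass-weighted COM over all beads, nm)
#'   and `links` (molecule-pair matrix used for unwrapping); class
#'   `aggregate_list`
#' @export
detect_aggregates <- function(frame, cutoff = 0.6) {
  if (cutoff <= 0) stop("cutoff must be positive")
  b <- frame$beads
  ad <- b$molecule_kind == "AD"
  if (!any(ad)) stop("frame contains no AD molecules")
  hyd <- ad & b$hydrophobic
  idx <- which(hyd)
  mols <- sort(unique(b$molecule_id[ad]))
  xyz <- frame$positions[idx, , drop = FALSE]
  mol_of <- b$molecule_id[idx]
  d <- pdist_pbc(xyz, NULL, frame$box)
  hit <- which(d <= cutoff & upper.tri(d), arr.ind = TRUE)
  mi <- mol_of[hit[, 1]]; mj <- mol_of[hit[, 2]]
  keep <- mi != mj
  edges <- unique(cbind(pmin(mi[keep], mj[keep]), pmax(mi[keep], mj[keep])))
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges[, 1]), to = as.character(edges[, 2])),
    directed = FALSE,
    vertices = data.frame(name = as.character(mols)))
  comp <- igraph::components(g)
  out <- lapply(seq_len(comp$no), function(ci) {
    mem <- sort(as.integer(names(comp$membership)[comp$membership == ci]))
    lk <- edges[edges[, 1] %in% mem, , drop = FALSE]
    agg <- list(members = mem, n_agg = length(mem), links = lk)
    coords <- unwrap_aggregate(frame, agg)
    agg$centroid <- .centroid(coords, b$mass[attr(coords, "rows")])
    agg
  })
  # deterministic order: by descending size then smallest member id
  ord <- order(-vapply(out, `[[`, integer(1), "n_agg"),
               vapply(out, function(a) a$members[1], integer(1)))
  structure(out[ord], class = "aggregate_list")
}

#' @export
print.aggregate_list <- function(x, ...) {
  cat(sprintf("%d aggregate(s): N_agg = %s\n", length(x),
              paste(vapply(x, `[[`, integer(1), "n_agg"), collapse = ", ")))
  invisible(x)
}

#' Unwrap an aggregate across periodic boundaries
#'
#' Makes every member molecule whole, then walks a spanning tree of the
#' molecule linkage graph shifting each molecule by lattice vectors so that
#' every linked pair sits at its minimum image. Downstream geometry
#' (radius of gyration, core radii, COMs) uses these coordinates.
#'
#' @param frame the [cg_frame()] the aggregate was detected in
#' @param aggregate one element of [detect_aggregates()] output
#' @return coordinates (nm) of all beads of the member molecules, in frame
#'   bead order; attribute `rows` gives their row indices in the frame
#' @export
unwrap_aggregate <- function(frame, aggregate) {
  b <- frame$beads
  box <- frame$box
  mem <- aggregate$members
  rows_of <- lapply(mem, function(m)
    which(b$molecule_id == m & b$molecule_kind == "AD"))
  names(rows_of) <- as.character(mem)
  whole <- lapply(rows_of, function(r)
    .make_whole(frame$positions[r, , drop = FALSE], box))
  com <- t(vapply(whole, function(x) colMeans(x), numeric(3)))

  if (length(mem) > 1) {
    lk <- aggregate$links
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(lk[, 1]), to = as.character(lk[, 2])),
      directed = FALSE, vertices = data.frame(name = as.character(mem)))
    bfs <- igraph::bfs(g, root = 1, father = TRUE)
    order_v <- as.integer(bfs$order)
    father <- as.integer(bfs$father)
    shift <- matrix(0, length(mem), 3)
    for (vi in order_v[-1]) {
      fa <- father[vi]
      # shift so this molecule's COM is at minimum image from its father's
      d <- com[vi, ] + shift[vi, ] - (com[fa, ] + shift[fa, ])
      lat <- round(d / box) * box
      shift[vi, ] <- shift[vi, ] - lat
    }
    for (k in seq_along(mem))
      whole[[k]] <- whole[[k]] +
        matrix(shift[k, ], nrow(whole[[k]]), 3, byrow = TRUE)
  }
  coords <- do.call(rbind, whole)
  rows <- unlist(rows_of, use.names = FALSE)
  ext <- apply(coords, 2, function(v) diff(range(v)))
  if (all(ext > box / 2))
    warning("aggregate spans more than half the box in every dimension; ",
            "unwrapping is unreliable")
  attr(coords, "rows") <- rows
  coords
}

#' Track aggregates across a trajectory
#'
#' Aggregates in consecutive frames are linked into lineages by greedy
#' maximum member overlap (ties broken towards the lower lineage id). When
#' two lineages map onto one aggregate a merge event is recorded and the
#' larger-overlap lineage continues.
#'
#' @param trajectory a [cg_trajectory()]
#' @param cutoff linkage cutoff passed to [detect_aggregates()]
#' @return list with `table` (data.frame: frame, time_ns, lineage, n_agg,
#'   members as comma string), `merges` (data.frame: frame, time_ns,
#'   absorbed, into) and `aggregates` (per-frame [detect_aggregates()]
#'   output)
#' @export
track_aggregates <- function(trajectory, cutoff = 0.6) {
  nf <- length(trajectory$frames)
  if (nf < 2) stop("tracking needs at least 2 frames")
  per_frame <- lapply(trajectory$frames, detect_aggregates, cutoff = cutoff)
  next_lineage <- 0L
  prev_ids <- NULL
  rows <- list(); merges <- list()
  for (f in seq_len(nf)) {
    aggs <- per_frame[[f]]
    ids <- integer(length(aggs))
    if (f == 1) {
      ids <- seq_along(aggs)
      next_lineage <- length(aggs)
    } else {
      prev <- per_frame[[f - 1]]
      # overlap matrix lineage x aggregate
      cand <- expand.grid(p = seq_along(prev), a = seq_along(aggs))
      cand$ov <- mapply(function(p, a)
        length(intersect(prev[[p]]$members, aggs[[a]]$members)),
        cand$p, cand$a)
      cand <- cand[cand$ov > 0, , drop = FALSE]
      cand <- cand[order(-cand$ov, prev_ids[cand$p]), , drop = FALSE]
      taken_a <- rep(FALSE, length(aggs))
      taken_p <- rep(FALSE, length(prev))
      map_to <- rep(NA_integer_, length(aggs))
      for (r in seq_len(nrow(cand))) {
        p <- cand$p[r]; a <- cand$a[r]
        if (taken_p[p]) next
        if (!taken_a[a]) {
          map_to[a] <- prev_ids[p]
          taken_a[a] <- TRUE; taken_p[p] <- TRUE
        } else {
          # second lineage mapping onto an already-claimed aggregate: merge
          merges[[length(merges) + 1L]] <- data.frame(
            frame = f, time_ns = trajectory$times[f],
            absorbed = prev_ids[p], into = map_to[a])
          taken_p[p] <- TRUE
        }
      }
      for (a in seq_along(aggs)) {
        if (is.na(map_to[a])) {
          next_lineage <- next_lineage + 1L
          map_to[a] <- next_lineage
        }
      }
      ids <- map_to
    }
    prev_ids <- ids
    rows[[f]] <- data.frame(
      frame = f, time_ns = trajectory$times[f], lineage = ids,
      n_agg = vapply(aggs, `[[`, integer(1), "n_agg"),
      members = vapply(aggs, function(a)
        paste(a$members, collapse = ","), character(1)))
  }
  list(table = do.call(rbind, rows),
       merges = if (length(merges)) do.call(rbind, merges) else
         data.frame(frame = integer(0), time_ns = numeric(0),
                    absorbed = integer(0), into = integer(0)),
       aggregates = per_frame)
}

#' Fusion-event observables for a micelle pair
#'
#' Follows the two molecule groups that constitute a fusing micelle pair
#' through a trajectory and reports, per frame: the COM distance, the
#' number of chloride and water beads shared by both solvation shells
#' (within `solvation_cutoff` of beads of each group), and the cross-group
#' hydrophilic (head-head) and hydrophobic (tail/ring) contact pair counts
#' at `contact_cutoff`.
#'
#' @param trajectory a [cg_trajectory()]
#' @param members_a,members_b molecule ids of the two micelles (e.g. from a
#'   [track_aggregates()] lineage or the generator's `fusion` attribute)
#' @param solvation_cutoff nm (default 0.65, the solvation-shell convention)
#' @param contact_cutoff nm (default 0.75, the contact convention)
#' @return data.frame with columns `time_ns`, `com_distance`,
#'   `shared_chloride`, `shared_water`, `hydrophilic_contacts`,
#'   `hydrophobic_contacts`
#' @export
fusion_profile <- function(trajectory, members_a, members_b,
                           solvation_cutoff = 0.65, contact_cutoff = 0.75) {
  if (!length(members_a) || !length(members_b))
    stop("both molecule groups must be non-empty")
  if (length(intersect(members_a, members_b)))
    stop("micelle member sets overlap")
  nf <- length(trajectory$frames)
  out <- data.frame(time_ns = trajectory$times, com_distance = NA_real_,
                    shared_chloride = NA_integer_, shared_water = NA_integer_,
                    hydrophilic_contacts = NA_integer_,
                    hydrophobic_contacts = NA_integer_)
  for (f in seq_len(nf)) {
    fr <- trajectory$frames[[f]]
    b <- fr$beads
    ra <- which(b$molecule_id %in% members_a)
    rb <- which(b$molecule_id %in% members_b)
    if (!length(ra) || !length(rb))
      stop("molecule group absent from frame ", f)
    xa <- fr$positions[ra, , drop = FALSE]
    xb <- fr$positions[rb, , drop = FALSE]
    ca <- .centroid(.make_whole(xa, fr$box), b$mass[ra])
    cb <- .centroid(.make_whole(xb, fr$box), b$mass[rb])
    out$com_distance[f] <- pdist_pbc(rbind(ca), rbind(cb), fr$box)[1, 1]
    for (sp in c("Cl", "water")) {
      si <- which(b$molecule_kind == sp)
      if (!length(si)) {
        cnt <- 0L
      } else {
        xs <- fr$positions[si, , drop = FALSE]
        near_a <- apply(pdist_pbc(xs, xa, fr$box), 1, min) <= solvation_cutoff
        near_b <- apply(pdist_pbc(xs, xb, fr$box), 1, min) <= solvation_cutoff
        cnt <- sum(near_a & near_b)
      }
      if (sp == "Cl") out$shared_chloride[f] <- cnt else
        out$shared_water[f] <- cnt
    }
    head_a <- ra[b$role[ra] %in% c("head-node", "terminal-amine")]
    head_b <- rb[b$role[rb] %in% c("head-node", "terminal-amine")]
    hyd_a <- ra[b$hydrophobic[ra]]
    hyd_b <- rb[b$hydrophobic[rb]]
    out$hydrophilic_contacts[f] <- sum(
      pdist_pbc(fr$positions[head_a, , drop = FALSE],
                fr$positions[head_b, , drop = FALSE], fr$box) <= contact_cutoff)
    out$hydrophobic_contacts[f] <- sum(
      pdist_pbc(fr$positions[hyd_a, , drop = FALSE],
                fr$positions[hyd_b, , drop = FALSE], fr$box) <= contact_cutoff)
  }
  out
}
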