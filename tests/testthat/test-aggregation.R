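# Aggregate detection, unwrapping, tracking and fusion observables.

spec18 <- ad_spec(2, 18)

test_that("two ADs within the cutoff form one aggregate", {
  fr <- generate_micelle(spec18, 2, core_radius_target = 0.7, seed = 2)
  aggs <- detect_aggregates(fr, 0.6)
  expect_equal(length(aggs), 1L)
  expect_equal(aggs[[1]]$n_agg, 2L)
})

test_that("a dispersion at a tiny cutoff is all singletons", {
  fr <- make_dispersion(spec18, 30, box = c(40, 40, 40), seed = 5)
  aggs <- detect_aggregates(fr, 0.01)
  expect_equal(length(aggs), 30L)
  expect_true(all(vapply(aggs, `[[`, integer(1), "n_agg") == 1L))
})

test_that("detection equals the brute-force connected-components oracle", {
  # crowded boxes at several cutoffs, wrapped coordinates
  for (seed in 1:3) {
    fr <- make_dispersion(spec18, 14, box = c(9, 9, 9), seed = seed)
    fr <- wrap_frame(fr)
    for (cutoff in c(0.4, 0.8, 1.5)) {
      aggs <- detect_aggregates(fr, cutoff)
      got <- canon_partition(lapply(aggs, `[[`, "members"))
      want <- canon_partition(brute_partition(fr, cutoff))
      expect_equal(got, want)
    }
  }
})

test_that("detect_aggregates output is a partition and rejects bad cutoffs", {
  fr <- make_dispersion(spec18, 12, box = c(10, 10, 10), seed = 7)
  aggs <- detect_aggregates(fr, 0.8)
  members <- unlist(lapply(aggs, `[[`, "members"))
  expect_equal(sort(members), 1:12)          # disjoint and exhaustive
  expect_equal(sum(vapply(aggs, `[[`, integer(1), "n_agg")), 12L)
  expect_error(detect_aggregates(fr, 0), "positive")
})

test_that("aggregate count is non-increasing in the cutoff", {
  fr <- make_dispersion(spec18, 15, box = c(10, 10, 10), seed = 11)
  counts <- vapply(c(0.1, 0.3, 0.6, 1.0, 2.0, 4.0),
                   function(cu)
                     length(suppressWarnings(detect_aggregates(fr, cu))),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
  # an aggregate spanning the whole box in every dimension is flagged
  expect_warning(detect_aggregates(fr, 4.0), "unwrapping is unreliable")
})

test_that("partitions and COM distances are invariant to lattice translation", {
  fr <- make_dispersion(spec18, 10, box = c(8, 8, 8), seed = 13)
  fr <- wrap_frame(fr)
  aggs <- detect_aggregates(fr, 0.9)
  shifted <- fr
  shifted$positions <- shifted$positions +
    matrix(c(8, -16, 8), nrow(fr$positions), 3, byrow = TRUE)
  aggs2 <- detect_aggregates(shifted, 0.9)
  expect_equal(canon_partition(lapply(aggs, `[[`, "members")),
               canon_partition(lapply(aggs2, `[[`, "members")))
  # COM distance between the two largest groups unchanged
  tr1 <- cg_trajectory(list(fr), 0)
  tr2 <- cg_trajectory(list(shifted), 0)
  g1 <- which(fr$beads$molecule_id %in% 1:3)
  g2 <- which(fr$beads$molecule_id %in% 4:6)
  expect_equal(com_distance_series(tr1, g1, g2)$com_distance,
               com_distance_series(tr2, g1, g2)$com_distance,
               tolerance = 1e-9)
})

test_that("unwrapping restores the geometry of a boundary-straddling micelle", {
  fr <- generate_micelle(spec18, 13, core_radius_target = 1.0, seed = 3)
  agg <- detect_aggregates(fr, 0.6)[[1]]
  co_ref <- unwrap_aggregate(fr, agg)
  mass <- fr$beads$mass[attr(co_ref, "rows")]
  rg <- function(co) {
    com <- colSums(co * mass / sum(mass))
    sqrt(sum(rowSums((co - matrix(com, nrow(co), 3, byrow = TRUE))^2) *
               mass / sum(mass)))
  }
  # push the micelle across the +x boundary and wrap
  moved <- fr
  moved$positions[, 1] <- moved$positions[, 1] + fr$box[1] / 2
  moved <- wrap_frame(moved)
  agg2 <- detect_aggregates(moved, 0.6)[[1]]
  co2 <- unwrap_aggregate(moved, agg2)
  expect_lt(diff(range(co2[, 1])), moved$box[1] / 2)  # whole again
  expect_equal(rg(co2), rg(co_ref), tolerance = 1e-6)

  # fully interior aggregate: unwrapping is the identity
  co3 <- unwrap_aggregate(fr, agg)
  expect_equal(unname(co3[, ]), unname(fr$positions[attr(co3, "rows"), ]),
               tolerance = 1e-12)
})

test_that("tracking records lineages and exactly one merge for a fusion", {
  ma <- generate_micelle(spec18, 10, core_radius_target = 0.95, seed = 41)
  mb <- generate_micelle(spec18, 10, core_radius_target = 0.95, seed = 42)
  tr <- generate_fusion_trajectory(ma, mb, n_frames = 40, seed = 6)
  trk <- track_aggregates(tr, 0.6)
  expect_equal(nrow(trk$merges), 1L)
  # per-frame conservation of molecules
  per_frame <- tapply(trk$table$n_agg, trk$table$frame, sum)
  expect_true(all(per_frame == 20L))

  # static trajectory: constant membership, no merges
  st <- cg_trajectory(list(ma, ma, ma), 0:2)
  trk2 <- track_aggregates(st, 0.6)
  expect_equal(nrow(trk2$merges), 0L)
  expect_equal(length(unique(trk2$table$members)), 1L)
})

test_that("fusion profiles capture shared ions before hydrophobic contact", {
  ma <- generate_micelle(spec18, 13, core_radius_target = 1.0, seed = 21)
  mb <- generate_micelle(spec18, 13, core_radius_target = 1.0, seed = 22)
  tr <- generate_fusion_trajectory(ma, mb, n_frames = 60, seed = 5)
  fu <- attr(tr, "fusion")
  prof <- fusion_profile(tr, fu$members_a, fu$members_b)
  expect_equal(nrow(prof), 60L)
  expect_true(all(prof$shared_chloride >= 0))
  # chloride sharing rises before hydrophobic contacts do
  first_cl <- which(prof$shared_chloride >= 3)[1]
  first_hyd <- which(prof$hydrophobic_contacts >= 3)[1]
  expect_lt(first_cl, first_hyd)
  # fully merged at the end
  expect_lt(prof$com_distance[60], 1)
  # COM plateaus near 6 and 2 nm are detectable
  pl <- find_plateaus(prof$time_ns, prof$com_distance)
  expect_gte(nrow(pl), 2)
  expect_true(any(abs(pl$level - 6) < 0.3))
  expect_true(any(abs(pl$level - 2) < 0.3))
})

test_that("a chloride near both micelles counts as shared exactly once", {
  ma <- generate_micelle(spec18, 2, core_radius_target = 0.7, seed = 1,
                         box = c(12, 12, 12), noise = 0)
  # second micelle: same construction shifted +2.2 nm in x
  mb <- ma
  mb$positions[, 1] <- mb$positions[, 1] + 2.2
  tb <- mb$beads; tb$molecule_id <- tb$molecule_id + 2L
  both <- cg_frame(rbind(ma$positions, mb$positions), ma$box,
                   dendrimicelle:::.bind_beads(list(ma$beads, tb)))
  # place one Cl within 0.5 nm of the nearest bead of each micelle
  na <- nrow(ma$positions)
  d_all <- pdist_pbc(both$positions[1:na, ],
                     both$positions[(na + 1):(2 * na), ], both$box)
  ij <- which(d_all == min(d_all), arr.ind = TRUE)[1, ]
  mid <- (both$positions[ij[1], ] + both$positions[na + ij[2], ]) / 2
  withcl <- add_beads(both, mid, "Cl")
  tr <- cg_trajectory(list(withcl), 0)
  prof <- fusion_profile(tr, 1:2, 3:4)
  expect_equal(prof$shared_chloride, 1L)
})
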