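# SASA, contact counters, solvation shells, RDF maps, COM series and
# amine-binding statistics.

spec18 <- ad_spec(2, 18)

test_that("SASA matches analytic spheres and handles coincident beads", {
  # isolated bead: 4 pi (r + probe)^2
  one <- sasa_coords(matrix(0, 1, 3), 1)
  expect_equal(one, 4 * pi * 0.52^2, tolerance = 1e-9)
  # two fully overlapping identical beads: the area of one
  two <- sum(sasa_coords(rbind(c(0, 0, 0), c(0, 0, 0)), 1:2))
  expect_equal(two, 4 * pi * 0.52^2, tolerance = 1e-9)
  expect_error(sasa_coords(matrix(0, 1, 3), 1, radii = 0), "positive")
})

test_that("SASA is translation- and rotation-invariant within 0.5%", {
  set.seed(3)
  co <- matrix(rnorm(8 * 3, sd = 0.4), 8, 3)
  base <- sum(sasa_coords(co, 1:8))
  th <- 1.1
  Rm <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  rot <- co %*% t(Rm) + 2.5
  expect_lt(abs(sum(sasa_coords(rot, 1:8)) - base) / base, 0.005)
})

test_that("SASA agrees with a refined independent sampling oracle", {
  tri <- rbind(c(0, 0, 0), c(0.4, 0, 0), c(0.8, 0, 0))
  mine <- sum(sasa_coords(tri, 1:3))
  # independent Monte-Carlo surface integration
  set.seed(99)
  R <- 0.52; npt <- 40000
  oracle <- 0
  for (i in 1:3) {
    u <- matrix(rnorm(3 * npt), npt, 3)
    u <- u / sqrt(rowSums(u^2))
    p <- u * R + matrix(tri[i, ], npt, 3, byrow = TRUE)
    acc <- rep(TRUE, npt)
    for (j in setdiff(1:3, i))
      acc <- acc & rowSums((p - matrix(tri[j, ], npt, 3,
                                       byrow = TRUE))^2) >= R^2
    oracle <- oracle + 4 * pi * R^2 * mean(acc)
  }
  expect_lt(abs(mine - oracle) / oracle, 0.02)
})

test_that("contact counting matches brute force and honours the boundary", {
  fr <- empty_frame(c(5, 5, 5))
  fr <- add_beads(fr, rbind(c(1, 1, 1), c(1.5, 1, 1)), "water")
  expect_equal(count_contacts(fr, 1L, 2L, 0.75), 1L)
  fr2 <- empty_frame(c(5, 5, 5))
  fr2 <- add_beads(fr2, rbind(c(1, 1, 1), c(1.76, 1, 1)), "water")
  expect_equal(count_contacts(fr2, 1L, 2L, 0.75), 0L)
  expect_error(count_contacts(fr, 1:2, 2L), "disjoint")

  # random wrapped frame vs O(n^2) oracle
  set.seed(7)
  box <- c(4, 4, 4)
  xs <- matrix(runif(100 * 3, 0, 4), 100, 3)
  f3 <- add_beads(empty_frame(box), xs, "water")
  a <- 1:50; b <- 51:100
  expect_equal(count_contacts(f3, a, b, 0.75),
               brute_count_contacts(xs[a, ], xs[b, ], box, 0.75))
})

test_that("solvation counts average shell occupancy over frames", {
  built <- build_sirna_topology(sirna_duplex_spec(), box = c(12, 12, 12))
  fr <- built$frame
  # one water permanently 0.5 nm from a phosphate
  ph <- which(fr$beads$role == "phosphate")[1]
  w <- fr$positions[ph, ] + c(0.5, 0, 0)
  f2 <- add_beads(fr, w, "water")
  tr <- cg_trajectory(list(f2, f2, f2), 0:2)
  sc <- solvation_counts(tr, species = "water")
  expect_equal(sc$mean, 1.0)
  # absent species: zero with a warning, not an error
  expect_warning(sc2 <- solvation_counts(tr, species = "Na"), "absent")
  expect_equal(sc2$mean, 0)
  expect_error(window_trajectory(tr, 10, 20), "empty")
})

test_that("dendrimer coating displaces sodium from the siRNA shell", {
  # free siRNA with a sodium shell
  built <- build_sirna_topology(sirna_duplex_spec(), box = c(14, 14, 14))
  fr <- built$frame
  rna <- which(fr$beads$molecule_kind == "siRNA")
  set.seed(5)
  shell_pts <- fr$positions[sample(rna, 30), ] +
    matrix(rnorm(90, sd = 0.2), 30, 3)
  free <- add_beads(fr, shell_pts, "Na")
  ref <- solvation_counts(cg_trajectory(list(free), 0), species = "Na")

  # coated siRNA: micelles crowd the same shell positions; clashing sodiums
  # are pushed out of the shell
  cx <- generate_complex(replicate(4, list(spec = spec18, n_ads = 13,
                                           core_radius = 1.0),
                                   simplify = FALSE),
                         com_distances = rep(3.4, 4), seed = 6)
  rna2 <- which(cx$beads$molecule_kind == "siRNA")
  far <- matrix(rep(c(1, 1, 1), 30), 30, 3, byrow = TRUE) +
    matrix(runif(90, 0, 1), 30, 3)
  coated <- add_beads(cx, far, "Na")
  got <- solvation_counts(cg_trajectory(list(coated), 0), species = "Na")
  expect_lt(got$mean, ref$mean)
})

test_that("RDF of a uniform fixture converges to one", {
  set.seed(1)
  built <- build_sirna_topology(sirna_duplex_spec(), box = c(12, 12, 12))
  fr <- built$frame
  n <- 3000
  frames <- lapply(1:4, function(i)
    add_beads(fr, matrix(runif(3 * n, 0, 12), n, 3), "water"))
  tr <- cg_trajectory(frames, 0:3)
  g <- rdf_per_basepair(tr, "water", bin_width = 0.2, r_max = 5)
  outer <- g[, attr(g, "r") > 2.5]
  expect_lt(mean(abs(rowMeans(outer) - 1)), 0.05)
  expect_true(all(g >= 0))
  # r_max beyond half the box is rejected
  expect_error(rdf_per_basepair(tr, "water", r_max = 7), "half")
})

test_that("RDF reports exclusion zones and handles empty species", {
  set.seed(2)
  built <- build_sirna_topology(sirna_duplex_spec(), box = c(12, 12, 12))
  fr <- built$frame
  b <- fr$beads
  # COM positions of base pairs 10-15
  centres <- t(vapply(10:15, function(bp) {
    sel <- which(!is.na(b$basepair) & b$basepair == bp)
    dendrimicelle:::.centroid(fr$positions[sel, , drop = FALSE], b$mass[sel])
  }, numeric(3)))
  pts <- matrix(runif(3 * 6000, 0, 12), 6000, 3)
  dmin <- apply(pdist_pbc(pts, centres, fr$box), 1, min)
  keep <- pts[dmin > 1, , drop = FALSE]
  tr <- cg_trajectory(list(add_beads(fr, keep, "water")), 0)
  g <- rdf_per_basepair(tr, "water", bin_width = 0.25, r_max = 4)
  inner <- g[paste0("bp", 11:14), attr(g, "r") < 0.8, drop = FALSE]
  expect_true(all(inner < 0.2))
  far_rows <- g[paste0("bp", c(1, 2, 19, 20)), attr(g, "r") > 2, drop = FALSE]
  expect_lt(abs(mean(far_rows) - 1), 0.15)

  # zero species beads: all-zero map with a warning
  expect_warning(gz <- rdf_per_basepair(cg_trajectory(list(fr), 0), "Na"),
                 "absent")
  expect_true(all(gz == 0))
})

test_that("COM distance series are exact for static fixtures and PBC-safe", {
  fr <- empty_frame(c(10, 10, 10))
  fr <- add_beads(fr, rbind(c(2, 5, 5), c(5, 5, 5)), "water")
  tr <- cg_trajectory(list(fr, fr), 0:1)
  s <- com_distance_series(tr, 1L, 2L)
  expect_equal(s$com_distance, c(3, 3), tolerance = 1e-9)
  expect_error(com_distance_series(tr, integer(0), 2L), "empty")
})

test_that("fusion COM series plateaus near the scripted distances", {
  ma <- generate_micelle(spec18, 13, core_radius_target = 1.0, seed = 21)
  mb <- generate_micelle(spec18, 13, core_radius_target = 1.0, seed = 22)
  tr <- generate_fusion_trajectory(ma, mb, n_frames = 60, seed = 5)
  fu <- attr(tr, "fusion")
  ga <- function(fr) which(fr$beads$molecule_id %in% fu$members_a)
  gb <- function(fr) which(fr$beads$molecule_id %in% fu$members_b)
  s <- com_distance_series(tr, ga, gb)
  pl <- find_plateaus(s$time_ns, s$com_distance)
  expect_true(any(abs(pl$level - 6) < 0.3))
  expect_true(any(abs(pl$level - 2) < 0.3))
})

test_that("amine binding statistics follow the bound/unbound convention", {
  cx <- generate_complex(replicate(2, list(spec = spec18, n_ads = 10,
                                           core_radius = 1.0),
                                   simplify = FALSE),
                         com_distances = c(3.4, 8.5), seed = 9,
                         box = c(26, 26, 26))
  members <- attr(cx, "complex")$micelle_members
  tr <- cg_trajectory(list(cx), 0)
  st <- amine_binding_stats(tr, members)
  expect_true(st$bound[1])
  expect_false(st$bound[2])   # 8.5 nm is outside the 5 nm bound window
  expect_true(all(st$mean_amines >= 0))

  # static fixture: a fixed amine set in permanent contact has sem 0
  st2 <- amine_binding_stats(cg_trajectory(list(cx, cx, cx), 0:2), members)
  expect_equal(st2$sem_amines, c(0, 0))
  expect_equal(st2$mean_amines, st$mean_amines)
})

test_that("per-micelle unique-amine counts add up across micelles", {
  cx <- generate_complex(replicate(4, list(spec = spec18, n_ads = 13,
                                           core_radius = 1.0),
                                   simplify = FALSE),
                         com_distances = rep(3.4, 4), seed = 10)
  members <- attr(cx, "complex")$micelle_members
  tr <- cg_trajectory(list(cx), 0)
  st <- amine_binding_stats(tr, members)
  b <- cx$beads
  rna <- which(b$molecule_kind == "siRNA")
  all_am <- which(b$role == "terminal-amine")
  d <- pdist_pbc(cx$positions[all_am, ], cx$positions[rna, ], cx$box)
  total <- sum(apply(d, 1, min) <= 0.75)
  expect_equal(sum(st$mean_amines), total)
})
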