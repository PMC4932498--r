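# Geometry layer: sphere identities, packing parameter, published-table
# regression, derived indices, SASA fractions.

spec18 <- ad_spec(2, 18)

test_that("spherical core relations are exact for any radius", {
  for (R in c(0.3, 0.9, 1.25, 2.6)) {
    V <- sphere_core_volume(R)
    A <- sphere_core_area(R)
    expect_equal(3 * V / A, R, tolerance = 1e-12)
    expect_equal(core_radius_from_va(V / 7, A / 7), R, tolerance = 1e-12)
  }
})

test_that("packing parameter thresholds are applied exactly as stated", {
  expect_equal(packing_and_shape(0.33, 1, 1)$shape_class, "sphere")
  expect_equal(packing_and_shape(0.34, 1, 1)$shape_class, "cylinder")
  expect_equal(packing_and_shape(0.50, 1, 1)$shape_class, "cylinder")
  expect_equal(packing_and_shape(0.51, 1, 1)$shape_class, "bilayer")
  # v0 = a * l0 gives P = 1, bilayer branch
  ps <- packing_and_shape(0.8, 0.4, 2)
  expect_equal(ps$P, 1)
  expect_equal(ps$shape_class, "bilayer")
  expect_error(packing_and_shape(0, 1, 1), "positive")
})

test_that("published per-micelle packing parameters are reproduced from printed inputs", {
  # worked rows: core radius 0.9 with tail 1.2 -> 0.25; 1.0 with 1.5 -> 0.22
  expect_equal(round(packing_parameter_spherical(0.9, 1.2)$P, 2), 0.25)
  expect_equal(round(packing_parameter_spherical(1.0, 1.5)$P, 2), 0.22)
  expect_equal(packing_parameter_spherical(0.9, 1.2)$shape_class, "sphere")

  # full regression over self-consistent reference rows
  ref <- reference_micelles()
  rows <- ref[ref$consistent, ]
  P <- vapply(seq_len(nrow(rows)), function(i)
    packing_parameter_spherical(rows$core_radius[i],
                                rows$tail_length[i])$P, numeric(1))
  expect_true(all(abs(P - rows$packing) <= 0.015))
})

test_that("derived indices reproduce the published worked examples", {
  geom <- list(tail_length = 1.7, core_radius = 1.5,
               N = 19, surface_area = 53.4)
  di <- derived_indices(geom, spec18, duplex = sirna_duplex_spec(),
                        bound_n_aggs = c(13, 19, 24, 26))
  expect_equal(round(di$I_d, 1), 1.1)
  expect_equal(round(di$area_per_amine, 2), 0.35)
  # 82 ADs over 40 phosphates -> ~2:1
  expect_equal(di$np_ratio, 82 / 40)
  expect_equal(round(di$np_ratio), 2)

  # area-per-amine regression against the published table
  am <- reference_amine_binding()
  ref <- reference_micelles()
  am2 <- am[am$consistent, ]
  for (i in seq_len(nrow(am2))) {
    hit <- ref[ref$system == am2$system[i] & ref$label == am2$label[i], ]
    if (!nrow(hit)) next
    e <- am2$total_amines[i] / am2$n_ads[i]
    g <- list(tail_length = hit$tail_length, core_radius = hit$core_radius,
              N = am2$n_ads[i], surface_area = hit$surface_area)
    sp <- ad_spec(c(2, 1, 0)[match(substr(am2$system[i], 1, 2),
                                   c("G2", "G1", "G0"))],
                  as.integer(sub("C", "", sub(".*-", "", am2$system[i]))))
    di <- derived_indices(g, sp)
    expect_lte(abs(di$area_per_amine - am2$area_per_amine[i]), 0.015)
  }
})

test_that("sigma_m follows e N / S_m", {
  g <- list(tail_length = 1.7, core_radius = 1.1, N = 19,
            surface_area = 53.4)
  di <- derived_indices(g, spec18)
  expect_equal(di$sigma_m, 8 * 19 / 53.4, tolerance = 1e-12)
  g$surface_area <- 0
  expect_error(derived_indices(g, spec18), "surface area")
})

test_that("micelle geometry recovers construction parameters", {
  fr <- generate_micelle(spec18, 19, core_radius_target = 1.2, seed = 8)
  agg <- detect_aggregates(fr, 0.6)[[1]]
  g <- micelle_geometry(fr, agg, spec18)
  expect_equal(g$N, 19L)
  expect_lt(abs(g$core_radius - 1.2) / 1.2, 0.10)
  # internal consistency of the reported fields
  expect_equal(g$core_volume, sphere_core_volume(g$core_radius),
               tolerance = 1e-12)
  expect_equal(g$core_area, sphere_core_area(g$core_radius),
               tolerance = 1e-12)
  expect_equal(g$v0, g$core_volume / g$N, tolerance = 1e-12)
  expect_equal(g$a, g$core_area / g$N, tolerance = 1e-12)
  expect_equal(g$P, g$core_radius / (3 * g$tail_length), tolerance = 1e-9)
  expect_equal(g$surface_area, 4 * pi * g$micelle_radius^2,
               tolerance = 1e-12)
  expect_equal(g$headgroup_volume,
               (4 / 3) * pi * g$micelle_radius^3 - g$core_volume,
               tolerance = 1e-9)
})

test_that("single-molecule aggregates are reported degenerate", {
  fr <- single_ad_frame(spec18)
  agg <- list(members = 1L, n_agg = 1L, links = matrix(0, 0, 2))
  g <- micelle_geometry(fr, agg, spec18)
  expect_true(g$degenerate)
})

test_that("hydrophobic surface exposure behaves like a micelle", {
  # a lone AD exposes its full tail
  f1 <- single_ad_frame(spec18)
  a1 <- list(members = 1L, n_agg = 1L, links = matrix(0, 0, 2))
  expect_gt(hydrophobic_sasa_fraction(f1, a1, n_sphere_points = 240), 0.3)

  # a large micelle (core diameter > 3.2 nm) buries its core almost fully
  fm <- generate_micelle(spec18, 40, core_radius_target = 1.65, seed = 5)
  am <- detect_aggregates(fm, 0.6)[[1]]
  gm <- micelle_geometry(fm, am, spec18)
  expect_gt(2 * gm$core_radius, 3.2)
  frac_in <- hydrophobic_sasa_fraction(fm, am, n_sphere_points = 240)
  expect_lte(frac_in, 0.05)

  # turning the tails outward increases exposure
  fo <- generate_micelle(spec18, 19, core_radius_target = 1.1, seed = 5,
                         orientation = "outward")
  fi <- generate_micelle(spec18, 19, core_radius_target = 1.1, seed = 5)
  frac_out <- hydrophobic_sasa_fraction(fo, detect_aggregates(fo, 0.6)[[1]],
                                        n_sphere_points = 240)
  frac_norm <- hydrophobic_sasa_fraction(fi, detect_aggregates(fi, 0.6)[[1]],
                                         n_sphere_points = 240)
  expect_gt(frac_out, frac_norm)
})

test_that("micelle reports carry one row per micelle plus a mean row", {
  fr <- generate_micelle(spec18, 13, core_radius_target = 1.0, seed = 12)
  tab <- micelle_report(fr, spec18)
  expect_equal(nrow(tab), 2L)   # one micelle + mean row
  expect_equal(tab$shape[2], "(mean)")
  expect_equal(tab$n_ads[1], 13)
})
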