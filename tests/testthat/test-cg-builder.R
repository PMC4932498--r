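# Topology construction: bead counting, charge bookkeeping, elastic network,
# file round-trips.

test_that("AD topologies satisfy the closed-form bead and charge counts", {
  cases <- expand.grid(g = 0:2, tail = c(13, 15, 18))
  tail_beads <- c(`13` = 3L, `15` = 4L, `18` = 5L)
  for (r in seq_len(nrow(cases))) {
    g <- cases$g[r]; tl <- cases$tail[r]
    spec <- ad_spec(g, tl)
    topo <- build_ad_topology(spec)
    n_term <- 2L^(g + 1L)
    expect_equal(sum(topo$beads$role == "terminal-amine"), n_term)
    expect_equal(sum(topo$beads$role == "tail"),
                 unname(tail_beads[as.character(tl)]))
    expect_equal(sum(topo$beads$role == "ring"), 1L)
    expect_equal(sum(topo$beads$hydrophobic),
                 unname(tail_beads[as.character(tl)]) + 1L)
    expect_equal(topo$net_charge, n_term)
    expect_equal(topo$net_charge, sum(topo$beads$charge))
    # connectivity: bonds form a single tree over all beads
    bonds <- topo$bonded[topo$bonded$kind == "bond", ]
    expect_equal(nrow(bonds), nrow(topo$beads) - 1L)
  }
})

test_that("unsupported AD definitions are rejected with a message", {
  expect_error(ad_spec(3, 18), "unsupported dendron generation")
  expect_error(ad_spec(1, 16), "unsupported tail length")
})

test_that("siRNA topology maps nucleotides to the published bead complement", {
  # single adenosine: phosphate + sugar + 3 base beads
  one <- sirna_duplex_spec(sense = "A", antisense = "U",
                           include_overhangs = FALSE)
  topo1 <- build_sirna_topology(one)$topology
  expect_equal(nrow(topo1$beads), 5L + 4L)   # A (5 beads) paired with U (4)
  expect_equal(sum(topo1$beads$strand == 1), 5L)
  expect_equal(topo1$beads$martini_type[topo1$beads$strand == 1],
               c("Qa", "P1", "Na", "Na", "Nda"))

  # the study duplex: 92 beads on the sense core strand, one phosphate per
  # nucleotide, net core charge -40
  duplex <- sirna_duplex_spec()
  built <- build_sirna_topology(duplex)
  b <- built$topology$beads
  core <- b[!b$overhang, ]
  expect_equal(sum(core$strand == 1), 92L)
  expect_equal(sum(core$role == "phosphate"), 40L)
  expect_equal(sum(core$charge), -40L)
  expect_equal(duplex$n_phosphates_core, 40L)
  # per-base bead complements
  per_base <- c(A = 3L, G = 3L, C = 2L, U = 2L, T = 2L)
  for (bb in names(per_base)) {
    res <- b[b$base == bb & b$strand == 1 & b$resno == min(b$resno[b$base == bb & b$strand == 1]), ]
    if (nrow(res))
      expect_equal(sum(res$role == "base"), unname(per_base[bb]))
  }
})

test_that("non-complementary or invalid strands are rejected", {
  expect_error(sirna_duplex_spec("GCAU", "AUGG"), "reverse-complementary")
  expect_error(sirna_duplex_spec("GCTU", "AAGC", include_overhangs = FALSE),
               "RNA")
})

test_that("elastic network equals brute-force enumeration", {
  # pair below cutoff
  t2 <- cg_topology("pair", bead_table(c("X", "Y"), c("P1", "P1"),
                                       c(0L, 0L), c("sugar", "sugar")))
  en <- apply_elastic_network(t2, rbind(c(0, 0, 0), c(0.5, 0, 0)))
  el <- en$bonded[en$bonded$kind == "elastic", ]
  expect_equal(nrow(el), 1L)
  expect_equal(el$equilibrium, 0.5, tolerance = 1e-12)
  expect_equal(el$force_constant, 1500)

  # pair beyond cutoff
  en2 <- apply_elastic_network(t2, rbind(c(0, 0, 0), c(0.8, 0, 0)))
  expect_equal(sum(en2$bonded$kind == "elastic"), 0L)

  # equilateral triangle, side 0.6
  t3 <- cg_topology("tri", bead_table(c("X", "Y", "Z"), rep("P1", 3),
                                      rep(0L, 3), rep("sugar", 3)))
  tri <- rbind(c(0, 0, 0), c(0.6, 0, 0), c(0.3, 0.6 * sqrt(3) / 2, 0))
  en3 <- apply_elastic_network(t3, tri)
  expect_equal(sum(en3$bonded$kind == "elastic"), 3L)

  # full duplex vs brute force; covalent bonds excluded
  built <- build_sirna_topology(sirna_duplex_spec())
  en4 <- apply_elastic_network(built$topology, built$frame)
  el4 <- en4$bonded[en4$bonded$kind == "elastic", ]
  oracle <- brute_elastic(built$frame$positions, built$topology$bonded, 0.7)
  expect_equal(nrow(el4), nrow(oracle))
  key_impl <- paste(el4$i, el4$j)
  key_orc <- paste(oracle[, 1], oracle[, 2])
  expect_setequal(key_impl, key_orc)
  expect_equal(sort(el4$equilibrium), sort(oracle[, 3]), tolerance = 1e-9)
  expect_true(all(el4$force_constant == 1500))
})

test_that("elastic network rejects missing coordinates", {
  t2 <- cg_topology("pair", bead_table(c("X", "Y"), c("P1", "P1"),
                                       c(0L, 0L), c("sugar", "sugar")))
  expect_error(apply_elastic_network(t2, matrix(0, 1, 3)), "coordinate")
})

test_that("atomistic duplex mapping places beads at group mass centres", {
  spec <- sirna_duplex_spec("A", "U", include_overhangs = FALSE)
  # synthetic atomistic input: every atom of each mapped group at one point,
  # so the bead COM is exactly that point
  groups1 <- list(c("P", "OP1", "OP2", "O5'"),
                  c("C5'", "C4'", "O4'", "C3'", "O3'", "C2'", "O2'", "C1'"),
                  c("N9", "C8", "N7"), c("C5", "C6", "N6", "N1"),
                  c("C2", "N3", "C4"))
  groups2 <- list(c("P", "OP1", "OP2", "O5'"),
                  c("C5'", "C4'", "O4'", "C3'", "O3'", "C2'", "O2'", "C1'"),
                  c("N1", "C2", "O2", "N3"), c("C4", "O4", "C5", "C6"))
  mk <- function(groups, chain, offset) {
    do.call(rbind, lapply(seq_along(groups), function(gi)
      data.frame(elety = groups[[gi]], resno = 1L, chain = chain,
                 x = offset + gi, y = 2 * gi, z = 0)))
  }
  atoms <- rbind(mk(groups1, "A", 0), mk(groups2, "B", 100))
  coords <- map_atomistic_duplex(spec, atoms)
  expect_equal(coords[1, ], c(1, 2, 0))       # sense phosphate group
  expect_equal(coords[5, ], c(5, 10, 0))      # last adenine base bead
  expect_equal(coords[6, ], c(101, 2, 0))     # antisense phosphate
})

test_that("GRO export-import round-trips positions and metadata", {
  spec <- ad_spec(2, 18)
  fr <- generate_micelle(spec, 5, core_radius_target = 0.9, seed = 3)
  path <- tempfile(fileext = ".gro")
  write_gro(fr, path)
  back <- read_gro(path)
  expect_equal(back$positions, unname(fr$positions), tolerance = 5.1e-4)
  expect_equal(back$beads$name, fr$beads$name)
  expect_equal(back$beads$molecule_id, fr$beads$molecule_id)
  expect_equal(back$beads$molecule_kind, fr$beads$molecule_kind)
  expect_equal(back$box, fr$box)

  # single bead at an exact position: 3-decimal precision
  f1 <- empty_frame(c(5, 5, 5))
  f1 <- add_beads(f1, c(1, 1, 1), "water")
  p1 <- tempfile(fileext = ".gro")
  write_gro(f1, p1)
  expect_equal(read_gro(p1)$positions[1, ], c(1, 1, 1), tolerance = 1e-3)
})

test_that("ITP export-import round-trips beads, charges and bonded terms", {
  topo <- build_ad_topology(ad_spec(2, 18))
  path <- tempfile(fileext = ".itp")
  write_itp(topo, path)
  back <- read_itp(path)
  expect_equal(nrow(back$beads), nrow(topo$beads))
  expect_equal(back$beads$charge, topo$beads$charge)
  expect_equal(back$beads$martini_type, topo$beads$martini_type)
  expect_equal(back$net_charge, topo$net_charge)
  expect_equal(nrow(back$bonded), nrow(topo$bonded))

  # elastic terms land in their dedicated bonds section with k = 1500
  built <- build_sirna_topology(sirna_duplex_spec())
  en <- apply_elastic_network(built$topology, built$frame)
  p2 <- tempfile(fileext = ".itp")
  write_itp(en, p2)
  txt <- readLines(p2)
  expect_true(any(grepl("\\[ bonds \\] ; elastic", txt)))
  back2 <- read_itp(p2)
  el <- back2$bonded[back2$bonded$kind == "elastic", ]
  expect_equal(nrow(el), sum(en$bonded$kind == "elastic"))
  expect_true(all(el$force_constant == 1500))
})

test_that("export_system writes a consistent bundle", {
  spec <- ad_spec(1, 15)
  fr <- generate_micelle(spec, 4, core_radius_target = 0.8, seed = 2)
  dir <- tempfile()
  paths <- export_system(list(build_ad_topology(spec)), fr, dir,
                         basename = "mic")
  expect_true(all(file.exists(paths)))
  back <- read_gro(paths[["gro"]])
  expect_equal(nrow(back$positions), nrow(fr$positions))
})
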