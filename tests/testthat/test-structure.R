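test_that("built geometries reproduce the requested dihedrals", {
  ext <- build_ideal_geometry("extended", 6)
  pp <- phi_psi(ext)
  expect_true(all(abs(abs(pp$phi) - 180) < 1))
  expect_true(all(abs(abs(pp$psi) - 180) < 1))

  ppii <- build_ideal_geometry("custom_phi_psi", 8, phi = -75, psi = 140)
  pp2 <- phi_psi(ppii)
  expect_true(all(abs(pp2$phi + 75) < 1))
  expect_true(all(abs(pp2$psi - 140) < 1))

  expect_error(build_ideal_geometry("custom_phi_psi", 6, phi = 500, psi = 0),
               class = "looplab_parameter_error")
})

test_that("mirror images negate both backbone dihedrals", {
  st <- build_ideal_geometry("custom_phi_psi", 5, phi = -75, psi = 140)
  mir <- st
  mir$atoms$z <- -mir$atoms$z
  pp <- phi_psi(st); pm <- phi_psi(mir)
  expect_equal(pm$phi, -pp$phi, tolerance = 1e-9)
  expect_equal(pm$psi, -pp$psi, tolerance = 1e-9)
})

test_that("Kabsch-Sander energy matches the published formula by hand", {
  # acceptor C=O (res 1) and donor N-H (res 3) in a plane, sheet-like r
  st <- atoms_at(matrix(c(
    0.00, 0.391, 0.0,  # O  (acceptor, res 1): r_OH = 2.9 A
    0.00, 0.514, 0.0,  # C
    0.00, 0.000, 0.0,  # N  (donor, res 3)
    0.00, 0.101, 0.0), # H
    4, 3, byrow = TRUE),
    names = c("O", "C", "N", "H"), residues = c(1L, 1L, 3L, 3L))
  d <- function(a, b) sqrt(sum((a - b)^2)) * 10
  at <- as.matrix(st$atoms[, c("x", "y", "z")])
  O <- at[1, ]; C <- at[2, ]; N <- at[3, ]; H <- at[4, ]
  expected <- 0.084 * 332 * (1 / d(O, N) + 1 / d(C, H)
                             - 1 / d(O, H) - 1 / d(C, N))
  expect_equal(kabsch_sander_energy(st, 3, 1), expected, tolerance = 1e-6)
  expect_lt(expected, -0.5)  # a bona fide hydrogen bond

  # far-apart pair: energy above the cutoff
  far <- atoms_at(matrix(c(1, 0, 0, 1.123, 0, 0, 0, 0, 0, 0, 0.101, 0),
                         4, 3, byrow = TRUE),
                  names = c("O", "C", "N", "H"), residues = c(1L, 1L, 3L, 3L))
  expect_gt(kabsch_sander_energy(far, 3, 1), -0.5)
  expect_equal(ks_cutoff_kcal, -0.5)
})

test_that("geometric criterion agrees with an exhaustive re-check", {
  set.seed(70)
  for (rep in 1:4) {
    n_res <- 6L
    rows <- list()
    for (r in seq_len(n_res)) {
      base <- runif(3, 0, 1.2)
      rows[[length(rows) + 1L]] <- data.frame(
        atom_name = c("N", "H", "CA", "C", "O"), element = c("N", "H", "C", "C", "O"),
        residue_index = r, residue_name = "GLY", chain_id = "A",
        x = base[1L] + c(0, 0.05, 0.12, 0.25, 0.3),
        y = base[2L] + c(0, 0.08, 0.02, 0.05, 0.15),
        z = base[3L] + c(0, 0, 0.1, 0.12, 0.1))
    }
    st <- structure_from_atoms(do.call(rbind, rows))
    hb <- detect_hbonds_geometric(st)
    # independent double check of every candidate pair
    for (dres in 1:n_res) for (ares in 1:n_res) {
      if (abs(dres - ares) < 2) next
      a <- st$atoms
      N <- unlist(a[a$residue_index == dres & a$atom_name == "N", c("x", "y", "z")])
      H <- unlist(a[a$residue_index == dres & a$atom_name == "H", c("x", "y", "z")])
      O <- unlist(a[a$residue_index == ares & a$atom_name == "O", c("x", "y", "z")])
      rno <- sqrt(sum((N - O)^2))
      ang <- acos(sum((H - N) * (O - N)) /
                    sqrt(sum((H - N)^2) * sum((O - N)^2))) * 180 / pi
      expected <- rno <= 0.35 && ang <= 30
      got <- any(hb$donor == dres & hb$acceptor == ares)
      expect_identical(got, expected)
    }
  }
})

test_that("ideal N-H...O geometries pass and far ones fail", {
  near <- atoms_at(matrix(c(0, 0, 0, 0, 0.101, 0, 0, 0.29, 0, 0, 0.413, 0),
                          4, 3, byrow = TRUE),
                   names = c("N", "H", "O", "C"),
                   residues = c(1L, 1L, 4L, 4L))
  hb <- detect_hbonds_geometric(near)
  expect_true(any(hb$donor == 1 & hb$acceptor == 4))
  far <- atoms_at(matrix(c(0, 0, 0, 0, 0.101, 0, 0, 0.40, 0, 0, 0.523, 0),
                         4, 3, byrow = TRUE),
                  names = c("N", "H", "O", "C"),
                  residues = c(1L, 1L, 4L, 4L))
  expect_equal(nrow(detect_hbonds_geometric(far)), 0L)
})

test_that("the hairpin builder yields an antiparallel Kabsch-Sander ladder", {
  hp <- build_ideal_geometry("beta_hairpin", 12)
  segs <- beta_segments(detect_hbonds_ks(hp))
  expect_gt(length(segs), 0)
  anti <- Filter(function(s) s$orientation == "antiparallel", segs)
  expect_gt(length(anti), 0)
  expect_gte(max(vapply(anti, `[[`, 0, "n_bonds")), 2)
})

test_that("energy-criterion bonds form a subset of geometric ones on sheets", {
  hp <- build_ideal_geometry("beta_hairpin", 12)
  ks <- detect_hbonds_ks(hp)
  geo <- detect_hbonds_geometric(hp, dist_cutoff = 0.4, angle_cutoff = 40)
  keys <- function(h) paste(h$donor, h$acceptor)
  expect_true(all(keys(ks[abs(ks$donor - ks$acceptor) >= 3, ]) %in% keys(geo)))
})

test_that("extended and PPII chains contain no beta segments", {
  for (st in list(build_ideal_geometry("extended", 10),
                  build_ideal_geometry("custom_phi_psi", 10,
                                       phi = -75, psi = 140))) {
    expect_equal(length(beta_segments(detect_hbonds_ks(st))), 0L)
  }
})

test_that("hand-built ladders are grouped with the right orientation", {
  # 3-bond parallel ladder: donor - acceptor difference constant
  par3 <- data.frame(donor = c(2L, 4L, 6L), acceptor = c(10L, 12L, 14L),
                     energy = -1, criterion = "kabsch_sander")
  segs <- beta_segments(par3)
  expect_equal(length(segs), 1L)
  expect_equal(segs[[1L]]$orientation, "parallel")
  expect_equal(segs[[1L]]$n_bonds, 3L)

  # antiparallel: donor + acceptor sum constant, both directions present
  anti <- data.frame(donor = c(3L, 10L, 5L, 8L), acceptor = c(10L, 3L, 8L, 5L),
                     energy = -1, criterion = "kabsch_sander")
  segs2 <- beta_segments(anti)
  expect_equal(length(segs2), 1L)
  expect_equal(segs2[[1L]]$orientation, "antiparallel")
  expect_equal(segs2[[1L]]$n_bonds, 4L)

  # swapping strand roles (donor <-> acceptor) keeps the segments
  swapped <- data.frame(donor = par3$acceptor, acceptor = par3$donor,
                        energy = -1, criterion = "kabsch_sander")
  segs3 <- beta_segments(swapped)
  expect_equal(length(segs3), 1L)
  expect_equal(segs3[[1L]]$n_bonds, 3L)

  # isolated bonds or short-range contacts never form segments
  expect_equal(length(beta_segments(data.frame(
    donor = c(2L, 9L), acceptor = c(12L, 4L), energy = -1,
    criterion = "kabsch_sander"))), 0L)
})

test_that("PPII chains put all non-glycine mass in the PPII region", {
  st <- build_ideal_geometry("custom_phi_psi", 10, phi = -75, psi = 140)
  fr <- region_fractions(rama_histogram(phi_psi(st)))
  expect_equal(unname(fr["ppii"]), 1)
  expect_equal(unname(fr["beta"]), 0)

  st2 <- build_ideal_geometry("custom_phi_psi", 10, phi = -135, psi = 135)
  fr2 <- region_fractions(rama_histogram(phi_psi(st2)))
  expect_equal(unname(fr2["beta"]), 1)
})

test_that("amide hydrogens are reconstructed close to their ideal sites", {
  st <- build_ideal_geometry("custom_phi_psi", 6, phi = -75, psi = 140)
  built_h <- st$atoms[st$atoms$atom_name == "H", ]
  stripped <- structure_from_atoms(st$atoms[st$atoms$atom_name != "H", ])
  rec <- reconstruct_amide_h(stripped)
  rec_h <- rec$atoms[rec$atoms$atom_name == "H", ]
  expect_equal(nrow(rec_h), nrow(built_h))
  d <- sqrt(rowSums((as.matrix(rec_h[, c("x", "y", "z")]) -
                       as.matrix(built_h[, c("x", "y", "z")]))^2))
  expect_lt(max(d), 0.03)  # within 0.3 A of the builder's position
})

test_that("open-state statistics are frame-set statistics", {
  hp <- build_ideal_geometry("beta_hairpin", 12)
  ext <- build_ideal_geometry("extended", 12)
  frames <- list(hp, ext, hp, ext)
  tr <- trajectory(frames, dt = 0.1)
  states <- state_series(rep(1L, 4), dt = 0.1)
  stats <- open_state_structure_stats(tr, states)
  expect_equal(stats$fraction_with_beta, 0.5)
  expect_equal(stats$n_open, 4)
  # invariance under frame reordering
  tr2 <- trajectory(frames[c(2, 1, 4, 3)], dt = 0.1)
  stats2 <- open_state_structure_stats(tr2, states)
  expect_equal(stats2$fraction_with_beta, stats$fraction_with_beta)
  expect_equal(stats2$mean_hbond_count, stats$mean_hbond_count)
  # all-closed records are an error
  expect_error(open_state_structure_stats(tr, state_series(rep(0L, 4), dt = 0.1)),
               class = "looplab_empty_state_error")
})

test_that("per-trajectory existence matrices label in-beta bonds", {
  hp <- build_ideal_geometry("beta_hairpin", 12)
  ext <- build_ideal_geometry("extended", 12)
  tr <- trajectory(list(hp, ext, hp), dt = 0.1)
  hm <- hbond_existence_matrix(tr)
  expect_s3_class(hm, "hbond_matrix")
  expect_equal(nrow(hm), 3L)
  expect_true("in_beta" %in% attr(hm, "labels"))
  # bonds present in the hairpin frames are absent in the extended frame
  expect_true(all(hm[2L, attr(hm, "labels") == "in_beta"] == 0L))
})
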