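# explicit hydrogen-bond geometry: donor at origin, H on +z, acceptor beyond,
# antecedent placed at the ideal acceptor angle so F = 1
hb_geom <- function(d, dha = 180, bah = 120) {
  donor <- c(0, 0, 0)
  hydrogen <- c(0, 0, 1.01)
  th <- pi * (180 - dha) / 180
  acceptor <- donor + c(d * sin(th), 0, d * cos(th))
  oh <- rignet:::unitv(hydrogen - acceptor)
  perp <- rignet:::unitv(c(0, 1, 0) - sum(c(0, 1, 0) * oh) * oh)
  phi <- pi * bah / 180
  ante <- acceptor + 1.23 * (cos(phi) * oh + sin(phi) * perp)
  list(donor = donor, hydrogen = hydrogen, acceptor = acceptor, ante = ante)
}

test_that("hydrogen-bond energy reproduces its closed form", {
  g <- hb_geom(2.8)
  expect_equal(hbond_energy(g$donor, g$hydrogen, g$acceptor, g$ante), -8)
  g2 <- hb_geom(3.2)
  expect_equal(hbond_energy(g2$donor, g2$hydrogen, g2$acceptor, g2$ante),
               8 * (5 * (2.8 / 3.2)^12 - 6 * (2.8 / 3.2)^10), tolerance = 1e-9)
  # 90 degree D-H...A: angular factor vanishes
  g3 <- hb_geom(2.8, dha = 90)
  expect_equal(hbond_energy(g3$donor, g3$hydrogen, g3$acceptor, g3$ante), 0)
  expect_error(hbond_energy(c(0, 0, 0), c(0, 0, 1), c(0, 0, 0), NULL),
               "degenerate|coincident")
})

test_that("energy is minimized at d0 and strictly increasing beyond", {
  ds <- seq(2.8, 4.5, by = 0.05)
  es <- vapply(ds, function(d) {
    g <- hb_geom(d)
    hbond_energy(g$donor, g$hydrogen, g$acceptor, g$ante)
  }, numeric(1))
  expect_equal(min(es), es[1])
  expect_equal(es[1], -8)
  expect_true(all(diff(es) > 0))
  expect_gt(es[length(es)], -1)
})

test_that("detectors are invariant under rigid motion", {
  h <- make_helix(12)
  key <- function(x) paste(x$chain_a, x$resno_a, x$atom_a,
                           x$chain_b, x$resno_b, x$atom_b)
  a <- detect_hbonds(h)
  b <- detect_hbonds(transform_structure(h))
  a <- a[order(key(a)), ]
  b <- b[order(key(b)), ]
  expect_identical(key(a), key(b))
  expect_equal(a$energy, b$energy, tolerance = 1e-9)
})

test_that("salt bridges: cutoff, termini-free pairing and deduplication", {
  lys <- rbind(atom_row("CA", "C", "LYS", "A", 5, 0, 0, 0),
               atom_row("NZ", "N", "LYS", "A", 5, 1.5, 0, 0))
  glu <- rbind(atom_row("CA", "C", "GLU", "A", 20, 6.5, 0, 0),
               atom_row("OE1", "O", "GLU", "A", 20, 5.0, 0, 0))
  s <- mini_structure(lys, glu)
  sb <- detect_salt_bridges(s)
  expect_equal(nrow(sb), 1)
  expect_equal(sb$energy, -10)
  expect_equal(sb$distance, 3.5)

  glu_far <- glu; glu_far$x <- glu_far$x + 1.0   # N-O distance 4.5
  s2 <- mini_structure(lys, glu_far)
  expect_equal(nrow(detect_salt_bridges(s2)), 0)

  # Arg with both NH atoms near both carboxylate oxygens: one interaction
  arg <- rbind(atom_row("CA", "C", "ARG", "A", 5, 0, 0, 0),
               atom_row("NH1", "N", "ARG", "A", 5, 1.5, 0.6, 0),
               atom_row("NH2", "N", "ARG", "A", 5, 1.5, -0.6, 0))
  asp <- rbind(atom_row("CA", "C", "ASP", "A", 30, 6.5, 0, 0),
               atom_row("OD1", "O", "ASP", "A", 30, 4.6, 0.6, 0),
               atom_row("OD2", "O", "ASP", "A", 30, 4.6, -0.6, 0))
  s3 <- mini_structure(arg, asp)
  expect_equal(nrow(detect_salt_bridges(s3)), 1)
})

test_that("hydrophobic tethers respect vdW cutoffs and adjacency", {
  at <- function(d, el2 = "C", resno2 = 10)
    mini_structure(atom_row("CB", "C", "ALA", "A", 1, 0, 0, 0),
                   atom_row(if (el2 == "S") "SG" else "CB", el2,
                            if (el2 == "S") "CYS" else "ALA", "A", resno2,
                            d, 0, 0))
  expect_equal(nrow(detect_hydrophobic(at(3.5))), 1)   # cutoff 3.65
  expect_equal(nrow(detect_hydrophobic(at(3.8))), 0)
  expect_equal(nrow(detect_hydrophobic(at(3.7, "S"))), 1)  # cutoff 3.75
  expect_equal(nrow(detect_hydrophobic(at(3.5, resno2 = 2))), 0)  # adjacent
})

test_that("interaction summary counts, strongest fraction and occupancy", {
  ints <- do.call(rbind, lapply(1:10, function(k)
    rignet:::interaction_row("hbond",
                             data.frame(chain = c("A", "A"), resno = c(k, k + 20),
                                        resid = "ALA", elety = c("N", "O"),
                                        stringsAsFactors = FALSE),
                             1, 2, 3.0, -k)))
  sm <- interaction_summary(ints, strength_percentile = 0.3)
  expect_equal(sm$counts$n[sm$counts$kind == "hbond"], 10)
  expect_equal(sm$counts$n_strongest[sm$counts$kind == "hbond"], 3)
  sm1 <- interaction_summary(ints, strength_percentile = 1)
  expect_equal(sm1$counts$n_strongest[sm1$counts$kind == "hbond"], 10)

  h <- make_helix(20)
  smh <- interaction_summary(detect_interactions(h))
  expect_equal(smh$counts$n[smh$counts$kind == "hbond"], 16)
  expect_equal(smh$counts$n[smh$counts$kind == "salt_bridge"], 0)
  expect_gte(smh$counts$n[smh$counts$kind == "hydrophobic"], 0)

  # ensemble occupancy: an interaction present in 1 of 2 models
  sm2 <- interaction_summary(list(ints, ints[1:5, ]), max_occupancy = 0.5)
  expect_equal(nrow(sm2$occupancy), 5)
  expect_true(all(sm2$occupancy$occupancy == 0.5))
  expect_equal(interaction_summary(rignet:::empty_interactions())$counts$n,
               c(0L, 0L, 0L))
})
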