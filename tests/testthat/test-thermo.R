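fake_map <- function(df) {
  class(df) <- c("stability_map", "data.frame")
  attr(df, "level") <- "residue"
  df
}

test_that("interface energy sums E_rc over present pairs only", {
  m <- fake_map(data.frame(chain_a = "A", resno_a = c(1, 2),
                           chain_b = "B", resno_b = c(1, 2),
                           e_rc = c(-3, -1), persistent = FALSE,
                           stringsAsFactors = FALSE))
  pairs <- data.frame(chain_a = "A", resno_a = c(1, 2, 3),
                      chain_b = "B", resno_b = c(1, 2, 3),
                      stringsAsFactors = FALSE)
  expect_equal(interface_rigidity_energy(m, pairs), -4)
  # reversed pair order matches too (symmetry)
  rev <- data.frame(chain_a = "B", resno_a = 1, chain_b = "A", resno_b = 1,
                    stringsAsFactors = FALSE)
  expect_equal(interface_rigidity_energy(m, rev), -3)
  expect_equal(interface_rigidity_energy(m, pairs[0, ]), 0)
})

test_that("per-element rigidity energies divide by element size", {
  # element of 4 residues (1-4), cross contacts to residues 10/11 sum to -8
  m <- fake_map(data.frame(chain_a = "A", resno_a = c(1, 2, 3, 2),
                           chain_b = "A", resno_b = c(10, 11, 10, 2),
                           e_rc = c(-3, -2, -3, -5), persistent = FALSE,
                           stringsAsFactors = FALSE))
  el <- data.frame(label = "H1", type = "helix", chain = "A",
                   start = 1, end = 4, stringsAsFactors = FALSE)
  out <- sse_rigidity_energy(m, el)
  expect_equal(out$energy_total, -8)          # (2,2) pair is internal
  expect_equal(out$energy_per_res, -2)
  expect_equal(out$n_res, 4)
  # element with no cross contacts
  el0 <- data.frame(label = "E1", type = "strand", chain = "A",
                    start = 20, end = 22, stringsAsFactors = FALSE)
  expect_equal(sse_rigidity_energy(m, el0)$energy_per_res, 0)
})

test_that("element energies are invariant under renumbering offsets", {
  d <- bridged_dimer(-2.5, -2.5, n = 10)
  traj <- dilute(d)
  m <- stability_map(traj)
  el <- data.frame(label = "H1", type = "helix", chain = "A",
                   start = 2, end = 6, stringsAsFactors = FALSE)
  base <- sse_rigidity_energy(m, el)
  m2 <- m
  m2$resno_a <- m2$resno_a + 100
  m2$resno_b <- m2$resno_b + 100
  el2 <- el; el2$start <- el2$start + 100; el2$end <- el2$end + 100
  shifted <- sse_rigidity_energy(fake_map(m2), el2)
  expect_equal(shifted$energy_per_res, base$energy_per_res)
  expect_equal(shifted$se, base$se)
})

test_that("ensemble T_p moments match hand computation", {
  r <- ensemble_tp(c(350, 352, 354, 356))
  expect_equal(r$mean, 353)
  expect_equal(r$sd, sqrt(20 / 3))
  expect_equal(r$sem, sqrt(20 / 3) / 2)
  expect_equal(r$sem, 1.29, tolerance = 0.01)
  expect_equal(r$n_excluded, 0)

  # degenerate ensemble: identical members
  net <- make_two_block_network(4)
  r2 <- ensemble_tp(list(net, net, net))
  expect_equal(r2$sd, 0)
  expect_equal(r2$sem, 0)
  expect_equal(r2$mean, phase_transition(dilute_network(net))$tp)
})

test_that("OLS of T_p on T_org matches a closed-form oracle", {
  # brute-force OLS on toy points
  ols <- function(x, y) {
    sl <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    ic <- mean(y) - sl * mean(x)
    ss_res <- sum((y - ic - sl * x)^2)
    ss_tot <- sum((y - mean(y))^2)
    list(slope = sl, r2 = 1 - ss_res / ss_tot)
  }
  x <- c(0, 1, 2); y <- c(0, 1, 0)
  ref <- ols(x, y)
  got <- correlate_tp_torg(x, y)
  expect_equal(got$slope, ref$slope)
  expect_equal(got$r_squared, ref$r2)
  expect_equal(got$r_squared, 0)

  set.seed(1)
  x2 <- c(4, 15, 37, 60, 80); y2 <- 0.1 * x2 + 300 + rnorm(5, 0, 0.3)
  ref2 <- ols(x2 + 273.15, y2)
  got2 <- correlate_tp_torg(x2, y2)
  expect_equal(got2$slope, ref2$slope, tolerance = 1e-9)
  expect_equal(got2$r_squared, ref2$r2, tolerance = 1e-9)

  suppressWarnings({
    col <- correlate_tp_torg(c(0, 1, 2), 0.1 * c(0, 1, 2) + 300)
  })
  expect_equal(col$r_squared, 1)
  expect_equal(col$slope, 0.1)
  expect_equal(correlate_tp_torg(c(1, 2, 3), c(5, 5, 5))$r_squared, 0)
  expect_error(correlate_tp_torg(c(1, 2), c(1, 2)), ">= 3")
})

test_that("Kabsch RMSD: identity, rigid motion, and bio3d cross-check", {
  h <- make_helix(10)
  expect_equal(ca_rmsd(h, h), 0, tolerance = 1e-10)
  hr <- transform_structure(h, angle = 133, shift = c(-4, 8, 1))
  expect_lt(ca_rmsd(h, hr), 1e-6)

  set.seed(3)
  xa <- matrix(rnorm(12), 4, 3)
  xb <- matrix(rnorm(12), 4, 3)
  ours <- ca_rmsd(xa, xb)
  ref <- bio3d::rmsd(as.numeric(t(xa)), as.numeric(t(xb)), fit = TRUE)
  expect_equal(ours, ref, tolerance = 1e-3)  # bio3d rounds to 3 decimals
  expect_error(ca_rmsd(xa[1:2, ], xb[1:2, ]), ">= 3")
})

test_that("radius of gyration matches closed forms", {
  expect_equal(radius_of_gyration(matrix(c(0, 0, 0), 1, 3)), 0)
  expect_equal(radius_of_gyration(matrix(c(0, 0, 0, 2, 0, 0), 2, 3,
                                         byrow = TRUE)), 1)
  cube <- as.matrix(expand.grid(c(0, 1), c(0, 1), c(0, 1)))
  expect_equal(radius_of_gyration(cube), sqrt(3) / 2)
})

test_that("RMSIP: self-identity, orthogonal subspaces, random expectation", {
  h <- make_helix(12)
  e <- make_ensemble(h, 15, 0.3, seed = 8)
  expect_equal(rmsip(e, e), 1, tolerance = 1e-6)

  # constructed orthogonal subspaces
  v <- diag(30)[, 1:10]
  w <- diag(30)[, 11:20]
  expect_equal(rmsip(v, w), 0)
  expect_equal(rmsip(v, v), 1)

  # random 10-dim subspaces of a 300-dim space concentrate near sqrt(10/300)
  set.seed(5)
  vals <- replicate(12, {
    qa <- qr.Q(qr(matrix(rnorm(300 * 10), 300, 10)))
    qb <- qr.Q(qr(matrix(rnorm(300 * 10), 300, 10)))
    rmsip(qa, qb)
  })
  expect_equal(mean(vals), sqrt(10 / 300), tolerance = 0.1)
})

test_that("rmsip is symmetric and bounded on perturbed ensembles", {
  h <- make_helix(12)
  a <- make_ensemble(h, 14, 0.2, seed = 1)
  b <- make_ensemble(h, 14, 0.2, seed = 2)
  r1 <- rmsip(a, b)
  r2 <- rmsip(b, a)
  expect_equal(r1, r2, tolerance = 1e-9)
  expect_gte(r1, 0); expect_lte(r1, 1)
})
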