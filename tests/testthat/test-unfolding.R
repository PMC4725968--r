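fake_trajectory <- function(p_inf, t = seq(300, by = 10,
                                           length.out = length(p_inf))) {
  out <- list(states = data.frame(state = seq_along(p_inf),
                                  e_cut = -(seq_along(p_inf) - 1),
                                  t = t, p_inf = p_inf,
                                  n_clusters = seq_along(p_inf), dof = 6))
  class(out) <- "unfolding_trajectory"
  out
}

test_that("the temperature map is linear with the documented defaults", {
  expect_equal(temperature_of(0), 300)
  expect_equal(temperature_of(-1), 320)
  expect_equal(temperature_of(-5), 400)
  expect_error(temperature_map(slope = 2), "slope")
  m <- temperature_map(slope = -10, intercept = 280)
  expect_equal(temperature_of(-2, m), 300)
})

test_that("dilution requires dilutable constraints and orders states", {
  net <- make_two_block_network(4)
  traj <- dilute_network(net)
  expect_true(all(diff(traj$states$e_cut) < 0))
  expect_true(all(diff(traj$states$t) > 0))
  expect_true(all(diff(traj$states$p_inf) <= 0))
  expect_true(all(diff(traj$states$n_clusters) >= 0))

  hydronet <- constraint_network(2, data.frame(a = 1, b = 2, mult = 2L,
                                               source = "hydrophobic",
                                               energy = NA_real_))
  expect_error(dilute_network(hydronet), "trajectory undefined")
})

test_that("bonds sharing an energy leave in a single dilution step", {
  net <- make_two_block_network(4, bridge_energies = c(-3, -3), n_bridges = 2)
  traj <- dilute_network(net)
  expect_equal(nrow(traj$states), 3)  # initial, bridges, internal
})

test_that("equal-energy planted networks put T_p exactly on the grid", {
  for (estar in c(-2, -3, -4.5)) {
    net <- make_two_block_network(4, bridge_energies = estar, n_bridges = 2)
    traj <- dilute_network(net)
    tp <- phase_transition(traj)
    expect_true(tp$transition)
    expect_equal(tp$tp, temperature_of(estar - 1e-5))
  }
})

test_that("max_drop ties resolve to the lowest temperature", {
  traj <- fake_trajectory(c(1.0, 0.7, 0.4, 0.1))
  tp <- phase_transition(traj)
  expect_equal(tp$tp, 310)  # first of the equal drops
})

test_that("transition-free trajectories are flagged, not numeric", {
  expect_false(phase_transition(fake_trajectory(c(1, 1, 1, 1)))$transition)
  expect_false(phase_transition(fake_trajectory(c(1, 0.5)))$transition)  # < 3 states
  expect_true(is.na(phase_transition(fake_trajectory(c(1, 1, 1)))$tp))
})

test_that("sigmoid fit recovers the midpoint of a clean two-state decay", {
  t <- seq(300, 400, by = 5)
  p <- 0.05 + 0.9 / (1 + exp((t - 352) / 4))
  traj <- fake_trajectory(p, t)
  tp <- phase_transition(traj, method = "sigmoid_fit")
  expect_true(tp$transition)
  expect_equal(tp$tp, 352, tolerance = 0.01)
})

test_that("T_p is invariant to refining the grid below per-bond resolution", {
  net <- make_two_block_network(4, bridge_energies = -3, n_bridges = 2)
  tp_pb <- phase_transition(dilute_network(net, grid = "per_bond"))$tp
  tp_fs <- phase_transition(dilute_network(net, grid = "fixed_step",
                                           step = 0.05))$tp
  expect_lt(abs(tp_pb - tp_fs), 0.05 * 20 + 1e-6)
})

test_that("stability maps record separation energies and persistence", {
  net <- make_two_block_network(4, bridge_energies = -3, n_bridges = 2)
  traj <- dilute_network(net)
  m <- stability_map(traj, level = "body")
  # cross-block pairs separate when the bridges leave
  cross <- m[(m$body_a <= 4) != (m$body_b <= 4), ]
  expect_true(all(!cross$persistent))
  expect_true(all(abs(cross$e_rc - (-3 - 1e-5)) < 1e-9))
  within <- m[(m$body_a <= 4) == (m$body_b <= 4), ]
  expect_true(all(within$persistent))
  expect_true(all(within$e_rc == min(traj$states$e_cut)))

  # never co-rigid pairs are absent: single bridge cannot rigidify the union
  net1 <- make_two_block_network(4, bridge_energies = -3, n_bridges = 1)
  m1 <- stability_map(dilute_network(net1), level = "body")
  cross1 <- m1[(m1$body_a <= 4) != (m1$body_b <= 4), ]
  expect_equal(nrow(cross1), 0)

  # single-state trajectory: everything co-rigid is persistent
  tr1 <- dilute_network(net)
  tr1$states <- tr1$states[1, , drop = FALSE]
  tr1$body_clusters <- tr1$body_clusters[, 1, drop = FALSE]
  m2 <- stability_map(tr1, level = "body")
  expect_true(all(m2$persistent))
})

test_that("E_rc ordering is consistent with separation order", {
  net <- make_two_block_network(4, bridge_energies = c(-2, -2), n_bridges = 2)
  # add a third block hanging on block 2 by two weaker bridges
  extra <- data.frame(a = c(9, 10, 9, 11, 5, 6),
                      b = c(10, 11, 11, 9, 9, 10),
                      mult = c(6L, 6L, 6L, 6L, 5L, 5L),
                      source = c(rep("covalent_locked", 4), "hbond", "hbond"),
                      energy = c(rep(NA, 4), -1, -1))
  net2 <- constraint_network(11, rbind(net$bars, extra))
  traj <- dilute_network(net2)
  m <- stability_map(traj, level = "body")
  erc <- function(i, j) m$e_rc[(m$body_a == i & m$body_b == j) |
                                 (m$body_a == j & m$body_b == i)]
  # body 1 loses the far block (body 9, at -1) before the sibling block
  # (body 5, at -2): later separation means more negative E_rc
  expect_gt(erc(1, 9), erc(1, 5))
})
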