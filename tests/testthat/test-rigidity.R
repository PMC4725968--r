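abstract_net <- function(n, a, b, mult) {
  constraint_network(n, data.frame(a = a, b = b, mult = mult,
                                   source = "abstract", energy = NA_real_,
                                   stringsAsFactors = FALSE))
}

test_that("pebble game reproduces counting-rule reference cases", {
  d <- pebble_game(constraint_network(1))
  expect_equal(d$dof, 6); expect_equal(d$sizes, 1); expect_equal(d$p_inf, 1)

  d <- pebble_game(abstract_net(2, 1, 2, 6))
  expect_equal(d$dof, 6); expect_equal(d$sizes, 2)

  d <- pebble_game(abstract_net(2, 1, 2, 5))       # hinge
  expect_equal(d$dof, 7); expect_equal(d$sizes, c(1, 1))

  # 3-ring of 5-bar edges: isostatic without redundancy inside pairs
  d <- pebble_game(abstract_net(3, c(1, 2, 1), c(2, 3, 3), c(5, 5, 5)))
  expect_equal(d$dof, 6); expect_equal(d$sizes, 3)

  # open chain of 4 bodies: three hinges
  d <- pebble_game(abstract_net(4, 1:3, 2:4, 5))
  expect_equal(d$dof, 9); expect_equal(d$sizes, rep(1, 4))

  # 6-ring of 5-bar edges: 30 bars = 6*6 - 6, one rigid cluster
  d <- pebble_game(abstract_net(6, 1:6, c(2:6, 1), 5))
  expect_equal(d$dof, 6); expect_equal(d$sizes, 6)
})

test_that("pebble game equals the count-matroid oracle on random multigraphs", {
  for (k in 1:60) {
    set.seed(k)
    n <- sample(2:6, 1)
    nb <- sample(0:min(6 * n * (n - 1) / 2, 36), 1)
    net <- random_body_bar_graph(n, nb, seed = k)
    pg <- pebble_game(net)
    bf <- brute_force_decomposition(net)
    expect_equal(pg$dof, bf$dof)
    expect_identical(pg$cluster, bf$cluster)
    expect_equal(pg$n_independent, bf$n_independent)
  }
})

test_that("oracle refuses oversized networks", {
  expect_error(brute_force_decomposition(random_body_bar_graph(9, 10, 1)),
               "refused")
})

test_that("adding bars never increases DOF nor splits clusters", {
  for (k in 1:15) {
    net <- random_body_bar_graph(6, 25, seed = 100 + k)
    d0 <- pebble_game(net)
    set.seed(k)
    extra <- data.frame(a = 1, b = sample(2:6, 1), mult = 1L,
                        source = "abstract", energy = NA_real_)
    net2 <- constraint_network(6, rbind(net$bars, extra))
    d1 <- pebble_game(net2)
    expect_lte(d1$dof, d0$dof)
    # clusters only merge: same cluster before implies same cluster after
    for (i in 1:5) for (j in (i + 1):6) {
      if (d0$cluster[i] == d0$cluster[j])
        expect_equal(d1$cluster[i], d1$cluster[j])
    }
  }
})

test_that("decomposition is invariant to bar insertion order", {
  net <- random_body_bar_graph(6, 30, seed = 42)
  d0 <- pebble_game(net)
  for (k in 1:5) {
    set.seed(k)
    shuffled <- net
    shuffled$bars <- net$bars[sample(nrow(net$bars)), ]
    d1 <- pebble_game(shuffled)
    expect_equal(d1$dof, d0$dof)
    expect_identical(d1$cluster, d0$cluster)
  }
})

test_that("structure networks follow the bond-order bar table", {
  h <- make_helix(5)
  net <- build_network(h, NULL)
  b <- net$bars
  bo <- net$bodies
  body_at <- function(resno, atom) which(bo$resno == resno & bo$atom == atom)
  # peptide bond C(1)-N(2): locked, 6 bars
  e <- b[(b$a == body_at(1, "C") & b$b == body_at(2, "N")) |
           (b$b == body_at(1, "C") & b$a == body_at(2, "N")), ]
  expect_equal(e$mult, 6L)
  expect_equal(e$source, "covalent_locked")
  # N(2)-CA(2) and CA(2)-C(2): rotatable, 5 bars
  for (pair in list(c("N", "CA"), c("CA", "C"))) {
    e <- b[(b$a == body_at(2, pair[1]) & b$b == body_at(2, pair[2])) |
             (b$b == body_at(2, pair[1]) & b$a == body_at(2, pair[2])), ]
    expect_equal(e$mult, 5L)
    expect_equal(e$source, "covalent_rotatable")
  }
  # carbonyl O and Ala CB are merged away (terminal atoms)
  expect_false(any(bo$atom == "O"))
  expect_false(any(bo$atom == "CB"))
})

test_that("hydrogen bonds rigidify the helix core; removing them shatters it", {
  h <- make_helix(20)
  ints <- detect_interactions(h)
  net <- build_network(h, ints, e_cut = 0)
  rcm <- residue_cluster_membership(pebble_game(net), net)
  core <- rcm$cluster[rcm$resno %in% 2:19]
  expect_equal(length(unique(core)), 1)

  net2 <- build_network(h, ints[ints$kind == "hydrophobic", ], e_cut = 0)
  rcm2 <- residue_cluster_membership(pebble_game(net2), net2)
  expect_gt(length(unique(rcm2$cluster)), 10)
})

test_that("e_cut filters dilutable constraints at network build", {
  h <- make_helix(10)
  ints <- detect_interactions(h)
  net_all <- build_network(h, ints, e_cut = 0)
  expect_equal(sum(net_all$bars$source == "hbond"), 6)
  net_none <- build_network(h, ints, e_cut = -20)
  expect_equal(sum(net_none$bars$source == "hbond"), 0)
  expect_gt(nrow(net_none$bars), 0)  # covalent skeleton remains
})

test_that("single-residue structures get a valid cluster assignment", {
  # a lone residue keeps its three backbone bodies (N, CA, C) joined by
  # rotatable bonds: three singleton clusters, the residue reported at its
  # CA body's cluster
  s <- mini_structure(single_ala())
  net <- build_network(s, NULL)
  dec <- pebble_game(net)
  rcm <- residue_cluster_membership(dec, net)
  expect_equal(nrow(rcm), 1)
  expect_true(rcm$cluster %in% seq_along(dec$sizes))
})
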