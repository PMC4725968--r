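# Synthetic structure and network generators. These define the study
# conditions for the whole pipeline: idealized helices with known hydrogen
# bond networks, toy dimers with planted interface interactions, perturbed
# ensembles standing in for MD snapshots, and abstract body-bar multigraphs
# for validating the pebble game.

helix_geometry <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231, b_n_h = 1.01,
  a_n_ca_c = 111.0, a_ca_c_n = 116.2, a_c_n_ca = 121.7, a_ca_c_o = 120.8,
  phi = -57, psi = -47, omega = 180
)

# ideal CB reconstruction from N, CA, C (standard virtual-CB coefficients,
# L-configuration)
ideal_cb <- function(N, CA, C) {
  b <- CA - N
  c <- C - CA
  a <- cross3(b, c)
  CA - 0.58273431 * a + 0.56802827 * b - 0.54067466 * c
}

#' Ideal poly-alanine alpha-helix
#'
#' Builds an n-residue poly-Ala helix with ideal backbone dihedrals
#' (phi = -57, psi = -47, omega = 180) and standard bond geometry, places the
#' backbone amide hydrogens (in-plane, bisecting C-N-CA), and annotates all
#' residues as helix. By construction the structure carries exactly
#' `n_residues - 4` i -> i+4 backbone hydrogen bonds.
#'
#' @param n_residues number of residues (>= 5, so at least one i -> i+4
#'   contact exists)
#' @param seed accepted for interface uniformity; the geometry is fully
#'   deterministic
#' @param chain_id chain identifier
#' @param start_resno first residue number
#' @return a `structure3d` with helix annotation
#' @export
make_helix <- function(n_residues, seed = 1, chain_id = "A", start_resno = 1L) {
  if (n_residues < 5)
    stop("n_residues must be >= 5: no i -> i+4 hydrogen bond possible")
  g <- helix_geometry
  N <- list(); CA <- list(); C <- list(); O <- list(); CB <- list(); H <- list()
  N[[1]] <- c(0, 0, 0)
  CA[[1]] <- c(g$b_n_ca, 0, 0)
  ang <- deg2rad(180 - g$a_n_ca_c)
  C[[1]] <- CA[[1]] + g$b_ca_c * c(cos(ang), sin(ang), 0)
  for (i in seq_len(n_residues)) {
    if (i > 1) {
      N[[i]] <- place_atom(N[[i - 1]], CA[[i - 1]], C[[i - 1]],
                           g$b_c_n, g$a_ca_c_n, g$psi)
      CA[[i]] <- place_atom(CA[[i - 1]], C[[i - 1]], N[[i]],
                            g$b_n_ca, g$a_c_n_ca, g$omega)
      C[[i]] <- place_atom(C[[i - 1]], N[[i]], CA[[i]],
                           g$b_ca_c, g$a_n_ca_c, g$phi)
      H[[i]] <- N[[i]] + g$b_n_h *
        unitv(-(unitv(C[[i - 1]] - N[[i]]) + unitv(CA[[i]] - N[[i]])))
    }
    O[[i]] <- place_atom(N[[i]], CA[[i]], C[[i]], g$b_c_o, g$a_ca_c_o,
                         g$psi + 180)
    CB[[i]] <- ideal_cb(N[[i]], CA[[i]], C[[i]])
  }
  rows <- list()
  addrow <- function(name, elesy, resno, xyz)
    rows[[length(rows) + 1]] <<- data.frame(
      eleno = 0L, elety = name, elesy = elesy, resid = "ALA",
      chain = chain_id, resno = resno, insert = "",
      x = xyz[1], y = xyz[2], z = xyz[3], o = 1, b = 0, het = FALSE,
      stringsAsFactors = FALSE)
  for (i in seq_len(n_residues)) {
    rn <- start_resno + i - 1L
    addrow("N", "N", rn, N[[i]])
    addrow("CA", "C", rn, CA[[i]])
    addrow("C", "C", rn, C[[i]])
    addrow("O", "O", rn, O[[i]])
    addrow("CB", "C", rn, CB[[i]])
    if (i > 1) addrow("H", "H", rn, H[[i]])
  }
  atom <- do.call(rbind, rows)
  atom$eleno <- seq_len(nrow(atom))
  s <- structure3d(atom,
                   helix = data.frame(chain = chain_id, start = start_resno,
                                      end = start_resno + n_residues - 1L,
                                      stringsAsFactors = FALSE))
  s
}

apply_transform <- function(xyz, R, t) sweep(xyz %*% t(R), 2, t, "+")

rigid_transform <- function(par) {
  # par = (rotation vector, translation)
  rv <- par[1:3]
  theta <- vnorm(rv)
  R <- if (theta < 1e-12) diag(3) else rotation_matrix(rv / theta, rad2deg(theta))
  list(R = R, t = par[4:6])
}

c2_transform <- function(par, centroid) {
  # 180 degree rotation about the line through p with direction u
  u <- c(sin(par[1]) * cos(par[2]), sin(par[1]) * sin(par[2]), cos(par[1]))
  p <- centroid + par[3:5]
  R <- rotation_matrix(u, 180)
  # x -> R (x - p) + p = R x + (p - R p)
  list(R = R, t = p - as.numeric(R %*% p))
}

# TRUE when a candidate placement realizes every plant within tolerance
plant_ok <- function(par, c2, centroid, xyzA, hb_spec, cb_spec, salt_spec,
                     params) {
  tr <- if (c2) c2_transform(par, centroid) else rigid_transform(par)
  xyzB <- apply_transform(xyzA, tr$R, tr$t)
  for (x in hb_spec) {
    e <- hbond_energy(xyzA[x$iN, ], xyzA[x$iH, ], xyzB[x$jO, ], xyzB[x$jC, ],
                      params)
    if (abs(e - x$energy) > 0.2) return(FALSE)
    # the detector must also see it: distance and angle screens
    if (vnorm(xyzB[x$jO, ] - xyzA[x$iN, ]) > params$dist_cutoff) return(FALSE)
    if (vnorm(xyzB[x$jO, ] - xyzA[x$iH, ]) > params$ha_cutoff) return(FALSE)
    if (angle3(xyzA[x$iN, ], xyzA[x$iH, ], xyzB[x$jO, ]) < params$dha_min)
      return(FALSE)
  }
  for (x in c(cb_spec, salt_spec)) {
    if (abs(vnorm(xyzB[x$jCB, ] - xyzA[x$iCB, ]) - x$dist) > 0.01) return(FALSE)
  }
  TRUE
}

# geometric plan realizing a target hydrogen-bond energy within the detector
# cutoffs: donor-acceptor distance on the 10-12 well (capped at d_cap so the
# distance screens pass), with any remaining weakening expressed as a
# deliberate acceptor-angle deviation (D-H...A stays linear)
hbond_plant_geometry <- function(target, params = hbond_params(), d_cap = 3.3) {
  if (target >= params$e_cutoff || target <= -params$v0)
    stop("geometrically unrealizable plant: hydrogen-bond energy ", target,
         " kcal/mol outside (", -params$v0, ", ", params$e_cutoff, ")")
  radial <- function(d) {
    u <- params$d0 / d
    params$v0 * (5 * u^12 - 6 * u^10)
  }
  if (target <= radial(d_cap)) {
    d <- stats::uniroot(function(d) radial(d) - target, c(params$d0, d_cap),
                        tol = 1e-12)$root
    bah <- params$bah_ideal
  } else {
    d <- d_cap
    f_needed <- target / radial(d_cap)
    bah <- params$bah_ideal + rad2deg(acos(sqrt(f_needed)))
  }
  list(d_target = d, bah_target = bah)
}

#' Toy dimer with planted interface interactions
#'
#' Two identical short helices (chains A and B); chain B is rigid-body placed
#' by numerical optimization so that planted interchain hydrogen bonds are
#' realized at their target energies (ideal angles, distance tuned on the
#' 10-12 well), planted Cbeta-Cbeta pairs at their target distances (within
#' 0.01 A), and planted salt bridges via single-atom side-chain stubs (the
#' donor residue is renamed LYS with an NZ stub, the acceptor GLU with an OE1
#' stub, on the line between the partner residues). Non-participating atoms
#' are kept farther apart than the hydrophobic detection cutoff, so no
#' accidental interchain tethers arise.
#'
#' @param n_residues residues per chain
#' @param planted_hbonds data.frame(res_a, res_b, energy): backbone N-H of
#'   residue `res_a` in chain A (res_a >= 2) donates to backbone O of residue
#'   `res_b` in chain B; energy in kcal/mol
#' @param planted_cb_pairs data.frame(res_a, res_b, dist): target
#'   Cbeta-Cbeta distances in Angstrom
#' @param planted_salt_bridges data.frame(res_a, res_b): Lys(A)-Glu(B) stub
#'   pairs at 3.5 A N-O distance
#' @param c2 constrain chain B to be an exact C2 copy of chain A (the
#'   transform is a 180-degree rotation)
#' @param separation initial axis-to-axis offset in Angstrom
#' @param seed seeds the monomer jitter and optimizer restarts (results are
#'   reproducible for a fixed spec)
#' @param jitter_sd per-coordinate Gaussian jitter applied to the monomer
#'   before dimerization, in Angstrom. The default 0.01 A leaves the helix
#'   hydrogen-bond count untouched but breaks the exact energy degeneracy of
#'   the ideal geometry, so dilution removes backbone bonds in many small
#'   steps instead of one catastrophic one (as in any real structure)
#' @param max_restarts random restarts before declaring the plant unrealizable
#' @return a two-chain `structure3d`; attribute `"diagnostics"` carries the
#'   realized energies/distances
#' @export
make_toy_dimer <- function(n_residues = 10, planted_hbonds = NULL,
                           planted_cb_pairs = NULL, planted_salt_bridges = NULL,
                           c2 = FALSE, separation = 12, seed = 1,
                           jitter_sd = 0.01, max_restarts = 20) {
  A <- make_helix(n_residues, chain_id = "A")
  atomA <- A$atom
  xyzA <- as.matrix(atomA[, c("x", "y", "z")])
  if (jitter_sd > 0) {
    set.seed(seed)
    xyzA <- xyzA + matrix(stats::rnorm(length(xyzA), 0, jitter_sd), ncol = 3)
    atomA$x <- xyzA[, 1]; atomA$y <- xyzA[, 2]; atomA$z <- xyzA[, 3]
  }
  centroid <- colMeans(xyzA)
  has_plants <- !is.null(planted_hbonds) || !is.null(planted_cb_pairs) ||
    !is.null(planted_salt_bridges)
  if (!is.null(planted_hbonds) && any(planted_hbonds$res_a < 2))
    stop("planted hydrogen-bond donors need res_a >= 2 (amide H required)")

  aidx <- function(resno, name) which(atomA$resno == resno & atomA$elety == name)
  params <- hbond_params()
  hb_spec <- NULL
  if (!is.null(planted_hbonds)) {
    hb_spec <- lapply(seq_len(nrow(planted_hbonds)), function(k) {
      geom <- hbond_plant_geometry(planted_hbonds$energy[k], params)
      list(iN = aidx(planted_hbonds$res_a[k], "N"),
           iH = aidx(planted_hbonds$res_a[k], "H"),
           jO = aidx(planted_hbonds$res_b[k], "O"),
           jC = aidx(planted_hbonds$res_b[k], "C"),
           energy = planted_hbonds$energy[k],
           d_target = geom$d_target, bah_target = geom$bah_target)
    })
  }
  cb_spec <- NULL
  if (!is.null(planted_cb_pairs)) {
    cb_spec <- lapply(seq_len(nrow(planted_cb_pairs)), function(k) {
      list(iCB = aidx(planted_cb_pairs$res_a[k], "CB"),
           jCB = aidx(planted_cb_pairs$res_b[k], "CB"),
           dist = planted_cb_pairs$dist[k])
    })
  }
  salt_spec <- NULL
  if (!is.null(planted_salt_bridges)) {
    salt_spec <- lapply(seq_len(nrow(planted_salt_bridges)), function(k) {
      list(iCB = aidx(planted_salt_bridges$res_a[k], "CB"),
           jCB = aidx(planted_salt_bridges$res_b[k], "CB"),
           res_a = planted_salt_bridges$res_a[k],
           res_b = planted_salt_bridges$res_b[k],
           dist = 6.5)  # CB-CB distance leaving 3.5 A between 1.5 A stubs
    })
  }
  participants <- unique(c(
    unlist(lapply(hb_spec, function(x) c(x$iN, x$iH, x$jO, x$jC))),
    unlist(lapply(cb_spec, function(x) c(x$iCB, x$jCB))),
    unlist(lapply(salt_spec, function(x) c(x$iCB, x$jCB)))))
  heavyA <- which(atomA$elesy != "H")
  clash_set <- setdiff(heavyA, participants)
  # keep carbon/sulfur pairs beyond the hydrophobic detection cutoff so no
  # accidental interchain tethers arise; other pairs only avoid hard overlap
  is_cs <- atomA$elesy[clash_set] %in% c("C", "S")
  clash_thr <- ifelse(outer(is_cs, is_cs, "&"), 3.72, 3.0)
  # keep unplanted interchain CB pairs out of the cystine screen window
  cb_all <- which(atomA$elety == "CB")
  planted_cb_keys <- vapply(c(cb_spec, salt_spec),
                            function(x) paste(x$iCB, x$jCB), character(1))

  objective <- function(par, we = 0, wc = 5) {
    tr <- if (c2) c2_transform(par, centroid) else rigid_transform(par)
    xyzB <- apply_transform(xyzA, tr$R, tr$t)
    val <- 0
    for (x in hb_spec) {
      dNO <- vnorm(xyzB[x$jO, ] - xyzA[x$iN, ])
      dha_dev <- 180 - angle3(xyzA[x$iN, ], xyzA[x$iH, ], xyzB[x$jO, ])
      bah_off <- angle3(xyzB[x$jC, ], xyzB[x$jO, ], xyzA[x$iH, ]) - x$bah_target
      dHO <- vnorm(xyzB[x$jO, ] - xyzA[x$iH, ])
      val <- val + 10 * (dNO - x$d_target)^2 +
        200 * (1 - cos(deg2rad(dha_dev)))^2 +
        200 * (1 - cos(deg2rad(bah_off)))^2 +
        # stay inside the detector screens with margin
        2000 * max(dNO - 3.45, 0)^2 + 2000 * max(dHO - 2.45, 0)^2 +
        0.05 * max(130 - (180 - dha_dev), 0)^2
      if (we > 0) {
        e <- hbond_energy(xyzA[x$iN, ], xyzA[x$iH, ], xyzB[x$jO, ], xyzB[x$jC, ],
                          params)
        val <- val + we * (e - x$energy)^2
      }
    }
    for (x in cb_spec)
      val <- val + 100 * (vnorm(xyzB[x$jCB, ] - xyzA[x$iCB, ]) - x$dist)^2
    for (x in salt_spec)
      val <- val + 100 * (vnorm(xyzB[x$jCB, ] - xyzA[x$iCB, ]) - x$dist)^2
    if (length(clash_set) > 0) {
      dm <- cross_dist(xyzA[clash_set, , drop = FALSE],
                       xyzB[clash_set, , drop = FALSE])
      close <- dm < clash_thr
      if (any(close)) val <- val + wc * sum((clash_thr[close] - dm[close])^2)
    }
    if (length(cb_all) > 0) {
      dcb <- cross_dist(xyzA[cb_all, , drop = FALSE],
                        xyzB[cb_all, , drop = FALSE])
      keys <- outer(cb_all, cb_all, function(i, j) paste(i, j))
      inwin <- dcb > 3.55 & dcb < 4.11 & !(keys %in% planted_cb_keys)
      if (any(inwin)) val <- val + 20 * sum((4.11 - dcb[inwin])^2)
    }
    val
  }

  # without plants the chains are placed with a guaranteed gap of at least
  # `separation` (pure translation beyond the chain's own x-extent)
  gap_shift <- diff(range(xyzA[, 1])) + separation
  par0 <- if (c2) c(pi / 2, pi / 2, if (has_plants) separation / 2 else gap_shift / 2, 0, 0)
          else if (has_plants) c(0, 0, pi, separation, 0, 0)
          else c(0, 0, 0, gap_shift, 0, 0)
  # candidate initializations: realize the first planted hydrogen bond
  # exactly (collinear N-H...O, acceptor at its target angle) and spin chain
  # B about the bond axis
  starts <- list(par0)
  if (!c2 && !is.null(hb_spec)) {
    x <- hb_spec[[1]]
    u <- unitv(xyzA[x$iH, ] - xyzA[x$iN, ])
    p_o <- xyzA[x$iN, ] + x$d_target * u
    tperp <- xyzA[x$iN, ] - centroid
    tperp <- tperp - sum(tperp * u) * u
    tperp <- if (vnorm(tperp) < 1e-6) unitv(cross3(u, c(0, 0, 1))) else unitv(tperp)
    th <- deg2rad(x$bah_target)            # acceptor angle from O -> H direction
    w <- -cos(th) * u + sin(th) * tperp
    p_c <- p_o + vnorm(xyzA[x$jC, ] - xyzA[x$jO, ]) * w
    # align B's O -> C bond onto p_o -> p_c
    vB <- unitv(xyzA[x$jC, ] - xyzA[x$jO, ])
    vT <- unitv(p_c - p_o)
    axis <- cross3(vB, vT)
    R1 <- if (vnorm(axis) < 1e-9) diag(3)
          else rotation_matrix(axis, rad2deg(atan2(vnorm(axis), sum(vB * vT))))
    spins <- lapply(seq(0, 350, by = 10), function(phi) {
      R <- rotation_matrix(vT, phi) %*% R1
      tv <- p_o - as.numeric(R %*% xyzA[x$jO, ])
      c(rotvec_from_matrix(R), tv)
    })
    raw <- vapply(spins, objective, numeric(1))
    starts <- spins[order(raw)]
  }
  set.seed(seed)
  best <- NULL
  nm <- function(p, we, maxit = 2500) {
    stats::optim(p, objective, we = we, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-14))
  }
  if (has_plants) {
    tries <- c(starts,
               lapply(seq_len(max_restarts), function(r)
                 starts[[1]] + stats::rnorm(length(par0), 0, r / 4)))
    batches <- split(tries, ceiling(seq_along(tries) / 8))
    for (batch in batches) {
      stage1 <- lapply(batch, nm, we = 0)       # locate the bond basin
      cand <- stage1[[which.min(vapply(stage1, `[[`, numeric(1), "value"))]]
      fit <- nm(cand$par, we = 500)             # enforce detector energies
      fit <- nm(fit$par, we = 500)
      if (is.null(best) || fit$value < best$value) best <- fit
      if (plant_ok(best$par, c2, centroid, xyzA, hb_spec, cb_spec, salt_spec,
                   params)) break
    }
    par <- best$par
  } else par <- par0

  tr <- if (c2) c2_transform(par, centroid) else rigid_transform(par)
  xyzB <- apply_transform(xyzA, tr$R, tr$t)

  atomB <- atomA
  atomB$chain <- "B"
  atomB$x <- xyzB[, 1]; atomB$y <- xyzB[, 2]; atomB$z <- xyzB[, 3]

  # verify the plants at detector level
  diag_hb <- NULL
  for (x in hb_spec) {
    e <- hbond_energy(xyzA[x$iN, ], xyzA[x$iH, ], xyzB[x$jO, ], xyzB[x$jC, ], params)
    seen <- vnorm(xyzB[x$jO, ] - xyzA[x$iN, ]) <= params$dist_cutoff &&
      vnorm(xyzB[x$jO, ] - xyzA[x$iH, ]) <= params$ha_cutoff &&
      angle3(xyzA[x$iN, ], xyzA[x$iH, ], xyzB[x$jO, ]) >= params$dha_min
    if (abs(e - x$energy) > 0.2 || !seen)
      stop("geometrically unrealizable plant: hydrogen bond target ", x$energy,
           " kcal/mol realized at ", signif(e, 4),
           " kcal/mol (detector-visible: ", seen, ")")
    diag_hb <- c(diag_hb, e)
  }
  diag_cb <- NULL
  for (x in c(cb_spec, salt_spec)) {
    d <- vnorm(xyzB[x$jCB, ] - xyzA[x$iCB, ])
    if (abs(d - x$dist) > 0.01)
      stop("geometrically unrealizable plant: Cbeta pair target ", x$dist,
           " A realized at ", signif(d, 5), " A (clashing constraints?)")
    diag_cb <- c(diag_cb, d)
  }

  # salt-bridge stubs: rename residues, add NZ (chain A) / OE1 (chain B)
  stub_rows <- NULL
  for (x in salt_spec) {
    pa <- xyzA[x$iCB, ]; pb <- xyzB[x$jCB, ]
    dir <- unitv(pb - pa)
    nz <- pa + 1.5 * dir
    oe <- pb - 1.5 * dir
    atomA$resid[atomA$resno == x$res_a] <- "LYS"
    atomB$resid[atomB$resno == x$res_b] <- "GLU"
    stub_rows <- rbind(stub_rows,
      data.frame(eleno = 0L, elety = "NZ", elesy = "N", resid = "LYS",
                 chain = "A", resno = x$res_a, insert = "",
                 x = nz[1], y = nz[2], z = nz[3], o = 1, b = 0, het = FALSE,
                 stringsAsFactors = FALSE),
      data.frame(eleno = 0L, elety = "OE1", elesy = "O", resid = "GLU",
                 chain = "B", resno = x$res_b, insert = "",
                 x = oe[1], y = oe[2], z = oe[3], o = 1, b = 0, het = FALSE,
                 stringsAsFactors = FALSE))
  }
  atom <- rbind(atomA, atomB, stub_rows)
  ord <- order(match(atom$chain, c("A", "B")), atom$resno, atom$elesy == "H")
  atom <- atom[ord, , drop = FALSE]
  atom$eleno <- seq_len(nrow(atom))
  s <- structure3d(atom, helix = data.frame(
    chain = c("A", "B"), start = 1L, end = n_residues,
    stringsAsFactors = FALSE))
  attr(s, "diagnostics") <- list(hbond_energies = diag_hb, cb_distances = diag_cb,
                                 objective = if (has_plants) best$value else 0)
  s
}

#' Coordinate-perturbed ensemble
#'
#' Model k = base coordinates + i.i.d. isotropic Gaussian displacement
#' (sd = `noise_sd`) per atom; with `noise_sd = 0` every model equals the
#' base. Stands in for snapshots of a structural ensemble.
#'
#' @param base a single-model `structure3d`
#' @param n_models number of models (>= 2)
#' @param noise_sd per-coordinate displacement SD in Angstrom (>= 0)
#' @param seed RNG seed; fully determines the ensemble
#' @return a `structure3d` with `n_models` models (model 1 is also perturbed)
#' @export
make_ensemble <- function(base, n_models, noise_sd, seed = 1) {
  stopifnot(n_models >= 2, noise_sd >= 0)
  xyz <- as.matrix(base$atom[, c("x", "y", "z")])
  set.seed(seed)
  models <- lapply(seq_len(n_models), function(k)
    xyz + matrix(stats::rnorm(length(xyz), 0, noise_sd), ncol = 3))
  out <- base
  out$models <- models
  out$atom$x <- models[[1]][, 1]
  out$atom$y <- models[[1]][, 2]
  out$atom$z <- models[[1]][, 3]
  out
}

#' Random body-bar multigraph
#'
#' Distributes exactly `n_bars` bars uniformly at random over the body pairs,
#' with at most 6 bars per pair (sampling without replacement from the 6 slots
#' of every pair).
#'
#' @param n_bodies number of bodies (>= 1)
#' @param n_bars total bars, 0 <= n_bars <= 6 * choose(n_bodies, 2)
#' @param seed RNG seed
#' @return a [constraint_network()] with bar source `"abstract"`
#' @export
random_body_bar_graph <- function(n_bodies, n_bars, seed = 1) {
  stopifnot(n_bodies >= 1)
  n_pairs <- n_bodies * (n_bodies - 1) / 2
  if (n_bars < 0 || n_bars > 6 * n_pairs)
    stop("infeasible n_bars: must be within [0, ", 6 * n_pairs, "]")
  if (n_bars == 0) return(constraint_network(n_bodies))
  pairs <- t(utils::combn(n_bodies, 2))
  set.seed(seed)
  slots <- sample.int(6 * n_pairs, n_bars)
  pair_id <- (slots - 1) %/% 6 + 1
  counts <- table(pair_id)
  ids <- as.integer(names(counts))
  bars <- data.frame(a = pairs[ids, 1], b = pairs[ids, 2],
                     mult = as.integer(counts), source = "abstract",
                     energy = NA_real_, stringsAsFactors = FALSE)
  constraint_network(n_bodies, bars)
}

#' Planted two-state (two-block) network
#'
#' Two internally rigid blocks (locked 6-bar backbone paths plus one internal
#' hydrogen-bond bar at `internal_energy`) connected by `n_bridges` bridging
#' hydrogen bonds at `bridge_energies`. With >= 2 bridges the union is rigid
#' (P_inf = 1); once dilution leaves fewer than two bridges the network
#' splits into two equal clusters, so the transition energy is the
#' second-strongest bridge energy and, when all bridges share one energy E*,
#' T_p = temperature_of(E* - eps) exactly under the per-bond grid.
#'
#' @param n_per_block bodies per block (>= 3)
#' @param bridge_energies bridge energies in kcal/mol (recycled to
#'   `n_bridges`)
#' @param n_bridges number of bridging bonds (>= 2 for an initially rigid
#'   union; must be <= n_per_block)
#' @param internal_energy energy of the within-block hydrogen bonds; should be
#'   stronger (more negative) than the bridges so the split comes first
#' @return a [constraint_network()]
#' @export
make_two_block_network <- function(n_per_block = 4, bridge_energies = -3,
                                   n_bridges = 2, internal_energy = -8) {
  stopifnot(n_per_block >= 3, n_bridges >= 1, n_bridges <= n_per_block)
  n <- 2L * n_per_block
  be <- rep_len(bridge_energies, n_bridges)
  bars <- list()
  for (blk in 0:1) {
    off <- blk * n_per_block
    for (i in seq_len(n_per_block - 1))
      bars[[length(bars) + 1]] <- data.frame(
        a = off + i, b = off + i + 1, mult = 6L, source = "covalent_locked",
        energy = NA_real_, stringsAsFactors = FALSE)
    bars[[length(bars) + 1]] <- data.frame(
      a = off + 1, b = off + 3, mult = 5L, source = "hbond",
      energy = internal_energy, stringsAsFactors = FALSE)
  }
  for (k in seq_len(n_bridges))
    bars[[length(bars) + 1]] <- data.frame(
      a = k, b = n_per_block + k, mult = 5L, source = "hbond",
      energy = be[k], stringsAsFactors = FALSE)
  constraint_network(n, do.call(rbind, bars))
}

#' Ensemble of planted two-state networks
#'
#' Each member is a [make_two_block_network()] whose (shared) bridge energy is
#' drawn from Normal(`bridge_mean`, `bridge_sd`); emulates snapshot-to-
#' snapshot variation of interface strength in a conformational ensemble.
#'
#' @param n_models number of networks
#' @param bridge_mean,bridge_sd bridge-energy distribution, kcal/mol
#' @param seed RNG seed
#' @param ... passed to [make_two_block_network()]
#' @return list of `constraint_network` objects
#' @export
make_two_block_ensemble <- function(n_models, bridge_mean = -3, bridge_sd = 0.2,
                                    seed = 1, ...) {
  set.seed(seed)
  e <- stats::rnorm(n_models, bridge_mean, bridge_sd)
  lapply(e, function(x) make_two_block_network(bridge_energies = x, ...))
}
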