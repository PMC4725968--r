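#' Hydrogen-bond energy function parameters
#'
#' Parameters of the distance/angle hydrogen-bond potential used to rank
#' constraints for dilution: a 10-12 well of depth `v0` at donor-acceptor
#' distance `d0`, modulated by squared-cosine angular terms. All constants are
#' exposed because different force-field lineages use slightly different
#' values.
#'
#' @param v0 well depth, kcal/mol (> 0; energy at the optimum is -v0)
#' @param d0 equilibrium donor-acceptor distance, Angstrom
#' @param dist_cutoff maximum donor-acceptor distance considered, Angstrom
#' @param ha_cutoff maximum hydrogen-acceptor distance, Angstrom (the second
#'   standard geometric screen; it discards bent contacts such as the
#'   i -> i+3 approaches inside an alpha-helix)
#' @param dha_min minimum D-H...A angle in degrees (linearity threshold)
#' @param e_cutoff energy acceptance cutoff, kcal/mol: candidates with
#'   E > e_cutoff are reported as non-bonds
#' @param acceptor_mode `"sp_agnostic"` applies a squared-cosine penalty on
#'   the deviation of the antecedent-acceptor-hydrogen angle from
#'   `bah_ideal`; `"none"` skips the acceptor term
#' @param bah_ideal ideal B-A...H angle in degrees for the acceptor term
#' @return list of class `hbond_params`
#' @export
hbond_params <- function(v0 = 8, d0 = 2.8, dist_cutoff = 3.6, ha_cutoff = 2.6,
                         dha_min = 100, e_cutoff = -0.1,
                         acceptor_mode = c("sp_agnostic", "none"),
                         bah_ideal = 120) {
  acceptor_mode <- match.arg(acceptor_mode)
  stopifnot(v0 > 0, d0 > 0, dist_cutoff > 0, ha_cutoff > 0)
  p <- list(v0 = v0, d0 = d0, dist_cutoff = dist_cutoff, ha_cutoff = ha_cutoff,
            dha_min = dha_min, e_cutoff = e_cutoff, acceptor_mode = acceptor_mode,
            bah_ideal = bah_ideal)
  class(p) <- "hbond_params"
  p
}

cos2_penalty <- function(dev) {
  dev <- abs(dev)
  ifelse(dev >= 90, 0, cos(deg2rad(dev))^2)
}

#' Hydrogen-bond energy from explicit geometry
#'
#' E = v0 * (5 (d0/d)^12 - 6 (d0/d)^10) * F with d the donor-acceptor
#' distance and F in \[0, 1\] the product of a squared-cosine term on the
#' deviation of the D-H...A angle from linearity and (optionally) a
#' squared-cosine acceptor-angle term about the acceptor antecedent. At
#' d = d0 with ideal angles the energy is exactly -v0; it is strictly
#' increasing in d for d > d0 and tends to 0 from below.
#'
#' @param donor,hydrogen,acceptor numeric xyz coordinates (length 3)
#' @param antecedent coordinates of the acceptor's bonded heavy atom, or NULL
#' @param params an [hbond_params()] object
#' @return energy in kcal/mol (0 when the angular factor vanishes)
#' @export
hbond_energy <- function(donor, hydrogen, acceptor, antecedent = NULL,
                         params = hbond_params()) {
  d <- vnorm(acceptor - donor)
  if (d < 1e-6) stop("degenerate geometry: coincident donor and acceptor")
  u <- params$d0 / d
  radial <- params$v0 * (5 * u^12 - 6 * u^10)
  dha <- angle3(donor, hydrogen, acceptor)
  f <- cos2_penalty(180 - dha)
  if (params$acceptor_mode == "sp_agnostic" && !is.null(antecedent)) {
    bah <- angle3(antecedent, acceptor, hydrogen)
    f <- f * cos2_penalty(bah - params$bah_ideal)
  }
  radial * f
}

interaction_row <- function(kind, atom, i, j, distance, energy) {
  # canonical order: (chain, resno, atom name)
  ka <- paste(atom$chain[i], sprintf("%06d", atom$resno[i]), atom$elety[i])
  kb <- paste(atom$chain[j], sprintf("%06d", atom$resno[j]), atom$elety[j])
  if (ka > kb) { tmp <- i; i <- j; j <- tmp }
  data.frame(kind = kind,
             chain_a = atom$chain[i], resno_a = atom$resno[i],
             resid_a = atom$resid[i], atom_a = atom$elety[i],
             chain_b = atom$chain[j], resno_b = atom$resno[j],
             resid_b = atom$resid[j], atom_b = atom$elety[j],
             distance = distance, energy = energy,
             interchain = atom$chain[i] != atom$chain[j],
             stringsAsFactors = FALSE)
}

empty_interactions <- function() {
  data.frame(kind = character(), chain_a = character(), resno_a = integer(),
             resid_a = character(), atom_a = character(), chain_b = character(),
             resno_b = integer(), resid_b = character(), atom_b = character(),
             distance = numeric(), energy = numeric(), interchain = logical(),
             stringsAsFactors = FALSE)
}

#' Detect hydrogen bonds
#'
#' Enumerates donor (N/O/S with attached hydrogen) against acceptor (N/O/S)
#' pairs, scores them with [hbond_energy()], and keeps pairs passing the
#' distance, D-H...A angle and energy cutoffs. Polar backbone hydrogens are
#' placed first when the structure has none. Water/HETATM entities are
#' excluded unless `include_het = TRUE`.
#'
#' @param s a `structure3d`
#' @param params an [hbond_params()] object
#' @param include_het include HETATM atoms as donors/acceptors
#' @return interaction data.frame sorted by energy (strongest first); one row
#'   per donor-acceptor atom pair
#' @export
detect_hbonds <- function(s, params = hbond_params(), include_het = FALSE) {
  if (!any(s$atom$elesy == "H" & !s$atom$het)) s <- place_polar_hydrogens(s)
  atom <- s$atom
  ok <- if (include_het) rep(TRUE, nrow(atom)) else !atom$het
  xyz <- as.matrix(atom[, c("x", "y", "z")])
  bonds <- covalent_bonds(s)
  adj <- bond_adjacency(bonds, nrow(atom))

  hs <- which(atom$elesy == "H" & ok)
  polar <- which(atom$elesy %in% c("N", "O", "S") & ok)
  if (length(hs) == 0 || length(polar) == 0) return(empty_interactions())

  # hydrogen -> parent heavy atom
  parent <- vapply(hs, function(h) {
    nb <- adj[[h]]
    nb <- nb[atom$elesy[nb] != "H"]
    if (length(nb) == 0) NA_integer_ else nb[1]
  }, integer(1))
  keep <- !is.na(parent) & atom$elesy[parent] %in% c("N", "O", "S")
  hs <- hs[keep]; parent <- parent[keep]
  if (length(hs) == 0) return(empty_interactions())

  acceptors <- polar
  keys <- residue_keys(atom)
  out <- list()
  dm <- cross_dist(xyz[parent, , drop = FALSE], xyz[acceptors, , drop = FALSE])
  for (k in seq_along(hs)) {
    don <- parent[k]
    cand <- acceptors[dm[k, ] <= params$dist_cutoff & dm[k, ] > 0.1]
    for (acc in cand) {
      if (acc == don) next
      if (keys[acc] == keys[don]) next
      if (within_bonds(adj, don, acc, depth = 2)) next
      ante_idx <- adj[[acc]]
      ante_idx <- ante_idx[atom$elesy[ante_idx] != "H"]
      ante <- if (length(ante_idx) > 0) xyz[ante_idx[1], ] else NULL
      if (vnorm(xyz[acc, ] - xyz[hs[k], ]) > params$ha_cutoff) next
      dha <- angle3(xyz[don, ], xyz[hs[k], ], xyz[acc, ])
      if (dha < params$dha_min) next
      e <- hbond_energy(xyz[don, ], xyz[hs[k], ], xyz[acc, ], ante, params)
      if (e > params$e_cutoff) next
      out[[length(out) + 1]] <- interaction_row("hbond", atom, don, acc,
                                                vnorm(xyz[acc, ] - xyz[don, ]), e)
    }
  }
  if (length(out) == 0) return(empty_interactions())
  res <- do.call(rbind, out)
  # one row per donor-acceptor atom pair: keep the strongest; identifier
  # tie-breaks make the order reproducible across energy-degenerate bonds
  id <- paste(res$chain_a, res$resno_a, res$atom_a, res$chain_b, res$resno_b,
              res$atom_b)
  ord <- order(res$energy, id)
  res <- res[ord, , drop = FALSE]
  res <- res[!duplicated(id[ord]), , drop = FALSE]
  rownames(res) <- NULL
  res
}

salt_bridge_atoms <- list(
  basic = list(ARG = c("NH1", "NH2", "NE"), LYS = "NZ", HIS = c("ND1", "NE2")),
  acidic = list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
)

#' Detect salt bridges
#'
#' Charged-group nitrogen/oxygen pairs (Arg/Lys/His versus Asp/Glu side
#' chains, plus free termini) within `cutoff`. Each residue pair is reported
#' once, at its minimum-distance atom pair, with the fixed energy `energy` so
#' salt bridges rank as strong constraints in the dilution.
#'
#' @param s a `structure3d`
#' @param cutoff N-O distance cutoff in Angstrom
#' @param energy fixed energy assigned to a salt bridge, kcal/mol
#' @return interaction data.frame
#' @export
detect_salt_bridges <- function(s, cutoff = 4.0, energy = -10) {
  atom <- s$atom
  prot <- !atom$het
  keys <- residue_keys(atom)
  rt <- residue_table(s)
  sel <- function(groups) {
    idx <- integer(0)
    for (rn in names(groups))
      idx <- c(idx, which(prot & atom$resid == rn & atom$elety %in% groups[[rn]]))
    idx
  }
  basic <- sel(salt_bridge_atoms$basic)
  acidic <- sel(salt_bridge_atoms$acidic)
  # termini: N of each chain's first residue (basic), OXT (acidic)
  for (ch in chain_ids(s)) {
    r1 <- rt[rt$chain == ch, , drop = FALSE]
    if (nrow(r1) == 0) next
    basic <- c(basic, which(keys == r1$key[1] & atom$elety == "N" & prot))
  }
  acidic <- c(acidic, which(prot & atom$elety == "OXT"))
  basic <- unique(basic); acidic <- unique(acidic)
  if (length(basic) == 0 || length(acidic) == 0) return(empty_interactions())
  xyz <- as.matrix(atom[, c("x", "y", "z")])
  dm <- cross_dist(xyz[basic, , drop = FALSE], xyz[acidic, , drop = FALSE])
  out <- list()
  hits <- which(dm <= cutoff, arr.ind = TRUE)
  if (nrow(hits) == 0) return(empty_interactions())
  pairkey <- paste(keys[basic[hits[, 1]]], keys[acidic[hits[, 2]]])
  for (pk in unique(pairkey)) {
    rows <- which(pairkey == pk)
    best <- rows[which.min(dm[hits[rows, , drop = FALSE]])]
    i <- basic[hits[best, 1]]; j <- acidic[hits[best, 2]]
    if (keys[i] == keys[j]) next
    out[[length(out) + 1]] <- interaction_row("salt_bridge", atom, i, j,
                                              dm[hits[best, 1], hits[best, 2]], energy)
  }
  if (length(out) == 0) return(empty_interactions())
  res <- do.call(rbind, out)
  res <- res[order(res$distance), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Detect hydrophobic contacts
#'
#' Carbon/sulfur atom pairs from different, non-adjacent residues within the
#' sum of their van der Waals radii (C 1.7 A, S 1.8 A) plus `pad`. At most one
#' tether per residue pair (the closest atom pair).
#'
#' @param s a `structure3d`
#' @param pad distance padding in Angstrom
#' @return interaction data.frame (no energies; hydrophobic tethers are not
#'   diluted)
#' @export
detect_hydrophobic <- function(s, pad = 0.25) {
  atom <- s$atom
  prot <- !atom$het
  idx <- which(prot & atom$elesy %in% c("C", "S"))
  if (length(idx) < 2) return(empty_interactions())
  xyz <- as.matrix(atom[idx, c("x", "y", "z")])
  rvdw <- ifelse(atom$elesy[idx] == "S", 1.8, 1.7)
  keys <- residue_keys(atom)
  rt <- residue_table(s)
  resix <- match(keys[idx], rt$key)
  dm <- cross_dist(xyz, xyz)
  cut <- outer(rvdw, rvdw, "+") + pad
  hit <- which(dm <= cut & upper.tri(dm), arr.ind = TRUE)
  if (nrow(hit) == 0) return(empty_interactions())
  same_res <- resix[hit[, 1]] == resix[hit[, 2]]
  adjacent <- abs(rt$resno[resix[hit[, 1]]] - rt$resno[resix[hit[, 2]]]) == 1 &
    rt$chain[resix[hit[, 1]]] == rt$chain[resix[hit[, 2]]]
  hit <- hit[!same_res & !adjacent, , drop = FALSE]
  if (nrow(hit) == 0) return(empty_interactions())
  pairkey <- paste(pmin(resix[hit[, 1]], resix[hit[, 2]]),
                   pmax(resix[hit[, 1]], resix[hit[, 2]]))
  out <- list()
  for (pk in unique(pairkey)) {
    rows <- which(pairkey == pk)
    d <- dm[hit[rows, , drop = FALSE]]
    best <- rows[which.min(d)]
    out[[length(out) + 1]] <- interaction_row("hydrophobic", atom,
                                              idx[hit[best, 1]], idx[hit[best, 2]],
                                              min(d), NA_real_)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$distance), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Detect all non-covalent interactions
#'
#' Convenience wrapper running [detect_hbonds()], [detect_salt_bridges()] and
#' [detect_hydrophobic()] with their defaults.
#'
#' @param s a `structure3d`
#' @param hbond_params an [hbond_params()] object
#' @param salt_cutoff salt-bridge N-O cutoff, Angstrom
#' @param salt_energy fixed salt-bridge energy, kcal/mol
#' @param hydrophobic_pad hydrophobic padding, Angstrom
#' @return combined interaction data.frame
#' @export
detect_interactions <- function(s, hbond_params = rignet::hbond_params(),
                                salt_cutoff = 4.0, salt_energy = -10,
                                hydrophobic_pad = 0.25) {
  rbind(detect_hbonds(s, hbond_params),
        detect_salt_bridges(s, salt_cutoff, salt_energy),
        detect_hydrophobic(s, hydrophobic_pad))
}

#' Summaries of interaction counts and strengths
#'
#' Counts per interaction kind (total and interchain), over all interactions
#' and over the strongest `strength_percentile` fraction by energy (applies
#' to energy-bearing kinds only). When given a list of per-model interaction
#' tables (an ensemble), also reports per-model counts and the occupancy of
#' each unique interaction (fraction of models containing it), enabling a
#' "least frequent" filter via `max_occupancy`.
#'
#' @param interactions an interaction data.frame, or a list of them (one per
#'   ensemble model)
#' @param strength_percentile fraction in (0, 1\]
#' @param max_occupancy if not NULL, restrict the occupancy table to
#'   interactions with occupancy <= this threshold
#' @return a list with `counts` (data.frame kind/n/n_interchain/n_strongest)
#'   and, for ensembles, `per_model` and `occupancy`
#' @export
interaction_summary <- function(interactions, strength_percentile = 1,
                                max_occupancy = NULL) {
  stopifnot(strength_percentile > 0, strength_percentile <= 1)
  if (is.data.frame(interactions)) {
    return(list(counts = count_table(interactions, strength_percentile)))
  }
  stopifnot(is.list(interactions), length(interactions) >= 1)
  counts <- count_table(do.call(rbind, interactions), strength_percentile)
  per_model <- do.call(rbind, lapply(seq_along(interactions), function(m) {
    ct <- count_table(interactions[[m]], strength_percentile)
    ct$model <- m
    ct
  }))
  ids <- lapply(interactions, function(x)
    unique(paste(x$kind, x$chain_a, x$resno_a, x$atom_a,
                 x$chain_b, x$resno_b, x$atom_b)))
  tab <- table(unlist(ids))
  occ <- data.frame(id = names(tab),
                    occupancy = as.numeric(tab) / length(interactions),
                    stringsAsFactors = FALSE)
  if (!is.null(max_occupancy)) occ <- occ[occ$occupancy <= max_occupancy, , drop = FALSE]
  occ <- occ[order(occ$occupancy), , drop = FALSE]
  rownames(occ) <- NULL
  list(counts = counts, per_model = per_model, occupancy = occ)
}

count_table <- function(x, p) {
  kinds <- c("hbond", "salt_bridge", "hydrophobic")
  out <- data.frame(kind = kinds, n = 0L, n_interchain = 0L, n_strongest = 0L,
                    stringsAsFactors = FALSE)
  if (is.null(x) || nrow(x) == 0) return(out)
  for (k in seq_along(kinds)) {
    sub <- x[x$kind == kinds[k], , drop = FALSE]
    out$n[k] <- nrow(sub)
    out$n_interchain[k] <- sum(sub$interchain)
    if (kinds[k] == "hydrophobic") {
      out$n_strongest[k] <- nrow(sub)
    } else if (nrow(sub) > 0) {
      ns <- floor(p * nrow(sub) + 1e-9)
      out$n_strongest[k] <- ns
    }
  }
  out
}
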