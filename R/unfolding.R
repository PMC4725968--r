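#' Linear map from energy cutoff to temperature
#'
#' Thermal unfolding is simulated by removing hydrogen-bond-class constraints
#' in order of increasing strength; the cutoff `E_cut` is converted to a
#' temperature with the empirical linear relation T = slope * E_cut +
#' intercept. The defaults are config-exposed placeholders: rank orders and
#' correlation statistics are invariant to any fixed linear map with negative
#' slope.
#'
#' @param slope K * mol / kcal, must be negative (stronger cutoff, higher T)
#' @param intercept temperature at E_cut = 0, in K
#' @return object of class `temperature_map`
#' @export
temperature_map <- function(slope = -20, intercept = 300) {
  stopifnot(slope < 0)
  m <- list(slope = slope, intercept = intercept)
  class(m) <- "temperature_map"
  m
}

#' Temperature corresponding to an energy cutoff
#' @param e_cut energy cutoff, kcal/mol
#' @param map a [temperature_map()]
#' @return temperature in K
#' @export
temperature_of <- function(e_cut, map = temperature_map()) {
  map$slope * e_cut + map$intercept
}

#' Thermal unfolding of a constraint network by dilution
#'
#' Generates a sequence of dilution states with strictly decreasing energy
#' cutoff. In the `per_bond` grid one state is placed just below each
#' distinct dilutable energy (offset `eps`), so bonds sharing an energy leave
#' in one step and separation energies are exact; `fixed_step` walks a
#' regular grid instead. Each state contains only the dilutable constraints
#' (hydrogen bonds, salt bridges) with energy <= E_cut, plus all covalent and
#' hydrophobic constraints, and is decomposed from scratch with
#' [pebble_game()].
#'
#' @param net a [constraint_network()] containing at least one dilutable bar
#' @param tmap a [temperature_map()]
#' @param grid `"per_bond"` or `"fixed_step"`
#' @param step step size in kcal/mol for the fixed grid
#' @param eps offset below each distinct energy for the per-bond grid (must
#'   exceed the 1e-6 energy rounding)
#' @return object of class `unfolding_trajectory`: `states` data.frame
#'   (`state`, `e_cut`, `t`, `p_inf`, `n_clusters`, `dof`), a body-level
#'   cluster matrix, and a residue-level cluster matrix plus residue table
#'   when the network carries body annotations
#' @export
dilute_network <- function(net, tmap = temperature_map(),
                           grid = c("per_bond", "fixed_step"),
                           step = 0.1, eps = 1e-5) {
  grid <- match.arg(grid)
  bars <- net$bars
  dil <- bars$source %in% c("hbond", "salt_bridge")
  if (!any(dil))
    stop("trajectory undefined: no dilutable constraints (hbond/salt_bridge)")
  energies <- bars$energy[dil]
  if (any(is.na(energies))) stop("dilutable bars with missing energy")
  if (grid == "per_bond") {
    # tolerance-based uniqueness: energies agreeing to 1e-6 kcal/mol share a
    # dilution step
    ecuts <- c(0, sort(unique(round(energies, 6)), decreasing = TRUE) - eps)
  } else {
    ecuts <- seq(0, min(energies) - step, by = -step)
  }
  ecuts <- ecuts[!duplicated(ecuts)]

  has_res <- !is.null(net$bodies)
  states <- NULL
  body_cl <- matrix(0L, nrow = net$n_bodies, ncol = length(ecuts))
  res_cl <- NULL
  residues <- NULL
  for (k in seq_along(ecuts)) {
    keep <- !dil | (bars$energy <= ecuts[k])
    sub <- constraint_network(net$n_bodies, bars[keep, , drop = FALSE], net$bodies)
    dec <- pebble_game(sub)
    body_cl[, k] <- dec$cluster
    if (has_res) {
      rcm <- residue_cluster_membership(dec, net)
      if (is.null(res_cl)) {
        residues <- rcm[, c("chain", "resno", "insert")]
        res_cl <- matrix(0L, nrow = nrow(rcm), ncol = length(ecuts))
      }
      res_cl[, k] <- rcm$cluster
    }
    states <- rbind(states, data.frame(
      state = k, e_cut = ecuts[k], t = temperature_of(ecuts[k], tmap),
      p_inf = dec$p_inf, n_clusters = length(dec$sizes), dof = dec$dof))
  }
  out <- list(states = states, body_clusters = body_cl,
              residue_clusters = res_cl, residues = residues, tmap = tmap,
              grid = grid, n_bodies = net$n_bodies)
  class(out) <- "unfolding_trajectory"
  out
}

#' Thermal unfolding of a structure
#'
#' Convenience wrapper: detects interactions if not supplied, builds the full
#' constraint network, and runs [dilute_network()].
#'
#' @param s a `structure3d`
#' @param interactions interaction table; computed with
#'   [detect_interactions()] when NULL
#' @param tmap,grid,step,eps passed to [dilute_network()]
#' @return an `unfolding_trajectory`
#' @export
dilute <- function(s, interactions = NULL, tmap = temperature_map(),
                   grid = c("per_bond", "fixed_step"), step = 0.1, eps = 1e-5) {
  if (is.null(interactions)) interactions <- detect_interactions(s)
  net <- build_network(s, interactions, e_cut = 0)
  dilute_network(net, tmap = tmap, grid = match.arg(grid), step = step, eps = eps)
}

#' @export
print.unfolding_trajectory <- function(x, ...) {
  cat("unfolding_trajectory:", nrow(x$states), "states, P_inf",
      signif(x$states$p_inf[1], 3), "->",
      signif(x$states$p_inf[nrow(x$states)], 3), "\n")
  invisible(x)
}

#' Phase-transition temperature of an unfolding trajectory
#'
#' `max_drop` (default): T_p is the temperature of the state with the largest
#' single-step decrease in the order parameter P_inf (ties resolved to the
#' lowest temperature). `sigmoid_fit`: least-squares two-state logistic fit
#' of P_inf(T); T_p is the midpoint. A trajectory with fewer than 3 states or
#' an overall P_inf decrease below `min_drop` is flagged as having no
#' transition (`tp` is NA).
#'
#' @param traj an `unfolding_trajectory`
#' @param method `"max_drop"` or `"sigmoid_fit"`
#' @param min_drop minimum overall P_inf decrease for a transition
#' @return list of class `tp_estimate` with `tp` (K), `transition` (logical),
#'   `method`, `state` (index of the transition state, max_drop only)
#' @export
phase_transition <- function(traj, method = c("max_drop", "sigmoid_fit"),
                             min_drop = 0.2) {
  method <- match.arg(method)
  st <- traj$states
  p <- st$p_inf
  if (nrow(st) < 3 || (p[1] - p[length(p)]) < min_drop) {
    out <- list(tp = NA_real_, transition = FALSE, method = method, state = NA_integer_)
    class(out) <- "tp_estimate"
    return(out)
  }
  drops <- p[-length(p)] - p[-1]
  imax <- which.max(drops)  # first maximum = lowest T on ties
  tp <- st$t[imax + 1]
  state <- imax + 1L
  if (method == "sigmoid_fit") {
    dat <- data.frame(t = st$t, p = p)
    phi <- max(p); plo <- min(p)
    fit <- tryCatch(
      stats::nls(p ~ plo_ + (phi_ - plo_) / (1 + exp((t - tp_) / w_)),
                 data = dat,
                 start = list(plo_ = plo, phi_ = phi, tp_ = tp,
                              w_ = max(diff(range(st$t)) / 20, 1e-3)),
                 algorithm = "port",
                 lower = c(0, 0, min(st$t), 1e-4),
                 upper = c(1, 1, max(st$t), diff(range(st$t)) + 1)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      tp <- unname(stats::coef(fit)["tp_"])
      state <- NA_integer_
    } else {
      warning("sigmoid fit failed; falling back to max_drop estimate")
    }
  }
  out <- list(tp = tp, transition = TRUE, method = method, state = state)
  class(out) <- "tp_estimate"
  out
}

#' @export
print.tp_estimate <- function(x, ...) {
  if (!x$transition) cat("tp_estimate: no transition detected\n")
  else cat("tp_estimate: T_p =", signif(x$tp, 6), "K (", x$method, ")\n")
  invisible(x)
}

#' Rigid-contact stability map
#'
#' For every unit pair (residues by default, bodies for abstract networks)
#' sharing a rigid cluster in the initial state, records the rigid-contact
#' energy E_rc: the E_cut of the first dilution state at which the pair no
#' longer shares a cluster. Pairs co-rigid through the final state get the
#' final E_cut and `persistent = TRUE`. More negative E_rc means a later
#' separation, i.e. a stronger rigid contact.
#'
#' @param traj an `unfolding_trajectory`
#' @param level `"residue"` (requires a structure-derived network) or `"body"`
#' @return data.frame of class `stability_map` with unit identifiers, `e_rc`
#'   and `persistent`; symmetric pairs stored once with unit A before unit B
#' @export
stability_map <- function(traj, level = c("residue", "body")) {
  level <- match.arg(level)
  if (level == "residue") {
    cl <- traj$residue_clusters
    if (is.null(cl)) stop("trajectory has no residue-level clusters; use level = 'body'")
    units <- traj$residues
  } else {
    cl <- traj$body_clusters
    units <- data.frame(body = seq_len(nrow(cl)))
  }
  n <- nrow(cl)
  S <- ncol(cl)
  ecuts <- traj$states$e_cut
  rows <- list()
  for (i in seq_len(n - 1)) {
    same0 <- cl[i, 1] == cl[(i + 1):n, 1]
    for (joff in which(same0)) {
      j <- i + joff
      diffcol <- which(cl[i, ] != cl[j, ])
      if (length(diffcol) == 0) {
        e_rc <- ecuts[S]; pers <- TRUE
      } else {
        e_rc <- ecuts[min(diffcol)]; pers <- FALSE
      }
      rows[[length(rows) + 1]] <- c(i, j, e_rc, pers)
    }
  }
  if (length(rows) == 0) {
    m <- data.frame(i = integer(), j = integer(), e_rc = numeric(),
                    persistent = logical())
  } else {
    m <- as.data.frame(do.call(rbind, rows))
    names(m) <- c("i", "j", "e_rc", "persistent")
    m$persistent <- as.logical(m$persistent)
  }
  if (level == "residue") {
    out <- data.frame(chain_a = units$chain[m$i], resno_a = units$resno[m$i],
                      chain_b = units$chain[m$j], resno_b = units$resno[m$j],
                      e_rc = m$e_rc, persistent = m$persistent,
                      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(body_a = m$i, body_b = m$j, e_rc = m$e_rc,
                      persistent = m$persistent)
  }
  class(out) <- c("stability_map", "data.frame")
  attr(out, "level") <- level
  out
}
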