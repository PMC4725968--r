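# The (6,6) body-bar pebble game.
#
# Every body holds 6 pebbles. A bar between u and v is independent iff 7
# pebbles can be gathered on {u, v}; accepting it pins one pebble of u on the
# directed edge u -> v. Pebbles are recovered by reversing directed paths.
# After all bars are played: DOF = pebbles left free = 6 n - #independent
# bars, and the rigid cluster of a seed body u is found by gathering u's 6
# pebbles home and taking all bodies that cannot reach any other free pebble
# (body-body rigid connectivity is transitive for full 6-DOF bodies, so the
# clusters partition the body set).

# internal game state: env with out (list of integer vectors: multiset of
# directed edge heads), peb (integer vector)
pg_new <- function(n) {
  e <- new.env(parent = emptyenv())
  e$n <- n
  e$out <- vector("list", n)
  e$peb <- rep(6L, n)
  e
}

# depth-first search from `from` for a body with a free pebble, excluding
# bodies in `excl`; if found, reverse the path and move one pebble to `from`.
# Returns TRUE on success.
pg_pull_pebble <- function(e, from, excl) {
  n <- e$n
  seen <- rep(FALSE, n)
  seen[excl] <- TRUE
  seen[from] <- TRUE
  parent <- rep(0L, n)
  stack <- from
  found <- 0L
  while (length(stack) > 0) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    for (w in unique(e$out[[v]])) {
      if (!seen[w]) {
        seen[w] <- TRUE
        parent[w] <- v
        if (e$peb[w] > 0L) { found <- w; stack <- integer(0); break }
        stack <- c(stack, w)
      }
    }
    if (found > 0L) break
  }
  if (found == 0L) return(FALSE)
  # reverse path found -> ... -> from: each step v -> w becomes w -> v
  w <- found
  while (w != from) {
    v <- parent[w]
    # remove one v -> w edge, add w -> v
    k <- match(w, e$out[[v]])
    e$out[[v]] <- e$out[[v]][-k]
    e$out[[w]] <- c(e$out[[w]], v)
    w <- v
  }
  e$peb[found] <- e$peb[found] - 1L
  e$peb[from] <- e$peb[from] + 1L
  TRUE
}

# try to gather `target` pebbles in total on {u, v}; returns TRUE if reached
pg_gather_pair <- function(e, u, v, target) {
  repeat {
    if (e$peb[u] + e$peb[v] >= target) return(TRUE)
    if (e$peb[u] < 6L && pg_pull_pebble(e, u, c(u, v))) next
    if (e$peb[v] < 6L && pg_pull_pebble(e, v, c(u, v))) next
    return(FALSE)
  }
}

# insert one bar; returns TRUE if independent (accepted)
pg_insert_bar <- function(e, u, v) {
  if (!pg_gather_pair(e, u, v, 7L)) return(FALSE)
  # consume one pebble from u (ensure u has one; it does since sum >= 7)
  if (e$peb[u] == 0L) { tmp <- u; u <- v; v <- tmp }
  e$peb[u] <- e$peb[u] - 1L
  e$out[[u]] <- c(e$out[[u]], v)
  TRUE
}

pg_play <- function(net) {
  e <- pg_new(net$n_bodies)
  indep <- 0L
  bars <- net$bars
  if (!is.null(bars) && nrow(bars) > 0) {
    for (k in seq_len(nrow(bars))) {
      for (m in seq_len(bars$mult[k])) {
        if (pg_insert_bar(e, bars$a[k], bars$b[k])) indep <- indep + 1L
      }
    }
  }
  e$indep <- indep
  e
}

# rigid cluster of seed u: gather 6 pebbles home on u, then take the
# complement of the set of bodies that can reach a free pebble not on u
pg_cluster_of <- function(e, u) {
  while (e$peb[u] < 6L) {
    if (!pg_pull_pebble(e, u, u)) stop("internal error: cannot gather 6 pebbles")
  }
  n <- e$n
  canreach <- e$peb > 0L
  canreach[u] <- FALSE
  # reverse reachability: w can acquire a pebble if a directed path w ~> seed
  # exists; propagate backwards along edges (tail inherits from head)
  repeat {
    changed <- FALSE
    for (v in seq_len(n)) {
      if (!canreach[v] && length(e$out[[v]]) > 0 && any(canreach[e$out[[v]]])) {
        canreach[v] <- TRUE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  which(!canreach)
}

#' Rigid cluster decomposition by the (6,6) pebble game
#'
#' Plays all bars of the network through the pebble game, then extracts the
#' rigid cluster partition and the number of internal degrees of freedom
#' (DOF = 6 n_bodies - number of independent bars; >= 6 for any non-empty
#' network because of the trivial rigid-body motions). Results are
#' independent of bar insertion order.
#'
#' @param net a [constraint_network()]
#' @return object of class `rigid_decomposition`: list with `cluster`
#'   (integer body -> cluster id, clusters numbered by decreasing size, ties
#'   by smallest contained body index), `sizes`, `dof`, `n_independent`,
#'   `p_inf` (fraction of bodies in the largest cluster) and `n_bodies`
#' @export
pebble_game <- function(net) {
  stopifnot(inherits(net, "constraint_network"))
  e <- pg_play(net)
  n <- net$n_bodies
  cluster_raw <- rep(0L, n)
  cid <- 0L
  for (u in seq_len(n)) {
    if (cluster_raw[u] != 0L) next
    cid <- cid + 1L
    members <- pg_cluster_of(e, u)
    members <- members[cluster_raw[members] == 0L]
    cluster_raw[members] <- cid
  }
  finalize_decomposition(cluster_raw, dof = sum(e$peb), n_independent = e$indep,
                         n_bodies = n)
}

finalize_decomposition <- function(cluster_raw, dof, n_independent, n_bodies) {
  sizes <- tabulate(cluster_raw)
  firsts <- vapply(seq_along(sizes), function(k) min(which(cluster_raw == k)),
                   integer(1))
  ord <- order(-sizes, firsts)
  relabel <- match(seq_along(sizes), ord)
  cluster <- relabel[cluster_raw]
  sizes <- sizes[ord]
  out <- list(cluster = cluster, sizes = sizes, dof = dof,
              n_independent = n_independent, n_bodies = n_bodies,
              p_inf = max(sizes) / n_bodies)
  class(out) <- "rigid_decomposition"
  out
}

#' @export
print.rigid_decomposition <- function(x, ...) {
  cat("rigid_decomposition:", x$n_bodies, "bodies,", length(x$sizes),
      "clusters, DOF =", x$dof, ", P_inf =", signif(x$p_inf, 4), "\n")
  invisible(x)
}

#' Residue-level rigid cluster membership
#'
#' Assigns every residue the cluster of its CA body (residues lacking a CA
#' body fall back to the majority cluster of their bodies, with a warning).
#' Two residues lie "in one rigid region" iff they share a cluster id.
#'
#' @param decomp a `rigid_decomposition` from [pebble_game()]
#' @param net the `constraint_network` it was computed from (must carry a
#'   `bodies` table)
#' @return data.frame with `chain`, `resno`, `insert`, `cluster`
#' @export
residue_cluster_membership <- function(decomp, net) {
  b <- net$bodies
  if (is.null(b)) stop("network has no body -> residue map")
  key <- paste(b$chain, b$resno, b$insert, sep = "|")
  ukey <- unique(key)
  cl <- integer(length(ukey))
  warned <- FALSE
  for (k in seq_along(ukey)) {
    rows <- which(key == ukey[k])
    ca <- rows[b$is_ca[rows]]
    if (length(ca) >= 1) {
      cl[k] <- decomp$cluster[ca[1]]
    } else {
      tab <- table(decomp$cluster[rows])
      cl[k] <- as.integer(names(tab)[which.max(tab)])
      warned <- TRUE
    }
  }
  if (warned) warning("residue(s) lacking a CA body assigned by majority vote")
  first <- match(ukey, key)
  data.frame(chain = b$chain[first], resno = b$resno[first],
             insert = b$insert[first], cluster = cl, stringsAsFactors = FALSE)
}
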