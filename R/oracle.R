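# Brute-force validation oracle for the pebble game, computed directly from
# the (6,6) count matroid: a bar multiset is independent iff every sub-multiset
# spanning n' >= 2 bodies has at most 6 n' - 6 bars. Exponential in the number
# of bodies, so restricted to tiny networks.

popcount <- function(masks) {
  out <- integer(length(masks))
  m <- masks
  while (any(m > 0)) {
    out <- out + (m %% 2L)
    m <- m %/% 2L
  }
  out
}

#' Brute-force rigid decomposition (count-matroid oracle)
#'
#' Computes the number of independent bars by greedy growth with full subset
#' verification over all body subsets, the DOF, and the rigid cluster
#' partition by pairwise trial-bar redundancy. Must agree exactly with
#' [pebble_game()]; used to validate it on small random multigraphs.
#'
#' @param net a [constraint_network()] with at most `max_bodies` bodies
#' @param max_bodies refusal threshold (enumeration is exponential)
#' @return a `rigid_decomposition`, same structure as [pebble_game()]
#' @export
brute_force_decomposition <- function(net, max_bodies = 8) {
  stopifnot(inherits(net, "constraint_network"))
  n <- net$n_bodies
  if (n > max_bodies)
    stop("brute-force oracle refused: ", n, " bodies > ", max_bodies)
  masks <- seq_len(2^n) - 1L
  pop <- popcount(masks)
  limit <- ifelse(pop >= 2, 6L * pop - 6L, NA_integer_)
  cnt <- integer(length(masks))

  contains_pair <- function(a, b) {
    bit <- bitwOr(bitwShiftL(1L, a - 1L), bitwShiftL(1L, b - 1L))
    bitwAnd(masks, bit) == bit
  }
  is_dependent <- function(a, b) {
    sel <- contains_pair(a, b) & !is.na(limit)
    any(cnt[sel] >= limit[sel])
  }

  n_indep <- 0L
  bars <- net$bars
  if (!is.null(bars) && nrow(bars) > 0) {
    for (k in seq_len(nrow(bars))) {
      for (m in seq_len(bars$mult[k])) {
        a <- bars$a[k]; b <- bars$b[k]
        if (!is_dependent(a, b)) {
          cnt[contains_pair(a, b)] <- cnt[contains_pair(a, b)] + 1L
          n_indep <- n_indep + 1L
        }
      }
    }
  }

  # pairwise rigidity: trial bar (u, v) redundant <=> same rigid cluster;
  # transitive for 6-DOF bodies, so a union-find suffices
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  if (n >= 2) {
    for (u in seq_len(n - 1)) for (v in (u + 1):n) {
      if (is_dependent(u, v)) {
        ru <- find(u); rv <- find(v)
        if (ru != rv) parent[max(ru, rv)] <- min(ru, rv)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  cluster_raw <- match(roots, unique(roots))
  finalize_decomposition(cluster_raw, dof = 6L * n - n_indep,
                         n_independent = n_indep, n_bodies = n)
}
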