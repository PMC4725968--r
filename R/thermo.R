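#' Interchain residue pairs at a dimer interface
#'
#' Residue pairs (one per chain pair) whose closest heavy-atom distance is at
#' most `cutoff`.
#'
#' @param s a `structure3d` with >= 2 chains
#' @param cutoff heavy-atom distance cutoff in Angstrom
#' @return data.frame with `chain_a`, `resno_a`, `chain_b`, `resno_b`,
#'   `min_dist`
#' @export
interface_pairs <- function(s, cutoff = 5.0) {
  chains <- chain_ids(s)
  if (length(chains) < 2) stop("interface requires >= 2 chains")
  atom <- s$atom[!s$atom$het & s$atom$elesy != "H", , drop = FALSE]
  out <- NULL
  for (i in seq_along(chains)[-length(chains)]) for (j in (i + 1):length(chains)) {
    a <- atom[atom$chain == chains[i], , drop = FALSE]
    b <- atom[atom$chain == chains[j], , drop = FALSE]
    if (nrow(a) == 0 || nrow(b) == 0) next
    dm <- cross_dist(as.matrix(a[, c("x", "y", "z")]), as.matrix(b[, c("x", "y", "z")]))
    keya <- paste(a$chain, a$resno); keyb <- paste(b$chain, b$resno)
    hits <- which(dm <= cutoff, arr.ind = TRUE)
    if (nrow(hits) == 0) next
    pk <- paste(keya[hits[, 1]], keyb[hits[, 2]], sep = "||")
    for (p in unique(pk)) {
      rows <- which(pk == p)
      best <- rows[which.min(dm[hits[rows, , drop = FALSE]])]
      out <- rbind(out, data.frame(
        chain_a = a$chain[hits[best, 1]], resno_a = a$resno[hits[best, 1]],
        chain_b = b$chain[hits[best, 2]], resno_b = b$resno[hits[best, 2]],
        min_dist = dm[hits[best, 1], hits[best, 2]], stringsAsFactors = FALSE))
    }
  }
  if (is.null(out))
    out <- data.frame(chain_a = character(), resno_a = integer(),
                      chain_b = character(), resno_b = integer(),
                      min_dist = numeric(), stringsAsFactors = FALSE)
  out <- out[order(out$chain_a, out$resno_a, out$resno_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# E_rc lookup for unordered residue pairs; absent pairs give NA
map_lookup <- function(map, chain_a, resno_a, chain_b, resno_b) {
  k1 <- paste(map$chain_a, map$resno_a, map$chain_b, map$resno_b)
  k2 <- paste(map$chain_b, map$resno_b, map$chain_a, map$resno_a)
  q <- paste(chain_a, resno_a, chain_b, resno_b)
  i <- match(q, k1)
  j <- match(q, k2)
  ifelse(!is.na(i), map$e_rc[i], map$e_rc[j])
}

#' Interface rigidity energy
#'
#' Sum of rigid-contact energies E_rc over the given interchain residue
#' pairs; pairs absent from the stability map contribute 0. The more negative
#' the value, the more structurally stable the interface region.
#'
#' @param map a [stability_map()] at residue level
#' @param pairs data.frame from [interface_pairs()] (same structure)
#' @return energy in kcal/mol (<= 0)
#' @export
interface_rigidity_energy <- function(map, pairs) {
  if (nrow(pairs) == 0) return(0)
  e <- map_lookup(map, pairs$chain_a, pairs$resno_a, pairs$chain_b, pairs$resno_b)
  sum(e, na.rm = TRUE)
}

#' Per-element rigidity energies
#'
#' For each secondary-structure element, sums E_rc over pairs connecting a
#' residue inside the element to a residue outside it, divided by the number
#' of residues in the element (a per-residue average), with the standard
#' error over the per-residue sums.
#'
#' @param map a residue-level [stability_map()]
#' @param elements data.frame of elements (`label`, `type`, `chain`, `start`,
#'   `end`) as produced by [assign_secondary_structure()]
#' @return data.frame with `label`, `type`, `chain`, `n_res`, `energy_total`,
#'   `energy_per_res`, `se`
#' @export
sse_rigidity_energy <- function(map, elements) {
  out <- NULL
  for (k in seq_len(nrow(elements))) {
    el <- elements[k, ]
    resnos <- seq(el$start, el$end)
    n_res <- length(resnos)
    if (n_res == 0) { warning("empty element ", el$label, " skipped"); next }
    inside_a <- map$chain_a == el$chain & map$resno_a %in% resnos
    inside_b <- map$chain_b == el$chain & map$resno_b %in% resnos
    cross <- xor(inside_a, inside_b)
    per_res <- vapply(resnos, function(r) {
      hit <- cross & ((map$chain_a == el$chain & map$resno_a == r) |
                        (map$chain_b == el$chain & map$resno_b == r))
      sum(map$e_rc[hit])
    }, numeric(1))
    tot <- sum(per_res)
    se <- if (n_res > 1) stats::sd(per_res) / sqrt(n_res) else 0
    out <- rbind(out, data.frame(label = el$label, type = el$type,
                                 chain = el$chain, n_res = n_res,
                                 energy_total = tot,
                                 energy_per_res = tot / n_res, se = se,
                                 stringsAsFactors = FALSE))
  }
  if (is.null(out))
    out <- data.frame(label = character(), type = character(), chain = character(),
                      n_res = integer(), energy_total = numeric(),
                      energy_per_res = numeric(), se = numeric())
  rownames(out) <- NULL
  out
}

#' Ensemble phase-transition statistics
#'
#' Runs the full dilution pipeline on every member of an ensemble (a
#' multi-model `structure3d`, a list of `constraint_network` objects, or a
#' plain numeric vector of per-model T_p values) and summarizes the T_p
#' distribution: mean, sample SD (n-1), standard error of the mean, skewness.
#' Members without a detectable transition are excluded from the moments and
#' counted.
#'
#' @param x ensemble input (see above)
#' @param tmap a [temperature_map()]
#' @param method passed to [phase_transition()]
#' @param ... passed to [dilute()] / [dilute_network()]
#' @return list of class `ensemble_tp`: `tp` (per-model values, NA where no
#'   transition), `mean`, `sd`, `sem`, `skewness`, `n_models`, `n_excluded`
#' @export
ensemble_tp <- function(x, tmap = temperature_map(), method = "max_drop", ...) {
  if (is.numeric(x)) {
    tp <- x
  } else if (inherits(x, "structure3d")) {
    if (n_models(x) < 2) stop("ensemble requires >= 2 models")
    tp <- vapply(seq_len(n_models(x)), function(k) {
      sk <- use_model(x, k)
      traj <- dilute(sk, tmap = tmap, ...)
      phase_transition(traj, method = method)$tp
    }, numeric(1))
  } else if (is.list(x) && all(vapply(x, inherits, logical(1), "constraint_network"))) {
    if (length(x) < 2) stop("ensemble requires >= 2 members")
    tp <- vapply(x, function(net) {
      traj <- dilute_network(net, tmap = tmap, ...)
      phase_transition(traj, method = method)$tp
    }, numeric(1))
  } else stop("unsupported ensemble input")
  ok <- tp[!is.na(tp)]
  if (length(ok) == 0) stop("no ensemble member shows a transition")
  m <- mean(ok)
  sdv <- if (length(ok) > 1) stats::sd(ok) else 0
  skw <- if (length(ok) > 2 && sdv > 0)
    mean((ok - m)^3) / (sqrt(mean((ok - m)^2)))^3 else 0
  out <- list(tp = tp, mean = m, sd = sdv, sem = sdv / sqrt(length(ok)),
              skewness = skw, n_models = length(tp),
              n_excluded = sum(is.na(tp)))
  class(out) <- "ensemble_tp"
  out
}

#' @export
print.ensemble_tp <- function(x, ...) {
  cat("ensemble_tp:", x$n_models, "models (", x$n_excluded, "excluded ), mean T_p =",
      signif(x$mean, 6), "K, SEM =", signif(x$sem, 4), "K\n")
  invisible(x)
}

#' Correlate phase-transition temperature with host growth temperature
#'
#' Ordinary least squares of the per-ortholog mean T_p on the optimal growth
#' temperature of the source organism. Both variables are put on the Kelvin
#' scale for the fit (T_org tables are usually in Celsius); slope and R^2 are
#' unchanged by the shift, the intercept refers to the Kelvin scale. An
#' inverse-variance weighted fit (1/SEM^2) is available.
#'
#' @param torg numeric vector of growth temperatures, in Celsius by default
#' @param tp numeric vector of mean T_p values in K (same length), or a list
#'   of `ensemble_tp` objects
#' @param sem optional SEMs for weighting
#' @param torg_unit `"C"` or `"K"`
#' @param weighted use 1/SEM^2 weights (requires `sem`)
#' @return list with `slope`, `intercept`, `r_squared`, `p_value`, `n`, `fit`
#' @export
correlate_tp_torg <- function(torg, tp, sem = NULL, torg_unit = c("C", "K"),
                              weighted = FALSE) {
  torg_unit <- match.arg(torg_unit)
  if (is.list(tp) && all(vapply(tp, inherits, logical(1), "ensemble_tp"))) {
    if (is.null(sem)) sem <- vapply(tp, function(x) x$sem, numeric(1))
    tp <- vapply(tp, function(x) x$mean, numeric(1))
  }
  if (length(torg) != length(tp)) stop("torg and tp lengths differ")
  if (length(torg) < 3) stop("need >= 3 orthologs for a correlation")
  x <- if (torg_unit == "C") torg + 273.15 else torg
  if (stats::var(tp) < 1e-12)
    return(list(slope = 0, intercept = mean(tp), r_squared = 0,
                p_value = NA_real_, n = length(x), fit = NULL))
  dat <- data.frame(x = x, y = tp)
  w <- NULL
  if (weighted) {
    if (is.null(sem)) stop("weighted fit requires SEMs")
    w <- 1 / pmax(sem, 1e-9)^2
  }
  fit <- if (is.null(w)) stats::lm(y ~ x, data = dat)
         else stats::lm(y ~ x, data = dat, weights = w)
  sm <- summary(fit)
  slope <- unname(stats::coef(fit)[2])
  pval <- if (nrow(sm$coefficients) >= 2 && ncol(sm$coefficients) >= 4)
    sm$coefficients[2, 4] else NA_real_
  rsq <- sm$r.squared
  if (!is.finite(rsq)) rsq <- 0  # constant response: no variance explained
  list(slope = slope, intercept = unname(stats::coef(fit)[1]),
       r_squared = rsq, p_value = pval, n = length(x), fit = fit)
}
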