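#' Interchain disulfide-design screen
#'
#' Scans all interchain residue pairs (both non-proline) whose Cbeta-Cbeta
#' distance lies within `center +/- halfwidth` (closed interval), the
#' geometry compatible with a native cystine. Glycine has no Cbeta and is
#' skipped unless `virtual_cb = TRUE`, which reconstructs an ideal
#' tetrahedral Cbeta from N, CA, C. On ensembles the first model is screened.
#'
#' @param s a `structure3d` with >= 2 chains
#' @param center window center in Angstrom
#' @param halfwidth window half-width in Angstrom
#' @param virtual_cb reconstruct a virtual Cbeta for glycine
#' @return data.frame of candidates sorted by distance: `chain_a`, `resno_a`,
#'   `resid_a`, `chain_b`, `resno_b`, `resid_b`, `distance`, `symmetric`
#'   (TRUE when the residue numbers match across a homodimer, i.e. one
#'   mutation provides both cysteines)
#' @export
disulfide_screen <- function(s, center = 3.83, halfwidth = 0.18,
                             virtual_cb = FALSE) {
  chains <- chain_ids(s)
  if (length(chains) < 2) stop("disulfide screen requires >= 2 chains")
  if (n_models(s) > 1) s <- use_model(s, 1L)
  atom <- s$atom[!s$atom$het, , drop = FALSE]
  cb <- atom[atom$elety == "CB" & atom$resid != "PRO", , drop = FALSE]
  if (virtual_cb) {
    rt <- residue_table(s)
    gly <- rt[rt$resid == "GLY", , drop = FALSE]
    for (k in seq_len(nrow(gly))) {
      g <- atom[atom$chain == gly$chain[k] & atom$resno == gly$resno[k] &
                  atom$insert == gly$insert[k], , drop = FALSE]
      N <- g[g$elety == "N", c("x", "y", "z")]
      CA <- g[g$elety == "CA", c("x", "y", "z")]
      C <- g[g$elety == "C", c("x", "y", "z")]
      if (nrow(N) * nrow(CA) * nrow(C) == 0) next
      v <- ideal_cb(as.numeric(N[1, ]), as.numeric(CA[1, ]), as.numeric(C[1, ]))
      row <- g[g$elety == "CA", , drop = FALSE][1, ]
      row$elety <- "CB"; row$x <- v[1]; row$y <- v[2]; row$z <- v[3]
      cb <- rbind(cb, row)
    }
  }
  if (nrow(cb) == 0) stop("no Cbeta atoms present")
  out <- NULL
  for (i in seq_along(chains)[-length(chains)]) for (j in (i + 1):length(chains)) {
    a <- cb[cb$chain == chains[i], , drop = FALSE]
    b <- cb[cb$chain == chains[j], , drop = FALSE]
    if (nrow(a) == 0 || nrow(b) == 0) next
    dm <- cross_dist(as.matrix(a[, c("x", "y", "z")]),
                     as.matrix(b[, c("x", "y", "z")]))
    hits <- which(abs(dm - center) <= halfwidth, arr.ind = TRUE)
    for (h in seq_len(nrow(hits))) {
      ia <- hits[h, 1]; ib <- hits[h, 2]
      out <- rbind(out, data.frame(
        chain_a = a$chain[ia], resno_a = a$resno[ia], resid_a = a$resid[ia],
        chain_b = b$chain[ib], resno_b = b$resno[ib], resid_b = b$resid[ib],
        distance = dm[ia, ib],
        symmetric = a$resno[ia] == b$resno[ib] & a$resid[ia] == b$resid[ib],
        stringsAsFactors = FALSE))
    }
  }
  if (is.null(out))
    out <- data.frame(chain_a = character(), resno_a = integer(),
                      resid_a = character(), chain_b = character(),
                      resno_b = integer(), resid_b = character(),
                      distance = numeric(), symmetric = logical(),
                      stringsAsFactors = FALSE)
  out <- out[order(out$distance), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Ranked interface-residue report
#'
#' Ranks the residues participating in interchain pairs by (i) their summed
#' rigid-contact energy across the interface and (ii) their interchain
#' contact counts by interaction kind. Residues engaged in an interchain salt
#' bridge are flagged as repulsion-mutation candidates (a charge reversal
#' there creates electrostatic repulsion); members of interchain hydrophobic
#' contacts are flagged as steric-disruption candidates (a bulky substitution
#' there breaks shape complementarity).
#'
#' @param s a `structure3d`
#' @param map residue-level [stability_map()] of the dimer
#' @param pairs data.frame from [interface_pairs()]
#' @param interactions optional interaction table (computed when NULL)
#' @return data.frame ranked by summed E_rc (most negative first): `chain`,
#'   `resno`, `resid`, `e_rc_sum`, `n_hbond`, `n_salt`, `n_hydrophobic`,
#'   `repulsion_candidate`, `steric_candidate`
#' @export
interface_report <- function(s, map, pairs, interactions = NULL) {
  if (nrow(pairs) == 0)
    return(data.frame(chain = character(), resno = integer(), resid = character(),
                      e_rc_sum = numeric(), n_hbond = integer(), n_salt = integer(),
                      n_hydrophobic = integer(), repulsion_candidate = logical(),
                      steric_candidate = logical(), stringsAsFactors = FALSE))
  if (is.null(interactions)) interactions <- detect_interactions(s)
  e <- map_lookup(map, pairs$chain_a, pairs$resno_a, pairs$chain_b, pairs$resno_b)
  e[is.na(e)] <- 0
  res <- rbind(data.frame(chain = pairs$chain_a, resno = pairs$resno_a, e = e),
               data.frame(chain = pairs$chain_b, resno = pairs$resno_b, e = e))
  agg <- stats::aggregate(e ~ chain + resno, data = res, FUN = sum)

  ic <- interactions[interactions$interchain, , drop = FALSE]
  count_kind <- function(ch, rn, kind) {
    sum(ic$kind == kind & ((ic$chain_a == ch & ic$resno_a == rn) |
                             (ic$chain_b == ch & ic$resno_b == rn)))
  }
  rt <- residue_table(s)
  resid_of <- function(ch, rn) rt$resid[match(paste(ch, rn), paste(rt$chain, rt$resno))]
  out <- data.frame(chain = agg$chain, resno = agg$resno,
                    resid = resid_of(agg$chain, agg$resno),
                    e_rc_sum = agg$e, stringsAsFactors = FALSE)
  out$n_hbond <- mapply(count_kind, out$chain, out$resno, "hbond")
  out$n_salt <- mapply(count_kind, out$chain, out$resno, "salt_bridge")
  out$n_hydrophobic <- mapply(count_kind, out$chain, out$resno, "hydrophobic")
  out$repulsion_candidate <- out$n_salt > 0
  out$steric_candidate <- out$n_hydrophobic > 0
  out <- out[order(out$e_rc_sum, -out$n_hbond - out$n_salt - out$n_hydrophobic), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
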