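#' Place polar backbone hydrogens
#'
#' Crystal structures rarely include hydrogens, but hydrogen-bond detection
#' needs the amide H. For every residue with a preceding peptide bond (and not
#' proline), an H atom is placed on the backbone nitrogen, in the peptide
#' plane, bisecting the C(prev)-N-CA angle on the outside, at 1.01 A.
#' Residues that already have an H/HN/H1 on the nitrogen are left untouched.
#'
#' @param s a `structure3d`
#' @return the structure with amide hydrogens added (single-model working
#'   coordinates; ensemble models are dropped with a warning if present)
#' @export
place_polar_hydrogens <- function(s) {
  if (!is.null(s$models)) {
    warning("placing hydrogens on model 1 only; extra models dropped")
    s <- use_model(s, 1L)
  }
  rt <- residue_table(s)
  atom <- s$atom
  keys <- residue_keys(atom)
  new_rows <- NULL
  for (i in seq_len(nrow(rt))[-1]) {
    if (rt$chain[i] != rt$chain[i - 1]) next
    if (rt$resid[i] == "PRO") next
    idx <- which(keys == rt$key[i])
    has_h <- any(atom$elety[idx] %in% c("H", "HN", "H1") & atom$elesy[idx] == "H")
    if (has_h) next
    iN <- idx[atom$elety[idx] == "N"][1]
    iCA <- idx[atom$elety[idx] == "CA"][1]
    prev <- which(keys == rt$key[i - 1])
    iC <- prev[atom$elety[prev] == "C"][1]
    if (any(is.na(c(iN, iCA, iC)))) next
    N <- c(atom$x[iN], atom$y[iN], atom$z[iN])
    CA <- c(atom$x[iCA], atom$y[iCA], atom$z[iCA])
    C <- c(atom$x[iC], atom$y[iC], atom$z[iC])
    if (vnorm(N - C) > 2.0) next  # not actually bonded (chain break)
    h <- N + 1.01 * unitv(-(unitv(C - N) + unitv(CA - N)))
    new_rows <- rbind(new_rows, data.frame(
      eleno = 0L, elety = "H", elesy = "H", resid = rt$resid[i],
      chain = rt$chain[i], resno = rt$resno[i], insert = rt$insert[i],
      x = h[1], y = h[2], z = h[3], o = 1, b = 0, het = FALSE,
      stringsAsFactors = FALSE))
  }
  if (!is.null(new_rows)) {
    atom <- rbind(atom, new_rows)
    # keep atoms grouped by residue, H right after its residue's heavy atoms
    ord <- order(match(atom$chain, chain_ids(s)), atom$resno, atom$insert,
                 atom$elesy == "H")
    atom <- atom[ord, , drop = FALSE]
    atom$eleno <- seq_len(nrow(atom))
    s$atom <- atom
    s$models <- NULL
  }
  s
}
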