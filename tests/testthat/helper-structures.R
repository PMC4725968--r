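# Helpers to craft tiny structures with explicit coordinates and to reuse
# expensive generator outputs across tests in one file.

atom_row <- function(elety, elesy, resid, chain, resno, x, y, z, b = 0) {
  data.frame(eleno = 0L, elety = elety, elesy = elesy, resid = resid,
             chain = chain, resno = resno, insert = "", x = x, y = y, z = z,
             o = 1, b = b, het = FALSE, stringsAsFactors = FALSE)
}

mini_structure <- function(...) {
  atom <- do.call(rbind, list(...))
  atom$eleno <- seq_len(nrow(atom))
  structure3d(atom)
}

# one free alanine residue at the origin (idealized local geometry)
single_ala <- function(chain = "A", resno = 1, offset = c(0, 0, 0)) {
  rbind(
    atom_row("N",  "N", "ALA", chain, resno, 0 + offset[1], 0 + offset[2], 0 + offset[3]),
    atom_row("CA", "C", "ALA", chain, resno, 1.458 + offset[1], 0 + offset[2], 0 + offset[3]),
    atom_row("C",  "C", "ALA", chain, resno, 2.0 + offset[1], 1.4 + offset[2], 0 + offset[3]),
    atom_row("O",  "O", "ALA", chain, resno, 3.2 + offset[1], 1.6 + offset[2], 0 + offset[3]),
    atom_row("CB", "C", "ALA", chain, resno, 2.0 + offset[1], -0.8 + offset[2], 1.1 + offset[3])
  )
}

# rigid-body rotate + translate a structure3d
transform_structure <- function(s, axis = c(1, 2, 3), angle = 60,
                                shift = c(5, -3, 2)) {
  R <- rignet:::rotation_matrix(axis, angle)
  xyz <- as.matrix(s$atom[, c("x", "y", "z")]) %*% t(R)
  s$atom$x <- xyz[, 1] + shift[1]
  s$atom$y <- xyz[, 2] + shift[2]
  s$atom$z <- xyz[, 3] + shift[3]
  s
}

# shift author residue numbering of every chain by `by`
shift_resno <- function(s, by) {
  s$atom$resno <- s$atom$resno + by
  if (!is.null(s$helix)) {
    s$helix$start <- s$helix$start + by
    s$helix$end <- s$helix$end + by
  }
  s
}

# standard planted dimer used across files: bridges near the chain ends so the
# contact region stays small
bridged_dimer <- function(e1, e2 = e1, n = 12, seed = 1) {
  make_toy_dimer(n, planted_hbonds = data.frame(res_a = c(2, 3),
                                                res_b = c(n - 1, n - 2),
                                                energy = c(e1, e2)),
                 seed = seed)
}
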