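# Covalent topology from amino-acid templates, with a distance fallback for
# non-template residues/atoms. Bond-order chemistry decides which bonds are
# "locked" (peptide, resonance/planar groups, rings) versus rotatable; this
# drives the bar multiplicities of the constraint network.

aa_bond <- function(a, b, locked = FALSE)
  data.frame(a1 = a, a2 = b, locked = locked, stringsAsFactors = FALSE)

ring_bonds <- function(atoms) {
  n <- length(atoms)
  do.call(rbind, lapply(seq_len(n), function(i)
    aa_bond(atoms[i], atoms[i %% n + 1], locked = TRUE)))
}

aa_templates <- local({
  bb <- rbind(aa_bond("N", "CA"), aa_bond("CA", "C"),
              aa_bond("C", "O", locked = TRUE), aa_bond("C", "OXT", locked = TRUE))
  t <- list()
  t$GLY <- bb
  t$ALA <- rbind(bb, aa_bond("CA", "CB"))
  t$CYS <- rbind(t$ALA, aa_bond("CB", "SG"))
  t$SER <- rbind(t$ALA, aa_bond("CB", "OG"))
  t$THR <- rbind(t$ALA, aa_bond("CB", "OG1"), aa_bond("CB", "CG2"))
  t$VAL <- rbind(t$ALA, aa_bond("CB", "CG1"), aa_bond("CB", "CG2"))
  t$LEU <- rbind(t$ALA, aa_bond("CB", "CG"), aa_bond("CG", "CD1"), aa_bond("CG", "CD2"))
  t$ILE <- rbind(t$ALA, aa_bond("CB", "CG1"), aa_bond("CB", "CG2"), aa_bond("CG1", "CD1"))
  t$MET <- rbind(t$ALA, aa_bond("CB", "CG"), aa_bond("CG", "SD"), aa_bond("SD", "CE"))
  t$PRO <- rbind(bb, aa_bond("CA", "CB", locked = TRUE), aa_bond("CB", "CG", locked = TRUE),
                 aa_bond("CG", "CD", locked = TRUE), aa_bond("CD", "N", locked = TRUE))
  t$PHE <- rbind(t$ALA, aa_bond("CB", "CG"),
                 ring_bonds(c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")))
  t$TYR <- rbind(t$PHE, aa_bond("CZ", "OH", locked = TRUE))
  t$TRP <- rbind(t$ALA, aa_bond("CB", "CG"),
                 ring_bonds(c("CG", "CD1", "NE1", "CE2", "CD2")),
                 aa_bond("CE2", "CZ2", locked = TRUE), aa_bond("CZ2", "CH2", locked = TRUE),
                 aa_bond("CH2", "CZ3", locked = TRUE), aa_bond("CZ3", "CE3", locked = TRUE),
                 aa_bond("CE3", "CD2", locked = TRUE))
  t$HIS <- rbind(t$ALA, aa_bond("CB", "CG"),
                 ring_bonds(c("CG", "ND1", "CE1", "NE2", "CD2")))
  t$ASP <- rbind(t$ALA, aa_bond("CB", "CG"),
                 aa_bond("CG", "OD1", locked = TRUE), aa_bond("CG", "OD2", locked = TRUE))
  t$GLU <- rbind(t$ALA, aa_bond("CB", "CG"), aa_bond("CG", "CD"),
                 aa_bond("CD", "OE1", locked = TRUE), aa_bond("CD", "OE2", locked = TRUE))
  t$ASN <- rbind(t$ALA, aa_bond("CB", "CG"),
                 aa_bond("CG", "OD1", locked = TRUE), aa_bond("CG", "ND2", locked = TRUE))
  t$GLN <- rbind(t$ALA, aa_bond("CB", "CG"), aa_bond("CG", "CD"),
                 aa_bond("CD", "OE1", locked = TRUE), aa_bond("CD", "NE2", locked = TRUE))
  t$LYS <- rbind(t$ALA, aa_bond("CB", "CG"), aa_bond("CG", "CD"),
                 aa_bond("CD", "CE"), aa_bond("CE", "NZ"))
  t$ARG <- rbind(t$ALA, aa_bond("CB", "CG"), aa_bond("CG", "CD"), aa_bond("CD", "NE"),
                 aa_bond("NE", "CZ", locked = TRUE), aa_bond("CZ", "NH1", locked = TRUE),
                 aa_bond("CZ", "NH2", locked = TRUE))
  t
})

#' Covalent bond list of a structure
#'
#' Bonds come from amino-acid templates (plus the inter-residue peptide bond,
#' disulfides, and hydrogen attachment); atoms not covered by a template are
#' bonded by a distance fallback (heavy-heavy <= 1.9 A within the same or an
#' adjacent residue, H <= 1.25 A). Peptide bonds and resonance/ring bonds are
#' flagged `locked`.
#'
#' @param s a `structure3d`
#' @return data.frame with atom-table row indices `i`, `j` and logical `locked`
#' @export
covalent_bonds <- function(s) {
  atom <- s$atom
  prot <- !atom$het
  keys <- residue_keys(atom)
  rt <- residue_table(s)
  xyz <- as.matrix(atom[, c("x", "y", "z")])
  bonds_i <- integer(0); bonds_j <- integer(0); locked <- logical(0)
  add <- function(i, j, lk) {
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    bonds_i <<- c(bonds_i, i); bonds_j <<- c(bonds_j, j); locked <<- c(locked, lk)
  }

  for (r in seq_len(nrow(rt))) {
    idx <- which(keys == rt$key[r] & prot)
    if (length(idx) == 0) next
    heavy <- idx[atom$elesy[idx] != "H"]
    tpl <- aa_templates[[rt$resid[r]]]
    covered <- rep(FALSE, length(heavy))
    if (!is.null(tpl)) {
      for (k in seq_len(nrow(tpl))) {
        i <- heavy[atom$elety[heavy] == tpl$a1[k]][1]
        j <- heavy[atom$elety[heavy] == tpl$a2[k]][1]
        if (!is.na(i) && !is.na(j)) {
          add(i, j, tpl$locked[k])
          covered[match(c(i, j), heavy)] <- TRUE
        }
      }
    }
    # fallback for uncovered atoms (unknown residues, stub side chains)
    loose <- heavy[!covered]
    if (length(loose) > 0 && length(heavy) > 1) {
      found_any <- is.null(tpl) | logical(length(loose))
      for (i in loose) {
        d <- sqrt(colSums((t(xyz[heavy, , drop = FALSE]) - xyz[i, ])^2))
        near <- heavy[d > 0.1 & d <= 1.9]
        if (length(near) == 0 && is.null(tpl))
          stop("cannot derive covalent topology for residue ", rt$resid[r], " ",
               rt$chain[r], rt$resno[r], ": no template and no atom within 1.9 A")
        for (j in near) add(i, j, FALSE)
      }
    }
  }

  # peptide bonds C(i) - N(i+1), locked (partial double bond)
  for (r in seq_len(nrow(rt))[-1]) {
    if (rt$chain[r] != rt$chain[r - 1]) next
    iC <- which(keys == rt$key[r - 1] & atom$elety == "C" & prot)[1]
    iN <- which(keys == rt$key[r] & atom$elety == "N" & prot)[1]
    if (is.na(iC) || is.na(iN)) next
    if (vnorm(xyz[iN, ] - xyz[iC, ]) <= 1.9) add(iC, iN, TRUE)
  }

  # disulfides
  sg <- which(atom$elety == "SG" & prot)
  if (length(sg) > 1) {
    for (ii in seq_along(sg)) for (jj in seq_along(sg)) {
      if (ii < jj && vnorm(xyz[sg[ii], ] - xyz[sg[jj], ]) <= 2.3)
        add(sg[ii], sg[jj], FALSE)
    }
  }

  # hydrogens to nearest heavy atom
  hs <- which(atom$elesy == "H" & prot)
  heavy_all <- which(atom$elesy != "H" & prot)
  if (length(hs) > 0 && length(heavy_all) > 0) {
    dm <- cross_dist(xyz[hs, , drop = FALSE], xyz[heavy_all, , drop = FALSE])
    for (k in seq_along(hs)) {
      j <- which.min(dm[k, ])
      if (dm[k, j] <= 1.25) add(hs[k], heavy_all[j], FALSE)
    }
  }

  if (length(bonds_i) == 0)
    return(data.frame(i = integer(), j = integer(), locked = logical()))
  out <- data.frame(i = bonds_i, j = bonds_j, locked = locked)
  out <- out[!duplicated(paste(out$i, out$j)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# atom-level adjacency list from a bond table
bond_adjacency <- function(bonds, n_atoms) {
  adj <- vector("list", n_atoms)
  for (k in seq_len(nrow(bonds))) {
    adj[[bonds$i[k]]] <- c(adj[[bonds$i[k]]], bonds$j[k])
    adj[[bonds$j[k]]] <- c(adj[[bonds$j[k]]], bonds$i[k])
  }
  adj
}

# TRUE if atoms u, v are within `depth` covalent bonds of each other
within_bonds <- function(adj, u, v, depth = 2) {
  frontier <- u
  seen <- u
  for (d in seq_len(depth)) {
    frontier <- unique(unlist(adj[frontier]))
    frontier <- setdiff(frontier, seen)
    if (v %in% frontier) return(TRUE)
    seen <- c(seen, frontier)
    if (length(frontier) == 0) break
  }
  FALSE
}
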