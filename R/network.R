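#' Body-bar constraint network
#'
#' A multigraph whose vertices ("bodies") each carry 6 degrees of freedom and
#' whose edges ("bars") remove relative degrees of freedom between body
#' pairs. Bar multiplicity encodes the constraint type: locked covalent bonds
#' contribute 6 bars, rotatable covalent bonds / hydrogen bonds / salt
#' bridges 5, hydrophobic tethers 2.
#'
#' @param n_bodies number of bodies
#' @param bars data.frame with columns `a`, `b` (body indices), `mult`
#'   (1-6), `source` (one of covalent_locked, covalent_rotatable, hbond,
#'   salt_bridge, hydrophobic), `energy` (kcal/mol for dilutable sources, NA
#'   otherwise)
#' @param bodies optional data.frame of per-body annotations (e.g. `chain`,
#'   `resno`, `is_ca`, `atoms`)
#' @return object of class `constraint_network`
#' @export
constraint_network <- function(n_bodies, bars = NULL, bodies = NULL) {
  stopifnot(n_bodies >= 1)
  if (is.null(bars))
    bars <- data.frame(a = integer(), b = integer(), mult = integer(),
                       source = character(), energy = numeric(),
                       stringsAsFactors = FALSE)
  stopifnot(all(c("a", "b", "mult", "source") %in% names(bars)))
  if (!"energy" %in% names(bars)) bars$energy <- NA_real_
  if (nrow(bars) > 0) {
    stopifnot(all(bars$a >= 1), all(bars$b >= 1),
              all(bars$a <= n_bodies), all(bars$b <= n_bodies),
              all(bars$a != bars$b), all(bars$mult >= 1), all(bars$mult <= 6))
  }
  net <- list(n_bodies = as.integer(n_bodies), bars = bars, bodies = bodies)
  class(net) <- "constraint_network"
  net
}

#' @export
print.constraint_network <- function(x, ...) {
  cat("constraint_network:", x$n_bodies, "bodies,", sum(x$bars$mult), "bars in",
      nrow(x$bars), "edges\n")
  if (nrow(x$bars) > 0) print(table(x$bars$source))
  invisible(x)
}

bar_multiplicity <- function(source,
                             mult_table = c(covalent_locked = 6L,
                                            covalent_rotatable = 5L,
                                            hbond = 5L, salt_bridge = 5L,
                                            hydrophobic = 2L)) {
  out <- unname(mult_table[source])
  if (any(is.na(out))) stop("unknown bar source: ",
                            paste(unique(source[is.na(out)]), collapse = ", "))
  out
}

#' Build the body-bar network of a structure
#'
#' Bodies are heavy atoms, with hydrogens merged into their parent atom and
#' terminal single-bonded heavy atoms (carbonyl O, Ala CB, hydroxyl O, ...)
#' merged into their neighbor. Covalent bars: 6 for locked bonds (peptide,
#' resonance, rings), 5 for rotatable single bonds. Hydrogen bonds and salt
#' bridges contribute 5 bars each and are included iff their energy is at or
#' below `e_cut`; hydrophobic tethers always contribute 2 bars.
#'
#' @param s a `structure3d`
#' @param interactions interaction data.frame from [detect_interactions()]
#'   (or any subset of it)
#' @param e_cut energy cutoff in kcal/mol for dilutable constraints
#' @param merge_terminal merge terminal single-bonded heavy atoms into their
#'   parent body (the FIRST-style convention)
#' @param mult_table named integer vector of bar multiplicities per source
#' @return a `constraint_network` with a `bodies` table mapping bodies to
#'   residues (columns `chain`, `resno`, `insert`, `resid`, `is_ca`)
#' @export
build_network <- function(s, interactions = NULL, e_cut = 0,
                          merge_terminal = TRUE,
                          mult_table = c(covalent_locked = 6L,
                                         covalent_rotatable = 5L,
                                         hbond = 5L, salt_bridge = 5L,
                                         hydrophobic = 2L)) {
  atom <- s$atom
  prot <- !atom$het
  bonds <- covalent_bonds(s)

  # body assignment: start with each heavy protein atom its own body
  owner <- rep(NA_integer_, nrow(atom))   # atom -> representative atom index
  heavy <- which(prot & atom$elesy != "H")
  owner[heavy] <- heavy
  # hydrogens merge into their bonded heavy atom
  for (k in seq_len(nrow(bonds))) {
    i <- bonds$i[k]; j <- bonds$j[k]
    if (atom$elesy[i] == "H" && atom$elesy[j] != "H") owner[i] <- j
    if (atom$elesy[j] == "H" && atom$elesy[i] != "H") owner[j] <- i
  }
  if (merge_terminal) {
    hb <- bonds[atom$elesy[bonds$i] != "H" & atom$elesy[bonds$j] != "H", , drop = FALSE]
    deg <- tabulate(c(hb$i, hb$j), nbins = nrow(atom))
    repeat {
      # backbone N/CA/C are never merged away, so chain connectivity (and the
      # residue-level reporting anchored at CA bodies) is preserved
      terminal <- heavy[deg[heavy] == 1 & owner[heavy] == heavy &
                          !(atom$elety[heavy] %in% c("N", "CA", "C"))]
      if (length(terminal) == 0) break
      moved <- FALSE
      for (t in terminal) {
        nb <- c(hb$j[hb$i == t], hb$i[hb$j == t])
        nb <- nb[owner[nb] != t]
        if (length(nb) == 0) next
        owner[owner == t] <- owner[nb[1]]
        deg[t] <- 0L
        moved <- TRUE
      }
      if (!moved) break
    }
  }
  # resolve transitive merges
  repeat {
    nxt <- owner[owner]
    nxt[is.na(owner)] <- NA_integer_
    if (identical(nxt, owner)) break
    owner <- nxt
  }

  reps <- sort(unique(owner[!is.na(owner)]))
  body_of_atom <- match(owner, reps)
  n_bodies <- length(reps)
  if (n_bodies == 0) stop("no protein heavy atoms to build a network from")

  rt <- residue_table(s)
  keys <- residue_keys(atom)
  bodies <- data.frame(chain = atom$chain[reps], resno = atom$resno[reps],
                       insert = atom$insert[reps], resid = atom$resid[reps],
                       is_ca = atom$elety[reps] == "CA",
                       atom = atom$elety[reps], stringsAsFactors = FALSE)

  bars <- list()
  hb <- bonds[atom$elesy[bonds$i] != "H" & atom$elesy[bonds$j] != "H", , drop = FALSE]
  if (nrow(hb) > 0) {
    a <- body_of_atom[hb$i]; b <- body_of_atom[hb$j]
    keep <- !is.na(a) & !is.na(b) & a != b
    src <- ifelse(hb$locked[keep], "covalent_locked", "covalent_rotatable")
    bars[[1]] <- data.frame(a = pmin(a[keep], b[keep]), b = pmax(a[keep], b[keep]),
                            mult = bar_multiplicity(src, mult_table), source = src,
                            energy = NA_real_, stringsAsFactors = FALSE)
  }
  if (!is.null(interactions) && nrow(interactions) > 0) {
    x <- interactions
    dilutable <- x$kind %in% c("hbond", "salt_bridge")
    x <- x[!dilutable | (x$energy <= e_cut), , drop = FALSE]
    if (nrow(x) > 0) {
      ia <- atom_index(atom, x$chain_a, x$resno_a, x$atom_a)
      ib <- atom_index(atom, x$chain_b, x$resno_b, x$atom_b)
      a <- body_of_atom[ia]; b <- body_of_atom[ib]
      keep <- !is.na(a) & !is.na(b) & a != b
      bars[[length(bars) + 1]] <- data.frame(
        a = pmin(a[keep], b[keep]), b = pmax(a[keep], b[keep]),
        mult = bar_multiplicity(x$kind[keep], mult_table),
        source = x$kind[keep], energy = x$energy[keep], stringsAsFactors = FALSE)
    }
  }
  bars <- if (length(bars) > 0) do.call(rbind, bars) else NULL
  if (!is.null(bars)) {
    # deduplicate identical covalent edges (can arise from merges)
    cov <- bars$source %in% c("covalent_locked", "covalent_rotatable")
    covbars <- bars[cov, , drop = FALSE]
    if (nrow(covbars) > 0) {
      id <- paste(covbars$a, covbars$b)
      # a locked duplicate wins over a rotatable one
      covbars <- covbars[order(id, covbars$source != "covalent_locked"), , drop = FALSE]
      covbars <- covbars[!duplicated(paste(covbars$a, covbars$b)), , drop = FALSE]
    }
    bars <- rbind(covbars, bars[!cov, , drop = FALSE])
    rownames(bars) <- NULL
  }
  constraint_network(n_bodies, bars, bodies)
}

atom_index <- function(atom, chain, resno, elety) {
  key <- paste(atom$chain, atom$resno, atom$elety)
  match(paste(chain, resno, elety), key)
}
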