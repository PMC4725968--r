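#' Protein structure container
#'
#' `structure3d` is the package's light-weight structure class: a flat atom
#' table plus optional extra coordinate models (ensembles) and secondary
#' structure annotations. It deliberately mirrors the PDB fields so that
#' reading and writing are loss-free at PDB precision.
#'
#' @param atom data.frame with columns `eleno`, `elety` (atom name), `elesy`
#'   (element symbol), `resid` (3-letter residue name), `chain`, `resno`,
#'   `insert`, `x`, `y`, `z`, `o` (occupancy), `b` (B-factor), `het`
#'   (logical, HETATM flag).
#' @param models optional list of coordinate matrices (n_atoms x 3); when
#'   present, element 1 must equal the atom-table coordinates.
#' @param helix,sheet optional data.frames of annotated ranges with columns
#'   `chain`, `start`, `end` (author residue numbers), as carried by PDB
#'   HELIX/SHEET records.
#'
#' @return An object of class `structure3d`.
#' @export
structure3d <- function(atom, models = NULL, helix = NULL, sheet = NULL) {
  need <- c("eleno", "elety", "elesy", "resid", "chain", "resno",
            "insert", "x", "y", "z", "o", "b", "het")
  miss <- setdiff(need, names(atom))
  if (length(miss) > 0) stop("atom table missing columns: ", paste(miss, collapse = ", "))
  if (nrow(atom) == 0) stop("structure has zero atoms")
  if (!all(is.finite(atom$x) & is.finite(atom$y) & is.finite(atom$z)))
    stop("non-finite coordinates in atom table")
  rownames(atom) <- NULL
  s <- list(atom = atom, models = models, helix = helix, sheet = sheet,
            sse = NULL, elements = NULL)
  class(s) <- "structure3d"
  s
}

#' @export
print.structure3d <- function(x, ...) {
  rt <- residue_table(x)
  cat("structure3d:", nrow(x$atom), "atoms,", nrow(rt), "residues,",
      length(chain_ids(x)), "chain(s),", n_models(x), "model(s)\n")
  invisible(x)
}

#' Number of coordinate models in a structure
#' @param s a `structure3d`
#' @return integer count (1 for a single-model structure)
#' @export
n_models <- function(s) {
  if (is.null(s$models)) 1L else length(s$models)
}

#' Coordinates of one model as an n_atoms x 3 matrix
#' @param s a `structure3d`
#' @param model model index (1-based)
#' @return numeric matrix
#' @export
model_xyz <- function(s, model = 1L) {
  if (model == 1L || is.null(s$models)) {
    if (model > n_models(s)) stop("model index out of range")
    if (!is.null(s$models)) return(s$models[[model]])
    return(as.matrix(s$atom[, c("x", "y", "z")]))
  }
  if (model > length(s$models)) stop("model index out of range")
  s$models[[model]]
}

#' Replace the working coordinates of a structure with those of a model
#' @inheritParams model_xyz
#' @return a single-model `structure3d`
#' @export
use_model <- function(s, model = 1L) {
  xyz <- model_xyz(s, model)
  s$atom$x <- xyz[, 1]; s$atom$y <- xyz[, 2]; s$atom$z <- xyz[, 3]
  s$models <- NULL
  s
}

#' @export
chain_ids <- function(s) unique(s$atom$chain)

# Unique residue key strings, in atom-table order
residue_keys <- function(atom) paste(atom$chain, atom$resno, atom$insert, sep = "|")

#' Residue table of a structure
#'
#' One row per residue, in chain/sequence order, protein residues only unless
#' `het = TRUE`.
#' @param s a `structure3d`
#' @param het include HETATM residues
#' @return data.frame with `chain`, `resno`, `insert`, `resid` and the residue
#'   `key` used internally for indexing
#' @export
residue_table <- function(s, het = FALSE) {
  atom <- s$atom
  if (!het) atom <- atom[!atom$het, , drop = FALSE]
  key <- residue_keys(atom)
  keep <- !duplicated(key)
  out <- data.frame(chain = atom$chain[keep], resno = atom$resno[keep],
                    insert = atom$insert[keep], resid = atom$resid[keep],
                    key = key[keep], stringsAsFactors = FALSE)
  ord <- order(match(out$chain, chain_ids(s)), out$resno, out$insert)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Restrict a structure to selected chains
#'
#' Selecting a single chain of a dimer yields the monomer used for
#' monomer-versus-dimer comparisons; selecting all chains is the identity.
#'
#' @param s a `structure3d`
#' @param chain_ids character vector of chain identifiers to keep
#' @return a `structure3d` restricted to those chains (order preserved)
#' @export
select_assembly <- function(s, chain_ids) {
  have <- unique(s$atom$chain)
  missing <- setdiff(chain_ids, have)
  if (length(missing) > 0)
    stop("chain(s) not present: ", paste(missing, collapse = ", "),
         "; available: ", paste(have, collapse = ", "))
  keep <- s$atom$chain %in% chain_ids
  atom <- s$atom[keep, , drop = FALSE]
  models <- NULL
  if (!is.null(s$models)) models <- lapply(s$models, function(m) m[keep, , drop = FALSE])
  out <- structure3d(atom, models = models,
                     helix = filter_ranges(s$helix, chain_ids),
                     sheet = filter_ranges(s$sheet, chain_ids))
  out
}

filter_ranges <- function(r, chains) {
  if (is.null(r) || nrow(r) == 0) return(r)
  r[r$chain %in% chains, , drop = FALSE]
}

#' Relative (z-scored) B-factors
#'
#' Standardizes B-factors within each chain over the selected atom scope
#' (population standard deviation), then averages atom z-scores per residue.
#' Per-chain normalization makes homodimer chains directly comparable.
#'
#' @param s a `structure3d` with B-factors
#' @param scope `"backbone"` (N, CA, C, O) or `"all"` heavy atoms
#' @return data.frame with `chain`, `resno`, `resid`, `z`; mean 0 / SD 1 per
#'   chain at the atom level by construction
#' @export
relative_bfactors <- function(s, scope = c("backbone", "all")) {
  scope <- match.arg(scope)
  atom <- s$atom[!s$atom$het, , drop = FALSE]
  if (scope == "backbone")
    atom <- atom[atom$elety %in% c("N", "CA", "C", "O"), , drop = FALSE]
  atom <- atom[atom$elesy != "H", , drop = FALSE]
  if (nrow(atom) == 0) stop("no atoms in scope")
  res <- NULL
  for (ch in unique(atom$chain)) {
    a <- atom[atom$chain == ch, , drop = FALSE]
    mu <- mean(a$b)
    sdev <- sqrt(mean((a$b - mu)^2))  # population SD
    if (sdev < 1e-12)
      stop("all B-factors identical in chain ", ch, "; relative B-factors undefined")
    a$z <- (a$b - mu) / sdev
    zres <- tapply(a$z, paste(a$chain, a$resno, a$insert, sep = "|"), mean)
    key <- names(zres)
    first <- a[!duplicated(paste(a$chain, a$resno, a$insert, sep = "|")), , drop = FALSE]
    first_key <- paste(first$chain, first$resno, first$insert, sep = "|")
    res <- rbind(res, data.frame(chain = first$chain,
                                 resno = first$resno,
                                 resid = first$resid,
                                 z = as.numeric(zres[match(first_key, key)]),
                                 stringsAsFactors = FALSE))
  }
  res <- res[order(match(res$chain, chain_ids(s)), res$resno), , drop = FALSE]
  rownames(res) <- NULL
  res
}
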