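#' Backbone dihedral angles
#'
#' Computes phi/psi per residue from N, CA, C coordinates. Terminal residues
#' get NA for the undefined angle.
#'
#' @param s a `structure3d`
#' @return data.frame with `chain`, `resno`, `insert`, `phi`, `psi`
#' @export
backbone_dihedrals <- function(s) {
  rt <- residue_table(s)
  atom <- s$atom
  bb <- function(key, name) {
    i <- which(residue_keys(atom) == key & atom$elety == name)
    if (length(i) == 0) return(NULL)
    c(atom$x[i[1]], atom$y[i[1]], atom$z[i[1]])
  }
  n <- nrow(rt)
  phi <- rep(NA_real_, n); psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    N <- bb(rt$key[i], "N"); CA <- bb(rt$key[i], "CA"); C <- bb(rt$key[i], "C")
    if (is.null(N) || is.null(CA) || is.null(C)) next
    if (i > 1 && rt$chain[i - 1] == rt$chain[i]) {
      Cp <- bb(rt$key[i - 1], "C")
      if (!is.null(Cp) && vnorm(N - Cp) < 2.0) phi[i] <- torsion4(Cp, N, CA, C)
    }
    if (i < n && rt$chain[i + 1] == rt$chain[i]) {
      Nn <- bb(rt$key[i + 1], "N")
      if (!is.null(Nn) && vnorm(Nn - C) < 2.0) psi[i] <- torsion4(N, CA, C, Nn)
    }
  }
  data.frame(chain = rt$chain, resno = rt$resno, insert = rt$insert,
             phi = phi, psi = psi, stringsAsFactors = FALSE)
}

in_window <- function(x, lo, hi) !is.na(x) & x >= lo & x <= hi

# helix window: phi in [-100,-30], psi in [-80,-5]
# strand window: phi in [-180,-40] (wrapping +180 to -180), psi in [60,180] or [-180,-170]
helix_compatible <- function(phi, psi) {
  okp <- is.na(phi) | in_window(phi, -100, -30)
  oks <- is.na(psi) | in_window(psi, -80, -5)
  okp & oks & !(is.na(phi) & is.na(psi))
}

strand_compatible <- function(phi, psi) {
  phiw <- ifelse(!is.na(phi) & phi > 179.999, -180, phi)
  okp <- is.na(phiw) | in_window(phiw, -180, -40)
  oks <- is.na(psi) | in_window(psi, 60, 180) | in_window(psi, -180, -170)
  okp & oks & !(is.na(phi) & is.na(psi))
}

run_lengths_keep <- function(flag, minlen, chain) {
  keep <- rep(FALSE, length(flag))
  i <- 1
  while (i <= length(flag)) {
    if (flag[i]) {
      j <- i
      while (j < length(flag) && flag[j + 1] && chain[j + 1] == chain[i]) j <- j + 1
      if (j - i + 1 >= minlen) keep[i:j] <- TRUE
      i <- j + 1
    } else i <- i + 1
  }
  keep
}

#' Assign secondary structure
#'
#' Labels every residue H (helix), E (strand) or C (coil). HELIX/SHEET
#' records stored on the structure take precedence; residues not covered by
#' records are classified by a dihedral heuristic (helix: phi in
#' \[-100, -30\], psi in \[-80, -5\] over at least 4 consecutive residues;
#' strand: phi in \[-180, -40\], psi in \[60, 180\] or \[-180, -170\] over at
#' least 3). Contiguous runs are grouped into labeled elements.
#'
#' @param s a `structure3d`
#' @return the structure with `$sse` (per-residue data.frame with `sse`
#'   column) and `$elements` (data.frame: `label`, `type`, `chain`, `start`,
#'   `end`) filled in
#' @export
assign_secondary_structure <- function(s) {
  rt <- residue_table(s)
  if (nrow(rt) < 1) stop("no protein residues")
  dh <- backbone_dihedrals(s)
  sse <- rep("C", nrow(rt))

  hel <- run_lengths_keep(helix_compatible(dh$phi, dh$psi), 4, rt$chain)
  str <- run_lengths_keep(strand_compatible(dh$phi, dh$psi) & !hel, 3, rt$chain)
  sse[str] <- "E"
  sse[hel] <- "H"

  # records take precedence over the heuristic
  apply_ranges <- function(sse, ranges, code) {
    if (is.null(ranges) || nrow(ranges) == 0) return(sse)
    for (k in seq_len(nrow(ranges))) {
      hit <- rt$chain == ranges$chain[k] &
        rt$resno >= ranges$start[k] & rt$resno <= ranges$end[k]
      sse[hit] <- code
    }
    sse
  }
  sse <- apply_ranges(sse, s$sheet, "E")
  sse <- apply_ranges(sse, s$helix, "H")

  s$sse <- data.frame(chain = rt$chain, resno = rt$resno, insert = rt$insert,
                      resid = rt$resid, sse = sse, stringsAsFactors = FALSE)
  s$elements <- sse_elements(s$sse)
  s
}

#' Group per-residue SSE labels into elements
#' @param sse data.frame as stored by [assign_secondary_structure()]
#' @return data.frame with `label`, `type`, `chain`, `start`, `end`
#' @export
sse_elements <- function(sse) {
  out <- NULL
  counth <- 0; counte <- 0
  i <- 1
  while (i <= nrow(sse)) {
    code <- sse$sse[i]
    if (code %in% c("H", "E")) {
      j <- i
      while (j < nrow(sse) && sse$sse[j + 1] == code && sse$chain[j + 1] == sse$chain[i])
        j <- j + 1
      if (code == "H") { counth <- counth + 1; lab <- paste0("H", counth); ty <- "helix" }
      else { counte <- counte + 1; lab <- paste0("E", counte); ty <- "strand" }
      out <- rbind(out, data.frame(label = lab, type = ty, chain = sse$chain[i],
                                   start = sse$resno[i], end = sse$resno[j],
                                   stringsAsFactors = FALSE))
      i <- j + 1
    } else i <- i + 1
  }
  if (is.null(out))
    out <- data.frame(label = character(), type = character(), chain = character(),
                      start = integer(), end = integer(), stringsAsFactors = FALSE)
  out
}
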