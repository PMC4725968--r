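#' Read a PDB file
#'
#' Parses ATOM/HETATM/MODEL/HELIX/SHEET records (via bio3d) into a
#' [structure3d()]. Alternate locations are resolved to the highest-occupancy
#' conformer (ties broken alphabetically by altloc id); HETATM entities are
#' retained but flagged; hydrogens are kept when present. Multi-MODEL files
#' yield an ensemble structure.
#'
#' @param path path to a PDB file
#' @param biounit if TRUE and the entry carries REMARK 350 transforms, apply
#'   them and return the first biological assembly
#' @return a `structure3d`
#' @export
read_pdb <- function(path, biounit = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop("empty PDB file: ", path)
  validate_pdb_lines(lines)

  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                          verbose = FALSE))
  if (isTRUE(biounit)) {
    bu <- try(bio3d::biounit(pdb, multi = FALSE), silent = TRUE)
    if (!inherits(bu, "try-error") && length(bu) >= 1) pdb <- bu[[1]]
  }
  s <- bio3d_to_structure3d(pdb)
  if (sum(!s$atom$het) == 0) stop("no protein atoms in ", path)
  s
}

validate_pdb_lines <- function(lines) {
  rec <- substr(lines, 1, 6)
  coords <- which(rec %in% c("ATOM  ", "HETATM"))
  if (length(coords) == 0) stop("no ATOM/HETATM records found")
  for (i in coords) {
    l <- lines[i]
    if (nchar(l) < 54)
      stop("unparseable coordinate record at line ", i, ": too short")
    xyz <- suppressWarnings(as.numeric(c(substr(l, 31, 38), substr(l, 39, 46),
                                         substr(l, 47, 54))))
    if (any(is.na(xyz)))
      stop("unparseable coordinate record at line ", i, ": bad coordinates")
  }
  invisible(TRUE)
}

bio3d_to_structure3d <- function(pdb) {
  a <- pdb$atom
  a$chain[is.na(a$chain)] <- "A"
  a$insert[is.na(a$insert)] <- ""
  a$alt[is.na(a$alt)] <- ""
  a$o[is.na(a$o)] <- 1
  a$b[is.na(a$b)] <- 0
  if (is.null(a$elesy) || all(is.na(a$elesy)) || all(a$elesy == ""))
    a$elesy <- guess_element(a$elety)
  a$elesy[is.na(a$elesy) | a$elesy == ""] <- guess_element(a$elety[is.na(a$elesy) | a$elesy == ""])

  keep <- resolve_altloc(a)
  a <- a[keep, , drop = FALSE]

  atom <- data.frame(eleno = a$eleno, elety = a$elety, elesy = toupper(a$elesy),
                     resid = a$resid, chain = a$chain, resno = a$resno,
                     insert = a$insert, x = a$x, y = a$y, z = a$z,
                     o = a$o, b = a$b, het = a$type == "HETATM",
                     stringsAsFactors = FALSE)

  models <- NULL
  xyz <- pdb$xyz
  if (is.matrix(xyz) && nrow(xyz) > 1) {
    models <- lapply(seq_len(nrow(xyz)), function(k) {
      m <- matrix(xyz[k, ], ncol = 3, byrow = TRUE)
      m[keep, , drop = FALSE]
    })
    atom$x <- models[[1]][, 1]; atom$y <- models[[1]][, 2]; atom$z <- models[[1]][, 3]
  }
  helix <- sheet <- NULL
  if (!is.null(pdb$helix) && length(pdb$helix$start) > 0)
    helix <- data.frame(chain = pdb$helix$chain, start = as.integer(pdb$helix$start),
                        end = as.integer(pdb$helix$end), stringsAsFactors = FALSE)
  if (!is.null(pdb$sheet) && length(pdb$sheet$start) > 0)
    sheet <- data.frame(chain = pdb$sheet$chain, start = as.integer(pdb$sheet$start),
                        end = as.integer(pdb$sheet$end), stringsAsFactors = FALSE)
  structure3d(atom, models = models, helix = helix, sheet = sheet)
}

# keep highest-occupancy altloc per (chain, resno, insert, elety); ties -> first
# alphabetically by altloc code
resolve_altloc <- function(a) {
  key <- paste(a$chain, a$resno, a$insert, a$elety, sep = "|")
  ord <- order(key, -a$o, a$alt)
  first <- ord[!duplicated(key[ord])]
  sort(first)
}

guess_element <- function(elety) {
  e <- toupper(gsub("[^A-Za-z].*$", "", gsub("^[0-9]+", "", elety)))
  two <- substr(e, 1, 2)
  out <- substr(e, 1, 1)
  out[two %in% c("FE", "ZN", "MG", "MN", "SE", "CL", "BR", "NA", "CA")] <-
    two[two %in% c("FE", "ZN", "MG", "MN", "SE", "CL", "BR", "NA", "CA")]
  # PDB atom names like CA/CB are carbons; only treat CA as calcium for HETATM
  out[e %in% c("CA", "CB", "CG", "CD", "CE", "CZ", "CH")] <- "C"
  out[e %in% c("NA", "NB", "ND", "NE", "NH", "NZ")] <- "N"
  out
}

#' Write a structure to a PDB file
#'
#' Emits HELIX/SHEET records (from annotations when present), MODEL/ENDMDL
#' blocks for ensembles, and fixed-width ATOM/HETATM records at standard PDB
#' precision (3 decimals on coordinates).
#'
#' @param s a `structure3d`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_pdb <- function(s, path) {
  con <- file(path, "w")
  on.exit(close(con))
  hel <- s$helix
  if (is.null(hel) && !is.null(s$elements))
    hel <- s$elements[s$elements$type == "helix", c("chain", "start", "end")]
  sht <- s$sheet
  if (is.null(sht) && !is.null(s$elements))
    sht <- s$elements[s$elements$type == "strand", c("chain", "start", "end")]
  resname_at <- function(ch, rn) {
    i <- which(s$atom$chain == ch & s$atom$resno == rn)[1]
    if (is.na(i)) "ALA" else s$atom$resid[i]
  }
  if (!is.null(hel) && nrow(hel) > 0) {
    for (k in seq_len(nrow(hel))) {
      writeLines(sprintf("HELIX  %3d %3s %3s %1s %4d  %3s %1s %4d %2d%30s",
                         k, sprintf("H%-2d", k), resname_at(hel$chain[k], hel$start[k]),
                         hel$chain[k], hel$start[k],
                         resname_at(hel$chain[k], hel$end[k]), hel$chain[k],
                         hel$end[k], 1L, ""), con)
    }
  }
  if (!is.null(sht) && nrow(sht) > 0) {
    for (k in seq_len(nrow(sht))) {
      writeLines(sprintf("SHEET  %3d %3s%2d %3s %1s%4d  %3s %1s%4d %2d",
                         k, sprintf("S%-2d", k), 1L,
                         resname_at(sht$chain[k], sht$start[k]), sht$chain[k],
                         sht$start[k], resname_at(sht$chain[k], sht$end[k]),
                         sht$chain[k], sht$end[k], 0L), con)
    }
  }
  nm <- n_models(s)
  for (m in seq_len(nm)) {
    if (nm > 1) writeLines(sprintf("MODEL     %4d", m), con)
    xyz <- model_xyz(s, m)
    a <- s$atom
    name4 <- ifelse(nchar(a$elety) < 4, sprintf(" %-3s", a$elety), a$elety)
    lines <- sprintf("%-6s%5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                     ifelse(a$het, "HETATM", "ATOM"),
                     a$eleno %% 100000L, name4, "", a$resid, a$chain,
                     a$resno %% 10000L, substr(paste0(a$insert, " "), 1, 1),
                     xyz[, 1], xyz[, 2], xyz[, 3], a$o, a$b, a$elesy)
    writeLines(lines, con)
    if (nm > 1) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
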