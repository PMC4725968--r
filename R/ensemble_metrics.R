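# Ensemble diagnostics: Kabsch superposition / RMSD, radius of gyration, and
# the root-mean-square inner product between principal-component subspaces.

# optimal rotation (Kabsch, SVD-based) mapping xb onto xa after centering
kabsch_rotation <- function(xa, xb) {
  ca <- colMeans(xa); cb <- colMeans(xb)
  A <- sweep(xa, 2, ca); B <- sweep(xb, 2, cb)
  H <- t(B) %*% A
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  list(R = R, ca = ca, cb = cb)
}

superpose_xyz <- function(xa, xb, fit_idx = seq_len(nrow(xa))) {
  k <- kabsch_rotation(xa[fit_idx, , drop = FALSE], xb[fit_idx, , drop = FALSE])
  sweep(sweep(xb, 2, k$cb) %*% t(k$R), 2, k$ca, "+")
}

ca_coords <- function(s, model = 1L) {
  sel <- which(s$atom$elety == "CA" & !s$atom$het)
  model_xyz(s, model)[sel, , drop = FALSE]
}

#' C-alpha RMSD between two models
#'
#' Root-mean-square deviation over matched CA atoms, by default after optimal
#' least-squares superposition (Kabsch); `fit = FALSE` gives the raw
#' coordinate RMSD.
#'
#' @param a,b `structure3d` objects (or plain n x 3 coordinate matrices) with
#'   matched atom sets
#' @param selection optional integer indices into the CA set
#' @param fit superpose before measuring
#' @return RMSD in Angstrom
#' @export
ca_rmsd <- function(a, b, selection = NULL, fit = TRUE) {
  xa <- if (is.matrix(a)) a else ca_coords(a)
  xb <- if (is.matrix(b)) b else ca_coords(b)
  if (nrow(xa) != nrow(xb)) stop("atom sets differ in size")
  if (!is.null(selection)) {
    xa <- xa[selection, , drop = FALSE]
    xb <- xb[selection, , drop = FALSE]
  }
  if (nrow(xa) < 3) stop("need >= 3 matched atoms")
  if (fit) xb <- superpose_xyz(xa, xb)
  sqrt(mean(rowSums((xa - xb)^2)))
}

#' Radius of gyration
#'
#' Unweighted root-mean-square distance of the selected CA atoms from their
#' centroid, a measure of structural compactness.
#'
#' @param s a `structure3d` or an n x 3 coordinate matrix
#' @param selection optional indices into the CA set
#' @return Rg in Angstrom
#' @export
radius_of_gyration <- function(s, selection = NULL) {
  x <- if (is.matrix(s)) s else ca_coords(s)
  if (!is.null(selection)) x <- x[selection, , drop = FALSE]
  if (nrow(x) < 1) stop("no atoms selected")
  ctr <- colMeans(x)
  sqrt(mean(rowSums(sweep(x, 2, ctr)^2)))
}

# per-ensemble CA principal components after two-pass superposition:
# (1) fit all models on all residues to model 1, compute per-residue RMSF,
# (2) refit on the fit_fraction least-fluctuating residues, then eigen-
# decompose the 3N x 3N covariance of positional fluctuations
ensemble_modes <- function(s, n_modes = 10, fit_fraction = 0.8) {
  M <- n_models(s)
  if (M < n_modes + 1) stop("need >= n_modes + 1 models (", n_modes + 1, ")")
  xs <- lapply(seq_len(M), function(k) ca_coords(s, k))
  n <- nrow(xs[[1]])
  ref <- xs[[1]]
  fitted <- lapply(xs, function(x) superpose_xyz(ref, x))
  rmsf <- function(flist) {
    arr <- simplify2array(flist)                 # n x 3 x M
    mu <- apply(arr, c(1, 2), mean)
    sqrt(rowMeans(apply(arr, 3, function(x) rowSums((x - mu)^2))))
  }
  fl <- rmsf(fitted)
  n_fit <- max(3, floor(fit_fraction * n))
  fit_idx <- order(fl)[seq_len(n_fit)]
  fitted <- lapply(xs, function(x) superpose_xyz(ref, x, fit_idx))
  X <- t(vapply(fitted, function(x) as.numeric(t(x)), numeric(3 * n)))  # M x 3n
  X <- sweep(X, 2, colMeans(X))
  cv <- crossprod(X) / (M - 1)
  ev <- eigen(cv, symmetric = TRUE)
  ev$vectors[, seq_len(n_modes), drop = FALSE]
}

#' Root-mean-square inner product of essential subspaces
#'
#' RMSIP = sqrt( (1/D) * sum_ij (v_i . w_j)^2 ) over the first `n_modes`
#' principal components of the CA covariance matrices of two ensembles,
#' computed after superposing each ensemble on its `fit_fraction` least-
#' fluctuating residues (two-pass). 1 means identical essential subspaces,
#' values near sqrt(D / 3N) are expected for unrelated ones.
#'
#' @param a,b multi-model `structure3d` ensembles sharing the CA set, or
#'   plain matrices of column mode vectors (3N x D)
#' @param n_modes subspace dimension D
#' @param fit_fraction fraction of residues used for the superposition
#' @return RMSIP in \[0, 1\]
#' @export
rmsip <- function(a, b, n_modes = 10, fit_fraction = 0.8) {
  va <- if (is.matrix(a)) a else ensemble_modes(a, n_modes, fit_fraction)
  vb <- if (is.matrix(b)) b else ensemble_modes(b, n_modes, fit_fraction)
  if (nrow(va) != nrow(vb)) stop("ensembles do not share the CA set")
  D <- min(ncol(va), ncol(vb), n_modes)
  ip <- t(va[, seq_len(D), drop = FALSE]) %*% vb[, seq_len(D), drop = FALSE]
  sqrt(sum(ip^2) / D)
}
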