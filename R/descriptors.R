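#' Gyration tensor of a point cloud
#'
#' Second-moment matrix of centered coordinates,
#' \deqn{T = \frac{1}{N}\sum_i (x_i - \bar x)(x_i - \bar x)^T,}
#' with all points weighted uniformly (no masses, no atom types). The 1/N
#' normalization makes the trace equal the squared radius of gyration.
#'
#' @param coords N x 3 numeric matrix of coordinates in Angstroms, N >= 4.
#' @return Symmetric positive semidefinite 3 x 3 matrix (Angstrom^2).
#' @export
gyration_tensor <- function(coords) {
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || ncol(coords) != 3L) {
    stop("coords must be an N x 3 numeric matrix")
  }
  if (nrow(coords) < 4L) {
    stop("degenerate pocket: need at least 4 points to define a 3-D shape, got ",
         nrow(coords))
  }
  if (!all(is.finite(coords))) stop("coords contain non-finite values")
  cc <- sweep(coords, 2L, colMeans(coords))
  crossprod(cc) / nrow(coords)
}

#' Sorted eigenvalue spectrum of a gyration tensor
#'
#' @param tensor Symmetric 3 x 3 matrix.
#' @return Named numeric vector `c(lambda1, lambda2, lambda3)` with
#'   `lambda1 >= lambda2 >= lambda3 >= 0`; negative round-off below 1e-12 is
#'   clamped to zero.
#' @export
eigen_spectrum <- function(tensor) {
  tensor <- as.matrix(tensor)
  stopifnot(is.numeric(tensor), all(dim(tensor) == c(3L, 3L)))
  if (max(abs(tensor - t(tensor))) > 1e-9 * max(1, max(abs(tensor)))) {
    stop("tensor is not symmetric")
  }
  ev <- eigen(tensor, symmetric = TRUE, only.values = TRUE)$values
  ev <- sort(ev, decreasing = TRUE)
  ev[ev < 0 & ev > -1e-12] <- 0
  if (any(ev < 0)) stop("tensor is not positive semidefinite")
  setNames(ev, c("lambda1", "lambda2", "lambda3"))
}

#' Shape and size descriptors of a pocket point cloud
#'
#' Computes the gyration-tensor eigenvalues and the three scale-invariant
#' anisotropy ratios
#' \deqn{rEV21 = \lambda_2/\lambda_1,\quad rEV32 = \lambda_3/\lambda_2,\quad
#'       rEV31 = \lambda_3/\lambda_1,}
#' each in \[0, 1\] (1 = isotropy), together with the radius of gyration
#' \eqn{R_g = \sqrt{\lambda_1+\lambda_2+\lambda_3}} and atom/residue counts.
#' The identity `rEV31 == rEV21 * rEV32` holds algebraically.
#'
#' @param x A `pocket_cloud` from [extract_pocket()] / [sample_cloud()], or
#'   an N x 3 coordinate matrix.
#' @param pocket_id Identifier for the output row; defaults to
#'   `structure_id/ligand_id` for pockets.
#' @return One-row data frame with columns `pocket_id`, `lambda1..3`,
#'   `rEV21`, `rEV32`, `rEV31`, `Rg`, `n_atoms`, `n_residues`.
#'   Collinear clouds (`lambda2 == 0`) get `rEV32 = 0` and a warning.
#' @export
shape_descriptors <- function(x, pocket_id = NULL) {
  if (inherits(x, "pocket_cloud")) {
    coords <- pocket_coords(x)
    if (is.null(pocket_id)) {
      pocket_id <- paste(x$structure_id, x$ligand_id, sep = "/")
    }
    n_res <- x$n_residues
  } else {
    coords <- as.matrix(x)
    if (is.null(pocket_id)) pocket_id <- "cloud"
    n_res <- NA_integer_
  }
  ev <- eigen_spectrum(gyration_tensor(coords))
  if (ev[1L] <= 0) stop("all points coincide: lambda1 = 0")
  r21 <- ev[[2L]] / ev[[1L]]
  if (ev[2L] > 0) {
    r32 <- ev[[3L]] / ev[[2L]]
  } else {
    warning("collinear cloud (lambda2 = 0); rEV32 set to 0")
    r32 <- 0
  }
  data.frame(pocket_id = pocket_id,
             lambda1 = ev[[1L]], lambda2 = ev[[2L]], lambda3 = ev[[3L]],
             rEV21 = r21, rEV32 = r32, rEV31 = ev[[3L]] / ev[[1L]],
             Rg = sqrt(sum(ev)),
             n_atoms = nrow(coords), n_residues = n_res,
             stringsAsFactors = FALSE)
}

#' Descriptor table for a batch of pockets
#'
#' @param pockets A list of `pocket_cloud` objects (or coordinate matrices).
#' @param ids Optional character vector of pocket identifiers.
#' @return Data frame with one [shape_descriptors()] row per pocket.
#' @export
describe_pockets <- function(pockets, ids = NULL) {
  stopifnot(is.list(pockets))
  if (is.null(ids)) ids <- names(pockets)
  rows <- lapply(seq_along(pockets), function(i) {
    shape_descriptors(pockets[[i]], pocket_id = if (!is.null(ids)) ids[i])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
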