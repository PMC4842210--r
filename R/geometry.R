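cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Signed dihedral (torsion) angle of four points
#'
#' Returns the torsion about the p2-p3 axis in degrees, IUPAC sign convention
#' (looking from p2 towards p3, a clockwise rotation carrying the p1 projection
#' onto the p4 projection is positive). The result lies in the half-open
#' interval (-180, 180]; exactly antiperiplanar geometry maps to +180.
#'
#' @param p1,p2,p3,p4 numeric 3-vectors, Angstrom.
#' @return angle in degrees.
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sum(n1^2) < 1e-16 || sum(n2^2) < 1e-16)
    stop("undefined dihedral: three consecutive points are collinear")
  b2u <- b2 / sqrt(sum(b2^2))
  ang <- atan2(sum(cross3(n1, n2) * b2u), sum(n1 * n2)) * 180 / pi
  # half-open (-180, 180]: the branch-cut neighbourhood collapses onto +180
  # so that an exactly antiperiplanar geometry cannot flip sign by rounding
  if (ang <= -180 + 1e-9) ang <- ang + 360
  if (ang > 180) ang <- 180
  ang
}

#' Backbone phi/psi/omega dihedral series of a model
#'
#' phi(i) = C(i-1)-N(i)-CA(i)-C(i); psi(i) = N(i)-CA(i)-C(i)-N(i+1);
#' omega(i) = CA(i)-C(i)-N(i+1)-CA(i+1). Angles are `NA` at the termini and
#' on either side of a flagged chain break, so no dihedral ever spans a gap.
#'
#' @param model a [structure_model].
#' @return data.frame with columns `phi`, `psi`, `omega` (degrees, `NA` where
#'   undefined), one row per residue.
#' @export
backbone_dihedrals <- function(model) {
  stopifnot(inherits(model, "structure_model"))
  nres <- n_residues(model)
  if (nres < 3L) stop("model shorter than 3 residues")
  phi <- psi <- omega <- rep(NA_real_, nres)
  brk <- model$chain_breaks  # TRUE at i: break between i and i+1
  for (i in seq_len(nres)) {
    if (i > 1L && !brk[i - 1L])
      phi[i] <- dihedral(model$c[i - 1L, ], model$n[i, ], model$ca[i, ],
                         model$c[i, ])
    if (i < nres && !brk[i]) {
      psi[i] <- dihedral(model$n[i, ], model$ca[i, ], model$c[i, ],
                         model$n[i + 1L, ])
      omega[i] <- dihedral(model$ca[i, ], model$c[i, ], model$n[i + 1L, ],
                           model$ca[i + 1L, ])
    }
  }
  data.frame(phi = phi, psi = psi, omega = omega)
}

#' Ideal mirror image of a model
#'
#' Reflects every atom through the yz plane (x -> -x). All improper
#' operations are equivalent up to a proper rotation, which superposition
#' later absorbs, so one canonical reflection plane keeps outputs
#' reproducible. Reflection negates every chiral backbone dihedral.
#'
#' @param model a [structure_model].
#' @return the reflected [structure_model] (same id with suffix `_mirror`).
#' @export
mirror_reflect <- function(model) {
  stopifnot(inherits(model, "structure_model"))
  out <- model
  for (nm in c("n", "ca", "c", "o")) out[[nm]][, 1L] <- -out[[nm]][, 1L]
  out$id <- paste0(model$id, "_mirror")
  out
}

#' Kabsch superposition of paired point sets
#'
#' Least-squares proper rotation + translation mapping `mobile` onto
#' `target`. The SVD solution is corrected by the determinant sign so the
#' rotation can never be an improper (reflecting) transform — essential here,
#' since allowing a reflection would silently superpose mirror images.
#'
#' @param mobile,target numeric n x 3 matrices, paired by row, n >= 3.
#' @return list with `rotation` (3 x 3, det +1), `translation` (length-3
#'   vector), `rmsd` (Angstrom). The aligned mobile set is
#'   `mobile %*% t(rotation) + translation` (row-wise).
#' @export
kabsch_superpose <- function(mobile, target) {
  mobile <- as_coord_matrix(mobile, "mobile")
  target <- as_coord_matrix(target, "target")
  if (nrow(mobile) != nrow(target))
    stop("point count mismatch: ", nrow(mobile), " vs ", nrow(target))
  if (nrow(mobile) < 3L) stop("need at least 3 paired points")
  cm <- colMeans(mobile)
  ct <- colMeans(target)
  p <- sweep(mobile, 2L, cm)
  q <- sweep(target, 2L, ct)
  # degenerate (collinear) sets have a rank-deficient covariance; the SVD
  # still yields a valid minimizer, just not a unique one
  h <- crossprod(p, q)
  if (qr(p)$rank < 2L || qr(q)$rank < 2L)
    warning("degenerate (collinear) point set; superposition not unique")
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  aligned <- p %*% t(rot)
  rmsd <- sqrt(mean(rowSums((aligned - q)^2)))
  list(rotation = rot, translation = as.numeric(ct - cm %*% t(rot)),
       rmsd = rmsd)
}

#' CA RMSD between two equal-length models
#'
#' Optimal-superposition root mean square deviation over CA atoms paired by
#' residue order. CA-only RMSD is the standard fold-level comparison for
#' backbone reconstructions.
#'
#' @param model_a,model_b [structure_model]s with equal residue counts.
#' @return RMSD in Angstrom.
#' @export
ca_rmsd <- function(model_a, model_b) {
  stopifnot(inherits(model_a, "structure_model"),
            inherits(model_b, "structure_model"))
  if (n_residues(model_a) != n_residues(model_b))
    stop("residue count mismatch: ", n_residues(model_a), " vs ",
         n_residues(model_b))
  kabsch_superpose(model_a$ca, model_b$ca)$rmsd
}
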