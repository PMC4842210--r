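#' Phi+ ratio: fraction of positive backbone phi angles
#'
#' The chirality statistic: the count of residues with phi > 0 (strictly;
#' phi exactly 0 counts as non-positive) over all residues with a defined
#' phi. Right-handed helical folds sit near 0; their mirror images near 1.
#'
#' @param model a [structure_model].
#' @return list with `phi_plus_ratio`, `n_positive_phi`, `n_defined_phi`.
#' @export
phi_plus_ratio <- function(model) {
  d <- backbone_dihedrals(model)
  phi <- d$phi[!is.na(d$phi)]
  if (!length(phi)) stop("no defined phi angle in model")
  npos <- sum(phi > 0)
  list(phi_plus_ratio = npos / length(phi),
       n_positive_phi = npos, n_defined_phi = length(phi))
}

#' Assign model orientation by superposition against a reference
#'
#' Superposes the model on the reference and on the reference's ideal mirror
#' image (reflection through the yz plane) and labels it by whichever RMSD is
#' smaller. RMSDs within `tie_tol` of each other give `"ambiguous"` rather
#' than silently picking a side.
#'
#' @param model,reference [structure_model]s of equal length.
#' @param tie_tol ambiguity tolerance in Angstrom (default 1e-6).
#' @return list with `label` (`"proper"`, `"mirror"` or `"ambiguous"`),
#'   `rmsd_to_ref` and `rmsd_to_mirror_ref`.
#' @export
assign_orientation <- function(model, reference, tie_tol = 1e-6) {
  r_ref <- ca_rmsd(model, reference)
  r_mir <- ca_rmsd(model, mirror_reflect(reference))
  label <- if (abs(r_ref - r_mir) < tie_tol) "ambiguous"
           else if (r_ref < r_mir) "proper" else "mirror"
  list(label = label, rmsd_to_ref = r_ref, rmsd_to_mirror_ref = r_mir)
}

#' Reference-free proper/mirror separation by 1-D two-means clustering
#'
#' Splits per-model scores (by default a dihedral-based score such as the
#' rama analog) into two clusters with deterministic 2-means: centers start
#' at the minimum and maximum score and assignments are iterated to
#' convergence. For a right-handed native fold the lower-score cluster is
#' labeled proper; for a left-handed native the interpretation flips.
#'
#' @param scores numeric vector, one score per model, length >= 4.
#' @param handedness `"right"` or `"left"` — handedness of the native fold.
#' @return character vector of `"proper"` / `"mirror"` labels.
#' @export
separate_ensemble <- function(scores, handedness = c("right", "left")) {
  handedness <- match.arg(handedness)
  scores <- as.numeric(scores)
  if (length(scores) < 4L) stop("need at least 4 models to separate")
  if (diff(range(scores)) == 0) stop("no separation: all scores identical")
  centers <- range(scores)
  assign <- NULL
  for (it in 1:100) {
    new_assign <- ifelse(abs(scores - centers[1L]) <= abs(scores - centers[2L]),
                         1L, 2L)
    if (identical(new_assign, assign)) break
    assign <- new_assign
    for (k in 1:2)
      if (any(assign == k)) centers[k] <- mean(scores[assign == k])
  }
  low <- if (centers[1L] <= centers[2L]) 1L else 2L
  proper_cluster <- if (handedness == "right") low else 3L - low
  ifelse(assign == proper_cluster, "proper", "mirror")
}
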