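# Ramachandran tables and dihedral knowledge-based scores.
#
# The tables are NOT Rosetta's: they are generated from an analytic
# Gaussian-mixture prior over the canonical backbone basins (right-handed
# alpha, beta, PPII, and a low-weight left-handed alpha), with the four
# residue classes of the Rampage scheme (general, glycine, proline,
# pre-proline). Only relative proper-vs-mirror comparisons matter for
# orientation filtering, and those depend solely on the right-handed-dominant
# basin asymmetry; absolute score values do not match PyRosetta's.

# basins: phi_mu, psi_mu, sigma_phi, sigma_psi (degrees), weight.
# 'background' is a uniform floor weight over the whole torus.
.rama_basins <- function(class) {
  b <- function(...) {
    m <- rbind(...)
    colnames(m) <- c("phi", "psi", "sphi", "spsi", "w")
    m
  }
  switch(class,
    general = list(background = 0.025, basins = b(
      c(-63, -43, 11, 11, 0.530),   # right-handed alpha
      c(-120, 135, 25, 28, 0.280),  # beta
      c(-65, 145, 14, 14, 0.150),   # PPII
      c(57, 43, 11, 11, 0.015))),   # left-handed alpha (rare)
    glycine = list(background = 0.10, basins = b(
      c(-63, -41, 13, 13, 0.27),
      c(63, 41, 13, 13, 0.27),      # Gly populates LH-alpha symmetrically
      c(-85, 150, 25, 25, 0.18),
      c(85, -150, 25, 25, 0.18))),
    proline = list(background = 0.06, basins = b(
      c(-63, -35, 10, 13, 0.46),
      c(-63, 145, 10, 16, 0.48))),
    preproline = list(background = 0.04, basins = b(
      c(-63, -42, 11, 11, 0.40),
      c(-120, 130, 24, 26, 0.33),
      c(-65, 145, 13, 13, 0.17),
      c(55, 40, 10, 10, 0.02)))
  )
}

# wrapped (periodic) angular difference, degrees in [-180, 180)
ang_diff <- function(x, mu) ((x - mu + 180) %% 360) - 180

# mixture density on a phi x psi grid of cell centers; per squared degree
.mixture_density <- function(centers, spec) {
  nb <- length(centers)
  dens <- matrix(spec$background / 360^2, nb, nb)
  for (k in seq_len(nrow(spec$basins))) {
    p <- spec$basins[k, ]
    gphi <- exp(-0.5 * (ang_diff(centers, p[["phi"]]) / p[["sphi"]])^2)
    gphi <- gphi / (sqrt(2 * pi) * p[["sphi"]])
    gpsi <- exp(-0.5 * (ang_diff(centers, p[["psi"]]) / p[["spsi"]])^2)
    gpsi <- gpsi / (sqrt(2 * pi) * p[["spsi"]])
    dens <- dens + p[["w"]] * outer(gphi, gpsi)
  }
  dens
}

#' Build the Ramachandran region / density / P(aa | phi,psi) tables
#'
#' Deterministic analytic construction (no random numbers): basin mixtures
#' are evaluated on a `step`-degree grid, normalized so that
#' sum(density) * cell_area = 1, floored at `floor`, and region labels are
#' assigned Lovell-contour style by ranking cells by density and taking the
#' smallest set holding `favored_mass` (favored) and `allowed_mass`
#' (favored + allowed) of the probability, per residue class. The amino-acid
#' table P(aa | 10-degree bin) is derived from per-residue-type mixtures
#' (glycine symmetric, proline restricted, Asn/Asp with a mildly elevated
#' left-handed-alpha weight) with Laplace pseudocount 1.
#'
#' @param step region/density grid spacing, degrees (default 2).
#' @param paap_step amino-acid table bin size, degrees (default 10).
#' @param favored_mass,allowed_mass probability mass enclosed by the favored
#'   and allowed contours (defaults 0.70 and 0.95).
#' @param floor density floor applied before log scoring (default 1e-6 per
#'   squared degree).
#' @return an object of class `rama_tables`.
#' @export
build_rama_tables <- function(step = 2, paap_step = 10,
                              favored_mass = 0.70, allowed_mass = 0.95,
                              floor = 1e-6) {
  stopifnot(360 %% step == 0, 360 %% paap_step == 0,
            favored_mass < allowed_mass, allowed_mass < 1)
  nb <- as.integer(360 / step)
  centers <- -180 + step * (seq_len(nb) - 0.5)
  cell <- step^2
  classes <- c("general", "glycine", "proline", "preproline")
  density <- region <- stats::setNames(vector("list", 4L), classes)
  for (cl in classes) {
    d <- .mixture_density(centers, .rama_basins(cl))
    d <- d / (sum(d) * cell)
    d[d < floor] <- floor
    density[[cl]] <- d
    ord <- order(d, decreasing = TRUE)
    cum <- cumsum(d[ord] * cell)
    lab <- matrix(3L, nb, nb)   # outlier
    lab[ord[cum <= allowed_mass | seq_along(ord) == 1L]] <- 2L
    lab[ord[cum <= favored_mass | seq_along(ord) == 1L]] <- 1L
    region[[cl]] <- lab
  }

  # P(aa | bin): per-aa mixtures; non-Gly/Pro use the general basins with an
  # aa-specific left-handed-alpha weight
  npb <- as.integer(360 / paap_step)
  pcent <- -180 + paap_step * (seq_len(npb) - 0.5)
  aa <- names(.AA3)
  counts <- array(0, c(npb, npb, length(aa)), dimnames = list(NULL, NULL, aa))
  n_pseudo_obs <- 1e5
  for (j in seq_along(aa)) {
    a <- aa[j]
    spec <- if (a == "GLY") .rama_basins("glycine")
            else if (a == "PRO") .rama_basins("proline")
            else {
              s <- .rama_basins("general")
              lh <- if (a %in% c("ASN", "ASP")) 0.06 else 0.01
              w <- s$basins[, "w"]
              w[-4L] <- w[-4L] * (sum(w) - lh) / sum(w[-4L])
              w[4L] <- lh
              s$basins[, "w"] <- w
              s
            }
    d <- .mixture_density(pcent, spec)
    d <- d / sum(d)
    counts[, , j] <- d * n_pseudo_obs / length(aa) + 1  # Laplace pseudocount
  }
  tot <- apply(counts, c(1L, 2L), sum)
  aa_given_bin <- sweep(counts, c(1L, 2L), tot, "/")

  structure(
    list(step = step, centers = centers, density = density, region = region,
         paap_step = paap_step, paap_centers = pcent,
         aa_given_bin = aa_given_bin, floor = floor,
         favored_mass = favored_mass, allowed_mass = allowed_mass),
    class = "rama_tables")
}

#' Default (memoized) Ramachandran tables
#' @return the package's bundled `rama_tables`, built once per session.
#' @export
default_rama_tables <- function() {
  if (is.null(.mirrorsep_cache$tables))
    .mirrorsep_cache$tables <- build_rama_tables()
  .mirrorsep_cache$tables
}

#' @export
print.rama_tables <- function(x, ...) {
  cat("<rama_tables> ", x$step, "-degree region/density grids (",
      paste(names(x$density), collapse = ", "), "); ",
      x$paap_step, "-degree P(aa | phi,psi) table\n", sep = "")
  invisible(x)
}

# nearest-cell index on a periodic grid
.grid_index <- function(angle, step, nb) {
  (floor((angle + 180) / step) %% nb) + 1L
}

#' Classify a (phi, psi) pair into favored / allowed / outlier
#'
#' Nearest-grid-cell lookup in the region table of the given residue class.
#'
#' @param phi,psi angles in degrees; must be defined (non-NA).
#' @param residue_class one of `"general"`, `"glycine"`, `"proline"`,
#'   `"preproline"`.
#' @param tables a `rama_tables` object.
#' @return `"favored"`, `"allowed"` or `"outlier"`.
#' @export
classify_region <- function(phi, psi, residue_class = "general",
                            tables = default_rama_tables()) {
  if (is.na(phi) || is.na(psi))
    stop("undefined angle: cannot classify; caller must skip this residue")
  residue_class <- match.arg(residue_class, names(tables$region))
  nb <- length(tables$centers)
  lab <- tables$region[[residue_class]][.grid_index(phi, tables$step, nb),
                                        .grid_index(psi, tables$step, nb)]
  c("favored", "allowed", "outlier")[lab]
}

# per-residue Rampage-style class from the sequence: Gly, Pro, pre-Pro
# (overriding general only), else general
residue_classes <- function(model) {
  rn <- model$residue_names
  cl <- rep("general", length(rn))
  cl[rn == "GLY"] <- "glycine"
  cl[rn == "PRO"] <- "proline"
  pre <- which(rn == "PRO") - 1L
  pre <- pre[pre >= 1L]
  cl[pre][cl[pre] == "general"] <- "preproline"
  cl
}

#' Ramachandran region fractions of a model
#'
#' Percentage of residues (with both phi and psi defined) in the favored,
#' allowed and outlier regions, applying the Gly/Pro/pre-Pro classes by
#' sequence.
#'
#' @param model a [structure_model].
#' @param tables a `rama_tables` object.
#' @return list with `favored`, `allowed`, `outlier` percentages
#'   (sum = 100) and `n_classified`.
#' @export
region_fractions <- function(model, tables = default_rama_tables()) {
  d <- backbone_dihedrals(model)
  ok <- !is.na(d$phi) & !is.na(d$psi)
  if (!any(ok)) stop("no residue with both phi and psi defined")
  cls <- residue_classes(model)
  lab <- vapply(which(ok), function(i)
    classify_region(d$phi[i], d$psi[i], cls[i], tables), "")
  n <- sum(ok)
  list(favored = 100 * sum(lab == "favored") / n,
       allowed = 100 * sum(lab == "allowed") / n,
       outlier = 100 * sum(lab == "outlier") / n,
       n_classified = n)
}

#' Count residues in the left-handed alpha-helix region
#'
#' Operationalized as phi > 0 and psi > 0 (both defined): mirror models of
#' right-handed bundles push residues into this quadrant.
#'
#' @param model a [structure_model].
#' @return integer count.
#' @export
count_lh_alpha <- function(model) {
  d <- backbone_dihedrals(model)
  sum(!is.na(d$phi) & !is.na(d$psi) & d$phi > 0 & d$psi > 0)
}

# periodic bilinear interpolation of a density grid at (phi, psi)
.bilinear <- function(grid, centers, step, phi, psi) {
  nb <- length(centers)
  fx <- (phi - centers[1L]) / step
  fy <- (psi - centers[1L]) / step
  ix <- floor(fx); iy <- floor(fy)
  tx <- fx - ix;  ty <- fy - iy
  i0 <- (as.integer(ix) %% nb) + 1L; i1 <- (as.integer(ix + 1) %% nb) + 1L
  j0 <- (as.integer(iy) %% nb) + 1L; j1 <- (as.integer(iy + 1) %% nb) + 1L
  grid[cbind(i0, j0)] * (1 - tx) * (1 - ty) +
    grid[cbind(i1, j0)] * tx * (1 - ty) +
    grid[cbind(i0, j1)] * (1 - tx) * ty +
    grid[cbind(i1, j1)] * tx * ty
}

#' Ramachandran-preference score of a model (rama analog)
#'
#' Sum over classifiable residues of -ln density(phi, psi) for the residue's
#' class, with bilinear interpolation on the density grid and the density
#' floored at the table's epsilon. Lower is more native-like; for
#' right-handed references the mirror models score systematically higher.
#'
#' @param model a [structure_model].
#' @param tables a `rama_tables` object.
#' @return unitless score (sum of negative log densities).
#' @export
rama_score <- function(model, tables = default_rama_tables()) {
  d <- backbone_dihedrals(model)
  ok <- !is.na(d$phi) & !is.na(d$psi)
  if (!any(ok)) stop("no residue with both phi and psi defined")
  cls <- residue_classes(model)
  total <- 0
  for (cl in unique(cls[ok])) {
    sel <- ok & cls == cl
    dens <- .bilinear(tables$density[[cl]], tables$centers, tables$step,
                      d$phi[sel], d$psi[sel])
    dens[dens < tables$floor] <- tables$floor
    total <- total + sum(-log(dens))
  }
  total
}

#' Amino-acid-given-dihedral score of a model (p_aa_p analog)
#'
#' Sum over classifiable residues of -ln P(aa | phi,psi bin) from the
#' pseudocount-smoothed table. Unknown (nonstandard) residues contribute a
#' uniform P = 1/20 with a warning.
#'
#' @param model a [structure_model].
#' @param tables a `rama_tables` object.
#' @return unitless score.
#' @export
p_aa_p_score <- function(model, tables = default_rama_tables()) {
  d <- backbone_dihedrals(model)
  ok <- !is.na(d$phi) & !is.na(d$psi)
  if (!any(ok)) stop("no residue with both phi and psi defined")
  aa_names <- dimnames(tables$aa_given_bin)[[3L]]
  npb <- length(tables$paap_centers)
  idx <- which(ok)
  rn <- model$residue_names[idx]
  known <- rn %in% aa_names
  if (any(!known))
    warning(sum(!known), " residue(s) with unknown type scored as uniform 1/20")
  p <- rep(1 / length(aa_names), length(idx))
  if (any(known)) {
    bi <- .grid_index(d$phi[idx[known]], tables$paap_step, npb)
    bj <- .grid_index(d$psi[idx[known]], tables$paap_step, npb)
    p[known] <- tables$aa_given_bin[cbind(bi, bj, match(rn[known], aa_names))]
  }
  sum(-log(p))
}

#' Serialize Ramachandran tables to CSV files
#'
#' Writes one density and one region CSV matrix per residue class plus a long
#' CSV of the P(aa | bin) table into `dir`. [read_rama_tables()] inverts this.
#'
#' @param tables a `rama_tables` object.
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
write_rama_tables <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (cl in names(tables$density)) {
    utils::write.csv(tables$density[[cl]],
                     file.path(dir, paste0("density_", cl, ".csv")),
                     row.names = FALSE)
    utils::write.csv(tables$region[[cl]],
                     file.path(dir, paste0("region_", cl, ".csv")),
                     row.names = FALSE)
  }
  ab <- tables$aa_given_bin
  long <- expand.grid(phi_bin = seq_len(dim(ab)[1L]),
                      psi_bin = seq_len(dim(ab)[2L]),
                      aa = dimnames(ab)[[3L]], stringsAsFactors = FALSE)
  long$p <- ab[as.matrix(cbind(long$phi_bin, long$psi_bin,
                               match(long$aa, dimnames(ab)[[3L]])))]
  utils::write.csv(long, file.path(dir, "aa_given_bin.csv"), row.names = FALSE)
  meta <- data.frame(step = tables$step, paap_step = tables$paap_step,
                     floor = tables$floor, favored_mass = tables$favored_mass,
                     allowed_mass = tables$allowed_mass)
  utils::write.csv(meta, file.path(dir, "meta.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read Ramachandran tables previously written by [write_rama_tables()]
#' @param dir directory containing the CSV files.
#' @return a `rama_tables` object.
#' @export
read_rama_tables <- function(dir) {
  meta <- utils::read.csv(file.path(dir, "meta.csv"))
  nb <- as.integer(360 / meta$step)
  classes <- c("general", "glycine", "proline", "preproline")
  density <- region <- stats::setNames(vector("list", 4L), classes)
  for (cl in classes) {
    density[[cl]] <- unname(as.matrix(utils::read.csv(
      file.path(dir, paste0("density_", cl, ".csv")))))
    region[[cl]] <- unname(as.matrix(utils::read.csv(
      file.path(dir, paste0("region_", cl, ".csv")))))
    storage.mode(region[[cl]]) <- "integer"
  }
  long <- utils::read.csv(file.path(dir, "aa_given_bin.csv"),
                          stringsAsFactors = FALSE)
  npb <- as.integer(360 / meta$paap_step)
  aa <- sort(unique(long$aa))
  ab <- array(NA_real_, c(npb, npb, length(aa)),
              dimnames = list(NULL, NULL, aa))
  ab[cbind(long$phi_bin, long$psi_bin, match(long$aa, aa))] <- long$p
  structure(
    list(step = meta$step, centers = -180 + meta$step * (seq_len(nb) - 0.5),
         density = density, region = region, paap_step = meta$paap_step,
         paap_centers = -180 + meta$paap_step * (seq_len(npb) - 0.5),
         aa_given_bin = ab, floor = meta$floor,
         favored_mass = meta$favored_mass, allowed_mass = meta$allowed_mass),
    class = "rama_tables")
}
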