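# independent vector-algebra oracle for the torsion sign convention:
# project p1 and p4 onto the plane normal to the p2->p3 axis and measure the
# signed rotation from the p1 projection to the p4 projection about that
# axis (the convention Biopython's calc_dihedral follows)
dihedral_oracle <- function(p1, p2, p3, p4) {
  axis <- (p3 - p2) / sqrt(sum((p3 - p2)^2))
  u <- p1 - p2; u <- u - sum(u * axis) * axis
  w <- p4 - p3; w <- w - sum(w * axis) * axis
  ang <- atan2(sum(cross_oracle(axis, u) * w), sum(u * w)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}
cross_oracle <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

test_that("dihedral reproduces coplanar and orthogonal geometry", {
  expect_equal(dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)), 0)
  expect_equal(dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0)), 180)
  # orthogonal case: magnitude 90, sign frozen from the independent oracle
  p <- list(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 0, 1))
  expected <- dihedral_oracle(p[[1]], p[[2]], p[[3]], p[[4]])
  expect_equal(abs(expected), 90)
  expect_equal(dihedral(p[[1]], p[[2]], p[[3]], p[[4]]), expected)
  expect_error(dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "collinear")
})

test_that("dihedral antisymmetry and mirror properties hold on random points", {
  set.seed(42)
  for (i in 1:25) {
    p <- lapply(1:4, function(j) rnorm(3))
    a <- dihedral(p[[1]], p[[2]], p[[3]], p[[4]])
    expect_gt(a, -180); expect_lte(a, 180)
    # path reversal preserves the angle
    expect_equal(dihedral(p[[4]], p[[3]], p[[2]], p[[1]]), a,
                 tolerance = 1e-10)
    # reflection negates it
    q <- lapply(p, function(v) c(-v[1], v[2], v[3]))
    expect_equal(dihedral(q[[1]], q[[2]], q[[3]], q[[4]]), -a,
                 tolerance = 1e-10)
    # agreement with the independent projection oracle
    expect_equal(a, dihedral_oracle(p[[1]], p[[2]], p[[3]], p[[4]]),
                 tolerance = 1e-9)
  }
})

test_that("backbone_dihedrals recovers generator angles and break policy", {
  m <- make_helix(12)
  d <- backbone_dihedrals(m)
  expect_equal(d$phi[-1L], rep(-57, 11), tolerance = 1e-6)
  expect_equal(d$psi[-12L], rep(-47, 11), tolerance = 1e-6)
  expect_true(is.na(d$phi[1L]) && is.na(d$psi[12L]))

  # minimal chain: phi defined for residues 2..n, psi for 1..n-1, so only
  # the middle residue of a 3-residue chain carries both angles
  m3 <- make_helix(3)
  d3 <- backbone_dihedrals(m3)
  expect_equal(sum(!is.na(d3$phi)), 2L)
  expect_equal(sum(!is.na(d3$psi)), 2L)
  expect_equal(sum(!is.na(d3$phi) & !is.na(d3$psi)), 1L)

  mb <- make_helix(10)
  mb$chain_breaks[5L] <- TRUE
  db <- backbone_dihedrals(mb)
  expect_true(is.na(db$psi[5L]) && is.na(db$omega[5L]) && is.na(db$phi[6L]))
})

test_that("mirror_reflect negates dihedrals and is an involution", {
  m <- make_helix(15)
  d <- backbone_dihedrals(m)
  dm <- backbone_dihedrals(mirror_reflect(m))
  ok <- !is.na(d$phi)
  expect_equal(dm$phi[ok], -d$phi[ok], tolerance = 1e-9)
  ok <- !is.na(d$psi)
  expect_equal(dm$psi[ok], -d$psi[ok], tolerance = 1e-9)
  m2 <- mirror_reflect(mirror_reflect(m))
  expect_equal(m2$ca, m$ca)
  # a chiral object differs from its mirror image
  expect_gt(ca_rmsd(m, mirror_reflect(m)), 0.5)
})

# brute-force superposition oracle for coplanar point sets
grid_rmsd_oracle <- function(mobile, target, step = 0.01) {
  # for coplanar (z = 0) sets every proper rotation mapping the plane to
  # itself is either an in-plane rotation Rz(t) or Rz(t) composed with a
  # half-turn about an in-plane axis (which acts in-plane as a reflection);
  # scan both branches at 0.01 degrees
  p <- sweep(mobile, 2, colMeans(mobile))
  q <- sweep(target, 2, colMeans(target))
  th <- seq(0, 360 - step, by = step) * pi / 180
  flip <- diag(c(1, -1, -1))
  best <- Inf
  for (t in th) {
    r <- matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
    best <- min(best, mean(rowSums((p %*% r - q)^2)),
                mean(rowSums((p %*% (flip %*% r) - q)^2)))
  }
  sqrt(best)
}

test_that("kabsch_superpose matches identity, rigid motion and grid oracle", {
  set.seed(7)
  pts <- matrix(rnorm(30), 10, 3)
  expect_lt(kabsch_superpose(pts, pts)$rmsd, 1e-9)

  th <- 0.9
  rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- pts %*% rot + matrix(c(3, -2, 5), 10, 3, byrow = TRUE)
  sup <- kabsch_superpose(pts, moved)
  expect_lt(sup$rmsd, 1e-9)
  expect_equal(det(sup$rotation), 1, tolerance = 1e-9)
  # aligned coordinates really land on the target
  aligned <- pts %*% t(sup$rotation) +
    matrix(sup$translation, 10, 3, byrow = TRUE)
  expect_equal(aligned, moved, tolerance = 1e-9)

  square <- cbind(c(0.5, -0.5, -0.5, 0.5), c(0.5, 0.5, -0.5, -0.5), 0)
  rect <- cbind(c(0.5, -0.5, -0.5, 0.5), c(1, 1, -1, -1), 0)
  expect_equal(kabsch_superpose(square, rect)$rmsd,
               grid_rmsd_oracle(square, rect), tolerance = 1e-4)
})

test_that("kabsch rotation stays proper even when a reflection fits better", {
  set.seed(11)
  pts <- matrix(rnorm(24), 8, 3)
  reflected <- pts %*% diag(c(-1, 1, 1))
  sup <- kabsch_superpose(pts, reflected)
  expect_equal(det(sup$rotation), 1, tolerance = 1e-9)
  expect_gt(sup$rmsd, 0.1)  # cannot be superposed by a proper rotation
})

test_that("rmsd behaves as a pseudo-metric on random triples", {
  set.seed(21)
  for (i in 1:10) {
    a <- matrix(rnorm(18), 6, 3)
    b <- matrix(rnorm(18), 6, 3)
    cc <- matrix(rnorm(18), 6, 3)
    rab <- kabsch_superpose(a, b)$rmsd
    expect_equal(rab, kabsch_superpose(b, a)$rmsd, tolerance = 1e-9)
    expect_lte(kabsch_superpose(a, cc)$rmsd,
               rab + kabsch_superpose(b, cc)$rmsd + 1e-9)
  }
})

test_that("ca_rmsd grows with dihedral noise", {
  ref <- make_helix(25)
  means <- vapply(c(1, 5, 10), function(s) {
    r <- vapply(1:10, function(k) {
      set.seed(100 * s + k)
      ca_rmsd(perturb(ref, s), ref)
    }, 0)
    mean(r)
  }, 0)
  expect_equal(ca_rmsd(ref, ref), 0, tolerance = 1e-9)
  expect_true(all(diff(means) > 0))
  expect_true(all(means > 0))
})
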