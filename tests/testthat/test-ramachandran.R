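tb <- default_rama_tables()

test_that("classify_region places canonical basins correctly", {
  # right-handed alpha basin center is favored for general residues
  expect_equal(classify_region(-63, -43, "general", tb), "favored")
  # its reflection is populated only by the low-weight LH basin: not favored
  expect_true(classify_region(63, 43, "general", tb) %in%
                c("allowed", "outlier"))
  # glycine is symmetric: LH-alpha is a genuine glycine basin
  expect_equal(classify_region(63, 41, "glycine", tb), "favored")
  # grid boundary never fails and matches the wrapped corner cell
  expect_equal(classify_region(-180, -180, "general", tb),
               classify_region(-179.9, -179.9, "general", tb))
  expect_error(classify_region(NA, 50, "general", tb), "undefined")
})

test_that("region_fractions partition to 100 and detect mirrored helices", {
  m <- make_helix(30)
  rf <- region_fractions(m, tb)
  expect_equal(rf$favored, 100)
  expect_equal(rf$favored + rf$allowed + rf$outlier, 100, tolerance = 1e-9)

  rfm <- region_fractions(mirror_reflect(m), tb)
  expect_lt(rfm$favored, 100)
  expect_gt(rfm$allowed + rfm$outlier, 0)
  expect_equal(rfm$favored + rfm$allowed + rfm$outlier, 100, tolerance = 1e-9)

  set.seed(3)
  mr <- perturb(m, 25, 0.3)
  rr <- region_fractions(mr, tb)
  expect_equal(rr$favored + rr$allowed + rr$outlier, 100, tolerance = 1e-9)
})

test_that("count_lh_alpha counts the positive-positive quadrant", {
  m <- make_helix(20)
  expect_equal(count_lh_alpha(m), 0L)
  mm <- mirror_reflect(m)
  d <- backbone_dihedrals(mm)
  expect_equal(count_lh_alpha(mm), sum(!is.na(d$phi) & !is.na(d$psi)))

  phi <- rep(-57, 20); psi <- rep(-47, 20)
  phi[10] <- 57; psi[10] <- 47
  one <- build_chain(strrep("A", 20), phi, psi)
  expect_equal(count_lh_alpha(one), 1L)
})

test_that("rama_score depends only on dihedrals and penalizes mirrors", {
  m1 <- build_chain(strrep("A", 15), rep(-60, 15), rep(-45, 15))
  m2 <- build_chain(paste0(strrep("K", 7), strrep("E", 8)),
                    rep(-60, 15), rep(-45, 15))
  expect_equal(rama_score(m1, tb), rama_score(m2, tb), tolerance = 1e-9)

  bundle <- make_helix(40)
  expect_lt(rama_score(bundle, tb), rama_score(mirror_reflect(bundle), tb))
})

test_that("rama_score interpolation is exact at grid nodes and additive", {
  # constant-density table: score must reduce to n * (-ln density)
  flat <- tb
  for (cl in names(flat$density))
    flat$density[[cl]][] <- 1 / 360^2
  m <- make_helix(12)
  n_def <- sum(!is.na(backbone_dihedrals(m)$phi[-1]))  # residues with both
  expect_equal(rama_score(m, flat), 10 * (-log(1 / 360^2)), tolerance = 1e-9)

  # bilinear interpolation hits table values exactly at cell centers
  dens <- tb$density$general
  i <- 37L; j <- 55L
  val <- mirrorsep:::.bilinear(dens, tb$centers, tb$step,
                               tb$centers[i], tb$centers[j])
  expect_equal(val, dens[i, j], tolerance = 1e-12)
})

test_that("p_aa_p_score handles uniform tables and mirrors", {
  uni <- tb
  uni$aa_given_bin[] <- 1 / 20
  m <- make_helix(12)   # 10 residues with both angles defined
  expect_equal(p_aa_p_score(m, uni), 10 * log(20), tolerance = 1e-9)

  # same dihedrals and sequence => same score
  expect_equal(p_aa_p_score(m, tb), p_aa_p_score(make_helix(12), tb))

  # proper vs mirror groups at sigma = 8: group mean ratio < 1
  spec <- small_spec(seed = 5, n_proper = 6, n_mirror = 6, dihedral_sigma = 8)
  ens <- make_ensemble(spec)
  sc <- vapply(ens$models, p_aa_p_score, 0, tables = tb)
  ratio <- mean(sc[ens$labels == "proper"]) / mean(sc[ens$labels == "mirror"])
  expect_lt(ratio, 1)
})

test_that("rama tables survive CSV serialization round trip", {
  dir <- tempfile()
  write_rama_tables(tb, dir)
  tb2 <- read_rama_tables(dir)
  expect_equal(tb2$density$general, tb$density$general, tolerance = 1e-12)
  expect_equal(tb2$region$glycine, tb$region$glycine)
  expect_equal(tb2$aa_given_bin[, , "ALA"], tb$aa_given_bin[, , "ALA"],
               tolerance = 1e-12)
  m <- make_helix(10)
  expect_equal(rama_score(m, tb2), rama_score(m, tb), tolerance = 1e-9)
})

test_that("residue classes follow the Gly/Pro/pre-Pro scheme", {
  m <- build_chain("AAGPAA", rep(-60, 6), rep(-45, 6))
  expect_equal(mirrorsep:::residue_classes(m),
               c("general", "general", "glycine", "proline", "general",
                 "general"))
  # pre-proline overrides general only
  m2 <- build_chain("AAPG", rep(-60, 4), rep(-45, 4))
  expect_equal(mirrorsep:::residue_classes(m2)[2L], "preproline")
})
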