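one_atom <- function(x = 0, y = 0, z = 0, element = "C", radius = NULL) {
  df <- tibble::tibble(element = element, chain = "A", resid = "GLY",
                       resno = 1L, x = x, y = y, z = z)
  if (!is.null(radius)) df$radius <- radius
  df
}

test_that("atom sets validate elements, radii and coordinates", {
  expect_error(atom_set(one_atom(element = "X")), "X",
               class = "chromakit_error")
  a <- atom_set(one_atom(element = "X"), radii = c(X = 2.2))
  expect_equal(a$radius, 2.2)
  expect_error(atom_set(one_atom(x = Inf)), class = "chromakit_error")
  expect_equal(atom_set(one_atom(element = "P"))$radius, 1.80)
})

test_that("a lone sphere reproduces the analytic surface area within 1 percent", {
  a <- atom_set(one_atom())
  total <- sum(sasa(a, probe_radius = 1.4, n_points = 960)$sasa)
  expect_lt(abs(total - 4 * pi * 3.1^2) / (4 * pi * 3.1^2), 0.01)
})

test_that("well-separated atoms contribute independently", {
  df <- dplyr::bind_rows(one_atom(), one_atom(x = 100))
  df$resno <- 1:2
  total <- sum(sasa(atom_set(df), 1.4, 960)$sasa)
  single <- sum(sasa(atom_set(one_atom()), 1.4, 960)$sasa)
  expect_equal(total, 2 * single, tolerance = 1e-9)
})

test_that("an atom caged by a closed shell has zero accessible surface", {
  shell_pts <- chromakit:::sphere_points(80) * 3.4
  df <- dplyr::bind_rows(
    one_atom(),
    tibble::tibble(element = "C", chain = "B", resid = "SHL",
                   resno = 2:81, x = shell_pts[, 1], y = shell_pts[, 2],
                   z = shell_pts[, 3]))
  res <- sasa(atom_set(df), probe_radius = 1.4, n_points = 960)
  expect_equal(res$sasa[1], 0)
  # brute-force all-pairs oracle at 10x point density agrees
  oracle <- oracle_sasa_total(atom_set(df), 1.4, 9600,
                              select = seq_len(nrow(df)) == 1)
  expect_equal(oracle, 0)
})

test_that("SASA converges in point density and is invariant to rigid motion", {
  toy <- make_toy_complex(20, 36, occluder = list(center = c(30, 0, 5),
                                                  radius = 18))
  t960 <- sum(sasa(toy$bound, 5, 960)$sasa)
  t3840 <- sum(sasa(toy$bound, 5, 3840)$sasa)
  expect_lt(abs(t960 - t3840) / t3840, 0.005)
  # translation leaves the deterministic point construction untouched
  shifted <- toy$bound
  shifted$x <- shifted$x + 11.3
  shifted$y <- shifted$y - 4.2
  shifted$z <- shifted$z + 0.9
  expect_equal(sum(sasa(shifted, 5, 960)$sasa), t960, tolerance = 1e-9)
  # rotation re-aligns the fixed sphere points against the geometry, so
  # agreement is limited by the point discretization, not exact
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xyz <- as.matrix(toy$bound[, c("x", "y", "z")]) %*% R
  rotated <- toy$bound
  rotated$x <- xyz[, 1]
  rotated$y <- xyz[, 2]
  rotated$z <- xyz[, 3]
  t_rot <- sum(sasa(rotated, 5, 960)$sasa)
  expect_lt(abs(t_rot - t960) / t960, 0.005)
})

test_that("adding context atoms never increases the selection's surface", {
  toy <- make_toy_complex(20, 24)
  base <- sum(sasa(toy$free, 10, 480)$sasa)
  withr::with_seed(31, {
    for (i in 1:5) {
      extra <- one_atom(x = runif(1, -30, 30), y = runif(1, -30, 30),
                        z = runif(1, -10, 10), radius = runif(1, 2, 12))
      extra$chain <- "Z"
      grown <- atom_set(dplyr::bind_rows(as.data.frame(toy$free), extra))
      with_extra <- sum(sasa(grown, 10, 480)$sasa[seq_len(24)])
      expect_lte(with_extra, base + 1e-9)
    }
  })
})

test_that("probe sweep ratios behave at the identity and no-occlusion limits", {
  toy_id <- make_toy_complex(40, 48)
  sw <- probe_sweep_ratio(toy_id$free, toy_id$bound, radii = c(5, 20, 30),
                          n_points = 480)
  expect_true(all(abs(sw$ratio - 1) < 1e-12))
  toy_far <- make_toy_complex(40, 48,
                              occluder = list(center = c(1100, 0, 0),
                                              radius = 60))
  sw_far <- probe_sweep_ratio(toy_far$free, toy_far$bound,
                              radii = c(5, 30), n_points = 480)
  expect_true(all(abs(sw_far$ratio - 1) < 1e-12))
})

test_that("a half-occluded ring doubles the inaccessibility, matching the dense oracle", {
  # a 1000 A occluder sphere tangent to the origin approximates the
  # half-space x > 0: half of the 150 A ring is buried
  toy <- make_toy_complex(150, 150,
                          occluder = list(center = c(1000, 0, 0),
                                          radius = 1000))
  sw <- probe_sweep_ratio(toy$free, toy$bound, radii = 20, n_points = 960)
  sel_bound <- toy$bound$chain == "D"
  oracle_ratio <- oracle_sasa_total(toy$free, 20, 2400) /
    oracle_sasa_total(toy$bound, 20, 2400, sel_bound)
  expect_lt(abs(sw$ratio - oracle_ratio) / oracle_ratio, 0.10)
  expect_gt(sw$ratio, 1.7)
  expect_lt(sw$ratio, 2.4)
})

test_that("the free-over-bound ratio grows with probe size on the half-occluded ring", {
  toy <- make_toy_complex(150, 100,
                          occluder = list(center = c(1000, 0, 0),
                                          radius = 1000))
  sw <- probe_sweep_ratio(toy$free, toy$bound, radii = c(5, 10, 20, 30),
                          n_points = 480)
  expect_true(all(diff(sw$ratio) >= -1e-9))
})

test_that("probe sweep validates the selection contract", {
  toy <- make_toy_complex(30, 24, occluder = list(center = c(40, 0, 0),
                                                  radius = 20))
  expect_error(probe_sweep_ratio(toy$free, toy$bound, selection = "XX"),
               class = "chromakit_error")
  shifted <- toy$free
  shifted$x <- shifted$x + 1
  expect_error(probe_sweep_ratio(shifted, toy$bound, radii = 10),
               class = "chromakit_error")
})

test_that("PDB and mmCIF renderings of the same atoms parse identically", {
  skip_if_not_installed("bio3d")
  pdb_path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    sprintf("ATOM  %5d  P   DA  D%4d    %8.3f%8.3f%8.3f  1.00  0.00           P",
            1:3, 1:3, c(10, 20, 30), c(1, 2, 3), c(0, 0, 0)),
    "END"), pdb_path)
  at <- read_structure(pdb_path)
  expect_equal(nrow(at), 3)
  expect_equal(at$x, c(10, 20, 30))
  expect_equal(at$element, c("P", "P", "P"))
  expect_equal(at$radius, rep(1.80, 3))

  cif_path <- withr::local_tempfile(fileext = ".cif")
  writeLines(c(
    "data_toy",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_entity_id",
    "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    sprintf("ATOM %d P P . DA D 1 %d ? %.3f %.3f %.3f 1.00 0.00 ? %d DA D P 1",
            1:3, 1:3, c(10, 20, 30), c(1, 2, 3), c(0, 0, 0), 1:3)),
    cif_path)
  at_cif <- read_structure(cif_path)
  expect_equal(at_cif$x, at$x)
  expect_equal(at_cif$y, at$y)
  expect_equal(at_cif$element, at$element)
})
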