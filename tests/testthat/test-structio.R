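test_that("single-atom PDB fixture parses to its printed coordinates", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1      11.104  13.207   2.100  1.00  0.00           C",
    "END"), path)
  m <- read_structure(path)
  expect_equal(nrow(m$atoms), 1)
  expect_equal(unname(coords(m)[1, ]), c(11.104, 13.207, 2.100))
  expect_equal(m$atoms$chain, "A")
  expect_equal(m$atoms$resno, 1L)
})

test_that("write/read round trip preserves chains, residues and coordinates", {
  m <- make_fixture_structure("cloud", n_res = 3, n_chains = 2, seed = 4)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(m, path)
  m2 <- read_structure(path)
  expect_setequal(unique(m2$atoms$chain), c("A", "B"))
  expect_equal(nrow(m2$atoms), 6)
  expect_equal(m2$atoms$resno, m$atoms$resno)
  expect_equal(coords(m2), coords(m), tolerance = 1e-3)
})

test_that("multi-model files warn and use the first model", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL        1",
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  CA  ALA A   1       9.000   9.000   9.000  1.00  0.00           C",
    "ENDMDL", "END"), path)
  expect_warning(m <- read_structure(path), "first model")
  expect_equal(unname(coords(m)[1, ]), c(1, 2, 3))
})

test_that("altloc conformers reduce to the highest-occupancy one", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       1.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       2.000   0.000   0.000  0.60  0.00           C",
    "END"), path)
  m <- read_structure(path)
  expect_equal(nrow(m$atoms), 1)
  expect_equal(m$atoms$x, 2)
})

test_that("residue_anchor returns CA, falls back to centre, and errors informatively", {
  xyz <- rbind(c(1, 2, 3), c(4, 5, 6))
  m <- structure_model(data.frame(
    chain = "A", resno = c(10, 10), resid = "GLY",
    elety = c("CA", "N"), elesy = c("C", "N"),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], o = 1))
  a <- residue_anchor(m, "A", 10)
  expect_equal(as.numeric(a), c(1, 2, 3))
  expect_equal(attr(a, "anchor"), "atom")
  # ligand-like residue without CA -> geometric centre, flagged
  lig <- structure_model(data.frame(
    chain = "A", resno = 99, resid = "LIG", elety = c("C1", "C2"),
    elesy = "C", x = c(0, 2), y = 0, z = 0, o = 1))
  ctr <- residue_anchor(lig, "A", 99)
  expect_equal(as.numeric(ctr), c(1, 0, 0))
  expect_equal(attr(ctr, "anchor"), "center")
  # absent residue: error names the residue range present
  rng <- point_model(matrix(rnorm(33), ncol = 3), resno = 10:20)
  expect_error(residue_anchor(rng, "A", 25), "10-20")
})

test_that("max_pairwise_distance is exact against the brute-force oracle", {
  m <- point_model(rbind(c(0, 0, 0), c(3, 4, 0)))
  expect_equal(max_pairwise_distance(m), 5)
  set.seed(42)
  xyz <- matrix(rnorm(150, sd = 20), ncol = 3)
  m50 <- point_model(xyz)
  expect_equal(max_pairwise_distance(m50), brute_max_dist(xyz))
  expect_error(max_pairwise_distance(point_model(matrix(0, 1, 3))),
               "at least 2")
})

test_that("distances are invariant under rigid-body transformation", {
  m <- make_fixture_structure("cloud", n_res = 40, seed = 7)
  th <- 0.83
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  mt <- transform_model(m, R, c(12.3, -4.5, 67.8))
  expect_equal(max_pairwise_distance(mt), max_pairwise_distance(m),
               tolerance = 1e-9)
})

test_that("parse_symop reproduces hand-applied operators", {
  op <- parse_symop("-X,Y+1/2,-Z")
  f <- c(0.2, 0.3, 0.4)
  expect_equal(as.numeric(op$R %*% f) + op$t, c(-0.2, 0.8, -0.4))
  op2 <- parse_symop("Y,-X,Z+3/4")
  expect_equal(as.numeric(op2$R %*% f) + op2$t, c(0.3, -0.2, 1.15))
})

test_that("symmetry expansion: P1 small radius yields identity only", {
  m <- structure_model(atoms_df(matrix(c(5, 5, 5), 1)),
                       cell = c(50, 50, 50, 90, 90, 90),
                       symops = list(parse_symop("X,Y,Z")))
  ex <- symmetry_expand(m, center = c(5, 5, 5), radius = 10)
  expect_length(ex, 1)
  expect_true(ex[[1]]$is_identity)
})

test_that("symmetry expansion reproduces the hand-applied screw operator", {
  m <- structure_model(atoms_df(matrix(c(2, 3, 4), 1)),
                       cell = c(10, 10, 10, 90, 90, 90),
                       symops = list(parse_symop("X,Y,Z"),
                                     parse_symop("-X,Y+1/2,-Z")))
  ex <- symmetry_expand(m, center = c(2, 3, 4), radius = 11)
  copies <- t(vapply(ex, function(e) as.numeric(coords(e$model)), numeric(3)))
  # fractional (0.2,0.3,0.4) -> (-0.2,0.8,-0.4) -> cartesian (-2,8,-4)
  expect_true(any(apply(copies, 1, function(x)
    isTRUE(all.equal(x, c(-2, 8, -4))))))
})

test_that("symmetry expansion copy count matches brute-force lattice enumeration", {
  m <- make_crystal_fixture(n_res = 5, cell = c(20, 20, 20, 90, 90, 90),
                            seed = 3)
  radius <- 40  # 2 x cell edge
  center <- colMeans(coords(m))
  ex <- symmetry_expand(m, center, radius, lattice_range = 2)
  # oracle: enumerate ops x 5^3 shifts, count copies with an atom in range
  M <- cell_matrix(m$cell)
  frac <- coords(m) %*% t(solve(M))
  n_expected <- 0
  for (op in m$symops) {
    f1 <- sweep(frac %*% t(op$R), 2, op$t, "+")
    for (n1 in -2:2) for (n2 in -2:2) for (n3 in -2:2) {
      xyz <- sweep(f1, 2, c(n1, n2, n3), "+") %*% t(M)
      d <- sqrt(colSums((t(xyz) - center)^2))
      is_id <- isTRUE(all.equal(op$R, diag(3))) &&
        isTRUE(all.equal(as.numeric(op$t), c(0, 0, 0))) &&
        n1 == 0 && n2 == 0 && n3 == 0
      if (is_id || min(d) <= radius) n_expected <- n_expected + 1
    }
  }
  expect_equal(length(ex), n_expected)
  expect_error(symmetry_expand(m, center, Inf), "finite")
})

test_that("min distance over symmetry mates never exceeds the identity distance", {
  m <- make_crystal_fixture(n_res = 10, seed = 9)
  for (pair in list(c(1, 5), c(2, 9), c(3, 10))) {
    d_id <- sqrt(sum((residue_anchor(m, "A", pair[1]) -
                        residue_anchor(m, "A", pair[2]))^2))
    d_sym <- brute_sym_min_dist(m, "A", pair[1], "A", pair[2],
                                lattice_range = 1)
    expect_lte(d_sym, d_id + 1e-9)
  }
})

test_that("models without a cell refuse symmetry expansion with guidance", {
  m <- point_model(rbind(c(0, 0, 0), c(1, 1, 1)))
  expect_error(symmetry_expand(m, c(0, 0, 0), 10), "single-copy")
})

test_that("structure_model validates addresses and the identity operator", {
  xyz <- rbind(c(0, 0, 0), c(1, 0, 0))
  expect_error(point_model(xyz, resno = c(1, 1)), "duplicate")
  expect_error(structure_model(atoms_df(matrix(c(NA, 0, 0), 1))),
               "finite")
  expect_error(structure_model(atoms_df(matrix(0, 1, 3)),
                               cell = c(10, 10, 10, 90, 90, 90),
                               symops = list(parse_symop("-X,Y,-Z"))),
               "identity")
})
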