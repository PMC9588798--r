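test_that("PDB parsing reads back hand-written records and round-trips", {
  path <- write_mini_pdb()
  m <- load_model(path)
  expect_s3_class(m, "atomic_model")
  expect_equal(nrow(m$atoms), 6)
  expect_equal(sort(unique(m$atoms$chain)), c("A", "B"))
  expect_equal(atom_coord(m, "A", 1, "N"), c(1, 2, 3))
  expect_equal(atom_coord(m, "B", 7, "CA"), c(-1, 0, 5))
  out <- tempfile(fileext = ".pdb")
  write_model(m, out)
  m2 <- load_model(out)
  expect_equal(m2$atoms[, c("chain", "resno", "elety", "x", "y", "z")],
               m$atoms[, c("chain", "resno", "elety", "x", "y", "z")],
               ignore_attr = TRUE)
})

test_that("mmCIF parsing agrees with the PDB reader on shared fields", {
  m <- load_model(write_mini_cif(), format = "mmcif")
  expect_equal(nrow(m$atoms), 3)
  expect_equal(atom_coord(m, "A", 1, "N"), c(1, 2, 3))
  expect_equal(atom_coord(m, "A", 2, "CA"), c(5.1, 3.6, 3.4))
})

test_that("unreadable and empty inputs raise informative errors", {
  expect_error(load_model(tempfile()), "not found")
  bad <- tempfile(fileext = ".pdb")
  writeLines(c("REMARK nothing here", "END"), bad)
  expect_error(load_model(bad), "empty model|parse")
  m <- load_model(write_mini_pdb())
  expect_error(select_atoms(m, domain_selection("Z", c(1, 5))), "no atoms")
  expect_error(atom_distance(m, list("A", 1, "N"), list("A", 99, "CA")),
               "no such atom.*resno 99")
})

test_that("atom distances satisfy Pythagoras and the triangle inequality", {
  m <- model_from_xyz(rbind(c(0, 0, 0), c(3, 4, 0), c(-2, 1, 7)))
  a <- list("A", 1); b <- list("A", 2); cc <- list("A", 3)
  expect_equal(atom_distance(m, a, a), 0)
  expect_equal(atom_distance(m, a, b), 5)
  expect_equal(atom_distance(m, a, b), atom_distance(m, b, a))
  set.seed(11)
  for (i in 1:25) {
    mm <- model_from_xyz(matrix(rnorm(9, sd = 10), 3, 3))
    d12 <- atom_distance(mm, a, b); d13 <- atom_distance(mm, a, cc)
    d23 <- atom_distance(mm, b, cc)
    expect_lte(d13, d12 + d23 + 1e-12)
  }
})

test_that("extended-linker length is linear at 3.5 A per residue", {
  expect_equal(max_extended_length(0), 0)
  expect_equal(max_extended_length(1), 3.5)
  expect_equal(max_extended_length(8), 28)
  n <- 0:20
  expect_equal(max_extended_length(n), n * 3.5)
  expect_error(max_extended_length(-1), ">= 0")
})

test_that("superposition is exact on itself and invariant under rigid motion", {
  set.seed(3)
  A <- matrix(rnorm(36, sd = 6), 12, 3)
  ma <- model_from_xyz(A)
  self <- superpose(ma, ma)
  expect_equal(self$rmsd, 0, tolerance = 1e-12)
  expect_equal(self$R, diag(3), tolerance = 1e-9)
  # rigidly moved copy superposes to zero
  R <- rotation_matrix(c(2, -1, 5), 71)
  B <- t(R %*% t(A)) + matrix(c(10, -4, 2), 12, 3, byrow = TRUE)
  expect_lt(superpose(ma, model_from_xyz(B))$rmsd, 1e-9)
  # rmsd of a noisy pair is invariant under a common rigid transform
  Bn <- A + matrix(rnorm(36, sd = 0.5), 12, 3)
  r0 <- superpose(ma, model_from_xyz(Bn))$rmsd
  Q <- rotation_matrix(c(0, 1, 1), -33)
  A2 <- t(Q %*% t(A)) + 5
  B2 <- t(Q %*% t(Bn)) + 5
  r1 <- superpose(model_from_xyz(A2), model_from_xyz(B2))$rmsd
  expect_equal(r0, r1, tolerance = 1e-9)
})

test_that("superposition rmsd matches a dense rotation-grid oracle in 2D", {
  # 4-point square vs the same square with one corner displaced by 0.4 A;
  # planar problem, so the optimum is a rotation about z plus translation
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1), 0)
  sq2 <- sq
  sq2[3, 1:2] <- sq2[3, 1:2] + c(0.4, 0) / sqrt(2) * c(1, 1)
  got <- superpose(model_from_xyz(sq), model_from_xyz(sq2))$rmsd
  oracle <- function(th) {
    Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
    P <- t(Rz %*% t(sq))
    P <- sweep(P, 2, colMeans(P) - colMeans(sq2))
    sqrt(mean(rowSums((P - sq2)^2)))
  }
  best <- min(vapply(seq(-pi, pi, by = 1e-3), oracle, numeric(1)))
  expect_equal(got, best, tolerance = 1e-4)
  # and agrees with an independent library implementation (which reports
  # rounded values)
  expect_lt(abs(got - bio3d::rmsd(as.numeric(t(sq2)), as.numeric(t(sq)),
                                  fit = TRUE)), 6e-4)
})

test_that("superposition rejects mismatched or underdetermined pairings", {
  m5 <- model_from_xyz(matrix(rnorm(15), 5, 3))
  m4 <- model_from_xyz(matrix(rnorm(12), 4, 3))
  expect_error(superpose(m5, m4, domain_selection("A", c(1, 5)),
                         domain_selection("A", c(1, 4))), "pairing")
  m2 <- model_from_xyz(matrix(rnorm(6), 2, 3))
  expect_error(superpose(m2, m2), "nderdetermined")
})

test_that("pivot frame recovers a constructed two-fold axis, also under noise", {
  set.seed(7)
  # the dimer two-fold axis lies in the platform plane, so the slab is
  # flattened along a direction orthogonal to the tested axis
  build <- function(axis, flat_dim, jitter = 0) {
    base <- matrix(rnorm(60, sd = 8), 20, 3)
    base[, flat_dim] <- base[, flat_dim] * 0.2
    ch2 <- t(rotation_matrix(axis, 180) %*% t(base))
    xyz <- rbind(base, ch2) + matrix(rnorm(120, sd = jitter), 40, 3)
    model_from_xyz(rbind(xyz, c(0, 0, 6), c(0, 0, -6)),
                   chain = c(rep("A", 20), rep("B", 20), "X", "Y"),
                   resno = c(1:20, 1:20, 1, 1))
  }
  selA <- domain_selection("A", c(1, 20))
  selB <- domain_selection("B", c(1, 20))
  pair <- list(list("X", 1), list("Y", 1))
  # exact axis along z, platform plane containing z
  fr <- define_pivot_frame(build(c(0, 0, 1), flat_dim = 1), selA, selB, pair)
  expect_lt(min(sum((fr$zero_axis - c(0, 0, 1))^2),
                sum((fr$zero_axis + c(0, 0, 1))^2)), 1e-10)
  # oblique axis (1,1,0)/sqrt(2), with and without coordinate noise
  ax <- c(1, 1, 0) / sqrt(2)
  fr2 <- define_pivot_frame(build(ax, flat_dim = 3), selA, selB, pair)
  expect_lt(acos(min(1, abs(sum(fr2$zero_axis * ax)))) * 180 / pi, 1e-4)
  fr3 <- define_pivot_frame(build(ax, flat_dim = 3, jitter = 0.1),
                            selA, selB, pair)
  expect_lt(acos(min(1, abs(sum(fr3$zero_axis * ax)))) * 180 / pi, 1)
  expect_equal(fr2$pivot, c(0, 0, 0), tolerance = 1e-9)
  # a non-two-fold arrangement is refused
  base <- matrix(rnorm(60, sd = 8), 20, 3)
  notwofold <- model_from_xyz(rbind(base, base + 5, c(0, 0, 6), c(0, 0, -6)),
                              chain = c(rep("A", 20), rep("B", 20), "X", "Y"),
                              resno = c(1:20, 1:20, 1, 1))
  expect_error(define_pivot_frame(notwofold, selA, selB, pair), "symmetry")
})

test_that("arm orientation measurement matches its defining conventions", {
  fr <- pivot_frame(c(0, 0, 0), c(1, 0, 0), c(0, 0, 1))
  # small zero-centroid cluster placed at the arm tip
  tip_cluster <- rbind(c(0, 0, 0), 2 * diag(3), -2 * diag(3),
                       2 / sqrt(3) * rbind(c(1, 1, 1), c(1, -1, -1),
                                           c(-1, 1, -1), c(-1, -1, 1)))
  arm <- function(dir) {
    model_from_xyz(rbind(c(0, 0, 0), sweep(tip_cluster, 2, dir * 10, `+`)),
                   chain = "P", resno = c(1, 2:12))
  }
  sel <- domain_selection("P", c(2, 12))
  o <- measure_fab_orientation(arm(c(1, 0, 0)), fr, list("P", 1), sel)
  expect_equal(c(o$alpha, o$beta), c(0, 0), tolerance = 1e-9)
  # arm along the plane normal: beta +90, alpha tie-broken to 0
  o2 <- measure_fab_orientation(arm(c(0, 0, 1)), fr, list("P", 1), sel)
  expect_equal(o2$beta, 90, tolerance = 1e-9)
  expect_equal(o2$alpha, 0)
  # construct-and-recover at (-30, -45)
  toy <- make_toy_hinge_model(hinge_truth(splay = 0))
  rot <- rotate_about_pivot(toy$model, toy$frame, -30, -45)
  o3 <- measure_fab_orientation(rot, toy$frame, toy$arms$P$cterm,
                                toy$arms$P$constant_sel)
  expect_equal(c(o3$alpha, o3$beta), c(-30, -45), tolerance = 1e-6)
})

test_that("rotate-then-measure round-trips over a grid of angles", {
  toy <- make_toy_hinge_model(hinge_truth(splay = 0))
  for (ab in list(c(10, 0), c(0, -35), c(25, 40), c(-50, -50), c(170, 20))) {
    rot <- rotate_about_pivot(toy$model, toy$frame, ab[1], ab[2])
    o <- measure_fab_orientation(rot, toy$frame, toy$arms$P$cterm,
                                 toy$arms$P$constant_sel)
    expect_equal(c(o$alpha, o$beta), ab, tolerance = 1e-6)
    # applying the inverse rotation returns the original coordinates
    back <- rotate_about_pivot(rot, toy$frame, ab[1], ab[2], inverse = TRUE)
    expect_lt(max(abs(as.matrix(back$atoms[, c("x", "y", "z")]) -
                        as.matrix(toy$model$atoms[, c("x", "y", "z")]))), 1e-9)
  }
})

test_that("inter-arm angle is symmetric, frame-free, and exact on axes", {
  expect_equal(inter_arm_angle(c(1, 0, 0), c(1, 0, 0)), 0)
  expect_equal(inter_arm_angle(c(1, 0, 0), c(0, 1, 0)), 90)
  set.seed(5)
  for (i in 1:20) {
    u <- rnorm(3); v <- rnorm(3)
    a1 <- inter_arm_angle(u, v)
    expect_equal(a1, inter_arm_angle(v, u), tolerance = 1e-12)
    # invariant under a common rotation (frame choice)
    R <- rotation_matrix(rnorm(3), runif(1, -180, 180))
    expect_equal(a1, inter_arm_angle(as.numeric(R %*% u), as.numeric(R %*% v)),
                 tolerance = 1e-9)
    expect_gte(a1, 0); expect_lte(a1, 180)
  }
  # toy construction: splay is the inter-arm angle
  toy <- make_toy_hinge_model(hinge_truth(splay = 50))
  oP <- measure_fab_orientation(toy$model, toy$frame, toy$arms$P$cterm,
                                toy$arms$P$constant_sel)
  oQ <- measure_fab_orientation(toy$model, toy$frame, toy$arms$Q$cterm,
                                toy$arms$Q$constant_sel)
  expect_equal(inter_arm_angle(oP, oQ), 50, tolerance = 1e-6)
})
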