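# synthetic footprint generation and perturbation operators

test_that("generated meshes honor depth, determinism, and rotation of truth", {
  sp <- footprintSpec(kind = "cone", length = 0.2, depth = 0.05,
                      target_faces = 5000)
  fp <- generateFootprint(sp)
  expect_equal(range(fp$mesh$vertices[, 3]), c(-0.05, 0), tolerance = 1e-9)
  expect_equal(nrow(fp$mesh$faces), 5000, tolerance = 0.05 * 5000)

  sp2 <- footprintSpec(kind = "tridactyl", noise_sd = 5e-4,
                       target_faces = 4000, seed = 42L)
  a <- generateFootprint(sp2)
  b <- generateFootprint(sp2)
  expect_identical(a$mesh$vertices, b$mesh$vertices)
  c3 <- generateFootprint(footprintSpec(kind = "tridactyl", noise_sd = 5e-4,
                                        target_faces = 4000, seed = 43L))
  expect_false(identical(a$mesh$vertices, c3$mesh$vertices))

  # rotated truth equals the rotation of the upright truth
  f90 <- generateFootprint(footprintSpec(kind = "tridactyl",
                                         target_faces = 2000))
  f137 <- generateFootprint(footprintSpec(kind = "tridactyl",
                                          axis_angle = 137,
                                          target_faces = 2000))
  R <- trackline:::.rot2(137 - 90)
  expect_lt(max(abs(unname(f137$truth$landmarks) -
                      unname(f90$truth$landmarks %*% t(R)))), 2e-3)
})

test_that("the truth outline lies inside the depression's planar footprint", {
  fp <- generateFootprint(footprintSpec(kind = "tridactyl",
                                        target_faces = 8000))
  deep <- fp$mesh$vertices[, 3] < -0.5 * 0.03
  tp <- fp$truth$outline
  expect_true(all(tp[, 1] > min(fp$mesh$vertices[, 1]) &
                    tp[, 1] < max(fp$mesh$vertices[, 1]) &
                    tp[, 2] > min(fp$mesh$vertices[, 2]) &
                    tp[, 2] < max(fp$mesh$vertices[, 2])))
  # every deep vertex is enclosed by the truth outline's bounding box
  expect_true(all(fp$mesh$vertices[deep, 1] >= min(tp[, 1]) - 1e-6 &
                    fp$mesh$vertices[deep, 1] <= max(tp[, 1]) + 1e-6))
})

test_that("invalid specifications are rejected", {
  expect_error(footprintSpec(depth = 0), "spec error")
  expect_error(footprintSpec(kind = "tridactyl",
                             interdigital_angles = c(0, 30)), "spec error")
  expect_error(footprintSpec(kind = "tridactyl",
                             digit_lengths = c(0.4, 0.6)), "spec error")
})

test_that("decimation hits the requested face count", {
  fp <- generateFootprint(footprintSpec(kind = "oval",
                                        target_faces = 40000))
  m <- perturbMesh(fp$mesh, "decimate", list(target_faces = 5000L))
  expect_lt(abs(nrow(m$faces) - 5000) / 5000, 0.01)
  expect_error(perturbMesh(fp$mesh, "decimate", list(target_faces = 50L)),
               "parameter error")
})

test_that("rigid perturbations transform vertices exactly", {
  fp <- generateFootprint(footprintSpec(kind = "oval", target_faces = 2000))
  m <- fp$mesh
  rot <- perturbMesh(m, "rotate", list(angles = c(10, 20, 30)))
  R <- trackline:::.rot3(10, 20, 30)
  expect_equal(rot$vertices, m$vertices %*% t(R), tolerance = 1e-12)
  tra <- perturbMesh(m, "translate", list(offset = c(1, -2, 3)))
  expect_equal(tra$vertices, sweep(m$vertices, 2, -c(1, -2, 3)),
               tolerance = 1e-12)
  mir <- perturbMesh(m, "mirror", list(axis = "y"))
  expect_equal(mir$vertices[, 2], -m$vertices[, 2])
  neg <- perturbMesh(m, "negate_z", list())
  expect_equal(neg$vertices[, 3], -m$vertices[, 3])
})

test_that("crack and infill defects act locally", {
  fp <- generateFootprint(footprintSpec(kind = "tridactyl",
                                        target_faces = 8000))
  m <- fp$mesh
  cracked <- perturbMesh(m, "add_crack",
                         list(from = c(-0.1, 0.1), to = c(0.1, 0.1),
                              width = 0.01, depth = 0.02))
  changed <- which(cracked$vertices[, 3] != m$vertices[, 3])
  expect_gt(length(changed), 0L)
  expect_true(all(abs(m$vertices[changed, 2] - 0.1) < 0.02))
  expect_equal(cracked$vertices[changed, 3],
               m$vertices[changed, 3] - 0.02, tolerance = 1e-12)

  tip <- generateFootprint(footprintSpec(kind = "tridactyl",
                                         target_faces = 8000))
  filled <- perturbMesh(tip$mesh, "fill_digit_tip",
                        list(center = tip$truth$landmarks["L3", ],
                             radius = 0.03, level = -0.005))
  ch <- which(filled$vertices[, 3] != tip$mesh$vertices[, 3])
  expect_gt(length(ch), 0L)
  expect_true(all(filled$vertices[ch, 3] == -0.005))
  d <- sqrt(rowSums(sweep(tip$mesh$vertices[ch, 1:2], 2,
                          tip$truth$landmarks["L3", ])^2))
  expect_true(all(d < 0.03))
})

test_that("cracks distort the outline locally, as in weathered tracks", {
  fp <- generateFootprint(footprintSpec(kind = "hemisphere",
                                        target_faces = 30000))
  clean <- traceOutline(fp$mesh)$outline$points
  cracked_mesh <- perturbMesh(fp$mesh, "add_crack",
                              list(from = c(-0.4, 0.02), to = c(0.4, 0.02),
                                   width = 0.012, depth = 0.03))
  cracked <- traceOutline(cracked_mesh)$outline$points
  # the outline still closes, but deviates from the clean one
  expect_gt(outline_mean_dist(clean[-nrow(clean), ],
                              cracked[-nrow(cracked), ]), 1e-4)
})
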