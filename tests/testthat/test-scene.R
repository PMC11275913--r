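test_that("concentric-sphere scene keeps the intermembrane gap everywhere", {
  sc <- scene_config(semi_axes = c(2000, 2000, 2000), mesh_edge = 150,
                     ibm_gap = 135, seed = 1)
  s <- generate_scene(sc)
  d <- nearest_triangle(s$omm$centroids, s$imm, "centroid")$distance
  expect_true(all(abs(d - 135) < 2 * 150))
  expect_lt(max(abs(d - 135)), 5)  # spheres: far tighter than the bound
  # watertight and outward for both membranes, IMM strictly inside
  expect_gt(mesh_signed_volume(s$omm), 0)
  expect_gt(mesh_signed_volume(s$imm), 0)
  expect_lt(mesh_signed_volume(s$imm), mesh_signed_volume(s$omm))
})

test_that("a constriction lowers the local gap by its amplitude, at the site", {
  site <- c(0, 0, 2000)
  sc <- scene_config(mesh_edge = 150, seed = 2,
                     constrictions = list(list(point = site, amplitude = 35,
                                               radius = 300)))
  s <- generate_scene(sc)
  # brute-force point-to-centroid scan as the oracle
  omm_c <- s$omm$centroids
  dmin <- rep(Inf, nrow(omm_c))
  for (k in seq_len(nrow(s$imm$centroids))) {
    dk <- sqrt(colSums((t(omm_c) - s$imm$centroids[k, ])^2))
    dmin <- pmin(dmin, dk)
  }
  i <- which.min(dmin)
  expect_equal(min(dmin), 100, tolerance = 0.05)
  expect_lt(sqrt(sum((omm_c[i, ] - site)^2)), 300)
})

test_that("each crista contributes a junction-band component", {
  sc <- scene_config(mesh_edge = 150, n_cristae = 4, seed = 7)
  s <- generate_scene(sc)
  d <- nearest_triangle(s$imm$centroids, s$omm, "centroid")$distance
  band <- d >= 180 & d <= 300
  expect_gt(sum(band), 0)
  expect_gte(label_components(s$imm, band), 4)
  # away from cristae the gap stays at baseline
  far <- rep(TRUE, n_triangles(s$imm))
  for (i in seq_len(nrow(s$truth$crista_sites))) {
    dd <- sqrt(colSums((t(s$imm$centroids) - s$truth$crista_sites[i, ])^2))
    far <- far & dd > 3 * 2 * sc$crista_neck_radius
  }
  expect_lt(max(abs(d[far] - 135)), 2 * 150)
})

test_that("infeasible scene geometry is rejected with a diagnostic", {
  expect_error(scene_config(semi_axes = c(500, 500, 500), mesh_edge = 45,
                            n_cristae = 1, crista_depth = 600),
               "crista_depth")
  expect_error(
    scene_config(constrictions = list(list(point = c(0, 0, 2000),
                                           amplitude = 200, radius = 300))),
    "amplitude")
  expect_error(scene_config(semi_axes = c(100, 100, 100), mesh_edge = 50),
               "semi-axes")
})

test_that("scene and placement are reproducible under a fixed seed", {
  sc <- scene_config(mesh_edge = 180, n_cristae = 2, seed = 5)
  s1 <- generate_scene(sc)
  s2 <- generate_scene(sc)
  expect_identical(s1$imm$vertices, s2$imm$vertices)
  pc <- placement_config(n_particles = 40, frac_import_oriented = 0.5, seed = 9)
  p1 <- place_particles(s1$omm, pc)
  p2 <- place_particles(s2$omm, pc)
  expect_identical(p1$particles, p2$particles)
  expect_identical(p1$truth, p2$truth)
})

test_that("ground-truth class fractions are exact for integer splits", {
  sc <- scene_config(mesh_edge = 180, seed = 3)
  s <- generate_scene(sc)
  pl <- place_particles(s$omm, placement_config(n_particles = 40,
                                                frac_import_oriented = 0.25,
                                                seed = 8))
  expect_equal(sum(pl$truth$true_class == "import_oriented"), 10)
})

test_that("import flag controls the exit-tunnel distance by construction", {
  sc <- scene_config(mesh_edge = 150, seed = 4)
  s <- generate_scene(sc)
  # all import oriented, no noise: every exit point within 95 A
  pl <- place_particles(s$omm, placement_config(n_particles = 100, seed = 6))
  ann <- annotate_particles(pl$particles, s$omm)
  expect_true(all(ann$d_exit <= 95))
  expect_equal(sum(classify_import_oriented(ann)), 100)
  # all flipped outward: none import oriented
  pl0 <- place_particles(s$omm, placement_config(n_particles = 100,
                                                 frac_import_oriented = 0,
                                                 seed = 6))
  ann0 <- annotate_particles(pl0$particles, s$omm)
  expect_equal(sum(classify_import_oriented(ann0)), 0)
})

test_that("thomas offspring stay within the stated spread of their parent", {
  sc <- scene_config(mesh_edge = 180, seed = 2)
  s <- generate_scene(sc)
  pl <- place_particles(s$omm, placement_config(
    n_particles = 60, cluster_process = "thomas", n_parents = 6,
    offspring_spread = 150, seed = 12))
  expect_true(all(!is.na(pl$truth$parent_id)))
  # offspring of one parent are mutually within ~2 spreads (+ projection slack)
  by_parent <- split(seq_len(60), pl$truth$parent_id)
  pos <- cbind(pl$particles$x, pl$particles$y, pl$particles$z)
  for (ids in by_parent) {
    if (length(ids) < 2) next
    dd <- stats::dist(pos[ids, , drop = FALSE])
    expect_lt(max(dd), 2 * 150 + 100)
  }
})

test_that("thomas patterns beat CSR patterns in short-range pair counts", {
  sc <- scene_config(mesh_edge = 180, seed = 2)
  s <- generate_scene(sc)
  th <- place_particles(s$omm, placement_config(
    n_particles = 100, cluster_process = "thomas", n_parents = 10,
    offspring_spread = 150, seed = 21))
  un <- place_particles(s$omm, placement_config(n_particles = 100, seed = 21))
  pt <- cbind(th$particles$x, th$particles$y, th$particles$z)
  pu <- cbind(un$particles$x, un$particles$y, un$particles$z)
  expect_gt(brute_pair_count(pt, 400), brute_pair_count(pu, 400))
})

test_that("generated chains respect spacing and port-gap contracts", {
  sc <- scene_config(mesh_edge = 150, seed = 2)
  s <- generate_scene(sc)
  pl <- place_particles(s$omm, placement_config(
    n_particles = 5, polysome_chains = list(c(5, 250)), seed = 11))
  ports <- compute_ports(pl$particles)
  gaps <- sqrt(
    (ports$entry3_x[-1] - ports$exit5_x[-5])^2 +
    (ports$entry3_y[-1] - ports$exit5_y[-5])^2 +
    (ports$entry3_z[-1] - ports$exit5_z[-5])^2
  )
  expect_equal(gaps, rep(40, 4), tolerance = 1e-6)
  expect_true(all(pl$truth$true_class == "import_oriented"))
  ann <- annotate_particles(pl$particles, s$omm)
  expect_true(all(ann$d_exit <= 95))
})

test_that("chains larger than n_particles are rejected", {
  sc <- scene_config(mesh_edge = 180, seed = 1)
  s <- generate_scene(sc)
  expect_error(place_particles(s$omm, placement_config(
    n_particles = 3, polysome_chains = list(c(5, 250)))), "exceed")
})

test_that("infeasible minimum separation raises a diagnostic", {
  sc <- scene_config(semi_axes = c(600, 600, 600), mesh_edge = 50, seed = 1)
  s <- generate_scene(sc)
  expect_error(place_particles(s$omm, placement_config(
    n_particles = 500, min_separation = 400, seed = 2)), "separation")
})
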