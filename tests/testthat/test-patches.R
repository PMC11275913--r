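test_that("patch membership equals the exhaustive disc scan", {
  m <- flat_grid_mesh(nx = 20, ny = 20, h = 50)
  seed_tri <- 190L
  ps <- build_patches(m, seed_tri, radius = 150)
  want <- which(sqrt(colSums((t(m$centroids) - m$centroids[seed_tri, ])^2)) <= 150)
  expect_setequal(ps$member, want)
  expect_true(seed_tri %in% ps$member)
  # radius 0: the patch is its seed
  ps0 <- build_patches(m, c(3L, 17L), radius = 0)
  expect_identical(sort(ps0$member), c(3L, 17L))
  # two seeds a few tens of A apart: symmetric difference confined to the ring
  s1 <- 189L
  s2 <- 190L  # the two triangles of one grid cell
  sep <- sqrt(sum((m$centroids[s1, ] - m$centroids[s2, ])^2))
  expect_lt(sep, 50)
  psa <- build_patches(m, s1, 150)
  psb <- build_patches(m, s2, 150)
  sym <- union(setdiff(psa$member, psb$member), setdiff(psb$member, psa$member))
  da <- sqrt(colSums((t(m$centroids[sym, , drop = FALSE]) - m$centroids[s1, ])^2))
  expect_true(all(da > 150 - sep - 1e-9 & da <= 150 + sep + 1e-9))
  expect_error(build_patches(m, 10000L, 150), "invalid seed")
})

test_that("random scenes: patch membership matches brute force", {
  set.seed(33)
  for (i in 1:3) {
    m <- ellipsoid_mesh(runif(3, 600, 1000), 150)
    seeds <- sample.int(n_triangles(m), 5)
    ps <- build_patches(m, seeds, radius = 200)
    for (s in seeds) {
      want <- which(sqrt(colSums((t(m$centroids) - m$centroids[s, ])^2)) <= 200)
      expect_setequal(ps$member[ps$seed_triangle == s], want)
    }
  }
})

test_that("crista classification is empty on concentric spheres and localized on cristae", {
  s0 <- generate_scene(scene_config(mesh_edge = 150, seed = 1))
  cr0 <- classify_crista_associated_omm(s0$imm, s0$omm)
  expect_equal(sum(cr0$cj_imm), 0)
  expect_equal(sum(cr0$crista_associated_omm), 0)

  s1 <- generate_scene(scene_config(mesh_edge = 150, n_cristae = 1, seed = 3))
  cr1 <- classify_crista_associated_omm(s1$imm, s1$omm)
  expect_gt(sum(cr1$cj_imm), 0)
  expect_true(all(cr1$crista_associated_omm[cr1$cj_projected_omm]))
  # the crista-associated OMM is one patch over the crista footprint
  expect_equal(label_components(s1$omm, cr1$crista_associated_omm), 1L)
  site <- s1$truth$crista_sites[1, ]
  hit <- s1$omm$centroids[cr1$crista_associated_omm, , drop = FALSE]
  expect_lt(max(sqrt(colSums((t(hit) - site)^2))),
            2 * 300 + 300 + 150 + 200)  # influence + band + expansion + slack
  # an exclusion mask covering the crista empties all three labels
  mask <- sqrt(colSums((t(s1$imm$centroids) - site)^2)) < 2000
  crm <- classify_crista_associated_omm(s1$imm, s1$omm, exclusion_mask = mask)
  expect_equal(sum(crm$cj_imm), 0)
  expect_equal(sum(crm$cj_projected_omm), 0)
  expect_equal(sum(crm$crista_associated_omm), 0)
})

test_that("overlap_fraction obeys its identities and a constructed half case", {
  m <- flat_grid_mesh(nx = 5, ny = 3, h = 50)
  a <- rep(TRUE, n_triangles(m))
  expect_equal(overlap_fraction(m, a, a), 1)
  expect_equal(overlap_fraction(m, a, !a), 0)
  # equal-area triangles: b holding exactly half of a's area
  a2 <- seq_len(n_triangles(m)) <= 8
  b2 <- seq_len(n_triangles(m)) <= 4
  expect_equal(overlap_fraction(m, a2, b2), 0.5)
  expect_true(is.na(overlap_fraction(m, rep(FALSE, n_triangles(m)), a)))
  # monotone in label_b
  set.seed(4)
  la <- runif(n_triangles(m)) < 0.5
  lb <- runif(n_triangles(m)) < 0.3
  lb_big <- lb | runif(n_triangles(m)) < 0.3
  expect_gte(overlap_fraction(m, la, lb_big), overlap_fraction(m, la, lb))
})

test_that("randomize_patches enforces separation, determinism and the budget", {
  m <- ellipsoid_mesh(c(1000, 1000, 1000), 150)
  expect_equal(nrow(randomize_patches(m, 0, 150)), 0)
  p1 <- randomize_patches(m, 10, 150, min_center_sep = 150, seed = 5)
  p2 <- randomize_patches(m, 10, 150, min_center_sep = 150, seed = 5)
  expect_identical(unique(p1$seed_triangle), unique(p2$seed_triangle))
  seeds <- unique(p1$seed_triangle)
  dd <- stats::dist(m$centroids[seeds, ])
  expect_gt(min(dd), 150)
  # too many patches for the surface: diagnostic names the achieved count
  small <- ellipsoid_mesh(c(600, 600, 600), 55)
  expect_error(randomize_patches(small, 400, 100, min_center_sep = 500,
                                 seed = 1, max_attempts = 800),
               "placed only")
})

test_that("mean randomized overlap approaches the crista area fraction", {
  s <- generate_scene(scene_config(mesh_edge = 150, n_cristae = 2, seed = 9))
  cr <- classify_crista_associated_omm(s$imm, s$omm)
  omm <- mesh_set_label(s$omm, "crista", cr$crista_associated_omm)
  target <- sum(omm$areas[cr$crista_associated_omm]) / sum(omm$areas)
  fr <- vapply(1:40, function(i) {
    ps <- randomize_patches(omm, 5, 150, seed = i)
    overlap_fraction(omm, patch_label(ps), "crista")
  }, numeric(1))
  expect_lt(abs(mean(fr) - target), 0.05)
})

test_that("proximity_region thresholds the inter-mesh distance", {
  s <- generate_scene(scene_config(mesh_edge = 150, seed = 2))
  expect_true(all(proximity_region(s$omm, s$imm, 250)))
  expect_false(any(proximity_region(s$omm, s$imm, 100)))
  # brute-force oracle on a random pair
  m1 <- ellipsoid_mesh(c(500, 400, 300), 150)
  m2 <- triangle_mesh(m1$vertices + 600, m1$faces, "ER")
  got <- proximity_region(m1, m2, 700)
  want <- brute_nearest(m1$centroids, m2$centroids)$distance <= 700
  expect_identical(got, want)
  expect_warning(out <- proximity_region(m1, NULL, 100), "empty")
  expect_false(any(out))
})

test_that("patch_imm_distances partitions the OMM and localizes constrictions", {
  site <- c(0, 0, 2000)
  s <- generate_scene(scene_config(mesh_edge = 150, seed = 4,
    constrictions = list(list(point = site, amplitude = 35, radius = 300))))
  seed_tri <- nearest_triangle(rbind(site), s$omm, "centroid")$triangle
  lab <- patch_label(build_patches(s$omm, seed_tri, 150))
  pd <- patch_imm_distances(s$omm, s$imm, lab)
  # exact area partition
  expect_equal(pd$area_in + pd$area_out, sum(s$omm$areas), tolerance = 1e-12)
  expect_equal(length(pd$in_patch) + length(pd$out_of_patch), n_triangles(s$omm))
  expect_lte(min(pd$in_patch), min(pd$out_of_patch))
  expect_lt(mean(pd$in_patch), mean(pd$out_of_patch))
  expect_lt(histogram_peak(pd$in_patch), histogram_peak(pd$out_of_patch))
  # all-true label: nothing out of patch
  pd_all <- patch_imm_distances(s$omm, s$imm, rep(TRUE, n_triangles(s$omm)))
  expect_equal(length(pd_all$out_of_patch), 0)
  # concentric spheres: both groups concentrate at the gap
  s0 <- generate_scene(scene_config(mesh_edge = 150, seed = 5))
  lab0 <- patch_label(build_patches(s0$omm, 1L, 300))
  pd0 <- patch_imm_distances(s0$omm, s0$imm, lab0)
  expect_equal(histogram_peak(pd0$in_patch), 135, tolerance = 0.02)
  expect_equal(histogram_peak(pd0$out_of_patch), 135, tolerance = 0.02)
})
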