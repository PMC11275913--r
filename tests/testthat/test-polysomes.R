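chain_tbl <- function(exit5, entry3, pos = NULL) {
  n <- nrow(exit5)
  if (is.null(pos)) pos <- (exit5 + entry3) / 2
  tibble::tibble(
    tomogram_id = "t", particle_id = seq_len(n),
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    rot = 0, tilt = 0, psi = 0,
    exit5_x = exit5[, 1], exit5_y = exit5[, 2], exit5_z = exit5[, 3],
    entry3_x = entry3[, 1], entry3_y = entry3[, 2], entry3_z = entry3[, 3]
  )
}

test_that("compute_ports applies the rigid-body map per role", {
  cfg <- polysome_config()
  p <- make_particles(matrix(c(10, 20, 30), 1))
  got <- compute_ports(p, cfg)
  expect_equal(c(got$exit5_x, got$exit5_y, got$exit5_z), c(115, 20, 30))
  expect_equal(c(got$entry3_x, got$entry3_y, got$entry3_z), c(-95, 20, 30))
  # isometry: the port pair distance is preserved under random orientations
  set.seed(15)
  eul <- matrix(runif(45, -180, 180), 15)
  pts <- compute_ports(make_particles(matrix(rnorm(45, sd = 400), 15), eul), cfg)
  gap <- sqrt((pts$exit5_x - pts$entry3_x)^2 + (pts$exit5_y - pts$entry3_y)^2 +
              (pts$exit5_z - pts$entry3_z)^2)
  expect_equal(gap, rep(210, 15), tolerance = 1e-9)
  # matches the quaternion-free rotation oracle for one particle
  R <- euler_zyz_quat_oracle(eul[3, 1], eul[3, 2], eul[3, 3])
  want <- as.numeric(R %*% c(105, 0, 0))
  expect_equal(c(pts$exit5_x[3] - pts$x[3], pts$exit5_y[3] - pts$y[3],
                 pts$exit5_z[3] - pts$z[3]), want, tolerance = 1e-9)
})

test_that("link_chains applies both numbered criteria", {
  cfg <- polysome_config(nn_max = 300, adj_max = 60)
  # two particles 400 A apart: violates the 30 nm neighbour rule
  ex <- rbind(c(50, 0, 0), c(450, 0, 0))
  en <- rbind(c(-50, 0, 0), c(350, 0, 0))
  far <- chain_tbl(ex, en, pos = rbind(c(0, 0, 0), c(400, 0, 0)))
  expect_equal(nrow(link_chains(far, cfg)), 0)
  # within 30 nm but ports 200 A apart: violates adjacency
  ex2 <- rbind(c(50, 0, 0), c(200, 100, 0))
  en2 <- rbind(c(-50, 0, 0), c(250, 0, 0))
  near <- chain_tbl(ex2, en2, pos = rbind(c(0, 0, 0), c(250, 0, 0)))
  expect_equal(nrow(link_chains(near, cfg)), 0)
  # compliant pair links 5' exit -> 3' entry
  ex3 <- rbind(c(105, 0, 0), c(355, 0, 0))
  en3 <- rbind(c(-105, 0, 0), c(145, 0, 0))
  ok <- chain_tbl(ex3, en3, pos = rbind(c(0, 0, 0), c(250, 0, 0)))
  ch <- link_chains(ok, cfg)
  expect_equal(ch$particle_id, c(1L, 2L))
  expect_equal(ch$chain_order, c(1L, 2L))
})

test_that("degree conflicts resolve by the smallest port gap", {
  cfg <- polysome_config(nn_max = 300, adj_max = 100)
  # particles 2 and 3 both want to follow 1; 3's entry is closer to 1's exit
  ex <- rbind(c(100, 0, 0), c(400, 0, 0), c(100, 250, 0))
  en <- rbind(c(-100, 0, 0), c(180, 0, 0), c(130, 0, 0))
  tbl <- chain_tbl(ex, en, pos = rbind(c(0, 0, 0), c(280, 0, 0), c(90, 230, 0)))
  ch <- link_chains(tbl, cfg)
  expect_equal(ch$particle_id[ch$chain_order == 2], 3L)
})

test_that("cycles are broken at the largest port gap", {
  cfg <- polysome_config(nn_max = 400, adj_max = 120)
  # triangle of three members, consecutive gaps 10, 20, 100: the 100 edge drops
  pos <- rbind(c(0, 0, 0), c(300, 0, 0), c(150, 260, 0))
  ex <- rbind(c(50, 0, 0), c(310, 10, 0), c(10, 200, 0))
  en <- rbind(c(10, 100, 0), c(60, 0, 0), c(310, 30, 0))
  tbl <- chain_tbl(ex, en, pos = pos)
  ch <- link_chains(tbl, cfg)
  expect_equal(max(ch$chain_order), 3)  # a path of 3, not a cycle
  expect_equal(nrow(ch), 3)
})

test_that("chain metrics reproduce collinear and 3-4-5 closed forms", {
  # collinear rods 100 + 100 with coincident intra-member ports
  ex <- rbind(c(0, 0, 0), c(100, 0, 0), c(200, 0, 0))
  en <- rbind(c(-10, 0, 0), c(100, 0, 0), c(200, 0, 0))
  tbl <- chain_tbl(ex, en, pos = ex)
  ch <- structure(
    dplyr::mutate(tbl, chain_id = 1L, chain_order = dplyr::row_number()),
    class = c("polysome_chains", class(tbl)))
  m <- chain_metrics(ch)
  expect_equal(m$path_length, 200)
  expect_equal(m$end_to_end, 200)
  # right angle: rods 300 then 400 -> path 700, end-to-end 500
  ex2 <- rbind(c(0, 0, 0), c(300, 0, 0), c(0, 0, 0))
  en2 <- rbind(c(0, 0, 0), c(300, 0, 0), c(300, 400, 0))
  tbl2 <- chain_tbl(ex2, en2, pos = ex2)
  ch2 <- structure(
    dplyr::mutate(tbl2, chain_id = 1L, chain_order = dplyr::row_number()),
    class = c("polysome_chains", class(tbl2)))
  m2 <- chain_metrics(ch2)
  expect_equal(m2$path_length, 700)
  expect_equal(m2$end_to_end, 500)
  # random chain: path equals an independently summed segment list
  set.seed(16)
  ex3 <- matrix(rnorm(15, sd = 200), 5)
  en3 <- matrix(rnorm(15, sd = 200), 5)
  tbl3 <- chain_tbl(ex3, en3)
  ch3 <- structure(
    dplyr::mutate(tbl3, chain_id = 1L, chain_order = dplyr::row_number()),
    class = c("polysome_chains", class(tbl3)))
  rods <- vapply(1:4, function(k) sqrt(sum((en3[k + 1, ] - ex3[k, ])^2)),
                 numeric(1))
  within <- vapply(2:4, function(k) sqrt(sum((ex3[k, ] - en3[k, ])^2)),
                   numeric(1))
  expect_equal(chain_metrics(ch3)$path_length, sum(rods) + sum(within),
               tolerance = 1e-12)
})

test_that("generated chains are recovered with exact membership and order", {
  s <- generate_scene(scene_config(mesh_edge = 150, seed = 19))
  pl <- place_particles(s$omm, placement_config(
    n_particles = 5, polysome_chains = list(c(5, 250)), seed = 20))
  got <- find_polysomes(pl$particles)
  expect_equal(nrow(got$metrics), 1)
  expect_equal(got$chains$particle_id, pl$truth$particle_id)
  expect_equal(got$chains$chain_order, pl$truth$chain_order)
  expect_gte(got$metrics$path_length, got$metrics$end_to_end)
  # metrics are rigid-body invariant
  R <- euler_to_matrix(12, 34, 56)
  pos <- cbind(pl$particles$x, pl$particles$y, pl$particles$z)
  rotated <- pl$particles
  newpos <- t(R %*% t(pos)) + 500
  rotated$x <- newpos[, 1]; rotated$y <- newpos[, 2]; rotated$z <- newpos[, 3]
  eul <- t(vapply(seq_len(5), function(i) {
    matrix_to_euler(R %*% euler_to_matrix(pl$particles$rot[i],
                                          pl$particles$tilt[i],
                                          pl$particles$psi[i]))
  }, numeric(3)))
  rotated$rot <- eul[, 1]; rotated$tilt <- eul[, 2]; rotated$psi <- eul[, 3]
  got2 <- find_polysomes(rotated)
  expect_equal(got2$metrics$path_length, got$metrics$path_length, tolerance = 1e-6)
  expect_equal(got2$metrics$end_to_end, got$metrics$end_to_end, tolerance = 1e-6)
})

test_that("chains among a mixed population stay vertex-disjoint", {
  s <- generate_scene(scene_config(mesh_edge = 150, seed = 22))
  pl <- place_particles(s$omm, placement_config(
    n_particles = 40, frac_import_oriented = 0.4,
    polysome_chains = list(c(4, 250), c(3, 260)), seed = 23))
  got <- find_polysomes(pl$particles)
  expect_false(any(duplicated(got$chains$particle_id)))
  # every generated chain member should sit in a recovered chain
  want <- pl$truth$particle_id[!is.na(pl$truth$chain_id)]
  expect_true(all(want %in% got$chains$particle_id))
})
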