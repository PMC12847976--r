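test_that("growth without branching yields a single unbranched vessel", {
  net <- generate_network(n_seeds = 1, max_steps = 30, branch_prob = 0,
                          persistence = 1, geometry = small_geom(), seed = 2)
  expect_length(net$branches, 1)
  expect_equal(nrow(net$junctions), 0)
})

test_that("growth is deterministic given the seed", {
  a <- generate_network(geometry = net_geom(), seed = 11)
  b <- generate_network(geometry = net_geom(), seed = 11)
  expect_identical(a, b)
  c <- generate_network(geometry = net_geom(), seed = 12)
  expect_false(identical(a$total_length, c$total_length))
})

test_that("degenerate growth parameters are rejected", {
  expect_error(generate_network(n_seeds = 0, geometry = small_geom(), seed = 1),
               "empty network")
  expect_error(generate_network(max_steps = 0, geometry = small_geom(), seed = 1),
               "empty network")
  expect_error(generate_network(geometry = small_geom()), "seed")
})

test_that("junction count equals the successful branching events in the log", {
  for (s in c(5, 9, 21)) {
    net <- generate_network(branch_prob = 0.05, geometry = net_geom(),
                            seed = s)
    expect_equal(nrow(net$junctions), sum(net$events$branched))
  }
})

test_that("ground-truth geometry is self-consistent", {
  net <- generate_network(branch_prob = 0.06, geometry = net_geom(), seed = 5)
  arc <- sum(vapply(net$branches, function(b)
    sum(sqrt(rowSums(diff(b$path)^2))), numeric(1)))
  expect_equal(net$total_length, arc, tolerance = 1e-9)
  expect_true(all(vapply(net$branches, function(b) b$width > 0, logical(1))))
  # every junction sits on a daughter start and on some branch interior
  starts <- t(vapply(net$branches, function(b) b$path[1, ], numeric(2)))
  for (i in seq_len(nrow(net$junctions))) {
    j <- net$junctions[i, ]
    d_start <- min(sqrt((starts[, 1] - j[1])^2 + (starts[, 2] - j[2])^2))
    expect_lt(d_start, 1e-9)
    on_interior <- any(vapply(net$branches, function(b) {
      n <- nrow(b$path)
      if (n < 3) return(FALSE)
      inner <- b$path[2:(n - 1), , drop = FALSE]
      any(abs(inner[, 1] - j[1]) < 1e-9 & abs(inner[, 2] - j[2]) < 1e-9)
    }, logical(1)))
    expect_true(on_interior)
  }
})

test_that("a stroked bar rasterizes to its analytic pixel area", {
  ras <- rasterize_network(bar_network(), bar_network()$geometry)
  n <- sum(ras$labels > 0)
  expect_gte(n, 480)
  expect_lte(n, 520)
})

test_that("an empty network rasterizes to all background", {
  net <- bar_network()
  net$branches <- list()
  net$total_length <- 0
  ras <- rasterize_network(net, net$geometry)
  expect_equal(sum(ras$labels), 0)
  expect_equal(unname(ras$network$areas), c(0, 0))
})

test_that("thick wins where thick and thin strokes overlap", {
  geom <- small_geom(100, 30)
  net <- bar_network(geom, from = c(50, 10), to = c(50, 90), width = 6,
                     class = "thick")
  net$branches[[2]] <- list(path = rbind(c(10, 50), c(90, 50)), width = 2,
                            class = "thin")
  ras <- rasterize_network(net, geom)
  # the crossing region is inside both strokes
  expect_true(all(ras$labels[49:51, 49:51] == 2L))
  expect_true(any(ras$labels == 1L))
})

test_that("rasterized class areas partition the vessel area exactly", {
  for (s in c(3, 14)) {
    net <- generate_network(geometry = net_geom(), seed = s)
    ras <- rasterize_network(net, net_geom())
    expect_identical(sum(ras$labels > 0),
                     sum(ras$labels == 1L) + sum(ras$labels == 2L))
    expect_equal(unname(ras$network$areas["thick"]), sum(ras$labels == 2L))
    expect_equal(unname(ras$network$areas["thin"]), sum(ras$labels == 1L))
  }
})

test_that("out-of-frame polylines are clipped with a warning", {
  geom <- small_geom(100, 30)
  net <- bar_network(geom, from = c(50, -20), to = c(50, 60), width = 3)
  expect_warning(ras <- rasterize_network(net, geom), "clipped")
  expect_true(all(which(ras$labels > 0) >= 1))
})

test_that("corruption with no field, noise or specks is the identity", {
  ras <- rasterize_network(bar_network(), bar_network()$geometry)
  out <- corrupt_image(ras$image, noise_sigma = 0, seed = 1)
  expect_identical(out$intensity, ras$image$intensity)
})

test_that("a planar background field adds exactly, pre-clipping", {
  ras <- rasterize_network(bar_network(), bar_network()$geometry)
  f <- list(type = "plane", a = 100, b = 300, c = 200)
  out <- corrupt_image(ras$image, background_field = f, seed = 1)
  nr <- nrow(ras$image$intensity); nc <- ncol(ras$image$intensity)
  rr <- matrix(seq_len(nr) / nr, nr, nc)
  cc <- matrix(seq_len(nc) / nc, nr, nc, byrow = TRUE)
  expected <- f$a + f$b * cc + f$c * rr
  diff <- out$intensity - ras$image$intensity
  # no clipping occurs at these levels, so the difference is the field
  expect_equal(diff, expected, tolerance = 1e-12)
})

test_that("requested specks appear as exactly that many new components", {
  geom <- net_geom()
  net <- generate_network(geometry = geom, seed = 8)
  ras <- rasterize_network(net, geom)
  out <- corrupt_image(ras$image, specks = list(n = 10, size_range = c(3, 8)),
                       avoid = ras$labels > 0, seed = 99)
  added <- out$intensity - ras$image$intensity > 1000
  lab <- vesselchip:::label8(added)
  expect_equal(max(lab), 10)
  expect_false(any(added & ras$labels > 0))
})

test_that("negative noise sigma is rejected and corruption is seeded", {
  ras <- rasterize_network(bar_network(), bar_network()$geometry)
  expect_error(corrupt_image(ras$image, noise_sigma = -1, seed = 1), "sigma")
  a <- corrupt_image(ras$image, noise_sigma = 100, seed = 5)
  b <- corrupt_image(ras$image, noise_sigma = 100, seed = 5)
  expect_identical(a$intensity, b$intensity)
})

test_that("a zero-noise screen gives identical chips within a plate group", {
  des <- screen_design(donors = "D1", treatments = list(DMSO = list()),
                       control_replicates = 6, plates_per_donor = 1,
                       donor_cv = 0, plate_cv = 0, replicate_cv = 0,
                       seed = 7)
  scr <- generate_screen(des)
  expect_equal(stats::sd(scr$viability$viability), 0)
  expect_true(all(apply(scr$analytes[, -1], 2, stats::sd) == 0))
})

test_that("a scripted viability multiplier is recovered exactly by normalization", {
  des <- screen_design(
    donors = "D1",
    treatments = list(DMSO = list(), ator = list(viability = 0.47)),
    replicates = 2, control_replicates = 6, plates_per_donor = 2,
    donor_cv = 0.2, plate_cv = 0.15, replicate_cv = 0, seed = 3)
  scr <- generate_screen(des)
  nv <- normalize_to_vehicle(scr$viability, scr$layout)
  m <- merge(nv, scr$layout[, c("chip", "treatment")], by = "chip")
  expect_equal(m$viability[m$treatment == "ator"], rep(47, 4),
               tolerance = 1e-12)
  expect_equal(mean(m$viability[m$treatment == "DMSO"]), 100,
               tolerance = 1e-12)
})

test_that("screen generation is deterministic and validates its design", {
  expect_error(screen_design(replicates = 0), "replicate")
  expect_error(screen_design(treatments = list(
    DMSO = list(viability = 0.9))), "vehicle control")
  expect_error(screen_design(treatments = list(
    DMSO = list(), bad = list(viability = -1))), ">= 0")
  a <- generate_screen(null_design(5))
  b <- generate_screen(null_design(5))
  expect_identical(a$viability, b$viability)
  expect_identical(a$analytes, b$analytes)
})
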