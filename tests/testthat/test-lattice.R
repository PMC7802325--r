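# apical lattice: label-image adjacency, interior statistics, packing laws,
# aspect ratios

test_that("label adjacency follows the shared-boundary rule", {
  # three vertical stripes: middle cell touches both others, all on frame
  img <- cbind(matrix(1L, 6, 2), matrix(2L, 6, 2), matrix(3L, 6, 2))
  lat <- adjacency_from_labels(img, pixel_size = 1)
  expect_equal(lat$cells$neighbours[[2]], c(1L, 3L))
  expect_equal(lat$cells$neighbours[[1]], 2L)
  expect_true(all(lat$cells$is_border))
  expect_error(interior_stats(lat), "all cells are border cells")

  # single label: one cell, no neighbours
  one <- matrix(1L, 4, 4)
  lat1 <- adjacency_from_labels(one, pixel_size = 1)
  expect_equal(nrow(lat1$cells), 1L)
  expect_equal(lat1$cells$neighbours[[1]], integer(0))

  # empty image errors
  expect_error(adjacency_from_labels(matrix(0L, 4, 4)), "empty label image")

  # a single-pixel corner touch is not adjacency (needs >= 2 contacts)
  corner <- rbind(c(1L, 1L, 2L, 2L),
                  c(1L, 1L, 2L, 2L),
                  c(3L, 3L, 4L, 4L),
                  c(3L, 3L, 4L, 4L))
  latc <- adjacency_from_labels(corner, pixel_size = 1)
  expect_equal(latc$cells$neighbours[[1]], c(2L, 3L))  # not 4
})

test_that("hexagonal lattices have pure-hexagon interior statistics", {
  hl <- make_hex_lattice(8, 8)
  st <- interior_stats(hl)
  expect_equal(st$mean_neighbour_number, 6)
  expect_equal(st$neighbour_frequencies$n, 6L)
  expect_equal(st$neighbour_frequencies$frequency, 1)
  expect_equal(sum(st$neighbour_frequencies$frequency), 1, tolerance = 1e-9)
  expect_equal(mean(st$cells$aspect_ratio), 1, tolerance = 1e-9)
  # a single polygon class cannot support a law fit
  expect_error(empirical_law_tables(st), "at least 3 polygon classes")
})

test_that("hand-built five-cell lattice reproduces exact hand counts", {
  # plus-shaped arrangement: centre square with 4 side squares
  sq <- function(x, y) cbind(c(x, x + 1, x + 1, x), c(y, y, y + 1, y + 1))
  polys <- list(sq(1, 1), sq(0, 1), sq(2, 1), sq(1, 0), sq(1, 2))
  nbrs <- list(c(2L, 3L, 4L, 5L), 1L, 1L, 1L, 1L)
  lat <- cell_lattice(polys, nbrs, is_border = c(FALSE, rep(TRUE, 4)))
  st <- interior_stats(lat)
  expect_equal(st$n_cells_interior, 1L)
  expect_equal(st$neighbour_frequencies$count, 1L)
  expect_equal(st$neighbour_frequencies$n, 4L)
  expect_equal(st$aboav_table$m, 1)  # all four neighbours have n = 1
})

test_that("adjacency symmetry is enforced at construction", {
  sq <- function(x, y) cbind(c(x, x + 1, x + 1, x), c(y, y, y + 1, y + 1))
  expect_error(
    cell_lattice(list(sq(0, 0), sq(1, 0)), list(2L, integer(0)),
                 c(TRUE, TRUE)),
    "not symmetric")
})

test_that("periodic trivalent lattices have mean neighbour number 6", {
  lat <- big_periodic_lattice()
  st <- interior_stats(lat)
  expect_equal(st$n_cells_interior, 2000L)
  expect_equal(st$mean_neighbour_number, 6, tolerance = 0.02 / 6)
  # frequency-weighted mean equals the mean neighbour number
  f <- st$neighbour_frequencies
  expect_equal(sum(f$frequency * f$n), st$mean_neighbour_number,
               tolerance = 1e-9)
  expect_equal(sum(f$frequency), 1, tolerance = 1e-9)
})

test_that("packing-law reference values are evaluated correctly", {
  expect_equal(lewis_expected(6), 1)
  expect_equal(lewis_expected(4), 0.5)
  expect_equal(lewis_expected(7), 1.25)
  expect_error(lewis_expected(2), "n >= 3")

  expect_equal(aboav_expected(8), 6)
  expect_equal(aboav_expected(8, form = "literal"), 4)
  expect_equal(6 * aboav_expected(6), 38)  # n m(n) = 5 n + 8
  expect_equal(aboav_expected(6, form = "literal"), 4.25)
  expect_error(aboav_expected(1), "n >= 3")
})

test_that("a Lewis-exact lattice is fitted to machine precision", {
  lat <- lewis_exact_lattice()
  st <- interior_stats(lat)
  lf <- empirical_law_tables(st)
  lewis <- lf$fits[lf$fits$law == "lewis", ]
  expect_equal(lewis$slope, 0.25, tolerance = 1e-10)
  expect_equal(lewis$intercept, -0.5, tolerance = 1e-10)
  expect_equal(lf$lewis$observed, lewis_expected(lf$lewis$n),
               tolerance = 1e-10)
})

test_that("Aboav-exact class means are fitted to machine precision", {
  st <- interior_stats(big_periodic_lattice())
  st$aboav_table$m <- aboav_expected(st$aboav_table$n)
  lf <- empirical_law_tables(st)
  abo <- lf$fits[lf$fits$law == "aboav_weaire", ]
  expect_equal(abo$slope, 5, tolerance = 1e-10)
  expect_equal(abo$intercept, 8, tolerance = 1e-10)
})

test_that("relaxed Voronoi lattices follow Lewis' law with the known slope", {
  lat <- make_voronoi_lattice(2000, relaxation_steps = 1, seed = 31,
                              periodic = TRUE)
  lf <- empirical_law_tables(interior_stats(lat))
  lewis_slope <- lf$fits$slope[lf$fits$law == "lewis"]
  expect_gt(lewis_slope, 0.15)
  expect_lt(lewis_slope, 0.30)
  # n m(n) is increasing and roughly linear (standard Aboav behaviour)
  expect_gt(lf$fits$r_squared[lf$fits$law == "aboav_weaire"], 0.99)
})

test_that("tidy and glance expose law-fit coefficients", {
  lf <- empirical_law_tables(interior_stats(lewis_exact_lattice()))
  td <- tidy(lf)
  expect_true(all(c("law", "slope", "intercept", "reference_slope")
                  %in% names(td)))
  expect_equal(nrow(td), 2L)
  gl <- glance(lf)
  expect_equal(nrow(gl), 1L)
  expect_gt(gl$lewis_r_squared, 0.999)
})

test_that("aspect ratios match closed forms and are rotation-invariant", {
  rect <- cbind(c(0, 2, 2, 0), c(0, 0, 1, 1))
  expect_equal(cell_aspect_ratio(rect), 2, tolerance = 1e-12)

  ang <- pi / 6 + (0:5) * pi / 3
  hexagon <- cbind(cos(ang), sin(ang))
  expect_equal(cell_aspect_ratio(hexagon), 1, tolerance = 1e-12)

  t <- seq(0, 2 * pi, length.out = 65)[-65]
  ell <- cbind(3 * cos(t), sin(t))
  expect_equal(cell_aspect_ratio(ell), 3, tolerance = 0.01)

  set.seed(42)
  base <- cell_aspect_ratio(ell)
  devs <- vapply(stats::runif(100, 0, 2 * pi), function(a) {
    R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
    abs(cell_aspect_ratio(ell %*% R + 5) - base)
  }, double(1))
  expect_lt(max(devs), 1e-9)

  # translation and scale invariance
  expect_equal(cell_aspect_ratio(rect * 3 + 100), 2, tolerance = 1e-12)
  # degenerate polygon errors
  expect_error(cell_aspect_ratio(cbind(c(0, 1, 2), c(0, 0, 0))),
               "degenerate")
})

test_that("3D outlines are projected to their best-fit plane first", {
  t <- seq(0, 2 * pi, length.out = 33)[-33]
  flat <- cbind(2 * cos(t), sin(t))
  # embed in 3D, tilt about x axis by 30 degrees
  tilt <- pi / 6
  xyz <- cbind(flat[, 1], flat[, 2] * cos(tilt), flat[, 2] * sin(tilt))
  expect_equal(cell_aspect_ratio(xyz), 2, tolerance = 1e-9)
})

test_that("border exclusion is idempotent and border flags are respected", {
  lat <- make_voronoi_lattice(200, relaxation_steps = 0, seed = 13)
  st1 <- interior_stats(lat)
  # re-flagging the already-interior subset changes nothing
  keep <- !lat$cells$is_border
  expect_equal(st1$n_cells_interior, sum(keep))
  expect_true(all(!lat$cells$is_border[st1$cells$cell_id]))
})

test_that("rasterized lattices recover true interior adjacency", {
  lat <- make_voronoi_lattice(250, relaxation_steps = 2, seed = 17)
  img <- rasterize_lattice(lat, pixel_size = 0.1)
  expect_equal(mean(img == 0), 0)   # tessellation tiles the raster
  rl <- adjacency_from_labels(img, pixel_size = attr(img, "pixel_size"))
  truth <- lat$cells$neighbours
  interior <- which(!lat$cells$is_border)
  ok <- vapply(interior, function(i) {
    j <- which(rl$cells$label == i)
    length(j) == 1 &&
      identical(sort(truth[[i]]), sort(rl$cells$neighbours[[j]]))
  }, logical(1))
  expect_gt(mean(ok), 0.9)   # lightly relaxed mosaics keep sub-pixel edges
  # border flags agree exactly with the generator
  expect_equal(rl$cells$is_border[match(seq_len(250), rl$cells$label)],
               lat$cells$is_border)
})
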