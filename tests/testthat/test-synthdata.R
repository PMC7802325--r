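# ground-truth generators: solids, phantoms, lattices, studies

test_that("generated solids are closed and match analytic ground truth", {
  s <- make_solid("sphere", list(radius = 1), refinement = 4)
  expect_true(is_closed_mesh(s))
  expect_equal(mesh_volume(s), attr(s, "truth")$volume, tolerance = 0.005)
  expect_equal(mesh_area(s), attr(s, "truth")$area, tolerance = 0.005)

  hc <- make_solid("hollow_cylinder",
                   list(r_in = 0.5, r_out = 0.9, length = 2), refinement = 3)
  expect_true(is_closed_mesh(hc))
  expect_equal(mesh_volume(hc), attr(hc, "truth")$volume, tolerance = 0.005)

  b <- make_solid("blob", list(radius = 1, amplitude = 0.2), seed = 9,
                  refinement = 3)
  expect_true(is_closed_mesh(b))
})

test_that("solid generators reject impossible dimensions", {
  expect_error(make_solid("sphere", list(radius = -1)), "positive")
  expect_error(make_solid("hollow_cylinder",
                          list(r_in = 1.2, r_out = 1, length = 5)),
               "r_in < r_out")
  expect_error(make_solid("blob", list(radius = 1, amplitude = -0.1)),
               "non-negative")
})

test_that("zero-amplitude blobs equal spheres bit for bit", {
  b0 <- make_solid("blob", list(radius = 1, amplitude = 0), seed = 3,
                   refinement = 3)
  s <- make_solid("sphere", list(radius = 1), refinement = 3)
  expect_identical(b0$vertices, s$vertices)
  expect_identical(b0$faces, s$faces)
})

test_that("solid and lattice generation is deterministic under a seed", {
  b1 <- make_solid("blob", list(radius = 1, amplitude = 0.1), seed = 7,
                   refinement = 2)
  b2 <- make_solid("blob", list(radius = 1, amplitude = 0.1), seed = 7,
                   refinement = 2)
  expect_identical(b1$vertices, b2$vertices)

  l1 <- make_voronoi_lattice(100, relaxation_steps = 2, seed = 5)
  l2 <- make_voronoi_lattice(100, relaxation_steps = 2, seed = 5)
  expect_identical(l1$cells$polygon, l2$cells$polygon)
  expect_identical(l1$cells$neighbours, l2$cells$neighbours)
})

test_that("Voronoi lattices are valid and periodic mode has no border", {
  lat <- make_voronoi_lattice(300, relaxation_steps = 1, seed = 2,
                              periodic = TRUE)
  expect_false(any(lat$cells$is_border))
  expect_equal(sum(lat$cells$area), attr(lat, "truth")$domain^2,
               tolerance = 1e-9)
  # symmetry check runs inside the validating constructor
  relat <- cell_lattice(lat$cells$polygon, lat$cells$neighbours,
                        lat$cells$is_border, periodic = TRUE, check = TRUE)
  expect_s3_class(relat, "cell_lattice")
  expect_error(make_voronoi_lattice(3), "at least 4")
})

test_that("Lloyd relaxation increases hexagon ordering", {
  hex_frac <- function(steps, seed) {
    lat <- make_voronoi_lattice(200, relaxation_steps = steps, seed = seed,
                                periodic = TRUE)
    mean(lat$cells$n_neighbours == 6L)
  }
  seeds <- 1:5
  f0 <- mean(vapply(seeds, function(s) hex_frac(0, s), double(1)))
  f50 <- mean(vapply(seeds, function(s) hex_frac(50, s), double(1)))
  expect_gt(f50, f0)
})

test_that("phantom pupils sit exactly at the target intraocular distance", {
  ph <- make_brain_phantom(wt_targets, seed = 21)
  expect_equal(landmark_distance(ph$pupils[[1]], ph$pupils[[2]]), 1.75,
               tolerance = 1e-12)
})

test_that("study configuration validates and round-trips via YAML/JSON", {
  cfg <- study_config()
  expect_equal(cfg$groups$n_samples, c(2L, 5L))
  expect_equal(cfg$groups$sphericity_mean, c(0.70, 0.67))
  expect_equal(cfg$groups$intraocular_mean, c(1.75, 1.85))
  expect_error(study_config(tibble::tibble(genotype = "WT",
                                           sphericity_sd = -1)),
               "non-negative")
  for (ext in c(".yaml", ".json")) {
    f <- withr::local_tempfile(fileext = ext)
    write_study_config(cfg, f)
    back <- read_study_config(f)
    expect_equal(back$groups$volume_mean, cfg$groups$volume_mean)
    expect_equal(back$seed, cfg$seed)
  }
})

test_that("generated studies have the configured cohort layout", {
  cfg <- study_config(seed = 7)
  st <- generate_study(cfg, lattices = FALSE)
  expect_length(st$samples, 7L)
  expect_equal(table(st$truth$genotype)[["WT"]], 2L)
  expect_equal(table(st$truth$genotype)[["HET"]], 5L)
  expect_equal(st$truth$sample_id[1], "WT_01")
})

test_that("zero-SD studies hit the configured means exactly", {
  cfg <- study_config(tibble::tibble(
    genotype = c("WT", "HET"), n_samples = c(1L, 1L),
    sphericity_sd = 0, intraocular_sd = 0, thickness_sd = 0,
    volume_sd = 0), seed = 3)
  st <- generate_study(cfg, lattices = FALSE)
  expect_equal(st$truth$target_sphericity, c(0.70, 0.67))
  expect_equal(st$truth$target_volume, c(3.28, 3.60))
  rec <- analyze_sample(st$samples[[1]],
                        attr(st$samples[[1]], "split_plane"))
  expect_equal(rec$ventricle_sphericity_left, 0.70, tolerance = 1e-6)
  expect_equal(rec$brain_volume, 3.28, tolerance = 1e-9)
  expect_equal(rec$cortical_thickness, 0.08, tolerance = 1e-9)
})

test_that("written studies are byte-identical under a fixed seed", {
  cfg <- study_config(tibble::tibble(genotype = c("WT", "HET"),
                                     n_samples = c(1L, 1L),
                                     n_cells = c(60L, 60L)), seed = 11)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_study(cfg, dir = d1, refinement = list(cortex = 2, nx = 24,
                                                  nth = 32))
  generate_study(cfg, dir = d2, refinement = list(cortex = 2, nx = 24,
                                                  nth = 32))
  f1 <- sort(list.files(d1, recursive = TRUE))
  f2 <- sort(list.files(d2, recursive = TRUE))
  expect_identical(f1, f2)
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
})

test_that("study manifests carry genotype, plane and per-sample truth", {
  cfg <- study_config(tibble::tibble(genotype = "HET", n_samples = 1L,
                                     n_cells = 60L), seed = 19)
  d <- withr::local_tempdir()
  generate_study(cfg, dir = d, refinement = list(cortex = 2, nx = 24,
                                                 nth = 32))
  mf <- jsonlite::fromJSON(file.path(d, "manifest.json"),
                           simplifyDataFrame = FALSE)
  e <- mf$samples[[1]]
  expect_equal(e$genotype, "HET")
  expect_equal(unlist(e$split_plane$normal), c(1, 0, 0))
  expect_true(all(c("sphericity", "brain_volume") %in% names(e$truth)))
  expect_true(file.exists(file.path(d, e$dir, e$lattice)))
})
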