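# organ-scale statistics: sphericity, cortical thickness, sample records,
# group summaries

test_that("sphericity matches closed forms and is bounded by the sphere", {
  expect_equal(sphericity(4 * pi / 3, 4 * pi), 1, tolerance = 1e-12)
  # unit cube: pi^(1/3) * 6^(2/3) / 6, evaluated independently
  cube_expected <- pi^(1 / 3) * 6^(2 / 3) / 6
  expect_equal(sphericity(1, 6), cube_expected, tolerance = 1e-12)
  expect_equal(round(sphericity(1, 6), 5), 0.80600)

  sph <- make_solid("sphere", list(radius = 1), refinement = 4)
  s_sphere <- sphericity(mesh_volume(sph), mesh_area(sph))
  expect_gt(s_sphere, 0.995)
  expect_lte(s_sphere, 1 + 1e-6)

  ell <- make_solid("ellipsoid", list(semi_axes = c(2, 1, 1)),
                    refinement = 3)
  expect_lt(sphericity(mesh_volume(ell), mesh_area(ell)), s_sphere)

  expect_error(sphericity(-1, 6), "positive")
  expect_error(sphericity(1, 0), "positive")
})

test_that("every closed synthetic solid has sphericity at most 1", {
  solids <- list(
    make_solid("sphere", list(radius = 0.7), refinement = 3),
    make_solid("cube", list(side = 2)),
    make_solid("ellipsoid", list(semi_axes = c(3, 1, 0.5)), refinement = 3),
    make_solid("blob", list(radius = 1, amplitude = 0.2), seed = 8,
               refinement = 3))
  for (m in solids)
    expect_lte(sphericity(mesh_volume(m), mesh_area(m)), 1 + 1e-6)
})

test_that("cortical thickness recovers hollow-cylinder wall width", {
  # smooth closed form: h reduces to r_out - r_in for side walls
  expect_equal(cortical_thickness(pi * (1.2^2 - 1) * 5,
                                  2 * pi * 1.2 * 5, 2 * pi * 1 * 5),
               0.2, tolerance = 1e-12)
  expect_equal(cortical_thickness(1, 1, 1), 1)
  # homogeneity: doubling volume and both areas leaves h unchanged
  expect_equal(cortical_thickness(2 * 1.7, 2 * 3.1, 2 * 2.9),
               cortical_thickness(1.7, 3.1, 2.9), tolerance = 1e-12)
  expect_error(cortical_thickness(0, 1, 1), "positive")
})

test_that("mesh-measured hollow cylinder obeys the thickness identity", {
  hc <- make_solid("hollow_cylinder",
                   list(r_in = 1, r_out = 1.2, length = 5), refinement = 3)
  v <- mesh_volume(hc)
  V <- hc$vertices
  r <- sqrt(V[, 1]^2 + V[, 2]^2)
  f_r <- matrix(r[hc$faces], ncol = 3)
  outer_faces <- rowSums(abs(f_r - 1.2) < 1e-9) == 3L
  inner_faces <- rowSums(abs(f_r - 1.0) < 1e-9) == 3L
  a_out <- sum(neuromorph:::face_areas(V, hc$faces[outer_faces, ]))
  a_in <- sum(neuromorph:::face_areas(V, hc$faces[inner_faces, ]))
  h <- cortical_thickness(v, a_out, a_in)
  # algebraic identity for the polygonal prism: h = cos(pi/n) (r_out - r_in)
  nth <- sum(abs(V[, 3]) < 1e-12 & abs(r - 1.2) < 1e-9)
  expect_equal(h, cos(pi / nth) * 0.2, tolerance = 1e-9)
  expect_equal(h, 0.2, tolerance = 0.005)
})

test_that("analyze_sample recovers phantom ground truth end to end", {
  ph <- make_brain_phantom(wt_targets, sample_id = "wt1", seed = 1)
  rec <- analyze_sample(ph, attr(ph, "split_plane"))
  expect_equal(rec$brain_volume, 3.41, tolerance = 0.005)
  expect_equal(rec$ventricle_sphericity_left, 0.70, tolerance = 0.01)
  expect_equal(rec$ventricle_sphericity_right, 0.70, tolerance = 0.01)
  expect_equal(rec$cortical_thickness, 0.08, tolerance = 0.02)
  expect_equal(rec$intraocular_distance, 1.75, tolerance = 1e-12)
  truth <- attr(ph, "truth")
  expect_equal(rec$ventricle_volume_left + rec$ventricle_volume_right,
               truth$ventricle_volume, tolerance = 0.005)
  expect_lt(rec$ventricle_volume_left + rec$ventricle_volume_right,
            rec$brain_volume)
})

test_that("near-spherical ventricle lobes have near-unit sphericity", {
  ph <- make_brain_phantom(list(brain_volume = 3, sphericity = 0.99,
                                cortical_thickness = 0.3,
                                intraocular_distance = 1.7), seed = 2)
  rec <- analyze_sample(ph, attr(ph, "split_plane"))
  expect_equal(rec$ventricle_sphericity_left, 0.99, tolerance = 0.005)
})

test_that("unreachable phantom targets raise errors", {
  bad <- wt_targets; bad$sphericity <- 1.2
  expect_error(make_brain_phantom(bad), "unreachable")
  thick <- wt_targets; thick$cortical_thickness <- 5
  expect_error(make_brain_phantom(thick, seed = 3), "unreachable")
})

test_that("a split plane that misses the ventricles propagates an error", {
  ph <- make_brain_phantom(wt_targets, seed = 5)
  expect_error(analyze_sample(ph, plane(c(50, 0, 0), c(1, 0, 0))),
               "no intersection")
})

test_that("group summaries use sample SD and pool ventricles per lobe", {
  recs <- tibble::tibble(
    sample_id = c("a", "b"), genotype = "WT",
    cortical_thickness = c(0.69, 0.71),
    ventricle_sphericity_left = c(0.68, 0.72),
    ventricle_sphericity_right = c(0.70, 0.70))
  out <- summarize_groups(recs)
  th <- out[out$metric == "cortical_thickness", ]
  expect_equal(th$n, 2L)
  expect_equal(th$mean, 0.70)
  expect_equal(th$sd, stats::sd(c(0.69, 0.71)), tolerance = 1e-12)
  expect_equal(round(th$sd, 4), 0.0141)
  sp <- out[out$metric == "ventricle_sphericity", ]
  expect_equal(sp$n, 4L)  # 2 brains -> 4 ventricles
  expect_equal(sp$mean, 0.70)

  single <- summarize_groups(recs[1, ])
  expect_true(is.na(single$sd[single$metric == "cortical_thickness"]))
  expect_error(summarize_groups(recs[0, ]), "no morphometric records")
})

test_that("group summaries are invariant to record order", {
  ph1 <- make_brain_phantom(wt_targets, sample_id = "s1", seed = 11)
  ph2 <- make_brain_phantom(list(brain_volume = 3.6, sphericity = 0.67,
                                 cortical_thickness = 0.1,
                                 intraocular_distance = 1.85),
                            sample_id = "s2", genotype = "HET", seed = 12)
  r1 <- analyze_sample(ph1, attr(ph1, "split_plane"))
  r2 <- analyze_sample(ph2, attr(ph2, "split_plane"))
  both <- dplyr::bind_rows(r1, r2)
  expect_equal(summarize_groups(both),
               summarize_groups(dplyr::bind_rows(r2, r1)))
})

test_that("lobe-wise thickness columns appear on request", {
  ph <- make_brain_phantom(wt_targets, seed = 6)
  rec <- analyze_sample(ph, attr(ph, "split_plane"), lobe_thickness = TRUE)
  expect_true(all(c("cortical_thickness_left", "cortical_thickness_right")
                  %in% names(rec)))
  expect_gt(rec$cortical_thickness_left, 0)
})
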