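# shared fixtures, built once per test run

.fixtures <- new.env(parent = emptyenv())

# large periodic Lloyd-relaxed lattice used by topology and law tests
big_periodic_lattice <- function() {
  if (is.null(.fixtures$big))
    .fixtures$big <- make_voronoi_lattice(2000, relaxation_steps = 5,
                                          seed = 101, periodic = TRUE)
  .fixtures$big
}

# periodic lattice rebuilt so every cell's area is exactly the Lewis-law
# value for its neighbour class (polygons rescaled about their centroids);
# adjacency is untouched, so the lattice satisfies Lewis' law by
# construction
lewis_exact_lattice <- function(n_cells = 300, seed = 5) {
  lat <- make_voronoi_lattice(n_cells, relaxation_steps = 1, seed = seed,
                              periodic = TRUE)
  cells <- lat$cells
  target <- 20 * (cells$n_neighbours - 2) / 4
  polys <- lapply(seq_len(nrow(cells)), function(i) {
    xy <- cells$polygon[[i]]
    cen <- colMeans(xy)
    f <- sqrt(target[i] / cells$area[i])
    cbind(cen[1] + f * (xy[, 1] - cen[1]), cen[2] + f * (xy[, 2] - cen[2]))
  })
  cell_lattice(polys, cells$neighbours, cells$is_border,
               periodic = TRUE, check = FALSE)
}

# prolate spheroid surface area, semi-axes (a, b, b), a > b
prolate_area <- function(a, b) {
  e <- sqrt(1 - b^2 / a^2)
  2 * pi * b^2 * (1 + a / (b * e) * asin(e))
}

# default organ-scale targets used in phantom tests
wt_targets <- list(brain_volume = 3.41, sphericity = 0.70,
                   cortical_thickness = 0.08, intraocular_distance = 1.75)
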