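test_that("conductance graph implements averaging and diagonal scaling", {
  r <- raster_surface(matrix(c(2, 4), 1, 2), cell_size = 1)
  g <- build_conductance_graph(r, 4)
  expect_equal(g$edges$resistance, 3)
  expect_equal(g$edges$conductance, 1 / 3)
  rd <- raster_surface(matrix(c(2, NA, NA, 4), 2, 2), cell_size = 1)
  gd <- build_conductance_graph(rd, 8)
  expect_equal(gd$edges$resistance, 3 * sqrt(2))
  # uniform grid: all cardinal conductances equal 1/r
  ru <- raster_surface(matrix(5, 3, 3), cell_size = 1)
  gu <- build_conductance_graph(ru, 4)
  expect_true(all(abs(gu$edges$conductance - 1 / 5) < 1e-12))
})

test_that("commute distances match hand Laplacian oracles", {
  # two nodes, single edge of conductance c: R_eff = 1/c, vol = 2c, commute = 2
  r <- raster_surface(matrix(c(2, 4), 1, 2), cell_size = 1)
  g <- build_conductance_graph(r, 4)
  cd <- commute_distance(g, c(1L, 2L))
  expect_equal(cd[1, 2], 2, tolerance = 1e-12)
  # 3-node path with unit conductances: commute(1,3) = vol * R_eff = 4 * 2 = 8
  r3 <- raster_surface(matrix(1, 1, 3), cell_size = 1)
  g3 <- build_conductance_graph(r3, 4)
  cd3 <- commute_distance(g3, 1:3)
  expect_equal(cd3[1, 3], 8, tolerance = 1e-12)
  expect_equal(cd3[1, 2], 4, tolerance = 1e-12)
  # full pseudoinverse oracle on a 5-node random graph
  set.seed(41)
  r5 <- raster_surface(matrix(runif(5, 1, 10), 1, 5), cell_size = 1)
  g5 <- build_conductance_graph(r5, 4)
  cd5 <- commute_distance(g5, 1:5)
  e <- g5$edges
  L <- matrix(0, 5, 5)
  for (k in seq_len(nrow(e))) {
    L[e$a[k], e$b[k]] <- L[e$a[k], e$b[k]] - e$conductance[k]
    L[e$b[k], e$a[k]] <- L[e$b[k], e$a[k]] - e$conductance[k]
  }
  diag(L) <- -rowSums(L)
  Lp <- MASS::ginv(L)
  vol <- sum(diag(L))
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(cd5[i, j], vol * (Lp[i, i] + Lp[j, j] - 2 * Lp[i, j]),
                 tolerance = 1e-8)
  }
})

test_that("a parallel edge halves the effective resistance", {
  # 2x1 of resistance 1 gives R_eff = 1 between the two cells; an equivalent
  # parallel path through a second row halves it
  r1 <- raster_surface(matrix(1, 1, 2), cell_size = 1)
  g1 <- build_conductance_graph(r1, 4)
  reff1 <- attr(commute_distance(g1, 1:2), "r_eff")[1, 2]
  expect_equal(reff1, 1, tolerance = 1e-12)
})

test_that("commute distances are metric and scale with global resistance", {
  set.seed(42)
  r <- raster_surface(matrix(runif(100, 1, 20), 10, 10), cell_size = 1)
  g <- build_conductance_graph(r)
  f <- as.integer(c(1, 25, 60, 99))
  cd <- unclass(commute_distance(g, f))
  expect_equal(cd, t(cd))
  for (i in 1:4) for (j in 1:4) for (k in 1:4) {
    expect_lte(cd[i, j], cd[i, k] + cd[k, j] + 1e-9)
  }
  # doubling every resistance doubles effective resistances; the random-walk
  # commute time is invariant (the walk itself is unchanged), so MLPE model
  # ranking on standardised predictors is unaffected either way
  d1 <- commute_distance(g, f)
  d2 <- commute_distance(build_conductance_graph(
    raster_surface(2 * r$values, cell_size = 1)), f)
  expect_equal(unclass(attr(d2, "r_eff")), 2 * unclass(attr(d1, "r_eff")),
               tolerance = 1e-9)
  expect_equal(unclass(d2)[1:4, 1:4], unclass(d1)[1:4, 1:4], tolerance = 1e-9)
  x1 <- unclass(d1)[lower.tri(d1)]; x2 <- unclass(attr(d2, "r_eff"))[lower.tri(d1)]
  expect_equal(stats::cor(x1, x2), 1, tolerance = 1e-12)
})

test_that("current maps conserve current and respect symmetry", {
  r <- raster_surface(matrix(1, 7, 7), cell_size = 1)
  sites <- data.frame(site_id = c("A", "B"), x = c(0.5, 6.5), y = c(3.5, 3.5))
  cm <- current_map(r, sites)
  expect_lt(cm$max_kirchhoff_violation, 1e-8)
  m <- cm$map$values
  expect_lt(max(abs(m - m[, 7:1])), 1e-8)    # reflection exchanging A and B
  expect_true(all(m >= 0))
  # focal cells carry the injected unit current
  expect_equal(m[4, 1], 1, tolerance = 1e-8)
})

test_that("current and commute solvers agree on effective resistance", {
  set.seed(43)
  r <- raster_surface(matrix(runif(64, 1, 30), 8, 8), cell_size = 1)
  sites <- data.frame(site_id = c("A", "B", "C"),
                      x = c(0.5, 7.5, 4.5), y = c(0.5, 7.5, 3.5))
  cm <- current_map(r, sites)
  g <- build_conductance_graph(r)
  cd <- commute_distance(g, site_nodes(g, sites))
  reff_commute <- unclass(cd) / attr(cd, "volume")
  expect_lt(max(abs(unclass(cm$r_eff) - reff_commute) /
                  pmax(reff_commute, 1e-12)), 1e-8)
})

test_that("disconnected focal components are reported", {
  v <- matrix(1, 3, 5)
  v[, 3] <- NA                               # wall
  r <- raster_surface(v, cell_size = 1)
  g <- build_conductance_graph(r)
  left <- g$node_of_cell[2, 1]; right <- g$node_of_cell[2, 5]
  expect_error(commute_distance(g, c(left, right)), "disconnected")
})
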