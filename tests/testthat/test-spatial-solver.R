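test_that("grid geometry is exact", {
  g <- build_grid(4, 4, R = 3e-3, L = 12e-3)
  expect_equal(length(g$vol), 16)
  expect_equal(sum(g$vol), pi * (3e-3)^2 * 12e-3, tolerance = 1e-12)
  # refinement: each parent volume equals the sum of its four children
  g2 <- build_grid(8, 8, R = 3e-3, L = 12e-3)
  child <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    child[i, j] <- sum(g2$vol[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)])
  }
  expect_equal(child, g$vol, tolerance = 1e-12)
  expect_error(build_grid(2, 8), ">= 4")
  expect_error(build_grid(8, 8, R = 0), "> 0")
})

test_that("domain presets and explicit extents classify cells correctly", {
  g <- build_grid(8, 12)
  expect_true(all(assign_domains("depot-only", g) == 2L))
  m <- assign_domains("standard", g)
  expect_setequal(sort(unique(as.vector(m))), 1:3)
  # explicit extents agree with a brute-force centre-in-box check
  layout <- list(k2 = list(r = c(0, 1.1e-3), z = c(3e-3, 7e-3)),
                 k1 = list(z = c(11e-3, 12e-3)))
  m2 <- assign_domains(layout, g)
  for (i in seq_len(g$nr)) for (j in seq_len(g$nz)) {
    r <- g$r[i]; z <- g$z[j]
    want <- if (r >= 0 && r <= 1.1e-3 && z >= 3e-3 && z <= 7e-3) 2L
            else if (z >= 11e-3) 1L else 3L
    expect_identical(m2[i, j], want)
  }
  expect_error(assign_domains(list(k1 = list(z = c(0, 1e-3))), g), "depot")
  expect_error(assign_domains("bogus", g), "preset")
})

test_that("the diffusion operator is conservative and kills uniform fields", {
  g <- build_grid(9, 7)
  expect_equal(axisym_laplacian(matrix(3.7, 9, 7), 2e-10, g),
               matrix(0, 9, 7), tolerance = 1e-20)
  set.seed(42)
  f <- matrix(runif(63), 9, 7)
  D <- matrix(runif(63, 1e-11, 1e-9), 9, 7) # heterogeneous diffusivity
  lap <- axisym_laplacian(f, D, g)
  expect_lt(abs(sum(lap * g$vol)) / sum(abs(lap) * g$vol), 1e-12)
})

test_that("radial Gaussian spreading matches the closed-form kernel", {
  D <- water_diffusivity(103.12) # GABA-scale tracer
  R <- 3e-4
  t0 <- (0.2 * R)^2 / (4 * D)
  t_run <- 1
  p <- nrl_params(spatial = list(R = R, L = 1.2e-3, nr = 64, nz = 4,
                                 dt = 0.002, t_end = t_run,
                                 domain_factors = c(k1 = 1, k2 = 1, k3 = 1)))
  g <- build_grid(64, 4, R, 1.2e-3)
  gauss <- function(r, tt) (t0 / tt) * exp(-r^2 / (4 * D * tt))
  f0 <- uniform_fields(batch_state(), g)
  f0$GABA <- matrix(gauss(g$r, t0), g$nr, g$nz)
  rec <- run_spatial(p, fields0 = f0, out_times = t_run)
  got <- rec$fields[[1]]$GABA[, 1]
  want <- gauss(g$r, t0 + t_run)
  core <- want > 0.01 * max(want) # before boundary contact
  expect_lt(max(abs(got - want)[core] / max(want)), 0.02)
})

test_that("spatial convergence order on the diffusion-only problem is ~2", {
  D <- water_diffusivity(103.12)
  R <- 3e-4
  t0 <- (0.2 * R)^2 / (4 * D)
  gauss <- function(r, tt) (t0 / tt) * exp(-r^2 / (4 * D * tt))
  err <- vapply(c(16, 32, 64), function(nr) {
    p <- nrl_params(spatial = list(R = R, L = 1.2e-3, nr = nr, nz = 4,
                                   dt = 0.002, t_end = 1,
                                   domain_factors = c(k1 = 1, k2 = 1, k3 = 1)))
    g <- build_grid(nr, 4, R, 1.2e-3)
    f0 <- uniform_fields(batch_state(), g)
    f0$GABA <- matrix(gauss(g$r, t0), nr, 4)
    rec <- run_spatial(p, fields0 = f0, out_times = 1)
    got <- rec$fields[[1]]$GABA[, 1]
    sqrt(sum(g$vol_r * (got - gauss(g$r, t0 + 1))^2) / sum(g$vol_r))
  }, numeric(1))
  orders <- log2(err[-3] / err[-1])
  expect_true(all(orders >= 1.8))
})

test_that("spatial RHS reduces to the batch rate vector when D = 0", {
  p <- small_spatial_params(nr = 4, nz = 4,
                            domain_factors = c(k1 = 0, k2 = 0, k3 = 0),
                            preset = "depot-only")
  g <- build_grid(4, 4, p$spatial$R, p$spatial$L)
  m <- assign_domains("depot-only", g)
  st <- default_state0(p)
  f <- uniform_fields(st, g)
  d <- spatial_rhs(f, p, m, g)
  r <- rate_vector(st, p)
  for (s in c("SC", "p", "pSC", "mp", "mpSC", "GABA", "CO2")) {
    expect_equal(d[[s]], matrix(r[[s]], 4, 4), tolerance = 1e-14)
  }
  # equilibrated uniform fields with Vmax ~ 0 are stationary
  p0 <- nrl_params(kinetics = list(Vmax = 1e-300),
                   spatial = p$spatial)
  f0 <- uniform_fields(default_state0(p0), g)
  d0 <- spatial_rhs(f0, p0, m, g)
  expect_lt(max(abs(unlist(d0))), 1e-15)
})

test_that("spatial RHS matches a brute-force assembly on a 4x4 grid", {
  p <- small_spatial_params(nr = 4, nz = 4)
  g <- build_grid(4, 4, p$spatial$R, p$spatial$L)
  map <- assign_domains(list(k2 = list(z = c(0, 6e-3)),
                             k1 = list(z = c(9e-3, 12e-3))), g)
  set.seed(7)
  f <- lapply(stats::setNames(nm = c("SC", "p", "pSC", "mp", "mpSC",
                                     "enzyme", "GABA", "CO2")),
              function(s) matrix(runif(16, 0, 1e-2), 4, 4))
  f$mp <- f$mp * 1e-4; f$mpSC <- f$mpSC * 1e-4
  got <- spatial_rhs(f, p, map, g)
  # independent naive assembly: explicit loops, plain formulas
  k <- p$kinetics
  sp <- p$species
  fac <- c(1, 0.9, 1)
  dr <- g$dr; dz <- g$dz
  for (s in names(f)) {
    i_sp <- match(s, sp$name)
    want <- matrix(0, 4, 4)
    for (i in 1:4) for (j in 1:4) {
      csc <- f$SC[i, j]; cp <- f$p[i, j]; cpsc <- f$pSC[i, j]
      cmp <- f$mp[i, j]; cmpsc <- f$mpSC[i, j]
      vmax <- if (map[i, j] == 2L) k$Vmax else 0
      RMMmp <- vmax * cmp * k$Ssa / (k$KM + cmp * k$Ssa)
      RMMmpsc <- vmax * cmpsc * k$Ssa / (k$KM + cmpsc * k$Ssa)
      reac <- switch(s,
        SC = -k$kf1 * csc * (cmp * k$Ssa + cp) +
          k$kr1 * (cmpsc * k$Ssa + cpsc),
        p = -k$kf1 * csc * cp + k$kr1 * cpsc + RMMmp,
        pSC = k$kf1 * csc * cp - k$kr1 * cpsc + RMMmpsc,
        mp = -k$kf1 * csc * cmp + k$kr1 * cmpsc - RMMmp / k$Ssa,
        mpSC = k$kf1 * csc * cmp - k$kr1 * cmpsc - RMMmpsc / k$Ssa,
        enzyme = 0, GABA = RMMmpsc, CO2 = RMMmpsc)
      diffu <- 0
      if (sp$diffusive[i_sp]) {
        Dij <- sp$D_water[i_sp] * fac[map[i, j]]
        vol <- 2 * pi * g$r[i] * dr * dz
        for (nb in list(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1))) {
          ii <- nb[1]; jj <- nb[2]
          if (ii < 1 || ii > 4 || jj < 1 || jj > 4) next
          Dnb <- sp$D_water[i_sp] * fac[map[ii, jj]]
          Dh <- if (Dij + Dnb > 0) 2 * Dij * Dnb / (Dij + Dnb) else 0
          if (jj == j) { # radial face
            rf <- max(g$r[i], g$r[ii]) - dr / 2
            area <- 2 * pi * rf * dz
            diffu <- diffu + area * Dh * (f[[s]][ii, jj] - f[[s]][i, j]) /
              dr / vol
          } else {
            area <- 2 * pi * g$r[i] * dr
            diffu <- diffu + area * Dh * (f[[s]][ii, jj] - f[[s]][i, j]) /
              dz / vol
          }
        }
      }
      want[i, j] <- reac + diffu
    }
    expect_equal(got[[s]], want, tolerance = 1e-12)
  }
})

test_that("a no-reaction run conserves every species total to round-off", {
  p <- small_spatial_params(nr = 8, nz = 8, t_end = 1)
  g <- build_grid(8, 8, p$spatial$R, p$spatial$L)
  f0 <- uniform_fields(batch_state(), g)
  f0$GABA <- matrix(exp(-((matrix(g$r, 8, 8) - 1e-3)^2 +
                          (matrix(g$z, 8, 8, byrow = TRUE) - 6e-3)^2) /
                        1e-6), 8, 8)
  rec <- run_spatial(p, fields0 = f0, out_times = c(0, 0.5, 1))
  tot <- vapply(rec$fields, function(f) sum(f$GABA * g$vol), numeric(1))
  expect_lt(max(abs(tot - tot[1])) / tot[1], 1e-10)
  # and the bulk series of a conserved species is constant
  b <- total_bulk_concentration(rec, "GABA")
  expect_lt(max(abs(b$mean_conc - b$mean_conc[1])) / b$mean_conc[1], 1e-10)
})

test_that("with diffusion off the PDE solution equals the batch reactor", {
  p <- small_spatial_params(nr = 4, nz = 4, t_end = 2,
                            domain_factors = c(k1 = 0, k2 = 0, k3 = 0),
                            preset = "depot-only")
  st <- default_state0(p)
  g <- build_grid(4, 4, p$spatial$R, p$spatial$L)
  rec <- run_spatial(p, fields0 = uniform_fields(st, g), out_times = 2)
  tr <- integrate_batch(st, p, t_end = 2, dt_out = 0.5)
  row <- tr[tr$time == 2, ]
  for (s in c("SC", "p", "pSC", "mp", "mpSC", "GABA")) {
    expect_lt(max(rel_err(rec$fields[[1]][[s]], row[[s]])), 1e-6)
  }
})

test_that("uniform initial field gives its own bulk average", {
  p <- small_spatial_params()
  g <- build_grid(4, 8, p$spatial$R, p$spatial$L)
  f0 <- uniform_fields(batch_state(conc = c(GABA = 0.37)), g)
  rec <- run_spatial(p, fields0 = f0, out_times = 0)
  expect_equal(total_bulk_concentration(rec, "GABA")$mean_conc, 0.37)
})

test_that("mirror-symmetric layouts produce mirror-symmetric solutions", {
  L <- 12e-3
  p <- small_spatial_params(nr = 4, nz = 8, t_end = 1)
  g <- build_grid(4, 8, p$spatial$R, L)
  # depot over the central third only: symmetric about the mid-plane
  map <- assign_domains(list(k2 = list(z = c(L / 3, 2 * L / 3))), g)
  expect_true(all(map[, 1:4] == map[, 8:5]))
  f0 <- make_initial_fields(g, map, p) # enzyme in depot (no cellular zone)
  rec <- run_spatial(p, fields0 = f0, out_times = 1, domain_map = map)
  f1 <- rec$fields[[1]]
  for (s in names(f1)) {
    expect_equal(f1[[s]][, 1:4], f1[[s]][, 8:5], tolerance = 1e-12)
  }
})

test_that("GABA first appears inside the depot where matrix complex is high", {
  p <- nrl_params(spatial = list(nr = 8, nz = 32, t_end = 2))
  rec <- run_spatial(p)
  i <- which(rec$times >= 1)[1]
  f <- rec$fields[[i]]
  am <- which(f$GABA == max(f$GABA), arr.ind = TRUE)
  expect_true(all(rec$domain_map[am] == 2L))
  expect_gt(max(f$GABA), 0)
})
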