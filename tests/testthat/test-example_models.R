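test_that("every scenario builds, runs 100 steps and keeps its invariants", {
  # desk-scale smoke matrix across 5 seeds (scenario sizes reduced)
  sizes <- list(birth = list(), decay = list(n0 = 60L),
                bimolecular = list(n_each = 12L),
                free_diffusion = list(n = 27L),
                division = list(n_content = 4L),
                vesicle = list(scale = 0.005),
                yeast = list(n_cells = 2L, k_emit = 2e3, t_step = 1e-5),
                raft = list(n_each = 10L))
  for (name in list_scenarios()) {
    for (seed in 1:5) {
      st <- build_scenario(name, seed = seed, overrides = sizes[[name]])
      run_steps(st, 100)
      expect_silent(audit_forest(st))
      expect_length(audit_containment(st), 0L)
      expect_true(all(is.finite(st$pos)) && all(is.finite(st$vel)))
    }
  }
})

test_that("directed vesicle initial conditions match the stated world", {
  fx <- scenario_vesicle(seed = 1, directed = TRUE, scale = 0.01)
  m0 <- vesicle_metrics(fx$state)
  expect_equal(m0$v1 / m0$v2, 9.08, tolerance = 0.01)   # nine times bigger
  expect_equal(m0$v1, 0.118e-18, tolerance = 0.01)
  expect_equal(m0$totalX, 1000)                         # 90% + 10% at 0.01
  cell_row <- match(fx$cell, fx$state$id)
  expect_equal(fx$state$radius[cell_row], 2.5e-6)       # cell radius 2.5 um
  expect_error(scenario_vesicle(scale = 1e-6), "round to zero")
})

test_that("budding and fusion conserve SNARE counts at every step", {
  fx <- scenario_vesicle(seed = 3, directed = TRUE, scale = 0.01)
  st <- fx$state
  m0 <- vesicle_metrics(st)
  for (i in 1:60) {
    run_steps(st, 25)
    mm <- vesicle_metrics(st)
    expect_identical(mm$totalX, m0$totalX)
    expect_identical(mm$totalY, m0$totalY)
  }
})

test_that("the yeast oscillator divides at roughly the 120-minute period", {
  periods <- vapply(1:3, function(seed) {
    fx <- scenario_yeast(seed = seed, n_cells = 1, k_emit = 0, t_step = 10)
    st <- fx$state
    for (i in 1:3000) {
      step(st)
      if (length(st$transitions)) break
    }
    st$time
  }, numeric(1))
  # 100 exponential increments: mean 7200 s, CV 10%
  expect_true(all(abs(periods / 7200 - 1) < 0.35))
  expect_lt(sd(periods) / mean(periods), 0.3)
})

test_that("bound pheromone slows the cycle monotonically", {
  progress <- vapply(c(0, 50, 568), function(bound) {
    fx <- scenario_yeast(seed = 5, n_cells = 1, k_emit = 0, t_step = 10)
    st <- fx$state
    p_set_attr(st, fx$cells[1], "bound", bound)
    run_steps(st, 200)    # 2000 s
    p_attr(st, fx$cells[1], "cycM")
  }, numeric(1))
  expect_true(all(diff(progress) < 0))
})

test_that("raft geometry and mobility: 25% area, 10x slower inside", {
  fx <- scenario_raft(seed = 1, n_each = 5)
  st <- fx$state
  r_raft <- p_radius(st, fx$raft)
  box <- st$phys$domain_hi[1]
  expect_equal(pi * r_raft^2 / box^2, 0.25, tolerance = 1e-12)
  out <- st$id[st$species == "CK1"][1]
  D_out <- diffusion_coefficient(st, out)
  reparent(st, out, fx$raft)
  st$pos[match(out, st$id), ] <- p_position(st, fx$raft)
  expect_equal(diffusion_coefficient(st, out) / D_out, 0.1,
               tolerance = 1e-12)
  # proteins start outside the raft
  fx2 <- scenario_raft(seed = 2, n_each = 30)
  expect_identical(unname(raft_counts(fx2$state)), c(0L, 0L))
})

test_that("estimate_rate recovers generating constants from clean series", {
  t <- seq(0, 5, by = 0.25)
  k <- 0.8
  fit1 <- suppressWarnings(estimate_rate(t, 1000 * exp(-k * t), order = 1))
  expect_equal(fit1$rate, k, tolerance = 1e-4)
  # order 2: 1/N linear in t with slope k/V
  kV <- 3e-3
  fit2 <- suppressWarnings(estimate_rate(t, 1 / (1 / 400 + kV * t), order = 2))
  expect_equal(fit2$rate, kV, tolerance = 1e-6)
  expect_error(estimate_rate(1:2, c(5, 3), order = 1), "insufficient")
})

test_that("msd and occupancy agree with closed forms", {
  # deterministic linear motion: MSD(lag) = (v dt lag)^2 exactly
  v <- c(1e-6, 0, 0); dt <- 0.1
  frames <- lapply(0:10, function(k)
    list(time = k * dt, n = 4L, id = 1:4,
         pos = matrix(rep(k * dt * v, each = 4), 4, 3) +
           matrix(1e-5 * (1:4), 4, 3),
         species = rep("A", 4), radius = rep(1e-6, 4), parent = rep(0L, 4)))
  mm <- msd(frames, lags = 1:5)
  expect_equal(mm$msd, (v[1] * dt * (1:5))^2, tolerance = 1e-12)
  # occupancy boundary cases
  fr <- list(list(time = 0, n = 3L, id = 1:3,
                  pos = matrix(0, 3, 3),
                  species = c("Raft", "P", "P"),
                  radius = rep(1e-6, 3), parent = c(0L, 1L, 1L)))
  expect_equal(occupancy(fr, "P", "Raft")$occupancy, 1)
  fr[[1]]$parent <- c(0L, 0L, 0L)
  expect_equal(occupancy(fr, "P", "Raft")$occupancy, 0)
})
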