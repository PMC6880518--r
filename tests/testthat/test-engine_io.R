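test_that("an empty system step only advances time by max_timestep", {
  st <- tiny_state()
  step(st)
  expect_equal(st$time, st$phys$max_timestep)
  expect_identical(st$n, 0L)
})

test_that("the step trace follows the canonical phase order", {
  st <- tiny_state()
  spawn_particle(st, "A", rep(5e-5, 3))
  seen <- character(0)
  st$phase_hook <- function(phase) seen <<- c(seen, phase)
  step(st)
  expect_identical(seen, c("lower_order", "integrate", "collide",
                           "bimolecular", "second_kick", "observe"))
})

test_that("engine step equals the hand-assembled integrator path", {
  build <- function() {
    st <- scenario_free_diffusion(21, n = 3)
    st
  }
  a <- build()
  for (i in 1:30) step(a)
  # replay the same phases manually on an identically seeded state
  b <- build()
  for (i in 1:30) {
    dt <- adaptive_timestep(b)
    f_th <- thermal_force(nestforce:::.nf_frictions(b), b$phys$temperature,
                          dt, b$dim, b$phys$kB)
    kick(b, matrix(0, b$n, 3), f_th, dt / 2)
    drift(b, dt)
    kick(b, matrix(0, b$n, 3), f_th, dt / 2)
    b$time <- b$time + dt
  }
  expect_identical(a$pos, b$pos)
  expect_identical(a$vel, b$vel)
})

test_that("snapshots round-trip losslessly and idempotently", {
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  # empty state round trip
  st0 <- tiny_state()
  write_snapshot(st0, p1)
  st0b <- load_snapshot(st0$model, p1)
  expect_identical(st0b$n, 0L)
  expect_identical(st0b$time, 0)
  # populated state: write -> load -> write is byte-identical
  st <- scenario_bimolecular(seed = 3, n_each = 15)
  run_steps(st, 60)
  write_snapshot(st, p1)
  st2 <- load_snapshot(st$model, p1)
  write_snapshot(st2, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(st2$pos, st$pos)
  expect_identical(st2$attrs, st$attrs)
  expect_identical(st2$parent, st$parent)
})

test_that("snapshot restart reproduces the uninterrupted run exactly", {
  p <- withr::local_tempfile(fileext = ".json")
  st <- scenario_bimolecular(seed = 6, n_each = 15)
  run_steps(st, 80)
  write_snapshot(st, p)
  run_steps(st, 80)                      # uninterrupted reference
  st2 <- load_snapshot(st$model, p)      # restores the RNG stream
  run_steps(st2, 80)
  expect_identical(st2$pos, st$pos)
  expect_identical(st2$vel, st$vel)
  expect_identical(st2$id, st$id)
  expect_identical(st2$time, st$time)
})

test_that("counts CSV has the documented header and is seed-deterministic", {
  run_counts <- function() {
    p <- tempfile(fileext = ".csv")
    st <- scenario_decay(7, n0 = 200)
    obs <- counts_observer(every = 5L)
    run_steps(st, 50, list(obs))
    write_counts(obs, p)
    readLines(p)
  }
  a <- run_counts(); b <- run_counts()
  expect_identical(a[1], "time,species,count,compartment_context")
  expect_identical(a, b)
})

test_that("trajectory frames are scheduled as floor(t_end/interval) + 1", {
  st <- scenario_decay(1, n0 = 20, t_step = 0.05)   # constant dt
  obs <- trajectory_observer(interval = 0.25)
  run_until(st, 2, list(obs))
  expect_length(obs$data(), floor(2 / 0.25) + 1)
  # extended-XYZ output is well formed (2D frames get z = 0)
  p <- withr::local_tempfile(fileext = ".xyz")
  write_trajectory(obs, p)
  lines <- readLines(p)
  expect_identical(lines[1], "20")
  expect_match(lines[2], "^time=")
  expect_length(strsplit(lines[3], " ")[[1]], 6L)
})

test_that("observers never mutate the state", {
  run_with <- function(observers) {
    st <- scenario_bimolecular(seed = 12, n_each = 10)
    run_steps(st, 40, observers)
    list(pos = st$pos, vel = st$vel, id = st$id)
  }
  plain <- run_with(NULL)
  observed <- run_with(list(counts_observer(every = 1L),
                            trajectory_observer(every = 1L)))
  expect_identical(plain, observed)
})

test_that("run_scenario writes counts, trajectory, snapshot and a log", {
  out <- withr::local_tempdir()
  res <- run_scenario("decay", seed = 2, n_steps = 30, out_dir = out,
                      overrides = list(n0 = 50))
  expect_true(all(file.exists(unlist(res$paths))))
  cdf <- read.csv(res$paths$counts)
  expect_identical(names(cdf),
                   c("time", "species", "count", "compartment_context"))
  expect_match(readLines(res$paths$log)[2], "decay")
})

test_that("the command line lists and runs scenarios", {
  expect_output(nestforce_main(c("list-scenarios")), "raft")
  out <- withr::local_tempdir()
  expect_output(nestforce_main(c("run", "decay", "--seed", "3", "--steps",
                                 "10", "--out", out)), "wrote")
  expect_true(file.exists(file.path(out, "counts.csv")))
  expect_error(nestforce_main(c("run")), "scenario name")
  expect_error(nestforce_main(c("frobnicate")), "unknown command")
})
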