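test_that("the observation generator is exact, reproducible, and calibrated", {
  clean <- fixture_spec("bahamas", noise_sd = 0, zero_inflation = 0,
                        spawning = FALSE, seed = 4)
  obs <- generate_observations(clean)
  mu <- 10.16 / (1 + exp(-56.18 * (log(obs$density_per_ha) - log(64.35))))
  expect_equal(obs$pct_mating, mu)

  spec <- fixture_spec("florida", seed = 5)
  expect_identical(generate_observations(spec), generate_observations(spec))

  # empirical residual SD tracks the requested noise SD (away from the
  # 0/100 clipping region)
  big <- fixture_spec("custom", b = -1, d = 50, e = 50, densities = 50,
                      records_per_density = 10000, noise_sd = 2,
                      zero_inflation = 0, spawning = FALSE, seed = 6)
  y <- generate_observations(big)$pct_mating
  expect_lt(abs(sd(y) - 2) / 2, 0.05)
  expect_true(all(y >= 0 & y <= 100))
})

test_that("zero inflation only affects low-density records", {
  # shallow curve so the expected value is well above zero everywhere
  spec <- fixture_spec("custom", b = -1, d = 40, e = 30, noise_sd = 0,
                       zero_inflation = 0.5, records_per_density = 200,
                       spawning = FALSE, seed = 7)
  obs <- generate_observations(spec)
  high <- obs[obs$density_per_ha >= 100, ]
  mu <- 40 / (1 + exp(-(log(high$density_per_ha) - log(30))))
  expect_equal(high$pct_mating, mu)
  low <- obs[obs$density_per_ha < 100, ]
  frac0 <- mean(low$pct_mating == 0)
  expect_gt(frac0, 0.4)
  expect_lt(frac0, 0.6)
})

test_that("tables round-trip through CSV at full precision", {
  set.seed(23)
  grid <- build_design_grid(densities = c(10, 25), speeds = "low",
                            rests = "zero", tracking = FALSE,
                            pd_max = 0.5, tau = 0, barriers = "none")
  res <- data.frame(grid[rep(1:2, 50), ],
                    mean_pct_mating = runif(100, 0, 100),
                    ci_lo = runif(100), ci_hi = runif(100),
                    mean_pct_spawning = runif(100, 0, 100),
                    sp_ci_lo = runif(100), sp_ci_hi = runif(100),
                    replicates = 10L)
  res$design_index <- seq_len(100)
  f <- tempfile(fileext = ".csv")
  write_results(res, f)
  back <- read_results(f)
  for (col in c("mean_pct_mating", "ci_lo", "mean_pct_spawning"))
    expect_equal(back[[col]], res[[col]], tolerance = 1e-12)
  expect_identical(back$speed, res$speed)
  unlink(f)

  obs <- generate_observations(fixture_spec("bahamas", seed = 1))
  fo <- tempfile(fileext = ".csv")
  write_observations(obs, fo)
  back2 <- read_observations(fo)
  expect_equal(back2$pct_mating, obs$pct_mating, tolerance = 1e-12)
  unlink(fo)
})

test_that("schema validation names the offending row and column", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("source,density_per_ha,pct_mating",
               "a,100,5", "b,-5,4", "c,50,2"), f)
  expect_error(read_observations(f), "density_per_ha.*row 2")
  writeLines(c("source,density_per_ha,pct_mating",
               "a,100,5", "b,50,104"), f)
  expect_error(read_observations(f), "pct_mating.*row 2")
  writeLines(c("source,density_per_ha", "a,100"), f)
  expect_error(read_observations(f), "missing column")
  unlink(f)
  expect_error(read_observations(tempfile()), "not found")
})

test_that("header variants are normalised when lenient, rejected when strict", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("Source,Density_Per_Ha,PCT_MATING", "a,100,5", "b,20,0"), f)
  expect_error(read_observations(f, strict = TRUE), "missing column")
  lenient <- read_observations(f, strict = FALSE)
  expect_equal(lenient$density_per_ha, c(100, 20))
  unlink(f)

  # fuzz: case/spacing mutations always accepted leniently; corrupted
  # values always rejected
  set.seed(24)
  mutate_case <- function(x) {
    ch <- strsplit(x, "")[[1]]
    up <- runif(length(ch)) < 0.5
    ch[up] <- toupper(ch[up])
    paste(ch, collapse = "")
  }
  for (i in 1:60) {
    hdr <- paste(vapply(c("source", "density_per_ha", "pct_mating"),
                        mutate_case, ""), collapse = ",")
    writeLines(c(hdr, "a,100,5"), f)
    expect_silent(read_observations(f, strict = FALSE))
  }
  for (i in 1:60) {
    bad_dens <- sample(c(-10, 0, -0.1), 1)
    writeLines(c("source,density_per_ha,pct_mating",
                 sprintf("a,%g,5", bad_dens)), f)
    expect_error(read_observations(f), "out of range")
    bad_pct <- sample(c(-1, 101, 250), 1)
    writeLines(c("source,density_per_ha,pct_mating",
                 sprintf("a,100,%g", bad_pct)), f)
    expect_error(read_observations(f), "out of range")
  }
  unlink(f)
})

test_that("event ledgers record matings and spawns per replicate", {
  run <- run_simulation(design_point(500,
                                     perception = perception_scenario(3)),
                        run_config(), seed = 3)
  f <- tempfile(fileext = ".csv")
  write_events(run, f, replicate = 2L)
  ev <- read.csv(f)
  expect_setequal(unique(ev$type),
                  c("mating", if (nrow(run$spawns)) "spawn"))
  expect_equal(sum(ev$type == "mating"), nrow(run$events))
  expect_true(all(ev$replicate == 2L))
  unlink(f)
})

test_that("run configurations round-trip through YAML and JSON", {
  cfg <- run_config(days = 5, replicates = 3, base_seed = 99)
  for (ext in c(".yaml", ".json")) {
    f <- tempfile(fileext = ext)
    write_run_config(cfg, f, factors = list(densities = c(10, 25),
                                            speeds = "low"))
    back <- read_run_config(f)
    expect_equal(back$config$days, 5L)
    expect_equal(back$config$base_seed, 99L)
    expect_equal(back$config$spawn_delay$mean, 8.7)
    expect_equal(back$factors$densities, c(10, 25))
    unlink(f)
  }
})

test_that("the command-line interface runs every subcommand", {
  # totals prints the bookkeeping JSON and exits 0
  out <- capture.output(status <- conch_cli(c("totals", "--runs", "43200",
                                              "--days", "10")))
  expect_equal(status, 0L)
  expect_match(out, "432000")
  expect_match(out, "20671200")

  # fixtures: deterministic file output
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  expect_equal(suppressMessages(
    conch_cli(c("fixtures", "--out", f1, "--seed", "3"))), 0L)
  expect_equal(suppressMessages(
    conch_cli(c("fixtures", "--out", f2, "--seed", "3"))), 0L)
  expect_identical(readLines(f1), readLines(f2))

  # run: one design point
  fr <- tempfile(fileext = ".csv")
  expect_equal(suppressMessages(
    conch_cli(c("run", "--density", "100", "--replicates", "2",
                "--seed", "5", "--out", fr))), 0L)
  rr <- read.csv(fr)
  expect_true(rr$mean_pct_mating >= 0 && rr$mean_pct_mating <= 100)

  # grid from a config file
  fc <- tempfile(fileext = ".yaml")
  write_run_config(run_config(days = 3, replicates = 2, base_seed = 2), fc,
                   factors = list(densities = c(10, 100), speeds = "low",
                                  rests = "zero", tracking = FALSE,
                                  pd_max = 0.5, tau = 0,
                                  barriers = "none"))
  fg <- tempfile(fileext = ".csv")
  expect_equal(suppressMessages(
    conch_cli(c("grid", "--config", fc, "--out", fg))), 0L)
  gres <- read_results(fg)
  expect_equal(nrow(gres), 2L)

  # compare simulated results against synthetic observations
  fo <- tempfile(fileext = ".csv")
  suppressMessages(conch_cli(c("fixtures", "--out", fo, "--seed", "4")))
  cmp_out <- capture.output(status <- suppressMessages(
    conch_cli(c("compare", "--results", fg, "--observations", fo))))
  expect_equal(status, 0L)
  expect_match(paste(cmp_out, collapse = ""), "pct_superior")

  # validation failures exit 2
  expect_equal(suppressMessages(conch_cli(c("totals", "--days", "10"))), 2L)
  expect_equal(suppressMessages(conch_cli(c("nonsense"))), 2L)
  unlink(c(f1, f2, fr, fc, fg, fo))
})
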