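test_that("an unforced, compound-free scenario is a fixed point of the loop", {
  sc <- make_toy_uniform_scenario(0.5, 0, days = 10, T_steady = 0, C0 = 0)
  sc$initial$C_bottom <- 0
  run <- run_scenario(sc)
  g <- run$grid
  h0 <- hydrostatic_state(g, -25)$h
  expect_lt(max(abs(run$water$h - h0)), 1e-5)
  expect_equal(max(abs(run$solute$C)), 0)
  expect_equal(run$root_solute$m_collar, 0)
  expect_equal(sum(run$metrics$T_act), 0)
})

test_that("runs are deterministic: identical outputs for identical scenarios", {
  sc <- make_toy_uniform_scenario(0.5, 1, days = 2)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  run_scenario(sc, out_dir = d1)
  run_scenario(sc, out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(
      readLines(file.path(d1, f)), readLines(file.path(d2, f)),
      info = f
    )
  }
})

test_that("tidy, glance and the plot methods work on a run", {
  run <- run_scenario(make_toy_uniform_scenario(0.5, 0, days = 3))
  td <- tidy(run)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("day", "TSCF", "PUF") %in% names(td)))
  gl <- glance(run)
  expect_equal(nrow(gl), 1)
  expect_lt(gl$closure_error, 1e-8)
  expect_s3_class(autoplot(run), "ggplot")
  expect_s3_class(autoplot(run, "concentration"), "ggplot")
  expect_s3_class(autoplot(run, "water"), "ggplot")
  suf <- compute_suf(run$rs, run$scenario$hydraulics)
  expect_s3_class(autoplot(suf), "ggplot")
})

test_that("scenario configs validate, apply defaults and reject bad input", {
  sc <- make_toy_uniform_scenario(0.5, 0, days = 2)
  dir <- withr::local_tempdir()
  path <- write_scenario(sc, dir)
  back <- validate_config(path)
  expect_s3_class(back, "scenario")
  expect_equal(back$uptake$epsilon, 0.5)
  expect_equal(back$uptake$P, 0)
  expect_equal(back$domain$nz, sc$domain$nz)
  run <- run_scenario(back, window = c(0, 1))
  expect_s3_class(run, "uptake_run")
  # defaults: omitting the uptake section gives the tier-1 epsilon = 0.5
  cfg <- yaml::read_yaml(path)
  cfg$uptake <- NULL
  path2 <- file.path(dir, "noup.yaml")
  yaml::write_yaml(cfg, path2)
  expect_equal(validate_config(path2)$uptake$epsilon, 0.5)
  # structured errors
  cfg_bad <- yaml::read_yaml(path)
  cfg_bad$numerics$dt_max <- 0
  yaml::write_yaml(cfg_bad, file.path(dir, "bad1.yaml"))
  expect_error(validate_config(file.path(dir, "bad1.yaml")), "dt_max")
  cfg_bad2 <- yaml::read_yaml(path)
  cfg_bad2$uptake$P <- "from_logkow"
  cfg_bad2$compound$logKow <- NULL
  yaml::write_yaml(cfg_bad2, file.path(dir, "bad2.yaml"))
  expect_error(validate_config(file.path(dir, "bad2.yaml")), "logKow")
  cfg_bad3 <- yaml::read_yaml(path)
  cfg_bad3$banana <- 1
  yaml::write_yaml(cfg_bad3, file.path(dir, "bad3.yaml"))
  expect_error(validate_config(file.path(dir, "bad3.yaml")), "unknown")
  expect_error(validate_config(file.path(dir, "nope.yaml")), "no such file")
})

test_that("uptake parameters resolve the lipophilicity-derived permeability", {
  cp <- dummy_substance_b()
  up <- uptake_parameters(epsilon = 0, P = "from_logkow", compound = cp)
  expect_equal(up$P, permeability_from_logkow(cp$logKow))
  expect_error(uptake_parameters(P = "from_logkow"), "compound")
  expect_error(uptake_parameters(epsilon = 1.2), "epsilon")
})

test_that("VTK snapshots are valid rectilinear text files", {
  g <- small_column(nz = 5)
  f <- withr::local_tempfile(fileext = ".vtk")
  write_vtk_rectilinear(g, list(theta = rep(0.3, g$ncell)), f)
  lines <- readLines(f)
  expect_equal(lines[1], "# vtk DataFile Version 2.0")
  expect_true(any(grepl("DIMENSIONS 2 2 6", lines)))
  expect_true(any(grepl("SCALARS theta float 1", lines)))
})
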