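test_that("single vertical root follows the linear depth schedule", {
  rs <- generate_single_root(100, 89, radius = 0.05)
  expect_equal(nrow(alive_segments(rs, 0)), 0)
  expect_equal(rooting_depth(rs, 44.5), 50)
  expect_equal(rooting_depth(rs, 89), 100)
  expect_equal(rooting_depth(rs, 120), 100) # constant after full depth
  expect_error(generate_single_root(100, radius = -0.1), "radius")
})

test_that("alive root length is non-decreasing in time", {
  rs1 <- generate_single_root(60, 40, radius = 0.02)
  rs2 <- generate_stochastic_root_system(maize_root_params(), seed = 3)
  for (rs in list(rs1, rs2)) {
    lens <- vapply(seq(0, 120, by = 7), function(t) total_root_length(rs, t),
                   numeric(1))
    expect_true(all(diff(lens) >= 0))
  }
})

test_that("subdivision preserves geometry and connectivity", {
  rs <- root_system(tibble::tibble(
    id = 1L, parent_id = NA_integer_,
    x1 = 0, y1 = 0, z1 = 0, x2 = 0, y2 = 0, z2 = -3,
    radius = 0.05, order = 0L, emergence_time = 0, branch_id = 1L
  ))
  sub <- subdivide_segments(rs, 1)
  expect_equal(nrow(sub), 3)
  expect_equal(sub$parent_id, c(NA, sub$id[1], sub$id[2]))
  expect_equal(sum(sub$length), 3, tolerance = 1e-12)
  expect_true(all(sub$length <= 1 + 1e-9))
  # children re-attach to the deepest part
  y <- y_root()
  ysub <- subdivide_segments(y, 0.4)
  expect_equal(sum(ysub$length), sum(y$length), tolerance = 1e-12)
  expect_silent(root_system(tibble::as_tibble(ysub), collar_position(y)))
})

test_that("tree invariants are enforced", {
  bad <- tibble::tibble(
    id = 1:2, parent_id = c(NA_integer_, 99L),
    x1 = 0, y1 = 0, z1 = c(0, -1), x2 = 0, y2 = 0, z2 = c(-1, -2),
    radius = 0.05, order = 0L, emergence_time = 0, branch_id = 1L
  )
  expect_error(root_system(bad), "disconnected")
  detached <- bad
  detached$parent_id[2] <- 1L
  detached$z1[2] <- -1.5 # base away from parent tip
  expect_error(root_system(detached), "detached")
})

test_that("stochastic generator is reproducible and honours its parameters", {
  p <- maize_root_params()
  a <- generate_stochastic_root_system(p, seed = 11)
  b <- generate_stochastic_root_system(p, seed = 11)
  expect_identical(as.data.frame(a), as.data.frame(b))
  d <- generate_stochastic_root_system(p, seed = 12)
  expect_false(identical(as.data.frame(a), as.data.frame(d)))
  # infinite inter-branch distance: axes only
  p0 <- p
  p0$orders[[1]]$branch_distance <- Inf
  axes_only <- generate_stochastic_root_system(p0, seed = 11)
  expect_equal(unique(axes_only$order), 0L)
  expect_error(
    generate_stochastic_root_system(utils::modifyList(p, list(n_axes = 0)), 1),
    "axis"
  )
})

test_that("stochastic maize system has a uniform root length profile", {
  rs <- generate_stochastic_root_system(maize_root_params(), seed = 42)
  rld <- total_root_length(rs, 120) / (75 * 15 * 100)
  expect_gt(rld, 0.05) # about 0.1 cm/cm^3 +- 50%
  expect_lt(rld, 0.15)
  prof <- root_length_density(rs, 120, footprint_area = 75 * 15,
                              bin = 10, max_depth = 100)
  rel <- prof$rld / mean(prof$rld)
  expect_true(all(rel > 0.7 & rel < 1.3))
  # depth schedule close to the linear single-root progression
  expect_equal(rooting_depth(rs, 45), 45 * 100 / 89, tolerance = 0.12)
  expect_equal(rooting_depth(rs, 120), 100, tolerance = 0.05)
})

test_that("hydraulic lookup interpolates, clamps and rejects unknown orders", {
  tab <- hydraulic_table(
    list(age = c(0, 10), Lr = c(1e-4, 3e-4), Kx = c(0.1, 0.5))
  )
  expect_equal(lookup_hydraulics(tab, 0, 10)$Lr, 3e-4)
  expect_equal(lookup_hydraulics(tab, 0, 5)$Lr, 2e-4) # linear midpoint
  # beyond the last breakpoint: clamp equals direct table end value
  expect_equal(lookup_hydraulics(tab, 0, 250)$Lr, tab[[1]]$Lr[2])
  expect_equal(lookup_hydraulics(tab, 0, 250)$Kx, tab[[1]]$Kx[2])
  expect_error(lookup_hydraulics(tab, 1, 5), "order")
  expect_error(lookup_hydraulics(tab, 0, -1), "age")
  # constant single-root table returns its values at any age
  ct <- constant_hydraulics(2e-4, 0.5)
  for (age in c(0, 13, 200)) {
    hp <- lookup_hydraulics(ct, 0, age)
    expect_equal(hp$Lr, 2e-4)
    expect_equal(hp$Kx, 0.5)
  }
})
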