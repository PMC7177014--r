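# Grid-based packing-defect detection and exponential size-constant fits.

test_that("a complete head lattice has no defects", {
  fx <- make_fixture("defect_lattice", list(holes = integer(0)))
  d <- detect_defects(fx$system, zone = "thin", grid_spacing = 0.1)
  expect_identical(length(d$areas), 0L)
  expect_identical(d$n_defect_cells, 0L)
})

test_that("one removed head produces exactly one defect of the uncovered area", {
  # choose a hole inside the thin zone; count uncovered cells by brute force
  fx0 <- make_fixture("defect_lattice", list(holes = integer(0)))
  g <- fx0$truth$site_xy
  geom <- fx0$system$geom
  hole <- which.min((g$x - geom$x_c)^2 + (g$y - 3)^2)
  fx <- make_fixture("defect_lattice", list(hole_sites = hole))
  d <- detect_defects(fx$system, zone = "thin", grid_spacing = 0.1,
                      return_mask = TRUE)
  expect_identical(length(d$areas), 1L)
  # independent R oracle: scan thin-zone cells against covering heads
  sys <- fx$system
  heads <- which(sys$att == 1L & sys$pos[, 3] > sys$box[3] / 2)
  r_head <- 0.5 * 2^(1 / 6) * sys$sigma[heads]
  zr <- c(geom$x_c - geom$A_thin / 2, geom$A_thin)
  nx <- round(zr[2] / 0.1); ny <- round(sys$box[2] / 0.1)
  uncovered <- 0L
  for (ix in seq_len(nx)) for (iy in seq_len(ny)) {
    cx <- zr[1] + (ix - 0.5) * 0.1; cy <- (iy - 0.5) * 0.1
    dy <- abs(sys$pos[heads, 2] - cy); dy <- pmin(dy, sys$box[2] - dy)
    dd <- (sys$pos[heads, 1] - cx)^2 + dy^2
    if (!any(dd <= r_head^2)) uncovered <- uncovered + 1L
  }
  expect_identical(d$n_defect_cells, uncovered)
  expect_equal(d$areas[1], uncovered * d$cell_area)
})

test_that("adjacent holes merge but diagonal holes stay separate (4-connectivity)", {
  fx0 <- make_fixture("defect_lattice", list(holes = integer(0)))
  g <- fx0$truth$site_xy
  geom <- fx0$system$geom
  sp <- fx0$truth$spacing
  i1 <- which.min((g$x - geom$x_c)^2 + (g$y - 3)^2)
  nbr <- function(dx, dy) which(abs(g$x - (g$x[i1] + dx)) < 1e-9 &
                                  abs(g$y - (g$y[i1] + dy)) < 1e-9)[1]
  i_adj <- nbr(sp, 0); i_diag <- nbr(sp, sp)
  expect_false(is.na(i_adj) || is.na(i_diag))
  # laterally adjacent holes: the uncovered corridor joins them -> 1 defect
  d1 <- detect_defects(make_fixture("defect_lattice",
                                    list(hole_sites = c(i1, i_adj)))$system,
                       zone = "thin", grid_spacing = 0.1)
  expect_identical(length(d1$areas), 1L)
  # diagonal holes: the corner stays covered -> 2 separate defects
  d2 <- detect_defects(make_fixture("defect_lattice",
                                    list(hole_sites = c(i1, i_diag)))$system,
                       zone = "thin", grid_spacing = 0.1)
  expect_identical(length(d2$areas), 2L)
})

test_that("area is conserved between defect and covered cells", {
  fx <- make_fixture("defect_lattice", list(holes = 5), seed = 8)
  d <- detect_defects(fx$system, zone = "thin", grid_spacing = 0.1)
  expect_equal(sum(d$areas), d$n_defect_cells * d$cell_area)
  expect_lte(d$n_defect_cells, d$n_cells)
  geom <- fx$system$geom
  expect_equal(d$n_cells * d$cell_area,
               geom$A_thin * fx$system$box[2] * 100, tolerance = 1e-9)
})

test_that("narrow zones are rejected", {
  fx <- make_fixture("defect_lattice", list())
  expect_error(detect_defects(fx$system, zone = c(1, 0.2),
                              grid_spacing = 0.1), "3 grid cells")
})

test_that("exponential size constant is recovered from synthetic areas", {
  set.seed(42)
  areas <- rexp(1e5, rate = 1 / 20)
  st <- fit_size_constant(areas, A_min = 15, p_min = 1e-4, n_blocks = 10)
  expect_equal(st$size_constant, 20, tolerance = 0.02)
  expect_false(st$degenerate)
  expect_identical(st$n_defects, 100000L)
  # block SE should bracket the truth
  expect_lt(abs(st$size_constant - 20), 3 * st$size_constant_se)
})

test_that("identical areas are flagged degenerate", {
  st <- fit_size_constant(rep(20, 500), A_min = 15, p_min = 1e-4,
                          n_blocks = 5)
  expect_true(st$degenerate)
})

test_that("too few areas or too few histogram points error", {
  expect_error(fit_size_constant(rexp(50, 1 / 20)), "at least 100")
  set.seed(1)
  expect_error(fit_size_constant(runif(200, 0, 5), A_min = 15, p_min = 1e-4),
               "usable histogram")
})

test_that("fitted constant is stable under grid refinement", {
  set.seed(7)
  areas <- rexp(4e4, rate = 1 / 20)
  c1 <- fit_size_constant(areas, bin_area = 1)$size_constant
  c2 <- fit_size_constant(areas, bin_area = 0.5)$size_constant
  expect_lt(abs(c2 - c1) / c1, 0.05)
})
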