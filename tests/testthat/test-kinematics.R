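contracting_tube <- function(scale_ps = 0.8, nf = 20, r0 = 2) {
  # tube whose radii scale by `scale_ps` at peak systole (phase 0.35)
  phases <- seq(0, 1 - 1 / nf, length.out = nf)
  s <- 1 - (1 - scale_ps) * lvkin:::.contraction_bump(phases, 0.35)
  tube_radii(r0, r0 + 0.5, nf) |>
    dplyr::mutate(radius_mm = radius_mm * s[frame])
}

test_that("circumferential strain follows the Lagrangian definition", {
  # direct arithmetic: perimeters 5.0 -> 5.5 give strain 0.1
  expect_equal((5.5 - 5.0) / 5.0, 0.1)
  static <- build_lv_mesh(tube_radii(nf = 10), 0, 6, 0.12)
  cs <- circumferential_strain(static, "endo", c(10, 30, 55))
  expect_true(all(cs$strain == 0))
  # uniform radial scaling by s gives strain s - 1: at peak systole (a mesh
  # sample coinciding with a frame) the contour is exactly 0.8x the reference
  mesh <- build_lv_mesh(contracting_tube(0.8), 0, 6, 0.12)
  cs2 <- circumferential_strain(mesh, "endo", 30)
  expect_equal(cs2$strain[abs(cs2$phase - 0.35) < 1e-9], 0.8 - 1,
               tolerance = 1e-9)
  expect_equal(min(cs2$strain), 0.8 - 1, tolerance = 1e-3)
  expect_equal(cs2$strain[1], 0) # exactly zero at end-diastole
})

test_that("longitudinal strain measures the apex-to-base generatrix", {
  static <- build_lv_mesh(tube_radii(nf = 10), 0, 6, 0.12)
  ls <- longitudinal_strain(static)
  expect_true(all(ls$strain == 0))
  expect_equal(sort(unique(ls$theta_deg)), c(30, 90, 150, 210, 270, 330))
  # pure axial stretch of a straight wall: apex-base distance x 1.1
  nf <- 10
  phases <- seq(0, 0.9, length.out = nf)
  stretch <- 1 + 0.1 * lvkin:::.contraction_bump(phases, 0.5)
  mesh2 <- build_lv_mesh(tube_radii(nf = nf), 0, 6 * stretch, 0.12)
  ls2 <- longitudinal_strain(mesh2, angle_index = 1)
  # the straight generatrix is purely axial, so strain tracks the stretch
  expect_equal(max(ls2$strain), 0.1, tolerance = 1e-3)
  expect_equal(ls2$strain[1], 0)
})

test_that("strain is invariant to rigid rotation about the long axis", {
  cfg <- tiny_phantom_config(1, seed = 4)
  tr <- generate_cohort(cfg, render_images = FALSE)$truth[[1]]
  mesh <- build_lv_mesh(tr, 0, 6.5, 0.12)
  # rotating the radius field by one 60-degree step: the new radius at theta
  # is the old radius at theta - 60, i.e. the same contour rigidly rotated
  tr_rot <- tr |>
    dplyr::group_by(frame, boundary, z_frac) |>
    dplyr::mutate(radius_mm = radius_mm[match((theta_deg - 60) %% 360,
                                              theta_deg %% 360)]) |>
    dplyr::ungroup()
  mesh_rot <- build_lv_mesh(tr_rot, 0, 6.5, 0.12)
  cs_a <- circumferential_strain(mesh, "endo", 30)
  cs_b <- circumferential_strain(mesh_rot, "endo", 30)
  expect_equal(cs_a$strain, cs_b$strain, tolerance = 1e-9)
})

test_that("strain rates are OLS slopes over the four half-windows", {
  # linear ramp over systole: all samples on one line of slope -0.2/ (0.35*0.1)
  ph <- seq(0, 1 - 1 / 60, length.out = 60)
  ps <- 0.35; cyc <- 0.1
  eps <- ifelse(ph <= ps, -0.2 * ph / ps, -0.2 * (1 - ph) / (1 - ps))
  sr <- strain_rates(eps, ph, ps, cyc)
  expect_equal(sr$rate_per_s[sr$window == "early_systolic"], -0.2 / (ps * cyc),
               tolerance = 1e-6)
  expect_equal(sr$rate_per_s[sr$window == "late_systolic"], -0.2 / (ps * cyc),
               tolerance = 1e-6)
  expect_equal(sr$rate_per_s[sr$window == "early_diastolic"], 0.2 / ((1 - ps) * cyc),
               tolerance = 1e-6)
  # constant strain: all four rates zero
  sr0 <- strain_rates(rep(0.05, 60), ph, ps, cyc)
  expect_equal(sr0$rate_per_s, rep(0, 4))
  # quadratic strain over systole: OLS slopes match the analytic derivative
  # at the half-window midpoints to within 5%
  epsq <- ifelse(ph <= ps, -(ph / ps)^2 * 0.2, -0.2 * (1 - ph) / (1 - ps))
  srq <- strain_rates(epsq, ph, ps, cyc)
  slope_at <- function(t_mid) -0.4 * t_mid / (ps * cyc * ps) # d/dt of -0.2 (t/ps)^2 over seconds
  expect_equal(srq$rate_per_s[1], slope_at(ps / 4), tolerance = 0.05)
  expect_equal(srq$rate_per_s[2], slope_at(3 * ps / 4), tolerance = 0.05)
  expect_error(strain_rates(eps, ph, 0.01, cyc), "at least 3")
  expect_error(strain_rates(eps, ph, 1.2, cyc), "ps_phase")
})

test_that("global function metrics reproduce closed-form volumes", {
  static <- build_lv_mesh(tube_radii(2, 2.5, 10), 0, 6, 0.12)
  gf <- global_function(static)
  expect_equal(gf$edv_ul, pi * 4 * 6, tolerance = 0.02) # cylinder, within 2%
  expect_equal(gf$sv_ul, 0)
  expect_equal(gf$ef_pct, 0)
  mesh <- build_lv_mesh(contracting_tube(0.8), 0, 6, 0.12)
  gf2 <- global_function(mesh)
  expect_equal(gf2$ef_pct, 100 * (1 - 0.8^2), tolerance = 0.01)
  expect_lt(abs(gf2$ps_phase - 0.35), 1 / 60 + 1e-9)
  expect_equal(gf2$sv_ul, gf2$edv_ul - gf2$psv_ul)
  # volume scales with the square of a uniform radial scale
  mesh_s <- build_lv_mesh(tube_radii(2 * 1.3, 2.5 * 1.3, 10), 0, 6, 0.12)
  gf3 <- global_function(mesh_s)
  expect_equal(gf3$edv_ul / gf$edv_ul, 1.3^2, tolerance = 1e-6)
})

test_that("the metric table enumerates the contracted locations and metrics", {
  mesh <- build_lv_mesh(contracting_tube(0.85), 0, 6, 0.12)
  mt <- metric_table(mesh)
  circ <- mt[mt$frame_type == "circ", ]
  long <- mt[mt$frame_type == "long", ]
  glob <- mt[mt$frame_type == "global", ]
  expect_equal(length(unique(circ$location)), 3) # basal, mid-LV, apical
  expect_equal(length(unique(long$location)), 6) # six rotations
  expect_equal(nrow(circ) + nrow(long), 45)      # 9 locations x 5 curve metrics
  expect_equal(nrow(glob), 4)                    # EDV, PSV, SV, EF
  # uniform contraction: identical circumferential peak strain everywhere
  peaks <- circ$value[circ$metric == "peak_strain"]
  expect_lt(diff(range(peaks)), 1e-6)
  expect_true(all(glob$value[glob$metric == "ef"] >= 0 &
                    glob$value[glob$metric == "ef"] <= 100))
})

test_that("strain and volume are invariant to rigid axial translation", {
  tr <- contracting_tube(0.85)
  m1 <- build_lv_mesh(tr, 0, 6, 0.12)
  m2 <- build_lv_mesh(tr, 10, 16, 0.12)
  expect_equal(circumferential_strain(m1, "endo", 30)$strain,
               circumferential_strain(m2, "endo", 30)$strain)
  expect_equal(global_function(m1)$edv_ul, global_function(m2)$edv_ul)
  expect_equal(longitudinal_strain(m1, angle_index = 3)$strain,
               longitudinal_strain(m2, angle_index = 3)$strain, tolerance = 1e-12)
})
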