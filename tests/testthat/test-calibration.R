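# Camera intrinsics shared by the synthetic-photo tests.
test_intrinsics <- function() camera_intrinsics(800, 800, 320, 240)

test_that("the marker dictionary is rotation-unambiguous and well separated", {
  ids <- c(0, 5, 13, 31)
  pats <- lapply(ids, marker_pattern)
  rot <- retinowin:::rotate_bits
  for (p in pats) {
    rots <- list(p, rot(p), rot(rot(p)), rot(rot(rot(p))))
    for (a in 1:3) for (b in (a + 1):4) {
      expect_gte(sum(rots[[a]] != rots[[b]]), 4)
    }
  }
  # cross-marker distance over all rotations
  r1 <- list(pats[[1]], rot(pats[[1]]), rot(rot(pats[[1]])), rot(rot(rot(pats[[1]]))))
  for (q in pats[-1]) {
    for (r in r1) expect_gte(sum(r != q), 4)
  }
  expect_error(marker_pattern(32), "id")
})

test_that("uniform images contain no markers and bad input is rejected", {
  expect_length(detect_markers(matrix(0.5, 100, 100)), 0)
  expect_length(detect_markers(matrix(1, 50, 80)), 0)
  expect_error(detect_markers(matrix(NA_real_, 10, 10)), "finite")
})

test_that("a frontoparallel marker is detected with sub-pixel corners", {
  intr <- test_intrinsics()
  mp <- pose(c(0, 0, 0.5))
  photo <- render_marker_photo(list(list(id = 7L, side = 0.08, pose = mp)),
                               intr, 640, 480)
  obs <- detect_markers(photo)
  expect_length(obs, 1)
  expect_equal(obs[[1]]$marker_id, 7L)
  gt <- project_marker_corners(mp, 0.08, intr)
  expect_lt(max(abs(obs[[1]]$corners - gt)), 0.5)
  # corners sit symmetrically about the principal point
  expect_equal(colMeans(obs[[1]]$corners), c(u = 320, v = 240), tolerance = 0.1)
})

test_that("two markers at distinct poses are both recovered", {
  intr <- test_intrinsics()
  m1 <- pose(c(-0.1, 0.02, 0.5), rotation_from_euler(ry = 20))
  m2 <- pose(c(0.12, -0.04, 0.65), rotation_from_euler(rx = -15, rz = 10))
  photo <- render_marker_photo(list(
    list(id = 2L, side = 0.07, pose = m1),
    list(id = 9L, side = 0.07, pose = m2)
  ), intr, 640, 480)
  obs <- detect_markers(photo)
  expect_length(obs, 2)
  expect_setequal(vapply(obs, `[[`, 0L, "marker_id"), c(2L, 9L))
  for (o in obs) {
    truth <- if (o$marker_id == 2L) m1 else m2
    gt <- project_marker_corners(truth, 0.07, intr)
    expect_lt(max(abs(o$corners - gt)), 0.5)
  }
})

test_that("planar pose estimation recovers translation and rotation", {
  intr <- test_intrinsics()
  # frontoparallel at 0.5 m
  mp <- pose(c(0, 0, 0.5))
  obs <- list(corners = project_marker_corners(mp, 0.08, intr))
  est <- estimate_marker_pose(obs, intr, 0.08)
  expect_lt(abs(est$position[3] - 0.5) / 0.5, 0.01)
  expect_lt(rotation_error_deg(est$rotation, diag(3)), 1)
  # 30 degrees yaw about the vertical axis
  mp2 <- pose(c(0.05, -0.02, 0.6), rotation_from_euler(ry = 30))
  obs2 <- list(corners = project_marker_corners(mp2, 0.08, intr))
  est2 <- estimate_marker_pose(obs2, intr, 0.08)
  expect_lt(rotation_error_deg(est2$rotation, mp2$rotation), 1)
  expect_lt(sqrt(sum((est2$position - mp2$position)^2)) /
              sqrt(sum(mp2$position^2)), 0.01)
  expect_lt(attr(est2, "reprojection_rms"), 1e-6)
  # doubling the apparent size halves the recovered depth (similar triangles)
  big <- obs$corners
  big <- sweep(sweep(big, 2, c(320, 240)), 1, c(1, 1), `*`) * 2
  big <- sweep(big, 2, c(320, 240), `+`)
  est3 <- estimate_marker_pose(list(corners = big), intr, 0.08)
  expect_equal(est3$position[3], 0.25, tolerance = 0.01)
  # collinear corners are degenerate
  bad <- rbind(c(0, 0), c(10, 0), c(20, 0), c(30, 0))
  expect_error(estimate_marker_pose(list(corners = bad), intr, 0.08),
               "degenerate")
})

test_that("pose error shrinks statistically as markers cover more pixels", {
  intr <- test_intrinsics()
  set.seed(55)
  mp <- pose(c(0.02, 0.01, 0.8), rotation_from_euler(ry = 15))
  mean_err <- vapply(c(0.04, 0.08, 0.16), function(side) {
    errs <- vapply(1:5, function(rep) {
      photo <- render_marker_photo(list(list(id = 4L, side = side, pose = mp)),
                                   intr, 640, 480)
      noisy <- rw_image(matrix(
        pmin(1, pmax(0, unclass(photo) + rnorm(length(photo), 0, 0.04))),
        nrow = nrow(photo)))
      obs <- detect_markers(noisy)
      if (!length(obs)) return(NA_real_)
      est <- estimate_marker_pose(obs[[1]], intr, side)
      sqrt(sum((est$position - mp$position)^2))
    }, 0)
    mean(errs, na.rm = TRUE)
  }, 0)
  # the smallest marker must be the least accurate; beyond ~80 px the
  # sub-pixel refinement saturates, so compare against the small end
  expect_lt(mean_err[2], mean_err[1])
  expect_lt(mean_err[3], mean_err[1])
})

test_that("display geometry is solved in the observer frame", {
  intr <- test_intrinsics()
  # ground truth: display 0.45 m ahead of the camera, slightly yawed;
  # observer marker 0.1 m below the camera axis at 0.3 m
  disp_pose_cam <- pose(c(0.05, 0, 0.45), rotation_from_euler(ry = 18))
  obs_pose_cam <- pose(c(0, -0.1, 0.3))
  photo <- render_marker_photo(list(
    list(id = 1L, side = 0.06, pose = disp_pose_cam),
    list(id = 6L, side = 0.06, pose = obs_pose_cam)
  ), intr, 960, 720)
  mm <- marker_map(
    markers = list(
      list(id = 1, side_m = 0.06, attach = "main", offset_m = c(0, 0)),
      list(id = 6, side_m = 0.06, attach = "observer", offset_m = c(0, 0))
    ),
    displays = list(list(name = "main", width_m = 0.4, height_m = 0.25,
                         resolution = c(800, 500)))
  )
  res <- solve_display_geometry(detect_markers(photo), intr, mm)
  expect_s3_class(res, "calibration_result")
  expect_false(res$observer_from_camera)
  truth <- transform_pose(pose_inverse(obs_pose_cam), disp_pose_cam)
  got <- res$rig$displays$main$pose
  expect_lt(sqrt(sum((got$position - truth$position)^2)) /
              sqrt(sum(truth$position^2)), 0.01)
  expect_lt(rotation_error_deg(got$rotation, truth$rotation), 1)
  expect_true(all(res$markers$reprojection_rms < 0.5))
  # determinism: same photo twice gives identical results
  res2 <- solve_display_geometry(detect_markers(photo), intr, mm)
  expect_identical(tidy(res2), tidy(res))
})

test_that("two corner markers average to the panel centre", {
  intr <- test_intrinsics()
  centre <- pose(c(0, 0.02, 0.5), rotation_from_euler(ry = 10))
  off <- 0.12
  # markers mounted at opposite panel corners (offsets in the panel frame)
  mk_tl <- transform_pose(centre, pose(c(-off, off, 0)))
  mk_br <- transform_pose(centre, pose(c(off, -off, 0)))
  photo <- render_marker_photo(list(
    list(id = 3L, side = 0.05, pose = mk_tl),
    list(id = 8L, side = 0.05, pose = mk_br)
  ), intr, 960, 720)
  mm <- marker_map(
    markers = list(
      list(id = 3, side_m = 0.05, attach = "main", offset_m = c(-off, off)),
      list(id = 8, side_m = 0.05, attach = "main", offset_m = c(off, -off))
    ),
    displays = list(list(name = "main", width_m = 0.4, height_m = 0.3,
                         resolution = c(640, 480)))
  )
  res <- solve_display_geometry(detect_markers(photo), intr, mm)
  expect_true(res$observer_from_camera)   # no observer marker: camera frame
  got <- res$rig$displays$main$pose
  expect_lt(sqrt(sum((got$position - centre$position)^2)) /
              sqrt(sum(centre$position^2)), 0.01)
  expect_lt(rotation_error_deg(got$rotation, centre$rotation), 1)
})

test_that("a display with no detected markers is reported by name", {
  intr <- test_intrinsics()
  mm <- marker_map(
    markers = list(list(id = 1, side_m = 0.06, attach = "ghost",
                        offset_m = c(0, 0))),
    displays = list(list(name = "ghost", width_m = 0.3, height_m = 0.2,
                         resolution = c(100, 100)))
  )
  expect_error(solve_display_geometry(list(), intr, mm), "ghost")
})

test_that("calibration closes the loop: recovered rig reproduces the render", {
  intr <- test_intrinsics()
  disp_pose_cam <- pose(c(-0.03, 0.01, 0.4), rotation_from_euler(ry = -12))
  photo <- render_marker_photo(
    list(list(id = 5L, side = 0.06, pose = disp_pose_cam)), intr, 960, 720)
  mm <- marker_map(
    markers = list(list(id = 5, side_m = 0.06, attach = "main",
                        offset_m = c(0, 0))),
    displays = list(list(name = "main", width_m = 0.35, height_m = 0.25,
                         resolution = c(140, 100)))
  )
  res <- solve_display_geometry(detect_markers(photo), intr, mm)
  cv <- rasterize_stimulus(visual_field_canvas(0, 0, 160, 160, resolution = 4),
                           checkerboard_spec(15))
  cm <- canvas_to_cubemap(cv, 192)
  obs <- observer_spec()
  truth_disp <- display_spec("main", disp_pose_cam, 0.35, 0.25, 140, 100)
  img_truth <- render_display(cm, truth_disp, obs)
  img_recov <- render_display(cm, res$rig$displays$main, obs)
  # agreement within one texel of blur: every disagreeing pixel must sit
  # next to a luminance edge of the true image (sub-texel shifts only)
  mism <- abs(unclass(img_truth) - unclass(img_recov)) > 0.05
  gx <- abs(cbind(img_truth[, -1], img_truth[, ncol(img_truth)]) - img_truth) > 0.05
  gy <- abs(rbind(img_truth[-1, ], img_truth[nrow(img_truth), ]) - img_truth) > 0.05
  edge <- gx | gy
  near_edge <- edge
  near_edge[-1, ] <- near_edge[-1, ] | edge[-nrow(edge), ]
  near_edge[-nrow(edge), ] <- near_edge[-nrow(edge), ] | edge[-1, ]
  near_edge[, -1] <- near_edge[, -1] | edge[, -ncol(edge)]
  near_edge[, -ncol(edge)] <- near_edge[, -ncol(edge)] | edge[, -1]
  # the 1 px image border can face an edge lying just outside the frame
  interior <- matrix(FALSE, nrow(mism), ncol(mism))
  interior[2:(nrow(mism) - 1), 2:(ncol(mism) - 1)] <- TRUE
  expect_true(all(near_edge[mism & interior]))
  expect_lt(mean(mism), 0.05)
  expect_lt(mean(abs(img_truth - img_recov)), 0.01)
})

test_that("gamma fits recover the generating model exactly without noise", {
  v <- seq(0, 1, length.out = 26)
  d <- tibble::tibble(command = v, luminance = 0.5 + 99.5 * v^2.2)
  m <- fit_gamma(d)
  expect_equal(m$gamma, 2.2, tolerance = 1e-6)
  expect_equal(m$L_min, 0.5, tolerance = 1e-4)
  expect_equal(m$L_max, 100, tolerance = 1e-4)
  # linear data yields a unit-exponent model and an identity LUT
  dl <- tibble::tibble(command = v, luminance = 10 + 90 * v)
  ml <- fit_gamma(dl)
  expect_equal(ml$gamma, 1, tolerance = 1e-6)
  lut <- gamma_lut(ml, 256)
  expect_equal(lut$command, lut$value, tolerance = 1 / 255)
})

test_that("gamma recovery tolerates 1 percent measurement noise", {
  set.seed(99)
  v <- seq(0, 1, length.out = 26)
  clean <- 0.5 + 99.5 * v^2.2
  d <- tibble::tibble(command = v,
                      luminance = clean + rnorm(26, 0, 0.01 * 99.5))
  m <- fit_gamma(d)
  expect_lt(abs(m$gamma - 2.2) / 2.2, 0.05)
})

test_that("invalid luminance measurements are rejected", {
  expect_error(fit_gamma(tibble::tibble(command = c(0, 0.5, 1),
                                        luminance = c(1, 2, 3))), "4 distinct")
  expect_error(fit_gamma(tibble::tibble(command = seq(0.4, 0.9, 0.1),
                                        luminance = 1:6)), "span")
  expect_error(fit_gamma(tibble::tibble(command = seq(0, 1, 0.2),
                                        luminance = c(6, 5, 4, 3, 2, 1))),
               "monotonic")
})

test_that("gamma fitting is scale-equivariant", {
  v <- seq(0, 1, length.out = 20)
  base <- tibble::tibble(command = v, luminance = 2 + 80 * v^1.8)
  m1 <- fit_gamma(base)
  m2 <- fit_gamma(dplyr::mutate(base, luminance = luminance * 7.5))
  expect_equal(m2$gamma, m1$gamma, tolerance = 1e-9)
  expect_equal(m2$L_min, m1$L_min * 7.5, tolerance = 1e-6)
  expect_equal(m2$L_max, m1$L_max * 7.5, tolerance = 1e-6)
})

test_that("linearisation makes displayed luminance linear in request", {
  d <- tibble::tibble(command = seq(0, 1, length.out = 26),
                      luminance = 1 + 79 * seq(0, 1, length.out = 26)^2.4)
  m <- fit_gamma(d)
  expect_equal(linearize_image(matrix(0, 1, 1), m)[1, 1], 0)
  expect_equal(linearize_image(matrix(1, 1, 1), m)[1, 1], 1)
  # gamma 2 sends a request of 0.25 to command 0.5 (closed-form inverse)
  m2 <- m; m2$gamma <- 2
  expect_equal(linearize_image(matrix(0.25, 1, 1), m2)[1, 1], 0.5,
               tolerance = 1 / 255)
  # forward(inverse(x)) is linear with R^2 > 0.999 over 256 levels
  x <- seq(0, 1, length.out = 256)
  cmd <- as.vector(linearize_image(matrix(x, 1), m))
  lum <- predict(m, cmd)
  fit <- stats::lm(lum ~ x)
  expect_gt(summary(fit)$r.squared, 0.999)
  # max deviation from linearity stays within one quantisation step
  lin <- m$L_min + (m$L_max - m$L_min) * x
  step <- (m$L_max - m$L_min) * max(diff(predict(m, seq(0, 1, length.out = 256)))) /
    (m$L_max - m$L_min)
  expect_lt(max(abs(lum - lin)), max(step, (m$L_max - m$L_min) / 100))
})

test_that("tidy and glance summarise fits and calibrations", {
  d <- tibble::tibble(command = seq(0, 1, length.out = 10),
                      luminance = 2 + 50 * seq(0, 1, length.out = 10)^2)
  m <- fit_gamma(d)
  td <- tidy(m)
  expect_equal(td$term, c("L_min", "L_max", "gamma"))
  gl <- glance(m)
  expect_equal(gl$gamma, 2, tolerance = 1e-6)
  expect_equal(gl$n, 10L)
})

test_that("marker maps and intrinsics round-trip through files", {
  mm <- marker_map(
    markers = list(list(id = 2, side_m = 0.05, attach = "main",
                        offset_m = c(0.01, -0.02))),
    displays = list(list(name = "main", width_m = 0.3, height_m = 0.2,
                         resolution = c(640, 400)))
  )
  p <- withr::local_tempfile(fileext = ".yml")
  write_marker_map(mm, p)
  back <- read_marker_map(p)
  expect_equal(back$markers[[1]]$id, 2)
  expect_equal(back$displays$main$width_m, 0.3)
  pj <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(focal_x = 750, cx = 320, cy = 240), pj,
                       auto_unbox = TRUE)
  intr <- read_camera_intrinsics(pj)
  expect_equal(intr$focal_y, 750)   # defaults to focal_x
})
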