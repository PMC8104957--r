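test_that("empty scenes render the uniform background on every face", {
  cm <- render_cubemap(scene(background = 0.3), observer_spec(), 8)
  for (f in cm$faces) expect_true(all(f == 0.3))
})

test_that("a sphere ahead occupies its analytic angular disc on the +z face", {
  scn <- scene(scene_object("sphere", pose(c(0, 0, 2)), scale = 1,
                            surface = 1), background = 0)
  obs <- observer_spec()
  cm <- render_cubemap(scn, obs, 128)
  # brute-force raycast oracle on a fine direction grid near the +z axis:
  # angular radius of a 0.5 m radius sphere at 2 m is asin(0.25)
  ang_rad <- asin(0.25) * 180 / pi
  expect_equal(ang_rad, 14.4775, tolerance = 1e-4)
  sph <- spherical_from_direction(cube_face_directions("pz", 128))
  gc <- acos(pmin(1, cos(sph$azimuth * pi / 180) * cos(sph$elevation * pi / 180))) * 180 / pi
  vals <- as.vector(cm$faces$pz)
  texel_deg <- 90 / 128 * 1.6          # generous per-texel angular pitch
  expect_true(all(vals[gc < ang_rad - texel_deg] == 1))
  expect_true(all(vals[gc > ang_rad + texel_deg] == 0))
  # the face behind is untouched
  expect_true(all(cm$faces$nz == 0))
})

test_that("a plane behind the observer darkens only the -z face", {
  scn <- scene(scene_object("plane", pose(c(0, 0, -1)), scale = c(0.5, 0.5, 1),
                            surface = 1), background = 0)
  cm <- render_cubemap(scn, observer_spec(), 32)
  expect_true(any(cm$faces$nz == 1))
  for (f in c("px", "nx", "py", "ny", "pz")) {
    expect_true(all(cm$faces[[f]] == 0), label = paste("face", f, "untouched"))
  }
})

test_that("sampling a rendered cube map matches a direct raycast oracle", {
  set.seed(17)
  scn <- scene(list(
    scene_object("sphere", pose(c(0.3, 0.1, 1.5)), scale = 0.6, surface = 0.9),
    scene_object("cube", pose(c(-0.5, -0.2, 1), rotation_from_euler(ry = 25)),
                 scale = 0.4, surface = 0.6),
    scene_object("plane", pose(c(0, 0, 3)), scale = c(4, 3, 1), surface = 0.2)
  ), background = 0.05)
  obs <- observer_spec()
  n <- 256
  cm <- render_cubemap(scn, obs, n)
  d <- random_unit_directions(400)
  direct <- raycast_scene(scn, c(0, 0, 0), d)
  via_map <- sample_cubemap(cm, d, mode = "nearest")
  # nearest-texel lookup may differ only within one texel of a contour:
  # compare against the raycast at the texel-centre direction instead
  fs <- retinowin:::direction_to_face_st(d)
  snap <- function(x) (round((x + 1) * n / 2 + 0.5) - 0.5) * 2 / n - 1
  d_tex <- t(vapply(seq_len(nrow(d)), function(i) {
    as.numeric(retinowin:::face_st_to_direction(fs$face[i], snap(fs$s[i]),
                                                snap(fs$t[i])))
  }, numeric(3)))
  oracle_tex <- raycast_scene(scn, c(0, 0, 0), d_tex)
  expect_equal(via_map, oracle_tex)
  # and bilinear sampling stays between neighbouring surface values
  expect_lt(mean(abs(sample_cubemap(cm, d) - direct) > 0.05), 0.06)
})

test_that("cube-map face selection matches an exhaustive projection oracle", {
  set.seed(3)
  d <- rbind(c(0, 0, 1), c(1, 0, 0), c(0.9, 0.1, 0.3) / sqrt(0.91),
             random_unit_directions(200))
  fs <- retinowin:::direction_to_face_st(d)
  expect_equal(fs$face[1:3], c("pz", "px", "px"))
  # oracle: the face whose outward axis has the largest positive dot product
  axes <- rbind(px = c(1, 0, 0), nx = c(-1, 0, 0), py = c(0, 1, 0),
                ny = c(0, -1, 0), pz = c(0, 0, 1), nz = c(0, 0, -1))
  dots <- d %*% t(axes)
  oracle <- rownames(axes)[max.col(dots, ties.method = "first")]
  expect_equal(fs$face, oracle)
  # in-face coordinates invert exactly
  for (i in seq_len(nrow(d))) {
    back <- retinowin:::face_st_to_direction(fs$face[i], fs$s[i], fs$t[i])
    back <- back / sqrt(sum(back^2))
    expect_equal(as.numeric(back), as.numeric(d[i, ]), tolerance = 1e-12)
  }
})

test_that("axis directions hit the centre texels of their faces", {
  cm <- cube_map_uniform(9, 0.5)
  cm$faces$pz[5, 5] <- 1
  cm$faces$px[5, 5] <- 0
  expect_equal(sample_cubemap(cm, c(0, 0, 1), mode = "nearest"), 1)
  expect_equal(sample_cubemap(cm, c(1, 0, 0), mode = "nearest"), 0)
  expect_equal(sample_cubemap(cm, c(0, -1, 0), mode = "nearest"), 0.5)
  expect_error(sample_cubemap(cm, c(0, 0, 0)), "zero")
})

test_that("rendering a uniform cube map gives a uniform display image", {
  img <- render_display(cube_map_uniform(16, 0.42), frontal_display(32, 24),
                        observer_spec())
  expect_equal(dim(img), c(24, 32))
  expect_true(all(abs(img - 0.42) < 1e-12))
})

test_that("checkerboard edges land at the pixel with the matching azimuth", {
  cv <- rasterize_stimulus(visual_field_canvas(0, 0, 120, 120, resolution = 4),
                           checkerboard_spec(22.5))
  cm <- canvas_to_cubemap(cv, 256)
  disp <- frontal_display(180, 180)     # 90 x 90 degrees, 0.5 deg/px
  img <- render_display(cm, disp, observer_spec(), mode = "nearest")
  mid <- 90
  row_vals <- img[mid, ]
  u <- (seq_len(180) - 0.5) / 180
  az <- spherical_from_direction(
    pixel_to_direction(disp, observer_spec(), u, 0.5))$azimuth
  jumps <- which(abs(diff(row_vals)) > 0.5)
  # one edge of the 22.5-degree checkerboard must sit at azimuth 22.5
  px_pitch <- max(abs(diff(az)))
  expect_true(any(abs(az[jumps] - 22.5) <= px_pitch))
})

test_that("two different display geometries show the same visual scene", {
  # the architecture's display-independence: render the same retinotopic
  # checkerboard on two differently posed/sized displays, back-project
  # both to visual-angle space, and compare where both displays cover
  cv <- rasterize_stimulus(visual_field_canvas(0, 0, 120, 120, resolution = 4),
                           checkerboard_spec(15))
  cm <- canvas_to_cubemap(cv, 256)
  obs <- observer_spec()
  d1 <- display_spec("near", pose(c(0, 0, 0.15)), 0.35, 0.35, 220, 220)
  d2 <- display_spec("angled", pose(c(0.12, 0, 0.28), rotation_from_euler(ry = -25)),
                     0.55, 0.45, 260, 220)
  img1 <- render_display(cm, d1, obs)
  img2 <- render_display(cm, d2, obs)
  back_project <- function(img, disp, probe_az, probe_el) {
    # invert the window mapping analytically for a probe direction
    q <- direction_from_spherical(probe_az, probe_el)
    Rt <- t(disp$pose$rotation)
    o <- as.numeric(Rt %*% (-disp$pose$position))
    dl <- q %*% disp$pose$rotation
    tt <- -o[3] / dl[, 3]
    x <- o[1] + dl[, 1] * tt
    y <- o[2] + dl[, 2] * tt
    u <- x / disp$width + 0.5
    v <- 0.5 - y / disp$height
    ok <- tt > 0 & u >= 0 & u <= 1 & v >= 0 & v <= 1
    cc <- u * disp$resolution_x + 0.5
    rr <- v * disp$resolution_y + 0.5
    vals <- rep(NA_real_, length(tt))
    vals[ok] <- retinowin:::bilinear_sample(unclass(img), rr[ok], cc[ok])
    vals
  }
  set.seed(9)
  az <- runif(400, -28, 28); el <- runif(400, -28, 28)
  v1 <- back_project(img1, d1, az, el)
  v2 <- back_project(img2, d2, az, el)
  both <- !is.na(v1) & !is.na(v2)
  expect_gt(sum(both), 200)
  # agreement within one texel of blur: exclude probes within one canvas
  # texel of a checker edge, where resampling may legitimately disagree
  edge_dist <- pmin(abs(az %% 15), 15 - abs(az %% 15),
                    abs(el %% 15), 15 - abs(el %% 15))
  clear <- both & edge_dist > 0.5
  expect_gt(sum(clear), 100)
  expect_lt(max(abs(v1[clear] - v2[clear])), 0.25)
  expect_lt(mean(abs(v1[clear] - v2[clear])), 0.02)
})

test_that("render_display is invariant under a common rigid transform", {
  set.seed(41)
  scn <- scene(list(
    scene_object("sphere", pose(c(0.2, 0, 1)), scale = 0.5, surface = 1),
    scene_object("cube", pose(c(-0.4, 0.1, 0.8)), scale = 0.3, surface = 0.7)
  ), background = 0.1)
  disp <- display_spec("d", pose(c(0, 0, 0.2)), 0.4, 0.3, 64, 48)
  obs <- observer_spec()
  img0 <- render_display(render_cubemap(scn, obs, 64), disp, obs)
  g <- random_pose(scale = 1.5)
  scn2 <- scene(lapply(scn$objects, function(o) {
    scene_object(o$kind, transform_pose(g, o$pose), o$scale, o$surface)
  }), background = scn$background)
  disp2 <- display_spec("d", transform_pose(g, disp$pose), disp$width,
                        disp$height, disp$resolution_x, disp$resolution_y)
  obs2 <- observer_spec(transform_pose(g, obs$pose))
  img1 <- render_display(render_cubemap(scn2, obs2, 64), disp2, obs2)
  expect_equal(unclass(img1), unclass(img0), tolerance = 1e-9)
})

test_that("warp meshes reproduce flat displays and map constant directions", {
  cv <- rasterize_stimulus(visual_field_canvas(0, 0, 140, 140, resolution = 4),
                           checkerboard_spec(20))
  cm <- canvas_to_cubemap(cv, 192)
  disp <- frontal_display(96, 96)
  obs <- observer_spec()
  direct <- render_display(cm, disp, obs)
  mesh <- display_warp_mesh(disp, obs, 33, 33)
  warped <- render_warped(cm, mesh, 96, 96)
  # equal up to mesh interpolation: most pixels identical, edges blurred
  expect_lt(mean(abs(warped - direct)), 0.02)
  expect_gt(mean(abs(warped - direct) < 0.05), 0.95)

  # a degenerate mesh sending everything to (0,0) samples the forward texel
  m0 <- warp_mesh(matrix(0, 5, 5), matrix(0, 5, 5))
  img0 <- render_warped(cm, m0, 16, 16)
  expect_true(all(abs(img0 - sample_cubemap(cm, c(0, 0, 1))) < 1e-12))
})

test_that("a demi-sphere warp mesh puts a dot stimulus at the matching node", {
  # synthetic dome mesh: nodes span azimuth/elevation +/-90 linearly
  nn <- 41
  az <- matrix(seq(-90, 90, length.out = nn), nn, nn, byrow = TRUE)
  el <- matrix(seq(90, -90, length.out = nn), nn, nn)
  mesh <- warp_mesh(az, el)
  cv <- rasterize_stimulus(visual_field_canvas(30, 15, 180, 150, resolution = 2,
                                               background = 0),
                           dot_spec(60, 30, 10, polarity = "white"))
  cm <- canvas_to_cubemap(cv, 128)
  img <- render_warped(cm, mesh, nn, nn)
  bright <- which(unclass(img) > 0.5, arr.ind = TRUE)
  expect_gt(nrow(bright), 0)
  centroid <- colMeans(bright)
  target <- which.min(abs(seq(-90, 90, length.out = nn) - 60))   # column (azimuth)
  target_row <- which.min(abs(seq(90, -90, length.out = nn) - 30))
  expect_lt(abs(centroid[2] - target), 1.5)
  expect_lt(abs(centroid[1] - target_row), 1.5)
})

test_that("warp mesh invalid nodes and out-of-hull pixels render black", {
  valid <- matrix(TRUE, 5, 5); valid[1, 1] <- FALSE
  mesh <- warp_mesh(matrix(0, 5, 5), matrix(0, 5, 5), valid)
  img <- render_warped(cube_map_uniform(8, 1), mesh, 20, 20)
  expect_equal(img[1, 1], 0)           # cell with the invalid node
  expect_equal(img[20, 20], 1)
  p <- withr::local_tempfile(fileext = ".csv")
  write_warp_mesh(mesh, p)
  back <- read_warp_mesh(p)
  expect_equal(back$valid, mesh$valid)
  expect_equal(back$azimuth, mesh$azimuth)
})

test_that("stereo rendering: identical eyes agree, skybox has zero disparity", {
  sky <- rasterize_stimulus(visual_field_canvas(0, 0, 360, 180, resolution = 1),
                            checkerboard_spec(30))
  scn <- scene(background = sky)
  eye <- eye_matrices_from_pose(pose(), fov_y_deg = 80)
  st <- render_stereo(scn, eye, eye, 64, 64)
  expect_identical(unclass(st$left), unclass(st$right))
  # skybox-only: eyes at different positions still see identical images
  eyes <- stereo_eye_poses(observer_spec(interpupillary_distance = 0.06))
  st2 <- render_stereo(scn, eye_matrices_from_pose(eyes$left, 80),
                       eye_matrices_from_pose(eyes$right, 80), 64, 64)
  expect_equal(unclass(st2$left), unclass(st2$right), tolerance = 1e-12)
})

test_that("stereo vergence of a 1 m target matches projection arithmetic", {
  eyes <- stereo_eye_poses(observer_spec(interpupillary_distance = 0.06))
  eL <- eye_matrices_from_pose(eyes$left, 90)
  eR <- eye_matrices_from_pose(eyes$right, 90)
  target <- c(0, 0, 1)
  pL <- project_point(eL, target)
  pR <- project_point(eR, target)
  # ndc x maps to tan of the visual angle at fov 90 (tan(fov/2) = 1)
  ang <- (atan(pL[["x"]]) - atan(pR[["x"]])) * 180 / pi
  expect_equal(ang, 2 * atan(0.03 / 1) * 180 / pi, tolerance = 1e-9)
  expect_equal(ang, 3.434, tolerance = 1e-3)
  expect_error(eye_matrices(matrix(0, 4, 4), diag(4)), "singular")
})

test_that("the sync square alternates white/black and touches nothing else", {
  img <- rw_image(matrix(0.5, 40, 60))
  rect <- c(50, 30, 8, 8)
  f0 <- apply_sync_square(img, 0, rect)
  f1 <- apply_sync_square(img, 1, rect)
  expect_true(all(f0[31:38, 51:58] == 1))
  expect_true(all(f1[31:38, 51:58] == 0))
  for (k in 0:5) {
    fk <- apply_sync_square(img, k, rect)
    expect_equal(fk[35, 55], as.numeric(k %% 2 == 0))
  }
  untouched <- unclass(f0)
  untouched[31:38, 51:58] <- 0.5
  expect_identical(untouched, unclass(img) + 0)   # bitwise outside the rect
  expect_error(apply_sync_square(img, 0, c(55, 35, 10, 10)), "outside")
  expect_error(apply_sync_square(img, 0, c(0, 0, 0, 4)), "positive size")
})

test_that("rendered luminances never exceed the input range", {
  cv <- rasterize_stimulus(visual_field_canvas(0, 0, 120, 120, resolution = 2),
                           grating_spec(0.1, mean_luminance = 0.6, contrast = 0.5))
  cm <- canvas_to_cubemap(cv, 64)
  img <- render_display(cm, frontal_display(48, 48), observer_spec())
  expect_gte(min(img), min(cv))
  expect_lte(max(img), max(cv))
})
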