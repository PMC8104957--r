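# 3D scenes built from primitive objects (planes, spheres, cubes) with
# uniform or checker-textured grayscale surfaces, rendered by analytic
# raycasting.  The software raycaster is the reference path: it is exact,
# deterministic and platform-free, and defines correctness for every
# rendering operation in the package.

#' Scene object (plane, sphere or cube)
#'
#' Primitives are unit shapes in their local frame, placed by `pose` and
#' sized by the per-axis `scale`:
#' * `plane`: the local `z = 0` rectangle spanning
#'   `[-sx/2, sx/2] x [-sy/2, sy/2]`, visible from both sides;
#' * `sphere`: ellipsoid with semi-axes `scale / 2` (so `scale` is the
#'   diameter per axis);
#' * `cube`: box with side lengths `scale`.
#'
#' @param kind `"plane"`, `"sphere"` or `"cube"`.
#' @param pose A [pose()] placing the object in the world.
#' @param scale Per-axis size in metres (length 1 recycled to 3), > 0.
#' @param surface Either a single luminance in `[0, 1]`, or a texture list
#'   `list(grid = <matrix in [0,1]>, repeat_x = , repeat_y = )` applied in
#'   the object's surface coordinates.
#' @return An object of class `scene_object`.
#' @export
scene_object <- function(kind = c("plane", "sphere", "cube"),
                         pose = pose_identity(), scale = 1, surface = 0.8) {
  kind <- match.arg(kind)
  stopifnot(inherits(pose, "pose"))
  scale <- rep_len(as.numeric(scale), 3)
  if (any(scale <= 0)) stop("scale must be positive")
  if (is.numeric(surface) && length(surface) == 1) {
    if (surface < 0 || surface > 1) stop("surface colour must be in [0, 1]")
  } else if (is.list(surface)) {
    if (!is.matrix(surface$grid)) stop("texture surface needs a $grid matrix")
    surface$repeat_x <- surface$repeat_x %||% 1
    surface$repeat_y <- surface$repeat_y %||% 1
  } else {
    stop("surface must be a luminance or a texture list")
  }
  structure(list(kind = kind, pose = pose, scale = scale, surface = surface),
            class = "scene_object")
}

#' Checker texture helper
#' @param n_checks Checks along each texture axis.
#' @param luminances `c(black, white)`.
#' @return Texture list usable as a `scene_object` surface.
#' @export
checker_texture <- function(n_checks = 8, luminances = c(0, 1)) {
  g <- outer(seq_len(n_checks), seq_len(n_checks),
             function(i, j) luminances[(i + j) %% 2 + 1])
  list(grid = g, repeat_x = 1, repeat_y = 1)
}

#' Assemble a scene
#'
#' @param objects List of [scene_object()]s (may be empty).
#' @param background Either a uniform luminance in `[0, 1]` or a
#'   [visual_field_canvas()] acting as a spherical panorama (skybox)
#'   sampled by miss-ray direction.
#' @return An object of class `rw_scene`.
#' @export
scene <- function(objects = list(), background = 0.5) {
  if (inherits(objects, "scene_object")) objects <- list(objects)
  stopifnot(all(vapply(objects, inherits, TRUE, "scene_object")))
  if (is.numeric(background) && length(background) == 1) {
    if (background < 0 || background > 1) stop("background must be in [0, 1]")
  } else if (!inherits(background, "visual_field_canvas")) {
    stop("background must be a luminance or a visual_field_canvas skybox")
  }
  structure(list(objects = objects, background = background), class = "rw_scene")
}

RAY_EPS <- 1e-9

# Intersect rays (single origin, many directions) with one object.
# Returns list(t = hit distances (Inf = miss), colour = luminance at hit).
# The nearest intersection with t > RAY_EPS is used even when the origin is
# inside the object, so an enclosed observer sees the interior surface.
intersect_object <- function(obj, origin, dirs) {
  Rt <- t(obj$pose$rotation)
  o <- as.numeric(Rt %*% (origin - obj$pose$position))
  dl <- dirs %*% obj$pose$rotation     # = t(Rt %*% t(dirs))
  n <- nrow(dirs)
  t_hit <- rep(Inf, n)
  u <- v <- rep(NA_real_, n)

  if (obj$kind == "sphere") {
    half <- obj$scale / 2
    p <- o / half
    q <- sweep(dl, 2, half, `/`)
    a <- rowSums(q^2)
    b <- 2 * (q[, 1] * p[1] + q[, 2] * p[2] + q[, 3] * p[3])
    cc <- sum(p^2) - 1
    disc <- b^2 - 4 * a * cc
    ok <- disc >= 0
    sq <- sqrt(pmax(0, disc))
    t1 <- (-b - sq) / (2 * a)
    t2 <- (-b + sq) / (2 * a)
    t0 <- ifelse(t1 > RAY_EPS, t1, ifelse(t2 > RAY_EPS, t2, Inf))
    t_hit[ok] <- t0[ok]
    hit <- is.finite(t_hit)
    if (any(hit)) {
      hp <- o + dl[hit, , drop = FALSE] * t_hit[hit]   # local hit point
      # surface coords from the local normal direction
      sph <- spherical_from_direction(sweep(hp, 2, half, `/`))
      u[hit] <- (sph$azimuth + 180) / 360
      v[hit] <- (90 - sph$elevation) / 180
    }
  } else if (obj$kind == "plane") {
    hx <- obj$scale[1] / 2; hy <- obj$scale[2] / 2
    tz <- ifelse(abs(dl[, 3]) < 1e-15, Inf, -o[3] / dl[, 3])
    px <- o[1] + dl[, 1] * tz
    py <- o[2] + dl[, 2] * tz
    ok <- is.finite(tz) & tz > RAY_EPS & abs(px) <= hx & abs(py) <= hy
    t_hit[ok] <- tz[ok]
    u[ok] <- px[ok] / (2 * hx) + 0.5
    v[ok] <- 0.5 - py[ok] / (2 * hy)
  } else { # cube
    h <- obj$scale / 2
    tmin <- rep(-Inf, n); tmax <- rep(Inf, n)
    for (k in 1:3) {
      dk <- dl[, k]
      par <- abs(dk) < 1e-15
      ta <- (-h[k] - o[k]) / dk
      tb <- (h[k] - o[k]) / dk
      lo <- pmin(ta, tb); hi <- pmax(ta, tb)
      lo[par] <- ifelse(abs(o[k]) <= h[k], -Inf, Inf)[1]
      hi[par] <- ifelse(abs(o[k]) <= h[k], Inf, -Inf)[1]
      tmin <- pmax(tmin, lo); tmax <- pmin(tmax, hi)
    }
    ok <- tmax >= pmax(tmin, RAY_EPS)
    t0 <- ifelse(tmin > RAY_EPS, tmin, tmax)
    t_hit[ok] <- t0[ok]
    hit <- is.finite(t_hit)
    if (any(hit)) {
      hp <- o + dl[hit, , drop = FALSE] * t_hit[hit]
      np <- sweep(hp, 2, h, `/`)                  # in [-1, 1]^3 on a face
      ax <- max.col(abs(np), ties.method = "first")
      idx <- cbind(seq_len(nrow(np)), ax)
      # uv from the two remaining axes (fixed per-face convention)
      o1 <- c(2, 1, 1)[ax]; o2 <- c(3, 3, 2)[ax]
      u[hit] <- np[cbind(seq_len(nrow(np)), o1)] / 2 + 0.5
      v[hit] <- np[cbind(seq_len(nrow(np)), o2)] / 2 + 0.5
    }
  }

  colour <- rep(NA_real_, n)
  hit <- is.finite(t_hit)
  if (any(hit)) {
    if (is.numeric(obj$surface)) {
      colour[hit] <- obj$surface
    } else {
      g <- obj$surface$grid
      uu <- (u[hit] * obj$surface$repeat_x) %% 1
      vv <- (v[hit] * obj$surface$repeat_y) %% 1
      ci <- pmin(ncol(g), 1L + floor(uu * ncol(g)))
      ri <- pmin(nrow(g), 1L + floor(vv * nrow(g)))
      colour[hit] <- g[cbind(ri, ci)]
    }
  }
  list(t = t_hit, colour = colour)
}

#' Raycast a scene
#'
#' Casts one ray per row of `dirs` from `origin`; the nearest intersection
#' determines the luminance, and rays that miss every object sample the
#' scene background (uniform value or skybox panorama).
#'
#' @param scn An [scene()].
#' @param origin Length-3 ray origin (world frame, metres).
#' @param dirs `n x 3` matrix of ray directions (need not be unit).
#' @return Numeric vector of luminances in `[0, 1]`.
#' @export
raycast_scene <- function(scn, origin, dirs) {
  stopifnot(inherits(scn, "rw_scene"))
  dirs <- as_direction_matrix(dirs)
  n <- nrow(dirs)
  best_t <- rep(Inf, n)
  col <- rep(NA_real_, n)
  for (obj in scn$objects) {
    hit <- intersect_object(obj, origin, dirs)
    closer <- hit$t < best_t
    best_t[closer] <- hit$t[closer]
    col[closer] <- hit$colour[closer]
  }
  miss <- !is.finite(best_t)
  if (any(miss)) {
    if (inherits(scn$background, "visual_field_canvas")) {
      sph <- spherical_from_direction(dirs[miss, , drop = FALSE])
      col[miss] <- sample_canvas(scn$background, sph$azimuth, sph$elevation)
    } else {
      col[miss] <- scn$background
    }
  }
  pmin(1, pmax(0, col))
}
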