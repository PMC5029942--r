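# Synthetic stimulus generator: textured height-field surfaces rendered
# under orthographic or perspective projection together with exact
# ground-truth relative depth and an object mask. The surfaces and
# procedural textures are analogs of typical rendered test stimuli
# (slanted planes, a plane with a central semisphere, bell convexities and
# concavities, doubly curved objects, multi-level depth steps, cylinders)
# -- synthetic throughout, not replicas of any particular render.
#
# Geometry convention: world x/y in pixels with origin at the image
# center, z the height toward the viewer (camera above, looking down).
# Textures live on the surface: texture coordinates are per-axis arc
# lengths, so a slanted patch carries the same texture density on the
# surface and its projection is compressed by cos(slant) -- the
# foreshortening cue the model exploits. Under orthographic projection the
# dot scale carries no depth information; under perspective, magnification
# (D - z)/D adds the scale/density gradient.

#' Scene specification
#'
#' @param shape one of `"flat"`, `"slanted_plane"`, `"plane_plus_semisphere"`,
#'   `"bell"`, `"doubly_curved"`, `"depth_steps"`, `"cylinder"`,
#'   `"sinusoidal_plane"`.
#' @param texture one of `"polka"`, `"anisotropic_dots"`,
#'   `"contour_lines"`, `"noise"`.
#' @param projection `"orthographic"` or `"perspective"`.
#' @param image_size image side in pixels (square output).
#' @param seed integer; together with the spec it fully determines the
#'   render.
#' @param fov perspective field of view in degrees (ignored for
#'   orthographic).
#' @param shape_args named list of geometric parameters:
#'   `slant` (deg) and `tilt` (deg, direction of steepest descent in the
#'   image; 90 = downward) for `slanted_plane`; `radius` for the
#'   semisphere and cylinder; `sign` (`"convex"`/`"concave"`), `width` and
#'   `height` for `bell`; `levels` and `step_height` for `depth_steps`;
#'   `axis` (deg) for `cylinder`; `rotations` (deg, about x) for
#'   `sinusoidal_plane`.
#' @param texture_args named list: `dot_radius`, `spacing`, `jitter`
#'   (fraction of spacing) for dots; `axis_ratio` and `axis` (deg) for
#'   anisotropic dots; `spacing`, `orientation` (deg), `line_width`,
#'   `shape_linked` for contour lines; `correlation_length` for noise.
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(shape = "flat", texture = "polka",
                       projection = c("orthographic", "perspective"),
                       image_size = 300L, seed = 1L, fov = 50,
                       shape_args = list(), texture_args = list()) {
  projection <- match.arg(projection)
  shapes <- c("flat", "slanted_plane", "plane_plus_semisphere", "bell",
              "doubly_curved", "depth_steps", "cylinder", "sinusoidal_plane")
  textures <- c("polka", "anisotropic_dots", "contour_lines", "noise")
  shape <- match.arg(shape, shapes)
  texture <- match.arg(texture, textures)
  if (projection == "perspective" && (fov <= 0 || fov >= 180)) {
    stop("perspective fov must lie in (0, 180) degrees")
  }
  stopifnot(image_size >= 32L)
  structure(list(shape = shape, texture = texture, projection = projection,
                 image_size = as.integer(image_size), seed = as.integer(seed),
                 fov = fov, shape_args = shape_args,
                 texture_args = texture_args),
            class = "scene_spec")
}

#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' @keywords internal
shape_defaults <- function(spec) {
  n <- spec$image_size
  a <- spec$shape_args
  def <- switch(spec$shape,
    flat = list(),
    slanted_plane = list(slant = 50, tilt = 90),
    plane_plus_semisphere = list(radius = n / 4),
    bell = list(sign = "convex", width = n / 6, height = n / 5),
    doubly_curved = list(slope = 0.08, bump = n / 7, dip = n / 9),
    depth_steps = list(levels = 5L, step_height = n / 20),
    cylinder = list(radius = n / 3, axis = 0),
    sinusoidal_plane = list(rotations = 45, period = n / 3, amp = n / 12))
  utils::modifyList(def, a)
}

#' @keywords internal
height_fun <- function(spec) {
  a <- shape_defaults(spec)
  n <- spec$image_size
  switch(spec$shape,
    flat = function(X, Y) X * 0,
    slanted_plane = {
      sl <- tan(a$slant * pi / 180); ti <- a$tilt * pi / 180
      # height decreases along the tilt (steepest-descent) direction
      function(X, Y) -sl * (X * cos(ti) + Y * sin(ti))
    },
    plane_plus_semisphere = {
      r <- a$radius
      function(X, Y) {
        d2 <- X^2 + Y^2
        z <- sqrt(pmax(r^2 - d2, 0))
        z
      }
    },
    bell = {
      s <- if (identical(a$sign, "concave")) -1 else 1
      function(X, Y) s * a$height * exp(-(X^2 + Y^2) / (2 * a$width^2))
    },
    doubly_curved = {
      # curvature-dominated blob: one steep convexity and one concavity on
      # a mild tilt; flank slants reach ~45 degrees so the compression cue
      # is strong
      function(X, Y) {
        -a$slope * Y +
          (n / 4) * exp(-((X - n / 8)^2 + (Y + n / 10)^2) / (2 * a$bump^2)) -
          (n / 6) * exp(-((X + n / 6)^2 + (Y - n / 8)^2) / (2 * a$dip^2))
      }
    },
    depth_steps = {
      L <- a$levels; sh <- a$step_height
      function(X, Y) {
        lev <- pmin(pmax(floor((Y + n / 2) / (n / L)), 0), L - 1)
        sh * lev
      }
    },
    cylinder = {
      r <- a$radius; ax <- a$axis * pi / 180
      function(X, Y) {
        s <- -X * sin(ax) + Y * cos(ax)   # signed distance from the axis
        sqrt(pmax(r^2 - s^2, 0))
      }
    },
    sinusoidal_plane = {
      rot <- a$rotations * pi / 180
      function(X, Y) {
        -tan(rot) * Y + a$amp * sin(2 * pi * (X * cos(rot * 0.5) +
                                              Y * sin(rot * 0.5)) / a$period)
      }
    })
}

#' @keywords internal
mask_fun <- function(spec) {
  a <- shape_defaults(spec)
  switch(spec$shape,
    plane_plus_semisphere = function(X, Y) X^2 + Y^2 <= a$radius^2,
    cylinder = {
      ax <- a$axis * pi / 180
      function(X, Y) abs(-X * sin(ax) + Y * cos(ax)) <= a$radius
    },
    function(X, Y) X == X  # full support
  )
}

#' Analytic height field and mask of a scene
#'
#' Evaluates the surface height (pixels, toward the viewer) and the object
#' support on the orthographic image grid, without texturing or
#' projection.
#'
#' @param spec a [scene_spec()].
#' @return list with matrices `z` and `mask`.
#' @export
make_height_field <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  n <- spec$image_size
  ctr <- (n + 1) / 2
  X <- matrix(seq_len(n) - ctr, n, n, byrow = TRUE)
  Y <- matrix(seq_len(n) - ctr, n, n)
  list(z = height_fun(spec)(X, Y), mask = mask_fun(spec)(X, Y))
}

# ---- procedural textures -------------------------------------------------

#' @keywords internal
smoothstep <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x * x * (3 - 2 * x)
}

#' Procedural texture evaluator
#'
#' Returns a seeded texture function `f(x, y, z, gx, gy)` with values in
#' `[0, 1]`, evaluated at world coordinates on the scene's surface with
#' the local height gradient `(gx, gy)` (defaults 0 reproduce the planar
#' texture). Texturing is local -- no global surface parameterization --
#' so curved surfaces carry no path-dependent distortion:
#'
#' * dots (`polka`, `anisotropic_dots`) live on a jittered world lattice
#'   (repeating every 64 cells, so arbitrary coordinates are supported
#'   deterministically); each dot is a disc of radius `dot_radius` on the
#'   local tangent plane, so its projection is foreshortened by
#'   cos(slant) along the gradient direction, and extra dots are added in
#'   slanted cells so that density is uniform per unit *surface* area;
#' * `contour_lines` are planar cuts: level sets of
#'   `cos(rho) z + sin(rho) (x cos(phi_n) + y sin(phi_n))` with cut tilt
#'   `rho` (`cut_tilt`, degrees; `shape_linked = TRUE` forces horizontal
#'   cuts, i.e. height contours) and in-image line orientation
#'   `orientation`;
#' * `noise` is 3D value noise sampled on the surface, so steep regions
#'   traverse it faster and appear compressed.
#'
#' Dots are dark on a light ground.
#'
#' @param spec a [scene_spec()] (its `texture`, `texture_args` and `seed`
#'   fields are used).
#' @return a vectorized function of `(x, y, z, gx, gy)`.
#' @export
make_texture <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  ta <- spec$texture_args
  K <- 64L
  switch(spec$texture,
    polka = ,
    anisotropic_dots = {
      d <- utils::modifyList(list(dot_radius = 6, spacing = 18, jitter = 0.5,
                                  axis_ratio = if (spec$texture == "polka") 1 else 2,
                                  axis = 30), ta)
      if (spec$texture == "polka") { d$axis_ratio <- 1; d$axis <- 0 }
      sp <- d$spacing
      jmax <- d$jitter * sp
      kx_extra <- 3L   # up to 4 dots per cell on steep slant
      ju <- with_seed(spec$seed,
                      array(stats::runif(K * K * (kx_extra + 1L), -jmax, jmax),
                            c(K, K, kx_extra + 1L)))
      jv <- with_seed(spec$seed + 1L,
                      array(stats::runif(K * K * (kx_extra + 1L), -jmax, jmax),
                            c(K, K, kx_extra + 1L)))
      ue <- with_seed(spec$seed + 2L,
                      array(stats::runif(K * K * kx_extra),
                            c(K, K, kx_extra)))
      aa <- d$axis * pi / 180
      sq <- sqrt(d$axis_ratio)
      R <- d$dot_radius
      hfun <- height_fun(spec)
      function(x, y, z = 0, gx = 0, gy = 0) {
        val <- rep(1, length(x))
        ix <- floor(x / sp); iy <- floor(y / sp)
        for (dx in -1:1) for (dy in -1:1) {
          ci <- ix + dx; cj <- iy + dy
          mi <- (ci %% K) + 1L; mj <- (cj %% K) + 1L
          for (k in seq_len(kx_extra + 1L)) {
            cx <- (ci + 0.5) * sp + ju[cbind(mi, mj, k)]
            cy <- (cj + 0.5) * sp + jv[cbind(mi, mj, k)]
            # local slant at the dot center sets both the extra-dot
            # acceptance (area-uniform density) and the foreshortening;
            # one slope per dot keeps each dot a coherent ellipse
            gxc <- hfun(cx + 0.5, cy) - hfun(cx - 0.5, cy)
            gyc <- hfun(cx, cy + 0.5) - hfun(cx, cy - 0.5)
            sec_b <- pmin(sqrt(1 + gxc^2 + gyc^2), kx_extra + 1)
            if (k > 1L) {
              keep <- ue[cbind(mi, mj, k - 1L)] < (sec_b - k + 1)
              if (!any(keep)) next
            } else keep <- TRUE
            ex <- x - cx; ey <- y - cy
            # anisotropy in the dot frame (area preserving)
            p <- ex * cos(aa) + ey * sin(aa)
            q <- -ex * sin(aa) + ey * cos(aa)
            ex <- p / sq; ey <- q * sq
            # foreshorten along the slant (gradient) direction
            gn <- sqrt(gxc^2 + gyc^2)
            cosb <- 1 / sqrt(1 + gn^2)
            hasg <- gn > 1e-9
            ux <- ifelse(hasg, gxc / pmax(gn, 1e-9), 1)
            uy <- ifelse(hasg, gyc / pmax(gn, 1e-9), 0)
            dpar <- ex * ux + ey * uy
            dperp <- -ex * uy + ey * ux
            rr <- sqrt((dpar / cosb)^2 + dperp^2)
            v_dot <- 0.15 + 0.7 * smoothstep((rr - R) / 1.5)
            v_dot[!keep] <- 1
            val <- pmin(val, v_dot)
          }
        }
        val
      }
    },
    contour_lines = {
      d <- utils::modifyList(list(spacing = 12, orientation = 0,
                                  line_width = 3, cut_tilt = 55,
                                  shape_linked = FALSE), ta)
      rho <- if (isTRUE(d$shape_linked)) 0 else d$cut_tilt * pi / 180
      phin <- (d$orientation + 90) * pi / 180
      function(x, y, z = 0, gx = 0, gy = 0) {
        s <- cos(rho) * z + sin(rho) * (x * cos(phin) + y * sin(phin))
        frac <- abs(((s / d$spacing) %% 1) - 0.5) * 2   # 0 at line center
        w <- d$line_width / d$spacing
        edge <- 2 / d$spacing
        0.15 + 0.7 * smoothstep((frac - w) / (2 * edge) + 0.5)
      }
    },
    noise = {
      d <- utils::modifyList(list(correlation_length = 8), ta)
      vals <- with_seed(spec$seed + 2L, array(stats::runif(K^3), c(K, K, K)))
      cl <- d$correlation_length
      function(x, y, z = 0, gx = 0, gy = 0) {
        gu <- x / cl; gv <- y / cl; gw <- rep_len(z, length(x)) / cl
        i0 <- floor(gu); j0 <- floor(gv); k0 <- floor(gw)
        fu <- smoothstep(gu - i0); fv <- smoothstep(gv - j0)
        fw <- smoothstep(gw - k0)
        at <- function(i, j, k) {
          vals[cbind((i %% K) + 1L, (j %% K) + 1L, (k %% K) + 1L)]
        }
        lerp <- function(a, b, f) a * (1 - f) + b * f
        v00 <- lerp(at(i0, j0, k0), at(i0 + 1, j0, k0), fu)
        v10 <- lerp(at(i0, j0 + 1, k0), at(i0 + 1, j0 + 1, k0), fu)
        v01 <- lerp(at(i0, j0, k0 + 1), at(i0 + 1, j0, k0 + 1), fu)
        v11 <- lerp(at(i0, j0 + 1, k0 + 1), at(i0 + 1, j0 + 1, k0 + 1), fu)
        xx <- lerp(lerp(v00, v10, fv), lerp(v01, v11, fv), fw)
        0.5 + 0.45 * tanh(4 * (xx - 0.5))   # binary-ish
      }
    })
}

#' Render a synthetic scene
#'
#' Ray-casts the height field (orthographic parallel rays, or a pinhole
#' camera with the given field of view), evaluates the surface texture at
#' the hit points with the local height gradient (so foreshortening and
#' density cues arise from the surface itself), applies a mild anti-alias
#' blur, quantises to 8-bit-safe gray levels, and returns the image
#' together with the exact ground-truth relative depth (distance along
#' the camera ray, inverted and rescaled to `[0, 1]`, 1 = nearest) and
#' the object mask.
#'
#' @param spec a [scene_spec()].
#' @return an object of class `rendered_scene`: list with `image`,
#'   `depth` (ground truth, `[0, 1]`), `z` (raw heights), `mask`, `spec`.
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  n <- spec$image_size
  ctr <- (n + 1) / 2
  hf <- height_fun(spec)
  mf <- mask_fun(spec)
  tex <- make_texture(spec)

  # image pixel rays -> world coordinates
  px <- matrix(seq_len(n) - ctr, n, n, byrow = TRUE)
  py <- matrix(seq_len(n) - ctr, n, n)
  if (spec$projection == "orthographic") {
    X <- px; Y <- py
    Z <- hf(X, Y)
    dist <- -Z
  } else {
    D <- (n / 2) / tan(spec$fov * pi / 360)
    X <- px; Y <- py
    for (i in 1:8) {
      Z <- hf(X, Y)
      X <- px * (D - Z) / D
      Y <- py * (D - Z) / D
    }
    Z <- hf(X, Y)
    dist <- D - Z
  }

  # local height gradient at the hit points (central differences)
  gx <- (hf(X + 0.5, Y) - hf(X - 0.5, Y))
  gy <- (hf(X, Y + 0.5) - hf(X, Y - 0.5))

  img <- matrix(tex(as.vector(X), as.vector(Y), as.vector(Z),
                    as.vector(gx), as.vector(gy)), n, n)
  img <- gauss_smooth(img, 0.7)
  img <- pmin(pmax(img, 0), 1)
  img <- round(img * 255) / 255

  mask <- mf(X, Y)
  depth <- matrix(NA_real_, n, n)
  depth[mask] <- normalize_relative_depth(dist[mask], invert = TRUE)

  structure(list(image = img, depth = depth, z = hf(px, py), mask = mask,
                 spec = spec),
            class = "rendered_scene")
}

#' @export
print.rendered_scene <- function(x, ...) {
  cat(sprintf("<rendered_scene> %s / %s, %s, %dx%d px, seed %d\n",
              x$spec$shape, x$spec$texture, x$spec$projection,
              nrow(x$image), ncol(x$image), x$spec$seed))
  invisible(x)
}

#' Write a rendered scene to disk
#'
#' Emits the image and mask as PNG, the ground-truth depth as both PNG and
#' a plain-text matrix, and a provenance sidecar with the serialized spec.
#'
#' @param scene a `rendered_scene`.
#' @param dir output directory (created if needed).
#' @param stem file name stem.
#' @export
export_scene <- function(scene, dir, stem = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  png::writePNG(scene$image, file.path(dir, paste0(stem, "_image.png")))
  png::writePNG(scene$mask * 1, file.path(dir, paste0(stem, "_mask.png")))
  d <- scene$depth; d[is.na(d)] <- 0
  png::writePNG(d, file.path(dir, paste0(stem, "_depth.png")))
  utils::write.table(scene$depth, file.path(dir, paste0(stem, "_depth.txt")),
                     row.names = FALSE, col.names = FALSE)
  sidecar <- c(
    paste0("shape: ", scene$spec$shape),
    paste0("texture: ", scene$spec$texture),
    paste0("projection: ", scene$spec$projection),
    paste0("image_size: ", scene$spec$image_size),
    paste0("seed: ", scene$spec$seed),
    paste0("fov: ", scene$spec$fov),
    paste0("shape_args: ", paste(names(scene$spec$shape_args),
                                 unlist(scene$spec$shape_args),
                                 sep = "=", collapse = ", ")),
    paste0("texture_args: ", paste(names(scene$spec$texture_args),
                                   unlist(scene$spec$texture_args),
                                   sep = "=", collapse = ", ")))
  writeLines(sidecar, file.path(dir, paste0(stem, "_provenance.yml")))
  invisible(dir)
}
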