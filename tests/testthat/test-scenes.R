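# Synthetic stimulus generator: geometry, textures, projection and
# ground-truth contracts.

test_that("height fields realise their analytic definitions", {
  flat <- make_height_field(scene_spec("flat", image_size = 64))
  expect_equal(diff(range(flat$z)), 0)
  expect_true(all(flat$mask))
  semi <- make_height_field(scene_spec("plane_plus_semisphere",
                                       image_size = 64,
                                       shape_args = list(radius = 16)))
  expect_equal(max(semi$z), 16, tolerance = 0.05)  # center height = radius
  expect_equal(sum(semi$mask), sum(semi$z > 0) + sum(semi$z == 0 & semi$mask))
  sl <- make_height_field(scene_spec("slanted_plane", image_size = 64,
                                     shape_args = list(slant = 50, tilt = 90)))
  dz <- diff(sl$z[, 32])
  expect_equal(unique(round(dz, 9)), round(-tan(50 * pi / 180), 9))
  cyl <- make_height_field(scene_spec("cylinder", image_size = 64,
                                      shape_args = list(radius = 20, axis = 0)))
  expect_equal(max(cyl$z), 20, tolerance = 0.05)
  expect_true(all(cyl$z[!cyl$mask] == 0))
})

test_that("textures are seeded, tileable and degenerate correctly", {
  # zero jitter: a perfect lattice (dot centers exactly on cell centers)
  sp0 <- scene_spec("flat", "polka", image_size = 64, seed = 5,
                    texture_args = list(jitter = 0, spacing = 10,
                                        dot_radius = 3))
  tex <- make_texture(sp0)
  u <- seq(5, 635, by = 10)   # cell centers
  expect_true(all(tex(u, rep(5, length(u))) < 0.2))        # dark dot centers
  expect_true(all(tex(u + 5, rep(0, length(u))) > 0.8))    # light corners
  # same seed -> identical texture values
  spA <- scene_spec("flat", "noise", image_size = 64, seed = 9)
  spB <- scene_spec("flat", "noise", image_size = 64, seed = 9)
  pts <- runif(50, 0, 500)
  expect_identical(make_texture(spA)(pts, rev(pts)),
                   make_texture(spB)(pts, rev(pts)))
  # anisotropic dots with axis ratio 1 reduce to polka
  spP <- scene_spec("flat", "polka", image_size = 64, seed = 7)
  spE <- scene_spec("flat", "anisotropic_dots", image_size = 64, seed = 7,
                    texture_args = list(axis_ratio = 1))
  expect_equal(make_texture(spP)(pts, rev(pts)),
               make_texture(spE)(pts, rev(pts)), tolerance = 1e-12)
})

test_that("rendering is bit-deterministic in (spec, seed)", {
  sp <- scene_spec("plane_plus_semisphere", "polka", "orthographic",
                   image_size = 72, seed = 13)
  s1 <- render_scene(sp); s2 <- render_scene(sp)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$depth, s2$depth)
  s3 <- render_scene(scene_spec("plane_plus_semisphere", "polka",
                                "orthographic", image_size = 72, seed = 14))
  expect_false(identical(s1$image, s3$image))
  # fov validation
  expect_error(scene_spec("flat", projection = "perspective", fov = 0), "fov")
  expect_error(scene_spec("flat", projection = "perspective", fov = 190), "fov")
})

test_that("ground-truth depth is normalized, near = 1, and idempotent under renormalization", {
  sc <- render_scene(scene_spec("slanted_plane", "polka", "orthographic",
                                image_size = 64, seed = 2,
                                shape_args = list(slant = 40, tilt = 90)))
  expect_equal(range(sc$depth), c(0, 1))
  # the top of the image (higher surface) is nearer
  expect_gt(mean(sc$depth[1:10, ]), mean(sc$depth[55:64, ]))
  expect_equal(normalize_relative_depth(sc$depth), sc$depth,
               tolerance = 1e-12)
})

test_that("orthographic flat dots stay round; slanted dots compress by cos(slant)", {
  skip_if_not_installed("EBImage")
  ratios <- function(slant, seed = 3) {
    sc <- render_scene(scene_spec(
      if (slant == 0) "flat" else "slanted_plane", "polka", "orthographic",
      image_size = 180, seed = seed,
      shape_args = if (slant == 0) list() else list(slant = slant, tilt = 90),
      texture_args = list(spacing = 22, dot_radius = 5, jitter = 0.2)))
    lab <- EBImage::bwlabel(sc$image < 0.5)
    ft <- EBImage::computeFeatures.moment(lab)
    ecc <- ft[ft[, "m.majoraxis"] > 4, , drop = FALSE]
    # minor/major from eccentricity
    sqrt(1 - ecc[, "m.eccentricity"]^2)
  }
  r0 <- median(ratios(0))
  expect_gt(r0, 0.9)
  for (s in c(30, 55)) {
    rs <- median(ratios(s))
    expect_lt(abs(rs - cos(s * pi / 180)), 0.05)
  }
})

test_that("narrow field of view reduces projected dot-size variation", {
  skip_if_not_installed("EBImage")
  sizes <- function(fov) {
    sc <- render_scene(scene_spec("slanted_plane", "polka", "perspective",
      image_size = 180, seed = 6, fov = fov,
      shape_args = list(slant = 45, tilt = 90),
      texture_args = list(spacing = 24, dot_radius = 6, jitter = 0.2)))
    lab <- EBImage::bwlabel(sc$image < 0.5)
    ft <- EBImage::computeFeatures.moment(lab)
    ft[ft[, "m.majoraxis"] > 4, "m.majoraxis"]
  }
  cv <- function(x) sd(x) / mean(x)
  expect_lt(cv(sizes(5)), cv(sizes(50)))
})

test_that("scene export writes the full artifact set", {
  sc <- render_scene(scene_spec("flat", "noise", image_size = 48, seed = 1))
  d <- tempfile("scene")
  export_scene(sc, d, "s")
  files <- list.files(d)
  expect_setequal(files, c("s_image.png", "s_mask.png", "s_depth.png",
                           "s_depth.txt", "s_provenance.yml"))
  back <- as.matrix(read.table(file.path(d, "s_depth.txt")))
  expect_equal(unname(back), unname(sc$depth), tolerance = 1e-6)
  unlink(d, recursive = TRUE)
})
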