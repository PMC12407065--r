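# expanded unit volume of a given class (hull = 1 m^3 cube, k = 1 expansion)
unit_vol <- function(class) {
  h <- compute_hull(segment_mesh(unit_cube_pts(), class))
  pol <- expansion_policy("NAS_isometric", floor_classes = character(0),
                          exempt_classes = character(0))
  expand_segment(h, scaling_model(class, "NAS", "isometric", k = 1), pol)
}

test_that("density presets assign the stated densities per segment class", {
  primary <- density_scheme("primary")
  expect_equal(segment_mass(unit_vol("torso"), scheme = primary)$mass, 850)
  expect_equal(segment_mass(unit_vol("neck"), scheme = primary)$mass, 800)
  for (cl in c("head", "tail", "thigh", "shank", "metatarsus", "pes",
               "brachium", "antebrachium", "manus")) {
    expect_equal(segment_mass(unit_vol(cl), scheme = primary)$mass, 1000)
  }
  expect_equal(segment_mass(unit_vol("ornament"), scheme = primary)$mass, 2000)
  expect_equal(segment_mass(unit_vol("osteoderm"), scheme = primary)$mass, 2000)
  expect_equal(segment_mass(unit_vol("sail"), scheme = primary)$mass, 1000)

  expect_equal(segment_mass(unit_vol("torso"),
                            scheme = density_scheme("homogeneous_max"))$mass,
               1169)
  expect_equal(segment_mass(unit_vol("thigh"),
                            scheme = density_scheme("homogeneous_min"))$mass,
               731)
  expect_equal(segment_mass(unit_vol("neck"),
                            scheme = density_scheme("sauropod_low_neck"))$mass,
               500)
  expect_equal(segment_mass(unit_vol("ornament"),
                            scheme = density_scheme("ornament_light"))$mass,
               1000)
  expect_equal(segment_mass(unit_vol("sail"),
                            scheme = density_scheme("sail_compact"))$mass,
               2000)
})

test_that("whole-body assembly is a mass-weighted mean of segment COMs", {
  m <- box_skeleton(list(
    list(class = "torso", center = c(0, 0, 0), size = c(0.1, 0.1, 0.1)),
    list(class = "head", center = c(1, 0, 0), size = c(0.1, 0.1, 0.1))))
  tab <- flat_scaling_table(k = 1)
  hom <- density_scheme("custom", homogeneous_value = 1000)

  # equal masses at x = 0 and x = 1 -> COM x = 0.5
  b <- body_mass_props(m, expansion_policy("NAS_isometric"), tab, hom)
  expect_equal(b$com[1L], 0.5, tolerance = 1e-12)

  # masses 1:3 -> COM x = 0.75
  m2 <- box_skeleton(list(
    list(class = "torso", center = c(0, 0, 0), size = c(0.1, 0.1, 0.1)),
    list(class = "head", center = c(1, 0, 0),
         size = c(0.1, 0.1, 0.1) * 3^(1 / 3))))
  b2 <- body_mass_props(m2, expansion_policy("NAS_isometric"), tab, hom)
  expect_equal(b2$com[1L], 0.75, tolerance = 1e-9)

  # single segment -> COM equals the segment COM, total its mass
  m1 <- box_skeleton(list(list(class = "torso", center = c(0.3, 0, 0.2),
                               size = c(0.2, 0.2, 0.2))))
  b1 <- body_mass_props(m1, expansion_policy("NAS_isometric"), tab, hom)
  expect_equal(b1$com, c(0.3, 0, 0.2), tolerance = 1e-12)
  expect_equal(b1$total_mass, 0.2^3 * 1000, tolerance = 1e-9)
  expect_equal(unname(b1$segment_fraction), 100)
})

test_that("mass conservation, COM linearity and density proportionality hold", {
  g <- generate_skeleton(template_quadruped(armoured = TRUE), seed = 17)
  body <- body_mass_props(g$manifest, expansion_policy("NAS_isometric"))
  per <- body$per_segment

  expect_equal(body$total_mass, sum(per$mass), tolerance = 1e-12)
  expect_equal(sum(body$segment_fraction), 100, tolerance = 1e-6)
  expect_equal(body$com,
               c(sum(per$com_x * per$mass), sum(per$com_y * per$mass),
                 sum(per$com_z * per$mass)) / sum(per$mass),
               tolerance = 1e-12)

  # COM of a union is the mass-weighted mean of the parts' COMs
  half1 <- per[1:10, ]; half2 <- per[-(1:10), ]
  com_of <- function(p) c(sum(p$com_x * p$mass), sum(p$com_y * p$mass),
                          sum(p$com_z * p$mass)) / sum(p$mass)
  w <- c(sum(half1$mass), sum(half2$mass))
  expect_equal(body$com,
               (com_of(half1) * w[1L] + com_of(half2) * w[2L]) / sum(w),
               tolerance = 1e-12)

  # scaling every density by c scales masses by c, COM unchanged
  primary <- density_scheme("primary")
  scaled <- density_scheme("custom",
                           class_density = primary$class_density * 2.5)
  b_sc <- variant_redensify(body, scaled)
  expect_equal(b_sc$total_mass, 2.5 * body$total_mass, tolerance = 1e-12)
  expect_equal(b_sc$com, body$com, tolerance = 1e-12)

  # homogeneous density: COM equals the volume-weighted centroid mean
  b_hom <- variant_redensify(body, density_scheme("homogeneous_max"))
  vw <- c(sum(per$com_x * per$point_volume),
          sum(per$com_y * per$point_volume),
          sum(per$com_z * per$point_volume)) / sum(per$point_volume)
  expect_equal(b_hom$com, vw, tolerance = 1e-12)
})

test_that("osteoderm exclusion removes exactly the osteoderm mass and shifts COM ventrally", {
  # hand-computable: torso at origin + one dorsal osteoderm
  m <- box_skeleton(list(
    list(class = "torso", center = c(0, 0, 0), size = c(1, 1, 1)),
    list(class = "osteoderm", center = c(0, 0, 1), size = c(0.3, 0.3, 0.3))))
  tab <- flat_scaling_table(k = 1)
  b <- body_mass_props(m, expansion_policy("NAS_isometric"), tab,
                       density_scheme("primary"))
  b_ex <- variant_exclude_osteoderms(b)
  ost_mass <- 0.3^3 * 2000
  expect_equal(b$total_mass - b_ex$total_mass, ost_mass, tolerance = 1e-9)
  expect_lt(b_ex$com[3L], b$com[3L])       # ventral shift
  # fraction f removed: new total = (1 - f) * old total
  f <- ost_mass / b$total_mass
  expect_equal(b_ex$total_mass, (1 - f) * b$total_mass, tolerance = 1e-12)
  # hand value: COM z of two point masses 850 kg @ 0 and 54 kg @ 1
  expect_equal(b$com[3L], ost_mass / (850 + ost_mass), tolerance = 1e-9)
  expect_equal(b_ex$com[3L], 0, tolerance = 1e-12)

  # a body without osteoderms is returned unchanged
  m0 <- box_skeleton(list(list(class = "torso", center = c(0, 0, 0),
                               size = c(1, 1, 1))))
  b0 <- body_mass_props(m0, expansion_policy("NAS_isometric"), tab)
  expect_identical(variant_exclude_osteoderms(b0), b0)
})

test_that("redensify variants change masses but not volumes or centroids", {
  m <- box_skeleton(list(
    list(class = "torso", center = c(0.5, 0, 0), size = c(1, 1, 1)),
    list(class = "neck", center = c(1.5, 0, 0.4), size = c(0.9, 0.5, 0.5)),
    list(class = "ornament", center = c(2, 0, 0.8),
         size = rep(0.1^(1 / 3), 3))))
  tab <- flat_scaling_table(k = 1)
  b <- body_mass_props(m, expansion_policy("NAS_isometric",
                                           floor_classes = character(0)),
                       tab, density_scheme("primary"))
  per <- b$per_segment

  # ornament 0.1 m^3: 2000 -> 1000 kg/m^3 halves that segment's mass
  expect_equal(per$mass[per$class == "ornament"], 200, tolerance = 1e-9)
  b_l <- variant_redensify(b, density_scheme("ornament_light"))
  expect_equal(b_l$per_segment$mass[per$class == "ornament"], 100,
               tolerance = 1e-9)

  # neck 800 -> 500
  vneck <- per$point_volume[per$class == "neck"]
  b_n <- variant_redensify(b, density_scheme("sauropod_low_neck"))
  expect_equal(b_n$per_segment$mass[per$class == "neck"], 500 * vneck,
               tolerance = 1e-9)

  # volumes and centroids untouched
  expect_equal(b_n$per_segment$point_volume, per$point_volume)
  expect_equal(b_n$per_segment$com_x, per$com_x)

  # identical scheme -> identical body
  b_same <- variant_redensify(b, density_scheme("primary"))
  expect_equal(b_same$total_mass, b$total_mass)
  expect_equal(b_same$com, b$com)

  # missing class in a custom scheme errors
  expect_error(variant_redensify(b, density_scheme("custom",
                                                   class_density = c(torso = 850))),
               "missing from density scheme")
})

test_that("whole-body bounds sum segment-wise extremes", {
  g <- generate_skeleton(template_quadruped(), seed = 23)
  b <- body_mass_props(g$manifest, expansion_policy("NAS_isometric"))
  per <- b$per_segment
  expect_equal(b$total_mass_lower, sum(per$mass_lower), tolerance = 1e-12)
  expect_equal(b$total_mass_upper, sum(per$mass_upper), tolerance = 1e-12)
  expect_lte(b$total_mass_lower, b$total_mass)
  expect_gte(b$total_mass_upper, b$total_mass)
})
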