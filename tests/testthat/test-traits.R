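test_that("projected area counts foreground pixels", {
  expect_equal(projected_plant_area(make_rect_mask(10, 10)), 100L)
  m <- matrix(FALSE, 5, 5); m[3, 3] <- TRUE
  expect_equal(projected_plant_area(m), 1L)
  expect_error(projected_plant_area(matrix(FALSE, 3, 3)), "empty")
})

test_that("object extents match the bounding box, verified by full scan", {
  expect_equal(object_extent(make_rect_mask(10, 10)),
               c(x_px = 10L, y_px = 10L))
  line <- matrix(FALSE, 5, 12); line[3, 4:10] <- TRUE
  expect_equal(object_extent(line), c(x_px = 7L, y_px = 1L))
  expect_equal(object_extent(make_L_mask()), scan_extent(make_L_mask()))
  set.seed(31)
  for (i in 1:10) {
    m <- random_mask(15, 18, 0.2)
    expect_equal(unname(object_extent(m)), unname(scan_extent(m)))
  }
})

test_that("convex hull area matches closed forms and the brute-force oracle", {
  expect_equal(convex_hull_area(make_rect_mask(10, 10)), 100)
  one <- matrix(FALSE, 4, 4); one[2, 2] <- TRUE
  expect_equal(convex_hull_area(one), 1)
  expect_equal(convex_hull_area(make_plus_mask()),
               brute_hull_area(make_plus_mask()), tolerance = 1e-9)
  set.seed(19)
  for (i in 1:25) {
    m <- random_mask(sample(3:20, 1), sample(3:20, 1), 0.25)
    expect_equal(convex_hull_area(m), brute_hull_area(m), tolerance = 1e-9)
  }
})

test_that("compactness is area over hull area, bounded in (0, 1]", {
  expect_equal(compactness(make_rect_mask(8, 8)), 1)
  plus <- make_plus_mask()
  expect_equal(compactness(plus),
               projected_plant_area(plus) / brute_hull_area(plus),
               tolerance = 1e-9)
  set.seed(23)
  for (i in 1:15) {
    cmp <- compactness(random_mask(12, 12, 0.3))
    expect_gt(cmp, 0); expect_lte(cmp, 1)
  }
})

test_that("eccentricity spans circle to line with the moment closed form", {
  expect_lt(eccentricity(make_disc_mask(20)), 0.1)
  line <- matrix(FALSE, 3, 54); line[2, 3:52] <- TRUE
  expect_gte(eccentricity(line), 0.999)
  # discrete 2:1 rectangle: variance of 1..n is (n^2 - 1)/12
  rect <- make_rect_mask(100, 50)
  expect_equal(eccentricity(rect), sqrt(1 - (50^2 - 1) / (100^2 - 1)),
               tolerance = 1e-12)
  one <- matrix(FALSE, 3, 3); one[2, 2] <- TRUE
  expect_equal(eccentricity(one), 0)
})

test_that("center of mass Y averages row indices and tracks droop", {
  col10 <- matrix(FALSE, 12, 5); col10[1:10, 3] <- TRUE
  expect_equal(center_of_mass_y(col10), 5.5)
  one <- matrix(FALSE, 9, 9); one[7, 4] <- TRUE
  expect_equal(center_of_mass_y(one), 7)
  erect <- render_scene(plant_spec(stress = 0.3, droop = 0,
                                   canvas_height_px = 160L,
                                   canvas_width_px = 200L,
                                   leaf_length_px = 48, rng_seed = 3))
  wilted <- render_scene(plant_spec(stress = 0.3, droop = 1,
                                    canvas_height_px = 160L,
                                    canvas_width_px = 200L,
                                    leaf_length_px = 48, rng_seed = 3))
  expect_gt(center_of_mass_y(wilted$mask_truth),
            center_of_mass_y(erect$mask_truth))
  expect_gt(object_extent(wilted$mask_truth)["x_px"],
            object_extent(erect$mask_truth)["x_px"])
})

test_that("perimeter follows the marching-squares contour convention", {
  # hand-traced reference: an n x n square is four straight sides of
  # length (n - 1) plus four diagonal corner cuts of length sqrt(2)/2
  expect_equal(perimeter(make_rect_mask(10, 10)), 4 * 9 + 2 * sqrt(2),
               tolerance = 1e-12)
  one <- matrix(FALSE, 4, 4); one[2, 2] <- TRUE
  expect_equal(perimeter(one), 2 * sqrt(2), tolerance = 1e-12)
  # doubling the side ~doubles the perimeter
  ratio <- perimeter(make_rect_mask(20, 20)) / perimeter(make_rect_mask(10, 10))
  expect_equal(ratio, 2, tolerance = 0.05)
  # interior holes are not part of the outside boundary
  holed <- make_rect_mask(10, 10)
  holed[6:8, 6:8] <- FALSE
  expect_equal(perimeter(holed), perimeter(make_rect_mask(10, 10)))
})

test_that("hue histogram bins plant pixels on the 0-180 degree axis", {
  green <- uniform_rgb(c(0, 1, 0))
  mask <- matrix(TRUE, 8, 8)
  h <- hue_histogram(green, mask)
  expect_equal(sum(h), 64)
  expect_equal(which(as.numeric(h) > 0) - 1L, 120L) # pure green at 120 deg

  # 30% yellow (60 deg) / 70% green mixture, constructed exactly
  arr <- uniform_rgb(c(0, 1, 0), 10, 10)
  yellow_rows <- 1:3
  arr[yellow_rows, , 1] <- 1 # RGB (1,1,0) is hue 60
  h2 <- hue_histogram(arr, matrix(TRUE, 10, 10))
  expect_equal(sum(h2), 100)
  frac <- color_fractions(h2)
  expect_equal(unname(frac["yellow_fraction"]), 0.30)
  expect_equal(unname(frac["green_fraction"]), 0.70)
})

test_that("color fractions split at the 72/73 bin boundary and sum to one", {
  all_green <- numeric(181); all_green[121] <- 50
  expect_equal(unname(color_fractions(all_green)),
               c(1, 0)) # (green, yellow)
  at72 <- numeric(181); at72[73] <- 10 # bin 72 -> yellow region
  expect_equal(unname(color_fractions(at72)["yellow_fraction"]), 1)
  at73 <- numeric(181); at73[74] <- 10 # bin 73 -> green region
  expect_equal(unname(color_fractions(at73)["green_fraction"]), 1)
  set.seed(3)
  mix <- as.numeric(rmultinom(1, 500, rep(1 / 181, 181)))
  frac <- color_fractions(mix)
  expect_equal(sum(frac), 1)
  expect_error(color_fractions(numeric(181)), "empty")
})

test_that("growth rate is the area difference per day", {
  ser <- data.frame(day = c(4, 6, 8), area_px = c(10000, 14000, 12000))
  expect_equal(growth_rate(ser, 4, 6), 2000)
  expect_equal(growth_rate(ser, 6, 8), -1000) # shrinking while wilting
  expect_equal(growth_rate(data.frame(day = 1:2, area_px = c(5, 5)), 1, 2), 0)
  expect_error(growth_rate(ser, 6, 4), "earlier")
  expect_error(growth_rate(ser, 4, 7), "not present")
})

test_that("shape traits are translation invariant; center of mass shifts", {
  set.seed(41)
  inner <- random_mask(12, 12, 0.3)
  embed <- function(at) {
    m <- matrix(FALSE, 40, 40)
    m[at[1]:(at[1] + 11), at[2]:(at[2] + 11)] <- inner
    m
  }
  a <- embed(c(3, 3)); b <- embed(c(17, 9))
  expect_equal(projected_plant_area(a), projected_plant_area(b))
  expect_equal(object_extent(a), object_extent(b))
  expect_equal(convex_hull_area(a), convex_hull_area(b), tolerance = 1e-9)
  expect_equal(compactness(a), compactness(b), tolerance = 1e-9)
  expect_equal(eccentricity(a), eccentricity(b), tolerance = 1e-9)
  expect_equal(perimeter(a), perimeter(b), tolerance = 1e-9)
  expect_equal(center_of_mass_y(b) - center_of_mass_y(a), 14)
})
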