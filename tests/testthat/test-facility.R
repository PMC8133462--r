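# Voronoi service areas, overlap tagging, and phone-hour labelling.

test_that("a 2x2 tower grid in its bounding box gives four equal square cells", {
  towers <- data.frame(tower_id = paste0("T", 1:4), city = 1,
                       x = c(0.5, 1.5, 0.5, 1.5), y = c(0.5, 0.5, 1.5, 1.5))
  sa <- voronoi_service_areas(towers, region = list("1" = c(0, 0, 2, 2)))
  expect_equal(sa$areas$area, rep(1, 4), tolerance = 1e-12)
  # and an exact grid keeps interior cells equal-area under the default
  # padded region
  tw <- grid_towers(m = 5, extent = 1000)
  sa5 <- voronoi_service_areas(tw, region = list("1" = c(0, 0, 1000, 1000)))
  expect_equal(sa5$areas$area, rep(200^2, 25), tolerance = 1e-9)
})

test_that("Voronoi cells tile the bounding region and match a Monte-Carlo oracle", {
  set.seed(14)
  towers <- data.frame(tower_id = sprintf("T%02d", 1:16), city = 1,
                       x = runif(16, 0, 1000), y = runif(16, 0, 1000))
  region <- c(-50, -50, 1050, 1050)
  sa <- voronoi_service_areas(towers, region = list("1" = region))
  reg_area <- (region[3] - region[1]) * (region[4] - region[2])
  expect_equal(sum(sa$areas$area), reg_area, tolerance = 1e-9)
  # nearest-tower point-count oracle
  n <- 2e5
  px <- runif(n, region[1], region[3]); py <- runif(n, region[2], region[4])
  d2 <- outer(px, towers$x, "-")^2 + outer(py, towers$y, "-")^2
  counts <- tabulate(max.col(-d2, ties.method = "first"), 16)
  mc_area <- counts / n * reg_area
  p <- sa$areas$area / reg_area
  se <- sqrt(p * (1 - p) / n) * reg_area
  expect_true(all(abs(mc_area - sa$areas$area) <= 3.5 * se))
})

test_that("duplicate tower coordinates are rejected by name", {
  towers <- data.frame(tower_id = c("A", "B", "C", "D"), city = 1,
                       x = c(0, 1, 0, 2), y = c(0, 1, 0, 2))
  expect_error(voronoi_service_areas(towers), "A.*C|duplicate")
})

test_that("towers are tagged at the five-percent overlap threshold", {
  cell <- rect_poly <- cbind(c(0, 1000, 1000, 0), c(0, 0, 1000, 1000))
  sa <- structure(list(
    cells = list(T1 = cell),
    areas = data.frame(tower_id = "T1", city = 1, area = 1e6),
    regions = list("1" = c(0, 0, 1000, 1000))
  ), class = "service_areas")
  park <- function(w, h) list(id = "pk", city = 1, kind = "park",
                              poly = cbind(c(0, w, w, 0), c(0, 0, h, h)),
                              centroid = c(w / 2, h / 2))
  # 4% overlap: untagged
  t4 <- tag_towers(sa, list(park(200, 200)))
  expect_false(t4$is_park_tower)
  expect_equal(t4$park_overlap_frac, 0.04)
  # exactly 5%: tagged ("at least" is inclusive)
  t5 <- tag_towers(sa, list(park(200, 250)))
  expect_true(t5$is_park_tower)
  # full cover: tagged with fraction one; mall tag computed independently
  mall <- list(id = "ml", city = 1, kind = "mall",
               poly = cbind(c(0, 2000, 2000, 0), c(0, 0, 2000, 2000)),
               centroid = c(1000, 1000))
  tf <- tag_towers(sa, list(park(2000, 2000), mall))
  expect_equal(tf$park_overlap_frac, 1)
  expect_true(tf$is_park_tower)
  expect_true(tf$is_mall_tower)
  # raising the threshold never adds tags (monotonicity)
  set.seed(8)
  parks <- lapply(1:5, function(i) {
    x0 <- runif(1, 0, 900); y0 <- runif(1, 0, 900)
    list(id = paste0("p", i), city = 1, kind = "park",
         poly = cbind(c(x0, x0 + 100, x0 + 100, x0), c(y0, y0, y0 + 90, y0 + 90)),
         centroid = c(x0 + 50, y0 + 45))
  })
  tags_lo <- tag_towers(sa, parks, threshold = 0.01)
  tags_hi <- tag_towers(sa, parks, threshold = 0.03)
  expect_true(all(tags_hi$is_park_tower <= tags_lo$is_park_tower))
})

test_that("phone-hours are labelled h > p/m > o with strict thresholds", {
  tags <- data.frame(tower_id = c("PK", "ML", "OT"),
                     is_park_tower = c(TRUE, FALSE, FALSE),
                     is_mall_tower = c(FALSE, TRUE, FALSE))
  mk_dwell <- function(phone, tower, secs) {
    data.table::data.table(phone_id = phone, day = 1, hour = 10,
                           tower_id = tower, city = 1, x = 0, y = 0,
                           dwell = secs)
  }
  dwell <- data.table::rbindlist(list(
    mk_dwell("near_home", "PK", 3600),   # 120 m from home, full hour in park
    mk_dwell("parker", "PK", 2700),      # 45 min on park towers
    mk_dwell("parker", "OT", 900),
    mk_dwell("boundary", "PK", 2400),    # exactly 40 min: not enough
    mk_dwell("boundary", "OT", 1200),
    mk_dwell("both", "PK", 2500),        # park and mall both above threshold
    mk_dwell("both", "ML", 2600)
  ))
  placements <- data.frame(
    phone_id = c("near_home", "parker", "boundary", "both"),
    city = 1, day = 1, hour = 10, x = 0, y = 0,
    distance = c(120, 2000, 2000, 2000),
    distance_mid = c(150, 1950, 1950, 1950), censored_upper = FALSE,
    stringsAsFactors = FALSE
  )
  lab <- label_hours(placements, tags, dwell = dwell)
  got <- setNames(lab$label, lab$phone_id)
  expect_identical(got[["near_home"]], "h")  # home takes precedence
  expect_identical(got[["parker"]], "p")
  expect_identical(got[["boundary"]], "o")   # strictly more than 40 minutes
  expect_identical(got[["both"]], "p")       # default precedence p before m
  expect_equal(attr(lab, "label_conflicts"), 1)
  lab_m <- label_hours(placements, tags, dwell = dwell, precedence = c("m", "p"))
  expect_identical(setNames(lab_m$label, lab_m$phone_id)[["both"]], "m")
  # labels are exhaustive and exclusive
  expect_true(all(lab$label %in% c("h", "p", "m", "o")))
  expect_equal(nrow(lab), nrow(placements))
})

test_that("raising the home radius never shrinks the at-home count", {
  tp <- tiny_pipeline()
  l500 <- label_hours(tp$placements, tp$tags, home_radius = 500)
  l600 <- label_hours(tp$placements, tp$tags, home_radius = 600)
  expect_gte(sum(l600$label == "h"), sum(l500$label == "h"))
  expect_true(all(lengths(split(l500$label, l500$label)) > 0))
})

test_that("facility polygons survive a GeoJSON round trip", {
  tp <- tiny_pipeline()
  path <- tempfile(fileext = ".geojson")
  write_facilities_geojson(c(tp$world$parks, tp$world$malls), path)
  back <- read_facilities_geojson(path)
  expect_length(back, length(tp$world$parks) + length(tp$world$malls))
  expect_equal(back[[1]]$poly, unname(tp$world$parks[[1]]$poly))
  expect_identical(vapply(back, `[[`, "", "kind"),
                   vapply(c(tp$world$parks, tp$world$malls), `[[`, "", "kind"))
  # retagging from the round-tripped polygons gives identical tags
  t1 <- tag_towers(tp$sa, c(tp$world$parks, tp$world$malls))
  t2 <- tag_towers(tp$sa, back)
  expect_equal(t1, t2)
})
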