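# Sample-selection filters, dwell accounting, weighted positions, home
# inference, and distance binning.

test_that("sample-selection filters enforce both record count and time span", {
  mk <- function(phone, n, span_hours) {
    data.frame(phone_id = phone, tower_id = "T001",
               timestamp = seq(0, span_hours * 3600, length.out = n),
               event = "connect", stringsAsFactors = FALSE)
  }
  records <- rbind(mk("keep", 25, 100),  # both thresholds met
                   mk("few", 19, 120),   # too few records
                   mk("short", 30, 95))  # span under 96 h
  expect_identical(filter_users(records), "keep")
  expect_identical(filter_users(records[0, ]), character(0))
  # thresholds are configurable
  expect_setequal(filter_users(records, min_records = 10, min_span_hours = 90),
                  c("keep", "few", "short"))
})

test_that("dwell accounting splits, clips, renews on service, and merges", {
  win <- c(0, 3600)
  # split hour between two towers
  r <- phone_records("P1",
                     rec(0, "A", "connect"), rec(1800, "A", "disconnect"),
                     rec(1800, "B", "connect"))
  expect_equal(dwell_times(r, win), c(A = 1800, B = 1800))
  # single connect at start holds for the whole window
  r <- phone_records("P1", rec(0, "A", "connect"))
  expect_equal(dwell_times(r, win), c(A = 3600))
  # overlapping reconnect to the same tower merges durations
  r <- phone_records("P1", rec(0, "A", "connect"), rec(600, "A", "connect"),
                     rec(1200, "A", "disconnect"))
  expect_equal(dwell_times(r, win), c(A = 1200))
  # interval-union oracle on a random single-tower stream: total connected
  # time equals the union of [connect, next-event) intervals
  set.seed(42)
  for (i in 1:10) {
    ts <- sort(runif(8, 0, 3600))
    evs <- sample(c("connect", "connect", "disconnect"), 8, replace = TRUE)
    r <- do.call(phone_records, c(list("P1"),
                                  lapply(1:8, function(k) rec(ts[k], "A", evs[k]))))
    # oracle: walk a fine grid and mark instants where the last event at or
    # before that instant was a connect
    grid <- seq(0.05, 3600, by = 0.1)
    state <- vapply(grid, function(g) {
      prev <- which(ts <= g)
      length(prev) > 0 && evs[max(prev)] != "disconnect"
    }, logical(1))
    expect_lt(abs(sum(dwell_times(r, c(0, 3600))) - sum(state) * 0.1), 1.5)
  }
  # service events renew the current tower after a disconnect
  r <- phone_records("P1", rec(0, "A", "connect"), rec(600, "A", "disconnect"),
                     rec(1200, "A", "service"))
  expect_equal(dwell_times(r, win), c(A = 600 + 2400))
})

test_that("weighted positions are dwell-weighted tower averages", {
  towers <- data.frame(tower_id = c("A", "B", "C"), city = 1,
                       x = c(0, 100, 0), y = c(0, 0, 100))
  expect_equal(unname(weighted_position(c(A = 900), towers)), c(0, 0))
  expect_equal(unname(weighted_position(c(A = 5, B = 5), towers)), c(50, 0))
  # direct weighted-sum arithmetic: dwell 10/20/30 minutes
  pos <- weighted_position(c(A = 600, B = 1200, C = 1800), towers)
  expect_equal(unname(pos), c(100 * 1200 / 3600, 100 * 1800 / 3600),
               tolerance = 1e-12)
  # zero dwell is a no-fix signal
  expect_null(weighted_position(numeric(0), towers))
  # convex-hull and rescaling invariance, property-style
  set.seed(7)
  for (i in 1:20) {
    dw <- runif(3) * 1000
    names(dw) <- c("A", "B", "C")
    p1 <- weighted_position(dw, towers)
    expect_identical(p1, weighted_position(dw * 3.5, towers))
    expect_gte(min(p1), 0)          # hull of the three towers
    expect_lte(p1["x"] / 100 + p1["y"] / 100, 1 + 1e-12)
  }
})

test_that("home inference pools night dwell and flags phones without nights", {
  towers <- data.frame(tower_id = c("A", "B"), city = 1,
                       x = c(0, 1000), y = c(0, 0))
  # all nights on one tower -> home at that tower; equal pooled dwell over
  # two nights -> midpoint
  r <- rbind(
    phone_records("one", rec(0, "A", "connect"), rec(6 * 3600, "A", "disconnect")),
    phone_records("two", rec(0, "A", "connect"), rec(3 * 3600, "A", "disconnect"),
                  rec(86400, "B", "connect"), rec(86400 + 3 * 3600, "B", "disconnect")),
    phone_records("dayonly", rec(10 * 3600, "B", "connect"),
                  rec(11 * 3600, "B", "disconnect"))
  )
  hm <- infer_home(r, towers)
  expect_equal(hm$x[hm$phone_id == "one"], 0)
  expect_equal(hm$x[hm$phone_id == "two"], 500)
  expect_equal(hm$night_seconds[hm$phone_id == "two"], 6 * 3600)
  expect_identical(attr(hm, "no_home"), "dayonly")
  expect_false("dayonly" %in% hm$phone_id)
})

test_that("records naming an unknown tower fail loudly", {
  towers <- data.frame(tower_id = "A", city = 1, x = 0, y = 0)
  r <- phone_records("P1", rec(0, "ghost", "connect"))
  expect_error(infer_home(r, towers), "ghost")
})

test_that("distance binning follows the 501-interval midpoint scheme", {
  expect_equal(bin_distance(0), data.frame(distance_mid = 50, censored_upper = FALSE))
  expect_equal(bin_distance(150)$distance_mid, 150)   # interval (100, 200]
  expect_equal(bin_distance(100)$distance_mid, 50)    # boundary joins (0, 100]
  expect_equal(bin_distance(49950)$distance_mid, 49950)
  b <- bin_distance(60000)
  expect_equal(b$distance_mid, 50000)
  expect_true(b$censored_upper)
  expect_false(bin_distance(50000)$censored_upper)
  expect_error(bin_distance(-1), "negative")
  # idempotence on the finite bins
  set.seed(5)
  d <- runif(200, 0, 50000)
  mids <- bin_distance(d)$distance_mid
  expect_identical(bin_distance(mids)$distance_mid, mids)
  expect_true(all(mids %in% seq(50, 49950, by = 100)))
})

test_that("hourly placements respect hour windows and city assignment", {
  towers <- data.frame(tower_id = c("A", "B"), city = c(1, 2),
                       x = c(0, 5000), y = c(0, 0))
  # phone splits hour 10 (09:00-10:00) 40/20 minutes across cities ->
  # assigned to city 1; also needs a night for home inference
  r <- phone_records("P1",
                     rec(0, "A", "connect"), rec(6 * 3600, "A", "disconnect"),
                     rec(9 * 3600, "A", "connect"),
                     rec(9 * 3600 + 2400, "B", "connect"),
                     rec(10 * 3600, "B", "disconnect"))
  pl <- hourly_placements(r, towers, hours = 7:22)
  row <- pl[pl$hour == 10, ]
  expect_equal(row$city, 1)
  expect_equal(row$x, 5000 * (1200 / 3600))
  expect_equal(row$distance, row$x)  # home is at tower A
  # a phone with no records in an hour is absent from placements
  expect_false(11 %in% pl$hour[pl$phone_id == "P1" & pl$day == 1])
})
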