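# Voronoi service areas, park/mall tower tagging, and phone-hour labelling.

#' Voronoi service areas of towers
#'
#' Computes each tower's service area as its Voronoi cell clipped to a
#' bounding region, per city. Cells are built by successive half-plane
#' clipping of the region against the perpendicular bisectors to all other
#' towers in the city, so each cell is a convex polygon and the cells of a
#' city tile the region exactly.
#'
#' @param towers tower table (tower_id, city, x, y).
#' @param region optional named list city -> 4-vector c(xmin, ymin, xmax,
#'   ymax); default is the city's tower bounding box padded by one median
#'   nearest-neighbour tower spacing.
#' @return object of class `service_areas`: list with `cells` (named list of
#'   polygon matrices per tower_id), `areas` (data.frame tower_id, city,
#'   area) and `regions` (per-city bounding rectangles).
#' @export
voronoi_service_areas <- function(towers, region = NULL) {
  dup <- duplicated(towers[, c("x", "y")]) | duplicated(towers[, c("x", "y")], fromLast = TRUE)
  if (any(dup)) {
    stop("duplicate tower coordinates: ",
         paste(towers$tower_id[dup], collapse = ", "))
  }
  cells <- list()
  areas <- list()
  regions <- list()
  for (j in sort(unique(towers$city))) {
    tw <- towers[towers$city == j, ]
    n <- nrow(tw)
    if (n < 3) stop("need at least 3 towers per city (city ", j, ")")
    if (abs(signed_area(cbind(tw$x, tw$y)[1:3, ])) == 0 && n == 3) {
      stop("towers in city ", j, " are collinear")
    }
    reg <- if (!is.null(region)) region[[as.character(j)]] else NULL
    if (is.null(reg)) {
      d2 <- outer(tw$x, tw$x, "-")^2 + outer(tw$y, tw$y, "-")^2
      diag(d2) <- Inf
      pad <- stats::median(sqrt(apply(d2, 1, min)))
      reg <- c(min(tw$x) - pad, min(tw$y) - pad, max(tw$x) + pad, max(tw$y) + pad)
    }
    regions[[as.character(j)]] <- reg
    box <- rect_poly(reg[1], reg[2], reg[3], reg[4])
    for (i in seq_len(n)) {
      cell <- box
      xi <- tw$x[i]; yi <- tw$y[i]
      # clip by bisector half-planes, nearest neighbours first (they trim
      # the most, keeping intermediate polygons small)
      ord <- order((tw$x - xi)^2 + (tw$y - yi)^2)
      for (q in ord[-1]) {
        a <- tw$x[q] - xi
        b <- tw$y[q] - yi
        cc <- a * (xi + tw$x[q]) / 2 + b * (yi + tw$y[q]) / 2
        cell <- clip_halfplane(cell, a, b, cc)
        if (is.null(cell)) break
      }
      if (is.null(cell)) stop("degenerate Voronoi cell for tower ", tw$tower_id[i])
      cells[[tw$tower_id[i]]] <- cell
      areas[[tw$tower_id[i]]] <- data.frame(
        tower_id = tw$tower_id[i], city = j, area = polygon_area(cell),
        stringsAsFactors = FALSE
      )
    }
  }
  structure(
    list(cells = cells, areas = do.call(rbind, areas), regions = regions),
    class = "service_areas"
  )
}

#' Tag towers as park / mall towers by service-area overlap
#'
#' A tower is a park (mall) tower when the fraction of its Voronoi cell
#' covered by park (mall) polygons is at least `threshold` (default 5%).
#' The two kinds are tagged independently. Overlap areas are computed by
#' exact polygon clipping; facility polygons of one kind are assumed
#' disjoint (overlapping same-kind polygons would double-count).
#'
#' @param service_areas a [voronoi_service_areas()] result.
#' @param facilities facility list (from [gen_world()] or
#'   [read_facilities_geojson()]).
#' @param threshold minimum overlap fraction (default 0.05).
#' @return data.frame tower_id, city, park_overlap_frac, mall_overlap_frac,
#'   is_park_tower, is_mall_tower.
#' @export
tag_towers <- function(service_areas, facilities, threshold = 0.05) {
  ar <- service_areas$areas
  if (any(ar$area <= 0)) {
    stop("zero-area service cell for tower ",
         paste(ar$tower_id[ar$area <= 0], collapse = ", "))
  }
  kinds <- vapply(facilities, function(f) f$kind, character(1))
  frac_for <- function(kind) {
    facs <- facilities[kinds == kind]
    out <- numeric(nrow(ar))
    if (length(facs) == 0) return(out)
    fb <- t(vapply(facs, function(f) {
      c(min(f$poly[, 1]), min(f$poly[, 2]), max(f$poly[, 1]), max(f$poly[, 2]))
    }, numeric(4)))
    for (i in seq_len(nrow(ar))) {
      cell <- service_areas$cells[[ar$tower_id[i]]]
      cb <- c(min(cell[, 1]), min(cell[, 2]), max(cell[, 1]), max(cell[, 2]))
      hit <- which(fb[, 1] <= cb[3] & fb[, 3] >= cb[1] &
                     fb[, 2] <= cb[4] & fb[, 4] >= cb[2])
      ov <- 0
      for (q in hit) {
        inter <- clip_polygon_convex(facs[[q]]$poly, cell)
        if (!is.null(inter)) ov <- ov + polygon_area(inter)
      }
      out[i] <- ov / ar$area[i]
    }
    pmin(out, 1)
  }
  pf <- frac_for("park")
  mf <- frac_for("mall")
  data.frame(
    tower_id = ar$tower_id, city = ar$city,
    park_overlap_frac = pf, mall_overlap_frac = mf,
    is_park_tower = pf >= threshold, is_mall_tower = mf >= threshold,
    stringsAsFactors = FALSE
  )
}

#' Label phone-hours as home / park / mall / other
#'
#' Applies the location rules to each placement: (1) a phone whose raw
#' (unbinned) distance from home is below `home_radius` is at home; (2)
#' otherwise, a phone with strictly more than `facility_min` seconds of
#' within-hour dwell on park towers (union over towers) is at a park; (3)
#' likewise for mall towers; (4) otherwise "other". The facility rules use
#' the raw per-tower dwell from before hourly aggregation. Precedence among
#' p and m when both criteria are met is configurable; home always wins.
#'
#' @param placements output of [hourly_placements()] (its attached dwell
#'   table is used unless `dwell` is given).
#' @param tags tower tags from [tag_towers()].
#' @param dwell optional per-phone-hour per-tower dwell table.
#' @param home_radius at-home distance threshold, metres (strict `<`).
#' @param facility_min facility dwell threshold, seconds (strict `>`;
#'   default 2400 s = 40 min).
#' @param precedence order of p and m when both qualify.
#' @return `placements` with a `label` column in \{h, p, m, o\}; the number
#'   of p/m conflicts is attached as `attr(, "label_conflicts")`.
#' @export
label_hours <- function(placements, tags, dwell = attr(placements, "dwell"),
                        home_radius = 500, facility_min = 2400,
                        precedence = c("p", "m")) {
  if (is.null(dwell)) stop("per-tower dwell data are required for labelling")
  precedence <- match.arg(precedence, c("p", "m"), several.ok = TRUE)
  dt <- data.table::as.data.table(dwell)
  tg <- data.table::as.data.table(tags[, c("tower_id", "is_park_tower", "is_mall_tower")])
  dt <- tg[dt, on = "tower_id"]
  fac <- dt[, list(
    park_secs = sum(dwell[is_park_tower %in% TRUE]),
    mall_secs = sum(dwell[is_mall_tower %in% TRUE])
  ), by = c("phone_id", "day", "hour")]
  pl <- data.table::as.data.table(placements)
  pl <- fac[pl, on = c("phone_id", "day", "hour")]
  pl[is.na(park_secs), park_secs := 0]
  pl[is.na(mall_secs), mall_secs := 0]
  at_p <- pl$park_secs > facility_min
  at_m <- pl$mall_secs > facility_min
  lab <- rep("o", nrow(pl))
  first <- precedence[1]
  if (first == "p") {
    lab[at_m] <- "m"; lab[at_p] <- "p"
  } else {
    lab[at_p] <- "p"; lab[at_m] <- "m"
  }
  lab[pl$distance < home_radius] <- "h"
  out <- as.data.frame(pl[, c("phone_id", "city", "day", "hour", "x", "y",
                              "distance", "distance_mid", "censored_upper")])
  out$label <- lab
  attr(out, "label_conflicts") <- sum(at_p & at_m & pl$distance >= home_radius)
  attr(out, "dwell") <- dwell
  out
}
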