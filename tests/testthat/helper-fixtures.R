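# Shared fixtures, built in code at test time.

# A small but fully featured world: 2 cities, 4 days, default hours.
tiny_config <- function(...) {
  world_config(n_cities = 2, n_days = 4, n_users_per_city = 250,
               towers_per_city = 25, n_parks = 2, n_malls = 2,
               seed = 99, ...)
}

# World -> labelled panel, cached per session to keep the suite fast.
tiny_pipeline <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- tiny_config()
    world <- gen_world(cfg)
    aqi <- gen_aqi(cfg, "wave")
    choices <- gen_choices(world, aqi, seed = 7)
    records <- gen_logs(choices, world, log_noise(), seed = 8)
    placements <- hourly_placements(records, world$towers)
    sa <- voronoi_service_areas(world$towers)
    tags <- tag_towers(sa, c(world$parks, world$malls))
    labeled <- label_hours(placements, tags)
    panel <- build_panel(labeled, aqi)
    cache <<- list(config = cfg, world = world, aqi = aqi, choices = choices,
                   records = records, placements = placements, sa = sa,
                   tags = tags, labeled = labeled, panel = panel)
    cache
  }
})

# Zero out every systematic component of a truth object (uniform shares).
flatten_truth <- function(truth) {
  truth$gamma[] <- 0
  truth$delta[] <- 0
  truth$eta[] <- 0
  truth$beta_level[] <- 0
  truth$beta_aqi[] <- 0
  truth$beta_t[] <- 0
  truth$beta_t2[] <- 0
  truth
}

# Hand-built record stream for one phone (timestamps in seconds).
phone_records <- function(phone = "P1", ...) {
  ev <- list(...)
  data.frame(
    phone_id = phone,
    tower_id = vapply(ev, `[[`, "", 2),
    timestamp = as.numeric(vapply(ev, `[[`, "", 1)),
    event = vapply(ev, `[[`, "", 3),
    stringsAsFactors = FALSE
  )
}

rec <- function(t, tower, event = "connect") c(as.character(t), tower, event)

# Simple square-grid tower table centred in [0, extent]^2.
grid_towers <- function(m = 5, extent = 1000, city = 1) {
  s <- extent / m
  g <- expand.grid(ix = seq_len(m), iy = seq_len(m))
  data.frame(
    tower_id = sprintf("T%03d", seq_len(nrow(g))),
    city = city,
    x = (g$ix - 0.5) * s,
    y = (g$iy - 0.5) * s,
    stringsAsFactors = FALSE
  )
}
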