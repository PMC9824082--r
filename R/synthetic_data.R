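# Synthetic low-resolution thermal scene simulator.
#
# Emulates the statistical structure of the study datasets: 8x8 frames at
# 10 fps, record durations 2-28 s, ambient background drifting 18->21 degC
# across a session, one or two warm moving subjects rendered as
# anisotropic Gaussian temperature bumps, three sensor viewpoints (two
# side, one front), small/large layouts (the large layout shrinks the
# apparent blob), sensor quantization, and injectable horizontal/vertical
# periodic noise in the map domain. Activity scripts are minimal kinematic
# sketches whose only contract is class separability and a plausible
# ordering of motion energy; they are not biomechanical models.
#
# Scene coordinates: unit square ground plane, x = left-right as seen from
# the front sensor, y = depth toward the front sensor, z = height in [0,1].
# Sensor S1 (side, left) images y horizontally and z vertically with depth
# x; S2 (front) images x and z with depth y; S3 (side, right) mirrors S1.

#' Scene configuration for the simulator
#'
#' @param layout `"small"` (sensors 1.5 m from the activity area) or
#'   `"large"` (2.5 m; apparent blob size and amplitude shrink).
#' @param ambient_start,ambient_end ambient temperature (degC) at the
#'   start and end of a simulated session; drift is linear in between.
#' @param blob_dt peak subject temperature above ambient (degC).
#' @param fps frames per second (default 10).
#' @param duration_range record duration bounds in seconds (uniform draw).
#' @param pixel_noise_sd per-pixel Gaussian noise sd (degC).
#' @param quant sensor quantization step (degC, default 0.25).
#' @param sensors sensor channels to render.
#' @param temp_band plausibility clamp for rendered temperatures.
#' @return an object of class `scene_config`.
#' @export
scene_config <- function(layout = "large", ambient_start = 18, ambient_end = 21,
                         blob_dt = 10, fps = 10, duration_range = c(2, 28),
                         pixel_noise_sd = 0.1, quant = 0.25,
                         sensors = c("S1", "S2", "S3"),
                         temp_band = c(0, 60)) {
  stopifnot(fps > 0, duration_range[1] >= 2, duration_range[2] <= 28,
            duration_range[1] < duration_range[2])
  structure(list(layout = layout, ambient_start = ambient_start,
                 ambient_end = ambient_end, blob_dt = blob_dt, fps = fps,
                 duration_range = duration_range,
                 pixel_noise_sd = pixel_noise_sd, quant = quant,
                 sensors = sensors, temp_band = temp_band),
            class = "scene_config")
}

# Subject body parameters: diverse sizes and paces across participants.
subject_params <- function(id) {
  i <- ((id - 1) %% 9)
  list(size = c(0.90, 1.00, 1.15)[i %% 3 + 1],
       speed = c(1.10, 1.00, 0.90)[i %% 3 + 1],
       warmth = c(0.0, 0.6, -0.4)[(i %/% 3) %% 3 + 1])
}

## ---- Activity scripts --------------------------------------------------
# Each script maps normalized time tau in [0,1] (plus the record duration
# in seconds) to a list of subject states: (x, y, z, height) in scene
# coordinates. Postural transitions (sit, stand, fall) are timed within
# the record via tau; locomotion advances at natural walking pace in
# wall-clock time (one crossing of the scene takes about 5 s, turning
# around at the ends), so a long record holds several crossings rather
# than one slowed-down crossing. `sp` is the per-subject parameters.

# continuous walking at natural pace: position in [0, 1], one crossing per
# `cross` seconds, turning around at the ends for as long as the record
# lasts; t in seconds.
walk_path <- function(t, speed = 1, cross = 5) {
  ph <- (t * speed / (2 * cross)) %% 1
  ifelse(ph < 0.5, 2 * ph, 2 - 2 * ph)
}

# sustained oscillation (stepping side to side / fore and aft); t in seconds.
sway_path <- function(t, speed = 1, period = 5) {
  ph <- (t * speed / period) %% 1
  ifelse(ph < 0.5, 2 * ph, 2 - 2 * ph)
}

single_scripts <- function() list(
  A1 = function(tau, sp, dur) list(list(x = .5, y = .5,                  # Sit-Down
                                   z = .72 - .3 * pmin(1, pmax(0, (tau - .3) / .4)),
                                   height = .45 - .12 * pmin(1, pmax(0, (tau - .3) / .4)))),
  A2 = function(tau, sp, dur) list(list(x = .5, y = .5, z = .72, height = .45)),  # Stand-Still
  A3 = function(tau, sp, dur) {                                          # Sit-Down & Stand-Up
    u <- 1 - abs(2 * pmin(1, pmax(0, (tau - .15) / .7)) - 1)
    list(list(x = .5, y = .5, z = .72 - .3 * u, height = .45 - .12 * u))
  },
  A4 = function(tau, sp, dur) list(list(x = .5, y = .5,                  # Stand-Up
                                   z = .42 + .3 * pmin(1, pmax(0, (tau - .3) / .4)),
                                   height = .33 + .12 * pmin(1, pmax(0, (tau - .3) / .4)))),
  A5 = function(tau, sp, dur) list(list(                                 # Left & Right Move
    x = .2 + .6 * sway_path(tau * dur, sp$speed, period = 5),
    y = .5, z = .72, height = .45)),
  A6 = function(tau, sp, dur) list(list(x = .5,                          # For-backward Move
    y = .2 + .6 * sway_path(tau * dur, sp$speed, period = 5),
    z = .72, height = .45)),
  A7 = function(tau, sp, dur) {                                          # Walking-Diagonally 1
    p <- .1 + .8 * walk_path(tau * dur, sp$speed)
    list(list(x = p, y = p, z = .72, height = .45))
  },
  A8 = function(tau, sp, dur) {                                          # Walking-Diagonally 2
    p <- .1 + .8 * walk_path(tau * dur, sp$speed)
    list(list(x = 1 - p, y = p, z = .72, height = .45))
  }
)

double_scripts <- function() list(
  B1 = function(tau, sp, dur) list(list(x = .3, y = .4, z = .42, height = .3),   # Both Sitting
                              list(x = .7, y = .6, z = .42, height = .3)),
  B2 = function(tau, sp, dur) list(list(x = .3, y = .4, z = .42, height = .3),   # Sitting & Moving
                              list(x = .55 + .35 * sway_path(tau * dur, sp$speed, period = 6),
                                   y = .5 + .25 * sin(2 * pi * tau * dur / 7),
                                   z = .72, height = .45)),
  B3 = function(tau, sp, dur) list(list(x = .3, y = .4, z = .42, height = .3),   # Sitting & Standing
                              list(x = .7, y = .6, z = .72, height = .45)),
  B4 = function(tau, sp, dur) {                                                  # Random Moving
    t <- tau * dur
    list(list(x = .35 + .18 * sin(2 * pi * (t / 4.3 + sp$phase1)),
              y = .5 + .2 * cos(2 * pi * (t / 5.7 + sp$phase1)), z = .72, height = .45),
         list(x = .65 + .18 * cos(2 * pi * (t / 4.9 + sp$phase2)),
              y = .5 + .2 * sin(2 * pi * (t / 3.6 + sp$phase2)), z = .72, height = .45))
  },
  B5 = function(tau, sp, dur) list(list(x = .35, y = .4, z = .72, height = .45), # Both Standing
                              list(x = .65, y = .6, z = .72, height = .45)),
  B6 = function(tau, sp, dur) list(list(x = .3, y = .4, z = .72, height = .45),  # Standing & Moving
                              list(x = .55 + .3 * sway_path(tau * dur, sp$speed, period = 6),
                                   y = .5 + .25 * cos(2 * pi * tau * dur / 6),
                                   z = .72, height = .45)),
  B7 = function(tau, sp, dur) {                                                  # Walking Across
    p <- .08 + .84 * walk_path(tau * dur, sp$speed)
    list(list(x = p, y = .35, z = .72, height = .45),
         list(x = 1 - p, y = .65, z = .72, height = .45))
  }
)

# Nine single-subject activities of the second (single-layout) design.
infra_scripts <- function() list(
  I1 = function(tau, sp, dur) list(list(                                 # Walking LR
    x = .1 + .8 * walk_path(tau * dur, sp$speed), y = .5, z = .72, height = .45)),
  I2 = function(tau, sp, dur) list(list(                                 # Walking RL
    x = .9 - .8 * walk_path(tau * dur, sp$speed), y = .5, z = .72, height = .45)),
  I3 = function(tau, sp, dur) list(list(x = .5,                          # Walking Away
    y = .1 + .8 * walk_path(tau * dur, sp$speed), z = .72, height = .45)),
  I4 = function(tau, sp, dur) list(list(x = .5,                          # Walking Toward
    y = .9 - .8 * walk_path(tau * dur, sp$speed), z = .72, height = .45)),
  I5 = function(tau, sp, dur) {                                          # Falling
    u <- pmin(1, pmax(0, (tau - .4) / .15))
    list(list(x = .5 + .1 * u, y = .5, z = .72 - .55 * u, height = .45 - .3 * u))
  },
  I6 = function(tau, sp, dur) list(list(x = .5, y = .5,                  # Stand to Sit
                                   z = .72 - .3 * pmin(1, pmax(0, (tau - .3) / .4)),
                                   height = .45 - .12 * pmin(1, pmax(0, (tau - .3) / .4)))),
  I7 = function(tau, sp, dur) list(list(x = .5, y = .5,                  # Sit to Stand
                                   z = .42 + .3 * pmin(1, pmax(0, (tau - .3) / .4)),
                                   height = .33 + .12 * pmin(1, pmax(0, (tau - .3) / .4)))),
  I8 = function(tau, sp, dur) list(list(x = .5, y = .5, z = .42, height = .3)),  # Sitting Still
  I9 = function(tau, sp, dur) list(list(x = .5, y = .5, z = .72, height = .45))  # Standing Still
)

activity_script <- function(code) {
  base <- sub("^A[SL]", "A", code)
  s <- c(single_scripts(), double_scripts(), infra_scripts())[[base]]
  if (is.null(s)) stop("unknown activity code '", code, "'")
  s
}

## ---- Rendering ---------------------------------------------------------

# Project a subject state into (col, row, depth) image coordinates for a
# sensor; u, v in [0,1], v measured upward.
project_state <- function(state, sensor) {
  switch(sensor,
         S1 = list(u = state$y, v = state$z, depth = state$x),
         S2 = list(u = state$x, v = state$z, depth = state$y),
         S3 = list(u = 1 - state$y, v = state$z, depth = 1 - state$x),
         stop("unknown sensor ", sensor))
}

# Render one 8x8 frame (returned vectorized, row-major pixel order).
# At the larger sensor distance (2.5 m vs 1.5 m) the field of view widens,
# so the subject's apparent size and apparent excursion shrink toward the
# image center, and each pixel averages the warm body over a larger ground
# patch: the measured temperature bump scales with the solid-angle
# fraction, about (1.5/2.5)^2 = 0.36.
render_frame <- function(states, sps, sensor, scene, ambient) {
  # Perspective: the activity area is ~1.5 m deep; the sensor sits 1.5 m
  # (small layout) or 2.5 m (large) from its center, so the subject is at
  # dist = sensor_dist - 0.75 + 1.5*depth metres. Apparent body size
  # scales with 1/dist, the measured temperature bump with the solid-angle
  # fraction (1.5/dist)^2 (capped: a pixel fully covered by the body reads
  # body temperature, no more). The wider field of view at distance also
  # compresses apparent positions toward the image center.
  sensor_dist <- if (scene$layout == "large") 2.5 else 1.5
  fov <- if (scene$layout == "large") 0.51 else 0.85
  gx <- (seq_len(8) - 0.5) / 8   # column centers
  gz <- (seq_len(8) - 0.5) / 8   # row centers, top row = high v
  img <- matrix(ambient, 8, 8)
  for (s in seq_along(states)) {
    st <- states[[s]]; sp <- sps[[s]]
    pr <- project_state(st, sensor)
    dist <- sensor_dist - 0.75 + 1.5 * pr$depth
    app <- 1.5 / dist              # apparent-size factor
    u <- 0.5 + (pr$u - 0.5) * fov
    v <- 0.5 + (pr$v - 0.5) * fov
    amp <- (scene$blob_dt + sp$warmth) * min(app^2, 1.3)
    sig_u <- 0.15 * sp$size * app
    sig_v <- st$height * 1.2 * app
    du <- gx - u
    dv <- (1 - gz) - (v - st$height * 0.2)  # blob centered below head height
    img <- img + amp * exp(-outer(dv^2 / (2 * sig_v^2), du^2 / (2 * sig_u^2), "+"))
  }
  img <- img + matrix(stats::rnorm(64, sd = scene$pixel_noise_sd), 8, 8)
  img <- round(img / scene$quant) * scene$quant
  pmin(pmax(img, scene$temp_band[1]), scene$temp_band[2])
}

#' Simulate one activity record
#'
#' Draws a duration from the configured range, runs the activity's
#' kinematic script, and renders per-sensor 8x8 frame streams with ambient
#' drift, pixel noise and quantization. Deterministic given `seed`.
#'
#' @param activity activity code (AS1-8, AL1-8, B1-7 or I1-9).
#' @param scene a [scene_config()]; its `layout` is overridden by the
#'   AS/AL prefix when present.
#' @param subjects participant id(s); one id for single-subject codes, two
#'   for B codes.
#' @param seed RNG seed for this record.
#' @param session_frac position of the record within the session in [0,1];
#'   controls the ambient drift.
#' @return an [activity_record()].
#' @export
simulate_record <- function(activity, scene = scene_config(), subjects = 1L,
                            seed = 1L, session_frac = 0.5) {
  script <- activity_script(activity)
  if (grepl("^AS", activity)) scene$layout <- "small"
  if (grepl("^AL", activity)) scene$layout <- "large"
  n_subj <- if (grepl("^B", activity)) 2L else 1L
  if (length(subjects) != n_subj)
    stop("activity ", activity, " needs ", n_subj, " subject id(s)")
  with_seed(seed, {
    duration <- stats::runif(1, scene$duration_range[1], scene$duration_range[2])
    n <- max(2L, as.integer(round(duration * scene$fps)))
    ts <- (seq_len(n) - 1L) / scene$fps
    sps <- lapply(subjects, subject_params)
    # random script phases (used by B4) shared by all sensors
    ph1 <- stats::runif(1); ph2 <- stats::runif(1)
    for (s in seq_along(sps)) { sps[[s]]$phase1 <- ph1; sps[[s]]$phase2 <- ph2 }
    ambient0 <- scene$ambient_start +
      (scene$ambient_end - scene$ambient_start) * session_frac
    streams <- lapply(scene$sensors, function(sensor) {
      px <- matrix(0, n, 64)
      for (t in seq_len(n)) {
        tau <- (t - 1) / max(1, n - 1)
        states <- script(tau, sps[[1]], duration)
        if (n_subj == 2L) {
          s2 <- script(tau, sps[[2]], duration)
          states <- list(states[[1]], s2[[2]])
        }
        ambient <- ambient0 + 0.2 * tau  # slight within-record drift
        px[t, ] <- frame_to_vector(render_frame(states, sps, sensor, scene, ambient))
      }
      frame_stream(px, ts, sensor_id = sensor, fps = scene$fps,
                   temp_band = scene$temp_band)
    })
    names(streams) <- scene$sensors
    activity_record(streams, label = activity, subjects = subjects,
                    layout = scene$layout, n_subjects = n_subj)
  })
}

#' Build a full synthetic dataset with the two-layout study design
#'
#' Enumerates 3 participants x 8 single-subject activities x 10 repeats in
#' each of the small and large layouts (labels AS1-8 and AL1-8; 480
#' records), plus 3 participant pairs x 7 double-subject activities x 10
#' repeats in the large layout (labels B1-7; 210 records). The ambient
#' temperature drifts linearly across the enumeration order (small layout
#' first), emulating the 18->21 degC session rise.
#'
#' @param scene a [scene_config()].
#' @param seed base seed; every record derives its own child seed.
#' @param layouts which layouts to generate (default both).
#' @param include_double include the double-subject block (default TRUE).
#' @param sensors sensor channels to render (defaults to the scene's).
#' @param subjects participant ids (default 1:3).
#' @param repeats repeats per (subject, activity, layout) cell (default 10).
#' @return list of [activity_record()] objects.
#' @export
build_coventry_like <- function(scene = scene_config(), seed = 1L,
                                layouts = c("small", "large"),
                                include_double = TRUE,
                                sensors = scene$sensors,
                                subjects = 1:3, repeats = 10L) {
  scene$sensors <- sensors
  records <- list()
  counter <- 0L
  total <- length(layouts) * length(subjects) * 8L * repeats +
    if (include_double) 3L * 7L * repeats else 0L
  for (layout in layouts) {
    prefix <- if (layout == "small") "AS" else "AL"
    sc <- scene; sc$layout <- layout
    for (subj in subjects) for (a in 1:8) for (rep in seq_len(repeats)) {
      counter <- counter + 1L
      records[[counter]] <- simulate_record(
        paste0(prefix, a), sc, subjects = subj,
        seed = derive_seed(seed, counter),
        session_frac = counter / total)
    }
  }
  if (include_double) {
    pairs <- utils::combn(subjects[seq_len(min(3, length(subjects)))], 2)
    sc <- scene; sc$layout <- "large"
    for (p in seq_len(ncol(pairs))) for (a in 1:7) for (rep in seq_len(repeats)) {
      counter <- counter + 1L
      records[[counter]] <- simulate_record(
        paste0("B", a), sc, subjects = pairs[, p],
        seed = derive_seed(seed, counter),
        session_frac = counter / total)
    }
  }
  records
}

#' Build a synthetic dataset with the single-layout, nine-participant design
#'
#' Enumerates 9 participants x 9 single-subject activities (labels I1-9) x
#' `repeats` repeats (default 3), 243 records in all, in one layout.
#'
#' @param scene a [scene_config()] (layout `"small"` by default here: the
#'   design used a single close-range layout).
#' @param seed base seed.
#' @param subjects participant ids (default 1:9).
#' @param repeats repeats per cell (default 3).
#' @return list of [activity_record()] objects.
#' @export
build_infra_adl_like <- function(scene = scene_config(layout = "small"),
                                 seed = 1L, subjects = 1:9, repeats = 3L) {
  records <- list()
  counter <- 0L
  total <- length(subjects) * 9L * repeats
  for (subj in subjects) for (a in 1:9) for (rep in seq_len(repeats)) {
    counter <- counter + 1L
    records[[counter]] <- simulate_record(
      paste0("I", a), scene, subjects = subj,
      seed = derive_seed(seed, 100000L + counter),
      session_frac = counter / total)
  }
  records
}

## ---- Periodic-noise injection ------------------------------------------

#' Periodic-noise injection specification
#'
#' Describes additive sinusoidal stripe noise in the map domain. Vertical
#' stripes vary along the 64-pixel axis (frequencies 1..31 cycles over the
#' axis; they surface on the central horizontal stripe of the shifted
#' power spectrum); horizontal stripes vary along the 40-frame time axis
#' (frequencies 1..19, surfacing on the central vertical stripe).
#'
#' @param direction `"vertical"`, `"horizontal"` or `"both"`.
#' @param freq_v,amp_v integer frequencies and amplitudes (degC) of the
#'   vertical stripe components.
#' @param freq_h,amp_h frequencies and amplitudes of the horizontal
#'   components.
#' @return an object of class `noise_injection`.
#' @export
noise_injection <- function(direction = c("vertical", "horizontal", "both"),
                            freq_v = integer(0), amp_v = numeric(0),
                            freq_h = integer(0), amp_h = numeric(0)) {
  direction <- match.arg(direction)
  if (direction %in% c("vertical", "both")) {
    if (length(freq_v) == 0) stop("vertical injection needs freq_v")
    if (any(freq_v != round(freq_v)) || any(freq_v < 1) || any(freq_v > 31))
      stop("vertical frequencies must be integers in 1..31 (central-stripe bins)")
  } else freq_v <- integer(0)
  if (direction %in% c("horizontal", "both")) {
    if (length(freq_h) == 0) stop("horizontal injection needs freq_h")
    if (any(freq_h != round(freq_h)) || any(freq_h < 1) || any(freq_h > 19))
      stop("horizontal frequencies must be integers in 1..19 (central-stripe bins)")
  } else freq_h <- integer(0)
  stopifnot(length(amp_v) == length(freq_v), length(amp_h) == length(freq_h))
  structure(list(direction = direction, freq_v = as.integer(freq_v),
                 amp_v = amp_v, freq_h = as.integer(freq_h), amp_h = amp_h),
            class = "noise_injection")
}

#' Canonical noise injection used for the simulator's noisy datasets
#'
#' `default_noise_injection()` is a fixed two-direction injection
#' (vertical components at 8 and 16 cycles at 2.0 and 1.5 degC, one
#' horizontal component at 5 cycles at 1.2 degC), useful when a
#' deterministic spectral footprint is wanted.
#'
#' `sample_noise_injection()` draws the per-record footprint of the
#' stripe-noise phenomenon: which pixels stay unchanged (vertical
#' stripes) and which frames repeat (horizontal stripes) differ from
#' record to record, so each record receives 2-3 vertical components
#' (frequencies 3..28) and 1-2 horizontal components (frequencies 2..17)
#' with amplitudes uniform in 1.0-2.5 degC. This is the default noisy
#' condition of [inject_dataset_noise()].
#'
#' @param seed RNG seed for the draw.
#' @return a [noise_injection()].
#' @export
default_noise_injection <- function() {
  noise_injection("both", freq_v = c(8L, 16L), amp_v = c(2.0, 1.5),
                  freq_h = 5L, amp_h = 1.2)
}

#' @rdname default_noise_injection
#' @export
sample_noise_injection <- function(seed = 1L) {
  with_seed(seed, {
    nv <- sample(2:3, 1)
    nh <- sample(1:2, 1)
    noise_injection("both",
                    freq_v = sample(3:28, nv),
                    amp_v = stats::runif(nv, 1.0, 2.5),
                    freq_h = sample(2:17, nh),
                    amp_h = stats::runif(nh, 1.0, 2.5))
  })
}

#' Inject periodic stripe noise into a spatiotemporal map
#'
#' Adds the configured sinusoidal stripe components with random phases.
#' The clean input is retained as attribute `"clean"` for oracle
#' comparisons.
#'
#' @param map an [st_map()] or 40x64 matrix.
#' @param spec a [noise_injection()].
#' @param seed RNG seed for the phases.
#' @return the noisy map with attribute `"clean"`.
#' @export
inject_periodic_noise <- function(map, spec, seed = 1L) {
  m <- unclass(as.matrix(map))
  M <- nrow(m); N <- ncol(m)
  clean <- m
  with_seed(seed, {
    for (i in seq_along(spec$freq_v)) {
      phi <- stats::runif(1, 0, 2 * pi)
      stripe <- spec$amp_v[i] * cos(2 * pi * spec$freq_v[i] * (0:(N - 1)) / N + phi)
      m <- m + matrix(stripe, M, N, byrow = TRUE)
    }
    for (i in seq_along(spec$freq_h)) {
      phi <- stats::runif(1, 0, 2 * pi)
      stripe <- spec$amp_h[i] * cos(2 * pi * spec$freq_h[i] * (0:(M - 1)) / M + phi)
      m <- m + matrix(stripe, M, N)
    }
  })
  out <- if (inherits(map, "st_map"))
    st_map(m, label = attr(map, "label"), subjects = attr(map, "subjects"),
           layout = attr(map, "layout"), sensor_id = attr(map, "sensor_id"))
  else m
  attr(out, "clean") <- clean
  out
}

#' Inject periodic noise into every map of a dataset tensor
#'
#' With a fixed [noise_injection()] every map receives the same components
#' with its own random phases; with the default `spec = NULL` each map
#' receives its own draw from [sample_noise_injection()], emulating stripe
#' noise whose frequency content varies from record to record. The clean
#' maps are retained as attribute `"clean_maps"` of the result.
#'
#' @param data a [dataset_tensor()].
#' @param spec a [noise_injection()], or `NULL` for per-record draws.
#' @param seed base seed; per-map phases (and draws) derive from it.
#' @return a noisy [dataset_tensor()] with attribute `"clean_maps"`.
#' @export
inject_dataset_noise <- function(data, spec = NULL, seed = 1L) {
  clean <- data$maps
  out <- data$maps
  for (i in seq_len(n_samples(data))) {
    spec_i <- spec %||% sample_noise_injection(derive_seed(seed, 7000L + i))
    out[i, , ] <- inject_periodic_noise(data$maps[i, , ], spec_i,
                                        seed = derive_seed(seed, i))
  }
  res <- dataset_tensor(out, data$labels, subjects = data$subjects,
                        layout = data$layout, sensor_id = data$sensor_id)
  attr(res, "clean_maps") <- clean
  res
}
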