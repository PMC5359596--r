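#' Simulation parameters for the imaging protocol
#'
#' Bundles the rendering-level settings of the synthetic imaging protocol:
#' frame geometry, optical background, drive calibration, bleaching between
#' passages, the rigid stage repositioning error exercised by registration,
#' and the cell population drawn per sampling area. Defaults emulate a 16-bit
#' EM-CCD-like camera imaging bright membrane-stained cells at ~3.5% peak
#' dF/F.
#'
#' @param frame_dim Frame size `(rows, cols)` in pixels.
#' @param background Optical background in counts.
#' @param k Drive calibration constant passed to [induced_delta_v()] (mV of
#'   plateau polarization at the cell pole per unit drive).
#' @param bleach_fraction Fractional fluorescence loss between the reference
#'   and test passages (multiplicative on all test-passage counts); must lie
#'   in `[0, 0.5)`.
#' @param shift_max Maximum rigid integer translation (pixels, per axis)
#'   between passages; each area draws its shift uniformly from
#'   `-shift_max:shift_max`.
#' @param v_rest_offset Uniform resting-potential offset (mV) applied to the
#'   test passage (e.g. a drug-induced resting depolarization); exercises the
#'   method's robustness to resting-potential changes.
#' @param noise Logical; apply camera noise. `FALSE` renders exact
#'   expectations (closed-form frames).
#' @param n_cells Cells drawn per sampling area.
#' @param radius_range Cell radius range (pixels), sampled uniformly.
#' @param ring_width,f_rest,dye_sens,tau_m,interior_frac Cell model defaults,
#'   see [cell_model()].
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(frame_dim = c(160, 160), background = 800, k = 35,
                       bleach_fraction = 0.03, shift_max = 3,
                       v_rest_offset = 0, noise = TRUE, n_cells = 5,
                       radius_range = c(20, 26), ring_width = 3.5,
                       f_rest = 40000, dye_sens = -0.001, tau_m = 5,
                       interior_frac = 0.25) {
  if (bleach_fraction < 0 || bleach_fraction >= 0.5) {
    abort("`bleach_fraction` must lie in [0, 0.5)")
  }
  if (shift_max < 0) abort("`shift_max` must be >= 0")
  structure(
    list(frame_dim = as.integer(frame_dim), background = background, k = k,
         bleach_fraction = bleach_fraction, shift_max = as.integer(shift_max),
         v_rest_offset = v_rest_offset, noise = isTRUE(noise),
         n_cells = as.integer(n_cells), radius_range = radius_range,
         ring_width = ring_width, f_rest = f_rest, dye_sens = dye_sens,
         tau_m = tau_m, interior_frac = interior_frac),
    class = "sim_params"
  )
}

apply_camera_noise <- function(expectation, camera) {
  x <- expectation
  if (camera$shot_noise) {
    x[] <- rpois(length(x), lambda = pmax(x, 0))
  }
  if (camera$read_noise_sd > 0) {
    x <- x + rnorm(length(x), 0, camera$read_noise_sd)
  }
  x <- round(x)
  pmin(pmax(x, 0), 2^camera$bit_depth - 1)
}

#' Render one fluorescence frame
#'
#' Renders the expected image of a set of membrane-stained cells - membrane
#' annuli over a dim interior on a flat optical background - and optionally
#' applies camera noise. Membrane-ring pixels are scaled by
#' `1 + dye_sens * dV`, where the local potential change `dV` is supplied by
#' `dv_fun(cell, cos_theta)` (`cos_theta` = cosine of the angle between the
#' pixel's outward membrane normal and the field direction). With
#' `dv_fun = NULL` the resting frame is rendered. Overlapping cells sum their
#' fluorescence with a warning. Deterministic given `seed`.
#'
#' @param cells A [cell_model()] or list of them; every cell must fit inside
#'   the frame.
#' @param field A [field_geometry()].
#' @param camera A [camera_model()].
#' @param dim Frame size `(rows, cols)`.
#' @param background Background counts.
#' @param dv_fun `NULL`, or `function(cell, cos_theta)` returning the local
#'   membrane potential change in mV per membrane pixel.
#' @param gain Global multiplicative illumination/gain factor applied to the
#'   expected counts (before noise); used for inter-passage bleaching.
#' @param noise Logical; apply camera noise.
#' @param seed Optional integer seed for the noise draw (RNG state is
#'   restored afterwards).
#' @return A numeric matrix of counts (integer-valued when `noise = TRUE`).
#' @export
render_frame <- function(cells, field = field_geometry(),
                         camera = camera_model(), dim = c(160, 160),
                         background = 800, dv_fun = NULL, gain = 1,
                         noise = TRUE, seed = NULL) {
  if (inherits(cells, "cell_model")) cells <- list(cells)
  stopifnot(length(cells) >= 1, all(map_lgl(cells, inherits, "cell_model")))
  expectation <- matrix(background, dim[1], dim[2])
  coverage <- matrix(0L, dim[1], dim[2])
  fdir <- field$direction
  for (cell in cells) {
    r0 <- cell$center[1]; c0 <- cell$center[2]; rad <- cell$radius
    if (r0 - rad < 1 || r0 + rad > dim[1] || c0 - rad < 1 || c0 + rad > dim[2]) {
      abort("cells must fit inside the frame")
    }
    rows <- floor(r0 - rad):ceiling(r0 + rad)
    cols <- floor(c0 - rad):ceiling(c0 + rad)
    dr <- rows - r0
    dc <- cols - c0
    dist <- sqrt(outer(dr^2, dc^2, "+"))
    ring <- dist <= rad & dist >= rad - cell$ring_width
    interior <- dist < rad - cell$ring_width
    patch <- matrix(0, length(rows), length(cols))
    patch[interior] <- cell$f_rest * cell$interior_frac
    if (any(ring)) {
      proj <- outer(dr, dc, function(a, b) a * fdir[1] + b * fdir[2])
      costh <- proj[ring] / dist[ring]
      dv <- if (is.null(dv_fun)) 0 else dv_fun(cell, costh)
      patch[ring] <- cell$f_rest * (1 + cell$dye_sens * dv)
    }
    expectation[rows, cols] <- expectation[rows, cols] + patch
    coverage[rows, cols] <- coverage[rows, cols] + (ring | interior)
  }
  if (any(coverage > 1L)) warn("overlapping cells: fluorescence summed")
  expectation <- expectation * gain
  if (!noise) return(expectation)
  if (is.null(seed)) {
    apply_camera_noise(expectation, camera)
  } else {
    with_seed(as.integer(seed), apply_camera_noise(expectation, camera))
  }
}

#' Draw a random cell population for one sampling area
#'
#' Places non-overlapping cells (rejection sampling from the current RNG
#' stream) with radii drawn from the configured range, keeping a margin so
#' that every cell - including its rigidly shifted copy in the test passage -
#' stays fully inside the frame. Crowded draws that cannot be placed are
#' skipped.
#'
#' @param sim A [sim_params()].
#' @param dim Frame dimensions; defaults to the configured frame.
#' @param max_tries Placement attempts per cell before skipping it.
#' @return A list of [cell_model()] objects (at least one).
#' @export
place_cells <- function(sim, dim = sim$frame_dim, max_tries = 300) {
  cells <- list()
  centers <- matrix(numeric(0), ncol = 2)
  radii <- numeric(0)
  for (i in seq_len(sim$n_cells)) {
    rad <- runif(1, sim$radius_range[1], sim$radius_range[2])
    margin <- rad + sim$shift_max + 2
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      pos <- c(runif(1, margin, dim[1] - margin),
               runif(1, margin, dim[2] - margin))
      if (nrow(centers) == 0 ||
          all(sqrt(rowSums(sweep(centers, 2, pos)^2)) > radii + rad + 2)) {
        placed <- TRUE
        break
      }
    }
    if (!placed) next  # area is crowded; carry on with fewer cells
    centers <- rbind(centers, pos)
    radii <- c(radii, rad)
    cells[[length(cells) + 1]] <- cell_model(
      center = pos, radius = rad, tau_m = sim$tau_m, f_rest = sim$f_rest,
      dye_sens = sim$dye_sens, ring_width = sim$ring_width,
      interior_frac = sim$interior_frac)
  }
  if (length(cells) == 0) abort("could not place any cell in the frame")
  cells
}

shift_cells <- function(cells, shift) {
  map(cells, function(cl) {
    cl$center <- cl$center + shift
    cl
  })
}

#' Simulate the two-passage frame pairs for one sampling area
#'
#' Renders the four frames of the protocol for one sampling area: a
#' reference passage (pre-pulse and plateau frames at control conductance)
#' and a test passage (after administering the compound at `conc`, or a mock
#' solution). The test passage is rendered with the drug's conductance fold
#' (hemisphere-specific if the drug rectifies), scaled by
#' `1 - bleach_fraction`, rigidly translated by `shift`, and optionally
#' shifted in resting potential by `v_rest_offset` mV.
#'
#' @param cells List of [cell_model()] (shared scene of both passages).
#' @param drug A [drug_model()] / [antagonist_model()], or `NULL` for mock.
#' @param conc Compound concentration (M) in the test passage.
#' @param pulse,field,camera Protocol objects.
#' @param sim A [sim_params()].
#' @param shift Integer `(row, col)` rigid translation of the test passage.
#' @param mock Logical; force control conductance regardless of `conc`
#'   (mock-solution experiment with nominal concentration labels).
#' @param seed Optional integer seed: the four frames draw noise from
#'   `seed + 0:3`.
#' @return A list of class `passage_pair`: matrices `f_pre_ref`,
#'   `f_plateau_ref`, `f_pre_test`, `f_plateau_test` and a `truth` list
#'   (concentration, conductance fold, hemisphere folds, shift, bleach).
#' @export
simulate_passage_pair <- function(cells, drug = NULL, conc = 0,
                                  pulse = pulse_protocol(),
                                  field = field_geometry(),
                                  camera = camera_model(),
                                  sim = sim_params(),
                                  shift = c(0L, 0L), mock = FALSE,
                                  seed = NULL) {
  if (conc < 0) abort("`conc` must be nonnegative")
  g_pair <- if (mock || is.null(drug)) c(depol = 1, hyper = 1) else
    hemisphere_folds(drug, conc)
  t_plat <- pulse$plateau_sample_time
  k <- sim$k
  v0 <- sim$v_rest_offset
  dv_ref_plateau <- function(cell, costh) {
    dv_from_cos(cell, costh, pulse, 1, t_plat, k)
  }
  dv_test_pre <- if (v0 != 0) function(cell, costh) rep(v0, length(costh))
    else NULL
  dv_test_plateau <- function(cell, costh) {
    dv_from_cos(cell, costh, pulse, g_pair, t_plat, k) + v0
  }
  cells_t <- shift_cells(cells, shift)
  seeds <- if (is.null(seed)) vector("list", 4) else as.list(seed + 0:3)
  dim <- sim$frame_dim
  bg <- sim$background
  g1 <- 1 - sim$bleach_fraction
  rec <- list(
    f_pre_ref = render_frame(cells, field, camera, dim, bg, NULL,
                             1, sim$noise, seeds[[1]]),
    f_plateau_ref = render_frame(cells, field, camera, dim, bg,
                                 dv_ref_plateau, 1, sim$noise, seeds[[2]]),
    f_pre_test = render_frame(cells_t, field, camera, dim, bg, dv_test_pre,
                              g1, sim$noise, seeds[[3]]),
    f_plateau_test = render_frame(cells_t, field, camera, dim, bg,
                                  dv_test_plateau, g1, sim$noise, seeds[[4]]),
    truth = list(conc = conc, g_fold = unname(g_pair[["depol"]]),
                 g_pair = g_pair, shift = as.integer(shift),
                 bleach_fraction = sim$bleach_fraction)
  )
  structure(rec, class = "passage_pair")
}

#' Plate map for a well row
#'
#' One row of wells, each assigned a concentration of the test compound and
#' a number of sampling areas. Mirrors the screening layout of up to 9
#' sampling areas per well over 8 wells in a row.
#'
#' @param concentrations Concentration (M) per well, in well order;
#'   nonnegative. For a mock (control) plate these are nominal labels only.
#' @param areas_per_well Sampling areas per well (1 to 9).
#' @param seed Master seed of the plate; every `(well, area)` derives its own
#'   RNG stream from it, so results are independent of execution order.
#' @param row Row label used to build well ids.
#' @param mock Logical; mock-solution plate (no drug effect in the test
#'   passage).
#' @return A tibble of class `plate_map` with columns `well`, `well_index`,
#'   `concentration`.
#' @export
plate_map <- function(concentrations, areas_per_well = 5, seed = 1,
                      row = "A", mock = FALSE) {
  if (any(concentrations < 0)) abort("concentrations must be nonnegative")
  if (areas_per_well < 1 || areas_per_well > 9) {
    abort("`areas_per_well` must be between 1 and 9")
  }
  pm <- tibble(
    well = sprintf("%s%02d", row, seq_along(concentrations)),
    well_index = seq_along(concentrations),
    concentration = as.numeric(concentrations)
  )
  structure(pm, class = c("plate_map", class(pm)),
            areas_per_well = as.integer(areas_per_well),
            seed = as.integer(seed), mock = isTRUE(mock))
}

area_stream_seed <- function(master, well_index, area) {
  as.integer((as.numeric(master) * 10007 + well_index * 101 + area) %%
               2147483647)
}

#' Simulate a whole plate row
#'
#' Runs [simulate_passage_pair()] for every sampling area of every well of a
#' [plate_map()]. Each `(well, area)` uses its own RNG stream seeded from the
#' plate's master seed, so the simulation is reproducible and independent of
#' execution order. If the plate map is marked `mock`, the test passage is
#' rendered at control conductance for all wells.
#'
#' @param plate A [plate_map()].
#' @param drug A [drug_model()] or [antagonist_model()].
#' @param pulse,field,camera Protocol objects.
#' @param sim A [sim_params()].
#' @param seed Master seed; defaults to the plate map's.
#' @return A tibble of class `plate_sim`: one row per sampling area with
#'   columns `well`, `well_index`, `area`, `concentration`, `seed` and a
#'   `record` list-column of `passage_pair` objects. The full configuration
#'   and its hash are attached as attributes.
#' @export
simulate_plate <- function(plate, drug, pulse = pulse_protocol(),
                           field = field_geometry(), camera = camera_model(),
                           sim = sim_params(), seed = attr(plate, "seed")) {
  stopifnot(inherits(plate, "plate_map"))
  if (nrow(plate) == 0) abort("empty plate map")
  mock <- isTRUE(attr(plate, "mock"))
  n_areas <- attr(plate, "areas_per_well")
  grid <- tidyr::expand_grid(well_index = plate$well_index,
                             area = seq_len(n_areas))
  grid <- left_join(grid, plate, by = "well_index")
  grid$seed <- area_stream_seed(seed, grid$well_index, grid$area)
  grid$record <- pmap(
    list(grid$concentration, grid$seed),
    function(conc, area_seed) {
      with_seed(area_seed, {
        cells <- place_cells(sim)
        shift <- if (sim$shift_max > 0) {
          sample(seq(-sim$shift_max, sim$shift_max), 2, replace = TRUE)
        } else c(0L, 0L)
        simulate_passage_pair(cells, drug, conc, pulse, field, camera,
                              sim, shift = shift, mock = mock, seed = NULL)
      })
    })
  out <- grid[, c("well", "well_index", "area", "concentration", "seed",
                  "record")]
  config <- list(plate = as.list(plate[, c("well", "concentration")]),
                 areas_per_well = n_areas, mock = mock,
                 drug = unclass_deep(drug), pulse = unclass(pulse),
                 field = unclass(field), camera = unclass(camera),
                 sim = unclass(sim), seed = seed)
  structure(out, class = c("plate_sim", class(out)),
            config = config, config_hash = config_hash(config))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_json(config, tmp, auto_unbox = TRUE, digits = 12, force = TRUE)
  unname(md5sum(tmp))
}
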