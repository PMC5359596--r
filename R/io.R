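#' Write a simulated plate as TIFF stacks plus a JSON manifest
#'
#' One multi-page TIFF per sampling area, page order: reference pre-pulse,
#' reference plateau, test pre-pulse, test plateau. A `manifest.json`
#' sidecar records the full configuration, its hash, per-area seeds and the
#' ground-truth parameters for later scoring. Integer-valued frames (the
#' noisy camera output) are stored as 16-bit; noiseless expectation frames
#' are stored as 32-bit float (lossy only at float32 precision).
#'
#' @param sim A [simulate_plate()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_plate <- function(sim, dir) {
  stopifnot(is.data.frame(sim), "record" %in% names(sim))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  page_names <- c("f_pre_ref", "f_plateau_ref", "f_pre_test",
                  "f_plateau_test")
  areas <- vector("list", nrow(sim))
  for (i in seq_len(nrow(sim))) {
    rec <- sim$record[[i]]
    frames <- rec[page_names]
    integral <- all(map_lgl(frames, function(f) {
      all(is.finite(f)) && all(f == round(f)) && max(f) <= 65535
    }))
    storage <- if (integral) "uint16" else "float32"
    file <- sprintf("%s_area%02d.tif", sim$well[i], sim$area[i])
    pages <- map(frames, function(f) pmin(pmax(f, 0), 65535) / 65535)
    writeTIFF(pages, file.path(dir, file),
              bits.per.sample = if (integral) 16L else 32L,
              compression = "none", reduce = FALSE)
    areas[[i]] <- list(well = sim$well[i], well_index = sim$well_index[i],
                       area = sim$area[i],
                       concentration = sim$concentration[i],
                       seed = sim$seed[i], file = file, storage = storage,
                       truth = rec$truth)
  }
  manifest <- list(schema_version = "1.0",
                   package = "opticond",
                   config = attr(sim, "config"),
                   config_hash = attr(sim, "config_hash"),
                   page_order = page_names,
                   areas = areas)
  write_json(manifest, file.path(dir, "manifest.json"),
             auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  invisible(dir)
}

#' Read a plate written by [write_plate()]
#'
#' @param dir Directory containing `manifest.json` and the TIFF stacks.
#' @return A `plate_sim` tibble equivalent to the one written (frame values
#'   exactly recovered for 16-bit stacks, to float32 precision otherwise).
#' @export
read_plate <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path)) abort("manifest.json not found in `dir`")
  manifest <- read_json(mf_path, simplifyVector = FALSE)
  if (!identical(manifest$schema_version, "1.0")) {
    abort("unsupported manifest schema_version")
  }
  page_names <- unlist(manifest$page_order)
  rows <- map(manifest$areas, function(a) {
    path <- file.path(dir, a$file)
    if (!file.exists(path)) abort(paste("missing stack:", a$file))
    pages <- readTIFF(path, all = TRUE)
    frames <- map(pages, function(p) {
      counts <- p * 65535
      if (identical(a$storage, "uint16")) round(counts) else counts
    })
    names(frames) <- page_names
    truth <- a$truth
    truth$g_pair <- unlist(truth$g_pair)
    truth$shift <- as.integer(unlist(truth$shift))
    rec <- structure(c(frames, list(truth = truth)), class = "passage_pair")
    tibble(well = a$well, well_index = a$well_index, area = a$area,
           concentration = a$concentration, seed = a$seed,
           record = list(rec))
  })
  out <- list_rbind(rows)
  structure(out, class = c("plate_sim", class(out)),
            config = manifest$config, config_hash = manifest$config_hash)
}

run_config_defaults <- function() {
  list(
    schema_version = "1.0",
    plate = list(concentrations = NULL, areas_per_well = 5, mock = FALSE),
    drug = list(ec50 = 1e-6, hill = 1, g_max_fold = 5, rectification = 1),
    pulse = unclass(pulse_protocol()),
    field = list(direction = c(0, 1)),
    camera = unclass(camera_model()),
    sim = unclass(sim_params()),
    analysis = unclass(analysis_params()),
    output_dir = "opticond-out"
  )
}

merge_config <- function(defaults, user) {
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && is.list(user[[nm]]) &&
        !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]])
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Read and validate a run configuration
#'
#' Reads a YAML or JSON run configuration, fills unspecified values with the
#' package defaults, and validates it. Required fields are `seed` and
#' `plate$concentrations`; schema violations name the offending field.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return A validated configuration list of class `run_config`, with
#'   constructed protocol objects under `$objects`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste("config file not found:", path))
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    read_yaml(path)
  } else {
    read_json(path, simplifyVector = TRUE)
  }
  cfg <- merge_config(run_config_defaults(), raw)
  if (is.null(raw$seed)) abort('invalid config: missing required field "seed"')
  cfg$seed <- as.integer(raw$seed)
  if (is.null(cfg$plate$concentrations)) {
    abort('invalid config: missing required field "plate.concentrations"')
  }
  if (any(cfg$plate$concentrations < 0)) {
    abort('invalid config: field "plate.concentrations" must be nonnegative')
  }
  objects <- list(
    plate = plate_map(cfg$plate$concentrations,
                      areas_per_well = cfg$plate$areas_per_well,
                      seed = cfg$seed, mock = isTRUE(cfg$plate$mock)),
    drug = drug_model(ec50 = cfg$drug$ec50, hill = cfg$drug$hill,
                      g_max_fold = cfg$drug$g_max_fold,
                      rectification = cfg$drug$rectification),
    pulse = do.call(pulse_protocol, cfg$pulse),
    field = field_geometry(unlist(cfg$field$direction)),
    camera = do.call(camera_model, cfg$camera),
    sim = do.call(sim_params, cfg$sim),
    analysis = do.call(analysis_params, cfg$analysis)
  )
  cfg$objects <- objects
  structure(cfg, class = "run_config")
}

#' Write an analysis result bundle
#'
#' Exports a [analyze_plate()] result as delimited text and JSON: per-area
#' slope table (`areas.csv`), per-well conductance table (`wells.csv`), the
#' CRC fit (`crc.json`), and a provenance record (`bundle.json` with config
#' hash, seed and package version).
#'
#' @param analysis A `plate_analysis`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_result_bundle <- function(analysis, dir) {
  stopifnot(inherits(analysis, "plate_analysis"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  areas <- analysis$areas
  areas$pairs <- NULL
  utils::write.csv(areas, file.path(dir, "areas.csv"), row.names = FALSE)
  utils::write.csv(analysis$wells, file.path(dir, "wells.csv"),
                   row.names = FALSE)
  crc <- if (!is.null(analysis$crc)) {
    as.list(glance(analysis$crc))
  } else NULL
  write_json(list(crc = crc, z_prime = analysis$z_prime),
             file.path(dir, "crc.json"), auto_unbox = TRUE, digits = NA,
             pretty = TRUE, force = TRUE)
  write_json(list(package = "opticond",
                  version = as.character(utils::packageVersion("opticond")),
                  config_hash = analysis$config_hash,
                  seed = analysis$config$seed,
                  params = unclass(analysis$params)),
             file.path(dir, "bundle.json"), auto_unbox = TRUE, digits = NA,
             pretty = TRUE, force = TRUE)
  invisible(dir)
}
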