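#' Assign files to tilt series
#'
#' Groups micrograph files by a series token and orders them by tilt angle.
#' The filename pattern is explicit (no vendor-scheme sniffing): `{series}`
#' matches the series index, `{angle}` the signed tilt angle, `{ignore}` an
#' arbitrary token.
#'
#' @param input_dir directory to scan.
#' @param name_pattern e.g. `"TS_{series}_{angle}.mrc"`.
#' @return list with `groups` (named list: series id -> data.frame of
#'   `file`, `angle`, ordered by angle), `unassigned` (non-matching files)
#'   and `flagged` (series with missing/irregular angle steps).
#' @export
sort_files <- function(input_dir, name_pattern) {
  if (!dir.exists(input_dir)) stop("no such directory: ", input_dir)
  files <- list.files(input_dir)
  rx <- glob_pattern_to_regex(name_pattern)
  m <- regmatches(files, regexec(rx$regex, files))
  ok <- lengths(m) == rx$ngroups + 1L
  if (!length(files) || !any(ok))
    warning("no files matched pattern '", name_pattern, "'")
  unassigned <- files[!ok]
  rows <- lapply(which(ok), function(i) {
    g <- m[[i]][-1]
    data.frame(file = files[i], series = g[rx$series_idx],
               angle = as.numeric(g[rx$angle_idx]))
  })
  df <- do.call(rbind, rows)
  groups <- list()
  flagged <- character()
  if (!is.null(df)) {
    for (s in sort(unique(df$series))) {
      gd <- df[df$series == s, ]
      dup <- duplicated(gd$angle)
      if (any(dup)) {
        first <- gd$file[match(gd$angle[dup][1], gd$angle)]
        stop("duplicate (series, angle) pair: ", first, " and ",
             gd$file[dup][1])
      }
      gd <- gd[order(gd$angle), ]
      row.names(gd) <- NULL
      groups[[s]] <- gd
      steps <- diff(gd$angle)
      if (length(steps) > 1 && max(abs(steps - stats::median(steps))) > 1e-6)
        flagged <- c(flagged, s)
    }
  }
  list(groups = groups, unassigned = unassigned, flagged = flagged)
}

glob_pattern_to_regex <- function(pattern) {
  tokens <- regmatches(pattern, gregexpr("\\{[a-z]+\\}", pattern))[[1]]
  if (!"{series}" %in% tokens || !"{angle}" %in% tokens)
    stop("pattern must contain {series} and {angle} tokens")
  parts <- strsplit(pattern, "\\{[a-z]+\\}")[[1]]
  esc <- function(s) gsub("([^A-Za-z0-9_ ])", "\\\\\\1", s)
  rx <- paste0("^")
  gi <- 0L; series_idx <- NA_integer_; angle_idx <- NA_integer_
  for (i in seq_along(tokens)) {
    rx <- paste0(rx, esc(parts[i]))
    gi <- gi + 1L
    tk <- tokens[i]
    if (tk == "{series}") { rx <- paste0(rx, "([A-Za-z0-9]+)"); series_idx <- gi }
    else if (tk == "{angle}") { rx <- paste0(rx, "([-+]?[0-9.]+)"); angle_idx <- gi }
    else rx <- paste0(rx, "(.*)")
  }
  if (length(parts) > length(tokens))
    rx <- paste0(rx, esc(parts[length(parts)]))
  list(regex = paste0(rx, "$"), ngroups = gi,
       series_idx = series_idx, angle_idx = angle_idx)
}

# ---------------------------------------------------------------------------
# Resumable execution engine with SUCCESS-file semantics

success_path <- function(dir) file.path(dir, "SUCCESS")

# Atomic marker: write to a temp name, then rename.
write_success <- function(dir) {
  tmp <- file.path(dir, ".SUCCESS.tmp")
  writeLines(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), tmp)
  file.rename(tmp, success_path(dir))
}

module_registry <- function() {
  list(
    Simulate = run_simulate_module,
    Reconstruct = run_reconstruct_module,
    CtfCorrect = run_ctf_module,
    TemplateMatching = run_match_module,
    ExtractParticles = run_extract_module
  )
}

#' Run a configured pipeline
#'
#' Executes the config's module sections in order.  Every module owns a
#' folder `NN_ModuleName` under `workdir` with one subfolder per item
#' (tilt-series/tomogram id, zero-padded); a per-item `SUCCESS` marker is
#' written on completion (atomically, write-then-rename) and a global
#' `SUCCESS` in the module folder once all items are done.  Items with an
#' existing marker are skipped, so a re-run performs no recomputation;
#' deleting a global marker re-executes that module for every item.  One
#' item's failure is recorded and does not abort its siblings.
#'
#' @param config an `effective_config` from [merge_config()], or a user
#'   config (list / JSON path) merged against the packaged defaults.
#' @param workdir working directory for module folders.
#' @param selection optional character vector restricting item ids.
#' @return data.frame execution report: module, item, status
#'   (`done` / `skipped` / `failed`), seconds, message.
#' @export
run_pipeline <- function(config, workdir, selection = NULL) {
  if (!inherits(config, "effective_config"))
    config <- merge_config(default_config(), load_json_arg(config))
  dir.create(workdir, recursive = TRUE, showWarnings = FALSE)
  registry <- module_registry()
  report <- list()
  state <- new.env(parent = emptyenv())
  state$workdir <- workdir
  state$general <- config$general
  for (mi in seq_along(config$modules)) {
    mod <- config$modules[[mi]]
    impl <- registry[[mod$name]]
    if (is.null(impl))
      stop("configuration error: no registered implementation for module '",
           mod$name, "'")
  }
  for (mi in seq_along(config$modules)) {
    mod <- config$modules[[mi]]
    impl <- registry[[mod$name]]
    mdir <- file.path(workdir, sprintf("%02d_%s", mi, mod$section))
    dir.create(mdir, showWarnings = FALSE)
    items <- pipeline_items(mod, state)
    if (!is.null(selection)) items <- intersect(items, selection)
    global_ok <- file.exists(success_path(mdir))
    all_done <- TRUE
    for (it in items) {
      idir <- file.path(mdir, it)
      dir.create(idir, showWarnings = FALSE)
      if (global_ok && file.exists(success_path(idir))) {
        report[[length(report) + 1L]] <- data.frame(
          module = mod$section, item = it, status = "skipped", seconds = 0,
          message = "")
        next
      }
      if (!global_ok && file.exists(success_path(idir))) {
        # global marker removed: force re-execution of this module
        unlink(success_path(idir))
      }
      t0 <- proc.time()[3]
      res <- tryCatch({
        impl(mod$params, state, it, idir)
        write_success(idir)
        list(status = "done", message = "")
      }, error = function(e) list(status = "failed",
                                  message = conditionMessage(e)))
      if (res$status == "failed") all_done <- FALSE
      report[[length(report) + 1L]] <- data.frame(
        module = mod$section, item = it, status = res$status,
        seconds = round(proc.time()[3] - t0, 3), message = res$message)
      if (res$status == "failed")
        writeLines(res$message, file.path(idir, "FAILURE"))
    }
    if (all_done && length(items)) write_success(mdir)
  }
  out <- do.call(rbind, report)
  jsonlite::write_json(out, file.path(workdir, "execution_report.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  out
}

# Item ids: tomogram indices from the Simulate section (or existing folders).
pipeline_items <- function(mod, state) {
  if (mod$name == "Simulate")
    return(sprintf("%03d", seq_len(mod$params$n_tomograms %||% 1L)))
  sim <- list.files(state$workdir, pattern = "^[0-9]+_Simulate",
                    full.names = TRUE)
  if (length(sim)) {
    its <- list.dirs(sim[1], recursive = FALSE, full.names = FALSE)
    if (length(its)) return(its)
  }
  sprintf("%03d", seq_len(1L))
}

run_simulate_module <- function(p, state, item, idir) {
  seed <- (p$seed %||% 1) + as.integer(item)
  phantom <- make_phantom(p$phantom %||% "torus", p$phantom_box %||% 48)
  gt <- place_particles(unlist(p$volume_shape), p$n_particles, p$min_dist,
                        p$border, seed = seed, n_beads = p$n_beads %||% 0L)
  spec <- render_specimen(gt, phantom, unlist(p$volume_shape))
  ztd <- p$zero_tilt_dose %||% 0          # 0 = no override
  scheme <- tilt_scheme(p$tilt_start, p$tilt_stop, p$tilt_increment,
                        p$ordering %||% "dose-symmetric",
                        p$dose_per_tilt %||% 3,
                        if (ztd > 0) ztd else NULL)
  ctf <- ctf_params(p$voltage_kv %||% 300, p$cs_mm %||% 2.7,
                    p$amplitude_contrast %||% 0.07, p$defocus_um %||% 3,
                    p$pixel_size)
  ts <- simulate_tilt_series(spec, scheme, ctf = ctf, seed = seed)
  ts$images <- degrade_to_snr(ts$images, p$snr %||% 0.5, seed = seed + 7)
  write_tilt_series(ts, file.path(idir, "tilt_series.mrc"))
  tbl <- particle_table(nrow(gt$positions))
  tbl$tag <- seq_len(nrow(gt$positions))
  tbl$x <- gt$positions[, 1]; tbl$y <- gt$positions[, 2]
  tbl$z <- gt$positions[, 3]
  tbl$tdrot <- gt$orientations[, 1]; tbl$tilt <- gt$orientations[, 2]
  tbl$narot <- gt$orientations[, 3]
  tbl$tomogram_id <- as.integer(item)
  write_table(tbl, file.path(idir, "ground_truth.tbl"))
  invisible(NULL)
}

find_item_file <- function(state, item, filename) {
  hits <- Sys.glob(file.path(state$workdir, "*", item, filename))
  if (!length(hits)) stop("missing upstream artifact '", filename,
                          "' for item ", item)
  hits[length(hits)]
}

run_ctf_module <- function(p, state, item, idir) {
  ts <- read_tilt_series(find_item_file(state, item, "tilt_series.mrc"))
  cp <- ctf_params(pixel_size = p$pixel_size)
  est <- estimate_defocus(ts$images[, , which.min(abs(ts$angles))], cp,
                          p$search_min_um, p$search_max_um, p$search_step_um)
  d <- dim(ts$images)
  cp$defocus_um <- est$defocus_um
  for (i in seq_len(d[3]))
    ts$images[, , i] <- phase_flip(ts$images[, , i], cp,
                                   tilt_deg = ts$angles[i],
                                   strip_width = p$strip_width %||% 256,
                                   handedness = p$handedness %||% 1)
  # phase flipping keeps the underfocus first-band polarity; invert so the
  # tomogram correlates positively with density (template convention)
  ts$images <- -ts$images
  ts$ctf_corrected <- TRUE
  write_tilt_series(ts, file.path(idir, "tilt_series.mrc"))
  write_defocus(rep(est$defocus_um, d[3]), file.path(idir, "defocus.txt"))
  invisible(NULL)
}

run_reconstruct_module <- function(p, state, item, idir) {
  ts <- read_tilt_series(find_item_file(state, item, "tilt_series.mrc"))
  tomo <- wbp_reconstruct(ts, p$thickness, p$filter %||% "ramp")
  if ((p$nad_iterations %||% 0) > 0)
    tomo$volume <- nad_denoise(tomo$volume, p$nad_kappa %||% 0.5,
                               p$nad_iterations, p$nad_dt %||% 0.1)
  write_mrc(tomo$volume, file.path(idir, "tomogram.mrc"),
            voxel_size = tomo$voxel_size)
  invisible(NULL)
}

run_match_module <- function(p, state, item, idir) {
  tomo <- read_mrc(find_item_file(state, item, "tomogram.mrc"))
  phantom <- make_phantom("torus", p$template_box %||% 32,
                          ring_radius = (p$template_box %||% 32) / 5,
                          tube_radius = (p$template_box %||% 32) / 10)
  prep <- prepare_template(phantom, 1, 1)
  grid <- generate_grid(p$cone_sampling, p$cone_range,
                        p$inplane_sampling, p$inplane_range,
                        p$symmetry %||% "C1")
  ts_meta <- jsonlite::read_json(
    paste0(find_item_file(state, item, "tilt_series.mrc"), ".json"),
    simplifyVector = TRUE)
  chunk <- unlist(p$chunk)               # 0 = whole volume in one chunk
  if (is.null(chunk) || all(chunk == 0)) chunk <- NULL
  res <- match_template(tomo$data, prep$template, prep$mask, grid,
                        wedge = ts_meta$angles, chunk = chunk)
  write_mrc(res$cc_map, file.path(idir, "cc_map.mrc"))
  write_mrc(array(as.numeric(res$orient_map), dim(res$orient_map)),
            file.path(idir, "orient_map.mrc"))
  utils::write.csv(as.data.frame(res$grid), file.path(idir, "grid.csv"),
                   row.names = FALSE)
  invisible(NULL)
}

run_extract_module <- function(p, state, item, idir) {
  cc <- read_mrc(find_item_file(state, item, "cc_map.mrc"))$data
  ori <- read_mrc(find_item_file(state, item, "orient_map.mrc"))$data
  grid <- utils::read.csv(find_item_file(state, item, "grid.csv"))
  mr <- structure(list(cc_map = cc, orient_map = array(as.integer(round(ori)),
                                                       dim(ori)),
                       grid = grid), class = "match_result")
  if ((p$island_max_size %||% 0) > 0)
    mr$cc_map <- postprocess_cc(mr$cc_map, p$island_max_size)
  maxp <- p$max_particles %||% 0          # 0 = uncapped
  excl <- p$exclusion_radius %||% 0       # 0 = half the box (default)
  tbl <- extract_peaks(mr, threshold_sigma = p$threshold_sigma,
                       max_particles = if (maxp > 0) maxp else NULL,
                       exclusion_radius = if (excl > 0) excl
                                          else (p$box %||% 32) / 2,
                       tomogram_id = as.integer(item))
  write_table(tbl, file.path(idir, "particles.tbl"))
  invisible(NULL)
}

#' Live reconstruction mode
#'
#' Watches a directory for arriving tilt images (named by the sort
#' pattern).  When a series reaches the expected image count, or no new
#' file arrives within the timeout, the series is closed, binned by
#' Fourier cropping and reconstructed through the simplified path (no
#' motion or CTF steps).  The loop ends when the timeout elapses with no
#' open series.
#'
#' @param watch_dir directory to watch.
#' @param out_dir output directory for tomograms.
#' @param name_pattern filename pattern (see [sort_files()]).
#' @param expected_images_per_series images per complete series (>= 1).
#' @param listen_timeout_s inactivity timeout in seconds (> 0).
#' @param binning Fourier-crop factor for the simplified reconstruction.
#' @param thickness output thickness in binned voxels.
#' @param poll_s polling interval.
#' @return data.frame report: series, n_images, complete, tomogram path.
#' @export
run_live <- function(watch_dir, out_dir, name_pattern = "{series}_{angle}.mrc",
                     expected_images_per_series, listen_timeout_s,
                     binning = 8, thickness = 64, poll_s = 0.2) {
  if (!dir.exists(watch_dir)) stop("watch_dir does not exist: ", watch_dir)
  stopifnot(expected_images_per_series >= 1, listen_timeout_s > 0)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  done <- character()
  report <- list()
  last_event <- Sys.time()
  n_seen <- -1L
  repeat {
    srt <- suppressWarnings(sort_files(watch_dir, name_pattern))
    n_now <- sum(vapply(srt$groups, nrow, integer(1)))
    if (n_now != n_seen) { n_seen <- n_now; last_event <- Sys.time() }
    idle <- as.numeric(difftime(Sys.time(), last_event, units = "secs"))
    open_series <- setdiff(names(srt$groups), done)
    for (s in open_series) {
      g <- srt$groups[[s]]
      if (nrow(g) < expected_images_per_series && idle <= listen_timeout_s)
        next
      imgs_list <- lapply(g$file, function(f) {
        m <- read_mrc(file.path(watch_dir, f))$data
        m[, , 1]
      })
      imgs <- array(unlist(imgs_list),
                    c(dim(imgs_list[[1]]), length(imgs_list)))
      ts <- structure(list(images = imgs, angles = g$angle, pixel_size = 1),
                      class = "tilt_series")
      tomo <- wbp_reconstruct(ts, thickness, "ramp", binning = binning)
      tomo_path <- file.path(out_dir, paste0("tomogram_", s, ".mrc"))
      write_mrc(tomo$volume, tomo_path, voxel_size = tomo$voxel_size)
      report[[length(report) + 1L]] <- data.frame(
        series = s, n_images = nrow(g),
        complete = nrow(g) >= expected_images_per_series,
        tomogram = tomo_path)
      done <- c(done, s)
    }
    if (idle > listen_timeout_s &&
        length(setdiff(names(srt$groups), done)) == 0L) break
    Sys.sleep(poll_s)
  }
  if (length(report)) do.call(rbind, report)
  else data.frame(series = character(), n_images = integer(),
                  complete = logical(), tomogram = character())
}

#' Remove declared-temporary pipeline artifacts
#'
#' Only artifacts in the declared stage categories are removed; SUCCESS
#' markers, particle tables and final maps are protected and can never be
#' declared temporary.
#'
#' @param workdir pipeline working directory.
#' @param stages categories to remove: `"cc_maps"` (matching maps),
#'   `"tilt_series"` (intermediate corrected stacks), `"scratch"`.
#' @param dry_run list without deleting.
#' @return character vector of removed (or listed) paths.
#' @export
cleanup <- function(workdir, stages = c("scratch"), dry_run = FALSE) {
  categories <- list(
    cc_maps = c("cc_map.mrc", "orient_map.mrc"),
    tilt_series = "tilt_series.mrc",
    scratch = "*.tmp")
  protected <- c("SUCCESS", "particles.tbl", "average*.mrc", "*.tbl")
  bad <- setdiff(stages, names(categories))
  if (length(bad))
    stop("configuration error: unknown or protected cleanup category: ",
         paste(bad, collapse = ", "))
  targets <- character()
  for (st in stages) for (pat in categories[[st]])
    targets <- c(targets, Sys.glob(file.path(workdir, "*", "*", pat)))
  for (pp in protected)
    targets <- setdiff(targets, Sys.glob(file.path(workdir, "*", "*", pp)))
  if (!dry_run) unlink(targets)
  targets
}
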