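#' Phase-point grid specification
#'
#' The (T*, p*) grid to simulate, the MD protocol, and the model preset.
#' Reduced units: T* = k_B T / eps_hb, p* = p r_hb^2 / eps_hb. The
#' production grid of the study spans roughly T* in [0.05, 0.30] and p* in
#' [0.01, 20] (log-spaced in pressure); desk-scale grids are much coarser.
#'
#' @param temperatures Positive reduced temperatures.
#' @param pressures Positive reduced pressures.
#' @param protocol An [md_protocol()].
#' @param params_preset `"mb"` or `"real"`.
#' @return Object of class `grid_spec`.
#' @export
grid_spec <- function(temperatures, pressures, protocol = md_protocol(),
                      params_preset = c("mb", "real")) {
  stopifnot(all(temperatures > 0), all(pressures > 0))
  structure(list(temperatures = as.numeric(temperatures),
                 pressures = as.numeric(pressures),
                 protocol = protocol,
                 params_preset = match.arg(params_preset)),
            class = "grid_spec")
}

#' Read/write grid specifications (YAML)
#'
#' @param spec A `grid_spec`.
#' @param path File path.
#' @return `write_grid_spec` returns `path` invisibly; `read_grid_spec` a
#'   `grid_spec` (round-trip identity).
#' @export
write_grid_spec <- function(spec, path) {
  yaml::write_yaml(list(temperatures = spec$temperatures,
                        pressures = spec$pressures,
                        protocol = unclass(spec$protocol),
                        params_preset = spec$params_preset), path)
  invisible(path)
}

#' @rdname write_grid_spec
#' @export
read_grid_spec <- function(path) {
  y <- yaml::read_yaml(path)
  grid_spec(y$temperatures, y$pressures,
            protocol = do.call(md_protocol, y$protocol),
            params_preset = y$params_preset)
}

#' The five characteristic ADF distances
#'
#' 0.7 (LJ contact), 1.0 (direct hydrogen bond), 1.73 (two molecules
#' bonded to the same third), 2.0 and 3.0 - the peaks of the radial
#' distribution function, where the molecular ordering is strongest.
#'
#' @return Numeric vector of length 5.
#' @export
adf_distances <- function() c(0.7, 1.0, 1.73, 2.0, 3.0)

grid_fingerprint <- function(spec) {
  jsonlite::toJSON(list(temperatures = spec$temperatures,
                        pressures = spec$pressures,
                        protocol = unclass(spec$protocol),
                        params_preset = spec$params_preset),
                   auto_unbox = TRUE, digits = NA)
}

#' Run the phase-point grid
#'
#' One NPT MD run per (T*, p*) point, condensed to the observable set and
#' the five angular distribution functions, and assembled into the two
#' machine-learning feature tables. Finished points are cached on disk
#' (one file per point, keyed to a fingerprint of the spec), so an
#' interrupted grid resumes and a warm rerun performs zero MD steps.
#' Individual point failures are recorded and the grid continues.
#'
#' @param spec A [grid_spec()].
#' @param outputs `"both"`, `"adf"`, or `"properties"`.
#' @param cache_dir Cache directory (created if missing); `NULL` disables
#'   caching.
#' @return List with `adf_table` (125-dim `feature_table` or NULL),
#'   `property_table` (15-dim standardized `feature_table` or NULL),
#'   `observables` (list of observable sets), `diffusion` (raw values),
#'   `failed` (data.frame of failed points).
#' @export
run_grid <- function(spec, outputs = c("both", "adf", "properties"),
                     cache_dir = NULL) {
  outputs <- match.arg(outputs)
  params <- rose_params(spec$params_preset)
  points <- expand.grid(T = spec$temperatures, p = spec$pressures,
                        KEEP.OUT.ATTRS = FALSE)
  points <- points[order(points$p, points$T), , drop = FALSE]
  rownames(points) <- NULL
  fp <- grid_fingerprint(spec)
  if (!is.null(cache_dir)) {
    dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
    fp_file <- file.path(cache_dir, "spec.json")
    if (file.exists(fp_file) &&
        !identical(trimws(readChar(fp_file, file.size(fp_file))),
                   as.character(fp)))
      stop("run_grid: cache_dir was built from a different grid spec")
    writeLines(as.character(fp), fp_file)
  }
  results <- vector("list", nrow(points))
  failed <- list()
  for (i in seq_len(nrow(points))) {
    Tt <- points$T[i]; pp <- points$p[i]
    cache_file <- if (!is.null(cache_dir))
      file.path(cache_dir, sprintf("pt_T%.6g_p%.6g.rds", Tt, pp)) else NULL
    if (!is.null(cache_file) && file.exists(cache_file)) {
      res <- readRDS(cache_file)
      res$n_md_steps <- 0  # nothing simulated on a warm cache hit
      results[[i]] <- res
      next
    }
    res <- tryCatch({
      proto <- spec$protocol
      proto$seed <- proto$seed + i  # independent, reproducible per point
      run <- run_npt(proto, params, T = Tt, p = pp)
      obs <- observable_set(run)
      adfs <- lapply(adf_distances(), function(r)
        compute_adf(run$frames, r_target = r, params = params))
      list(T = Tt, p = pp, observables = obs,
           adf_row = build_adf_descriptor(adfs),
           n_md_steps = proto$n_equil + proto$n_series * proto$series_len)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed[[length(failed) + 1]] <-
        data.frame(T = Tt, p = pp, message = conditionMessage(res))
      next
    }
    results[[i]] <- res
    if (!is.null(cache_file)) saveRDS(res, cache_file)
  }
  ok <- !vapply(results, is.null, logical(1))
  res_ok <- results[ok]
  pts_ok <- points[ok, , drop = FALSE]
  adf_table <- NULL
  property_table <- NULL
  if (length(res_ok)) {
    if (outputs %in% c("both", "adf")) {
      adf_mat <- do.call(rbind, lapply(res_ok, `[[`, "adf_row"))
      adf_table <- feature_table(pts_ok, adf_mat,
                                 paste0("adf_", seq_len(ncol(adf_mat))),
                                 standardized = FALSE)
    }
    if (outputs %in% c("both", "properties"))
      property_table <- build_property_table(pts_ok,
                                             lapply(res_ok, `[[`,
                                                    "observables"))
  }
  list(adf_table = adf_table,
       property_table = property_table,
       observables = lapply(res_ok, `[[`, "observables"),
       phase_points = pts_ok,
       diffusion = vapply(res_ok, function(r) r$observables$diffusion,
                          numeric(1)),
       n_md_steps = sum(vapply(res_ok, function(r)
         r$n_md_steps %||% 0, numeric(1))),
       failed = if (length(failed)) do.call(rbind, failed) else NULL)
}
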