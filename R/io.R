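# File formats and deterministic fixture generation. Track tables travel as
# UTF-8 CSV with a mandatory header: track_id, frame (0-based, contiguous
# within a track), t_s, x_um, y_um, optional z_um and bound.

#' Read a track table from CSV
#'
#' Validates the schema: mandatory columns, unique `(track_id, frame)` keys,
#' contiguous frames within each track, and plausible positions (within
#' +/- 10 um). Tracks are 3D iff a `z_um` column is present.
#'
#' @param path CSV file path.
#' @return A validated track table (data.frame).
#' @export
read_tracks <- function(path) {
  x <- as.data.frame(data.table::fread(path, sep = ",", header = TRUE,
                                       encoding = "UTF-8"))
  need <- c("track_id", "frame", "t_s", "x_um", "y_um")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("malformed track file: missing column(s) ", paste(miss, collapse = ", "))
  x$track_id <- as.character(x$track_id)
  x$frame <- as.integer(x$frame)
  key <- paste(x$track_id, x$frame)
  dup <- which(duplicated(key))
  if (length(dup))
    stop(sprintf("duplicate (track_id, frame) key at row %d", dup[1]))
  o <- x[order(x$track_id, x$frame), , drop = FALSE]
  same <- o$track_id[-1] == o$track_id[-nrow(o)]
  step <- diff(o$frame)
  bad <- which(same & step != 1L)
  if (length(bad))
    stop(sprintf("non-contiguous frames in track '%s' near row %d",
                 o$track_id[bad[1]], bad[1]))
  coords <- c("x_um", "y_um", if ("z_um" %in% names(x)) "z_um")
  for (cl in coords) {
    if (!is.numeric(x[[cl]])) stop("column ", cl, " must be numeric")
    out <- which(abs(x[[cl]]) > 10)
    if (length(out))
      stop(sprintf("implausible position (|%s| > 10 um) at row %d", cl, out[1]))
  }
  x
}

#' Write a track table to CSV
#'
#' Round-trips losslessly with [read_tracks()] at 9 significant digits.
#'
#' @param tracks A track table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  out <- tracks
  for (cl in intersect(c("t_s", "x_um", "y_um", "z_um"), names(out)))
    out[[cl]] <- signif(out[[cl]], 9)
  data.table::fwrite(out, path, sep = ",")
  invisible(path)
}

#' Read a flat key/value configuration file
#'
#' YAML with the parameter symbols used throughout: `r_f, r_n, Dn, D0, A, b,
#' rho, Db, r_b, kappa, k_off, sigma_noise, dt, n_steps, seed`. Missing keys
#' fall back to the package defaults (the typical-value column).
#'
#' @param path YAML file path.
#' @return Named list of parameters.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  defaults <- list(r_f = 0.1, r_n = 0.5, Dn = 1.0, D0 = 0.05, A = 5.0,
                   b = 1000, rho = 4.8e4, Db = 0.005, r_b = 0.01, kappa = 100,
                   k_off = 500, sigma_noise = 0.03, dt = 1e-6, n_steps = 1e6,
                   seed = 1L, record_every = 1L)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  utils::modifyList(defaults, user)
}

#' Write a run manifest
#'
#' Records the full parameter set, seed, package version, timestamp and MD5
#' digests of the listed files, so a run can be reproduced bit-identically.
#'
#' @param path Output JSON path.
#' @param params Named list of parameters.
#' @param seed Integer seed.
#' @param files Character vector of input/output files to digest.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, params, seed, files = character()) {
  digests <- if (length(files)) as.list(tools::md5sum(files)) else list()
  jsonlite::write_json(
    list(package = "focisim",
         version = as.character(utils::packageVersion("focisim")),
         created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         seed = seed, params = params, file_md5 = digests),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Generate small deterministic track fixtures
#'
#' Seeded, fast (seconds each) CSV fixtures at the typical parameter values,
#' used by the examples and the test-suite:
#' `"lpm-default"` (droplet), `"pbm-fast-exchange"`, `"pbm-slow-exchange"`,
#' `"free-diffusion"` and `"crowded"`.
#'
#' @param suite_name One of the suite names above.
#' @param seed Integer seed; the same seed yields byte-identical files.
#' @param out_dir Output directory (created if needed).
#' @return Paths of the written files, invisibly.
#' @export
generate_fixtures <- function(suite_name, seed = 1L, out_dir = ".") {
  suites <- c("lpm-default", "pbm-fast-exchange", "pbm-slow-exchange",
              "free-diffusion", "crowded")
  if (!suite_name %in% suites)
    stop("unknown suite; choose one of: ", paste(suites, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  g <- geometry(r_f = 0.1, r_n = 0.25)
  tr <- switch(suite_name,
    "lpm-default" = simulate_lpm(lpm_params(g),
                                 sim_config(1e-6, 2e6, seed, 1000L)),
    "free-diffusion" = simulate_lpm(lpm_params(g, D0 = 1, Dn = 1, A = 0),
                                    sim_config(1e-6, 5e5, seed, 250L)),
    "pbm-fast-exchange" = {
      p <- pbm_params(g, k_off = 1500)
      dt <- pbm_stable_dt(p)
      simulate_pbm(p, sim_config(dt, round(2 / dt), seed,
                                 round(1e-3 / dt)))
    },
    "pbm-slow-exchange" = {
      p <- pbm_params(g, k_off = 20)
      dt <- pbm_stable_dt(p)
      simulate_pbm(p, sim_config(dt, round(2 / dt), seed,
                                 round(1e-3 / dt)))
    },
    "crowded" = {
      p <- pbm_params(g, crowder_count = 100L)
      dt <- pbm_stable_dt(p)
      simulate_pbm(p, sim_config(dt, round(2 / dt), seed,
                                 round(1e-3 / dt)))
    })
  f <- file.path(out_dir, paste0(suite_name, ".csv"))
  write_tracks(as_track_table(tr, track_id = suite_name), f)
  invisible(f)
}
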