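# Plain-text serialization: trajectories and density tables as CSV, run
# manifests as JSON.  Every artifact records the seed, step size and model
# configuration needed to reproduce it exactly.

#' Write / read a trajectory as CSV with a JSON manifest
#'
#' The CSV holds the time grid and state columns; the sidecar
#' `<path>.json` records the model name, seed, step size and package
#' version.
#'
#' @param traj a `cg_trajectory`.
#' @param path CSV file path.
#' @export
write_trajectory <- function(traj, path) {
  df <- data.frame(t = traj$t)
  uI <- traj$uI
  colnames(uI) <- paste0("uI.", seq_len(ncol(uI)))
  df <- cbind(df, uI)
  if (!is.null(traj$uII)) {
    uII <- traj$uII
    colnames(uII) <- paste0("uII.", seq_len(ncol(uII)))
    df <- cbind(df, uII)
  }
  utils::write.csv(df, path, row.names = FALSE)
  manifest <- list(model = traj$model, seed = traj$seed, dt = traj$dt,
                   n_steps = length(traj$t) - 1L,
                   n_clipped = traj$n_clipped,
                   package_version = as.character(utils::packageVersion("condgauss")))
  jsonlite::write_json(manifest, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path)
  man_path <- paste0(path, ".json")
  man <- if (file.exists(man_path)) jsonlite::read_json(man_path) else list()
  iI <- grep("^uI\\.", names(df)); iII <- grep("^uII\\.", names(df))
  structure(list(t = df$t,
                 uI = as.matrix(df[iI]),
                 uII = if (length(iII)) as.matrix(df[iII]) else NULL,
                 dt = man$dt %||% stats::median(diff(df$t)),
                 seed = man$seed %||% NA_integer_,
                 n_clipped = man$n_clipped %||% 0L,
                 model = man$model %||% "unknown"),
            class = "cg_trajectory")
}

#' Read a model configuration from JSON
#'
#' Configuration format: `{"name": ..., "params": {...}}` with optional
#' `"split"` forwarded as a parameter for models registering more than one
#' observed/hidden split.
#'
#' @param path JSON file path.
#' @return a [cg_model()].
#' @export
read_model_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- as.list(cfg$params %||% list())
  if (!is.null(cfg$split)) args$split <- cfg$split
  do.call(build_model, c(list(cfg$name), args))
}

write_manifest <- function(dir, ...) {
  manifest <- c(list(...),
                list(package_version =
                       as.character(utils::packageVersion("condgauss")),
                     created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}
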