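#' Write a node snapshot to CSV with a JSON metadata sidecar
#'
#' One row per node with columns `id`, `t_created`, `w`, `p_*`, `v_*`,
#' written with 17 significant digits so that a read-back reproduces every
#' double bit-exactly.  The sidecar (same path with a `.json` extension)
#' records the medium's parameters, dimensionality, motor indices, clock
#' and (optionally) the normalization ranges.
#'
#' @param idsm An `idsm` object.
#' @param path CSV file path.
#' @param map Optional [sm_map_new()] normalization map to record.
#' @return `path`, invisibly.
#' @export
write_nodes <- function(idsm, path, map = NULL) {
  df <- idsm_nodes(idsm)
  num <- vapply(df, is.numeric, TRUE) & names(df) != "id"
  df[num] <- lapply(df[num], function(col) sprintf("%.17g", col))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(dim = idsm$dim, motor_idx = idsm$motor_idx,
               params = unclass(idsm$params), t = idsm$t, n_nodes = idsm$n)
  if (!is.null(map)) {
    meta$normalization <- list(names = map$names, raw_min = unname(map$raw_min),
                               raw_max = unname(map$raw_max))
  }
  jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

.sidecar_path <- function(path) {
  if (grepl("\\.csv$", path)) sub("\\.csv$", ".json", path) else paste0(path, ".json")
}

#' Read a node snapshot written by [write_nodes()]
#'
#' @param path CSV file path (the JSON sidecar is read from the matching
#'   `.json` path).
#' @return An `idsm` object with the stored parameters, clock and nodes.
#' @export
read_nodes <- function(path) {
  meta <- jsonlite::read_json(.sidecar_path(path), simplifyVector = TRUE)
  prm <- do.call(idsm_params, lapply(meta$params, as.numeric))
  medium <- idsm_new(dim = meta$dim, motor_idx = meta$motor_idx, params = prm)
  medium$t <- as.numeric(meta$t)
  df <- utils::read.csv(path)
  if (nrow(df)) {
    pcols <- paste0("p_", seq_len(meta$dim))
    vcols <- paste0("v_", seq_len(meta$dim))
    add_nodes(medium, as.matrix(df[pcols]), as.matrix(df[vcols]),
              w = df$w, t_created = df$t_created)
  }
  medium
}

#' Write a trajectory to CSV with a JSON metadata sidecar
#'
#' @param run An `idsm_run` object from [run_experiment()], or a plain
#'   trajectory data frame.
#' @param path CSV file path.
#' @param meta Extra metadata fields to merge into the sidecar.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(run, path, meta = list()) {
  traj <- if (inherits(run, "idsm_run")) run$trajectory else run
  utils::write.csv(traj, path, row.names = FALSE)
  if (inherits(run, "idsm_run")) {
    meta <- c(meta, list(
      experiment = run$config$experiment, seed = run$config$seed,
      params = unclass(run$config$params),
      normalization = list(names = run$map$names,
                           raw_min = unname(run$map$raw_min),
                           raw_max = unname(run$map$raw_max))))
  }
  jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
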