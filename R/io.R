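#' Read a pipeline configuration from YAML
#'
#' Sections `grid`, `optics`, `probe`, `mc` and `cohort` override the
#' corresponding constructor defaults; absent sections fall back to the
#' defaults.
#'
#' @param path Path to a YAML file.
#' @return List with `grid`, `optics`, `probe`, `mc` objects and the raw
#'   `cohort` settings.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  build <- function(fn, args) do.call(fn, as.list(args %||% list()))
  list(grid = build(voxel_grid, cfg$grid),
       optics = build(optical_properties, cfg$optics),
       probe = build(make_probe, cfg$probe),
       mc = build(mc_config, cfg$mc),
       cohort = cfg$cohort %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read averaged correlation curves as CSV
#'
#' Long format with columns `m`, `j`, `tau`, `value` (one row per delay
#' bin per pair).
#'
#' @param frame An [simulate_acquisition()] frame (or named `corr_curve`
#'   list).
#' @param path CSV path.
#' @return `write_curves_csv()` returns `path` invisibly;
#'   `read_curves_csv()` a named list of g1 [corr_curve()]s.
#' @export
write_curves_csv <- function(frame, path) {
  curves <- if (inherits(frame, "acquisition_frame")) frame$curves else frame
  rows <- lapply(curves, function(cv)
    data.frame(m = cv$pair[1], j = cv$pair[2], tau = cv$taus,
               value = cv$values))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curves_csv
#' @export
read_curves_csv <- function(path) {
  df <- utils::read.csv(path)
  out <- list()
  for (key in unique(paste0("m", df$m, "_j", df$j))) {
    sub <- df[paste0("m", df$m, "_j", df$j) == key, ]
    out[[key]] <- corr_curve(sub$tau, sub$value, "g1",
                             pair = c(sub$m[1], sub$j[1]))
  }
  out
}

#' Write / read a cohort feature table as CSV
#'
#' Header: `id`, the 12 feature names in fixed order, `label`.
#'
#' @param df Feature data.frame from [feature_table()].
#' @param path CSV path.
#' @return Path invisibly / the data.frame with `label` as a factor.
#' @export
write_features_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if ("label" %in% names(df))
    df$label <- factor(df$label, levels = c("benign", "malignant"))
  df
}

#' Persist / restore heavyweight pipeline objects
#'
#' Sensitivity tensors, acquisition frames and reconstructed maps are
#' stored as RDS files with a small type tag.
#'
#' @param object The object to store.
#' @param path File path (`.rds`).
#' @return `save_object()` returns `path` invisibly; `load_object()` the
#'   restored object.
#' @export
save_object <- function(object, path) {
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_object
#' @export
load_object <- function(path) readRDS(path)
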