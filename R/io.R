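#' Read or write a design configuration file
#'
#' A design is serialized as a flat YAML or JSON mapping with exactly the keys
#' `alpha`, `beta`, `sigma`, `n_max_per_arm`, `info_interim`,
#' `info_pipeline`, `spending_family`, `design_kind`.  Unknown keys are
#' rejected so that typos cannot silently change a trial plan.  The format is
#' chosen from the file extension (`.yaml`/`.yml` vs `.json`).
#'
#' @param path file to read from / write to.
#' @return `read_design_config()` returns a validated [design_spec()];
#'   `write_design_config()` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' write_design_config(design_spec(info_interim = 0.29, info_pipeline = 0.3,
#'                                 sigma = 7.5, n_max = 345,
#'                                 design_kind = "DR_GSD"), f)
#' read_design_config(f)
#' @export
read_design_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path)
  else yaml::read_yaml(path)
  keys <- c("alpha", "beta", "sigma", "n_max_per_arm", "info_interim",
            "info_pipeline", "spending_family", "design_kind")
  extra <- setdiff(names(cfg), keys)
  if (length(extra))
    stop("unknown config keys: ", paste(extra, collapse = ", "),
         call. = FALSE)
  missing <- setdiff(keys, names(cfg))
  if (length(missing))
    stop("missing config keys: ", paste(missing, collapse = ", "),
         call. = FALSE)
  design_spec(alpha = cfg$alpha, beta = cfg$beta, sigma = cfg$sigma,
              n_max = cfg$n_max_per_arm, info_interim = cfg$info_interim,
              info_pipeline = cfg$info_pipeline,
              spending_family = cfg$spending_family,
              design_kind = cfg$design_kind)
}

#' @rdname read_design_config
#' @param spec a [design_spec()] (or fitted [drgsd()] object).
#' @export
write_design_config <- function(spec, path) {
  spec <- as_spec(spec)
  cfg <- list(alpha = spec$alpha, beta = spec$beta, sigma = spec$sigma,
              n_max_per_arm = spec$n_max, info_interim = spec$info_interim,
              info_pipeline = spec$info_pipeline,
              spending_family = spec$spending_family,
              design_kind = spec$design_kind)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Serialize solved boundaries to JSON records
#'
#' One record per design with fields `design`, `l1`, `u1`, `d1`, `d2`,
#' `alpha1`, `beta1`, `delta_tilde`, at full precision.
#'
#' @param ... fitted [drgsd()] objects (or a single list of them).
#' @param path optional file; if omitted the JSON string is returned.
#' @return JSON string (invisibly, when written to `path`).
#' @export
boundaries_json <- function(..., path = NULL) {
  fits <- list(...)
  if (length(fits) == 1L && !inherits(fits[[1L]], "drgsd"))
    fits <- fits[[1L]]
  stopifnot(all(vapply(fits, inherits, logical(1), "drgsd")))
  tab <- do.call(rbind, lapply(fits, function(f) {
    d <- as.data.frame(f)
    d[, c("design", "l1", "u1", "d1", "d2", "alpha1", "beta1", "delta_tilde")]
  }))
  js <- jsonlite::toJSON(tab, dataframe = "rows", na = "null", digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
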