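#' Load a scenario configuration
#'
#' Reads a YAML (or JSON) scenario file holding model parameters under
#' their ASCII names (`rho_max`, `alpha_max`, `b`, `K_B`, `r`, `h`,
#' `I_in`, `k`, `l`, `m_rho`, `m_alpha`, `T0_rho`, `T0_alpha`, `z`,
#' `thermal_response`) plus optional analysis settings under `analysis:`
#' (`T_min`, `T_max`, `T_step`, `grid_n`, `reference_T`, `theta_init`).
#' Missing parameters take the canonical defaults, except the trade-off
#' shape `z`, which must be given explicitly. Unknown keys are rejected
#' with a message listing them.
#'
#' @param path path to the scenario file.
#' @return An object of class `mixo_scenario`: list with elements `params`
#'   (a [mixo_params()] object) and `analysis` (named list of settings).
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("scenario file must contain a key-value mapping")

  analysis_defaults <- list(T_min = 13, T_max = 33, T_step = 1,
                            grid_n = 101, reference_T = 13,
                            theta_init = 0.5)
  an_raw <- raw$analysis
  raw$analysis <- NULL

  unknown <- setdiff(names(raw), PARAM_KEYS)
  if (length(unknown)) {
    stop("unknown scenario keys: ", paste(unknown, collapse = ", "),
         "\n  admissible parameter keys: ", paste(PARAM_KEYS, collapse = ", "))
  }
  if (!"z" %in% names(raw)) {
    stop("scenario must set 'z' explicitly: there is no default trade-off shape")
  }
  # YAML leaves exponent forms like "3.0e8" as strings; coerce numerics
  for (nm in setdiff(names(raw), "thermal_response")) {
    v <- suppressWarnings(as.numeric(raw[[nm]]))
    if (!is.na(v)) raw[[nm]] <- v
  }
  params <- do.call(mixo_params, raw)

  analysis <- analysis_defaults
  if (!is.null(an_raw)) {
    bad <- setdiff(names(an_raw), names(analysis_defaults))
    if (length(bad)) {
      stop("unknown analysis keys: ", paste(bad, collapse = ", "),
           "\n  admissible analysis keys: ",
           paste(names(analysis_defaults), collapse = ", "))
    }
    analysis[names(an_raw)] <- lapply(an_raw, function(v) {
      if (is.character(v)) {
        vn <- suppressWarnings(as.numeric(v))
        if (!is.na(vn)) vn else v
      } else if (is.numeric(v)) as.numeric(v) else v
    })
  }
  if (analysis$T_step <= 0 || analysis$T_max < analysis$T_min) {
    stop("analysis temperature grid must be well-ordered with positive step")
  }
  if (analysis$grid_n < 3) stop("analysis 'grid_n' must be >= 3")
  analysis$T_grid <- seq(analysis$T_min, analysis$T_max,
                         by = analysis$T_step)
  structure(list(params = params, analysis = analysis),
            class = "mixo_scenario")
}

#' Write result tables deterministically
#'
#' Writes a data.frame as RFC-4180 CSV or JSON lines with a fixed column
#' order and floating-point values at 12 significant digits, so repeated
#' runs of the deterministic pipeline diff clean.
#'
#' @param records a data.frame (may have zero rows: a header-only CSV is
#'   written).
#' @param path output file path.
#' @param format `"csv"` or `"jsonl"`.
#' @return Invisibly, `path`.
#' @export
write_table <- function(records, path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  if (!is.data.frame(records)) stop("'records' must be a data.frame")
  fmt <- records
  num <- vapply(fmt, is.numeric, logical(1))
  fmt[num] <- lapply(fmt[num], function(v) sprintf("%.12g", v))
  if (format == "csv") {
    utils::write.csv(fmt, path, row.names = FALSE, quote = TRUE)
  } else {
    con <- file(path, open = "wt")
    on.exit(close(con))
    for (i in seq_len(nrow(fmt))) {
      writeLines(jsonlite::toJSON(as.list(fmt[i, , drop = FALSE]),
                                  auto_unbox = TRUE), con)
    }
  }
  invisible(path)
}

#' Write the canonical scenario fixtures
#'
#' Emits the three canonical scenario YAML files (specialist `z = -1`,
#' linear `z = 0`, generalist `z = 1`; `K_B = 1e8`, `I_in = 100`) into a
#' directory.
#'
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_canonical_scenarios <- function(dir = ".") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  shapes <- c(specialist = -1, linear = 0, generalist = 1)
  paths <- character(0)
  for (nm in names(shapes)) {
    p <- canonical_params(nm)
    cfg <- unclass(p)
    cfg$analysis <- list(T_min = 13, T_max = 33, T_step = 1, grid_n = 101,
                         reference_T = 13, theta_init = 0.5)
    out <- file.path(dir, paste0(nm, ".yaml"))
    yaml::write_yaml(cfg, out, precision = 12)
    paths <- c(paths, out)
  }
  invisible(paths)
}
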