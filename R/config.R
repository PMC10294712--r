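# Flat key/value run configuration ("key: value" lines, YAML-ish dialect).
# Unknown keys are rejected exhaustively so typos cannot silently change a
# run. The imputation/normalization/balancing hooks of the subsampling
# protocol are present as explicit disabled stages: only "none" is accepted.

CONFIG_KEYS <- c(
  "grid.dims", "grid.voxel_mm", "grid.full_scale",
  "cohort.tracer",
  "effects.delta_bpnd", "effects.n_effect_voxels", "effects.phase_effect",
  "effects.noise_sd", "effects.smoothing_fwhm_mm", "effects.baseline_rich",
  "effects.baseline_grey",
  "wrangle.mask", "wrangle.threshold", "wrangle.consistency",
  "wrangle.interictal_only",
  "cbda.m", "cbda.csr", "cbda.fsr", "cbda.top_fraction", "cbda.k",
  "cbda.replications", "cbda.library", "cbda.v",
  "cbda.impute", "cbda.normalize", "cbda.balance",
  "seed"
)

CONFIG_DEFAULTS <- list(
  "grid.full_scale" = FALSE,
  "cohort.tracer" = "CFN",
  "effects.delta_bpnd" = 0.5,
  "effects.n_effect_voxels" = 20L,
  "effects.phase_effect" = 0.1,
  "effects.noise_sd" = 0.3,
  "effects.smoothing_fwhm_mm" = 3,
  "effects.baseline_rich" = 2.5,
  "effects.baseline_grey" = 1.3,
  "wrangle.mask" = "grey",
  "wrangle.threshold" = 2.0,
  "wrangle.consistency" = 0.8,
  "wrangle.interictal_only" = FALSE,
  "cbda.m" = 100L,
  "cbda.csr" = "all",
  "cbda.fsr" = 20L,
  "cbda.top_fraction" = 0.05,
  "cbda.k" = 50L,
  "cbda.replications" = 5L,
  "cbda.library" = "glm,lasso,knn",
  "cbda.v" = 10L,
  "cbda.impute" = "none",
  "cbda.normalize" = "none",
  "cbda.balance" = "none",
  "seed" = 1L
)

parse_config_value <- function(v) {
  v <- trimws(v)
  if (toupper(v) %in% c("TRUE", "YES")) return(TRUE)
  if (toupper(v) %in% c("FALSE", "NO")) return(FALSE)
  if (grepl("^-?[0-9.eE+,-]+$", v) &&
      !is.na(suppressWarnings(as.numeric(strsplit(v, ",")[[1]][1])))) {
    num <- suppressWarnings(as.numeric(strsplit(v, ",")[[1]]))
    if (!anyNA(num)) return(num)
  }
  v
}

#' Read a flat key/value run configuration
#'
#' Lines of the form `key: value`; `#` starts a comment; blank lines are
#' ignored. Numbers and comma-separated number lists are parsed as numeric
#' vectors; `true`/`false` as logicals. Unknown keys are an error listing
#' every offender; missing keys take documented defaults.
#'
#' @param path config file path.
#' @return named list of class `run_config` covering every known key.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("read_config: no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- CONFIG_DEFAULTS
  bad <- character(0)
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) != 3) {
      bad <- c(bad, paste0("unparseable line: '", ln, "'"))
      next
    }
    key <- m[2]
    if (!(key %in% CONFIG_KEYS)) {
      bad <- c(bad, paste0("unknown key: '", key, "'"))
      next
    }
    cfg[[key]] <- parse_config_value(m[3])
  }
  for (hook in c("cbda.impute", "cbda.normalize", "cbda.balance")) {
    if (!identical(cfg[[hook]], "none")) {
      bad <- c(bad, paste0(hook, ": only 'none' is supported (got '",
                           cfg[[hook]], "')"))
    }
  }
  if (length(bad) > 0) {
    stop("read_config: invalid configuration:\n  ",
         paste(bad, collapse = "\n  "))
  }
  structure(cfg, class = "run_config")
}

#' Write a configuration echo
#' @param cfg a `run_config` (or plain named list).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  lines <- vapply(names(cfg), function(k) {
    sprintf("%s: %s", k, paste(format(cfg[[k]], scientific = FALSE),
                               collapse = ","))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

config_grid <- function(cfg) {
  if (isTRUE(cfg[["grid.full_scale"]])) return(default_grid(TRUE))
  if (is.null(cfg[["grid.dims"]])) return(default_grid(FALSE))
  brain_grid(cfg[["grid.dims"]], cfg[["grid.voxel_mm"]] %||% c(4, 4, 4))
}
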