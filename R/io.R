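# Recognized configuration keys and their defaults. Protocol defaults are the
# full long-run protocol (256 x 256 lattice, 5000 transient + 250 averaging).
.config_defaults <- function() {
  list(
    delta = 0.1, e = 0, c = 0, alpha = 1, r_col = 1, r_con = NULL,
    competition = FALSE, fraction_nc = 0.5,
    L = 256, t_transient = 5000, t_avg = 250, t_max = NULL, sample_dt = 1,
    replicates = 1, seed = 1, out_dir = "."
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML or JSON configuration file (dispatching on the file
#' extension), rejects unknown keys, validates every field and fills in the
#' protocol defaults (`L = 256`, `t_transient = 5000`, `t_avg = 250`,
#' `r_col = 1`, ...). An empty file yields the full default protocol.
#' `r_con` defaults to `r_col`; the string `"global"` (or `.inf` in YAML)
#' selects global construction. `t_max` defaults to
#' `t_transient + t_avg`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return A validated `run_config` object: list with `params`
#'   (a [model_params()]), `protocol` (`L`, `t_transient`, `t_avg`, `t_max`,
#'   `sample_dt`, `replicates`, `fraction_nc`), `seed` and `out_dir`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required for YAML configs")
    }
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported config format '.", ext, "' (use .yaml or .json)")
  }
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config must be a key: value mapping")
  defaults <- .config_defaults()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- modifyList(defaults, raw, keep.null = TRUE)
  if (is.null(cfg$r_con)) cfg$r_con <- cfg$r_col
  if (identical(cfg$r_con, "global")) cfg$r_con <- Inf
  if (is.null(cfg$t_max)) cfg$t_max <- cfg$t_transient + cfg$t_avg

  check_num <- function(field, lo = 0, hi = Inf, integer = FALSE) {
    x <- cfg[[field]]
    ok <- length(x) == 1 && is.numeric(x) && !is.na(x) && x >= lo && x <= hi &&
      (!integer || is.infinite(x) || x == round(x))
    if (!ok) {
      stop(sprintf(
        "config field '%s' = %s is invalid (need %s in [%s, %s])",
        field, format(cfg[[field]]), if (integer) "an integer" else "a number",
        format(lo), format(hi)
      ))
    }
  }
  check_num("delta")
  check_num("e")
  check_num("c", 0, 1)
  check_num("alpha")
  check_num("r_col", 1, integer = TRUE)
  check_num("r_con", 1, integer = TRUE)
  check_num("fraction_nc", 0, 1)
  check_num("L", 4, integer = TRUE)
  check_num("t_transient", 0)
  check_num("t_avg", 0)
  check_num("t_max", 1e-12)
  check_num("sample_dt", 1e-12)
  check_num("replicates", 1, integer = TRUE)
  check_num("seed", 1, 2^31 - 1, integer = TRUE)
  if (!isTRUE(cfg$competition) && !isFALSE(cfg$competition)) {
    stop("config field 'competition' must be true or false")
  }
  if (!is.character(cfg$out_dir) || length(cfg$out_dir) != 1) {
    stop("config field 'out_dir' must be a single path")
  }

  structure(
    list(
      params = model_params(
        delta = cfg$delta, e = cfg$e, c = cfg$c, alpha = cfg$alpha,
        r_col = cfg$r_col, r_con = cfg$r_con, competition = cfg$competition
      ),
      protocol = list(
        L = as.integer(cfg$L), t_transient = cfg$t_transient,
        t_avg = cfg$t_avg, t_max = cfg$t_max, sample_dt = cfg$sample_dt,
        replicates = as.integer(cfg$replicates), fraction_nc = cfg$fraction_nc
      ),
      seed = as.integer(cfg$seed),
      out_dir = cfg$out_dir
    ),
    class = "run_config"
  )
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf(
    "<run_config> %s  L=%d  t=[%g + %g]  seed=%d  out=%s\n",
    format(x$params), x$protocol$L, x$protocol$t_transient, x$protocol$t_avg,
    x$seed, x$out_dir
  ))
  invisible(x)
}

#' Write a reproducibility manifest
#'
#' Records everything needed to reproduce and audit a run in a JSON manifest:
#' the full parameter set and protocol, the seed, wall-clock timing, event
#' tallies, the list of output files with their MD5 checksums, and a
#' completion flag. [read_manifest()] round-trips it.
#'
#' @param config A `run_config` (or any list with `params`, `protocol`,
#'   `seed`).
#' @param results Named list of summary results (event counts, occupancies,
#'   timings...); anything `jsonlite` can serialize.
#' @param path Output path for the JSON manifest.
#' @param files Character vector of produced output files to checksum.
#' @param complete Whether the run finished normally; aborted runs are
#'   flagged `incomplete`.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, results = list(), path, files = character(),
                           complete = TRUE) {
  params <- config$params
  manifest <- list(
    package = "nichesim",
    version = as.character(utils::packageVersion("nichesim")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    complete = isTRUE(complete),
    params = list(
      delta = params$delta, e = params$e, c = params$c, alpha = params$alpha,
      r_col = params$r_col,
      r_con = if (is.infinite(params$r_con)) "global" else params$r_con,
      competition = params$competition
    ),
    protocol = config$protocol,
    seed = config$seed,
    results = results,
    files = if (length(files)) {
      data.frame(
        path = files,
        md5 = unname(tools::md5sum(files)),
        stringsAsFactors = FALSE
      )
    } else {
      NULL
    }
  )
  jsonlite::write_json(manifest, path,
    auto_unbox = TRUE, digits = NA,
    null = "null", pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
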