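#' Read an age-indexed curve from CSV
#'
#' Reads a two-column CSV (`age,value`, or `age,p` for prevalence curves;
#' comma-separated, dot decimal, UTF-8, header mandatory) and validates it:
#' ages strictly increasing, all cells finite numbers. Parse failures report
#' the offending line number.
#'
#' @param path Path to the CSV file.
#' @return A tibble with columns `age` and `value`.
#' @seealso [write_curve_csv()]
#' @export
read_curve_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("File not found: %s", path), call. = FALSE)
  raw <- utils::read.csv(path, header = TRUE, colClasses = "character",
                         fileEncoding = "UTF-8", strip.white = TRUE)
  if (ncol(raw) < 2L || names(raw)[1L] != "age" ||
      !(names(raw)[2L] %in% c("value", "p"))) {
    stop(sprintf("%s: expected header `age,value` (or `age,p`).", path),
         call. = FALSE)
  }
  parse_col <- function(x, col) {
    v <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad)) {
      stop(sprintf("%s: non-numeric `%s` on line %d.", path, col, bad[1L] + 1L),
           call. = FALSE)
    }
    v
  }
  age <- parse_col(raw[[1L]], "age")
  value <- parse_col(raw[[2L]], names(raw)[2L])
  dup <- which(duplicated(age))
  if (length(dup)) {
    stop(sprintf("%s: duplicated age on line %d.", path, dup[1L] + 1L),
         call. = FALSE)
  }
  nonmono <- which(diff(age) <= 0)
  if (length(nonmono)) {
    stop(sprintf("%s: ages not strictly increasing at line %d.",
                 path, nonmono[1L] + 2L), call. = FALSE)
  }
  tibble::tibble(age = age, value = value)
}

#' Write an age-indexed curve to CSV
#'
#' Writes with the fixed dialect (comma, dot decimal, UTF-8, header) at 15
#' significant digits, so that a write/read round trip reproduces values to
#' within 1e-12.
#'
#' @param x A data frame whose first column is `age`; remaining columns are
#'   written as-is (e.g. `p`, or `S`, `C`, `N`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(x, path) {
  stopifnot(is.data.frame(x), names(x)[1L] == "age")
  fmt <- as.data.frame(lapply(x, function(col) {
    if (is.numeric(col)) formatC(col, digits = 15, format = "g") else as.character(col)
  }))
  names(fmt) <- names(x)
  utils::write.csv(fmt, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

signif_chr <- function(x) formatC(x, digits = 10, format = "g")

# Build a rate_fn from a CLI/config specification: either a path to a CSV
# rate table or a "gompertz:beta0,beta1" string.
rate_from_spec <- function(spec, domain, what = "rate") {
  if (is_rate_fn(spec)) return(spec)
  if (is.list(spec) && !is.null(spec$beta0)) {
    return(gompertz_rate(as.numeric(spec$beta0), as.numeric(spec$beta1), domain))
  }
  if (is.character(spec) && length(spec) == 1L) {
    if (grepl("^gompertz:", spec)) {
      coef <- as.numeric(strsplit(sub("^gompertz:", "", spec), ",")[[1L]])
      if (length(coef) != 2L || anyNA(coef)) {
        stop(sprintf("Malformed Gompertz spec for %s: %s (want gompertz:beta0,beta1).",
                     what, spec), call. = FALSE)
      }
      return(gompertz_rate(coef[1L], coef[2L], domain))
    }
    if (grepl("^const:", spec)) {
      return(constant_rate(as.numeric(sub("^const:", "", spec)), domain))
    }
    tab <- read_curve_csv(spec)
    return(tabulated_rate(tibble::tibble(age = tab$age, value = tab$value), domain))
  }
  stop(sprintf("Cannot interpret the %s specification.", what), call. = FALSE)
}

#' Validate and resolve a run configuration
#'
#' Takes a flat named list (parsed from a YAML config file and/or CLI
#' flags), applies defaults, checks consistency (known mortality tag, the
#' tag's required components present and no extras, `p0` in `[0, 1]`), and
#' returns the resolved configuration with the constructed [age_domain()]
#' and [mortality_input()].
#'
#' Recognised keys: `a0`, `omega`, `step` (domain; defaults 0, 100, 0.1),
#' `tag`, `m`, `m0`, `m1`, `R` (mortality; rate specs are CSV paths,
#' `gompertz:beta0,beta1` or `const:value` strings), `incidence` (rate
#' spec), `p0` (default 0), `rtol`/`atol` (defaults 1e-8/1e-10), `seed`,
#' `n0`, `derivative` (`central`/`spline`), `spar`.
#'
#' @param raw A named list of raw settings.
#' @return A list of class `run_config` with resolved components.
#' @export
validate_config <- function(raw) {
  stopifnot(is.list(raw))
  known <- c("a0", "omega", "step", "tag", "m", "m0", "m1", "R", "incidence",
             "p0", "rtol", "atol", "seed", "n0", "derivative", "spar",
             "epsilon", "n", "noise_sd_scale", "out", "prevalence", "mortality")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop(sprintf("Unknown configuration key(s): %s.",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  num <- function(key, default) {
    if (is.null(raw[[key]])) default else as.numeric(raw[[key]])
  }
  cfg <- list(
    a0 = num("a0", 0), omega = num("omega", 100), step = num("step", 0.1),
    p0 = num("p0", 0), rtol = num("rtol", 1e-8), atol = num("atol", 1e-10),
    seed = if (is.null(raw$seed)) NULL else as.integer(raw$seed),
    n0 = if (is.null(raw$n0)) 1e5 else as.numeric(raw$n0),
    derivative = if (is.null(raw$derivative)) "central" else
      match.arg(raw$derivative, c("central", "spline")),
    spar = if (is.null(raw$spar)) NULL else as.numeric(raw$spar),
    out = raw$out)
  if (cfg$p0 < 0 || cfg$p0 > 1) {
    stop("`p0` must lie in [0, 1].", call. = FALSE)
  }
  cfg$domain <- age_domain(cfg$a0, cfg$omega, cfg$step)
  if (!is.null(raw$incidence)) {
    cfg$incidence <- rate_from_spec(raw$incidence, cfg$domain, "incidence")
  }
  if (!is.null(raw$tag)) {
    tag <- match.arg(raw$tag, MORTALITY_TAGS)
    comp <- list()
    for (nm in c("m", "m0", "m1")) {
      if (!is.null(raw[[nm]])) comp[[nm]] <- rate_from_spec(raw[[nm]], cfg$domain, nm)
    }
    if (!is.null(raw$R)) {
      comp$R <- if (is.character(raw$R) && !grepl("^[0-9.eE+-]+$", raw$R)) {
        rate_from_spec(raw$R, cfg$domain, "R")
      } else {
        as.numeric(raw$R)
      }
    }
    cfg$mortality <- do.call(mortality_input,
                             c(list(tag = tag, domain = cfg$domain), comp))
  }
  structure(cfg, class = "run_config")
}
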