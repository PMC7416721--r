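#' Build a validated run configuration
#'
#' Gathers every knob of a Monte Carlo sweep in one object with the study
#' defaults filled in: significance levels 0.05 and 0.20, 10,000
#' replicates per scenario, all three estimators, the full factorial grid
#' and the `map` EM variant.
#'
#' @param seed Master integer seed.
#' @param grid A [scenario_grid_config()] or the string `"default"`.
#' @param approaches Subset of `c("unregularized", "normal", "cauchy")`.
#' @param alphas Significance levels in (0, 1).
#' @param n_reps Replicates per scenario (>= 1).
#' @param em_variant `"map"` (default) or `"with_variance"`.
#' @param xi Skeptical tail probability of the Cauchy prior.
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(seed = 1L, grid = "default",
                       approaches = c("unregularized", "normal",
                                      "cauchy"),
                       alphas = c(0.05, 0.20), n_reps = 10000L,
                       em_variant = "map", xi = 0.025) {
  if (identical(grid, "default")) grid <- default_grid_config()
  stopifnot(inherits(grid, "scenario_grid_config"))
  bad <- setdiff(approaches, c("unregularized", "normal", "cauchy"))
  if (length(bad))
    stop("unknown approaches: ", paste(bad, collapse = ", "))
  if (length(alphas) == 0 || any(alphas <= 0) || any(alphas >= 1))
    stop("field 'alphas' must lie in (0, 1)")
  if (!is.numeric(n_reps) || n_reps < 1)
    stop("field 'n_reps' must be a positive integer")
  if (!em_variant %in% c("map", "with_variance"))
    stop("field 'em_variant' must be 'with_variance' or 'map'")
  if (xi <= 0 || xi >= 0.5) stop("field 'xi' must be in (0, 0.5)")
  seed <- as.integer(seed)
  if (is.na(seed)) stop("field 'seed' must be an integer")
  structure(list(seed = seed, grid = grid, approaches = approaches,
                 alphas = as.numeric(alphas),
                 n_reps = as.integer(n_reps), em_variant = em_variant,
                 xi = xi),
            class = "run_config")
}

#' Parse a YAML run configuration
#'
#' Reads a YAML file with any subset of the keys `seed`, `T_values`,
#' `r_values`, `cv_settings` (list of two-element lower/upper pairs),
#' `approaches`, `alphas`, `n_reps`, `em_variant`, `xi`. Missing keys
#' take the study defaults; unknown keys are an error (listed by name),
#' as are out-of-range values. An empty file yields the full default
#' configuration.
#'
#' @param path Path to the YAML file.
#' @return A validated [run_config()].
#' @export
parse_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("seed", "T_values", "r_values", "cv_settings", "approaches",
             "alphas", "n_reps", "em_variant", "xi")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  grid_keys <- intersect(c("T_values", "r_values", "cv_settings"),
                         names(raw))
  if (length(grid_keys) == 0) {
    grid <- "default"
  } else {
    dg <- default_grid_config()
    cvs <- if ("cv_settings" %in% grid_keys)
      lapply(raw$cv_settings, unlist) else dg$cv_settings
    grid <- scenario_grid_config(
      T_values = if ("T_values" %in% grid_keys) raw$T_values else
        dg$T_values,
      r_values = if ("r_values" %in% grid_keys) raw$r_values else
        dg$r_values,
      cv_settings = cvs)
  }
  args <- raw[setdiff(names(raw), grid_keys)]
  args$grid <- grid
  do.call(run_config, args)
}

#' Serialize a run configuration to YAML
#'
#' Round-trips losslessly through [parse_config()].
#'
#' @param config A [run_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(
    list(seed = config$seed,
         T_values = as.integer(config$grid$T_values),
         r_values = config$grid$r_values,
         cv_settings = lapply(config$grid$cv_settings, as.numeric),
         approaches = config$approaches, alphas = config$alphas,
         n_reps = config$n_reps, em_variant = config$em_variant,
         xi = config$xi),
    path)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  g <- x$grid
  cat(sprintf(
    paste0("Run config: seed %d, %d scenarios ",
           "(%d T x %d r x %d cv), approaches {%s},\n",
           "  alphas {%s}, %d reps, em_variant %s, xi %g\n"),
    x$seed,
    length(g$T_values) * length(g$r_values) * length(g$cv_settings),
    length(g$T_values), length(g$r_values), length(g$cv_settings),
    paste(x$approaches, collapse = ", "),
    paste(x$alphas, collapse = ", "), x$n_reps, x$em_variant, x$xi))
  invisible(x)
}
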