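# Run configuration: one JSON document describing a full pipeline run.
# Unknown keys are rejected at every level so that typos fail loudly.

.check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  .assert(length(extra) == 0,
          sprintf("unknown key(s) in %s: %s", where,
                  paste(extra, collapse = ", ")))
}

#' Build a validated run configuration
#'
#' @param config a named list (e.g. parsed from JSON) with optional keys
#'   `n_knees`, `seed`, `outdir`, `render`, `write_maps`, `layers`,
#'   `phantom` (arguments of [phantom_spec()]), `progression` (arguments of
#'   [progression_model()]; multiplier lists are named lists keyed KL2/KL3),
#'   `fit` (`exclude_first`, `quantile_type`), `voi` (`ap_fractions`,
#'   `ml_fractions`), `stats` (`alpha`, `bonferroni_alpha`, `gate`,
#'   `gate_reject_frac`, `exact_cutoff`). Unknown keys are rejected.
#' @return an object of class `run_config`.
#' @export
run_config <- function(config = list()) {
  .check_keys(config, c("n_knees", "seed", "outdir", "render", "write_maps",
                        "layers", "phantom", "progression", "fit", "voi",
                        "stats"), "config")
  ph <- config$phantom %||% list()
  .check_keys(ph, names(formals(phantom_spec)), "config$phantom")
  pr <- config$progression %||% list()
  .check_keys(pr, names(formals(progression_model)), "config$progression")
  fit <- config$fit %||% list()
  .check_keys(fit, c("exclude_first", "quantile_type"), "config$fit")
  voi <- config$voi %||% list()
  .check_keys(voi, c("ap_fractions", "ml_fractions"), "config$voi")
  st <- config$stats %||% list()
  .check_keys(st, c("alpha", "bonferroni_alpha", "gate", "gate_reject_frac",
                    "exact_cutoff"), "config$stats")

  seed <- as.integer(config$seed %||% 1L)
  ph$seed <- ph$seed %||% seed
  spec <- do.call(phantom_spec, ph)
  # multiplier lists arrive from JSON as named lists of named lists/numbers
  fix_mult <- function(m) {
    if (is.null(m)) return(NULL)
    lapply(m, function(x) if (is.null(x)) NULL else unlist(x))
  }
  if (!is.null(pr$t2_mult)) pr$t2_mult <- fix_mult(pr$t2_mult)
  if (!is.null(pr$th_mult)) pr$th_mult <- fix_mult(pr$th_mult)
  model <- do.call(progression_model, pr)

  structure(list(
    n_knees = as.integer(config$n_knees %||% 19L),
    seed = seed,
    outdir = config$outdir %||% NULL,
    render = isTRUE(config$render %||% TRUE),
    write_maps = isTRUE(config$write_maps %||% FALSE),
    layers = isTRUE(config$layers %||% TRUE),
    spec = spec, model = model,
    fit = list(exclude_first = isTRUE(fit$exclude_first %||% TRUE),
               quantile_type = as.integer(fit$quantile_type %||% 7L)),
    voi = list(ap_fractions = as.numeric(voi$ap_fractions %||% c(1, 2) / 3),
               ml_fractions = as.numeric(voi$ml_fractions %||% c(1, 2) / 3)),
    stats = list(alpha = st$alpha %||% 0.05,
                 bonferroni_alpha = st$bonferroni_alpha %||% 0.017,
                 gate = st$gate %||% "auto",
                 gate_reject_frac = st$gate_reject_frac %||% 0.2,
                 exact_cutoff = as.integer(st$exact_cutoff %||% 25L)),
    raw = config
  ), class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname run_config
#' @param path path to a JSON configuration document.
#' @export
read_run_config <- function(path) {
  .assert(file.exists(path), paste("file not found:", path))
  run_config(jsonlite::read_json(path, simplifyVector = TRUE))
}
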