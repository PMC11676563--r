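# Run configuration: YAML file + command-line overrides, with stage seeds
# fanned out from one global seed.

.default_run_config <- function() {
  list(
    data = list(numeric_vars = default_numeric_vars(), min_count = 5),
    timeline = list(window_weeks = 52, n_periods = 10),
    model = list(embed_dim = 16, hidden = 16, ff_dim = 32),
    train = list(lr = 3e-3, batch = 32, epochs = 20, anneal_epochs = 10,
                 sg_window = 5, sg_negatives = 5, sg_epochs = 3,
                 sg_lr = 0.025),
    eval = list(folds = 10, boots = 10, frac = 0.9,
                specificity_floor = 0.75),
    seed = 1
  )
}

.merge_config <- function(base, override) {
  for (nm in names(override)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      .merge_config(base[[nm]], override[[nm]])
    } else {
      override[[nm]]
    }
  }
  base
}

#' Read a run configuration
#'
#' YAML with sections `data`, `timeline`, `model`, `train`, `eval` plus a
#' global `seed`; missing entries fall back to the package defaults.
#'
#' @param path Optional YAML path; `NULL` returns the defaults.
#' @return Nested configuration list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- .default_run_config()
  if (!is.null(path)) {
    cfg <- .merge_config(cfg, yaml::read_yaml(path))
  }
  cfg
}

#' Stage seed derived from the global seed
#'
#' Fans one global seed out to independent per-stage seeds (simulate,
#' pretrain, train, ...) through a splittable linear counter, so each stage
#' is individually reproducible.
#'
#' @param seed Global integer seed.
#' @param stage Stage name.
#' @return Integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  stages <- c(simulate = 1L, pretrain = 2L, init = 3L, train = 4L,
              evaluate = 5L, rank = 6L, baseline = 7L, split = 8L)
  k <- stages[[stage]]
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483647)
}
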