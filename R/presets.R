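#' Resolve a named hyperparameter preset for the iterative search
#'
#' Benchmark settings for the iterative coordinate search.  Each preset
#' fixes gridsize, epochs and the three refinement periods, and enables
#' exactly the mechanisms it is meant to exercise: the plain preset runs
#' bare coordinate descent, \code{Shift}/\code{Shuffle}/\code{Finer} each
#' enable a single mechanism, and the \code{Combined} presets enable all
#' three.
#'
#' \tabular{lccccc}{
#'   \strong{Name} \tab gridsize \tab epochs \tab shift \tab shuffle \tab finer \cr
#'   Iterative grid search \tab 11 \tab 4 \tab 4 \tab 4 \tab 4 \cr
#'   Shift \tab 11 \tab 8 \tab 4 \tab 8 \tab 8 \cr
#'   Shuffle \tab 11 \tab 8 \tab 8 \tab 2 \tab 8 \cr
#'   Finer \tab 11 \tab 8 \tab 8 \tab 8 \tab 4 \cr
#'   Combined 1 \tab 11 \tab 16 \tab 8 \tab 2 \tab 4 \cr
#'   Combined 2 \tab 21 \tab 16 \tab 8 \tab 2 \tab 4
#' }
#'
#' @param name preset name (see table).
#' @param seed seed stored in the returned configuration.
#' @param start_policy initial-point rule (default \code{"mle"}).
#' @return a \code{"bcx_config"}.
#' @export
resolve_preset <- function(name, seed = 42L, start_policy = "mle") {
  presets <- list(
    `Iterative grid search` = list(11L, 4L, 4L, 4L, 4L, FALSE, FALSE, FALSE),
    `Shift`      = list(11L, 8L, 4L, 8L, 8L, TRUE, FALSE, FALSE),
    `Shuffle`    = list(11L, 8L, 8L, 2L, 8L, FALSE, TRUE, FALSE),
    `Finer`      = list(11L, 8L, 8L, 8L, 4L, FALSE, FALSE, TRUE),
    `Combined 1` = list(11L, 16L, 8L, 2L, 4L, TRUE, TRUE, TRUE),
    `Combined 2` = list(21L, 16L, 8L, 2L, 4L, TRUE, TRUE, TRUE)
  )
  if (!name %in% names(presets)) {
    stop(sprintf("unknown preset '%s'; valid presets: %s", name,
                 paste(names(presets), collapse = ", ")))
  }
  p <- presets[[name]]
  optimizer_config(
    gridsize = p[[1L]], epochs = p[[2L]], shift_epoch = p[[3L]],
    shuffle_epoch = p[[4L]], finer_epoch = p[[5L]],
    use_shift = p[[6L]], use_shuffle = p[[7L]], use_finer = p[[8L]],
    start_policy = start_policy, seed = seed
  )
}
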