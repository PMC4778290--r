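## Deterministic reduced-scale instances for tests and examples. Particle
## counts follow the N_par ~ 37 * M_dim scaling with proportional central
## and corner counts, so a small lobule is a scaled copy of the reference
## recipe, not a different morphology class.

#' Build a deterministic fixture instance
#'
#' Scales: `"tiny"` (M_dim = 32), `"small"` (M_dim = 64) and `"paper"`
#' (M_dim = 256, the reference size). Returns a built 2D morphology, its
#' property fields and a solved flow; optionally writes the morphology
#' container, port-rate CSV and the config used.
#'
#' @param scale `"tiny"`, `"small"` or `"paper"`.
#' @param seed Master seed.
#' @param delta_p_Pa Pressure drop for the bundled flow solve (default 10).
#' @param dir Optional output directory for container files.
#' @return List with `morph`, `props`, `flow`, `recipe` and (when `dir` is
#'   given) `files`.
#' @export
#' @examples
#' fx <- make_fixture("tiny", seed = 3)
#' fx$flow$total_inflow_cm3_min
make_fixture <- function(scale = c("tiny", "small", "paper"), seed = 1L,
                         delta_p_Pa = 10, dir = NULL) {
  scale <- match.arg(scale)
  M <- switch(scale, tiny = 32L, small = 64L, paper = 256L)
  recipe <- dla_recipe(M_dim = M, seed = as.integer(seed))
  morph <- build_lobule_2d(recipe)
  props <- assign_properties(morph)
  flow <- solve_pressure(props, well_config(delta_p_Pa = delta_p_Pa))
  out <- list(morph = morph, props = props, flow = flow, recipe = recipe)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    fm <- file.path(dir, sprintf("morph2d_%s.txt", scale))
    write_morphology(morph, fm)
    fr <- file.path(dir, "port_rates.csv")
    utils::write.csv(port_flow_rates(flow), fr, row.names = FALSE,
                     quote = FALSE)
    fc <- file.path(dir, "config.yaml")
    yaml::write_yaml(list(scale = scale, seed = as.integer(seed),
                          delta_p_Pa = delta_p_Pa,
                          recipe = unclass(recipe)), fc)
    out$files <- c(morphology = fm, port_rates = fr, config = fc)
  }
  out
}
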