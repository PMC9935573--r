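# Shared fixtures, built once per test run and memoised.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

tube_phantom <- function(radius = 3, depth = NULL, noise_sd = 0, seed = 1,
                         width = 2, spacing = 0.6, length = 30, axis = "z") {
  st <- if (is.null(depth)) NULL else
    data.frame(position = 0.5, depth = depth, width = width)
  generate_phantom(straight_tube_spec(radius = radius, length = length,
                                      spacing = spacing, axis = axis,
                                      stenoses = st, noise_sd = noise_sd,
                                      seed = seed))
}

default_tree <- function(...) generate_phantom(posterior_circulation_spec(...))

# Independent oracle for the true score: numerical integration of the
# closed-form Gaussian-dip radius profile on a very fine grid.
oracle_tube_score <- function(base_radius, depth, width, length, position = 0.5) {
  s <- seq(0, length, length.out = 200001)
  r <- base_radius * (1 - depth * exp(-(s - position * length)^2 / (2 * width^2)))
  (1 - min(r) / mean(r)) * 100
}

# Quick small null/separable tabular cohorts for the prediction layer.
synthetic_table <- function(n, seed, kind = c("null", "separable")) {
  kind <- match.arg(kind)
  withr::with_seed(seed, {
    tab <- data.frame(sbp = rnorm(n, 130, 9), dbp = rnorm(n, 70, 6),
                      pulse = rnorm(n, 70, 5))
    tab$ci_label <- if (kind == "null") rbinom(n, 1, 0.5) else
      as.integer(tab$sbp > 130)
    tab
  })
}
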