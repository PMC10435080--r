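# Shared fixtures, built once per test run and cached.
.fx <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fx)) assign(name, force(expr), envir = .fx)
  get(name, envir = .fx)
}

fx_array <- function() fixture("array", build_array())
fx_grid_map <- function() fixture("grid_map", map_to_grid(fx_array()))
fx_disc <- function() fixture("disc", discretize_array(fx_array(), 10))

# a reduced whisker array (6 whiskers) for fast load-model tests
fx_mini_array <- function() fixture("mini_array", {
  tab <- expand.grid(base_x = c(0, 10, 20), base_z = c(-5, 5))
  tab$base_y <- 22
  tab$side <- "right"
  tab$length <- 30
  tab$azimuth <- 100
  tab$elevation <- 0
  tab$id <- seq_len(nrow(tab))
  build_array(table = tab, allow_nonstandard = TRUE)
})

# constant-coefficient table (CD = 1, CL = 0) for closed-form load checks
fx_unit_table <- function() fixture("unit_table",
  coeff_table(c(1, 1000), c(0, 90),
              matrix(1, 2, 2), matrix(0, 2, 2)))

# the desk-scale study: 81-case dataset and one holdout-fold fit; these are
# the expensive shared fixtures behind the end-to-end checks
fx_desk_dataset <- function() fixture("desk_dataset", {
  dp <- desk_protocol(seed = 1)
  build_dataset(dp$grid)
})

# recovery fit: trained on the complete reduced dataset
fx_desk_fit <- function() fixture("desk_fit", {
  dp <- desk_protocol(seed = 1)
  wvt_fit(fx_desk_dataset(), dp$config, dp$control)
})

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(abs(object - expected) / max(abs(expected), 1e-300), tol)
}
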