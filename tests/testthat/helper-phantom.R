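# Shared fixtures: all test data is generated in code.

# Small abdominal phantom for fast unit tests; acceptance-scale runs use the
# full default spec.
small_phantom <- function(seed = 1L, size = 160L, n_slices = 1L, noise = 0,
                          ...) {
  phantom_generate(phantom_spec(size = size, n_slices = n_slices,
                                noise_sigma_hu = noise, seed = seed, ...))
}

# Concentric circular phantom: muscle annulus with fat inside and out, no
# organs. `wall_radii` in px.
concentric_phantom <- function(size = 200L, body_r = 85, wall_radii = c(60, 70),
                               seed = 1L, ...) {
  phantom_generate(phantom_spec(
    size = size, n_slices = 1L, seed = seed,
    body_semi_px = c(body_r, body_r),
    wall_outer_frac = wall_radii[2] / body_r,
    wall_inner_frac = wall_radii[1] / body_r,
    lining_frac = wall_radii[1] / body_r - 0.08,
    visceral_fat_fraction = 1,
    include_psoas = FALSE, include_vertebra = FALSE, ...))
}

phantom_hu <- function(ph, slice = 1L) to_hu(ph$series$slices[[slice]])

mask_area_mm2 <- function(mask, spacing) sum(mask$grid) * prod(spacing)

pct_err <- function(measured, truth) 100 * abs(measured - truth) / truth

# Start the plugin server in a background R process; waits until the port
# accepts connections. Returns list(proc, port, capture_dir); callers kill
# the process when done.
start_plugin_server <- function(registry = NULL, capture = FALSE) {
  capture_dir <- if (capture) {
    d <- tempfile("capture"); dir.create(d); d
  }
  port <- httpuv::randomPort()
  proc <- callr::r_bg(function(port, cap, reg) {
    if (is.null(reg)) reg <- ctmorph::autoseg_registry()
    ctmorph::serve_plugins(reg, port = port, capture_dir = cap,
                           blocking = TRUE)
  }, args = list(port = port, cap = capture_dir, reg = registry))
  for (i in 1:100) {
    Sys.sleep(0.2)
    con <- try(suppressWarnings(
      socketConnection("127.0.0.1", port, timeout = 1)), silent = TRUE)
    if (!inherits(con, "try-error")) { close(con); break }
    if (!proc$is_alive()) stop("plugin server failed to start")
  }
  list(proc = proc, port = port, capture_dir = capture_dir)
}

plugin_url <- function(server, name) {
  sprintf("http://127.0.0.1:%d/%s", server$port, name)
}

rot90 <- function(m) t(m[nrow(m):1, , drop = FALSE])
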