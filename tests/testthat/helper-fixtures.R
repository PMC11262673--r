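# Shared fixtures, built once per test run (all generated in code).

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

phantom128 <- function() fixture("ph128", function() phantom_image(128))

sino128 <- function() {
  fixture("sino128", function() {
    radon_project(phantom128(), grid_angles(angle_grid(0, 360, 128)))
  })
}

phantom64 <- function() fixture("ph64", function() phantom_image(64))

sino64 <- function() {
  fixture("sino64", function() {
    radon_project(phantom64(), grid_angles(angle_grid(0, 360, 64)))
  })
}

micro_setup <- function() setup_preset("micro")

micro_consecutive <- function() {
  acq_order_consecutive(setup_grid(micro_setup()))
}
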