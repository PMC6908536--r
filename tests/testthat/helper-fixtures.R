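# Shared fixtures, built once per test run. Coarse grids (0.4 mm) keep the
# unit suite fast; the acceptance suite re-runs key checks at 0.2 mm.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- make()
  .fixtures[[name]]
}

iq_vox_coarse <- function() fixture("iq_vox", function() {
  ph <- build_iq_phantom()
  list(phantom = ph,
       vox = voxelize(ph, grid_for_phantom(ph, spacing = 0.4), supersample = 3))
})

derenzo_vox_slab <- function() fixture("derenzo_vox", function() {
  ph <- build_derenzo()
  list(phantom = ph,
       vox = voxelize(ph, grid_for_phantom(ph, spacing = 0.2, nz = 1)))
})

# a recon_image wrapped around a bare array on a unit grid
manual_image <- function(values, voxel = 1) {
  petbench:::.recon_image(values, voxel_grid(dim(values), voxel))
}
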