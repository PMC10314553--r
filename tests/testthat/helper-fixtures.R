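# shared fixtures built in code

# asymmetric registration phantom: tube with rounded (spherical) caps plus
# two off-axis marker spheres -- curved surfaces everywhere, so voxelization
# error decorrelates and all six degrees of freedom are observable
registration_markers <- function() {
  list(list(center = c(12, 0, 10), radius = 4),
       list(center = c(0, 13, -8), radius = 4),
       list(center = c(0, 0, 45), radius = 10),
       list(center = c(0, 0, -15), radius = 10))
}

# small mask on an identity-spacing grid for fast I/O and transform tests
small_box_mask <- function(spacing = 0.5, n = 20) {
  aff <- diag(4)
  aff[1:3, 1:3] <- diag(rep(spacing, 3))
  aff[1:3, 4] <- -spacing  # voxel (1,1,1) centre at origin
  voxel_mask(array(1L, c(n, n, n)), aff)
}

oriented_head_landmarks <- function() {
  landmark_set(rbind(PoR = c(-60, 0, 0), PoL = c(60, 0, 0),
                     OrR = c(-30, 70, 0), OrL = c(30, 70, 0)))
}

expect_rel_error <- function(measured, truth, tol) {
  expect_lt(abs(measured / truth - 1), tol)
}
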