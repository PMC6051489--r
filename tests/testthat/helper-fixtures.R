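# Shared fixtures, built lazily and cached for the whole test run.
.fix <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fix[[name]])) .fix[[name]] <- build()
  .fix[[name]]
}

phantom48 <- function() fixture("phantom48", function() make_phantom(48, 1, seed = 3))
phantom96 <- function() fixture("phantom96", function() make_phantom(96, 1, seed = 1))

# motion-free axial stack of the 96 phantom (registration fixtures)
stack96 <- function() fixture("stack96", function()
  sample_interleaved_stack(phantom96(), phantom96(), stack_spec("axial")))

study48_skew <- function() fixture("study48_skew", function()
  simulate_study(size = 48, seed = 1, motion = motion_spec("skew", theta_xyz = 1)))

# a small consistent SR problem: 16^3 random volume observed by 3 patches
sr_problem <- function() fixture("sr_problem", function() {
  set.seed(6)
  vol <- pvr_volume(array(runif(16^3, 0, 100), c(16, 16, 16)),
                    spacing = rep(1.25, 3), origin = -rep(7.5 * 1.25, 3))
  st <- pvr_volume(array(0, c(12, 12, 6)), spacing = c(1.25, 1.25, 2.5),
                   origin = c(-7, -7, -6))
  psf <- psf_model(c(1.25, 1.25), 2.5)
  pix <- as.matrix(expand.grid(0:11, 0:11))
  mk <- function(k, rot, tr) {
    p <- new_patch(1, k, pix, rep(0, nrow(pix)), rigid_transform(rot, tr))
    y <- simulate_patch(vol, p, st, psf)
    p$y <- as.numeric(y) + rnorm(length(y), 0, 3)
    p$p <- runif(length(y), 0.5, 1)
    p$p_hat <- 0.9
    p
  }
  patches <- list(mk(1, c(0, 0, 0), c(0, 0, 0)),
                  mk(2, c(2, -1, 3), c(0.5, 0, 0)),
                  mk(3, c(-2, 1, 0), c(0, 0.3, -0.2)))
  cache <- pvr:::sr_prepare(patches, list(st), vol, psf)
  list(vol = vol, st = st, psf = psf, patches = patches, cache = cache)
})

# random rigid transform helper
random_rigid <- function(rot_max = 20, trans_max = 10, center_max = 10) {
  rigid_transform(runif(3, -rot_max, rot_max), runif(3, -trans_max, trans_max),
                  runif(3, -center_max, center_max))
}
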