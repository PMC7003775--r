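# Shared fixtures, built in code and cached for the test run.
# Small grids keep unit tests fast; acceptance tests build their own cohorts
# at the sizes the criteria state.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(build())
  .fixtures[[name]]
}

small_spec <- function(seed = 1L, noise_sd = 0.02, het = 0.05, ...) {
  phantom_spec(grid_shape = c(24, 24, 6), voxel_spacing = c(1, 1, 3),
               lesion_radius_voxels = 4, noise_sd = noise_sd,
               heterogeneity_amp = het, seed = seed, ...)
}

# exact, noiseless, homogeneous phantom: every voxel carries its class's
# deterministic signature
clean_phantom <- function(seed = 1L, ...) {
  generate_phantom(small_spec(seed = seed, noise_sd = 0, het = 0, ...))
}

noisy_phantom <- function(seed = 1L) {
  fixture(paste0("noisy_", seed),
          function() generate_phantom(small_spec(seed = seed)))
}

# tiny training configuration: enough epochs to converge on separable
# signatures, small enough to keep the suite quick
tiny_cfg <- function(seed = 1L, ...) {
  ssae_config(max_epochs = 120, fine_tune_epochs = 80, seed = seed, ...)
}

# a small trained model + its training set on clean phantoms, shared across
# tests that only need "some reasonable trained model"
trained_clean_model <- function() {
  fixture("trained_clean", function() {
    phs <- lapply(1:2, clean_phantom)
    bounds <- compute_channel_bounds(lapply(phs, `[[`, "study"))
    ns <- lapply(phs, function(p) normalize_channels(p$study, bounds = bounds))
    hv <- lapply(seq_along(phs), function(i)
      harvest_signatures(ns[[i]], auto_seeds(phs[[i]]$truth, 2, seed = i)))
    ts <- sample_balanced(hv, 500, seed = 3)
    list(model = train_ssae(ts, tiny_cfg(7),
                            channel_order = ns[[1]]$channel_order),
         train_set = ts, phantoms = phs, studies = ns, bounds = bounds)
  })
}

# independent brute-force BFS oracle for seeded region growing: evaluates
# frontier voxels once, in increasing linear-index order, against the
# running-mean band — a plain-R mirror of the documented semantics
rg_oracle <- function(volume, seed_voxel, tol = 0.05, eps_abs = NULL) {
  shp <- dim(volume)
  if (is.null(eps_abs)) eps_abs <- tol * sd(as.vector(volume))
  lin <- function(v) (v[3] - 1) * shp[1] * shp[2] + (v[2] - 1) * shp[1] + v[1]
  unlin <- function(l) {
    l0 <- l - 1
    c(l0 %% shp[1], (l0 %/% shp[1]) %% shp[2], l0 %/% (shp[1] * shp[2])) + 1
  }
  neighbors <- function(v) {
    out <- list()
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      u <- v + c(dx, dy, dz)
      if (all(u >= 1) && all(u <= shp)) out[[length(out) + 1]] <- u
    }
    out
  }
  state <- integer(prod(shp)) # 0 unseen, 1 seen, 2 accepted
  s <- lin(seed_voxel)
  state[s] <- 2L
  total <- volume[s]; cnt <- 1L
  frontier <- sort(vapply(neighbors(seed_voxel), lin, numeric(1)))
  frontier <- frontier[state[frontier] == 0L]
  state[frontier] <- 1L
  while (length(frontier) > 0) {
    v <- frontier[1]
    frontier <- frontier[-1]
    mu <- total / cnt
    if (abs(volume[v] - mu) <= max(tol * abs(mu), eps_abs)) {
      state[v] <- 2L
      total <- total + volume[v]; cnt <- cnt + 1L
      nb <- vapply(neighbors(unlin(v)), lin, numeric(1))
      nb <- nb[state[nb] == 0L]
      state[nb] <- 1L
      frontier <- sort(c(frontier, nb))
    }
  }
  array(state == 2L, shp)
}

# exact pairwise-comparison AUC oracle (ties count one half)
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}
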