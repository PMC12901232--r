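# Shared fixtures, built lazily and cached for the whole test run.

.fix <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fix[[name]])) .fix[[name]] <- force(expr)
  .fix[[name]]
}

# small protocol: enough shots for self-gating, fast to reconstruct
small_protocol <- function() {
  protocol_spec(matrix = 32, n_shots = 260, n_segments = 12)
}

small_dataset <- function() cached("small_dataset",
  simulate_freerun(rr_base_ms = 800, hrv_ms = 0, variant_id = 0, seed = 1,
                   protocol = small_protocol()))

small_fit <- function() cached("small_fit", quiescence(small_dataset()))

small_fit_trigger <- function() cached("small_fit_trigger",
  quiescence(small_dataset(), beats = "trigger"))

# desk-scale dataset with high heart-rate variability (comparison tests)
desk_dataset_hrv <- function() cached("desk_dataset_hrv",
  simulate_freerun(rr_base_ms = 650, hrv_ms = 165, variant_id = 0, seed = 7))

# the desk-scale grid experiment (the expensive shared fixture)
desk_grid <- function() cached("desk_grid",
  grid_experiment(grid_configs("desk", seed_base = 100L)))

# static (non-beating) k-space at the desk-scale protocol: one volume
# sampled for every line
static_kspace <- function() cached("static_kspace", {
  spec <- protocol_spec()
  traj <- generate_phyllotaxis(spec)
  plan <- nufft_plan(traj)
  ph <- phantom_spec(matrix = spec$matrix, fov_mm = spec$fov_mm)
  pv <- render_phases(ph, make_volume_curve(0))
  y <- cardiosync:::nufft_forward_one(plan, pv$volumes[[1]])
  list(kspace = structure(list(samples = matrix(y, plan$n_read), traj = traj,
                               n_read = plan$n_read, plan = plan),
                          class = "kspace_set"),
       volume = pv$volumes[[1]], plan = plan, traj = traj, spec = spec)
})

# independent BFS flood-fill oracle for 26-connected same-phase labeling
bfs_label_oracle <- function(phase, valid) {
  d <- dim(phase)
  lab <- array(NA_integer_, d)
  nb <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  nxt <- 0L
  for (start in which(valid)) {
    if (!is.na(lab[start])) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      ijk <- arrayInd(v, d)
      for (r in seq_len(nrow(nb))) {
        p <- ijk + nb[r, ]
        if (any(p < 1) || any(p > d)) next
        w <- p[1] + d[1] * (p[2] - 1) + d[1] * d[2] * (p[3] - 1)
        if (valid[w] && is.na(lab[w]) && phase[w] == phase[v]) {
          lab[w] <- nxt
          queue <- c(queue, w)
        }
      }
    }
  }
  lab
}

# two labelings describe the same partition of the labeled voxels
same_partition <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (!identical(which(!is.na(a)), which(!is.na(b)))) return(FALSE)
  ta <- as.integer(factor(a[ok], levels = unique(a[ok])))
  tb <- as.integer(factor(b[ok], levels = unique(b[ok])))
  identical(ta, tb)
}
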