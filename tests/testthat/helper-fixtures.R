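# shared fixtures and independent oracles, built in code at test time

`%||%` <- function(a, b) if (is.null(a)) b else a

# small, fast configuration for unit tests (not the study conditions;
# those are sim_config() defaults, exercised in test-acceptance.R)
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(stack_shape = c(30L, 17L, 40L, 40L), cell_radius_um = 4,
         arrest_window_min = c(6, 12), n_vesicles = 15L),
    list(...))
  do.call(sim_config, args)
}

# a fully scripted timeline with exact event times (minutes)
scripted_timeline <- function(cell_id = 1L, arrest = 10, onset = 12.3,
                              max_exp = 21.5, flat = 30.5, leak = 34.4,
                              group = 1L) {
  structure(list(cell_id = cell_id, group = group, flattened_within_4h = TRUE,
                 t_arrest = arrest, t_onset = onset, t_max_expansion = max_exp,
                 t_flattened = flat, t_leakage = leak),
            class = "true_timeline")
}

# brute-force two-pass Pearson oracle (independent of pearson_frame_pair)
pearson_oracle <- function(a, b) {
  ma <- sum(a) / length(a)
  mb <- sum(b) / length(b)
  num <- sum((a - ma) * (b - mb))
  num / sqrt(sum((a - ma)^2) * sum((b - mb)^2))
}

# exhaustive-enumeration oracle for the exact two-sided rank-sum p-value
wilcoxon_oracle <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  picks <- utils::combn(n + m, n)
  us <- apply(picks, 2, function(ix) sum(r[ix]) - n * (n + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# rectangular-box image stack: constant-intensity slab in a dark volume
slab_stack <- function(n_t = 3L, n_z = 25L, n_y = 16L, n_x = 16L,
                       z_on = 11L, z_off = 21L, level = 100,
                       z_step_um = 0.6) {
  data <- array(0, c(n_t, 1L, n_z, n_y, n_x))
  data[, , z_on:z_off, , ] <- level
  image_stack(data, 2, z_step_um, 0.25, "cyto")
}

square_roi <- function(cell_id = 1L, x0 = 1, y0 = 1, x1 = 14, y1 = 14) {
  cell_roi(cell_id, cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1)))
}
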