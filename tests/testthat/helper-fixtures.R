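# Shared fixtures: everything is generated in code at test time.

# dissim_matrix from an explicit symmetric matrix of values
make_dm <- function(d, ids = sprintf("S%02d", seq_len(nrow(d))),
                    index_name = "test") {
  dimnames(d) <- list(ids, ids)
  structure(list(index_name = index_name, subject_ids = ids, d = d),
            class = "dissim_matrix")
}

# random symmetric dissimilarity matrix with zero diagonal
random_dm <- function(n, ids = sprintf("S%02d", seq_len(n))) {
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- runif(n * (n - 1) / 2)
  make_dm(d + t(d), ids)
}

# random valid correlation matrix (via a random Gram matrix)
random_corr <- function(R) {
  A <- matrix(rnorm(R * (R + 2)), R + 2, R)
  cov2cor(crossprod(A))
}

# small gaze trace on an n-frame grid
small_trace <- function(x, y, width = 200, height = 100, fps = 24) {
  gaze_trace(x, y, frame_width_px = width, frame_height_px = height, fps = fps)
}

# fast simulation settings for unit tests: full-size generation is exercised
# in the acceptance suite
quick_sim <- function(n_subjects, mode = "annak", seed = 1, ...) {
  sim_config(n_subjects = n_subjects, mode = mode, seed = seed,
             gaze = list(n_frames = 480), embed_dim = 48, ...)
}
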