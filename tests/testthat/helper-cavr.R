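# Shared fixture builders. Everything is generated in code; no stored data.

# a single canonical pose as a length-36 vector; `angle` rotates every
# segment about the x-axis by that many radians
toy_pose <- function(angle = 0) {
  q <- c(cos(angle / 2), sin(angle / 2), 0, 0)
  rep(q, 9)
}

# pose matrix whose frame i rotates by angles[i]
toy_frames <- function(angles) {
  do.call(rbind, lapply(angles, toy_pose))
}

toy_recording <- function(angles, frame_rate = 1, label = "a",
                          subject = "s1", id = "r1") {
  cav_recording(toy_frames(angles), frame_rate, label, subject, id)
}

# small random (but seeded) canonical recording
random_recording <- function(n_frames, frame_rate = 30, label = "a",
                             subject = "s1", id = "r1", seed = 1) {
  set.seed(seed)
  m <- matrix(stats::rnorm(n_frames * 36), n_frames, 36)
  cav_recording(m, frame_rate, label, subject, id)
}

# quick small synthetic dataset for pipeline tests
small_dataset <- function(n_activities = 3L, n_subjects = 4L,
                          variation_level = 0.2, frame_rate = 10,
                          seed = 11L) {
  generate_dataset(n_activities = n_activities, n_subjects = n_subjects,
                   variation_level = variation_level,
                   frame_rate = frame_rate, seed = seed)
}

# config scaled for 10 Hz fixtures
small_config <- function(...) {
  cav_config(base_len = 8L, n_init = 2L, seed = 5L, ...)
}
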