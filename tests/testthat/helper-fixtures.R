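# Shared small fixtures, built once per test run.

small_world <- function(seed = 3, ...) {
  fixture_world(L = 48, duration_s = 5, seed = seed, ...)
}

# a short fixture video plus reference frames, cached across tests
.fix_env <- new.env()

get_fix <- function() {
  if (is.null(.fix_env$video)) {
    .fix_env$world <- small_world()
    .fix_env$video <- generate_fixture_video(.fix_env$world)
    .fix_env$refs <- fixture_reference_frames(.fix_env$video, n = 6,
                                              seed = 1)
  }
  .fix_env
}
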