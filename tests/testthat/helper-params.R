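# shared parameter sets: the reference measured set (vs = 42) and the
# simulation set (vs = 40) used throughout the figures
table_params <- function() dynamics_params(vg = 30, vs = 42, fcat = 3.3, fres = 2.0)
fig_params <- function() dynamics_params(vg = 30, vs = 40, fcat = 3, fres = 1)

# random valid bounded-regime parameter sets (J < 0), reproducible
random_bounded_params <- function(n, seed = 1) {
  set.seed(seed)
  purrr::map(seq_len(n), function(i) {
    vg <- stats::runif(1, 10, 50)
    vs <- stats::runif(1, 10, 60)
    fcat <- stats::runif(1, 1, 5)
    # fres below the J = 0 line so the regime is bounded
    fres <- stats::runif(1, 0, 0.9 * vs * fcat / vg)
    dynamics_params(vg, vs, fcat, fres)
  })
}
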