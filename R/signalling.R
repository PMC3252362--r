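# Signalling model interface: each mechanism provides
#   * a fast compiled whole-run path (run_signalling), and
#   * init/bias hooks used by the pure-R reference loop (signalling_init,
#     signalling_bias), which evaluates one bias vector per step.

#' Null signalling model
#'
#' All biases are identically zero; cells differentiate independently and
#' the terminal types realise the random-labelling null.
#'
#' @return A signalling model object.
#' @export
no_signalling <- function() {
  structure(list(), class = c("no_signalling", "signalling_model"))
}

run_signalling <- function(signalling, positions, domain, params,
                           nsteps, snap, noise) {
  UseMethod("run_signalling")
}

signalling_init <- function(signalling, positions, domain, params) {
  UseMethod("signalling_init")
}

# returns list(bias = <per-cell vector>, state = <updated state>)
signalling_bias <- function(signalling, state, s, f, params) {
  UseMethod("signalling_bias")
}

#' @export
run_signalling.no_signalling <- function(signalling, positions, domain, params,
                                         nsteps, snap, noise) {
  simulate_juxtacrine_cpp(nrow(positions), integer(0), integer(0), numeric(0),
                          0, 1, 1, params$chi, params$nu, params$delta,
                          params$dt, nsteps, snap, noise)
}

#' @export
signalling_init.no_signalling <- function(signalling, positions, domain, params) {
  list()
}

#' @export
signalling_bias.no_signalling <- function(signalling, state, s, f, params) {
  list(bias = rep(0, length(f)), state = state)
}
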